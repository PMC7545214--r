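# Pigment class map: chemical-component code -> pigment class.
# Editable: component codes vary across depositions.  These defaults are
# the standard PDB chemical-component IDs used in fucoxanthin-chlorophyll
# protein (FCP) depositions.
#   CLA  chlorophyll a
#   KC1  chlorophyll c1
#   KC2  chlorophyll c2
#   A86  fucoxanthin
#   DD6  diadinoxanthin
#   BCR  beta-carotene
# strict: true makes a chlorophyll residue without an Mg atom a hard
# error instead of a skipped warning.
classes:
  CLA: chl_a
  KC1: chl_c
  KC2: chl_c
  A86: fucoxanthin
  DD6: diadinoxanthin
  BCR: beta_carotene
strict: false
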