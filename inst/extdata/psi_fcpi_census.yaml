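# Published pigment census of the diatom PSI-FCPI supercomplex (ligand
# table of the deposition report): per-class totals, the core-bound
# chlorophyll-a count, and the number of FCPI antenna subunits.  Input
# for the pure-arithmetic census mode (censusFromCounts), no coordinate
# file needed.
counts:
  chl_a: 326
  chl_c: 34
  fucoxanthin: 102
  diadinoxanthin: 35
  beta_carotene: 18
chl_a_core: 94
n_antennas: 24
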