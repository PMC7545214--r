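# PARTIAL chain annotation config for the deposited diatom PSI-FCPI
# supercomplex (PDB 6LY5).  Only the chain assignments fixed by the
# publication itself are entered: chain h is the transmembrane core
# subunit PsaR and chain g the extrinsic core subunit PsaS.  The
# remaining core chains (PsaA/B/C/D/E/F/I/J/L/M) and the antenna
# numbering FCPI-1..FCPI-24 follow the publication's labelling, not the
# deposition's chain ids, and must be completed against the deposited
# mmCIF before running the pipeline on it.  Entries may be a bare
# subunit label ("PsaA", "FCPI-8"); role, pathway-code letter and
# antenna number are inferred from the label.
chains:
  h: PsaR
  g: PsaS
  # A: PsaA          <- complete from the deposition
  # B: PsaB
  # ...
  # <chain>: FCPI-1
  # ...
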