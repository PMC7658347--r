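# Segment definitions for the synthetic two-spoke assembly produced by
# makeToyPair(toySpokeParams()) with the default geometry
# (3 helices x 20 residues per block).
atom_subset: CA_ONLY
segments:
  Spc97-GRIP1:
    - {chain: A, first: 1, last: 60}
  Spc97-GRIP2:
    - {chain: A, first: 61, last: 120}
  Spc97-gamma:
    - {chain: C, first: 1, last: 60}
  Spc98-GRIP1:
    - {chain: B, first: 1, last: 60}
  Spc98-GRIP2:
    - {chain: B, first: 61, last: 120}
  Spc98-gamma:
    - {chain: D, first: 1, last: 60}
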