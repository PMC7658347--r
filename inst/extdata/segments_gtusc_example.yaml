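# EXAMPLE segment definitions for a deposited gamma-TuSC model
# (chains A = Spc97, B = Spc98, C/D = gamma-tubulins, as in PDB-7ANZ).
#
# IMPORTANT: the GRIP1/GRIP2 domain boundaries below are illustrative
# placeholders, NOT published values -- domain boundaries are not printed
# in the primary literature and depend on the deposition. Edit them to
# match your model before running a comparison.
atom_subset: CA_ONLY
segments:
  Spc97-GRIP1:
    - {chain: A, first: 92, last: 480}    # placeholder boundary: verify
  Spc97-GRIP2:
    - {chain: A, first: 481, last: 871}   # placeholder boundary: verify
  Spc97-gamma:
    - {chain: C, first: 1, last: 472}
  Spc98-GRIP1:
    - {chain: B, first: 150, last: 570}   # placeholder boundary: verify
  Spc98-GRIP2:
    - {chain: B, first: 571, last: 1069}  # placeholder boundary: verify
  Spc98-gamma:
    - {chain: D, first: 1, last: 472}
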