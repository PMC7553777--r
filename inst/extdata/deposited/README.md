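# Deposited experimental structures (user-supplied)

The real-structure reproduction checks in `tests/testthat/test-acceptance.R`
and the corresponding worked examples read PDB files from this directory.
They are not distributed with the package; download them from the PDB /
Zenodo and curate the annotation configs (domain, repeat and helix residue
ranges are not part of the deposited files and must be assigned by
inspection):

- `6WU1.pdb`  - LaINDY, outward-facing apo state (cryo-EM)
- `5UL9.pdb`  - VcINDY, inward-facing Na+/citrate state (X-ray)
- `6WU3.pdb`  - VcINDY-Na+ in amphipol (cryo-EM)
- `6WW5.pdb`  - VcINDY-Na+ with Fab in nanodisc (cryo-EM)
- `md_co_s.pdb`, `md_ci_s.pdb` - representative simulated outward/inward
  substrate-bound endpoint structures (Zenodo record 3965996)
- `laindy_vcindy_annotation.yaml` - protomers "LaINDY" and "VcINDY" with
  equal-length scaffold/transport residue-equivalence ranges
- `vcindy_pair_annotation.yaml`  - two protomers giving matched backbone
  ranges for the 6WU3/6WW5 comparison
- `md_endpoint_annotation.yaml`  - one protomer with scaffold/transport
  domains plus helices `HPin_a`, `H4c`, `HPout_a`, `H9c`

See `read_annotation()` for the YAML schema.
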