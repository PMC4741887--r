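# Packaged fixtures

- `mir375.fa` — the canonical mature hsa-miR-375 sequence (miRBase
  accession MIMAT0000728). Its seed reverse-complement yields the
  7mer-A1 heptamer `GAACAAA`, the site the pipeline's scanner is built
  around.
- `klf5_utr_synthetic.fa` — a SYNTHETIC stand-in 3'-UTR, 600 nt of
  uniform random sequence with the miR-375 7mer-A1 site written in at
  nt 482–488 (1-based inclusive) and no other ≥7mer miR-375 site. It is
  not the real KLF5 transcript UTR; it exists so the worked coordinate
  example is runnable offline.
- `regulator_targets_klf5_synthetic.tsv` — a SYNTHETIC 50-gene
  regulator→target list (containing KLF5 and BIRC5 among plausible KLF5
  pathway members) standing in for a pathway-analysis export; used to
  exercise the downstream-intersection step.
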