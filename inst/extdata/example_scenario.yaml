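# Example scenario override: smaller families, lognormal spacers.
n_codons: 273
spacer_law:
  dist: lognormal
  meanlog: 9.2103   # median ~10 kb
  sdlog: 0.5
bootstrap_reps: 50
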