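# Desk-scale demo configuration for run_pipeline() / `triophase run`.
# Completes in well under a minute on one CPU.
global:
  seed: 1
  outdir: triophase_demo
  log_level: info
simulate:
  genome_length: 100000
  d_between: 0.03
  long_read_mean_len: 8000
  long_read_min_len: 500
  long_read_coverage: 10
  short_read_coverage: 20
bin:
  k: 21
  min_count: 2
pha:
  d_within: 0.005
  replace: both
pdist:
  window_size: 10000
  min_sites: 500
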