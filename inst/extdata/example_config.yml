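# Example run configuration for run_pipeline() / read_run_config().
# Every key under `sim` maps onto a sim_config() argument.
sim:
  n_lines: 97
  n_snps: 2000
  n_qtl: 5
  var_g: 1.0
  var_gxe: 0.5
  var_e: 2.0
  seed: 1
cv:
  schemes: [within_2fold, across_LOEO]
  reps: 50          # or "paper" for the 1000/2000/3000/1000 preset
  n_boot: 1000
  seed: 1
hyper:
  rf:
    ntree: 200
  bayesb:
    n_iter: 3000
    burnin: 1000
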