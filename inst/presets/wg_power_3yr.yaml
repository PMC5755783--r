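# Weibull-gamma power analysis, 3-year average follow-up.
# Time in years, cost in $k, WTP in $k per life-year.
model: wg
design_prior:
  alpha0: {fixed: 0.75}
  lambda0: {fixed: 0.9}
  nu0: {fixed: 1.2}
  beta0: {fixed: 50.0}
  gamma0: {fixed: 75.0}
  alpha1: {fixed: 0.5}
  lambda1: {fixed: 1.5}
  nu1: {fixed: 3.0}
  beta1: {fixed: 100.0}
  gamma1: {fixed: 60.0}
censoring:
  kind: uniform_window
  window_lo: 2.5
  window_hi: 3.5
grids:
  wtp: [100.0, 150.0, 200.0, 250.0, 300.0, 350.0]
  "n_total": [100, 200, 300, 400, 500]
design:
  B: 300
  success_prob: 0.95
  target: 0.8
mcmc:
  chains: 3
  burn_in: 2000
  keep: 10000
seed: 20180105
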