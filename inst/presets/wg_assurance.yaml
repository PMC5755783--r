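# Weibull-gamma assurance analysis, 3-year average follow-up:
# design priors are normal around the planning values, truncated at zero
# by resampling, so r(n) is the unconditional (expected) power.
model: wg
design_prior:
  alpha0: {normal: [0.75, 0.1]}
  lambda0: {normal: [0.9, 0.1]}
  nu0: {normal: [1.2, 0.15]}
  beta0: {normal: [50.0, 10.0]}
  gamma0: {normal: [75.0, 15.0]}
  alpha1: {normal: [0.5, 0.05]}
  lambda1: {normal: [1.5, 0.2]}
  nu1: {normal: [3.0, 0.2]}
  beta1: {normal: [100.0, 18.0]}
  gamma1: {normal: [60.0, 15.0]}
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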