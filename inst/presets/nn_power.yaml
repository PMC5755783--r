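# Normal-normal power analysis. Time in months, cost in $k; study-end
# censoring normal with mean 36 months (3 years) and sd 2.4.
model: nn
design_prior:
  mu0: {fixed: 25.0}
  tauT0sq: {fixed: 72.25}    # 8.5^2
  theta1: {fixed: 103.5}
  theta2: {fixed: 1.06}
  tauC0sq: {fixed: 817.96}   # 28.6^2
  mu1: {fixed: 33.5}
  tauT1sq: {fixed: 72.25}
  theta3: {fixed: 539.9}
  theta4: {fixed: 4.78}
  tauC1sq: {fixed: 8649.0}   # 93.0^2
censoring:
  kind: normal_window
  mean: 36.0
  sd: 2.4
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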