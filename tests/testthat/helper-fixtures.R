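# Shared fixtures: the fixed design values of the two worked examples and
# short MCMC settings used throughout the suite.

table_wg <- function() wg_design_values()
table_nn <- function() nn_design_values()

quick_mcmc <- function(chains = 1L, burn_in = 300L, keep = 1000L, seed = NULL)
  mcmc_settings(chains = chains, burn_in = burn_in, keep = keep, seed = seed)

window_3yr <- function() censoring_spec("uniform_window",
                                        window_lo = 2.5, window_hi = 3.5)
window_4yr <- function() censoring_spec("uniform_window",
                                        window_lo = 3.5, window_hi = 4.5)

# uniform window producing ~30% overall censoring under the WG fixture
window_heavy <- function() censoring_spec("uniform_window",
                                          window_lo = 1, window_hi = 2)
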