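# Shared fixture builders: small, fast simulations with known truth.

ctrl_mono_truth <- function(noise_sd_fF = 0, seed = NULL) {
  cm_truth(jump_fF = 531, decay_model = "mono", tau_s = 10.2,
           noise_sd_fF = noise_sd_fF, seed = seed)
}

ctrl_bi_truth <- function(noise_sd_fF = 0, seed = NULL) {
  cm_truth(jump_fF = 1565, decay_model = "bi", tau1_s = 1.6, tau2_s = 15.5,
           weight1 = 0.31, noise_sd_fF = noise_sd_fF, seed = seed)
}

# A flat three-channel spot trace (no event) at given noise.
flat_spot_trace <- function(noise_sd = 0, seed = NULL) {
  simulate_spot_trace(spot_truth("no_close", noise_sd = noise_sd, seed = seed))
}

# Brute-force LS slope, written independently of the package internals.
brute_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}
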