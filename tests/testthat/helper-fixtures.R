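# Shared fixtures, all built in code.

# Constant (step) input from t = 0.
step_cp <- function(value = 100, tmax = 60, by = 0.5) {
  tt <- seq(0, tmax, by = by)
  sampled_curve(tt, rep(value, length(tt)), role = "plasma_free")
}

# Default bolus input on the canonical grid.
bolus_cp <- function(params = default_aif_params()) {
  make_aif(params, pbif_grid())
}

# The 27-point ground-truth grid the fit and Patlak are validated over.
truth_grid <- function() {
  expand.grid(K1 = c(0.02, 0.05, 0.1),
              k2 = c(0.05, 0.1, 0.2),
              k3 = c(0.02, 0.05, 0.1),
              KEEP.OUT.ATTRS = FALSE)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
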