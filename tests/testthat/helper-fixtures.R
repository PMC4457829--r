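# Shared fixtures: small rate sets and grids used across test files.

wt_rates <- function() pgb_rates("WT")

# coarse grid keeps ODE solves fast in tests
quick_grid <- function(t_min = 1e-8, t_max = 1, ppd = 20) {
  log_time_grid(t_min, t_max, ppd)
}

# random full rate set with magnitudes spanning the scheme's range
random_rates <- function() {
  v <- 10^stats::runif(17, 2, 8)
  structure(as.list(stats::setNames(v, rate_parameter_names())),
            class = "rate_constants")
}

# matrix-exponential propagation oracle, independent of the ODE route
expm_propagate <- function(A, y0, times) {
  t(vapply(times, function(t) as.numeric(Matrix::expm(A * t) %*% y0),
           numeric(8)))
}
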