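test_that("fit_spec validates constraint structure", {
  tr <- simulate_trace(wt_rates(), experiment_conditions(),
                       times = quick_grid())
  expect_error(fit_spec(wt_rates(), list(tr), list()), "same length")
  expect_error(
    fit_spec(wt_rates(), tr, experiment_conditions(),
             free = c("k3", "k2"), tie = c(k2 = "k3")),
    "both free and tied")
  expect_error(
    fit_spec(wt_rates(), tr, experiment_conditions(),
             tie = c(k2 = "k3", k3 = "k_3")),
    "acyclic")
  expect_error(
    fit_spec(rate_constants(k3 = 1e4), tr, experiment_conditions(),
             free = c("k3", "kout")),
    "positive initial values")
})

test_that("noiseless fit initialized at truth is a fixed point", {
  r <- wt_rates()
  conds <- list(experiment_conditions(co_atm = 1.0),
                experiment_conditions(co_atm = 0.1))
  traces <- lapply(conds, function(cc)
    simulate_trace(r, cc, times = quick_grid(ppd = 15)))
  spec <- fit_spec(r, traces, conds, free = c("kin_r", "kin_t", "kout"))
  fit <- suppressWarnings(global_fit(spec, maxiter = 50))
  expect_lt(fit$rss, 1e-12)
  for (p in spec$free) {
    expect_equal(fit$rates[[p]], r[[p]], tolerance = 1e-4)
  }
})

test_that("a x2-off kin_r is recovered from noiseless two-pressure traces", {
  r <- wt_rates()
  conds <- list(experiment_conditions(co_atm = 1.0),
                experiment_conditions(co_atm = 0.1))
  traces <- lapply(conds, function(cc)
    simulate_trace(r, cc, times = quick_grid(ppd = 15)))
  init <- update_rates(r, kin_r = 2 * r$kin_r)
  spec <- fit_spec(init, traces, conds, free = c("kin_r", "kin_t", "kout"))
  fit <- suppressWarnings(global_fit(spec))
  expect_true(fit$converged)
  expect_lt(abs(fit$rates$kin_r - r$kin_r) / r$kin_r, 0.05)
})

test_that("tied parameters are honoured bit-exactly", {
  r <- wt_rates()
  cond <- experiment_conditions(co_atm = 1.0)
  tr <- simulate_trace(r, cond, times = quick_grid(ppd = 10))
  init <- update_rates(r, k3 = 1.3 * r$k3)
  spec <- fit_spec(init, tr, cond, free = c("k3", "k_3"),
                   tie = c(k2 = "k3", k_2 = "k_3"))
  fit <- suppressWarnings(global_fit(spec, maxiter = 20))
  expect_identical(fit$rates$k2, fit$rates$k3)
  expect_identical(fit$rates$k_2, fit$rates$k_3)
})

test_that("derived dissociation rates track kout and kg during the fit", {
  r <- wt_rates()
  cond <- experiment_conditions(co_atm = 1.0)
  tr <- simulate_trace(r, cond, times = quick_grid(ppd = 10))
  koff_r <- r$kdiss_r * r$kout / (r$kout + r$kg_r)
  spec <- fit_spec(r, tr, cond, free = c("kout", "kg_r"),
                   derive = list(koff_r = koff_r))
  fit <- suppressWarnings(global_fit(spec, maxiter = 20))
  expect_equal(fit$rates$kdiss_r,
               koff_r * (fit$rates$kout + fit$rates$kg_r) / fit$rates$kout,
               tolerance = 1e-12)
})

test_that("freeing a parameter never increases the optimal residual", {
  r <- wt_rates()
  cond <- experiment_conditions(co_atm = 1.0)
  set.seed(3)
  tr0 <- simulate_trace(r, cond, times = quick_grid(ppd = 10))
  tr <- kinetic_trace(tr0$times,
                      pmin(pmax(tr0$signal +
                                  rnorm(length(tr0$times), 0, 0.005),
                                -0.05), 1.05))
  init <- update_rates(r, kin_r = 1.5 * r$kin_r)
  fit1 <- suppressWarnings(global_fit(
    fit_spec(init, tr, cond, free = "kin_r")))
  fit2 <- suppressWarnings(global_fit(
    fit_spec(init, tr, cond, free = c("kin_r", "kout"))))
  expect_lte(fit2$rss, fit1$rss + 1e-12)
})
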