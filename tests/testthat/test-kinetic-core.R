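test_that("rate constants validate their invariants", {
  expect_error(rate_constants(k1 = -1), "non-negative")
  expect_error(rate_constants(kout = Inf), "finite")
  expect_error(update_rates(wt_rates(), nope = 1), "unknown rate")
  r <- update_rates(wt_rates(), kout = 2e8)
  expect_equal(r$kout, 2e8)
  expect_equal(r$k1, wt_rates()$k1)
})

test_that("all-zero rates give the zero generator matrix", {
  A <- build_rate_matrix(rate_constants(), co_molar = 1e-3)
  expect_equal(A, matrix(0, 8, 8, dimnames = list(species_names(),
                                                  species_names())))
})

test_that("generator matrix conserves mass and has non-negative fluxes", {
  set.seed(42)
  for (i in 1:10) {
    A <- build_rate_matrix(random_rates(), co_molar = 1e-3)
    expect_lt(max(abs(colSums(A))), 1e-14 * max(abs(A)))
    off <- A - diag(diag(A))
    expect_true(all(off >= 0))
  }
})

test_that("unliganded two-state block reaches the k3/k_3 equilibrium", {
  r <- rate_constants(k3 = 6e4, k_3 = 2e4)
  A <- build_rate_matrix(r, co_molar = 0)
  blk <- A[c("R_free", "T_free"), c("R_free", "T_free")]
  ev <- eigen(blk)
  stat <- ev$vectors[, which.min(abs(ev$values))]  # rows: R_free, T_free
  expect_equal(stat[2] / stat[1], 3.0, tolerance = 1e-12)
})

test_that("solvent entry fluxes are pseudo-first-order in CO and vanish in scavenger mode", {
  r <- wt_rates()
  A1 <- build_rate_matrix(r, co_molar = 1e-3)
  A10 <- build_rate_matrix(r, co_molar = 1e-2)
  expect_equal(A1["R_dock1", "R_free"], r$kin_r * 1e-3)
  expect_equal(A1["T_dock1", "T_free"], r$kin_t * 1e-3)
  expect_equal(A10["R_dock1", "R_free"], 10 * A1["R_dock1", "R_free"])
  expect_equal(A10["T_dock1", "T_free"], 10 * A1["T_dock1", "T_free"])
  As <- build_rate_matrix(r, co_molar = 1e-3, scavenger_mode = TRUE)
  expect_identical(As["R_dock1", "R_free"], 0)
  expect_identical(As["T_dock1", "T_free"], 0)
  expect_error(build_rate_matrix(r, co_molar = -1), "co_molar")
})

test_that("isolated two-state pairs satisfy detailed balance", {
  # stationary ratio of each isolated pair equals forward/backward rates
  pairs <- list(
    list(rate_constants(k1 = 3e5, k_1 = 1e5), c("R_CO", "T_CO")),
    list(rate_constants(kc = 2e7, k_c = 5e6), c("R_dock1", "R_dock2")),
    list(rate_constants(kd2 = 4e7, k_d2 = 1e7), c("T_dock1", "T_dock2")))
  fwd <- c(3, 4, 4)
  for (i in seq_along(pairs)) {
    A <- build_rate_matrix(pairs[[i]][[1]], co_molar = 0)
    blk <- A[pairs[[i]][[2]], pairs[[i]][[2]]]
    ev <- eigen(blk)
    stat <- ev$vectors[, which.min(abs(ev$values))]
    expect_equal(stat[2] / stat[1], fwd[i], ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("photolysis initial state splits the bound equilibrium", {
  # K1 = 0.3, full yield
  r <- rate_constants(k1 = 0.3e5, k_1 = 1e5)
  y <- photolysis_initial_state(r, experiment_conditions())
  expect_equal(y[["R_dock1"]], 1 / 1.3, tolerance = 1e-12)
  expect_equal(y[["T_dock1"]], 0.3 / 1.3, tolerance = 1e-12)
  expect_equal(sum(y), 1, tolerance = 1e-12)
  # single-conformation limit
  y1 <- photolysis_initial_state(rate_constants(), experiment_conditions())
  expect_equal(y1[["R_dock1"]], 1)
  expect_equal(sum(abs(y1[-3])), 0)
  # no photolysis
  y0 <- photolysis_initial_state(
    r, experiment_conditions(photolysis_yield = 0))
  expect_equal(y0[["R_CO"]] + y0[["T_CO"]], 1, tolerance = 1e-12)
  expect_equal(sum(y0[c("R_dock1", "T_dock1")]), 0)
  # partial yield
  yh <- photolysis_initial_state(
    r, experiment_conditions(photolysis_yield = 0.4))
  expect_equal(yh[["R_dock1"]] + yh[["T_dock1"]], 0.4, tolerance = 1e-12)
  expect_error(
    photolysis_initial_state(rate_constants(k1 = 1e5),
                             experiment_conditions()),
    "degenerate")
})

test_that("frozen system keeps N(t) = 1", {
  tr <- simulate_trace(rate_constants(), experiment_conditions(),
                       times = quick_grid())
  expect_equal(tr$signal, rep(1, length(tr$times)))
})

test_that("long-time rebound fraction follows geminate branching", {
  # only geminate rebinding vs escape from R_dock1, no re-entry
  r <- rate_constants(kg_r = 5e7, kout = 1.5e8)
  tr <- simulate_trace(r, experiment_conditions(co_atm = 0),
                       times = quick_grid(1e-9, 1e-5))
  rebound <- 1 - tr$signal[length(tr$signal)]
  expect_equal(rebound, 5e7 / (5e7 + 1.5e8), tolerance = 1e-7)
})

test_that("ODE propagation matches the matrix-exponential oracle", {
  set.seed(7)
  times <- 10^seq(-8, 0, length.out = 17)
  for (i in 1:5) {
    r <- random_rates()
    A <- build_rate_matrix(r, co_molar = 1e-3)
    y0 <- photolysis_initial_state(r, experiment_conditions())
    ode <- propagate_states(A, y0, times)
    ref <- expm_propagate(A, y0, times)
    expect_lt(max(abs(ode - ref)) / max(abs(ref)), 1e-6)
  }
})

test_that("population sum is conserved along WT trajectories", {
  for (atm in c(1.0, 0.1)) {
    tr <- simulate_trace(wt_rates(), experiment_conditions(co_atm = atm),
                         times = quick_grid(ppd = 40))
    expect_lt(max(abs(rowSums(tr$species) - 1)), 1e-9)
  }
})

test_that("N(t) is non-increasing without thermal dissociation", {
  r <- update_rates(wt_rates(), kdiss_r = 0, kdiss_t = 0)
  tr <- simulate_trace(r, experiment_conditions(co_atm = 1),
                       times = quick_grid(ppd = 40))
  expect_true(all(diff(tr$signal) <= 1e-10))
})

test_that("kinetic_trace enforces its invariants", {
  expect_error(kinetic_trace(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(kinetic_trace(c(1, 2), c(0.5, 2)), "within")
  expect_silent(kinetic_trace(c(1, 2), c(1.04, -0.04)))
})
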