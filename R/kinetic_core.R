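#' Species names of the eight-state network
#'
#' Ordering used by all matrices and state vectors: the CO-bound r and t
#' conformers, the primary-docked pairs, the secondary-docked pairs, and
#' the unliganded proteins with CO in the solvent.
#'
#' @return Character vector of length 8.
#' @export
species_names <- function() {
  c("R_CO", "T_CO", "R_dock1", "T_dock1",
    "R_dock2", "T_dock2", "R_free", "T_free")
}

#' First-order generator matrix of the CO binding scheme
#'
#' Assembles the 8x8 rate matrix `A` such that `dx/dt = A x` for the state
#' vector of species populations, under the pseudo-first-order assumption
#' that dissolved CO is in excess (entry fluxes are `kin_* * co_molar`).
#' Every column sums to zero, so total protein is conserved by
#' construction.
#'
#' @param rates a [rate_constants] object.
#' @param co_molar dissolved CO concentration, M.
#' @param scavenger_mode if `TRUE` the bimolecular entry fluxes are zeroed
#'   (free CO is scavenged and cannot rebind).
#' @return An 8x8 matrix with dimnames [species_names()].
#' @examples
#' A <- build_rate_matrix(pgb_rates("WT"), co_molar = 1e-3)
#' colSums(A)  # all zero
#' @export
build_rate_matrix <- function(rates, co_molar, scavenger_mode = FALSE) {
  validate_rate_constants(rates)
  if (!is.numeric(co_molar) || length(co_molar) != 1L ||
      !is.finite(co_molar) || co_molar < 0) {
    stop("co_molar must be a single finite non-negative number",
         call. = FALSE)
  }
  sp <- species_names()
  A <- matrix(0, 8, 8, dimnames = list(sp, sp))
  add <- function(from, to, k) {
    A[to, from] <<- A[to, from] + k
    A[from, from] <<- A[from, from] - k
  }
  r <- rates
  # conformational interconversion (r -> t forward)
  add("R_CO", "T_CO", r$k1);        add("T_CO", "R_CO", r$k_1)
  add("R_dock1", "T_dock1", r$k2);  add("T_dock1", "R_dock1", r$k_2)
  add("R_free", "T_free", r$k3);    add("T_free", "R_free", r$k_3)
  # geminate bond formation / thermal dissociation
  add("R_dock1", "R_CO", r$kg_r);   add("R_CO", "R_dock1", r$kdiss_r)
  add("T_dock1", "T_CO", r$kg_t);   add("T_CO", "T_dock1", r$kdiss_t)
  # primary <-> secondary docking-site migration
  add("R_dock1", "R_dock2", r$kc);  add("R_dock2", "R_dock1", r$k_c)
  add("T_dock1", "T_dock2", r$kd2); add("T_dock2", "T_dock1", r$k_d2)
  # solvent exchange (entry is pseudo-first-order in CO)
  kin_r_eff <- if (scavenger_mode) 0 else r$kin_r * co_molar
  kin_t_eff <- if (scavenger_mode) 0 else r$kin_t * co_molar
  add("R_dock1", "R_free", r$kout); add("R_free", "R_dock1", kin_r_eff)
  add("T_dock1", "T_free", r$kout); add("T_free", "T_dock1", kin_t_eff)
  A
}

#' State vector immediately after the laser flash
#'
#' Before the flash the protein is fully CO-bound and the two bound
#' conformers are at their equilibrium ratio `R_CO : T_CO = 1 : k1/k_1`.
#' The flash photolyses a fraction `photolysis_yield` of each bound
#' conformer, depositing the ligand in the corresponding primary docking
#' site; secondary sites and the solvent-free states start empty.
#'
#' @param rates a [rate_constants] object; `k_1` must be positive whenever
#'   `k1` is, otherwise the bound equilibrium is undefined.
#' @param conditions an [experiment_conditions] object.
#' @return Named numeric vector of length 8 summing to 1.
#' @examples
#' photolysis_initial_state(pgb_rates("WT"), experiment_conditions())
#' @export
photolysis_initial_state <- function(rates, conditions) {
  validate_rate_constants(rates)
  stopifnot(inherits(conditions, "experiment_conditions"))
  if (rates$k1 > 0 && rates$k_1 == 0) {
    stop("degenerate bound equilibrium: k1 > 0 with k_1 = 0", call. = FALSE)
  }
  K1 <- if (rates$k1 == 0) 0 else rates$k1 / rates$k_1
  fR <- 1 / (1 + K1)
  fT <- K1 / (1 + K1)
  y <- stats::setNames(numeric(8), species_names())
  yield <- conditions$photolysis_yield
  y["R_CO"] <- fR * (1 - yield)
  y["T_CO"] <- fT * (1 - yield)
  y["R_dock1"] <- fR * yield
  y["T_dock1"] <- fT * yield
  y
}

#' Kinetic trace container
#'
#' @param times time points in seconds, strictly increasing, first >= 0.
#' @param signal dimensionless normalized signal (unliganded fraction for
#'   photolysis traces, bound fraction for dissociation traces). Must lie
#'   in \[-0.05, 1.05\] (tolerance band for noisy data).
#' @param noise_sigma optional standard deviation of additive noise.
#' @param species optional matrix (length(times) x 8) of species
#'   populations.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(times, signal, noise_sigma = NULL,
                          species = NULL) {
  times <- as.numeric(times); signal <- as.numeric(signal)
  if (length(times) != length(signal)) {
    stop("times and signal lengths differ", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("times must be finite and strictly increasing", call. = FALSE)
  }
  if (times[1] < 0) stop("times must be non-negative", call. = FALSE)
  if (any(!is.finite(signal)) ||
      any(signal < -0.05 - 1e-12) || any(signal > 1.05 + 1e-12)) {
    stop("signal must be finite and within [-0.05, 1.05]", call. = FALSE)
  }
  structure(list(times = times, signal = signal,
                 noise_sigma = noise_sigma, species = species),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace: %d points, t = [%.3g, %.3g] s, signal [%.3g, %.3g]\n",
              length(x$times), min(x$times), max(x$times),
              min(x$signal), max(x$signal)))
  invisible(x)
}

#' Default logarithmic time grid
#'
#' @param t_min,t_max grid limits in seconds.
#' @param points_per_decade grid density.
#' @return Strictly increasing numeric vector.
#' @export
log_time_grid <- function(t_min = 1e-8, t_max = 1,
                          points_per_decade = 200) {
  n <- round(log10(t_max / t_min) * points_per_decade) + 1
  10^seq(log10(t_min), log10(t_max), length.out = n)
}

# Propagate a state vector through the constant-coefficient network with a
# stiff implicit integrator. Returns a matrix (length(times) x 8). The
# Jacobian is the generator matrix itself, supplied analytically.
propagate_states <- function(A, y0, times, rtol = 1e-8, atol = 1e-12) {
  stopifnot(length(y0) == 8, all(diff(times) > 0), times[1] >= 0)
  t_in <- if (times[1] > 0) c(0, times) else times
  derivs <- function(t, y, parms) list(parms %*% y)
  jac <- function(t, y, parms) parms
  out <- tryCatch(
    deSolve::ode(y = y0, times = t_in, func = derivs, parms = A,
                 jacfunc = jac, jactype = "fullusr", method = "lsoda",
                 rtol = rtol, atol = atol),
    warning = function(w) {
      stop("stiff integration failed: ", conditionMessage(w), call. = FALSE)
    })
  if (nrow(out) < length(t_in)) {
    stop(sprintf("stiff integration stopped at t = %.3g s", out[nrow(out), 1]),
         call. = FALSE)
  }
  y <- out[, -1, drop = FALSE]
  if (times[1] > 0) y <- y[-1, , drop = FALSE]
  colnames(y) <- species_names()
  y
}

#' Simulate a flash-photolysis rebinding trace
#'
#' Propagates the eight-state network from the post-flash state through a
#' stiff implicit ODE integrator and returns the unliganded fraction
#' `N(t) = 1 - (R_CO + T_CO)`, together with all eight species time
#' courses (the reaction intermediates). At `t = 0`, `N` equals the
#' photolysis yield.
#'
#' @param rates a [rate_constants] object.
#' @param conditions an [experiment_conditions] object.
#' @param times output time grid (strictly increasing, first >= 0);
#'   defaults to [log_time_grid()].
#' @param rtol,atol integrator tolerances.
#' @return A [kinetic_trace] whose `species` field holds the populations.
#' @examples
#' tr <- simulate_trace(pgb_rates("WT"), experiment_conditions(co_atm = 1),
#'                      times = log_time_grid(points_per_decade = 20))
#' @export
simulate_trace <- function(rates, conditions, times = log_time_grid(),
                           rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(conditions, "experiment_conditions"))
  A <- build_rate_matrix(rates, co_molar(conditions),
                         conditions$scavenger_mode)
  y0 <- photolysis_initial_state(rates, conditions)
  y <- propagate_states(A, y0, times, rtol = rtol, atol = atol)
  drift <- max(abs(rowSums(y) - 1))
  if (drift > 1e-9) {
    warning(sprintf("population sum drifted by %.2g from 1", drift))
  }
  signal <- 1 - (y[, "R_CO"] + y[, "T_CO"])
  kinetic_trace(times, pmin(pmax(signal, -0.05), 1.05), species = y)
}

#' Simulate stopped-flow CO dissociation by NO displacement
#'
#' Starts from the pre-mix CO-bound equilibrium
#' (`R_CO : T_CO = 1 : k1/k_1`) and propagates the network with the
#' bimolecular re-entry fluxes switched off (`scavenger_mode`), modelling
#' displacement of CO by excess NO. The observable is the remaining bound
#' fraction `R_CO + T_CO`.
#'
#' With interconversion frozen (`freeze_interconversion = TRUE`, which
#' zeroes `k1, k_1, k2, k_2` during the decay while keeping the pre-mix
#' equilibrium split), the decay is biexponential with apparent rates
#' `kdiss_x * kout / (kout + kg_x)`: each thermally broken Fe-CO bond is
#' either re-formed geminately (probability `kg/(kg+kout)`) or the ligand
#' escapes and is scavenged.
#'
#' @param rates a [rate_constants] object.
#' @param conditions an [experiment_conditions] object with
#'   `scavenger_mode = TRUE`.
#' @param times output time grid, seconds.
#' @param freeze_interconversion freeze the bound/docked conformational
#'   exchange during the decay (the pre-mix equilibrium still uses
#'   `k1/k_1`).
#' @param rtol,atol integrator tolerances.
#' @return A [kinetic_trace] of the bound fraction.
#' @export
simulate_no_displacement <- function(rates, conditions,
                                     times = log_time_grid(1e-4, 100, 50),
                                     freeze_interconversion = FALSE,
                                     rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(conditions, "experiment_conditions"))
  if (!conditions$scavenger_mode) {
    stop("simulate_no_displacement requires conditions with scavenger_mode = TRUE",
         call. = FALSE)
  }
  y0 <- photolysis_initial_state(
    rates, experiment_conditions(co_atm = conditions$co_atm,
                                 temperature_C = conditions$temperature_C,
                                 co_solubility = conditions$co_solubility,
                                 photolysis_yield = 0,
                                 scavenger_mode = TRUE))
  prop_rates <- rates
  if (freeze_interconversion) {
    prop_rates <- update_rates(rates, k1 = 0, k_1 = 0, k2 = 0, k_2 = 0)
  }
  A <- build_rate_matrix(prop_rates, co_molar(conditions),
                         scavenger_mode = TRUE)
  y <- propagate_states(A, y0, times, rtol = rtol, atol = atol)
  signal <- y[, "R_CO"] + y[, "T_CO"]
  kinetic_trace(times, pmin(pmax(signal, -0.05), 1.05), species = y)
}
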