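#' Equilibrium and second-order constants derived from microscopic rates
#'
#' Computes the constants the microscopic scheme implies:
#' * `K1 = k1 / k_1` — bound-state conformational equilibrium (favours r
#'   when < 1);
#' * `K3 = k3 / k_3` — unliganded conformational equilibrium (favours t
#'   when > 1);
#' * `kON_x` (x = r, t) — second-order CO association constants, computed
#'   two ways: the entry-branching formula
#'   `kin_x * kg_x / (kg_x + kout)` (a ligand entering from solvent binds
#'   with probability `kg/(kg+kout)` before escaping), and numerically as
#'   the slope of the apparent bimolecular rebinding rate versus dissolved
#'   CO from [simulate_trace()] on an isolated single-conformation
#'   network;
#' * `kdiss_x` — thermal Fe-CO dissociation rates implied by measured
#'   apparent dissociation rates: `kdiss_x = koff_x * (kout + kg_x) / kout`
#'   (the inverse escape-branching relation).
#'
#' @param rates a [rate_constants] object.
#' @param koff_r,koff_t optional measured apparent dissociation rates
#'   (s^-1) from the NO-displacement experiment; when supplied the
#'   implied `kdiss_r`/`kdiss_t` are reported.
#' @param numeric_kon if `TRUE` (default), also estimate `kON_r`/`kON_t`
#'   numerically from simulated rebinding at several CO concentrations.
#' @param co_grid CO concentrations (M) used for the numerical slope.
#' @return A list with `K1`, `K3`, `kON_r_branching`, `kON_t_branching`,
#'   optionally `kON_r_numeric`, `kON_t_numeric`, `kdiss_r`, `kdiss_t`.
#' @examples
#' derive_constants(pgb_rates("WT"), numeric_kon = FALSE)$K3  # 3.0
#' @export
derive_constants <- function(rates, koff_r = NULL, koff_t = NULL,
                             numeric_kon = TRUE,
                             co_grid = c(0.5, 1, 2) * 1e-3) {
  validate_rate_constants(rates)
  if (rates$k_1 == 0) {
    stop("undefined bound equilibrium: k_1 = 0", call. = FALSE)
  }
  if (rates$k_3 == 0) {
    stop("undefined unliganded equilibrium: k_3 = 0", call. = FALSE)
  }
  out <- list(K1 = rates$k1 / rates$k_1, K3 = rates$k3 / rates$k_3)
  out$kON_r_branching <- rates$kin_r * rates$kg_r /
    (rates$kg_r + rates$kout)
  out$kON_t_branching <- rates$kin_t * rates$kg_t /
    (rates$kg_t + rates$kout)
  if (numeric_kon) {
    out$kON_r_numeric <- numeric_kon_pathway(rates, "r", co_grid)
    out$kON_t_numeric <- numeric_kon_pathway(rates, "t", co_grid)
  }
  if (!is.null(koff_r)) {
    out$kdiss_r <- koff_r * (rates$kout + rates$kg_r) / rates$kout
  }
  if (!is.null(koff_t)) {
    out$kdiss_t <- koff_t * (rates$kout + rates$kg_t) / rates$kout
  }
  out
}

# Apparent bimolecular association constant of one pathway, measured as
# the slope of the apparent rebinding rate vs [CO]. The conformational
# exchange and thermal dissociation are switched off so that the network
# reduces to the chosen pathway binding irreversibly from solvent; the
# decay of the unliganded fraction is then single-exponential on the
# bimolecular time scale and its rate is read off with a 1-exponential
# fit.
numeric_kon_pathway <- function(rates, pathway = c("r", "t"), co_grid) {
  pathway <- match.arg(pathway)
  iso <- update_rates(rates, k1 = 0, k_1 = 0, k2 = 0, k_2 = 0,
                      k3 = 0, k_3 = 0, kdiss_r = 0, kdiss_t = 0)
  kin <- if (pathway == "r") iso$kin_r else iso$kin_t
  kg <- if (pathway == "r") iso$kg_r else iso$kg_t
  if (kin == 0 || kg == 0) return(NA_real_)
  y0 <- stats::setNames(numeric(8), species_names())
  y0[if (pathway == "r") "R_free" else "T_free"] <- 1
  k_app <- vapply(co_grid, function(co) {
    rate0 <- kin * co * kg / (kg + iso$kout)  # coarse scale estimate
    times <- 10^seq(log10(0.05 / rate0), log10(6 / rate0), length.out = 60)
    A <- build_rate_matrix(iso, co)
    y <- propagate_states(A, y0, times)
    nfree <- 1 - (y[, "R_CO"] + y[, "T_CO"])
    fit <- fit_multiexponential(
      kinetic_trace(times, pmin(pmax(nfree, 0), 1)), 1)
    1 / fit$lifetimes[1]
  }, numeric(1))
  unname(stats::coef(stats::lm(k_app ~ co_grid))[2])
}
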