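#' Microscopic rate constants of the eight-state CO binding scheme
#'
#' Container for the microscopic rate constants of the two-conformation
#' (r/t) CO binding network. The scheme couples three conformational
#' equilibria (bound, primary-docked and unliganded protein), geminate
#' rebinding from the primary docking site, migration to a secondary
#' docking site, thermal Fe-CO bond dissociation, and bimolecular ligand
#' exchange with the solvent.
#'
#' Direction convention: `k1`, `k2`, `k3` are r -> t; `k_1`, `k_2`, `k_3`
#' are t -> r. Thus `K1 = k1/k_1` (bound) and `K3 = k3/k_3` (unliganded);
#' the liganded protein favours r (K1 < 1) while the unliganded protein
#' favours t (K3 > 1).
#'
#' @param k1,k_1 bound-state interconversion, s^-1 (r-CO <-> t-CO).
#' @param k2,k_2 primary-docked-state interconversion, s^-1.
#' @param k3,k_3 unliganded interconversion, s^-1 (r <-> t).
#' @param kc,k_c r-state primary <-> secondary docking-site migration, s^-1.
#' @param kd2,k_d2 t-state primary <-> secondary docking-site migration,
#'   s^-1.
#' @param kg_r,kg_t geminate Fe-CO bond re-formation from the primary
#'   docking site, s^-1.
#' @param kdiss_r,kdiss_t thermal Fe-CO bond dissociation into the primary
#'   docking site, s^-1.
#' @param kin_r,kin_t bimolecular ligand entry from solvent, M^-1 s^-1.
#' @param kout ligand escape from the primary docking site to solvent,
#'   s^-1 (one value shared by both conformations).
#'
#' @return An object of class `rate_constants` (a named list of
#'   non-negative numeric scalars).
#' @examples
#' rates <- rate_constants(k3 = 6e4, k_3 = 2e4)
#' rates$k3 / rates$k_3
#' @export
rate_constants <- function(k1 = 0, k_1 = 0, k2 = 0, k_2 = 0,
                           k3 = 0, k_3 = 0, kc = 0, k_c = 0,
                           kd2 = 0, k_d2 = 0, kg_r = 0, kg_t = 0,
                           kdiss_r = 0, kdiss_t = 0,
                           kin_r = 0, kin_t = 0, kout = 0) {
  x <- list(k1 = k1, k_1 = k_1, k2 = k2, k_2 = k_2, k3 = k3, k_3 = k_3,
            kc = kc, k_c = k_c, kd2 = kd2, k_d2 = k_d2,
            kg_r = kg_r, kg_t = kg_t, kdiss_r = kdiss_r, kdiss_t = kdiss_t,
            kin_r = kin_r, kin_t = kin_t, kout = kout)
  validate_rate_constants(x)
  structure(x, class = "rate_constants")
}

#' Names of all microscopic rate parameters
#' @return Character vector of the 17 parameter names.
#' @export
rate_parameter_names <- function() {
  c("k1", "k_1", "k2", "k_2", "k3", "k_3", "kc", "k_c", "kd2", "k_d2",
    "kg_r", "kg_t", "kdiss_r", "kdiss_t", "kin_r", "kin_t", "kout")
}

validate_rate_constants <- function(x) {
  nm <- rate_parameter_names()
  if (!all(nm %in% names(x))) {
    stop("rate_constants: missing parameters: ",
         paste(setdiff(nm, names(x)), collapse = ", "), call. = FALSE)
  }
  for (p in nm) {
    v <- x[[p]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("rate_constants: '", p,
           "' must be a single finite non-negative number", call. = FALSE)
    }
  }
  invisible(x)
}

#' Modify a set of rate constants
#'
#' Returns a copy of `rates` with the named parameters replaced.
#'
#' @param rates a [rate_constants] object.
#' @param ... named replacements, e.g. `kout = 2e8`.
#' @return A new `rate_constants` object.
#' @export
update_rates <- function(rates, ...) {
  stopifnot(inherits(rates, "rate_constants"))
  repl <- list(...)
  bad <- setdiff(names(repl), rate_parameter_names())
  if (length(bad)) {
    stop("unknown rate parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x <- unclass(rates)
  x[names(repl)] <- repl
  validate_rate_constants(x)
  structure(x, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Microscopic rate constants (s^-1; kin_* in M^-1 s^-1):\n")
  v <- unlist(unclass(x))
  print(format(v, digits = 4, scientific = TRUE), quote = FALSE)
  invisible(x)
}

#' @export
as.list.rate_constants <- function(x, ...) unclass(x)

#' Published microscopic rate constants for protoglobin variants
#'
#' The microscopic rate constants obtained from global fits of CO
#' rebinding after laser photolysis at 20 degrees C, for the
#' Cys101Ser-stabilised protoglobin (here "WT") and five heme-pocket
#' mutants, together with the stopped-flow CO dissociation rate constants
#' (NO displacement) and their fractional amplitudes. Units follow the
#' parameter definitions in [rate_constants()]; `koff_fast`/`koff_slow`
#' are the larger/smaller apparent dissociation rates in s^-1.
#'
#' @return A data.frame with one row per variant.
#' @examples
#' pgb_rate_table()[, c("variant", "k3", "k_3")]
#' @export
pgb_rate_table <- function() {
  data.frame(
    variant  = c("WT", "W60A", "F93Y", "F93A", "Y61A", "F145W"),
    k1       = c(1.3e5, 1.4e5, 1.4e5, 1.35e5, 1.35e5, 1.35e5),
    k_1      = c(5e5,   2e5,   3e5,   0.8e5,  4e5,    5e5),
    k3       = c(6e4,   0.5e4, 15e4,  4e4,    0.6e4,  4e4),
    k_3      = c(2.0e4, 0.9e4, 2e4,   1.7e4,  0.6e4,  1.7e4),
    kin_r    = c(7.8e7, 40e7,  38e7,  37e7,   70e7,   35e7),
    kin_t    = c(3.0e7, 3.0e7, 3.0e7, 1.0e7,  0.3e7,  3.0e7),
    kout     = c(1.5e8, 2.0e8, 1.4e8, 0.7e8,  4.5e8,  0.9e8),
    kg_r     = c(5e7,   5e7,   2e7,   5e7,    6e7,    4e7),
    kg_t     = c(6.0e6, 5e6,   6e6,   6e6,    6.0e6,  5e6),
    kc       = c(1.0e7, 5e7,   5e7,   1.0e7,  1.0e7,  0.7e7),
    k_c      = c(1.0e7, 5e7,   1e7,   1e7,    1e7,    3e7),
    kd2      = c(1.0e7, 5e7,   5e7,   1e7,    1e7,    0.7e7),
    k_d2     = c(1.0e7, 5e7,   1.0e7, 1.0e7,  1.0e7,  3e7),
    kon_r    = c(2.1e7, 8e7,   16e7,  6e7,    7.6e7,  1.0e7),
    kon_t    = c(1.1e6, 0.7e6, 0.8e6, 1.3e6,  0.4e6,  1.5e6),
    # apparent CO dissociation rates from NO displacement; fast phase
    # listed first in the source table. W60A dissociation is
    # mono-exponential (single phase, 100%).
    koff_fast     = c(0.081, NA,    0.24,  0.40,  0.23,  0.50),
    koff_fast_amp = c(0.33,  NA,    0.76,  0.34,  0.32,  0.33),
    koff_slow     = c(0.032, 0.020, 0.020, 0.21,  0.050, 0.100),
    koff_slow_amp = c(0.67,  1.00,  0.24,  0.66,  0.68,  0.67),
    stringsAsFactors = FALSE
  )
}

#' Rate constants for a published protoglobin variant
#'
#' Builds a full [rate_constants] object from [pgb_rate_table()]. The
#' interconversion rates of the primary-docked species are set equal to
#' those of the unliganded species (`k2 = k3`, `k_2 = k_3`), and the
#' thermal dissociation rates `kdiss_r`/`kdiss_t` are derived from the
#' measured apparent dissociation rates through
#' `kdiss = koff * (kout + kg) / kout`, i.e. the inverse of the escape
#' branching ratio, as in the original analysis.
#'
#' @param variant one of `"WT"`, `"W60A"`, `"F93Y"`, `"F93A"`, `"Y61A"`,
#'   `"F145W"`.
#' @param koff_assignment which apparent dissociation phase feeds which
#'   pathway: `"slow_r"` (default; the majority slow phase belongs to the
#'   majority bound conformer r) or `"fast_r"`.
#' @return A `rate_constants` object.
#' @examples
#' wt <- pgb_rates("WT")
#' wt$k3 / wt$k_3  # unliganded equilibrium constant, 3.0
#' @export
pgb_rates <- function(variant = "WT",
                      koff_assignment = c("slow_r", "fast_r")) {
  koff_assignment <- match.arg(koff_assignment)
  tab <- pgb_rate_table()
  row <- tab[tab$variant == variant, ]
  if (nrow(row) != 1L) {
    stop("unknown variant '", variant, "'; see pgb_rate_table()$variant",
         call. = FALSE)
  }
  koff_fast <- row$koff_fast
  koff_slow <- row$koff_slow
  if (is.na(koff_fast)) koff_fast <- koff_slow  # mono-exponential variant
  if (koff_assignment == "slow_r") {
    koff_r <- koff_slow; koff_t <- koff_fast
  } else {
    koff_r <- koff_fast; koff_t <- koff_slow
  }
  rate_constants(
    k1 = row$k1, k_1 = row$k_1,
    k2 = row$k3, k_2 = row$k_3,
    k3 = row$k3, k_3 = row$k_3,
    kc = row$kc, k_c = row$k_c,
    kd2 = row$kd2, k_d2 = row$k_d2,
    kg_r = row$kg_r, kg_t = row$kg_t,
    kdiss_r = koff_r * (row$kout + row$kg_r) / row$kout,
    kdiss_t = koff_t * (row$kout + row$kg_t) / row$kout,
    kin_r = row$kin_r, kin_t = row$kin_t,
    kout = row$kout
  )
}
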