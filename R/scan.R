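#' One-dimensional fitness-scan error of a parameter
#'
#' Scans a fitness (sum-of-squares) function along one parameter on a
#' log-spaced grid around `p0` and reports the interval where the fitness
#' stays below `threshold` times its minimum on the scan; the half-width
#' of that interval is the scan error. Crossings are located by linear
#' interpolation between grid points. For a quadratic fitness
#' `f(p) = f0 * (1 + ((p - p0)/w)^2)` and a 10% threshold the half-width
#' is `w * sqrt(0.1)`.
#'
#' @param fitness function of a single numeric argument returning the
#'   sum-of-squares fitness.
#' @param p0 parameter value at the optimum (must be > 0).
#' @param span scan range in decades on each side of `p0`.
#' @param n number of scan points (log-spaced).
#' @param threshold relative fitness increase defining the error
#'   (default 1.1, i.e. a 10% increase).
#' @return List with `lower`, `upper` (crossing points, `NA` if not
#'   reached within the scan), `half_width`, `unbounded` flag,
#'   `scan_values`, `scan_fitness`.
#' @examples
#' f <- function(p) 2 * (1 + ((p - 1) / 0.2)^2)
#' scan_parameter_error(f, 1)$half_width  # ~ 0.2 * sqrt(0.1)
#' @export
scan_parameter_error <- function(fitness, p0, span = 1, n = 81,
                                 threshold = 1.1) {
  stopifnot(is.function(fitness), p0 > 0, n >= 5)
  values <- p0 * 10^seq(-span, span, length.out = n)
  f <- vapply(values, fitness, numeric(1))
  i0 <- which.min(abs(values - p0))
  fmin <- f[i0]
  cut <- threshold * fmin
  cross <- function(idx) {
    # first grid interval, moving away from the optimum, where f crosses cut
    for (k in seq_len(length(idx) - 1)) {
      i <- idx[k]; j <- idx[k + 1]
      if (f[i] <= cut && f[j] > cut) {
        frac <- (cut - f[i]) / (f[j] - f[i])
        return(values[i] + frac * (values[j] - values[i]))
      }
    }
    NA_real_
  }
  upper <- cross(i0:n)
  lower <- cross(i0:1)
  unbounded <- is.na(upper) || is.na(lower)
  half_width <- if (unbounded) NA_real_ else (upper - lower) / 2
  list(lower = lower, upper = upper, half_width = half_width,
       unbounded = unbounded, scan_values = values, scan_fitness = f)
}

#' Fitness-scan errors for all free parameters of a global fit
#'
#' For each free parameter, scans the global-fit fitness along that
#' parameter with the others held at their optimum and reports the
#' half-width at a 10% fitness increase (see [scan_parameter_error()]).
#' The asymptotic error-matrix estimate from the fit is attached for
#' cross-checking.
#'
#' @param result a `fit_result` from [global_fit()].
#' @param spec the [fit_spec] that produced it (defaults to the one
#'   stored in the result).
#' @param span,n,threshold scan controls, passed to
#'   [scan_parameter_error()].
#' @return A data.frame with one row per free parameter: `parameter`,
#'   `estimate`, `lower`, `upper`, `half_width`, `unbounded`,
#'   `se_matrix` (error-matrix standard error mapped to the natural
#'   scale, `estimate * log(10) * se_log10`).
#' @export
scan_errors <- function(result, spec = result$spec, span = 1, n = 81,
                        threshold = 1.1) {
  stopifnot(inherits(result, "fit_result"), inherits(spec, "fit_spec"))
  est <- unlist(unclass(result$rates))[spec$free]
  rows <- lapply(seq_along(spec$free), function(j) {
    f1 <- function(p) {
      logp <- replace(result$par, j, log10(p))
      sum(fit_residuals(spec, logp)^2)
    }
    sc <- scan_parameter_error(f1, est[j], span = span, n = n,
                               threshold = threshold)
    data.frame(parameter = spec$free[j], estimate = est[j],
               lower = sc$lower, upper = sc$upper,
               half_width = sc$half_width, unbounded = sc$unbounded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$se_matrix <- est * log(10) * result$error_matrix[spec$free]
  out
}
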