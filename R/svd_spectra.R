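#' Time-resolved difference-spectra matrix
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param delay_times delay times in seconds, strictly increasing.
#' @param values difference-absorbance matrix, wavelengths x delays.
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(wavelengths, delay_times, values) {
  wavelengths <- as.numeric(wavelengths)
  delay_times <- as.numeric(delay_times)
  values <- as.matrix(values)
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (length(delay_times) > 1 && any(diff(delay_times) <= 0)) {
    stop("delay_times must be strictly increasing", call. = FALSE)
  }
  if (nrow(values) != length(wavelengths) ||
      ncol(values) != length(delay_times)) {
    stop("values must be a length(wavelengths) x length(delay_times) matrix",
         call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, delay_times = delay_times,
                 values = values), class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("Difference spectra: %d wavelengths (%.4g-%.4g nm) x %d delays (%.3g-%.3g s)\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              length(x$delay_times), min(x$delay_times), max(x$delay_times)))
  invisible(x)
}

# Lag-1 autocorrelation of a unit-norm vector: sum_j v_j v_{j+1}.
lag1_autocorrelation <- function(v) {
  v <- v / sqrt(sum(v^2))
  n <- length(v)
  if (n < 2) return(NA_real_)
  sum(v[-n] * v[-1])
}

#' Singular value decomposition of a difference-spectra matrix
#'
#' Exact SVD of the wavelengths x delays matrix. The sign of each
#' spectral component is fixed by making its largest-magnitude element
#' positive (the corresponding amplitude vector is flipped to
#' compensate), and the lag-1 autocorrelation of every spectral and
#' amplitude vector is computed as a smoothness diagnostic for component
#' selection.
#'
#' @param m a [spectra_matrix].
#' @return An object of class `svd_result`: `d` (singular values,
#'   descending), `spectral` (unit-norm columns over wavelength),
#'   `amplitude` (unit-norm columns over delay time),
#'   `autocorr_spectral`, `autocorr_amplitude`, plus the wavelength and
#'   delay grids.
#' @export
svd_decompose <- function(m) {
  stopifnot(inherits(m, "spectra_matrix"))
  if (nrow(m$values) < 2 || ncol(m$values) < 2) {
    stop("matrix must be at least 2x2", call. = FALSE)
  }
  s <- svd(m$values)
  for (i in seq_along(s$d)) {
    j <- which.max(abs(s$u[, i]))
    if (s$u[j, i] < 0) {
      s$u[, i] <- -s$u[, i]
      s$v[, i] <- -s$v[, i]
    }
  }
  structure(list(d = s$d, spectral = s$u, amplitude = s$v,
                 autocorr_spectral = apply(s$u, 2, lag1_autocorrelation),
                 autocorr_amplitude = apply(s$v, 2, lag1_autocorrelation),
                 wavelengths = m$wavelengths,
                 delay_times = m$delay_times),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  k <- min(length(x$d), 5)
  cat("SVD of difference spectra; leading components:\n")
  for (i in seq_len(k)) {
    cat(sprintf("  S_%d = %.4g, corr(spectral) = %.3f, corr(amplitude) = %.3f\n",
                i, x$d[i], x$autocorr_spectral[i], x$autocorr_amplitude[i]))
  }
  invisible(x)
}

#' Select the meaningful SVD components
#'
#' A component is kept when its singular value is significant relative to
#' the leading one (`s_i / s_1 >= sv_ratio_min`) and both its spectral
#' and amplitude vectors are smooth (lag-1 autocorrelation
#' `>= autocorr_min`). Random-noise components have near-zero
#' autocorrelation and are rejected even when their singular values are
#' not negligible.
#'
#' @param r an `svd_result` from [svd_decompose()].
#' @param sv_ratio_min minimum singular-value ratio, in (0, 1].
#' @param autocorr_min minimum lag-1 autocorrelation, in (0, 1].
#' @return Integer vector of selected component indices (possibly empty).
#' @export
select_components <- function(r, sv_ratio_min = 0.01, autocorr_min = 0.8) {
  stopifnot(inherits(r, "svd_result"))
  if (!(sv_ratio_min > 0 && sv_ratio_min <= 1) ||
      !(autocorr_min > 0 && autocorr_min <= 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (!length(r$d) || r$d[1] == 0) return(integer(0))
  keep <- (r$d / r$d[1] >= sv_ratio_min) &
    (r$autocorr_spectral >= autocorr_min) &
    (r$autocorr_amplitude >= autocorr_min)
  which(keep)
}

#' Low-rank reconstruction from an SVD
#'
#' Rank-`k` approximation built from the leading `k` components. By the
#' Eckart-Young theorem its Frobenius error equals
#' `sqrt(sum_{i>k} s_i^2)` and no rank-`k` matrix does better.
#'
#' @param r an `svd_result`.
#' @param k number of components, `1 <= k <= length(r$d)`.
#' @return A [spectra_matrix] holding the rank-`k` approximation.
#' @export
reconstruct <- function(r, k) {
  stopifnot(inherits(r, "svd_result"))
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(r$d) ||
      k != round(k)) {
    stop("k must be an integer in [1, ", length(r$d), "]", call. = FALSE)
  }
  idx <- seq_len(k)
  vals <- r$spectral[, idx, drop = FALSE] %*%
    (r$d[idx] * t(r$amplitude[, idx, drop = FALSE]))
  spectra_matrix(r$wavelengths, r$delay_times, vals)
}
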