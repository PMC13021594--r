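#' Centered 5-point moving variance
#'
#' Population variance (divisor = window) over a centered window:
#' `Var[i] = (1/w) * sum_{k=i-h}^{i+h} (x[k] - xbar[i])^2` with
#' `xbar[i]` the window mean. The first and last `h = (w-1)/2` samples have
#' no full window and are returned as `NA`.
#'
#' @param x numeric series, length >= `window`.
#' @param window odd window length; default 5 (0.1 s at 50 Hz).
#' @return Series of per-sample variances, `NA` at the undefined edges.
#' @export
moving_variance <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("parameter error: `window` must be an odd integer >= 3",
         call. = FALSE)
  if (length(x) < window)
    stop("input error: series shorter than the window", call. = FALSE)
  w <- rep(1 / window, window)
  m <- stats::filter(x, w, sides = 2)
  m2 <- stats::filter(x * x, w, sides = 2)
  v <- as.numeric(m2 - m * m)
  pmax(v, 0)  # clip tiny negative rounding residue
}

#' Steady-phase detection from the moment channels
#'
#' A sample belongs to a steady (low muscular activity) phase when the sum
#' of the 5-point moving variances of the two moment channels, divided by
#' the squared body mass, is at or below the threshold. ST(N) is the count
#' of steady samples; the two samples at each end of the record have no full
#' variance window and are never steady.
#'
#' @param moment_x,moment_y moment series about the mediolateral and
#'   anteroposterior axes, N·m, equal length.
#' @param mass body mass, kg (> 0).
#' @param threshold variance threshold; default 0.002 (derived from the
#'   lowest quartile of cohort weight-signal variance, see
#'   [calibrate_threshold()]).
#' @param window moving-variance window; default 5.
#' @return An object of class `steady_phase`: logical `mask`, integer
#'   `st_n`, the `threshold`, and `summed_norm_variance` (per sample).
#' @export
steady_mask <- function(moment_x, moment_y, mass, threshold = 0.002,
                        window = 5L) {
  if (length(moment_x) != length(moment_y))
    stop("input error: moment channels must have equal length", call. = FALSE)
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("parameter error: `mass` must be a positive scalar", call. = FALSE)
  sv <- (moving_variance(moment_x, window) +
         moving_variance(moment_y, window)) / mass^2
  mask <- !is.na(sv) & sv <= threshold
  structure(list(mask = mask, st_n = sum(mask), threshold = threshold,
                 summed_norm_variance = sv),
            class = "steady_phase")
}

#' @export
print.steady_phase <- function(x, ...) {
  cat(sprintf("<steady_phase> st_n = %d / %d samples at threshold %g\n",
              x$st_n, length(x$mask), x$threshold))
  invisible(x)
}

#' Derive the steady-phase threshold from cohort weight-signal variances
#'
#' The threshold is the upper limit of the lowest quartile — the 25th
#' linear-interpolation percentile — of the per-subject mean moving variance
#' of the normalized weight signal across the cohort. Applied to the default
#' synthetic cohort this statistic sits near 0.002, the packaged default.
#'
#' @param cohort_weight_variances per-subject mean 5-point moving variance
#'   of the normalized weight signal; at least 4 subjects.
#' @return The threshold (25th percentile).
#' @export
calibrate_threshold <- function(cohort_weight_variances) {
  v <- cohort_weight_variances[!is.na(cohort_weight_variances)]
  if (length(v) == 0L) stop("input error: no variance values", call. = FALSE)
  if (length(v) < 4L)
    stop("input error: need at least 4 subjects for a quartile",
         call. = FALSE)
  quantile(v, 0.25, type = 7, names = FALSE)
}
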