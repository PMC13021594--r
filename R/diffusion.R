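#' Stabilogram diffusion function
#'
#' Mean square planar CPF displacement as a function of the time lag between
#' samples: `msd[k]` is the exact average over all overlapping sample pairs
#' `(t, t + k)` of `(x[t+k]-x[t])^2 + (y[t+k]-y[t])^2` (no subsampling).
#' Healthy quiet stance produces a biphasic curve: a steep persistent
#' short-term regime and a flatter mean-reverting long-term regime.
#'
#' @param x mediolateral CPF series, cm (pass a single axis here and omit
#'   `y` for a one-dimensional curve).
#' @param y anteroposterior CPF series, cm, or `NULL`.
#' @param fs sampling rate, Hz.
#' @param max_lag largest lag, s; default 2.5 (about one fifth of a 12 s
#'   record, beyond which the curve is variance-dominated).
#' @return An object of class `sdf_curve`: `lags` (s), `msd` (cm^2),
#'   `n_pairs` (pairs averaged per lag), `fs`.
#' @export
compute_sdf <- function(x, y = NULL, fs, max_lag = 2.5) {
  n <- length(x)
  K <- floor(max_lag * fs)
  if (K >= n)
    stop("parameter error: `max_lag` must be shorter than the record",
         call. = FALSE)
  if (K < 1L) stop("parameter error: `max_lag` below one sample",
                   call. = FALSE)
  if (!is.null(y) && length(y) != n)
    stop("input error: x and y must have equal length", call. = FALSE)
  msd <- numeric(K)
  for (k in seq_len(K)) {
    dx <- x[(k + 1L):n] - x[1:(n - k)]
    s <- dx * dx
    if (!is.null(y)) {
      dy <- y[(k + 1L):n] - y[1:(n - k)]
      s <- s + dy * dy
    }
    msd[k] <- mean(s)
  }
  structure(list(lags = seq_len(K) / fs, msd = msd,
                 n_pairs = n - seq_len(K), fs = fs),
            class = "sdf_curve")
}

#' @export
print.sdf_curve <- function(x, ...) {
  cat(sprintf("<sdf_curve> %d lags up to %.2f s, msd range [%.3g, %.3g] cm^2\n",
              length(x$lags), max(x$lags), min(x$msd), max(x$msd)))
  invisible(x)
}

#' Critical point of the stabilogram diffusion function
#'
#' Scans every admissible breakpoint on the lag grid, fits ordinary
#' least-squares lines to the short-term segment (first lag up to the
#' breakpoint, inclusive) and the long-term segment (breakpoint to the last
#' lag), and keeps the breakpoint minimizing the pooled squared error (ties
#' broken toward the smaller breakpoint). The critical time CRI(T) is the
#' abscissa where the two fitted lines intersect — the lag at which
#' open-loop (feedforward) control hands over to closed-loop
#' (sensory-feedback) control. The fit is flagged degenerate when the two
#' slopes differ by less than `slope_tol` relative to the steeper one, or
#' when the intersection falls outside `(0, max lag)`; degenerate values are
#' excluded (not imputed) from cohort statistics.
#'
#' @param sdf an `sdf_curve` with at least 8 lag points.
#' @param min_seg minimum number of lag points in each segment; default 4.
#' @param slope_tol relative slope-difference floor below which the curve is
#'   treated as single-regime; default 0.05.
#' @return An object of class `critical_point`: `cri_t` (s, `NA` when
#'   degenerate), `short_slope`, `long_slope` (cm^2/s), `breakpoint` (s),
#'   `intersection_msd` (cm^2), `degenerate`.
#' @export
fit_critical_point <- function(sdf, min_seg = 4L, slope_tol = 0.05) {
  stopifnot(inherits(sdf, "sdf_curve"))
  x <- sdf$lags
  y <- sdf$msd
  K <- length(x)
  if (K < 8L) stop("fit error: need at least 8 lag points", call. = FALSE)
  if (K < 2L * min_seg - 1L)
    stop("fit error: fewer than `min_seg` points per segment at every ",
         "candidate breakpoint", call. = FALSE)
  # prefix/suffix sums give O(1) OLS per candidate (breakpoint shared by
  # both segments)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
  seg <- function(i, j) {  # OLS slope/intercept/SSE on x[i..j]
    n <- j - i + 1
    sx <- cx[j] - if (i > 1) cx[i - 1] else 0
    sy <- cy[j] - if (i > 1) cy[i - 1] else 0
    sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
    sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
    syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
    vx <- sxx - sx * sx / n
    vxy <- sxy - sx * sy / n
    vy <- syy - sy * sy / n
    b <- vxy / vx
    c(slope = b, intercept = (sy - b * sx) / n, sse = max(vy - b * vxy, 0))
  }
  best <- NULL
  for (j in seq(min_seg, K - min_seg + 1L)) {
    f1 <- seg(1L, j)
    f2 <- seg(j, K)
    sse <- f1[["sse"]] + f2[["sse"]]
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, f1 = f1, f2 = f2, b = x[j])
  }
  s1 <- best$f1[["slope"]]; s2 <- best$f2[["slope"]]
  a1 <- best$f1[["intercept"]]; a2 <- best$f2[["intercept"]]
  cri <- (a2 - a1) / (s1 - s2)
  degenerate <- !is.finite(cri) ||
    abs(s1 - s2) < slope_tol * max(abs(s1), abs(s2)) ||
    cri <= 0 || cri >= max(x)
  structure(list(cri_t = if (degenerate) NA_real_ else cri,
                 short_slope = s1, long_slope = s2,
                 breakpoint = best$b,
                 intersection_msd = if (degenerate) NA_real_
                                    else a1 + s1 * cri,
                 degenerate = degenerate),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  if (x$degenerate)
    cat("<critical_point> degenerate (single-regime or off-grid intersection)\n")
  else
    cat(sprintf(paste0("<critical_point> cri_t = %.3f s ",
                       "(slopes %.3g -> %.3g cm^2/s, breakpoint %.2f s)\n"),
                x$cri_t, x$short_slope, x$long_slope, x$breakpoint))
  invisible(x)
}
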