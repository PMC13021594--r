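#' Central 95% amplitude range of a sway component
#'
#' The spread of a centered positional series measured as the difference
#' between the 97.5th and 2.5th linear-interpolation percentiles, i.e. the
#' empirical interval covering 95% of the stabilogram samples. For the
#' anteroposterior component this is the feature C(Y).
#'
#' @param y numeric series (cm), at least 40 samples so the 2.5% tails are
#'   resolved.
#' @param coverage central coverage fraction; default 0.95.
#' @return Non-negative range in the units of `y`.
#' @export
amplitude_range <- function(y, coverage = 0.95) {
  if (length(y) == 0L) stop("input error: empty series", call. = FALSE)
  if (length(y) < 40L)
    stop("input error: need >= 40 samples to resolve the ",
         100 * (1 - coverage) / 2, "% tails", call. = FALSE)
  a <- (1 - coverage) / 2
  unname(diff(quantile(y, c(a, 1 - a), type = 7, names = FALSE)))
}

#' Mass-normalized mean absolute moment
#'
#' Mean absolute moment about the anteroposterior axis divided by body mass:
#' the feature M(MY), an index of corrective torque activity. Computed on
#' the filtered, un-normalized moment channel.
#'
#' @param my moment series, N·m.
#' @param mass body mass, kg (> 0).
#' @return `mean(abs(my)) / mass`.
#' @export
mean_abs_moment <- function(my, mass) {
  if (!is.numeric(mass) || length(mass) != 1L || !is.finite(mass) || mass <= 0)
    stop("parameter error: `mass` must be a positive scalar", call. = FALSE)
  mean(abs(my)) / mass
}

#' Zero-crossing count of a centered signal
#'
#' Counts strict sign changes between consecutive samples. Samples that are
#' exactly zero inherit the most recent nonzero sign, so a touch-and-return
#' at the axis is not double counted; a signal that never takes a nonzero
#' value has zero crossings by definition.
#'
#' @param x numeric series, length >= 2.
#' @return Integer count in `[0, length(x) - 1]`.
#' @export
zero_crossings <- function(x) {
  if (length(x) < 2L) stop("input error: need at least 2 samples",
                           call. = FALSE)
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0L)
  pos <- cumsum(nz)            # index of the last nonzero sign seen so far
  keep <- pos > 0              # drop leading zeros (no sign yet)
  filled <- s[nz][pos[keep]]
  sum(diff(filled) != 0)
}

#' Sway velocity by central differences
#'
#' Second-order accurate derivative estimate: central differences at
#' interior samples, one-sided differences at the two ends. A first-order
#' forward-difference variant is available for sensitivity checks.
#'
#' @param x position series, cm.
#' @param fs sampling rate, Hz.
#' @param method "central" (default) or "forward".
#' @return Velocity series, cm/s, same length as `x`.
#' @export
sway_velocity <- function(x, fs, method = c("central", "forward")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3L) stop("input error: need at least 3 samples", call. = FALSE)
  v <- numeric(n)
  if (method == "central") {
    v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
    v[1L] <- (x[2L] - x[1L]) * fs
    v[n] <- (x[n] - x[n - 1L]) * fs
  } else {
    v[1:(n - 1L)] <- diff(x) * fs
    v[n] <- v[n - 1L]
  }
  v
}

#' Zero-crossing count of mediolateral sway velocity
#'
#' The feature ZCR(VX): how many times the mediolateral CPF velocity changes
#' direction during the measuring period.
#'
#' @param x centered mediolateral position series, cm.
#' @param fs sampling rate, Hz.
#' @inheritParams sway_velocity
#' @return Integer count.
#' @export
zcr_vx <- function(x, fs, method = "central") {
  zero_crossings(sway_velocity(x, fs, method))
}

#' Anteroposterior sway path and mean velocity
#'
#' Cumulative path length of the AP component and the corresponding mean
#' sway velocity over the record duration.
#'
#' @param y AP position series, cm.
#' @param fs sampling rate, Hz.
#' @return List with `path` (cm) and `mean_velocity` (cm/s).
#' @export
ap_sway_path <- function(y, fs) {
  if (length(y) < 2L) stop("input error: need at least 2 samples",
                           call. = FALSE)
  path <- sum(abs(diff(y)))
  list(path = path, mean_velocity = path / (length(y) / fs))
}

#' Romberg quotient
#'
#' Ratio of a sway measure recorded with eyes closed to the same measure
#' recorded with eyes open. Values above 1 indicate reliance on vision.
#'
#' @param ec_value eyes-closed value(s), > 0 for a meaningful ratio.
#' @param eo_value eyes-open value(s), strictly positive.
#' @return `ec_value / eo_value`, vectorized.
#' @export
romberg_quotient <- function(ec_value, eo_value) {
  if (any(!is.finite(eo_value)) || any(eo_value <= 0))
    stop("degenerate input: eyes-open value must be positive", call. = FALSE)
  ec_value / eo_value
}

#' Extract the full time-domain feature vector from a preprocessed recording
#'
#' Computes C(Y) (95% AP amplitude range), M(MY) (mass-normalized mean
#' absolute AP-axis moment), ZCR(Y), ZCR(X), ZCR(VX), the
#' stabilogram-diffusion critical time CRI(T), the steady-phase sample count
#' ST(N), and the auxiliary Romberg inputs (peak-to-peak AP range, AP sway
#' path, AP mean velocity). Recordings without moment channels yield `NA`
#' for M(MY) and ST(N); a motionless recording yields a degenerate (NA)
#' CRI(T).
#'
#' @param rec a preprocessed `stabilogram` (600 samples).
#' @param max_lag maximum diffusion lag, s; default 2.5.
#' @param threshold steady-phase variance threshold; default 0.002.
#' @param min_seg minimum lag points per critical-point segment; default 4.
#' @return One-row `data.frame` with metadata and feature columns
#'   (`cy`, `m_my`, `zcr_y`, `zcr_x`, `zcr_vx`, `cri_t`, `cri_degenerate`,
#'   `st_n`, `ap_pp`, `ap_path`, `ap_mean_velocity`).
#' @export
extract_features <- function(rec, max_lag = 2.5, threshold = 0.002,
                             min_seg = 4L) {
  stopifnot(inherits(rec, "stabilogram"))
  if (!rec$preprocessed)
    stop("input error: recording must be preprocessed first", call. = FALSE)
  meta <- rec$meta
  mass <- meta$mass
  cy <- amplitude_range(rec$cpf_y)
  pathv <- ap_sway_path(rec$cpf_y, rec$fs)

  cri_t <- NA_real_
  cri_deg <- TRUE
  if (var(rec$cpf_x) + var(rec$cpf_y) > 0) {
    sdf <- compute_sdf(rec$cpf_x, rec$cpf_y, rec$fs, max_lag)
    cp <- fit_critical_point(sdf, min_seg = min_seg)
    cri_t <- cp$cri_t
    cri_deg <- cp$degenerate
  }

  m_my <- NA_real_
  st_n <- NA_integer_
  if (!rec$feature_limited && !is.null(mass)) {
    m_my <- mean_abs_moment(rec$moment_y, mass)
    st_n <- steady_mask(rec$moment_x, rec$moment_y, mass, threshold)$st_n
  }

  data.frame(
    subject_id = meta$subject_id %||% NA_character_,
    sex = meta$sex %||% NA_character_,
    age = meta$age %||% NA_real_,
    mass = mass %||% NA_real_,
    condition = meta$condition %||% NA_character_,
    cy = cy,
    m_my = m_my,
    zcr_y = zero_crossings(rec$cpf_y),
    zcr_x = zero_crossings(rec$cpf_x),
    zcr_vx = zcr_vx(rec$cpf_x, rec$fs),
    cri_t = cri_t,
    cri_degenerate = cri_deg,
    st_n = st_n,
    ap_pp = diff(range(rec$cpf_y)),
    ap_path = pathv$path,
    ap_mean_velocity = pathv$mean_velocity,
    stringsAsFactors = FALSE)
}

#' Natural-log transform strictly positive feature columns
#'
#' Applies `log()` to the named columns; non-positive values are set to `NA`
#' with a warning stating how many were excluded, since the transform is
#' only defined for strictly positive measurements.
#'
#' @param df feature table.
#' @param cols columns to transform.
#' @return The table with transformed columns.
#' @export
log_transform_features <- function(df, cols) {
  for (cl in cols) {
    v <- df[[cl]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      warning(sum(bad), " non-positive value(s) in `", cl,
              "` excluded from log transform", call. = FALSE)
      v[bad] <- NA_real_
    }
    df[[cl]] <- log(v)
  }
  df
}

#' Build a per-subject Romberg-quotient table from a two-condition
#' feature table
#'
#' Pairs each subject's eyes-open and eyes-closed rows and computes the
#' Romberg quotient for the peak-to-peak AP sway range (`rq_path`) and for
#' the AP mean sway velocity (`rq_velocity`). Subjects missing either
#' condition are dropped with a message.
#'
#' @param features feature table from [extract_features()] containing both
#'   conditions per subject.
#' @return `data.frame` with `subject_id`, `sex`, `age`, `rq_path`,
#'   `rq_velocity`.
#' @export
romberg_table <- function(features) {
  eo <- features[features$condition == "eyes_open", ]
  ec <- features[features$condition == "eyes_closed", ]
  common <- intersect(eo$subject_id, ec$subject_id)
  dropped <- setdiff(unique(features$subject_id), common)
  if (length(dropped))
    message(length(dropped), " subject(s) missing a condition, excluded")
  eo <- eo[match(common, eo$subject_id), ]
  ec <- ec[match(common, ec$subject_id), ]
  data.frame(subject_id = common, sex = ec$sex, age = ec$age,
             rq_path = romberg_quotient(ec$ap_pp, eo$ap_pp),
             rq_velocity = romberg_quotient(ec$ap_mean_velocity,
                                            eo$ap_mean_velocity),
             stringsAsFactors = FALSE)
}
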