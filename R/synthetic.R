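#' Simulation parameters for a synthetic sway recording
#'
#' The generator embodies the three postural-control strategies the feature
#' set probes. Positional control: each CPF axis follows a mean-reverting
#' (Ornstein-Uhlenbeck) process with stationary scale `sigma` (cm) and
#' relaxation time `tau` (s), smoothed by a Gaussian kernel so that the
#' short-term regime is persistent — this produces the biphasic diffusion
#' curve with a critical time near `tau`. Torque control: the moment
#' channels couple to the (further smoothed) sway through an inverted-
#' pendulum gain, `moment = moment_gain * mass * g * position`. Anticipatory
#' control: a two-state quiet/active Markov gate injects corrective control
#' noise into the moments only during active phases, creating the
#' steady-phase structure ST(N) measures. Small in-band sensor/tremor noise
#' on the position channels sets the zero-crossing rates.
#'
#' @param sigma_x,sigma_y stationary sway scale per axis, cm.
#' @param tau_x,tau_y mean-reversion relaxation times, s.
#' @param smooth_x,smooth_y Gaussian smoothing kernel SD, s (short-term
#'   persistence of each axis).
#' @param noise_x,noise_y in-band sensor/tremor noise SD, cm.
#' @param moment_gain pendulum coupling, N·m per kg per cm of displacement
#'   (the gravitational constant is folded in by the simulator).
#' @param moment_smooth smoothing SD of the moment-coupled sway copy, s.
#' @param control_noise corrective-moment white-noise scale during active
#'   phases, N·m per kg.
#' @param quiet_rate,active_rate Markov transition rates, per second:
#'   `quiet_rate` is the active-to-quiet rate, `active_rate` the
#'   quiet-to-active rate; the stationary quiet fraction is
#'   `quiet_rate / (quiet_rate + active_rate)`.
#' @param visual_gain eyes-closed / eyes-open sway-scale ratio; eyes-open
#'   traces are generated with `sigma / visual_gain`, giving Romberg
#'   quotients above 1.
#' @param breath_amp,breath_freq,weight_noise weight-channel model: a slow
#'   respiratory oscillation (amplitude in weight units, frequency in Hz)
#'   plus white sensor noise. Sized so the cohort quartile statistic behind
#'   the steady-phase threshold lands near 0.002.
#' @param mass body mass, kg.
#' @param fs sampling rate, Hz.
#' @param duration recording length, s (>= 27 for full-pipeline use).
#' @param seed integer seed; every recording is bit-reproducible from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sigma_x = 0.05, sigma_y = 0.07,
                       tau_x = 1.0, tau_y = 1.0,
                       smooth_x = 0.05, smooth_y = 0.06,
                       noise_x = 0.004, noise_y = 0.002,
                       moment_gain = 6, moment_smooth = 0.35,
                       control_noise = 0.25,
                       quiet_rate = 1.05, active_rate = 1.95,
                       visual_gain = 1.3,
                       breath_amp = 1.5, breath_freq = 0.24,
                       weight_noise = 0.04,
                       mass = 70, fs = 50, duration = 30, seed = 1L) {
  p <- list(sigma_x = sigma_x, sigma_y = sigma_y, tau_x = tau_x,
            tau_y = tau_y, smooth_x = smooth_x, smooth_y = smooth_y,
            noise_x = noise_x, noise_y = noise_y,
            moment_gain = moment_gain, moment_smooth = moment_smooth,
            control_noise = control_noise, quiet_rate = quiet_rate,
            active_rate = active_rate, visual_gain = visual_gain,
            breath_amp = breath_amp, breath_freq = breath_freq,
            weight_noise = weight_noise, mass = mass, fs = fs,
            duration = duration, seed = as.integer(seed))
  num <- p[setdiff(names(p), "seed")]
  if (any(!vapply(num, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), TRUE)))
    stop("parameter error: all parameters must be finite scalars",
         call. = FALSE)
  if (any(unlist(num[c("sigma_x", "sigma_y", "noise_x", "noise_y",
                       "control_noise", "quiet_rate", "active_rate")]) < 0))
    stop("parameter error: scales and rates must be >= 0", call. = FALSE)
  if (p$tau_x <= 0 || p$tau_y <= 0 || p$mass <= 0 || p$fs <= 0)
    stop("parameter error: tau, mass and fs must be positive", call. = FALSE)
  structure(p, class = "sim_params")
}

#' Replace fields of a `sim_params` object
#' @noRd
update_params <- function(params, ...) {
  upd <- list(...)
  params[names(upd)] <- upd
  do.call(sim_params, unclass(params))
}

# Gaussian kernel smoothing with reflection padding; sd in seconds
gauss_smooth <- function(x, sd_s, fs) {
  if (sd_s <= 0) return(x)
  sd_n <- sd_s * fs
  h <- max(1L, ceiling(4 * sd_n))
  k <- stats::dnorm(-h:h, 0, sd_n)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[(n - h):(n - 1L)]))
  as.numeric(stats::filter(xp, k, sides = 2))[(h + 1L):(h + n)]
}

# Exact-discretization Ornstein-Uhlenbeck sample path, stationary start
ou_path <- function(n, tau, sigma, dt) {
  if (sigma == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  innov <- rnorm(n, 0, sigma * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1L] <- rnorm(1, 0, sigma)
  for (i in 2:n) x[i] <- phi * x[i - 1L] + innov[i]
  x
}

#' Simulate one raw stabilogram recording
#'
#' Generates a 30 s, 50 Hz raw recording (CPF positions, moments, weight)
#' from a [sim_params()] specification. Identical seeds give bit-identical
#' channels. Eyes-open recordings shrink the positional scales by
#' `visual_gain`.
#'
#' @param params a `sim_params` object.
#' @param condition "eyes_closed" (default) or "eyes_open".
#' @param meta optional extra metadata fields (subject_id, sex, age)
#'   merged into the recording's metadata.
#' @return A raw `stabilogram` (pass through [preprocess_recording()]
#'   before feature extraction).
#' @export
simulate_cpf <- function(params, condition = c("eyes_closed", "eyes_open"),
                         meta = list()) {
  stopifnot(inherits(params, "sim_params"))
  condition <- match.arg(condition)
  p <- params
  vg <- if (condition == "eyes_open") p$visual_gain else 1
  n <- round(p$duration * p$fs)
  dt <- 1 / p$fs
  with_seed(p$seed, {
    x_core <- gauss_smooth(ou_path(n, p$tau_x, p$sigma_x / vg, dt),
                           p$smooth_x, p$fs)
    y_core <- gauss_smooth(ou_path(n, p$tau_y, p$sigma_y / vg, dt),
                           p$smooth_y, p$fs)
    cpf_x <- x_core + rnorm(n, 0, p$noise_x)
    cpf_y <- y_core + rnorm(n, 0, p$noise_y)
    # quiet/active anticipatory gate (TRUE = quiet)
    pq <- p$quiet_rate / (p$quiet_rate + p$active_rate)
    gate <- logical(n)
    gate[1L] <- runif(1) < pq
    u <- runif(n)
    for (i in 2:n)
      gate[i] <- if (gate[i - 1L]) u[i] > p$active_rate * dt
                 else u[i] < p$quiet_rate * dt
    active <- !gate
    gain <- p$moment_gain * p$mass * .g / 100  # per cm, g folded in
    moment_x <- gain * gauss_smooth(x_core, p$moment_smooth, p$fs) +
      active * p$control_noise * p$mass * rnorm(n)
    moment_y <- gain * gauss_smooth(y_core, p$moment_smooth, p$fs) +
      active * p$control_noise * p$mass * rnorm(n)
    weight <- p$mass * .g +
      p$breath_amp * sin(2 * pi * p$breath_freq * (0:(n - 1)) * dt +
                         runif(1, 0, 2 * pi)) +
      rnorm(n, 0, p$weight_noise)
    stabilogram(fs = p$fs, cpf_x = cpf_x, cpf_y = cpf_y,
                moment_x = moment_x, moment_y = moment_y, weight = weight,
                meta = c(meta, list(mass = p$mass, condition = condition)))
  })
}

#' Default per-group calibration targets and sizes for the synthetic cohort
#'
#' Mean feature values (C(Y) cm, M(MY), ZCR(Y), ZCR(VX), CRI(T) s, ST(N))
#' and group sizes for community-dwelling adults aged 65+, stratified by sex
#' and five age bins. These are the targets the cohort generator is
#' calibrated against and the default group sizes it emits.
#'
#' @return `data.frame` with columns `sex`, `age_group`, `n`, `cy`, `m_my`,
#'   `zcr_y`, `zcr_vx`, `cri_t`, `st_n`.
#' @export
default_cohort_spec <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 5),
    age_group = rep(c("65-69", "70-74", "75-79", "80-84", "85+"), 2),
    n = c(176, 588, 590, 431, 140,
          318, 809, 760, 594, 182),
    cy = c(0.23, 0.30, 0.35, 0.40, 0.49,
           0.23, 0.26, 0.29, 0.36, 0.41),
    m_my = c(0.43, 0.47, 0.48, 0.49, 0.53,
             0.32, 0.32, 0.33, 0.36, 0.36),
    zcr_y = c(14.8, 17.7, 18.7, 19.7, 22.1,
              15.7, 17.3, 17.7, 19.4, 22.1),
    zcr_vx = c(87, 140, 131, 124, 123,
               148, 165, 158, 145, 167),
    cri_t = c(1.03, 0.97, 0.91, 0.92, 0.83,
              1.10, 1.10, 1.00, 0.93, 0.96),
    st_n = c(141, 81, 83, 82, 66,
             225, 183, 182, 162, 146),
    stringsAsFactors = FALSE)
}

# Mean extracted features over n_rep fresh-seed recordings
eval_params <- function(params, seeds, kernel = 5L, design = NULL) {
  if (is.null(design)) design <- design_lowpass(params$fs)
  rows <- lapply(seeds, function(s) {
    rec <- simulate_cpf(update_params(params, seed = s))
    extract_features(preprocess_recording(rec, kernel, design = design))
  })
  ft <- do.call(rbind, rows)
  c(cy = mean(ft$cy), m_my = mean(ft$m_my),
    zcr_y = mean(ft$zcr_y), zcr_vx = mean(ft$zcr_vx),
    cri_t = mean(ft$cri_t, na.rm = TRUE), st_n = mean(ft$st_n))
}

clip <- function(x, lo, hi) min(max(x, lo), hi)

#' Calibrate simulator parameters against target feature means
#'
#' Coordinate-descent search: each feature target is steered by one
#' dedicated, monotone parameter (C(Y) by `sigma_y`, CRI(T) by the
#' relaxation times, M(MY) by `moment_gain`, ST(N) by the quiet-state
#' occupancy, ZCR(Y)/ZCR(VX) by the in-band position noise on each axis,
#' falling back to the smoothing kernels when a noise knob hits its floor).
#' Damped multiplicative updates are applied in the priority order
#' C(Y), CRI(T), M(MY), ST(N), ZCRs until the mean extracted features over
#' fresh replicates sit within the relative tolerance of every target.
#'
#' @param targets named vector/list with `cy`, `m_my`, `zcr_y`, `zcr_vx`,
#'   `cri_t`, `st_n`.
#' @param init starting `sim_params`; default [sim_params()].
#' @param n_rep replicates per evaluation; default 40.
#' @param max_iter iteration cap; default 20.
#' @param tol relative tolerance on every feature; default 0.1.
#' @param seed master seed for the calibration replicates.
#' @param verbose print per-iteration residuals.
#' @return List with `params` (calibrated `sim_params`), `achieved` (mean
#'   features at the final evaluation), `residuals` (relative errors),
#'   `iterations`, `converged`. On non-convergence a classed error
#'   (`posturo_calibration_error`) is signalled carrying the best-so-far
#'   result in its `result` field.
#' @export
calibrate_group <- function(targets, init = sim_params(), n_rep = 40L,
                            max_iter = 20L, tol = 0.1, seed = 1L,
                            verbose = FALSE) {
  tg <- unlist(targets[c("cy", "m_my", "zcr_y", "zcr_vx", "cri_t", "st_n")])
  if (any(is.na(tg))) stop("calibration error: incomplete targets",
                           call. = FALSE)
  design <- design_lowpass(init$fs)
  params <- init
  seed_mat <- matrix(derive_seeds(seed, 2L * n_rep * max_iter),
                     ncol = 2L * max_iter)
  best <- NULL
  achieved <- NULL
  for (it in seq_len(max_iter)) {
    achieved <- eval_params(params, seed_mat[, 2L * it - 1L],
                            design = design)
    rel <- (achieved - tg) / tg
    if (max(abs(rel)) <= 0.65 * tol) {
      # confirm on an independent batch before accepting: guards against
      # batch noise in the high-variance features (notably st_n)
      conf <- eval_params(params, seed_mat[, 2L * it], design = design)
      achieved <- (achieved + conf) / 2
      rel <- (achieved - tg) / tg
      confirmed <- TRUE
    } else confirmed <- FALSE
    if (verbose)
      message("iter ", it, ": ",
              paste(sprintf("%s=%+.2f", names(rel), rel), collapse = " "))
    if (is.null(best) || max(abs(rel)) < best$err)
      best <- list(err = max(abs(rel)), params = params,
                   achieved = achieved, residuals = rel, iterations = it)
    if (confirmed && max(abs(rel)) <= 0.65 * tol) {
      return(list(params = params, achieved = achieved, residuals = rel,
                  iterations = it, converged = TRUE))
    }
    damp <- 0.7
    f <- function(k) (tg[[k]] / achieved[[k]])^damp
    # priority order: cy -> cri_t -> m_my -> st_n -> zcr
    params <- update_params(params,
      sigma_y = clip(params$sigma_y * f("cy"), 1e-3, 2),
      sigma_x = clip(params$sigma_x * f("cy"), 1e-3, 2))
    tau_new <- clip(params$tau_y * f("cri_t"), 0.2, 4)
    params <- update_params(params, tau_y = tau_new, tau_x = tau_new)
    params <- update_params(params,
      moment_gain = clip(params$moment_gain * f("m_my"), 0.1, 100))
    rt <- params$quiet_rate + params$active_rate  # dwell scale is fixed
    pq <- params$quiet_rate / rt
    pq <- clip(pq * f("st_n"), 0.02, 0.95)
    params <- update_params(params, quiet_rate = pq * rt,
                            active_rate = (1 - pq) * rt)
    for (ax in c("y", "x")) {
      nk <- paste0("noise_", ax); sk <- paste0("smooth_", ax)
      zk <- if (ax == "y") "zcr_y" else "zcr_vx"
      fz <- (tg[[zk]] / achieved[[zk]])
      nn <- clip(params[[nk]] * fz^1.5, 1e-4, 0.08)
      upd <- setNames(list(nn), nk)
      if (nn <= 1.1e-4 && fz < 0.95)  # noise floor: widen smoothing instead
        upd[[sk]] <- clip(params[[sk]] * 1.3, 0.01, 0.3)
      params <- do.call(update_params, c(list(params), upd))
    }
  }
  res <- list(params = best$params, achieved = best$achieved,
              residuals = best$residuals, iterations = best$iterations,
              converged = FALSE)
  cond <- structure(
    class = c("posturo_calibration_error", "error", "condition"),
    list(message = sprintf(
           "calibration did not reach tolerance %.2f (best max residual %.3f)",
           tol, best$err),
         call = sys.call(-1), result = res))
  stop(cond)
}

#' Generate a full synthetic cohort
#'
#' For each group in the spec, draws `n` subjects with log-normal
#' per-subject jitter around the group's calibrated parameters, ages uniform
#' within the group's bin (the open-ended bin draws from 85-95), sex-typical
#' masses, and simulates recordings under the requested visual conditions.
#' Per-subject seeds derive deterministically from `master_seed`, so the
#' cohort is fully reproducible.
#'
#' @param spec cohort spec `data.frame` as from [default_cohort_spec()]
#'   (columns `sex`, `age_group`, `n`, and the six feature targets).
#' @param master_seed integer seed.
#' @param calibrations optional named list of calibrated `sim_params`, keyed
#'   `"<sex>.<age_group>"`; groups without an entry are calibrated on the
#'   fly (expensive).
#' @param conditions which visual conditions to simulate.
#' @param jitter_cv coefficient of variation of the log-normal per-subject
#'   parameter jitter; default 0.15.
#' @param extract if `TRUE` (default) extract features per recording and
#'   return a feature table; if `FALSE` return the raw recordings.
#' @param n_rep,max_iter,tol passed to [calibrate_group()] when a group
#'   needs on-the-fly calibration.
#' @return If `extract`, a `data.frame` of per-recording features with
#'   metadata columns (including `age_group`); otherwise a list of raw
#'   `stabilogram`s plus a metadata table.
#' @export
generate_cohort <- function(spec, master_seed = 1L, calibrations = NULL,
                            conditions = c("eyes_closed", "eyes_open"),
                            jitter_cv = 0.15, extract = TRUE,
                            n_rep = 40L, max_iter = 20L, tol = 0.1) {
  if (nrow(spec) == 0L)
    return(if (extract) data.frame() else list(recordings = list(),
                                               metadata = data.frame()))
  if (is.null(spec$n) || any(spec$n < 0))
    stop("spec error: each group needs a non-negative size `n`",
         call. = FALSE)
  design <- design_lowpass(50)
  meta <- cohort_metadata(spec, master_seed)
  group_seeds <- derive_seeds(master_seed + 1L, nrow(spec))
  subj_seeds <- matrix(derive_seeds(master_seed + 2L,
                                    2L * nrow(meta)), ncol = 2L)
  out_rows <- list()
  recs <- list()
  for (gi in seq_len(nrow(spec))) {
    g <- spec[gi, ]
    if (g$n == 0L) next
    key <- paste(g$sex, g$age_group, sep = ".")
    if (!is.null(calibrations) && !is.null(calibrations[[key]])) {
      gp <- calibrations[[key]]
    } else {
      if (any(is.na(g[c("cy", "m_my", "zcr_y", "zcr_vx", "cri_t", "st_n")])))
        stop("spec error: group ", key, " has no targets", call. = FALSE)
      gp <- calibrate_group(as.list(g), n_rep = n_rep, max_iter = max_iter,
                            tol = tol, seed = group_seeds[gi])$params
    }
    rows <- which(meta$group_index == gi)
    for (ri in rows) {
      jit <- with_seed(subj_seeds[ri, 1L],
                       exp(rnorm(6, -log(1 + jitter_cv^2) / 2,
                                 sqrt(log(1 + jitter_cv^2)))))
      sp <- update_params(gp,
        sigma_x = gp$sigma_x * jit[1], sigma_y = gp$sigma_y * jit[2],
        tau_x = gp$tau_x * jit[3], tau_y = gp$tau_y * jit[3],
        moment_gain = gp$moment_gain * jit[4],
        control_noise = gp$control_noise * jit[5],
        noise_x = gp$noise_x * jit[6], noise_y = gp$noise_y * jit[6],
        mass = meta$mass[ri], seed = subj_seeds[ri, 2L])
      for (cond in conditions) {
        sp_c <- update_params(sp, seed = subj_seeds[ri, 2L] +
                                (cond == "eyes_open"))
        rec <- simulate_cpf(sp_c, condition = cond,
                            meta = list(subject_id = meta$subject_id[ri],
                                        sex = meta$sex[ri],
                                        age = meta$age[ri]))
        if (extract) {
          fv <- extract_features(preprocess_recording(rec, design = design))
          fv$age_group <- g$age_group
          out_rows[[length(out_rows) + 1L]] <- fv
        } else {
          recs[[length(recs) + 1L]] <- rec
        }
      }
    }
  }
  if (extract) do.call(rbind, out_rows)
  else list(recordings = recs, metadata = meta)
}

#' Generate cohort subject metadata only
#'
#' Draws the subject table (ids, sex, age within bin, mass) for a cohort
#' spec without simulating any signals — the cheap input for balancing and
#' fold-structure work at full cohort scale.
#'
#' @param spec cohort spec `data.frame` (`sex`, `age_group`, `n`).
#' @param seed integer seed.
#' @return `data.frame` with `subject_id`, `sex`, `age`, `age_group`,
#'   `mass`, `group_index`.
#' @export
cohort_metadata <- function(spec, seed = 1L) {
  if (nrow(spec) == 0L) return(data.frame())
  bins <- list("65-69" = c(65, 69), "70-74" = c(70, 74),
               "75-79" = c(75, 79), "80-84" = c(80, 84),
               "85+" = c(85, 95))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(gi) {
      g <- spec[gi, ]
      if (g$n == 0L) return(NULL)
      b <- bins[[g$age_group]]
      if (is.null(b)) stop("spec error: unknown age group ", g$age_group,
                           call. = FALSE)
      mmu <- if (g$sex == "male") 80 else 67
      data.frame(sex = g$sex,
                 age = sample(b[1]:b[2], g$n, replace = TRUE),
                 age_group = g$age_group,
                 mass = round(pmax(40, rnorm(g$n, mmu, 10)), 1),
                 group_index = gi, stringsAsFactors = FALSE)
    })
    meta <- do.call(rbind, rows)
    meta$subject_id <- sprintf("S%05d", seq_len(nrow(meta)))
    meta[c("subject_id", "sex", "age", "age_group", "mass", "group_index")]
  })
}
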