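#' Construct a stabilogram recording object
#'
#' @param fs sampling rate, Hz.
#' @param cpf_x,cpf_y mediolateral / anteroposterior CPF position, cm.
#' @param moment_x,moment_y moments about the mediolateral / anteroposterior
#'   platform axes, N·m; may be `NULL` when the platform exports positions
#'   only (the recording is then flagged feature-limited).
#' @param weight vertical force channel (raw scale); may be `NULL`.
#' @param meta named list of subject metadata: `subject_id`, `sex`
#'   ("male"/"female"), `age` (years), `mass` (kg), `condition`
#'   ("eyes_open"/"eyes_closed").
#' @return An object of class `stabilogram`.
#' @export
stabilogram <- function(fs, cpf_x, cpf_y, moment_x = NULL, moment_y = NULL,
                        weight = NULL, meta = list()) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  chans <- list(cpf_x = cpf_x, cpf_y = cpf_y, moment_x = moment_x,
                moment_y = moment_y, weight = weight)
  lens <- vapply(chans[!vapply(chans, is.null, TRUE)], length, 0L)
  if (length(unique(lens)) != 1L)
    stop("format error: channels have unequal lengths (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  if (!is.null(meta$mass) && meta$mass <= 0)
    stop("`mass` must be positive", call. = FALSE)
  structure(list(fs = fs, cpf_x = as.numeric(cpf_x), cpf_y = as.numeric(cpf_y),
                 moment_x = if (is.null(moment_x)) NULL else as.numeric(moment_x),
                 moment_y = if (is.null(moment_y)) NULL else as.numeric(moment_y),
                 weight = if (is.null(weight)) NULL else as.numeric(weight),
                 weight_norm = NULL, meta = meta,
                 preprocessed = FALSE,
                 feature_limited = is.null(moment_x) || is.null(moment_y)),
            class = "stabilogram")
}

#' @export
print.stabilogram <- function(x, ...) {
  n <- length(x$cpf_x)
  cat(sprintf("<stabilogram> %d samples @ %g Hz (%.1f s)%s%s\n",
              n, x$fs, n / x$fs,
              if (x$preprocessed) ", preprocessed" else "",
              if (x$feature_limited) ", feature-limited (no moments)" else ""))
  if (length(x$meta))
    cat("  subject:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Read a raw stabilogram recording from delimited text
#'
#' Reads one row per sample from a CSV/TSV file. The schema maps file columns
#' to the required channels and carries subject metadata; it can be given as
#' a list or as the path to a JSON/YAML file with elements `columns` (named
#' list with entries `time`, `cpf_x`, `cpf_y`, and optionally `moment_x`,
#' `moment_y`, `weight`), `meta` (subject metadata) and optionally `fs`.
#' The sampling rate is taken from `schema$fs` if declared, otherwise
#' inferred as `1 / median(diff(time))`; a file without a time column and
#' without a declared rate is a configuration error.
#'
#' @param path path to the delimited file.
#' @param schema column-mapping configuration (list or path, see Details).
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma.
#' @return A `stabilogram` (not yet preprocessed). Recordings missing the
#'   moment channels are flagged `feature_limited`.
#' @export
read_recording <- function(path, schema, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  schema <- load_schema(schema)
  cols <- schema$columns
  if (is.null(cols$cpf_x) || is.null(cols$cpf_y))
    stop("config error: schema must map `cpf_x` and `cpf_y` columns",
         call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  dat <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  getcol <- function(nm) {
    if (is.null(nm)) return(NULL)
    if (!nm %in% names(dat))
      stop("format error: column `", nm, "` not found in ", path,
           call. = FALSE)
    as.numeric(dat[[nm]])
  }
  fs <- schema$fs
  if (!is.null(cols$time)) {
    tm <- getcol(cols$time)
    if (any(diff(tm) <= 0))
      stop("format error: time column is not strictly increasing",
           call. = FALSE)
    if (is.null(fs)) fs <- 1 / median(diff(tm))
  }
  if (is.null(fs))
    stop("config error: sampling rate neither declared in schema nor ",
         "derivable from a time column", call. = FALSE)
  stabilogram(fs = fs,
              cpf_x = getcol(cols$cpf_x), cpf_y = getcol(cols$cpf_y),
              moment_x = getcol(cols$moment_x),
              moment_y = getcol(cols$moment_y),
              weight = getcol(cols$weight),
              meta = schema$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L) {
    if (!file.exists(schema)) stop("schema file not found: ", schema,
                                   call. = FALSE)
    schema <- if (grepl("\\.ya?ml$", schema, ignore.case = TRUE))
      yaml::read_yaml(schema)
    else jsonlite::read_json(schema, simplifyVector = TRUE)
  }
  if (!is.list(schema)) stop("config error: schema must be a list or a path",
                             call. = FALSE)
  schema
}

#' Sliding median filter with reflection padding
#'
#' Removes short transient artifacts (1-2 sample spikes) before spectral
#' shaping. Output has the same length as the input; the ends are handled by
#' reflecting the signal about its first and last samples.
#'
#' @param x numeric sample series.
#' @param kernel odd window length, >= 3 and <= `length(x)`; default 5
#'   samples (0.1 s at 50 Hz).
#' @return Filtered series, same length as `x`.
#' @export
median_filter <- function(x, kernel = 5L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L == 0L || kernel < 3L)
    stop("parameter error: `kernel` must be an odd integer >= 3",
         call. = FALSE)
  n <- length(x)
  if (kernel > n) stop("parameter error: `kernel` exceeds signal length",
                       call. = FALSE)
  h <- kernel %/% 2L
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[(n - h):(n - 1L)]))
  # interior via the C running-median; edges come out right because the
  # series was reflection-padded before the call
  y <- stats::runmed(xp, kernel, endrule = "keep")
  as.numeric(y[(h + 1L):(h + n)])
}

#' Design an equiripple (Chebyshev-criterion) linear-phase low-pass FIR
#'
#' Parks-McClellan design meeting a printed passband-ripple / stopband-
#' attenuation specification. The order is searched upward from the Kaiser
#' estimate until the response, measured by direct discrete-time Fourier
#' summation over the taps on a dense grid, satisfies both constraints, so
#' the returned design is minimal-order among the attempted orders.
#'
#' @param fs sampling rate, Hz.
#' @param passband_edge,stopband_edge band edges, Hz; defaults 17 and 21.
#' @param max_ripple_db maximum passband deviation from unity, dB; default 1.
#' @param min_atten_db minimum stopband attenuation, dB; default 80.
#' @param grid_n number of frequencies per band used to verify the design.
#' @return An object of class `fir_design`: taps, group delay (samples),
#'   measured ripple and attenuation, and the design parameters.
#' @export
design_lowpass <- function(fs, passband_edge = 17, stopband_edge = 21,
                           max_ripple_db = 1, min_atten_db = 80,
                           grid_n = 4096) {
  if (!(0 < passband_edge && passband_edge < stopband_edge &&
        stopband_edge < fs / 2))
    stop("design error: need 0 < passband < stopband < fs/2", call. = FALSE)
  dp <- 1 - 10^(-max_ripple_db / 20)
  ds <- 10^(-min_atten_db / 20)
  # Kaiser order estimate for the transition width
  dfrac <- (stopband_edge - passband_edge) / fs
  n0 <- ceiling((min_atten_db - 7.95) / (14.36 * dfrac))
  n0 <- max(10L, as.integer(n0) - 10L)
  if (n0 %% 2L == 1L) n0 <- n0 + 1L  # even order -> odd length, integer delay
  fgrid_p <- seq(0, passband_edge, length.out = grid_n)
  fgrid_s <- seq(stopband_edge, fs / 2, length.out = grid_n)
  for (ord in seq(n0, n0 + 120L, by = 2L)) {
    taps <- signal::remez(ord,
                          c(0, passband_edge, stopband_edge, fs / 2) / (fs / 2),
                          c(1, 1, 0, 0), w = c(1, dp / ds))
    hp <- fir_response(taps, fgrid_p, fs)
    hs <- fir_response(taps, fgrid_s, fs)
    ripple <- max(abs(20 * log10(hp)))
    atten <- min(-20 * log10(pmax(hs, .Machine$double.xmin)))
    if (ripple <= max_ripple_db && atten >= min_atten_db) {
      return(structure(list(taps = as.numeric(taps), order = ord,
                            group_delay = ord %/% 2L,
                            fs = fs, passband_edge = passband_edge,
                            stopband_edge = stopband_edge,
                            max_ripple_db = max_ripple_db,
                            min_atten_db = min_atten_db,
                            measured_ripple_db = ripple,
                            measured_atten_db = atten),
                       class = "fir_design"))
    }
  }
  stop("design error: specification infeasible within attempted orders",
       call. = FALSE)
}

#' Magnitude response of an FIR tap sequence
#'
#' Direct discrete-time Fourier summation over the taps; used both to verify
#' designs and as an independent check in tests.
#' @param taps FIR coefficients.
#' @param f frequencies, Hz.
#' @param fs sampling rate, Hz.
#' @return |H(f)| at each frequency.
#' @export
fir_response <- function(taps, f, fs) {
  k <- seq_along(taps) - 1
  vapply(f, function(ff) Mod(sum(taps * exp(-1i * 2 * pi * ff * k / fs))), 0)
}

#' @export
print.fir_design <- function(x, ...) {
  cat(sprintf(paste0("<fir_design> order %d (%d taps), fs=%g Hz, ",
                     "pass %g Hz / stop %g Hz\n",
                     "  measured ripple %.4f dB (spec <= %g), ",
                     "attenuation %.1f dB (spec >= %g)\n"),
              x$order, length(x$taps), x$fs, x$passband_edge,
              x$stopband_edge, x$measured_ripple_db, x$max_ripple_db,
              x$measured_atten_db, x$min_atten_db))
  invisible(x)
}

#' Apply a linear-phase FIR filter with group-delay compensation
#'
#' Single forward convolution pass; the integer group delay of the
#' symmetric-tap design is removed by shifting, so the output is
#' time-aligned with the input and has the same length. The first and last
#' `group_delay` samples carry zero-padding edge effects; in the standard
#' pipeline these fall inside the trimmed transient.
#'
#' @param x numeric sample series, longer than the tap sequence.
#' @param design a `fir_design` (or any list with `taps` and `group_delay`).
#' @return Filtered, delay-compensated series of the same length.
#' @export
apply_fir <- function(x, design) {
  taps <- design$taps
  if (length(x) <= length(taps))
    stop("input error: signal shorter than the filter", call. = FALSE)
  d <- design$group_delay
  y <- stats::convolve(x, rev(taps), type = "open")  # length n + L - 1
  as.numeric(y[(d + 1L):(d + length(x))])
}

#' Discard the initial stance transient
#'
#' Subjects re-adjust their stance after stepping onto the platform, so the
#' first 15 s of every recording are excluded; exactly 12 s are retained
#' (600 samples at 50 Hz).
#'
#' @param rec a `stabilogram`.
#' @param skip_s seconds discarded at the start; default 15.
#' @param keep_s seconds retained; default 12.
#' @return The trimmed `stabilogram`.
#' @export
trim_transient <- function(rec, skip_s = 15, keep_s = 12) {
  stopifnot(inherits(rec, "stabilogram"))
  n <- length(rec$cpf_x)
  skip <- round(skip_s * rec$fs)
  keep <- round(keep_s * rec$fs)
  if (n < skip + keep)
    stop(sprintf(paste0("input error: recording too short: need %.1f s ",
                        "(%d samples), have %.2f s (%d samples)"),
                 skip_s + keep_s, skip + keep, n / rec$fs, n), call. = FALSE)
  idx <- (skip + 1L):(skip + keep)
  for (ch in c("cpf_x", "cpf_y", "moment_x", "moment_y", "weight"))
    if (!is.null(rec[[ch]])) rec[[ch]] <- rec[[ch]][idx]
  rec
}

#' Remove the mean of the positional channels
#'
#' @param rec a `stabilogram` (normally already trimmed).
#' @return The recording with `cpf_x` and `cpf_y` centered; moments and
#'   weight are left untouched.
#' @export
center_positions <- function(rec) {
  stopifnot(inherits(rec, "stabilogram"))
  rec$cpf_x <- rec$cpf_x - mean(rec$cpf_x)
  rec$cpf_y <- rec$cpf_y - mean(rec$cpf_y)
  rec
}

#' Standardize a weight signal to mean 0, variance 1
#'
#' The normalized copy feeds the steady-phase threshold derivation; moment
#' computations keep using the filtered, un-normalized weight.
#'
#' @param weight numeric series with positive variance.
#' @return Z-scored series (mean 0, variance 1).
#' @export
normalize_weight <- function(weight) {
  s <- sd(weight)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: weight signal has zero variance", call. = FALSE)
  (weight - mean(weight)) / s
}

#' Full signal-conditioning chain for a raw recording
#'
#' Applies, in order: sliding median filter (artifact removal), equiripple
#' low-pass FIR with group-delay compensation (noise shaping), transient
#' trimming to 600 samples, centering of the positional channels, and
#' z-scoring of the weight channel (kept as a separate `weight_norm` copy;
#' `weight` itself stays on the filtered raw scale for moment work).
#'
#' @param rec a raw `stabilogram` of at least 27 s.
#' @param kernel median-filter window, odd; default 5.
#' @param lowpass logical; apply the FIR low-pass (default `TRUE`).
#' @param design optional pre-built `fir_design`; one is designed from the
#'   recording's sampling rate when omitted.
#' @return The preprocessed `stabilogram` with a `provenance` attribute
#'   recording the kernel, filter order and trim window.
#' @export
preprocess_recording <- function(rec, kernel = 5L, lowpass = TRUE,
                                 design = NULL) {
  stopifnot(inherits(rec, "stabilogram"))
  if (rec$preprocessed) return(rec)
  if (lowpass && is.null(design)) design <- design_lowpass(rec$fs)
  for (ch in c("cpf_x", "cpf_y", "moment_x", "moment_y", "weight")) {
    if (is.null(rec[[ch]])) next
    v <- median_filter(rec[[ch]], kernel)
    if (lowpass) v <- apply_fir(v, design)
    rec[[ch]] <- v
  }
  rec <- trim_transient(rec)
  rec <- center_positions(rec)
  if (!is.null(rec$weight)) rec$weight_norm <- normalize_weight(rec$weight)
  rec$preprocessed <- TRUE
  attr(rec, "provenance") <- list(
    kernel = as.integer(kernel),
    filter_order = if (lowpass) design$order else NA_integer_,
    trim = c(skip_s = 15, keep_s = 12),
    n_out = length(rec$cpf_x))
  rec
}
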