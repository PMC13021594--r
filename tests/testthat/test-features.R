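test_that("amplitude range matches the percentile oracle", {
  expect_equal(amplitude_range(rep(1.5, 100)), 0)
  u <- seq(0, 1, length.out = 600)
  expect_equal(amplitude_range(u), 0.95)
  set.seed(4)
  y <- rnorm(600, sd = 0.4)
  s <- sort(y)   # brute-force interpolated percentile from the sorted copy
  pct <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  expect_equal(amplitude_range(y), pct(0.975) - pct(0.025))
  expect_error(amplitude_range(numeric(0)), "empty")
  expect_error(amplitude_range(rnorm(10)), "40")
})

test_that("mass-normalized moment is mean(|my|)/mass", {
  expect_equal(mean_abs_moment(rep(0, 100), 70), 0)
  expect_equal(mean_abs_moment(rep(c(6, -6), 50), 60), 0.1)
  set.seed(5)
  my <- rnorm(600, sd = 3)
  acc <- 0
  for (v in my) acc <- acc + abs(v)
  expect_equal(mean_abs_moment(my, 72.5), acc / 600 / 72.5)
  expect_error(mean_abs_moment(my, 0), "positive")
  expect_error(mean_abs_moment(my, -5), "positive")
})

test_that("zero crossings count strict sign changes with zero inheritance", {
  expect_identical(zero_crossings(rep(2, 50)), 0L)
  expect_equal(zero_crossings(rep(c(1, -1), 300)), 599)
  expect_identical(zero_crossings(rep(0, 100)), 0L)
  # touch-and-return is one event, not two
  expect_equal(zero_crossings(c(1, 0, 1, -1)), 1)
  expect_equal(zero_crossings(c(1, 0, -1)), 1)
  t <- (0:599) / 50
  # grid hits exact zeros at t = 0, 0.5, ...; the oracle counts 23
  expect_equal(zero_crossings(sin(2 * pi * t)), 23)
  # offset phase avoids grid zeros: 2 crossings per cycle x 12 cycles
  expect_equal(zero_crossings(sin(2 * pi * t + 0.3)), 24)
  # independent sign-change oracle on random data
  zc_oracle <- function(x) {
    last <- 0; cnt <- 0L
    for (v in x) {
      s <- sign(v)
      if (s == 0) next
      if (last != 0 && s != last) cnt <- cnt + 1L
      last <- s
    }
    cnt
  }
  set.seed(6)
  for (rep in 1:5) {
    x <- rnorm(400)
    expect_identical(zero_crossings(x), zc_oracle(x))
  }
})

test_that("central-difference velocity is second-order accurate", {
  expect_equal(sway_velocity(rep(1, 100), 50), rep(0, 100))
  ramp <- 2 * (0:99) / 50
  expect_equal(sway_velocity(ramp, 50), rep(2, 100))
  t <- (0:599) / 50
  f <- 1.5
  v <- sway_velocity(sin(2 * pi * f * t), 50)
  expect_equal(v[10:590], 2 * pi * f * cos(2 * pi * f * t[10:590]),
               tolerance = (f / 50)^2 * 50)
  expect_error(sway_velocity(c(1, 2), 50), "3 samples")
})

test_that("velocity zero crossings count direction changes", {
  expect_identical(zcr_vx(seq(0, 3, length.out = 100), 50), 0L)
  t <- (0:599) / 50
  expect_equal(zcr_vx(sin(2 * pi * t + 0.3), 50), 24)  # 2 extrema per cycle
  set.seed(8)
  x <- cumsum(rnorm(300))
  expect_identical(zcr_vx(x, 50), zero_crossings(sway_velocity(x, 50)))
})

test_that("sway path and mean velocity follow the summed-increment oracle", {
  expect_equal(ap_sway_path(rep(1, 100), 50)$path, 0)
  r <- ap_sway_path(seq(0, 3, length.out = 600), 50)
  expect_equal(r$path, 3)
  expect_equal(r$mean_velocity, 0.25)
  set.seed(9)
  y <- rnorm(500)
  acc <- 0
  for (i in 2:500) acc <- acc + abs(y[i] - y[i - 1])
  expect_equal(ap_sway_path(y, 50)$path, acc)
})

test_that("Romberg quotient is eyes-closed over eyes-open", {
  expect_equal(romberg_quotient(1.4, 1.4), 1)
  expect_equal(romberg_quotient(2, 1), 2)
  ec <- c(1.2, 3, 0.5); eo <- c(0.6, 1.5, 2)
  expect_equal(romberg_quotient(ec, eo), ec / eo)
  expect_error(romberg_quotient(1, 0), "positive")
})

test_that("feature extraction is deterministic and handles the static limit", {
  p <- sim_params(seed = 33)
  f1 <- sim_features(p)
  f2 <- sim_features(p)
  expect_identical(f1, f2)

  still <- sim_params(sigma_x = 0, sigma_y = 0, noise_x = 0, noise_y = 0,
                      control_noise = 0, breath_amp = 0, seed = 1)
  rec <- preprocess_recording(simulate_cpf(still), design = fir50,
                              lowpass = FALSE)
  rec$weight_norm <- NULL  # weight noise only; irrelevant here
  fv <- extract_features(rec)
  expect_equal(fv$cy, 0)
  expect_identical(fv$zcr_y, 0L)
  expect_equal(fv$ap_path, 0)
  expect_true(fv$cri_degenerate)
  expect_identical(fv$st_n, 596L)  # everywhere steady minus 4 edge samples
})

test_that("features respect translation and scale symmetries", {
  p <- sim_params(seed = 44)
  rec <- simulate_cpf(p)
  shifted <- rec
  shifted$cpf_x <- shifted$cpf_x + 3.7
  shifted$cpf_y <- shifted$cpf_y - 1.2
  f0 <- extract_features(preprocess_recording(rec, design = fir50))
  f1 <- extract_features(preprocess_recording(shifted, design = fir50))
  expect_equal(f1, f0, tolerance = 1e-10)  # translation invariance

  scaled <- rec
  scaled$cpf_y <- scaled$cpf_y * 2
  f2 <- extract_features(preprocess_recording(scaled, design = fir50))
  expect_equal(f2$cy, 2 * f0$cy)           # cy scales linearly
  expect_identical(f2$zcr_y, f0$zcr_y)     # counts are scale-invariant
})

test_that("log transform excludes non-positive values with a warning", {
  df <- data.frame(cy = c(0.3, 0, 0.5), st_n = c(10, 20, -1))
  expect_warning(out <- log_transform_features(df, c("cy", "st_n")),
                 "non-positive")
  expect_true(is.na(out$cy[2]))
  expect_true(is.na(out$st_n[3]))
  expect_equal(out$cy[1], log(0.3))
})

test_that("romberg_table pairs conditions and drops incomplete subjects", {
  p <- sim_params(seed = 55)
  rows <- list()
  for (i in 1:3) {
    pi <- posturo:::update_params(p, seed = 100 + i)
    for (cond in c("eyes_closed", "eyes_open")) {
      fv <- sim_features(pi, condition = cond)
      fv$subject_id <- paste0("S", i)
      rows[[length(rows) + 1]] <- fv
    }
  }
  ft <- do.call(rbind, rows)
  rq <- romberg_table(ft)
  expect_equal(nrow(rq), 3)
  expect_true(all(rq$rq_path > 0))
  # dropping one condition loses the subject
  expect_message(rq2 <- romberg_table(ft[-2, ]), "missing a condition")
  expect_equal(nrow(rq2), 2)
})
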