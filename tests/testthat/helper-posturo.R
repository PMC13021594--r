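# Shared fixtures built in code. The FIR design is deterministic, so one
# instance serves every test file.
fir50 <- design_lowpass(50)

# Simulate -> preprocess -> one feature row, reusing the shared design.
sim_features <- function(params, condition = "eyes_closed", ...) {
  rec <- simulate_cpf(params, condition = condition)
  extract_features(preprocess_recording(rec, design = fir50), ...)
}

# Write a raw recording to a temporary TSV + schema pair and return paths.
write_fixture_tsv <- function(n = 1500, fs = 50, seed = 7,
                              time_col = TRUE, sep = "\t") {
  set.seed(seed)
  dat <- data.frame(
    time_s = (seq_len(n) - 1) / fs,
    cpf_x_cm = cumsum(rnorm(n, 0, 0.01)),
    cpf_y_cm = cumsum(rnorm(n, 0, 0.01)),
    mx_nm = rnorm(n), my_nm = rnorm(n),
    fz = 70 * 9.80665 + rnorm(n, 0, 0.1))
  if (!time_col) dat$time_s <- NULL
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  write.table(dat, path, sep = sep, row.names = FALSE, quote = FALSE)
  schema <- list(
    columns = list(time = if (time_col) "time_s" else NULL,
                   cpf_x = "cpf_x_cm", cpf_y = "cpf_y_cm",
                   moment_x = "mx_nm", moment_y = "my_nm", weight = "fz"),
    meta = list(subject_id = "T01", sex = "female", age = 72,
                mass = 70, condition = "eyes_closed"))
  list(path = path, schema = schema, data = dat)
}

# Feature table sampled directly at the feature level (no signal
# simulation) for the statistical-layer tests.
make_feature_table <- function(n_per_sex = 100, seed = 1, sex_shift = 0,
                               age_slope = 0) {
  set.seed(seed)
  n <- 2 * n_per_sex
  sex <- rep(c("male", "female"), each = n_per_sex)
  age <- sample(65:94, n, replace = TRUE)
  base <- function(mu, cv) exp(rnorm(n, log(mu), cv))
  shift <- ifelse(sex == "male", sex_shift, 0)
  data.frame(
    subject_id = sprintf("P%04d", seq_len(n)), sex = sex, age = age,
    cy = base(0.3, 0.3) * exp(shift + age_slope * (age - 75)),
    m_my = base(0.4, 0.3) * exp(shift),
    zcr_y = base(17, 0.2),
    zcr_vx = base(140, 0.2) * exp(-shift),
    cri_t = base(1.0, 0.25),
    st_n = base(150, 0.4) * exp(-shift),
    stringsAsFactors = FALSE)
}
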