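test_that("age stratification uses inclusive printed boundaries", {
  g <- stratify_age_groups(c(65, 69, 70, 74, 75, 80, 84, 85, 95))
  expect_identical(as.integer(g), c(1L, 1L, 2L, 2L, 3L, 4L, 4L, 5L, 5L))
  expect_identical(levels(g),
                   c("65-69", "70-74", "75-79", "80-84", "85+"))
  expect_error(stratify_age_groups(c(70, 64)), "out-of-range")
})

test_that("balancing matches female counts to male counts per stratum", {
  spec <- default_cohort_spec()
  meta <- cohort_metadata(spec, seed = 31)
  bal <- balance_by_age(meta, seed = 32)
  expect_equal(sum(bal$sex == "female"), sum(bal$sex == "male"))
  expect_equal(sum(bal$sex == "male"), 1925)
  g <- stratify_age_groups(bal$age)
  tab <- table(g, bal$sex)
  expect_equal(unname(tab[, "female"]), unname(tab[, "male"]))
  expect_identical(balance_by_age(meta, seed = 32), bal)  # seeded
  # an already balanced cohort is passed through whole
  ages <- rep(c(66, 71, 76, 81, 86), 4)
  eq <- data.frame(sex = rep(c("male", "female"), each = 20),
                   age = c(ages, ages))
  expect_equal(nrow(balance_by_age(eq, 1)), 40)
  # failure names the starved stratum
  bad <- data.frame(sex = c(rep("male", 5), "female"),
                    age = c(66, 66, 66, 66, 66, 67))
  expect_error(balance_by_age(bad, 1), "65-69")
})

test_that("interleaving alternates sexes and folds partition the pairs", {
  df <- data.frame(sex = rep(c("male", "female"), each = 25),
                   id = 1:50)
  fl <- interleave_and_fold(df, k = 10, seed = 41)
  expect_identical(fl$sex, rep(c("male", "female"), 25))
  expect_equal(sum(is.na(fl$fold)), 2 * (25 %% 10))  # 5 leftover pairs
  for (f in 1:10) {
    tf <- fl[!is.na(fl$fold) & fl$fold == f, ]
    expect_equal(sum(tf$sex == "male"), 2)
    expect_equal(sum(tf$sex == "female"), 2)
  }
  # disjoint and exhaustive over ids
  expect_setequal(fl$id, df$id)
  expect_identical(interleave_and_fold(df, k = 10, seed = 41)$id, fl$id)
  expect_error(interleave_and_fold(df[1:49, ], 10, 1), "equal male")

  # 20 + 20 subjects, k = 10 -> folds of exactly 2 pairs
  df2 <- data.frame(sex = rep(c("male", "female"), each = 20))
  fl2 <- interleave_and_fold(df2, k = 10, seed = 1)
  expect_true(all(table(fl2$fold) == 4))
  expect_equal(sum(is.na(fl2$fold)), 0)
})

test_that("a perfectly separating feature is classified almost perfectly", {
  df <- make_feature_table(100, seed = 51)
  df$m_my <- ifelse(df$sex == "male", 2, 0.5) * exp(rnorm(200, 0, 0.05))
  fl <- interleave_and_fold(df, k = 10, seed = 52)
  rep <- sex_classification_cv(fl)
  expect_gt(rep$mean_accuracy, 95)
  expect_equal(rep$mean_accuracy,
               100 * mean(rep$fold_accuracy))  # aggregation consistency
  expect_true(all(rep$fold_accuracy >= 0 & rep$fold_accuracy <= 1))
})

test_that("sex-informative synthetic features beat the permutation null", {
  df <- make_feature_table(150, seed = 53, sex_shift = 0.35)
  fl <- interleave_and_fold(df, k = 10, seed = 54)
  rep <- sex_classification_cv(fl)
  # binomial null at 50% over the pooled test predictions
  n_test <- sum(!is.na(fl$fold))
  expect_gt(rep$mean_accuracy / 100, 0.5 + 1.96 * sqrt(0.25 / n_test))
  # directional rates agree with the pooled confusion matrix
  expect_equal(rep$male_as_female,
               100 * rep$confusion["male", "female"] /
                 sum(rep$confusion["male", ]))
})

test_that("age prediction recovers exact and noisy linear structure", {
  df <- make_feature_table(300, seed = 61)
  df$age <- 75 + 8 * log(df$cy) - 3 * log(df$cri_t)
  rep <- age_prediction(df, features = c("cy", "cri_t"), seed = 62)
  for (sx in names(rep)) {
    expect_equal(rep[[sx]]$r_squared, 1, tolerance = 1e-9)
    expect_lt(rep[[sx]]$residual_sd_cv, 1e-6)
  }
  # known noise: CV residual SD close to the injected 5 years
  df$age <- df$age + rnorm(nrow(df), 0, 5)
  rep2 <- age_prediction(df, features = c("cy", "cri_t"), seed = 63)
  for (sx in names(rep2))
    expect_equal(rep2[[sx]]$residual_sd_cv, 5, tolerance = 0.5 / 5)
  # independent features: R^2 near zero, residual SD near sd(age)
  df3 <- make_feature_table(300, seed = 64)
  rep3 <- age_prediction(df3, seed = 65)
  for (sx in names(rep3)) {
    expect_lt(rep3[[sx]]$r_squared, 0.08)
    expect_equal(rep3[[sx]]$residual_sd_cv,
                 sd(df3$age[df3$sex == sx]), tolerance = 0.1)
  }
  # tree model runs and reports
  rep4 <- age_prediction(df3, model = "tree", seed = 66)
  expect_true(all(vapply(rep4, function(r) r$residual_sd_cv > 0, TRUE)))
})

test_that("rank-sum indicator tables flag shifted groups only", {
  df <- make_feature_table(300, seed = 71)
  tab <- group_difference_tests(df, "sex_within_age")
  expect_identical(dim(tab$indicator), c(5L, 6L))
  expect_identical(rownames(tab$indicator),
                   c("65-69", "70-74", "75-79", "80-84", "85+"))
  # no signal injected: indicators mostly zero
  expect_lt(mean(tab$indicator, na.rm = TRUE), 0.2)

  # 5-pooled-SD shift has essentially unit power at these sizes
  df2 <- make_feature_table(300, seed = 72)
  df2$cy[df2$sex == "male"] <- df2$cy[df2$sex == "male"] +
    5 * sd(df2$cy)
  tab2 <- group_difference_tests(df2, "sex_within_age")
  expect_true(all(tab2$indicator[, "cy"] == 1))
  expect_identical(tab2$indicator == 1, tab2$p_value < 0.05)

  # successive-age table shape
  df3 <- make_feature_table(300, seed = 73, age_slope = 0.08)
  tab3 <- group_difference_tests(df3, "successive_age", sex = "male")
  expect_identical(rownames(tab3$indicator),
                   c("(1-2)", "(2-3)", "(3-4)", "(4-5)"))
  expect_gte(sum(tab3$indicator[, "cy"]), 3)  # strong age trend detected
})

test_that("correlation table is symmetric with unit diagonal", {
  df <- make_feature_table(500, seed = 81, sex_shift = 0.3,
                           age_slope = 0.06)
  cm <- correlation_table(df)
  expect_identical(dim(cm), c(8L, 8L))
  expect_equal(unname(diag(cm)), rep(1, 8))
  expect_equal(cm, t(cm))
  expect_gt(cm["cy", "age"], 0)      # amplitude rises with age
  expect_lt(cm["m_my", "sex"], 0)    # female = 1 coding, males higher
  cdf <- df
  cdf$cri_t <- 1
  expect_warning(correlation_table(cdf), "constant")
})

test_that("null correlations stay small at scale", {
  set.seed(91)
  df <- data.frame(sex = rep(c("male", "female"), 1000),
                   age = sample(65:94, 2000, TRUE),
                   cy = rnorm(2000), m_my = rnorm(2000),
                   zcr_y = rnorm(2000), zcr_vx = rnorm(2000),
                   cri_t = rnorm(2000), st_n = rnorm(2000))
  cm <- correlation_table(df)
  off <- abs(cm[upper.tri(cm)])
  expect_gt(mean(off < 0.05), 0.9)
})

test_that("RQ battery behaves on constructed signal and null cases", {
  set.seed(95)
  n <- 400
  latent <- exp(rnorm(n, 0, 0.3))
  rq <- data.frame(
    subject_id = sprintf("R%03d", 1:n),
    sex = rep(c("male", "female"), each = n / 2),
    age = sample(65:94, n, TRUE),
    rq_path = latent * exp(rnorm(n, 0, 0.08)),
    rq_velocity = latent * exp(rnorm(n, 0, 0.08)))
  out <- rq_cohort_analysis(rq, seed = 96)
  expect_gt(out$rq_correlation, 0.9)  # shared latent drives both variants
  # no sex signal: logistic accuracy near chance
  expect_lt(abs(out$logistic_accuracy - 50), 3 * 100 * sqrt(0.25 / n))
  expect_true(all(vapply(out$anova, function(a) a[["p"]] >= 0, TRUE)))
  expect_gte(out$tree_age_accuracy, 0)
})
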