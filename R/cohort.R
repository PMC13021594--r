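#' Stratify ages into the five cohort age groups
#'
#' Bins: 65-69, 70-74, 75-79, 80-84, 85+ (inclusive boundaries, so 70 falls
#' in the second group and 85 in the fifth).
#'
#' @param ages integer/numeric ages in years, all >= 65.
#' @return Factor with the five bin labels; `as.integer()` gives the group
#'   number 1-5.
#' @export
stratify_age_groups <- function(ages) {
  if (any(is.na(ages)) || any(ages < 65))
    stop("out-of-range error: all ages must be >= 65", call. = FALSE)
  cut(ages, breaks = c(65, 70, 75, 80, 85, Inf), right = FALSE,
      labels = c("65-69", "70-74", "75-79", "80-84", "85+"))
}

#' Balance the sexes by matching the female age distribution to the males
#'
#' Within every age-group stratum a seeded random subset of females of the
#' same size as the male count is selected; all males are kept. The output
#' therefore has equal per-stratum and total sex counts.
#'
#' @param cohort `data.frame` with at least `sex` and `age` columns.
#' @param seed integer seed for the per-stratum sampling.
#' @return The balanced subset of `cohort` (row order: original order of
#'   the retained rows).
#' @export
balance_by_age <- function(cohort, seed = 1L) {
  grp <- stratify_age_groups(cohort$age)
  keep <- rep(FALSE, nrow(cohort))
  with_seed(seed, {
    for (g in levels(grp)) {
      m_idx <- which(grp == g & cohort$sex == "male")
      f_idx <- which(grp == g & cohort$sex == "female")
      if (length(f_idx) < length(m_idx))
        stop("balance error: stratum ", g, " has ", length(f_idx),
             " females for ", length(m_idx), " males", call. = FALSE)
      keep[m_idx] <- TRUE
      if (length(m_idx) > 0L)
        keep[f_idx[sample.int(length(f_idx), length(m_idx))]] <- TRUE
    }
  })
  cohort[keep, , drop = FALSE]
}

#' Alternating male/female matrix and 10-fold partition
#'
#' Shuffles each sex independently, pairs the i-th male with the i-th
#' female, and arranges the pairs as an alternating M,F,M,F... sequence.
#' The pairs are divided into `k` mutually exclusive folds of
#' `floor(n_pairs / k)` pairs; leftover pairs are permanently assigned to
#' training (fold `NA`), so every test fold holds exactly the same number of
#' males and females.
#'
#' @param balanced a sex-balanced `data.frame` with a `sex` column.
#' @param k number of folds; default 10.
#' @param seed integer seed for the within-sex shuffles.
#' @return `balanced` with added columns `pair_id`, `order` (position in
#'   the alternating sequence) and `fold` (1..k or `NA` for
#'   training-always), sorted by `order`.
#' @export
interleave_and_fold <- function(balanced, k = 10L, seed = 1L) {
  m <- which(balanced$sex == "male")
  f <- which(balanced$sex == "female")
  if (length(m) != length(f))
    stop("input error: need equal male and female counts (",
         length(m), " vs ", length(f), ")", call. = FALSE)
  n_pairs <- length(m)
  with_seed(seed, {
    m <- sample(m)
    f <- sample(f)
  })
  per_fold <- n_pairs %/% k
  if (per_fold == 0L) stop("input error: fewer pairs than folds",
                           call. = FALSE)
  fold_of_pair <- rep(NA_integer_, n_pairs)
  fold_of_pair[seq_len(per_fold * k)] <- rep(seq_len(k), each = per_fold)
  idx <- as.vector(rbind(m, f))  # M,F,M,F,...
  out <- balanced[idx, , drop = FALSE]
  out$pair_id <- rep(seq_len(n_pairs), each = 2L)
  out$order <- seq_along(idx)
  out$fold <- rep(fold_of_pair, each = 2L)
  out
}

prep_model_frame <- function(df, features, log_transform) {
  if (log_transform) df <- log_transform_features(df, features)
  df
}

#' Cross-validated decision-tree sex classification
#'
#' Trains a binary classification tree (Gini impurity, minimum leaf size
#' `minbucket`, cost-complexity pruning at the internal-CV error minimum)
#' on the training folds and scores the held-out fold, for every fold in
#' turn. Features are natural-log transformed by default.
#'
#' @param folded output of [interleave_and_fold()] with feature columns.
#' @param features predictor columns; default the five sex-informative
#'   features `cy`, `m_my`, `zcr_vx`, `cri_t`, `st_n`.
#' @param log_transform log-transform the predictors; default `TRUE`.
#' @param minbucket minimum leaf size; default 20.
#' @return An object of class `classification_report`: per-fold accuracies,
#'   mean and SD accuracy (%), directional misclassification rates (%),
#'   pooled confusion matrix, and a printable description of the
#'   first-fold tree.
#' @export
sex_classification_cv <- function(folded,
                                  features = c("cy", "m_my", "zcr_vx",
                                               "cri_t", "st_n"),
                                  log_transform = TRUE, minbucket = 20L) {
  df <- prep_model_frame(folded, features, log_transform)
  df$sex <- factor(df$sex, levels = c("male", "female"))
  fml <- stats::as.formula(paste("sex ~", paste(features, collapse = " + ")))
  folds <- sort(unique(df$fold[!is.na(df$fold)]))
  acc <- numeric(length(folds))
  conf <- matrix(0, 2, 2, dimnames = list(truth = c("male", "female"),
                                          pred = c("male", "female")))
  tree_desc <- NULL
  for (i in seq_along(folds)) {
    test <- !is.na(df$fold) & df$fold == folds[i]
    fit <- rpart::rpart(fml, data = df[!test, , drop = FALSE],
                        method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(minbucket = minbucket,
                                                       xval = 10, cp = 1e-4))
    cp_tab <- fit$cptable
    fit <- rpart::prune(fit,
                        cp = cp_tab[which.min(cp_tab[, "xerror"]), "CP"])
    pred <- predict(fit, df[test, , drop = FALSE], type = "class")
    truth <- df$sex[test]
    acc[i] <- mean(pred == truth)
    conf <- conf + table(truth, pred)
    if (i == 1L) tree_desc <- utils::capture.output(print(fit))
  }
  n_const <- sum(vapply(features,
                        function(cl) var(df[[cl]], na.rm = TRUE) == 0, TRUE))
  if (n_const > 0) warning("degenerate model: ", n_const,
                           " constant feature(s)", call. = FALSE)
  structure(list(
    fold_accuracy = acc,
    mean_accuracy = 100 * mean(acc),
    sd_accuracy = 100 * sd(acc),
    male_as_female = 100 * conf["male", "female"] / sum(conf["male", ]),
    female_as_male = 100 * conf["female", "male"] / sum(conf["female", ]),
    confusion = conf,
    tree = tree_desc,
    features = features), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(paste0("<classification_report> accuracy %.1f +/- %.1f%% ",
                     "(%d folds)\n  male->female %.1f%%, ",
                     "female->male %.1f%%\n"),
              x$mean_accuracy, x$sd_accuracy, length(x$fold_accuracy),
              x$male_as_female, x$female_as_male))
  invisible(x)
}

#' Age prediction from sway features
#'
#' Fits, separately per sex, a linear model (or regression tree) of age on
#' the age-informative features, reporting the cross-validated residual SD
#' of the prediction error (headline), the in-sample residual SD, and for
#' the linear model the in-sample R^2 and F statistic.
#'
#' @param df feature table with `sex`, `age` and the feature columns.
#' @param features default `cy`, `zcr_y`, `cri_t`, `st_n`.
#' @param model "linear" or "tree".
#' @param k CV folds; default 10.
#' @param seed fold-assignment seed.
#' @param log_transform log-transform predictors; default `TRUE`.
#' @return Named list (one entry per sex) of class `age_model_report`
#'   entries: `residual_sd_cv`, `residual_sd_insample`, `r_squared`,
#'   `f_statistic`, `model`, `n`.
#' @export
age_prediction <- function(df, features = c("cy", "zcr_y", "cri_t", "st_n"),
                           model = c("linear", "tree"), k = 10L, seed = 1L,
                           log_transform = TRUE) {
  model <- match.arg(model)
  df <- prep_model_frame(df, features, log_transform)
  fml <- stats::as.formula(paste("age ~", paste(features, collapse = " + ")))
  out <- list()
  for (sx in unique(df$sex)) {
    d <- df[df$sex == sx, c("age", features)]
    d <- d[complete.cases(d), , drop = FALSE]
    n <- nrow(d)
    if (n < 30L) warning("small sample for sex ", sx, " (n=", n, ")",
                         call. = FALSE)
    fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
    resid_cv <- numeric(n)
    for (i in seq_len(k)) {
      tr <- d[fold != i, , drop = FALSE]
      te <- d[fold == i, , drop = FALSE]
      fit <- if (model == "linear") lm(fml, data = tr)
             else rpart::rpart(fml, data = tr, method = "anova")
      resid_cv[fold == i] <- te$age - predict(fit, te)
    }
    full <- if (model == "linear") lm(fml, data = d)
            else rpart::rpart(fml, data = d, method = "anova")
    ins_resid <- d$age - predict(full, d)
    rep_i <- list(sex = sx, model = model, n = n,
                  residual_sd_cv = sd(resid_cv),
                  residual_sd_insample = sd(ins_resid),
                  r_squared = if (model == "linear")
                      summary(full)$r.squared
                    else 1 - var(ins_resid) / var(d$age),
                  f_statistic = if (model == "linear")
                      unname(summary(full)$fstatistic[1]) else NA_real_)
    class(rep_i) <- "age_model_report"
    out[[sx]] <- rep_i
  }
  out
}

#' @export
print.age_model_report <- function(x, ...) {
  cat(sprintf(paste0("<age_model_report> %s (%s, n=%d): CV residual SD ",
                     "%.2f y, R^2 %.3f%s\n"),
              x$sex, x$model, x$n, x$residual_sd_cv, x$r_squared,
              if (is.finite(x$f_statistic))
                sprintf(", F %.1f", x$f_statistic) else ""))
  invisible(x)
}

#' Rank-sum indicator tables of group differences
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) tests per feature, either
#' male vs female within each age group, or successive age groups within
#' the pooled (or per-sex) table. Cells report the raw p-value and a 0/1
#' indicator of significance at `alpha`; no multiplicity correction is
#' applied unless `p_adjust` names a method.
#'
#' @param df feature table with `sex`, `age` and feature columns.
#' @param grouping "sex_within_age" or "successive_age".
#' @param features feature columns; default the six core features.
#' @param alpha significance level; default 0.05.
#' @param sex for `successive_age`, restrict to one sex (`NULL` = pooled).
#' @param p_adjust optional `p.adjust` method applied across the table.
#' @return An object of class `group_comparison_table`: `indicator` and
#'   `p_value` matrices (rows = comparisons, columns = features).
#' @export
group_difference_tests <- function(df,
                                   grouping = c("sex_within_age",
                                                "successive_age"),
                                   features = c("cy", "m_my", "zcr_y",
                                                "zcr_vx", "cri_t", "st_n"),
                                   alpha = 0.05, sex = NULL,
                                   p_adjust = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(sex)) df <- df[df$sex == sex, , drop = FALSE]
  grp <- stratify_age_groups(df$age)
  cmp <- if (grouping == "sex_within_age") levels(grp)
         else paste0("(", 1:4, "-", 2:5, ")")
  p <- matrix(NA_real_, length(cmp), length(features),
              dimnames = list(cmp, features))
  for (i in seq_along(cmp)) {
    if (grouping == "sex_within_age") {
      a <- df[grp == levels(grp)[i] & df$sex == "male", , drop = FALSE]
      b <- df[grp == levels(grp)[i] & df$sex == "female", , drop = FALSE]
    } else {
      a <- df[as.integer(grp) == i, , drop = FALSE]
      b <- df[as.integer(grp) == i + 1L, , drop = FALSE]
    }
    for (j in seq_along(features)) {
      va <- a[[features[j]]]; vb <- b[[features[j]]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 3L || length(vb) < 3L) {
        # warn only when a populated comparison is under-sized; absent
        # strata stay silently NA
        if (length(va) + length(vb) > 0L)
          warning("comparison ", cmp[i], " skipped for ", features[j],
                  ": group size < 3", call. = FALSE)
        next
      }
      p[i, j] <- suppressWarnings(wilcox.test(va, vb)$p.value)
    }
  }
  if (!is.null(p_adjust)) p[] <- stats::p.adjust(p, method = p_adjust)
  structure(list(indicator = (p < alpha) * 1L, p_value = p,
                 test = "Wilcoxon rank-sum", alpha = alpha,
                 grouping = grouping),
            class = "group_comparison_table")
}

#' @export
print.group_comparison_table <- function(x, ...) {
  cat(sprintf("<group_comparison_table> %s, %s, alpha=%g\n",
              x$grouping, x$test, x$alpha))
  print(x$indicator)
  invisible(x)
}

#' Correlation matrix of features, age and sex
#'
#' Pairwise Pearson correlations over the six features, age, and sex coded
#' numerically (female = 1, male = 0). Constant columns produce `NA`
#' entries and a warning.
#'
#' @param df feature table with `sex`, `age` and feature columns.
#' @param features default the six core features.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_table <- function(df, features = c("cy", "m_my", "zcr_y",
                                               "zcr_vx", "cri_t", "st_n")) {
  if (nrow(df) < 3L) stop("input error: need at least 3 rows", call. = FALSE)
  m <- as.matrix(df[, features, drop = FALSE])
  m <- cbind(m, age = df$age, sex = as.numeric(df$sex == "female"))
  const <- apply(m, 2, function(v) var(v, na.rm = TRUE) == 0)
  if (any(const)) warning("constant column(s): ",
                          paste(colnames(m)[const], collapse = ", "),
                          call. = FALSE)
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))
}

#' Romberg-quotient benchmark battery
#'
#' The classical-measure reference analyses on a per-subject RQ table:
#' correlation between the path-range and velocity quotients, rank-sum sex
#' comparisons, cross-validated logistic-regression sex-prediction
#' accuracy, one-way ANOVA of each quotient across age groups, and a
#' cross-validated decision-tree age-group classification accuracy.
#'
#' @param rq `data.frame` from [romberg_table()] with `sex`, `age`,
#'   `rq_path`, `rq_velocity`.
#' @param k CV folds; default 10.
#' @param seed fold-assignment seed.
#' @return List: `rq_correlation`, `sex_wilcoxon` (p-values),
#'   `logistic_accuracy` (%), `anova` (F and p per quotient),
#'   `tree_age_accuracy` (%).
#' @export
rq_cohort_analysis <- function(rq, k = 10L, seed = 1L) {
  rq <- rq[complete.cases(rq[c("sex", "age", "rq_path", "rq_velocity")]), ]
  rq$age_group <- stratify_age_groups(rq$age)
  rq$sex_f <- factor(rq$sex, levels = c("male", "female"))
  n <- nrow(rq)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  # logistic sex prediction
  correct <- logical(n)
  for (i in seq_len(k)) {
    fit <- glm(sex_f ~ rq_path + rq_velocity,
               data = rq[fold != i, ], family = binomial())
    pr <- predict(fit, rq[fold == i, ], type = "response")
    correct[fold == i] <- (pr > 0.5) == (rq$sex_f[fold == i] == "female")
  }
  # decision-tree age-group classification
  tree_ok <- logical(n)
  for (i in seq_len(k)) {
    fit <- rpart::rpart(age_group ~ rq_path + rq_velocity,
                        data = rq[fold != i, ], method = "class")
    pr <- predict(fit, rq[fold == i, ], type = "class")
    tree_ok[fold == i] <- pr == rq$age_group[fold == i]
  }
  an <- lapply(c(rq_path = "rq_path", rq_velocity = "rq_velocity"),
               function(v) {
                 a <- summary(aov(rq[[v]] ~ rq$age_group))[[1]]
                 c(F = a$`F value`[1], p = a$`Pr(>F)`[1])
               })
  list(
    rq_correlation = cor(rq$rq_path, rq$rq_velocity),
    sex_wilcoxon = c(
      rq_path = wilcox.test(rq_path ~ sex_f, data = rq)$p.value,
      rq_velocity = wilcox.test(rq_velocity ~ sex_f, data = rq)$p.value),
    logistic_accuracy = 100 * mean(correct),
    anova = an,
    tree_age_accuracy = 100 * mean(tree_ok),
    n = n)
}
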