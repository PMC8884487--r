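#' Assemble the participant-by-condition analysis table
#'
#' Runs the full per-participant analysis chain over a cohort - evoked
#' window scores for every condition and (optionally) induced gamma
#' log-ratios - and joins the behavioral phenotype columns. Epochs are
#' generated, analyzed and discarded one participant at a time, so memory
#' stays flat in cohort size.
#'
#' @param spec a [cohort_spec()].
#' @param params a [response_model_params()].
#' @param seed master seed (defaults to `spec$master_seed`).
#' @param induced compute induced gamma summaries.
#' @param induced_conditions conditions for which the (more expensive)
#'   induced analysis is run.
#' @param progress print progress.
#' @return list of class `cohort_table`: `measures` (one row per
#'   participant x condition: group, condition, m1_z, m2_z, combined_z,
#'   gamma_log_ratio) and `participants` (one row per participant with
#'   behavioral scores and generator latents).
#' @export
build_cohort_table <- function(spec, params = response_model_params(),
                               seed = spec$master_seed, induced = TRUE,
                               induced_conditions = spec$conditions,
                               progress = FALSE) {
  cohort <- simulate_cohort(spec, params, seed, keep_epochs = FALSE)
  pts <- cohort$participants
  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    es <- cohort_epochs(pts[i, ], spec, params, seed)
    ev <- evoked_summary(es)
    ev$gamma_log_ratio <- NA_real_
    if (induced) {
      keep <- es$conditions %in% induced_conditions
      es_sub <- es
      es_sub$conditions <- es$conditions[keep]
      es_sub$data <- es$data[keep]
      ind <- induced_summary(es_sub)
      ev$gamma_log_ratio[match(ind$condition, ev$condition)] <-
        ind$gamma_log_ratio
    }
    rows[[i]] <- ev
    if (progress) message(sprintf("analyzed %s (%d/%d)", pts$id[i], i, nrow(pts)))
  }
  structure(list(measures = do.call(rbind, rows), participants = pts,
                 spec = spec, params = params, seed = seed),
            class = "cohort_table")
}

# Flatten a cohort_table (or accept a ready data.frame) for modeling.
as_measures_df <- function(table) {
  df <- if (inherits(table, "cohort_table")) table$measures else as.data.frame(table)
  df$group <- factor(df$group, levels = c("TD", "ASD"))
  df$condition <- factor(df$condition)
  df$id <- factor(df$id)
  df
}

#' Mixed-effects group x condition inference
#'
#' Fits the linear mixed model `response ~ group * condition +
#' (1 | participant)` by restricted maximum likelihood and reports
#' F statistics for the fixed effects (group, condition, interaction) with
#' Satterthwaite denominator degrees of freedom - for the balanced
#' repeated-measures design used here this reproduces the classical
#' F approximation exactly (e.g. df = 1/45 for group and 2/90 for the
#' interaction at the default cohort sizes). If the design is unbalanced
#' the function falls back, with a warning, to a permutation test of the
#' same F statistics (group labels permuted across participants).
#'
#' @param table a `cohort_table` or a data.frame with columns `id`,
#'   `group`, `condition` and the response.
#' @param response measure to analyze (column name).
#' @param n_perm permutations for the unbalanced fallback.
#' @return list of class `group_stats`: `anova` (term, F, df1, df2, p),
#'   `ranef_var` (participant and residual variance), `method`.
#' @export
fit_group_condition_model <- function(table, response = "combined_z",
                                      n_perm = 999) {
  df <- as_measures_df(table)
  df$y <- df[[response]]
  if (any(is.na(df$y))) stop("response contains missing values")
  counts <- table(df$id, df$condition)
  balanced <- all(counts[rowSums(counts) > 0, ] == 1)
  if (!balanced) {
    warning("unbalanced design: using the permutation fallback")
    return(permutation_group_test(df, n_perm))
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- withCallingHandlers(
    lmerTest::lmer(y ~ group * condition + (1 | id), data = df, REML = TRUE),
    message = function(m) {
      # a zero participant-variance estimate is a legitimate boundary fit
      if (grepl("boundary \\(singular\\)", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    })
  an <- stats::anova(fit, type = 3)  # Satterthwaite ddf
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    anova = data.frame(term = rownames(an), F = an$`F value`,
                       df1 = an$NumDF, df2 = an$DenDF, p = an$`Pr(>F)`,
                       row.names = NULL),
    ranef_var = stats::setNames(vc$vcov, vc$grp),
    method = "REML mixed model, Satterthwaite F",
    fit = fit
  ), class = "group_stats")
}

# Permutation test of the group and interaction F statistics for
# unbalanced tables: participant-level group labels are permuted, the OLS
# two-way F statistics recomputed under each permutation.
permutation_group_test <- function(df, n_perm = 999) {
  f_stats <- function(d) {
    an <- stats::anova(stats::lm(y ~ group * condition, data = d))
    stats::setNames(an$`F value`[1:3], rownames(an)[1:3])
  }
  obs <- f_stats(df)
  ids <- unique(df$id)
  id_group <- df$group[match(ids, df$id)]
  exceed <- c(0, 0, 0)
  for (b in seq_len(n_perm)) {
    perm <- sample(id_group)
    d <- df
    d$group <- perm[match(d$id, ids)]
    exceed <- exceed + (f_stats(d) >= obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  structure(list(
    anova = data.frame(term = names(obs), F = as.numeric(obs),
                       df1 = NA, df2 = NA, p = as.numeric(p), row.names = NULL),
    ranef_var = NULL,
    method = sprintf("permutation test (%d permutations)", n_perm)
  ), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat("Group x condition inference (", x$method, ")\n", sep = "")
  print(transform(x$anova, F = round(F, 3), p = signif(p, 3)))
  invisible(x)
}

#' Two-sample group contrast at one condition
#'
#' Pooled-variance two-sample t test (TD vs ASD) on one measure at one
#' condition; df = n_TD + n_ASD - 2.
#'
#' @param table `cohort_table` or measures data.frame.
#' @param condition condition N at which to compare.
#' @param response measure column.
#' @return list: `t`, `df`, `p`, `means` (TD, ASD).
#' @export
per_condition_contrast <- function(table, condition = 18,
                                   response = "combined_z") {
  df <- as_measures_df(table)
  df <- df[df$condition == as.character(condition), ]
  y_td <- df[[response]][df$group == "TD"]
  y_asd <- df[[response]][df$group == "ASD"]
  if (!length(y_td) || !length(y_asd)) stop("both groups must be present")
  tt <- stats::t.test(y_td, y_asd, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = c(TD = mean(y_td), ASD = mean(y_asd)))
}

# One participant-level feature row per id: the classifier/regression
# features (default: combined evoked z and gamma log-ratio at N = 18).
participant_features <- function(table, condition = 18,
                                 features = c("combined_z", "gamma_log_ratio")) {
  stopifnot(inherits(table, "cohort_table"))
  m <- table$measures[table$measures$condition == condition, ]
  out <- m[, c("id", "group", features)]
  merge(out, table$participants[, c("id", "age", "srs_sci", "spq_aps",
                                    "icss_i", "latent")], by = "id")
}

#' Repeated-split linear-SVM diagnosis classification
#'
#' Trains a linear support-vector machine (cost 1; features standardized
#' on the training fold only) on a random 90% of participants and scores
#' accuracy on the held-out 10%, repeated `repeats` times (fresh random
#' partition each time; participants are never duplicated within a split).
#' A split whose training fold lacks one class is redrawn.
#'
#' @param table a `cohort_table`, or a data.frame with a `group` column and
#'   feature columns.
#' @param features feature column names (default: combined evoked z and
#'   gamma log-ratio at N = 18 when a `cohort_table` is given).
#' @param condition condition from which features are taken.
#' @param train_frac training fraction.
#' @param repeats number of random splits.
#' @param cost SVM regularization constant.
#' @param seed RNG seed for the split plan.
#' @return list of class `classifier_result`: `accuracy` (per split, %),
#'   `mean`, `se`, `plan`.
#' @export
classify_diagnosis <- function(table, features = c("combined_z", "gamma_log_ratio"),
                               condition = 18, train_frac = 0.9, repeats = 50,
                               cost = 1, seed = 1) {
  df <- if (inherits(table, "cohort_table")) {
    participant_features(table, condition, features)
  } else as.data.frame(table)
  if (any(is.na(df[, features]))) stop("features contain missing values")
  df$group <- factor(df$group)
  n <- nrow(df)
  n_test <- max(1, round((1 - train_frac) * n))
  acc <- with_seed(seed, vapply(seq_len(repeats), function(b) {
    repeat {
      test <- sample.int(n, n_test)
      if (nlevels(droplevels(df$group[-test])) == 2) break
    }
    fit <- e1071::svm(stats::reformulate(features, "group"),
                      data = df[-test, ], kernel = "linear", cost = cost,
                      scale = TRUE)
    pred <- stats::predict(fit, newdata = df[test, ])
    100 * mean(pred == df$group[test])
  }, numeric(1)))
  structure(list(accuracy = acc, mean = mean(acc),
                 se = stats::sd(acc) / sqrt(repeats),
                 plan = list(train_frac = train_frac, repeats = repeats,
                             n_test = n_test, cost = cost, seed = seed,
                             interpretation = "independent random re-partitions")),
            class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf("Linear SVM diagnosis classification: %.1f%% +/- %.1f%% (mean +/- SE over %d splits)\n",
              x$mean, x$se, length(x$accuracy)))
  invisible(x)
}

#' Predict a behavioral score from the neural measures
#'
#' Simple least-squares regression of a behavioral outcome on the
#' neurophysiological features (within the ASD group by default, as the
#' predictions target symptom severity). Predicted scores are the fitted
#' values (in-sample); the reported Pearson r between predicted and
#' observed equals the regression's multiple correlation coefficient and
#' is therefore optimistically biased under the null - interpret against
#' a permutation or analytic null, not zero.
#'
#' @param table a `cohort_table` or a participant-level data.frame.
#' @param outcome `"srs_sci"`, `"spq_aps"`, or `"spq_aps_ac"`
#'   (age-corrected SPQ-APS residuals, computed via [residualize_age()]).
#' @param features predictor columns.
#' @param condition condition from which neural features are taken.
#' @param group group analyzed.
#' @return list of class `behavior_prediction`: `r`, `p`, `coefficients`,
#'   `predicted`, `observed`, `outcome`.
#' @export
predict_behavior <- function(table, outcome = c("srs_sci", "spq_aps", "spq_aps_ac"),
                             features = c("combined_z", "gamma_log_ratio"),
                             condition = 18, group = "ASD") {
  outcome <- match.arg(outcome)
  df <- if (inherits(table, "cohort_table")) {
    participant_features(table, condition, features)
  } else as.data.frame(table)
  df <- df[df$group == group, ]
  if (outcome == "spq_aps_ac") {
    df$spq_aps_ac <- residualize_age(df$spq_aps, df$age)
  }
  df <- df[stats::complete.cases(df[, c(outcome, features)]), ]
  if (nrow(df) < length(features) + 1) stop("too few complete cases to fit")
  fit <- stats::lm(stats::reformulate(features, outcome), data = df)
  pred <- stats::fitted(fit)
  ct <- stats::cor.test(pred, df[[outcome]])
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 coefficients = stats::coef(fit),
                 predicted = pred, observed = df[[outcome]],
                 outcome = outcome, n = nrow(df)),
            class = "behavior_prediction")
}

#' @export
print.behavior_prediction <- function(x, ...) {
  cat(sprintf("Neural -> %s prediction (n = %d): r(predicted, observed) = %.3f, p = %.3g\n",
              x$outcome, x$n, x$r, x$p))
  invisible(x)
}

#' Residualize scores on age
#'
#' Least-squares regression of `scores` on `ages`; returns the residuals,
#' which are exactly uncorrelated with age. With a constant age vector the
#' centered scores are returned with a warning.
#'
#' @param scores numeric scores (NA allowed; preserved in the output).
#' @param ages ages in years.
#' @return age-corrected scores (residuals).
#' @export
residualize_age <- function(scores, ages) {
  ok <- stats::complete.cases(scores, ages)
  if (sum(ok) < 3) stop("need at least 3 complete cases")
  out <- rep(NA_real_, length(scores))
  if (stats::sd(ages[ok]) == 0) {
    warning("constant age vector: returning centered scores")
    out[ok] <- scores[ok] - mean(scores[ok])
    return(out)
  }
  out[ok] <- stats::residuals(stats::lm(scores[ok] ~ ages[ok]))
  out
}
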