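test_that("mixed-model F matches classical repeated-measures ANOVA exactly", {
  df <- toy_measures(seed = 1)
  g <- fit_group_condition_model(df)
  av <- summary(stats::aov(combined_z ~ group * condition + Error(id),
                           data = transform(df, group = factor(group),
                                            condition = factor(condition),
                                            id = factor(id))))
  f_between <- av[["Error: id"]][[1]]["group", "F value"]
  f_within <- av[["Error: Within"]][[1]][c("condition", "group:condition"),
                                         "F value"]
  expect_equal(g$anova$F[g$anova$term == "group"], f_between,
               tolerance = 1e-6)
  expect_equal(g$anova$F[g$anova$term == "condition"], f_within[1],
               tolerance = 1e-6)
  expect_equal(g$anova$F[g$anova$term == "group:condition"], f_within[2],
               tolerance = 1e-6)
  expect_equal(g$anova$df1, c(1, 2, 2))
  expect_equal(g$anova$df2, c(4, 8, 8), tolerance = 1e-6)
})

test_that("with zero participant variance the mixed model reduces to OLS", {
  set.seed(3)
  df <- toy_measures(seed = 3, sigma_id = 0)
  # remove residual between-participant variance exactly
  noise <- matrix(stats::rnorm(18), 6, 3)
  noise <- noise - rowMeans(noise)
  df$combined_z <- as.numeric(factor(df$condition)) +
    (df$group == "TD") + as.vector(noise)
  g <- suppressMessages(fit_group_condition_model(df))
  expect_equal(unname(g$ranef_var["id"]), 0, tolerance = 1e-10)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  ols <- stats::anova(stats::lm(combined_z ~ group * condition,
                                data = transform(df, group = factor(group),
                                                 condition = factor(condition))))
  expect_equal(g$anova$F, ols$`F value`[1:3], tolerance = 1e-5)
})

test_that("default cohort sizes give the published degrees of freedom", {
  df <- expand.grid(id = sprintf("P%02d", 1:47), condition = c(6, 12, 18))
  df$group <- ifelse(as.integer(factor(df$id)) <= 26, "TD", "ASD")
  set.seed(8)
  df$combined_z <- stats::rnorm(nrow(df)) +
    rep(stats::rnorm(47), 3)[as.integer(factor(df$id))]
  g <- fit_group_condition_model(df)
  expect_equal(g$anova$df1, c(1, 2, 2))
  expect_equal(g$anova$df2, c(45, 90, 90), tolerance = 1e-6)
  ct <- per_condition_contrast(df, 18)
  expect_identical(ct$df, 45)
})

test_that("unbalanced designs fall back to the permutation test", {
  df <- toy_measures(seed = 2)
  df <- df[-1, ]  # drop one cell
  expect_warning(g <- fit_group_condition_model(df, n_perm = 99),
                 "permutation")
  expect_true(all(g$anova$p >= 0 & g$anova$p <= 1))
  expect_match(g$method, "permutation")
})

test_that("the per-condition contrast matches a hand-computed pooled t", {
  df <- data.frame(id = paste0("P", 1:6),
                   group = rep(c("ASD", "TD"), each = 3),
                   condition = 18,
                   combined_z = c(4, 5, 6, 1, 2, 3))
  ct <- per_condition_contrast(df, 18)
  # pooled sd = 1, se = sqrt(2/3): t = (TD - ASD)/se = -3 / 0.8165
  expect_equal(ct$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_identical(ct$df, 4)
  expect_equal(ct$p, 2 * stats::pt(-3.674235, 4), tolerance = 1e-4)
  same <- df; same$combined_z <- rep(c(1, 2, 3), 2)
  ct0 <- per_condition_contrast(same, 18)
  expect_equal(ct0$t, 0)
  expect_equal(ct0$p, 1)
  only <- df[df$group == "TD", ]
  expect_error(per_condition_contrast(only, 18), "both groups")
})

test_that("the SVM classifier is perfect on separable features and seeded", {
  set.seed(5)
  df <- data.frame(group = rep(c("TD", "ASD"), each = 20),
                   f1 = c(stats::rnorm(20, 5), stats::rnorm(20, -5)),
                   f2 = stats::rnorm(40))
  res <- classify_diagnosis(df, features = c("f1", "f2"), repeats = 20,
                            seed = 3)
  expect_equal(res$mean, 100)
  res2 <- classify_diagnosis(df, features = c("f1", "f2"), repeats = 20,
                             seed = 3)
  expect_identical(res$accuracy, res2$accuracy)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 100))
  expect_gte(res$se, 0)
})

test_that("behavior prediction equals the multiple correlation coefficient", {
  set.seed(6)
  df <- data.frame(group = "ASD", age = stats::runif(21, 7, 17),
                   combined_z = stats::rnorm(21),
                   gamma_log_ratio = stats::rnorm(21))
  df$srs_sci <- 70 - 5 * df$combined_z + 2 * df$gamma_log_ratio +
    stats::rnorm(21)
  df$spq_aps <- 15 + 2 * df$combined_z
  df$icss_i <- stats::rnorm(21, 9)
  bp <- predict_behavior(df, "srs_sci")
  fit <- stats::lm(srs_sci ~ combined_z + gamma_log_ratio, data = df)
  expect_equal(bp$r, sqrt(summary(fit)$r.squared), tolerance = 1e-9)
  # noiseless outcome -> r = 1
  bp2 <- predict_behavior(df, "spq_aps", features = "combined_z")
  expect_equal(bp2$r, 1, tolerance = 1e-9)
  expect_error(predict_behavior(df[1:2, ], "srs_sci"), "too few")
})

test_that("in-sample prediction r is optimistically biased under the null", {
  set.seed(11)
  rs <- replicate(200, {
    df <- data.frame(group = "ASD", age = stats::runif(21, 7, 17),
                     combined_z = stats::rnorm(21),
                     gamma_log_ratio = stats::rnorm(21),
                     srs_sci = stats::rnorm(21, 70, 10))
    predict_behavior(df, "srs_sci")$r
  })
  # E[R^2] = p / (n - 1) = 2/20 under the null
  expect_gt(mean(rs), 0.2)
  expect_lt(mean(rs), 0.45)
})

test_that("age residualization removes age exactly", {
  set.seed(12)
  ages <- stats::runif(21, 7, 17)
  scores <- 20 - 0.5 * ages + stats::rnorm(21)
  res <- residualize_age(scores, ages)
  expect_lt(abs(stats::cor(res, ages)), 1e-10)
  # perfectly linear toy
  expect_equal(residualize_age(c(10, 20, 30), c(8, 10, 12)), rep(0, 3),
               tolerance = 1e-10)
  # age-independent scores come back centered
  s2 <- c(1, -2, 1)
  expect_equal(residualize_age(s2, c(8, 10, 12)), s2 - mean(s2),
               tolerance = 1e-12)
  expect_warning(r0 <- residualize_age(c(1, 2, 3), c(10, 10, 10)), "constant")
  expect_equal(r0, c(-1, 0, 1))
  expect_error(residualize_age(c(1, 2), c(8, 9)), "at least 3")
})
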