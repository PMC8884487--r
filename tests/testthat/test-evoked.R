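test_that("event collapsing averages the two coherence-change epochs", {
  spec <- fix_spec(trials = 2)
  par <- response_model_params()
  rec <- simulate_participant(spec, par, "TD", seed = 1, id = "TD01")
  es <- simulate_epochs(rec, spec, par, seed = 2)
  # identical events -> collapse returns either one
  es$data <- lapply(es$data, function(x) { x[, , 2, ] <- x[, , 1, ]; x })
  ce <- collapse_events(es, align = FALSE)
  expect_equal(ce$data[[1]][, 1, 1], es$data[[1]][, 1, 1, 1])
  # anti-phase events cancel when alignment is off
  es$data <- lapply(es$data, function(x) { x[, , 2, ] <- -x[, , 1, ]; x })
  ce0 <- collapse_events(es, align = FALSE)
  expect_lt(max(abs(ce0$data[[1]])), 1e-12)
  # missing second event errors
  es$data <- lapply(es$data, function(x) x[, , 1, , drop = FALSE])
  expect_error(collapse_events(es), "events")
})

test_that("polarity alignment makes the M1-window mean positive", {
  spec <- fix_spec(trials = 8)
  par <- response_model_params(noise_sd = 0.5)
  rec <- simulate_participant(spec, par, "TD", seed = 3, id = "TD01")
  es <- simulate_epochs(rec, spec, par, seed = 4)
  es$data <- lapply(es$data, function(x) -x)  # flipped source orientation
  ce <- collapse_events(es, align = TRUE)
  m1 <- in_window(es$time, c(0.05, 0.15))
  for (x in ce$data) expect_gt(mean(x[m1, , ]), 0)
})

test_that("baseline z-scoring matches its definition and is scale-free", {
  time <- seq(-0.2, 0.25, by = 0.05)  # 10 samples, 4 in the baseline
  x <- c(1, 2, 3, 2, 0, 0, 4, 0, 0, 0) # pulse of 4 at t = 0.1
  z <- baseline_zscore(x, time)
  b <- 1:4
  expect_equal(mean(z[b]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z[b]), 1, tolerance = 1e-12)
  # hand computation: baseline mean 2, sd sqrt(2/3)
  expect_equal(z[7], (4 - 2) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(baseline_zscore(10 * x, time), z, tolerance = 1e-12)
  expect_error(baseline_zscore(rep(1, 10), time), "zero baseline variance")
  expect_error(baseline_zscore(x, time, c(-2, -1)), "baseline window")
})

test_that("window scores follow boxcar arithmetic", {
  fs <- 1000
  time <- seq(-0.5, 1, by = 1 / fs)
  box <- function(w) as.numeric(in_window(time, w))
  s <- window_scores(box(c(0.05, 0.45)), time)
  expect_equal(unname(s), c(1, 1, 1))
  s1 <- window_scores(box(c(0.05, 0.15)), time)
  expect_equal(unname(s1), c(1, 0, 0.25))
  expect_equal(unname(window_scores(numeric(length(time)), time)), c(0, 0, 0))
  # linearity in the input
  x <- stats::rnorm(length(time))
  expect_equal(window_scores(3.7 * x, time), 3.7 * window_scores(x, time),
               tolerance = 1e-12)
  # hemisphere averaging commutes with scoring
  m <- cbind(x, stats::rnorm(length(time)))
  expect_equal(window_scores(m, time), window_scores(rowMeans(m), time),
               tolerance = 1e-12)
  expect_error(window_scores(x[1:100], time[1:100]), "outside")
})

test_that("collapsing the two events buys a sqrt(2) SNR gain", {
  fs <- 250
  time <- seq(-0.25, 0.5, by = 1 / fs)
  template <- exp(-(time - 0.1)^2 / (2 * 0.02^2))
  n_trials <- 300
  set.seed(42)
  noise1 <- matrix(stats::rnorm(length(time) * n_trials), ncol = n_trials)
  noise2 <- matrix(stats::rnorm(length(time) * n_trials), ncol = n_trials)
  avg1 <- rowMeans(template + noise1)                      # one event
  avg12 <- rowMeans(template + (noise1 + noise2) / 2)      # collapsed
  resid_sd <- function(avg) stats::sd(avg - template)
  gain <- resid_sd(avg1) / resid_sd(avg12)
  expect_gt(gain, sqrt(2) * 0.85)
  expect_lt(gain, sqrt(2) * 1.15)
})

test_that("evoked summaries carry one row per condition", {
  spec <- fix_spec(trials = 6)
  par <- response_model_params()
  rec <- simulate_participant(spec, par, "ASD", seed = 9, id = "ASD01")
  es <- simulate_epochs(rec, spec, par, seed = 10)
  ev <- evoked_summary(es)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$condition, c(6, 12, 18))
  expect_true(all(is.finite(ev$combined_z)))
})
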