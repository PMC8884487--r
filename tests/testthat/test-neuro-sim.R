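test_that("a cohort is bit-reproducible from its master seed", {
  spec <- fix_spec(trials = 4)
  a <- simulate_cohort(spec, seed = 11)
  b <- simulate_cohort(spec, seed = 11)
  expect_identical(a$participants, b$participants)
  expect_identical(a$epochs[["TD01"]]$data, b$epochs[["TD01"]]$data)
  c <- simulate_cohort(spec, seed = 12)
  expect_false(identical(a$participants, c$participants))
})

test_that("a minimal cohort runs end to end", {
  spec <- cohort_spec(n_td = 1, n_asd = 1, trials_per_condition = 1,
                      sample_rate = 250, epoch_window = c(-0.25, 0.5))
  co <- simulate_cohort(spec, seed = 1)
  expect_identical(nrow(co$participants), 2L)
  expect_identical(sort(unique(co$participants$group)), c("ASD", "TD"))
  es <- co$epochs[[1]]
  expect_identical(dim(es$data[["18"]]), c(189L, 1L, 2L, 2L))
})

test_that("behavioral scores follow the configured structure", {
  spec <- fix_spec()
  # noiseless: SRS-SCI is an exact linear function of the latent effect
  p0 <- response_model_params(behavior_noise_scale = 0)
  recs <- do.call(rbind, lapply(1:30, function(i) {
    simulate_participant(spec, p0, "ASD", seed = i, id = sprintf("A%02d", i))
  }))
  expect_equal(abs(stats::cor(recs$latent, recs$srs_sci)), 1, tolerance = 1e-12)
  expect_lt(stats::cor(recs$latent, recs$srs_sci), 0)  # weaker response, worse symptoms

  par <- response_model_params()
  big <- do.call(rbind, lapply(1:1000, function(i) {
    simulate_participant(spec, par, "ASD", seed = 5000 + i, id = "x")
  }))
  expect_gt(mean(big$srs_sci), 70)
  expect_lt(mean(big$srs_sci), 79)
  expect_true(all(big$age >= 7 & big$age <= 17))
  # ICSS-I is independent of the latent neural effect
  expect_lt(abs(stats::cor(big$latent, big$icss_i)), 0.1)
  # SPQ-APS declines weakly with age within ASD
  expect_lt(stats::cor(big$age, big$spq_aps), -0.1)
  expect_gt(stats::cor(big$age, big$spq_aps), -0.5)
})

test_that("noise-free epochs reproduce the deterministic evoked template", {
  spec <- fix_spec(trials = 3)
  par <- response_model_params(noise_sd = 0, trial_amp_sd = 0,
                               gamma_amp = list(TD = c(`6` = 0, `12` = 0, `18` = 0),
                                                ASD = c(`6` = 0, `12` = 0, `18` = 0)))
  rec <- simulate_participant(spec, par, "TD", seed = 2, id = "TD01")
  es <- simulate_epochs(rec, spec, par, seed = 3)
  t <- es$time
  for (i in seq_along(es$conditions)) {
    amp <- rec$gain * (par$a0 + par$slope[["TD"]] * i)
    template <- amp * tonecoh:::evoked_template(t, par, "TD")
    avg <- apply(es$data[[i]], 1, mean)
    expect_equal(avg, template, tolerance = 1e-9)
  }
})

test_that("TD window amplitude grows monotonically with coherence", {
  spec <- fix_spec(trials = 40, n_td = 1, n_asd = 1)
  par <- response_model_params(noise_sd = 0.5, trial_amp_sd = 0.1)
  rec <- simulate_participant(spec, par, "TD", seed = 4, id = "TD01")
  es <- simulate_epochs(rec, spec, par, seed = 5)
  win <- in_window(es$time, c(0.05, 0.45))
  m <- vapply(es$data, function(x) mean(x[win, , , ]), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("random-phase gamma cancels in the trial average", {
  spec <- cohort_spec(n_td = 1, n_asd = 1, trials_per_condition = 100,
                      sample_rate = 250, epoch_window = c(-0.25, 0.5))
  par <- response_model_params(noise_sd = 1e-6, trial_amp_sd = 0, a0 = 0,
                               slope = c(TD = 0, ASD = 0), m1_amp = 0,
                               m2_amp = 0, gamma_log_sd = 0)
  rec <- simulate_participant(spec, par, "TD", seed = 6, id = "TD01")
  es <- simulate_epochs(rec, spec, par, seed = 7, conditions = 18)
  x <- es$data[["18"]]
  dim(x) <- c(length(es$time), 400)
  band_power <- function(v) {
    P <- Mod(stats::fft(v))^2
    f <- pmin((0:(length(v) - 1)), length(v) - (0:(length(v) - 1))) *
      250 / length(v)
    sum(P[f >= 30 & f <= 70])
  }
  avg_power <- band_power(rowMeans(x))
  per_trial <- mean(apply(x[, 1:50], 2, band_power))
  expect_lt(avg_power / per_trial, 0.1)
})
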