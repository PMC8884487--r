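test_that("the default taper plan yields 3 orthonormal DPSS tapers", {
  v <- dpss_tapers(200, nw = 2)
  expect_identical(dim(v), c(200L, 3L))
  G <- crossprod(v)
  expect_lt(max(abs(G - diag(3))), 1e-10)
  # spectral concentration of the leading taper within +/- nw/n cycles/sample
  h <- c(v[, 1], numeric(1800))
  P <- Mod(stats::fft(h))^2
  f <- (0:1999) / 2000
  inb <- pmin(f, 1 - f) <= 2 / 200
  expect_gt(sum(P[inb]) / sum(P), 0.999)
})

test_that("a 40 Hz sinusoid peaks in the 40 Hz bin of every window", {
  fs <- 1000
  t <- seq(0, 1.5, by = 1 / fs)
  x <- sin(2 * pi * 40 * t)
  sg <- multitaper_spectrogram(x, fs)
  expect_equal(diff(sg$freq)[1], 5)     # 200-ms windows -> 5 Hz resolution
  peaks <- sg$freq[apply(sg$power, 2, which.max)]
  expect_true(all(peaks == 40))
  expect_error(multitaper_spectrogram(x[1:100], fs), "shorter")
})

test_that("white-noise multitaper spectra are flat within 1 dB over 5-70 Hz", {
  fs <- 1000
  set.seed(7)
  x <- matrix(stats::rnorm(501 * 200), 501, 200)  # 200 epochs of 0.5 s
  sg <- multitaper_spectrogram(x, fs)
  m <- apply(sg$power, 1, mean)                   # average windows + epochs
  sel <- sg$freq >= 5 & sg$freq <= 70
  db <- 10 * log10(m[sel] / mean(m[sel]))
  expect_lt(max(abs(db)), 1)
})

test_that("induced analysis sees random-phase gamma that the evoked average misses", {
  fs <- 500
  spec <- cohort_spec(n_td = 1, n_asd = 1, trials_per_condition = 60,
                      sample_rate = fs, epoch_window = c(-0.5, 1))
  par <- response_model_params(a0 = 0, slope = c(TD = 0, ASD = 0),
                               noise_sd = 1, trial_amp_sd = 0,
                               gamma_amp = list(TD = c(`6` = 0, `12` = 0, `18` = 1),
                                                ASD = c(`6` = 0, `12` = 0, `18` = 0)),
                               gamma_log_sd = 0)
  rec <- simulate_participant(spec, par, "TD", seed = 1, id = "TD01")
  es <- simulate_epochs(rec, spec, par, seed = 2, conditions = 18)
  x <- es$data[["18"]]
  dim(x) <- c(length(es$time), 240)
  sg <- multitaper_spectrogram(x, fs, time = es$time)
  ind <- induced_power(sg)
  expect_gt(ind$gamma, 0.05)  # clearly visible in the induced pipeline
  # absolute gamma-band power excess over the pre-event baseline: the
  # across-trial average (evoked pathway) must miss the burst by > 10x
  sg_avg <- multitaper_spectrogram(rowMeans(x), fs, time = es$time)
  band_excess <- function(power, freq, times) {
    P <- if (length(dim(power)) == 3) apply(power, c(1, 2), mean) else power
    fsel <- freq >= 30 & freq <= 70
    mean(P[fsel, times >= 0.5 & times <= 0.95]) -
      mean(P[fsel, times < -0.1])
  }
  exc_ind <- band_excess(sg$power, sg$freq, sg$times)
  exc_evo <- band_excess(sg_avg$power, sg_avg$freq, sg_avg$times)
  expect_gt(exc_ind, 0)
  expect_lt(abs(exc_evo), 0.1 * exc_ind)
})

test_that("log-ratios are invariant to overall amplitude scaling", {
  fs <- 500
  set.seed(9)
  x <- matrix(stats::rnorm(751 * 20), 751, 20)
  time <- seq(-0.5, 1, by = 1 / fs)
  sg1 <- multitaper_spectrogram(x, fs, time = time)
  sg2 <- multitaper_spectrogram(2 * x, fs, time = time)
  i1 <- induced_power(sg1)
  i2 <- induced_power(sg2)
  expect_equal(i2$log_ratio, i1$log_ratio, tolerance = 1e-12)
  # absolute log power shifts by log10(4) under amplitude doubling
  expect_equal(mean(log10(sg2$power / sg1$power)), log10(4), tolerance = 1e-12)
  expect_error(induced_power(multitaper_spectrogram(x[, 1], fs, time = time)),
               "epochs")
})

test_that("induced gamma separates the groups only at high coherence", {
  spec <- cohort_spec(n_td = 1, n_asd = 1, trials_per_condition = 40,
                      sample_rate = 500, epoch_window = c(-0.5, 1))
  par <- response_model_params()
  td <- simulate_participant(spec, par, "TD", seed = 21, id = "TD01")
  td$gamma_dev <- 0  # median-gain TD participant
  es <- simulate_epochs(td, spec, par, seed = 22)
  ind <- induced_summary(es)
  expect_gt(ind$gamma_log_ratio[ind$condition == 18],
            max(abs(ind$gamma_log_ratio[ind$condition != 18])))
  asd <- simulate_participant(spec, par, "ASD", seed = 23, id = "ASD01")
  es_a <- simulate_epochs(asd, spec, par, seed = 24)
  ind_a <- induced_summary(es_a)
  expect_lt(max(abs(ind_a$gamma_log_ratio)), 0.03)
})
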