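test_that("a trial is exactly 4 s with coherence events at 1 and 3 s", {
  tr <- fix_trial(12, seed = 3)
  expect_identical(length(tr$waveform), 4L * 20000L)
  expect_identical(tr$event_times, c(1, 3))
  sch <- tr$schedule
  expect_identical(sch$boundaries[sch$coherent_segments], c(1, 3))
  expect_identical(diff(sch$boundaries[c(2, 3)]), 1)  # 1-s coherent periods
  expect_length(sch$coherent_segments, 2)
})

test_that("coherent-subset envelopes are sample-identical; others are not", {
  fs <- 20000
  tr <- fix_trial(12, seed = 11)
  E <- tr$per_tone_envelopes
  idx <- tr$schedule$indices
  expect_length(idx, 12)
  for (seg in list(c(1, 2), c(3, 4))) {
    rows <- seg_interior(fs, seg[1], seg[2])
    for (j in idx[-1]) {
      expect_identical(E[rows, idx[1]], E[rows, j])
    }
    out <- setdiff(seq_len(20), idx)
    expect_gt(max(abs(E[rows, out[1]] - E[rows, out[2]])), 1e-6)
    expect_gt(max(abs(E[rows, out[1]] - E[rows, idx[1]])), 1e-6)
  }
  # incoherent segments: no identical pair anywhere
  rows <- seg_interior(fs, 0, 1)
  cm <- stats::cor(E[rows, ])
  expect_lt(max(cm[upper.tri(cm)]), 0.999)
})

test_that("degenerate coherence counts behave (N = 0 and N = 20)", {
  fs <- 20000
  tr0 <- fix_trial(0, seed = 2)
  expect_length(tr0$schedule$indices, 0)
  rows <- seg_interior(fs, 1, 2)
  E0 <- tr0$per_tone_envelopes
  expect_gt(min(1 - stats::cor(E0[rows, ])[upper.tri(diag(20))]), 1e-6)

  tr20 <- fix_trial(20, seed = 2)
  E20 <- tr20$per_tone_envelopes
  for (seg in list(c(1, 2), c(3, 4))) {
    rows <- seg_interior(fs, seg[1], seg[2])
    for (j in 2:20) expect_identical(E20[rows, 1], E20[rows, j])
  }
  expect_error(make_trial(fix_bank(), fix_env(),
                          coherence_schedule(21, n_tones = 20)),
               "exceeds")
})

test_that("per-tone envelope statistics are stationary across segments", {
  fs <- 4000
  env <- fix_env(fs)
  ratios <- replicate(15, {
    tr <- make_trial(fix_bank(), env, coherence_schedule(18),
                     seed = sample.int(1e6, 1), keep_envelopes = TRUE)
    E <- tr$per_tone_envelopes
    coh <- c(seg_interior(fs, 1, 2), seg_interior(fs, 3, 4))
    inc <- c(seg_interior(fs, 0, 1), seg_interior(fs, 2, 3))
    sqrt(colMeans(E[coh, ]^2) / colMeans(E[inc, ]^2))
  })
  expect_true(all(ratios > 0.8 & ratios < 1.25))
  expect_gt(mean(ratios), 0.97)
  expect_lt(mean(ratios), 1.03)
})

test_that("waveform level matches the tone-bank calibration", {
  tr <- fix_trial(6, seed = 9)
  level_db <- 20 * log10(rms(tr$waveform)) + 100
  expect_equal(level_db, 73.01, tolerance = 0.1)
})

test_that("session logs have the right counts, ISIs and determinism", {
  bank <- fix_bank()
  env <- fix_env()
  log <- make_session(bank, env, trials_per_condition = 240, seed = 5)
  expect_identical(nrow(log), 720L)
  expect_identical(sum(log$condition_N == 18), 240L)
  expect_identical(sum(log$condition_N == 6), 240L)
  expect_true(all(log$isi_s >= 1.2 & log$isi_s <= 1.3))
  expect_true(all(diff(log$onset_s) >= 4 + 1.2))
  # subsets have the right sizes
  sizes <- lengths(strsplit(log$coherent_indices, ","))
  expect_equal(as.integer(sizes), as.integer(log$condition_N))
  expect_identical(make_session(bank, env, trials_per_condition = 240, seed = 5),
                   log)
  one <- make_session(bank, env, conditions = 18, trials_per_condition = 1,
                      seed = 1)
  expect_identical(nrow(one), 1L)
  expect_error(make_session(bank, env, isi_range = c(1.3, 1.2)), "isi")
  expect_error(make_session(bank, env, trials_per_condition = 0), ">= 1")
})

test_that("logged trials re-render reproducibly with the logged subset", {
  bank <- fix_bank()
  env <- fix_env(4000)
  log <- make_session(bank, env, trials_per_condition = 2, seed = 31)
  tr1 <- render_session_trial(log, 3, bank, env)
  tr2 <- render_session_trial(log, 3, bank, env)
  expect_identical(tr1$waveform, tr2$waveform)
  logged <- as.integer(strsplit(log$coherent_indices[3], ",")[[1]]) + 1L
  expect_identical(tr1$schedule$indices, sort(logged))
})

test_that("separation variants select narrow vs interspersed subsets", {
  bank <- fix_bank()
  env <- fix_env(4000)
  nar <- make_separation_variant(6, "narrow", bank, env, seed = 1)
  sep_n <- attr(nar, "separation")
  expect_identical(diff(nar$schedule$indices), rep(1L, 5))
  expect_equal(sep_n$mean_separation_erb, bank$spacing_erb, tolerance = 1e-9)

  wid <- make_separation_variant(6, "wide", bank, env, seed = 1)
  sep_w <- attr(wid, "separation")
  expect_gte(min(diff(wid$schedule$indices)) * bank$spacing_erb, 4)
  expect_gt(sep_w$mean_separation_erb, 5)
  expect_identical(length(wid$schedule$indices), 6L)

  w4 <- make_separation_variant(4, "wide", bank, env, seed = 2)
  expect_gte(min(diff(w4$schedule$indices)) * bank$spacing_erb, 4)
  expect_error(make_separation_variant(12, "wide", bank, env), "infeasible")
})
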