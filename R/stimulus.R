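#' Coherence schedule of one trial
#'
#' A trial alternates 1-s incoherent and coherent segments (default
#' boundaries 0,1,2,3,4 s with coherent segments 2 and 4). During coherent
#' segments, `n_coherent` of the tones share a single envelope realization;
#' the rest stay independent. The coherent subset can be supplied
#' explicitly (1-based tone indices) or left `NULL` to be drawn at trial
#' synthesis time.
#'
#' @param n_coherent number of coherently modulated tones (0 to `n_tones`).
#' @param n_tones number of tones in the bank.
#' @param indices optional explicit coherent subset (1-based).
#' @param boundaries segment boundaries in s.
#' @param coherent_segments which segments (1-based) are coherent.
#' @return list of class `coherence_schedule`.
#' @export
coherence_schedule <- function(n_coherent, n_tones = 20, indices = NULL,
                               boundaries = c(0, 1, 2, 3, 4),
                               coherent_segments = c(2, 4)) {
  if (n_coherent > n_tones) stop("n_coherent exceeds the number of tones")
  if (n_coherent < 0) stop("n_coherent must be nonnegative")
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("segment boundaries must be strictly increasing")
  }
  if (!is.null(indices)) {
    indices <- sort(unique(as.integer(indices)))
    if (length(indices) != n_coherent || any(indices < 1 | indices > n_tones)) {
      stop("`indices` must be n_coherent distinct tone indices")
    }
  }
  structure(list(n_coherent = n_coherent, n_tones = n_tones,
                 indices = indices, boundaries = boundaries,
                 coherent_segments = coherent_segments),
            class = "coherence_schedule")
}

# Onset times (s) of the coherent segments.
schedule_event_times <- function(schedule) {
  schedule$boundaries[schedule$coherent_segments]
}

# Raised-cosine crossfade weights for a segment extended by `hl` samples on
# each side; ramps of length 2*hl are centered on the nominal boundaries so
# overlapping segments sum to unit weight.
segment_weights <- function(n_core, hl, fade_head, fade_tail) {
  w <- rep(1, n_core + 2 * hl)
  ramp <- if (hl > 0) 0.5 * (1 - cos(pi * (seq_len(2 * hl) - 0.5) / (2 * hl))) else numeric(0)
  if (fade_head && hl > 0) w[seq_len(2 * hl)] <- ramp
  if (fade_tail && hl > 0) w[n_core + 2 * hl + 1 - seq_len(2 * hl)] <- ramp
  w
}

#' Synthesize one figure-ground trial
#'
#' Builds the 4-s tone-cloud waveform: every tone carries an independent
#' stochastic envelope during incoherent segments; during coherent segments
#' the scheduled subset shares one fresh realization (maximal temporal
#' coherence) while the remaining tones stay independent. Segment
#' transitions are joined with a raised-cosine crossfade (default 10 ms) to
#' avoid spectral splatter; the crossfade can be disabled. Carrier phases
#' are randomized per trial. Each tone is calibrated so that its waveform
#' RMS corresponds to `bank$per_tone_level` dB SPL under the convention
#' that RMS 1.0 equals `calibration_ref` dB SPL.
#'
#' @param bank a [place_tones()] tone bank.
#' @param env an [envelope_params()] object (also fixes the sample rate).
#' @param schedule a [coherence_schedule()]; if its `indices` are `NULL`
#'   the coherent subset is drawn under `seed`.
#' @param seed optional integer seed; the whole trial is reproducible from it.
#' @param crossfade_ms raised-cosine crossfade duration at segment
#'   boundaries in ms (0 disables).
#' @param calibration_ref dB SPL assigned to a digital RMS of 1.0.
#' @param keep_envelopes store the per-tone envelope matrix (normalized
#'   units, i.e. before per-tone level scaling) in the result.
#' @return object of class `trial_stimulus`: `waveform`, `sample_rate`,
#'   `schedule` (with realized subset), `event_times` (s),
#'   `per_tone_envelopes` (samples x tones, or `NULL`), `bank`, `seed`.
#' @export
make_trial <- function(bank, env, schedule, seed = NULL, crossfade_ms = 10,
                       calibration_ref = 100, keep_envelopes = TRUE) {
  n_tones <- length(bank$frequencies)
  if (schedule$n_tones != n_tones) stop("schedule/bank tone counts differ")
  fs <- env$sample_rate
  dur <- schedule$boundaries[length(schedule$boundaries)] - schedule$boundaries[1]
  n <- round(dur * fs)
  hl <- round(crossfade_ms / 1000 * fs / 2)
  n_seg <- length(schedule$boundaries) - 1

  with_seed(seed, {
    phases <- stats::runif(n_tones, 0, 2 * pi)
    indices <- schedule$indices
    if (is.null(indices) && schedule$n_coherent > 0) {
      indices <- sort(sample.int(n_tones, schedule$n_coherent))
    }
    E <- matrix(0, n, n_tones)
    for (s in seq_len(n_seg)) {
      t0 <- schedule$boundaries[s] - schedule$boundaries[1]
      n_core <- round((schedule$boundaries[s + 1] - schedule$boundaries[s]) * fs)
      i0 <- round(t0 * fs)  # 0-based start of the core
      coh <- s %in% schedule$coherent_segments && length(indices) > 0
      seg_dur <- (n_core + 2 * hl) / fs
      # draw the shared figure envelope first, then the independent ones
      # (one batched draw, columns in tone order)
      Eseg <- matrix(0, n_core + 2 * hl, n_tones)
      if (coh) {
        Eseg[, indices] <- synth_envelope_mat(env, seg_dur, 1)[, 1]
        solo <- setdiff(seq_len(n_tones), indices)
        if (length(solo)) Eseg[, solo] <- synth_envelope_mat(env, seg_dur, length(solo))
      } else {
        Eseg[, ] <- synth_envelope_mat(env, seg_dur, n_tones)
      }
      w <- segment_weights(n_core, hl,
                           fade_head = s > 1, fade_tail = s < n_seg)
      # destination rows, clipped to the trial
      src0 <- i0 - (if (s > 1) hl else 0) + 1
      src1 <- i0 + n_core + (if (s < n_seg) hl else 0)
      off <- (if (s > 1) hl else 0)
      rows <- (hl - off + 1):(hl - off + (src1 - src0 + 1))
      E[src0:src1, ] <- E[src0:src1, ] + Eseg[rows, ] * (w[rows])
    }
    t <- (seq_len(n) - 1) / fs
    target_rms <- 10^((rep_len(bank$per_tone_level, n_tones) - calibration_ref) / 20)
    S <- E * sin(outer(2 * pi * t, bank$frequencies) +
                   rep(phases, each = n))
    g <- target_rms / sqrt(colMeans(S^2))
    waveform <- as.numeric(S %*% g)
    sched <- schedule
    sched$indices <- indices
    structure(list(
      waveform = waveform,
      sample_rate = fs,
      schedule = sched,
      event_times = schedule_event_times(sched),
      per_tone_envelopes = if (keep_envelopes) E else NULL,
      bank = bank,
      seed = seed
    ), class = "trial_stimulus")
  })
}

#' Generate a session log (and optionally render its audio)
#'
#' Pseudo-randomly interleaves the coherence conditions (default N = 6, 12,
#' 18 with 240 trials each), draws the coherent subset and a trial seed for
#' every trial, and assigns interstimulus intervals uniform on
#' `isi_range` (default 1.2-1.3 s). The log alone is cheap; full audio
#' rendering is opt-in via `render` (one float WAV per trial plus a
#' tab-separated event log in `out_dir`).
#'
#' @param bank a tone bank.
#' @param env an [envelope_params()] object.
#' @param conditions coherent-tone counts N.
#' @param trials_per_condition trials per condition (default 240).
#' @param isi_range interstimulus-interval range in s.
#' @param seed master session seed.
#' @param render render and write audio.
#' @param out_dir output directory (required when `render = TRUE`).
#' @param crossfade_ms passed to [make_trial()].
#' @return a `session_log`: data.frame with columns `trial_id`,
#'   `condition_N`, `onset_s`, `isi_s`, `coherent_indices` (comma-joined,
#'   0-based), `seed`.
#' @export
make_session <- function(bank, env, conditions = c(6, 12, 18),
                         trials_per_condition = 240,
                         isi_range = c(1.2, 1.3), seed = 1,
                         render = FALSE, out_dir = NULL, crossfade_ms = 10) {
  if (trials_per_condition < 1) stop("`trials_per_condition` must be >= 1")
  if (isi_range[1] > isi_range[2]) stop("isi_range must be nondecreasing")
  n_tones <- length(bank$frequencies)
  trial_dur <- 4
  log <- with_seed(seed, {
    pool <- rep(conditions, each = trials_per_condition)
    order <- pool[sample.int(length(pool))]
    n_trials <- length(order)
    isi <- stats::runif(n_trials, isi_range[1], isi_range[2])
    onset <- cumsum(c(0, (trial_dur + isi)[-n_trials]))
    subsets <- lapply(order, function(N) sort(sample.int(n_tones, N)))
    data.frame(
      trial_id = seq_len(n_trials),
      condition_N = order,
      onset_s = onset,
      isi_s = isi,
      coherent_indices = vapply(subsets, function(i) paste(i - 1, collapse = ","),
                                character(1)),
      seed = vapply(seq_len(n_trials), function(i) derive_seed(seed, "trial", i),
                    integer(1))
    )
  })
  class(log) <- c("session_log", "data.frame")
  if (render) {
    if (is.null(out_dir)) stop("`out_dir` is required when render = TRUE")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(log))) {
      tr <- render_session_trial(log, i, bank, env, crossfade_ms = crossfade_ms)
      write_wav(tr$waveform, file.path(out_dir, sprintf("trial_%04d.wav", i)),
                tr$sample_rate)
    }
    write_event_log(log, file.path(out_dir, "events.tsv"))
  }
  log
}

#' Re-render one trial of a session from its logged subset and seed
#'
#' @param log a `session_log`.
#' @param i trial index.
#' @param bank,env,crossfade_ms as in [make_trial()].
#' @return a `trial_stimulus`.
#' @export
render_session_trial <- function(log, i, bank, env, crossfade_ms = 10) {
  idx <- as.integer(strsplit(log$coherent_indices[i], ",")[[1]]) + 1L
  if (length(idx) == 1 && is.na(idx)) idx <- integer(0)
  sched <- coherence_schedule(log$condition_N[i],
                              n_tones = length(bank$frequencies),
                              indices = idx)
  make_trial(bank, env, sched, seed = log$seed[i], crossfade_ms = crossfade_ms)
}

#' Synthesize a frequency-separation variant trial
#'
#' Builds the supplementary-design trials in which the coherent tones are
#' either contiguous in frequency (`narrow`, ~1.445 ERB adjacent spacing on
#' the default bank) or maximally interspersed among the incoherent tones
#' (`wide`, adjacent spacing >= 4 ERB). Both modes keep the same number of
#' coherent tones, so the broadband amplitude statistics are matched and
#' only the cross-channel topology of the coherence differs.
#'
#' @param n_coherent number of coherent tones (e.g. 4 or 6).
#' @param mode `"narrow"` or `"wide"`.
#' @param bank,env,seed,crossfade_ms as in [make_trial()].
#' @return a `trial_stimulus` with attribute `separation`: list with
#'   `mode`, `n_coherent`, and realized `mean_separation_erb`.
#' @export
make_separation_variant <- function(n_coherent, mode = c("narrow", "wide"),
                                    bank, env, seed = NULL, crossfade_ms = 10) {
  mode <- match.arg(mode)
  n_tones <- length(bank$frequencies)
  if (n_coherent < 2 || n_coherent > n_tones) {
    stop("n_coherent must be between 2 and the number of tones")
  }
  if (mode == "wide") {
    if ((n_tones - 1) / (n_coherent - 1) < 2) {
      stop("wide mode infeasible: cannot intersperse that many coherent tones")
    }
    idx <- unique(round(seq(1, n_tones, length.out = n_coherent)))
  } else {
    start <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "subset"),
                       sample.int(n_tones - n_coherent + 1, 1))
    idx <- start:(start + n_coherent - 1)
  }
  sched <- coherence_schedule(n_coherent, n_tones = n_tones, indices = idx)
  # the trial stream is independent of the subset choice, so narrow and wide
  # variants under the same seed share envelope/phase realizations (paired
  # comparisons differ only in which tones carry the figure)
  tr <- make_trial(bank, env, sched,
                   seed = if (is.null(seed)) NULL else derive_seed(seed, "trial"),
                   crossfade_ms = crossfade_ms)
  attr(tr, "separation") <- list(
    mode = mode, n_coherent = n_coherent,
    mean_separation_erb = mean(diff(idx)) * bank$spacing_erb
  )
  tr
}
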