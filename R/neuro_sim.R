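#' Cohort specification for the synthetic two-group study
#'
#' Defines the design of a simulated cohort: group sizes (default 26
#' typically developing, 21 ASD), coherence conditions (N = 6, 12, 18 of 20
#' tones), trials per condition, and the event-locked epoch geometry of the
#' source-space ROI time courses (1000 Hz, -0.5 to +1.0 s around each
#' coherence-change event). The default 60 trials per condition is a
#' desk-scale setting; the full experiment used 240.
#'
#' @param n_td,n_asd participants per group (>= 1).
#' @param conditions coherent-tone counts N.
#' @param trials_per_condition trials per condition per participant.
#' @param sample_rate epoch sample rate in Hz.
#' @param epoch_window epoch window in s relative to the coherence-change
#'   event; must contain [-0.2, 0.45] (baseline plus both evoked windows).
#' @param master_seed integer master seed; all cohort randomness derives
#'   from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_td = 26, n_asd = 21, conditions = c(6, 12, 18),
                        trials_per_condition = 60, sample_rate = 1000,
                        epoch_window = c(-0.5, 1.0), master_seed = 1) {
  stopifnot(n_td >= 1, n_asd >= 1, trials_per_condition >= 1)
  if (epoch_window[1] > -0.2 || epoch_window[2] < 0.45) {
    stop("epoch_window must contain [-0.2, 0.45] s")
  }
  structure(list(n_td = n_td, n_asd = n_asd, conditions = conditions,
                 trials_per_condition = trials_per_condition,
                 sample_rate = sample_rate, epoch_window = epoch_window,
                 master_seed = master_seed),
            class = "cohort_spec")
}

#' Response-model parameters of the synthetic generator
#'
#' Generative model of the per-trial ROI time course: 1/f background noise
#' plus a deterministic evoked template (M1: Gaussian pulse peaking at 100
#' ms; M2: slow half-sine over 250-450 ms, attenuated in the ASD group)
#' whose amplitude grows linearly with the coherence rank of the condition
#' (slope reduced in ASD), plus a late (default 400-900 ms) induced 30-70
#' Hz gamma burst with random phase per trial, present by default only in
#' the TD group at N = 18. Amplitudes are in arbitrary source units; the
#' background SD of 5 puts the single-trial M1 component around -10 dB SNR.
#'
#' Behavioral scores are generated so that, within the ASD group, the
#' latent neural effect linearly predicts SRS-SCI (negatively: weaker
#' responses, more social symptoms) and SPQ-APS (positively: weaker
#' responses, lower i.e. more abnormal sensory scores), SPQ-APS declines
#' weakly with age, and ICSS-I is independent of the neural effect. Group
#' means/SDs follow the published phenotype table.
#'
#' @param ... overrides of the default parameter list (see source for the
#'   full set).
#' @return list of class `response_model_params`.
#' @export
response_model_params <- function(...) {
  p <- list(
    m1_latency = 0.100, m1_sd = 0.020, m1_amp = 1,
    m2_window = c(0.250, 0.450), m2_amp = 0.8,
    a0 = 1,
    slope = c(TD = 0.30, ASD = 0.10),          # amplitude per coherence rank
    m2_factor = c(TD = 1, ASD = 0.2),          # ASD: M2 nearly absent
    gamma_band = c(30, 70), gamma_window = c(0.40, 0.90),
    gamma_amp = list(TD = c(`6` = 0, `12` = 0, `18` = 0.8),
                     ASD = c(`6` = 0, `12` = 0, `18` = 0)),
    gamma_log_sd = 0.5, gamma_latent_cor = 0.5,
    noise_sd = 5, noise_exponent = 1,
    trial_amp_sd = 1,
    participant_sigma = 0.8,
    behavior = list(
      srs = list(td_mean = 45.2, td_sd = 5.5, asd_mean = 74.6, asd_sd = 11.5,
                 latent_cor = -0.6),
      spq = list(td_mean = 22.1, td_sd = 2.55, asd_mean = 15.35, asd_sd = 4.47,
                 latent_cor = 0.5, age_slope = -0.35),
      icss = list(td_mean = 10.32, td_sd = 4.2, asd_mean = 8.62, asd_sd = 4.1)
    ),
    behavior_noise_scale = 1,
    age_range = c(7, 17)
  )
  override <- list(...)
  bad <- setdiff(names(override), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(override)] <- override
  structure(p, class = "response_model_params")
}

#' Null variant of the response model (both groups share TD parameters)
#'
#' Convenience for type-I-error calibration: group labels have no effect on
#' the generated neural data or behavior links.
#'
#' @param params a [response_model_params()] list.
#' @return params with identical TD/ASD neural parameters.
#' @export
null_params <- function(params = response_model_params()) {
  params$slope["ASD"] <- params$slope["TD"]
  params$m2_factor["ASD"] <- params$m2_factor["TD"]
  params$gamma_amp$ASD <- params$gamma_amp$TD
  params
}

#' Simulate one participant's phenotype record
#'
#' Draws age (uniform on `age_range`), a standard-normal latent neural
#' effect `u` (the participant's response gain is `exp(participant_sigma *
#' u)`, so individual response strength is lognormal and always positive),
#' and behavioral scores from the configured linear models.
#' With `behavior_noise_scale = 0` the ASD SRS-SCI is an exact linear
#' function of the latent effect.
#'
#' @param spec a [cohort_spec()].
#' @param params a [response_model_params()].
#' @param group `"TD"` or `"ASD"`.
#' @param seed integer seed.
#' @param id participant identifier.
#' @return one-row data.frame: id, group, age, srs_sci, spq_aps, icss_i,
#'   latent (standard-normal), gain (multiplicative response gain),
#'   gamma_dev (latent gamma deviate, correlated with `latent`).
#' @export
simulate_participant <- function(spec, params, group = c("TD", "ASD"),
                                 seed = NULL, id = "P01") {
  group <- match.arg(group)
  b <- params$behavior
  ns <- params$behavior_noise_scale
  with_seed(seed, {
    age <- stats::runif(1, params$age_range[1], params$age_range[2])
    u <- stats::rnorm(1)
    rho <- params$gamma_latent_cor
    gamma_dev <- rho * u + sqrt(1 - rho^2) * stats::rnorm(1)
    if (group == "ASD") {
      r <- b$srs$latent_cor
      srs <- b$srs$asd_mean + b$srs$asd_sd * r * u +
        b$srs$asd_sd * sqrt(1 - r^2) * ns * stats::rnorm(1)
      rs <- b$spq$latent_cor
      age_part <- b$spq$age_slope * (age - mean(params$age_range))
      res_sd <- sqrt(max(0, b$spq$asd_sd^2 * (1 - rs^2) -
                           (b$spq$age_slope * diff(params$age_range) / sqrt(12))^2))
      spq <- b$spq$asd_mean + b$spq$asd_sd * rs * u + age_part +
        res_sd * ns * stats::rnorm(1)
      icss <- b$icss$asd_mean + b$icss$asd_sd * ns * stats::rnorm(1)
    } else {
      srs <- b$srs$td_mean + b$srs$td_sd * ns * stats::rnorm(1)
      spq <- b$spq$td_mean + b$spq$td_sd * ns * stats::rnorm(1)
      icss <- b$icss$td_mean + b$icss$td_sd * ns * stats::rnorm(1)
    }
    data.frame(id = id, group = group, age = age,
               srs_sci = srs, spq_aps = spq, icss_i = icss,
               latent = u, gain = exp(params$participant_sigma * u),
               gamma_dev = gamma_dev)
  })
}

# 1/f^alpha background noise, columns independent, deterministically scaled
# so each column has unit variance in expectation, then multiplied by `sd`.
one_over_f_noise <- function(n, cols, fs, exponent = 1, sd = 1) {
  np <- stats::nextn(n, c(2, 3, 5))   # keep FFT lengths 2-3-5 smooth
  f <- fft_freqs(np, fs)
  shape <- numeric(np)
  nz <- f > 0
  # 1/f amplitude profile, flattened below 1 Hz so the variance stays finite
  shape[nz] <- pmax(f[nz], 1)^(-exponent / 2)
  X <- stats::mvfft(matrix(stats::rnorm(np * cols), np, cols)) * shape
  y <- Re(stats::mvfft(X, inverse = TRUE)) / np
  y[seq_len(n), , drop = FALSE] * (sd / sqrt(mean(shape^2)))
}

# Band-limited unit-RMS-in-expectation noise bursts (gamma generator).
band_noise_mat <- function(n, cols, fs, band) {
  np <- stats::nextn(n, c(2, 3, 5))
  f <- fft_freqs(np, fs)
  keep <- f >= band[1] & f <= band[2]
  X <- stats::mvfft(matrix(stats::rnorm(np * cols), np, cols))
  X[!keep, ] <- 0
  y <- Re(stats::mvfft(X, inverse = TRUE)) / np
  y[seq_len(n), , drop = FALSE] / sqrt(mean(keep))
}

# Deterministic evoked template (unit M1 peak) on time axis `t` for a group.
evoked_template <- function(t, params, group) {
  m1 <- params$m1_amp * exp(-(t - params$m1_latency)^2 / (2 * params$m1_sd^2))
  w <- params$m2_window
  m2 <- ifelse(t >= w[1] & t < w[2],
               sin(pi * (t - w[1]) / (w[2] - w[1])), 0)
  m1 + params$m2_amp * params$m2_factor[[group]] * m2
}

#' Simulate event-locked epochs for one participant
#'
#' For every condition, generates `trials_per_condition` trials x 2
#' coherence-change events x 2 hemispheres of ROI time courses:
#' 1/f background + evoked template with amplitude
#' `gain * (a0 + slope[group] * rank(N)) + trial noise` (M2 additionally
#' attenuated for ASD; `gain` is the participant's lognormal response
#' gain) + a random-phase induced gamma burst. The gamma phase is random
#' per epoch, so it cancels in the trial average but survives per-trial
#' spectral analysis.
#'
#' @param record a [simulate_participant()] row.
#' @param spec a [cohort_spec()].
#' @param params a [response_model_params()].
#' @param seed integer seed.
#' @param conditions optional subset of `spec$conditions` to simulate.
#' @return object of class `epoch_set`: `time` (s), `sample_rate`,
#'   `conditions`, `group`, `id`, and `data` - a named list (one entry per
#'   condition) of arrays [time x trial x event x hemisphere].
#' @export
simulate_epochs <- function(record, spec, params, seed = NULL,
                            conditions = spec$conditions) {
  fs <- spec$sample_rate
  w <- spec$epoch_window
  n_t <- round((w[2] - w[1]) * fs) + 1
  t <- w[1] + (seq_len(n_t) - 1) / fs
  group <- as.character(record$group)
  template <- evoked_template(t, params, group)
  gw <- params$gamma_window
  gwin <- cos_window(t, gw[1], gw[2], ramp = 0.05)
  n_trial <- spec$trials_per_condition
  n_ep <- n_trial * 2 * 2
  gamma_amp_by_cond <- params$gamma_amp[[group]]
  with_seed(seed, {
    data <- lapply(conditions, function(N) {
      r <- match(N, spec$conditions)
      amp_te <- record$gain * (params$a0 + params$slope[[group]] * r) +
        stats::rnorm(n_trial * 2, sd = params$trial_amp_sd)
      amp <- rep(amp_te, times = 2)  # same amplitude in both hemispheres
      x <- one_over_f_noise(n_t, n_ep, fs, params$noise_exponent,
                            params$noise_sd) +
        outer(template, amp)
      g0 <- gamma_amp_by_cond[[as.character(N)]]
      g_i <- g0 * exp(params$gamma_log_sd * record$gamma_dev)
      if (g_i > 0) {
        x <- x + band_noise_mat(n_t, n_ep, fs, params$gamma_band) * gwin * g_i
      }
      dim(x) <- c(n_t, n_trial, 2, 2)
      dimnames(x) <- list(NULL, NULL, event = c("e1", "e2"),
                          hemisphere = c("lh", "rh"))
      x
    })
    names(data) <- as.character(conditions)
    structure(list(time = t, sample_rate = fs, conditions = conditions,
                   group = group, id = record$id, data = data),
              class = "epoch_set")
  })
}

# Raised-cosine gate on [t0, t1] with `ramp`-s flanks.
cos_window <- function(t, t0, t1, ramp = 0.05) {
  w <- numeric(length(t))
  w[t >= t0 + ramp & t <= t1 - ramp] <- 1
  up <- t >= t0 & t < t0 + ramp
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  dn <- t > t1 - ramp & t <= t1
  w[dn] <- 0.5 * (1 - cos(pi * (t1 - t[dn]) / ramp))
  w
}

#' Simulate a full cohort
#'
#' Generates participant records and (optionally) their epoch sets. All
#' per-participant seeds are derived deterministically from the master
#' seed, so the whole cohort is bit-reproducible.
#'
#' @param spec a [cohort_spec()].
#' @param params a [response_model_params()].
#' @param seed master seed (defaults to `spec$master_seed`).
#' @param keep_epochs return the epoch sets (can be large); when `FALSE`
#'   only the participant table is returned and epochs can be regenerated
#'   per participant via [cohort_epochs()].
#' @return list of class `cohort`: `participants` (data.frame), `epochs`
#'   (named list of `epoch_set` or `NULL`), `spec`, `params`, `seed`.
#' @export
simulate_cohort <- function(spec, params = response_model_params(),
                            seed = spec$master_seed, keep_epochs = TRUE) {
  groups <- c(rep("TD", spec$n_td), rep("ASD", spec$n_asd))
  ids <- sprintf("%s%02d", groups, c(seq_len(spec$n_td), seq_len(spec$n_asd)))
  participants <- do.call(rbind, lapply(seq_along(ids), function(i) {
    simulate_participant(spec, params, groups[i],
                         seed = derive_seed(seed, "participant", ids[i]),
                         id = ids[i])
  }))
  epochs <- NULL
  if (keep_epochs) {
    epochs <- lapply(seq_along(ids), function(i) {
      cohort_epochs(participants[i, ], spec, params, seed)
    })
    names(epochs) <- ids
  }
  structure(list(participants = participants, epochs = epochs,
                 spec = spec, params = params, seed = seed),
            class = "cohort")
}

#' Regenerate one participant's epochs from the cohort master seed
#'
#' @param record participant row.
#' @param spec,params cohort spec and model parameters.
#' @param seed cohort master seed.
#' @param conditions optional condition subset.
#' @return an `epoch_set`.
#' @export
cohort_epochs <- function(record, spec, params, seed,
                          conditions = spec$conditions) {
  simulate_epochs(record, spec, params,
                  seed = derive_seed(seed, "epochs", record$id),
                  conditions = conditions)
}
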