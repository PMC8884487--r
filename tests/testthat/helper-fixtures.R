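# Shared fixtures. Audio fixtures run at 20 kHz (Nyquist safely above the
# 8 kHz top carrier) to keep FFT sizes small; cohort fixtures run at a
# reduced epoch rate/window that still contains the baseline and both
# component windows.

fix_bank <- function() place_tones(20, 200, 8000)

fix_env <- function(fs = 20000) envelope_params(sample_rate = fs)

fix_trial <- function(n_coherent = 18, seed = 7, fs = 20000, ...) {
  make_trial(fix_bank(), fix_env(fs), coherence_schedule(n_coherent),
             seed = seed, ...)
}

# small, fast cohort geometry
fix_spec <- function(trials = 12, fs = 250, n_td = 3, n_asd = 3, seed = 1) {
  cohort_spec(n_td = n_td, n_asd = n_asd, trials_per_condition = trials,
              sample_rate = fs, epoch_window = c(-0.25, 0.5),
              master_seed = seed)
}

# time axis and index helpers
seg_interior <- function(fs, lo, hi, pad = 0.02) {
  (round((lo + pad) * fs) + 1):(round((hi - pad) * fs))
}

# balanced toy table for the mixed-model oracle tests
toy_measures <- function(seed = 1, sigma_id = 1) {
  set.seed(seed)
  df <- expand.grid(id = paste0("P", 1:6), condition = c(6, 12, 18))
  df$group <- ifelse(df$id %in% paste0("P", 1:3), "TD", "ASD")
  df$combined_z <- stats::rnorm(18) + as.numeric(factor(df$condition)) +
    2 * (df$group == "TD") +
    sigma_id * rep(stats::rnorm(6), 3)[as.integer(factor(df$id))]
  df
}
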