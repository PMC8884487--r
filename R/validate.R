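# Default analysis filterbank for a trial: channels at the tone
# frequencies, envelopes decimated to ~4 kHz when that divides the
# waveform rate evenly.
default_validation_spec <- function(stimulus, target_rate = 4000) {
  fs <- stimulus$sample_rate
  rate <- if (fs %% target_rate == 0) target_rate else NULL
  filterbank_spec(stimulus$bank$frequencies, env_sample_rate = rate)
}

#' Validate the figure-ground design claims for one trial
#'
#' Runs the periphery filterbank over a trial and checks the stimulus
#' design contract: within each tonotopic channel the modulation statistics
#' are stationary across coherent and incoherent segments (per-channel
#' envelope RMS ratio near 1), while the only cue to the figure is the
#' cross-channel coherence (coherent-pair envelope correlations exceed
#' incoherent-pair correlations). Also reports broadband (summed-envelope)
#' statistics per segment class; coherent alignment raises the broadband
#' envelope variance without changing overall level.
#'
#' @param stimulus a `trial_stimulus` (must carry its schedule).
#' @param spec optional [filterbank_spec()]; defaults to channels at the
#'   stimulus tone frequencies with envelopes demodulated to 4 kHz (exact
#'   frequency-domain decimation), which is ample for the 4-24 Hz
#'   modulation band.
#' @param guard_s seconds dropped after each segment boundary before
#'   computing segment statistics (excludes crossfade transients).
#' @param rms_tol pass tolerance on |RMS ratio - 1|.
#' @return object of class `validation_report`: per-channel
#'   `rms_ratio` (coherent/incoherent), within-segment-class correlation
#'   matrices, mean coherent-pair and incoherent-pair correlations,
#'   broadband envelope mean/variance per segment class, and pass flags.
#' @export
validate_trial <- function(stimulus, spec = NULL, guard_s = 0.05,
                           rms_tol = 0.25) {
  if (is.null(stimulus$schedule)) stop("stimulus carries no coherence schedule")
  if (is.null(spec)) spec <- default_validation_spec(stimulus)
  ce <- filterbank_analyze(stimulus, spec)
  env <- ce$envelopes
  n <- nrow(env)
  sm <- segment_masks(stimulus$schedule, ce$sample_rate, n, guard_s)
  idx_coh <- which(sm$class == "coherent")
  idx_inc <- which(sm$class == "incoherent")

  seg_rms <- function(segs) {
    m <- sapply(segs, function(s) sqrt(colMeans(env[sm$masks[[s]], , drop = FALSE]^2)))
    rowMeans(as.matrix(m))
  }
  rms_coh <- seg_rms(idx_coh)
  rms_inc <- seg_rms(idx_inc)
  rms_ratio <- rms_coh / rms_inc

  # correlation matrices averaged over segments of the same class
  seg_cor <- function(segs) {
    mats <- lapply(segs, function(s) stats::cor(env[sm$masks[[s]], , drop = FALSE]))
    Reduce(`+`, mats) / length(mats)
  }
  cor_coh <- seg_cor(idx_coh)
  cor_inc <- seg_cor(idx_inc)

  k <- ncol(env)
  subset <- stimulus$schedule$indices
  pair_means <- function(mat, subset) {
    ut <- upper.tri(mat)
    in_subset <- matrix(FALSE, k, k)
    if (length(subset) > 1) in_subset[subset, subset] <- TRUE
    list(coherent = if (length(subset) > 1) mean(mat[ut & in_subset]) else NA_real_,
         incoherent = mean(abs(mat[ut & !in_subset])))
  }
  pm <- pair_means(cor_coh, subset)

  broadband <- rowSums(env)
  bb_stats <- function(segs) {
    x <- unlist(lapply(segs, function(s) broadband[sm$masks[[s]]]))
    c(mean = mean(x), var = stats::var(x))
  }
  bb <- rbind(coherent = bb_stats(idx_coh), incoherent = bb_stats(idx_inc))

  structure(list(
    center_frequencies = ce$center_frequencies,
    rms_ratio = rms_ratio,
    cor_coherent_segments = cor_coh,
    cor_incoherent_segments = cor_inc,
    mean_coherent_pair_r = pm$coherent,
    mean_incoherent_pair_abs_r = pm$incoherent,
    broadband = bb,
    pass_rms = all(abs(rms_ratio - 1) <= rms_tol),
    pass_coherence = is.na(pm$coherent) || pm$coherent > pm$incoherent,
    rms_tol = rms_tol
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Stimulus validation: %d channels\n", length(x$rms_ratio)))
  cat(sprintf("  per-channel RMS ratio (coh/incoh): mean %.3f, range [%.3f, %.3f] (pass: %s)\n",
              mean(x$rms_ratio), min(x$rms_ratio), max(x$rms_ratio), x$pass_rms))
  cat(sprintf("  mean coherent-pair r: %s; mean incoherent-pair |r|: %.3f (pass: %s)\n",
              ifelse(is.na(x$mean_coherent_pair_r), "NA",
                     sprintf("%.3f", x$mean_coherent_pair_r)),
              x$mean_incoherent_pair_abs_r, x$pass_coherence))
  cat(sprintf("  broadband envelope variance coh/incoh: %.3f\n",
              x$broadband["coherent", "var"] / x$broadband["incoherent", "var"]))
  invisible(x)
}

#' Write a validation report as a tab-separated table
#'
#' @param report a `validation_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  df <- data.frame(channel_hz = report$center_frequencies,
                   rms_ratio = report$rms_ratio)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation-based model observer for figure detection
#'
#' Detection statistic for the presence of a temporally coherent figure:
#' the maximum, over sliding 1-s windows and over greedily grown channel
#' subsets, of the mean pairwise Pearson correlation between channel
#' envelopes. Scale-free (correlations), larger when a coherent subset is
#' present.
#'
#' @param stimulus a `trial_stimulus` or `channel_envelopes`.
#' @param spec optional [filterbank_spec()].
#' @param window_s sliding window length in s.
#' @param hop_s hop between windows in s.
#' @param max_subset largest channel subset considered by the greedy growth.
#' @return the detection statistic (dimensionless scalar).
#' @export
model_observer_detect <- function(stimulus, spec = NULL, window_s = 1,
                                  hop_s = 0.5, max_subset = 8) {
  if (!inherits(stimulus, "channel_envelopes") && is.null(spec)) {
    spec <- default_validation_spec(stimulus)
  }
  ce <- if (inherits(stimulus, "channel_envelopes")) stimulus
        else filterbank_analyze(stimulus, spec)
  env <- ce$envelopes
  n <- nrow(env)
  L <- round(window_s * ce$sample_rate)
  hop <- max(1, round(hop_s * ce$sample_rate))
  starts <- seq(1, max(1, n - L + 1), by = hop)
  best <- -Inf
  for (s0 in starts) {
    C <- stats::cor(env[s0:(s0 + L - 1), , drop = FALSE])
    diag(C) <- NA
    # greedy growth from the best pair
    pair <- which(C == max(C, na.rm = TRUE), arr.ind = TRUE)[1, ]
    subset <- as.integer(pair)
    mean_r <- C[pair[1], pair[2]]
    best <- max(best, mean_r)
    while (length(subset) < min(max_subset, ncol(env))) {
      cand <- setdiff(seq_len(ncol(env)), subset)
      gain <- vapply(cand, function(j) mean(C[subset, j]), numeric(1))
      j <- cand[which.max(gain)]
      subset <- c(subset, j)
      mean_r <- mean(C[subset, subset][upper.tri(diag(length(subset)))])
      best <- max(best, mean_r)
    }
  }
  best
}
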