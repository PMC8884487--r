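#' Collapse the two coherence-change events of each trial
#'
#' Each trial contains two coherence onsets (at 1 s and 3 s of the 4-s
#' stimulus); their event-locked epochs are averaged into one epoch per
#' trial. Optional polarity alignment flips the sign of a hemisphere's
#' epochs so that its average M1-window (50-150 ms) response is positive;
#' source-space current direction is arbitrary per participant and
#' hemisphere, so the flip standardizes it.
#'
#' @param es an `epoch_set` from [simulate_epochs()].
#' @param align apply polarity alignment (per hemisphere).
#' @param m1_window window (s) whose mean defines the alignment sign.
#' @return object of class `collapsed_epochs`: `time`, `sample_rate`,
#'   `conditions`, and `data` - list of arrays [time x trial x hemisphere].
#' @export
collapse_events <- function(es, align = TRUE, m1_window = c(0.05, 0.15)) {
  data <- lapply(es$data, function(x) {
    if (length(dim(x)) != 4 || dim(x)[3] < 2) {
      stop("both coherence-change events must be present in every trial")
    }
    collapsed <- (x[, , 1, , drop = TRUE] + x[, , 2, , drop = TRUE]) / 2
    if (length(dim(collapsed)) == 2) dim(collapsed) <- c(dim(collapsed), 1)
    if (align) {
      m1 <- in_window(es$time, m1_window)
      for (h in seq_len(dim(collapsed)[3])) {
        if (mean(collapsed[m1, , h]) < 0) {
          collapsed[, , h] <- -collapsed[, , h]
        }
      }
    }
    collapsed
  })
  structure(list(time = es$time, sample_rate = es$sample_rate,
                 conditions = es$conditions, group = es$group, id = es$id,
                 data = data),
            class = "collapsed_epochs")
}

#' Baseline z-scoring of an event-locked trace
#'
#' Normalizes a trace (or the columns of a matrix of traces) by the mean
#' and SD of its samples in the baseline window - by default the 200 ms
#' immediately preceding the coherence-change event. The baseline samples
#' of the output have mean 0 and SD 1; the result is invariant to overall
#' scaling of the input.
#'
#' @param x numeric vector, or matrix with time in rows.
#' @param time time axis in s (length `nrow(x)`).
#' @param baseline_window half-open window `[lo, hi)` in s.
#' @return z-scored traces, same shape as `x`.
#' @export
baseline_zscore <- function(x, time, baseline_window = c(-0.2, 0)) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (length(time) != nrow(x)) stop("`time` must match the number of samples")
  b <- in_window(time, baseline_window)
  if (!any(b)) stop("baseline window lies outside the epoch")
  mu <- colMeans(x[b, , drop = FALSE])
  sd <- apply(x[b, , drop = FALSE], 2, stats::sd)
  if (any(sd == 0)) stop("zero baseline variance")
  z <- sweep(sweep(x, 2, mu), 2, sd, `/`)
  if (vec) drop(z) else z
}

#' Evoked component window scores
#'
#' Means of a z-scored trace over the component windows: M1 = [50, 150) ms,
#' M2 = [250, 450) ms, combined = [50, 450) ms. When a matrix is given
#' (e.g. one column per hemisphere) each column is scored and the scores
#' are averaged across columns.
#'
#' @param z z-scored trace (vector) or matrix (time x traces).
#' @param time time axis in s.
#' @param m1_window,m2_window,combined_window half-open windows in s.
#' @return named numeric: `m1_z`, `m2_z`, `combined_z`.
#' @export
window_scores <- function(z, time, m1_window = c(0.05, 0.15),
                          m2_window = c(0.25, 0.45),
                          combined_window = c(0.05, 0.45)) {
  z <- as.matrix(z)
  if (time[length(time)] < combined_window[2] - 1e-9 ||
      time[1] > m1_window[1]) {
    stop("component windows lie outside the epoch")
  }
  score <- function(w) mean(colMeans(z[in_window(time, w), , drop = FALSE]))
  c(m1_z = score(m1_window), m2_z = score(m2_window),
    combined_z = score(combined_window))
}

#' Evoked summary of one participant's epoch set
#'
#' Full evoked chain: collapse the two events, average trials within each
#' hemisphere, z-score against the pre-event baseline per hemisphere, score
#' the component windows, and average the two hemispheres.
#'
#' @param es an `epoch_set`.
#' @param align,baseline_window,... passed to the stages.
#' @return data.frame: one row per condition with `id`, `group`,
#'   `condition`, `m1_z`, `m2_z`, `combined_z`.
#' @export
evoked_summary <- function(es, align = TRUE, baseline_window = c(-0.2, 0), ...) {
  ce <- collapse_events(es, align = align)
  rows <- lapply(seq_along(ce$conditions), function(i) {
    x <- ce$data[[i]]
    avg <- apply(x, c(1, 3), mean)          # time x hemisphere
    z <- baseline_zscore(avg, ce$time, baseline_window)
    s <- window_scores(z, ce$time, ...)
    data.frame(id = ce$id, group = ce$group, condition = ce$conditions[i],
               m1_z = s[["m1_z"]], m2_z = s[["m2_z"]],
               combined_z = s[["combined_z"]])
  })
  do.call(rbind, rows)
}
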