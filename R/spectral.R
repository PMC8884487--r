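#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-half-bandwidth
#' product `nw`, via the exact symmetric tridiagonal eigenproblem. The
#' tapers are orthonormal (pairwise inner products at machine precision)
#' and maximally concentrated in `[-nw/n, nw/n]` cycles/sample. The
#' default plan - 200-ms windows, full time-bandwidth product 4 (half
#' product `nw = 2`) - admits `k = 2 * nw - 1 = 3` well-concentrated
#' tapers.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product.
#' @param k number of tapers (default `2 * nw - 1`).
#' @return n x k matrix, one taper per column, unit energy.
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  if (k >= n) stop("need k < n")
  W <- nw / n
  i <- 0:(n - 1)
  A <- matrix(0, n, n)
  diag(A) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: positive mean for symmetric tapers, positive initial
  # lobe otherwise
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) < 1e-8) s <- v[which.max(abs(cumsum(v[, j]))), j]
    if (s < 0) v[, j] <- -v[, j]
  }
  v
}

#' Multitaper spectrogram of event-locked traces
#'
#' Sliding-window multitaper power estimation: windows of `window_s`
#' seconds (default 200 ms) tile the epoch with 50% overlap; within each
#' window the power is averaged over `k` orthogonal DPSS tapers at
#' time-half-bandwidth `nw` (default `nw = 2`, `k = 3`, i.e. a full
#' time-bandwidth product of 4).
#'
#' @param x trace vector, or matrix with one epoch per column.
#' @param fs sample rate in Hz.
#' @param time optional time axis (s); defaults to samples starting at 0.
#' @param window_s window length in s.
#' @param hop fraction of the window length between window starts.
#' @param nw,k taper plan (see [dpss_tapers()]).
#' @return list of class `mt_spectrogram`: `freq` (Hz), `times` (window
#'   centers, s), `power` (freq x window, or freq x window x epoch),
#'   `window_s`, `nw`, `k`.
#' @export
multitaper_spectrogram <- function(x, fs, time = NULL, window_s = 0.2,
                                   hop = 0.5, nw = 2, k = 2 * nw - 1) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n_t <- nrow(x)
  L <- round(window_s * fs)
  if (n_t < L) stop("epoch is shorter than one analysis window")
  if (is.null(time)) time <- (seq_len(n_t) - 1) / fs
  tapers <- dpss_tapers(L, nw, k)
  starts <- seq(1, n_t - L + 1, by = max(1, round(hop * L)))
  n_w <- length(starts)
  n_ep <- ncol(x)
  # assemble all (window, epoch) segments into one FFT batch per taper
  seg_idx <- outer(0:(L - 1), starts, `+`)        # L x n_w
  segs <- matrix(x[as.vector(seg_idx) + rep((0:(n_ep - 1)) * n_t, each = L * n_w)],
                 L, n_w * n_ep)
  n_f <- L %/% 2 + 1
  P <- 0
  for (j in seq_len(k)) {
    F <- stats::mvfft(segs * tapers[, j])
    P <- P + Mod(F[seq_len(n_f), , drop = FALSE])^2
  }
  P <- P / (k * fs * L)
  dim(P) <- c(n_f, n_w, n_ep)
  power <- P
  if (vec || n_ep == 1) power <- power[, , 1]
  structure(list(freq = (0:(n_f - 1)) * fs / L,
                 times = time[starts] + (L - 1) / (2 * fs),
                 power = power, window_s = window_s, nw = nw, k = k),
            class = "mt_spectrogram")
}

#' Induced (per-trial) power spectrum relative to the incoherent baseline
#'
#' Averages per-trial spectrogram power over trials, log-transforms
#' (base 10), collapses the time axis by averaging, and expresses the
#' post-event spectrum relative to the pre-event (incoherent-portion)
#' baseline as a log-ratio per frequency. Gamma-band power is the mean
#' log-ratio over 30-70 Hz. Because the power average runs over single
#' trials before the log, non-phase-locked (induced) activity survives.
#'
#' @param sg an `mt_spectrogram` of per-trial epochs (freq x window x
#'   epoch), or a 3-d power array with `freq`/`times` given.
#' @param freq,times frequency and window-center axes when `sg` is an array.
#' @param baseline_range time range (s) of baseline windows (a window is
#'   used if fully contained); default everything before the event.
#' @param signal_range time range (s) of signal windows; the default
#'   covers the late response from 400 ms on.
#' @param freq_range spectrum range retained, Hz.
#' @param gamma_band band (Hz) averaged into the gamma statistic.
#' @param window_s analysis window length (taken from `sg` when available).
#' @return list of class `induced_spectrum`: `freq`, `log_ratio` (log10
#'   power re baseline), `gamma` (mean log-ratio over `gamma_band`),
#'   `n_epochs`.
#' @export
induced_power <- function(sg, freq = NULL, times = NULL,
                          baseline_range = c(-Inf, 0),
                          signal_range = c(0.4, 1.0),
                          freq_range = c(5, 70), gamma_band = c(30, 70),
                          window_s = 0.2) {
  if (inherits(sg, "mt_spectrogram")) {
    freq <- sg$freq; times <- sg$times; window_s <- sg$window_s
    power <- sg$power
  } else {
    power <- sg
  }
  if (length(dim(power)) < 3) stop("induced analysis needs >= 2 per-trial epochs")
  if (dim(power)[3] < 2) stop("induced analysis needs >= 2 per-trial epochs")
  half <- window_s / 2 - 1e-9
  base_w <- times - half >= baseline_range[1] & times + half <= baseline_range[2]
  sig_w <- times - half >= signal_range[1] & times + half <= signal_range[2]
  if (!any(base_w)) stop("no analysis window lies inside the baseline range")
  if (!any(sig_w)) stop("no analysis window lies inside the signal range")
  avg <- apply(power, c(1, 2), mean)       # average over trials first
  lp <- log10(avg)
  fsel <- freq >= freq_range[1] & freq <= freq_range[2]
  log_ratio <- rowMeans(lp[fsel, sig_w, drop = FALSE]) -
    rowMeans(lp[fsel, base_w, drop = FALSE])
  fr <- freq[fsel]
  gsel <- fr >= gamma_band[1] & fr <= gamma_band[2]
  structure(list(freq = fr, log_ratio = log_ratio,
                 gamma = mean(log_ratio[gsel]),
                 n_epochs = dim(power)[3]),
            class = "induced_spectrum")
}

#' Induced gamma summary of one participant's epoch set
#'
#' Computes the induced log-ratio spectrum per hemisphere (pooling trials
#' and both coherence-change events as epochs) and averages the two
#' hemispheres, for each condition.
#'
#' @param es an `epoch_set`.
#' @param ... passed to [induced_power()].
#' @return data.frame: one row per condition with `id`, `group`,
#'   `condition`, `gamma_log_ratio`; the per-condition spectra are attached
#'   as the `"spectra"` attribute.
#' @export
induced_summary <- function(es, ...) {
  spectra <- list()
  rows <- lapply(seq_along(es$conditions), function(i) {
    x <- es$data[[i]]
    d <- dim(x)
    per_hemi <- lapply(1:2, function(h) {
      m <- x[, , , h]
      dim(m) <- c(d[1], d[2] * d[3])
      sg <- multitaper_spectrogram(m, es$sample_rate, time = es$time)
      induced_power(sg, ...)
    })
    ind <- per_hemi[[1]]
    ind$log_ratio <- (per_hemi[[1]]$log_ratio + per_hemi[[2]]$log_ratio) / 2
    ind$gamma <- (per_hemi[[1]]$gamma + per_hemi[[2]]$gamma) / 2
    spectra[[as.character(es$conditions[i])]] <<- ind
    data.frame(id = es$id, group = es$group, condition = es$conditions[i],
               gamma_log_ratio = ind$gamma)
  })
  out <- do.call(rbind, rows)
  attr(out, "spectra") <- spectra
  out
}
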