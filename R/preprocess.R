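#' Multi-channel raw EMG container
#'
#' @param samples M x T numeric matrix (channels in rows, arbitrary units).
#' @param rate sampling rate in Hz (default 2048).
#' @param labels M channel labels; defaults to the matrix row names, then to
#'   [muscle_labels_16] when M = 16.
#' @return an `emg_recording` object.
#' @export
emg_recording <- function(samples, rate = 2048, labels = NULL) {
  samples <- as.matrix(samples)
  if (is.null(labels)) {
    labels <- rownames(samples)
    if (is.null(labels) && nrow(samples) == 16) labels <- muscle_labels_16
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  }
  if (length(labels) != nrow(samples))
    stop("labels must match the number of channels")
  rownames(samples) <- labels
  structure(list(samples = samples, rate = rate, labels = labels),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("EMG recording: %d channels x %d samples @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$rate))
  invisible(x)
}

# Zero-phase (forward-backward) IIR filtering with odd reflective padding at
# both ends to suppress start-up transients; pad length is >= 3 filter
# lengths, capped at the signal length - 1.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  pad <- min(3L * max(length(a), length(b)) * 2L, n - 1L)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Band-pass filter a raw EMG recording
#'
#' Zero-phase second-order Butterworth band-pass (default 20-500 Hz), applied
#' forward and backward per channel.
#'
#' @param raw an [emg_recording()].
#' @param low,high band edges in Hz; `high` must lie below Nyquist.
#' @return an `emg_recording` with the same shape.
#' @export
bandpass <- function(raw, low = 20, high = 500) {
  if (!inherits(raw, "emg_recording")) raw <- emg_recording(raw)
  if (low >= high) stop("low cutoff must be below high cutoff")
  if (high >= raw$rate / 2)
    stop("high cutoff must be below the Nyquist frequency (",
         raw$rate / 2, " Hz)")
  bf <- signal::butter(2, c(low, high) / (raw$rate / 2), type = "pass")
  out <- t(apply(raw$samples, 1, function(x) filtfilt_refl(bf$b, bf$a, x)))
  rownames(out) <- raw$labels
  emg_recording(out, rate = raw$rate, labels = raw$labels)
}

#' Compute the EMG envelope (rectify + low-pass)
#'
#' Full-wave rectification followed by a zero-phase second-order Butterworth
#' low-pass (default 10 Hz). Residual filter undershoot below zero is clipped
#' to 0 so downstream factorization sees nonnegative data.
#'
#' @param raw a band-passed [emg_recording()].
#' @param lp low-pass cutoff in Hz.
#' @return M x T nonnegative envelope matrix with a `rate` attribute.
#' @export
envelope <- function(raw, lp = 10) {
  if (!inherits(raw, "emg_recording")) raw <- emg_recording(raw)
  if (lp >= raw$rate / 2) stop("low-pass cutoff must be below Nyquist")
  bf <- signal::butter(2, lp / (raw$rate / 2), type = "low")
  out <- t(apply(abs(raw$samples), 1,
                 function(x) filtfilt_refl(bf$b, bf$a, x)))
  out <- pmax(out, 0)
  rownames(out) <- raw$labels
  attr(out, "rate") <- raw$rate
  out
}

#' Time-normalize an envelope segment to a fixed number of cycle points
#'
#' Linearly interpolates every channel onto `n_points` equally spaced points
#' spanning `[window[1], window[2]]` (inclusive sample indices); the first
#' and last source values are preserved exactly.
#'
#' @param env M x T envelope matrix.
#' @param window integer length-2 vector: start and end sample of the cycle.
#' @param n_points number of output points (default 200).
#' @return M x `n_points` matrix.
#' @export
time_normalize <- function(env, window = c(1L, ncol(env)), n_points = 200) {
  env <- as.matrix(env)
  start <- window[1]; end <- window[2]
  if (start < 1 || end > ncol(env) || end - start < 1)
    stop("window must span at least 2 samples inside the recording")
  xout <- seq(start, end, length.out = n_points)
  out <- t(apply(env, 1, function(x)
    approx(seq_along(x), x, xout = xout)$y))
  rownames(out) <- rownames(env)
  out
}

# Shared worker for the two amplitude-normalization schemes: `cols` selects,
# per trial, the samples over which the per-muscle maximum is pooled.
normalize_pool <- function(trials, cols_list) {
  M <- nrow(trials[[1]])
  pooled_max <- rep(0, M)
  for (i in seq_along(trials)) {
    sel <- trials[[i]][, cols_list[[i]], drop = FALSE]
    pooled_max <- pmax(pooled_max, apply(sel, 1, max))
  }
  zero <- pooled_max == 0
  if (any(zero)) {
    warning("all-zero pooled activity for channel(s): ",
            paste(rownames(trials[[1]])[zero], collapse = ", "),
            "; left unscaled")
    pooled_max[zero] <- 1
  }
  out <- lapply(trials, function(x) x / pooled_max)
  attr(out, "norm_factors") <- pooled_max
  out
}

#' Amplitude-normalize envelopes to the pooled per-muscle peak
#'
#' Divides every muscle by its maximum over the pooled trial set (all
#' unperturbed and perturbed trials of one subject), so values lie in
#' `[0, 1]` and the pooled per-muscle maximum becomes exactly 1. This is the
#' normalization used before factorization.
#'
#' @param trials list of M x K envelope matrices sharing muscle order.
#' @return list of normalized matrices with a `norm_factors` attribute.
#' @export
normalize_amplitude <- function(trials) {
  if (is.matrix(trials)) trials <- list(trials)
  normalize_pool(trials, lapply(trials, function(x) seq_len(ncol(x))))
}

#' Amplitude-normalize envelopes to the pooled stance-period peak
#'
#' Like [normalize_amplitude()], but the per-muscle maximum is taken over
#' stance-period samples only (the normalization used for the epoch-window
#' and co-contraction analysis). Values outside stance may exceed 1.
#'
#' @param trials list of M x K envelope matrices.
#' @param stance integer length-2 vector of stance sample bounds, or a list
#'   of such vectors (one per trial).
#' @return list of normalized matrices with a `norm_factors` attribute.
#' @export
epoch_normalize_amplitude <- function(trials, stance) {
  if (is.matrix(trials)) trials <- list(trials)
  if (!is.list(stance)) stance <- rep(list(stance), length(trials))
  cols <- lapply(seq_along(trials), function(i) {
    w <- stance[[i]]
    if (w[2] < w[1] || w[1] < 1 || w[2] > ncol(trials[[i]]))
      stop("empty or out-of-range stance window for trial ", i)
    seq(w[1], w[2])
  })
  normalize_pool(trials, cols)
}

#' Full preprocessing chain: raw EMG to a normalized cycle envelope
#'
#' Applies the fixed pipeline order: band-pass, segment to the cycle window,
#' rectify and low-pass, time-normalize to `n_points`. Amplitude
#' normalization is a set-level operation and is applied afterwards with
#' [normalize_amplitude()] across all trials of a subject.
#'
#' @param raw an [emg_recording()].
#' @param window cycle window in source samples (left initial contact to end
#'   of right stance).
#' @param n_points cycle samples (default 200).
#' @param low,high,lp filter cutoffs in Hz.
#' @return M x `n_points` envelope matrix (un-normalized amplitude).
#' @export
preprocess_trial <- function(raw, window, n_points = 200,
                             low = 20, high = 500, lp = 10) {
  bp <- bandpass(raw, low, high)
  env <- envelope(bp, lp)
  time_normalize(env, window, n_points)
}
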