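#' Reject channels by electrode impedance
#'
#' Removes every channel whose impedance exceeds the threshold (100 kOhm by
#' default), as done once at the start of each recording session.
#'
#' @param recording an `eeg_recording` whose layout carries impedances.
#' @param threshold_kohm rejection threshold in kOhm.
#' @return The recording with offending channels dropped; the removal report
#'   (character vector of removed names) is attached as attribute `removed`.
#' @export
reject_high_impedance <- function(recording, threshold_kohm = 100) {
  layout <- recording$layout
  if (is.null(layout$impedances))
    stop("recording layout carries no impedances")
  bad <- layout$impedances > threshold_kohm
  if (all(bad)) stop("impedance rejection would remove every channel")
  removed <- layout$names[bad]
  recording$data <- recording$data[!bad, , drop = FALSE]
  recording$layout <- subset_layout(layout, !bad)
  attr(recording, "removed") <- removed
  recording
}

subset_layout <- function(layout, keep) {
  layout$names <- layout$names[keep]
  layout$positions <- layout$positions[keep, , drop = FALSE]
  layout$impedances <- layout$impedances[keep]
  layout
}

#' Design the zero-phase Hamming-window FIR bandpass
#'
#' Window-method (Hamming) FIR design with the transition-bandwidth rule
#' `lower = min(max(0.25 * l_freq, 2), l_freq)` and
#' `upper = min(max(0.25 * h_freq, 2), fs / 2 - h_freq)` Hz, giving
#' half-amplitude (-6 dB) cutoffs at `l_freq - lower / 2` and
#' `h_freq + upper / 2`. For the default 0.5-30 Hz band at 1 kHz these are
#' 0.25 and 33.75 Hz. The filter length is `3.3 / min(transition bw) * fs`,
#' rounded up to an odd number of taps (linear phase).
#'
#' @param l_freq,h_freq passband edges in Hz.
#' @param fs sampling frequency in Hz.
#' @return Object of class `fir_spec`: taps, band edges, transition
#'   bandwidths and the half-amplitude cutoffs.
#' @export
design_bandpass <- function(l_freq = 0.5, h_freq = 30, fs = 1000) {
  if (!(0 < l_freq && l_freq < h_freq && h_freq < fs / 2))
    stop("need 0 < l_freq < h_freq < fs/2")
  l_trans <- min(max(0.25 * l_freq, 2), l_freq)
  h_trans <- min(max(0.25 * h_freq, 2), fs / 2 - h_freq)
  f1 <- l_freq - l_trans / 2   # half-amplitude cutoffs
  f2 <- h_freq + h_trans / 2
  n_taps <- ceiling(3.3 / min(l_trans, h_trans) * fs)
  if (n_taps %% 2 == 0) n_taps <- n_taps + 1
  # windowed-sinc design: ideal bandpass with edges at the half-amplitude
  # cutoffs, Hamming-windowed. (signal::fir1 goes through fir2's 512-point
  # frequency grid, which quantizes sub-hertz edges too coarsely.)
  m <- (n_taps - 1) / 2
  k <- seq_len(n_taps) - 1 - m
  sinc_band <- function(fc) {
    h <- sin(2 * pi * fc / fs * k) / (pi * k)
    h[k == 0] <- 2 * fc / fs
    h
  }
  taps <- (sinc_band(f2) - sinc_band(f1)) *
    as.numeric(signal::hamming(n_taps))
  structure(list(taps = as.numeric(taps), l_freq = l_freq, h_freq = h_freq,
                 fs = fs, l_trans = l_trans, h_trans = h_trans,
                 half_amp_cutoffs = c(f1, f2), n_taps = n_taps),
            class = "fir_spec")
}

#' @export
print.fir_spec <- function(x, ...) {
  cat("<fir_spec>", x$l_freq, "-", x$h_freq, "Hz bandpass @", x$fs, "Hz,",
      x$n_taps, "taps; half-amplitude cutoffs",
      paste(round(x$half_amp_cutoffs, 3), collapse = " / "), "Hz\n")
  invisible(x)
}

#' Magnitude response of a FIR design at given frequencies
#'
#' Direct evaluation of `|H(f)|` from the taps (no FFT grid), handy for
#' locating the realized -6 dB points precisely.
#'
#' @param spec a [design_bandpass()] result.
#' @param freqs frequencies in Hz.
#' @return Numeric vector of linear-gain magnitudes.
#' @export
filter_response <- function(spec, freqs) {
  k <- seq_along(spec$taps) - 1
  vapply(freqs, function(f) {
    ph <- -2i * pi * f / spec$fs * k
    Mod(sum(spec$taps * exp(ph)))
  }, 0)
}

#' Apply the FIR filter with zero net group delay
#'
#' One-pass application of the linear-phase taps with group-delay
#' compensation (the "zero-phase, non-causal" scheme): each channel is
#' edge-reflected by half the filter length, convolved once via overlap-add
#' FFT filtering, then shifted and trimmed back.
#'
#' @param recording an `eeg_recording`.
#' @param spec a [design_bandpass()] result.
#' @return The filtered recording.
#' @export
apply_filter <- function(recording, spec) {
  n <- ncol(recording$data)
  delay <- (spec$n_taps - 1) / 2
  if (n <= spec$n_taps)
    stop("recording (", n, " samples) is shorter than the filter (",
         spec$n_taps, " taps)")
  pad <- delay
  for (j in seq_len(nrow(recording$data))) {
    x <- recording$data[j, ]
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    y <- signal::fftfilt(spec$taps, xp)
    recording$data[j, ] <- y[(pad + delay + 1):(pad + delay + n)]
  }
  recording
}

#' Extract stimulus-locked epochs
#'
#' For each event at onset `T_n`, takes `floor(1.05 * fs)` samples starting
#' `0.3 * fs` samples before the onset sample (window -0.3 to 0.75 s, sample
#' 0 at exactly -0.3 s; 0-based indexing of the recording). Events whose
#' window would be truncated by the recording edges are dropped with a
#' warning.
#'
#' @param recording an `eeg_recording`.
#' @param schedule event schedule (one session; onsets in this recording's
#'   time base).
#' @param session which session's events to use.
#' @return Object of class `epoch_set`: list with `data` (trials x channels x
#'   samples array, uV), `stimulus_id`, `fs`, `window = c(-0.3, 0.75)`,
#'   `channels`, `dropped` (indices of truncated events).
#' @export
extract_epochs <- function(recording, schedule, session = NULL) {
  ev <- schedule
  if (!is.null(session)) ev <- ev[ev$session == session, , drop = FALSE]
  fs <- recording$fs
  n_samp <- floor(1.05 * fs + 1e-9)
  n <- ncol(recording$data)
  start0 <- floor(ev$onset * fs) - round(0.3 * fs)  # 0-based first sample
  ok <- start0 >= 0 & (start0 + n_samp) <= n
  if (any(!ok))
    warning(sum(!ok), " event(s) truncated at the recording edges; dropped")
  idx_keep <- which(ok)
  nch <- nrow(recording$data)
  data <- array(0, dim = c(length(idx_keep), nch, n_samp))
  for (i in seq_along(idx_keep)) {
    s0 <- start0[idx_keep[i]]
    data[i, , ] <- recording$data[, (s0 + 1):(s0 + n_samp)]
  }
  structure(list(data = data, stimulus_id = ev$stimulus_id[idx_keep],
                 fs = fs, window = c(-0.3, 0.75),
                 channels = rownames(recording$data) %||%
                   recording$layout$names,
                 layout = recording$layout,
                 dropped = which(!ok)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set>", d[1], "trials x", d[2], "channels x", d[3],
      "samples @", x$fs, "Hz, window [", x$window[1], ",", x$window[2], ") s\n")
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean of the baseline interval
#' (-0.3, -0.1) s, i.e. the first `floor(0.2 * fs)` samples of the epoch.
#'
#' @param epochs an [extract_epochs()] result (window starting at -0.3 s).
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  stopifnot(abs(epochs$window[1] + 0.3) < 1e-9)
  nb <- floor(0.2 * epochs$fs + 1e-9)
  bl <- apply(epochs$data[, , seq_len(nb), drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over samples
  epochs
}

#' Per-channel average RMS over epochs
#'
#' For channel j, the mean over trials of the within-trial RMS amplitude:
#' `aRMS_j = (1/Nn) * sum_n sqrt((1/Nt) * sum_t X_j[n, t]^2)`.
#'
#' @param epochs an `epoch_set`.
#' @param quantile_type quartile convention for the Tukey fences passed to
#'   [stats::quantile()] (7 = linear interpolation, the default; 2 gives the
#'   Tukey-hinge-like averaging convention).
#' @return Object of class `channel_stats`: `arms` (named per-channel
#'   vector), quartiles `q1`, `q3`, `iqr` and the `fences`.
#' @export
compute_arms <- function(epochs, quantile_type = 7) {
  d <- dim(epochs$data)
  if (d[1] < 1) stop("no trials")
  rms_tj <- sqrt(apply(epochs$data^2, c(1, 2), mean))  # trials x channels
  arms <- colMeans(rms_tj)
  names(arms) <- epochs$channels
  q <- stats::quantile(arms, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  iqr <- q[2] - q[1]
  structure(list(arms = arms, q1 = q[1], q3 = q[2], iqr = iqr,
                 fences = c(low = q[1] - 1.5 * iqr, high = q[2] + 1.5 * iqr)),
            class = "channel_stats")
}

#' Reject channels with outlier average RMS
#'
#' Tukey-fence rule: channel j is removed iff its aRMS lies strictly outside
#' `[q1 - 1.5 IQR, q3 + 1.5 IQR]`, quartiles taken over the channel set.
#'
#' @param stats a [compute_arms()] result.
#' @return Logical keep-mask (named by channel) with attribute `removed`
#'   listing the rejected channel names.
#' @export
reject_outlier_channels <- function(stats) {
  if (length(stats$arms) < 4)
    stop("need at least 4 channels to estimate quartiles")
  keep <- stats$arms >= stats$fences["low"] &
    stats$arms <= stats$fences["high"]
  if (!any(keep)) stop("aRMS rejection would remove every channel")
  attr(keep, "removed") <- names(stats$arms)[!keep]
  keep
}

#' Drop channels from an epoch set
#'
#' @param epochs an `epoch_set`.
#' @param keep logical mask or character vector of channel names to keep.
#' @return The reduced `epoch_set` (channel order preserved).
#' @export
apply_channel_mask <- function(epochs, keep) {
  if (is.character(keep)) keep <- epochs$channels %in% keep
  epochs$data <- epochs$data[, keep, , drop = FALSE]
  epochs$channels <- epochs$channels[keep]
  if (!is.null(epochs$layout)) epochs$layout <- subset_layout(epochs$layout,
                                                              keep)
  epochs
}

#' Run the full preprocessing chain on one session
#'
#' Impedance rejection, FIR bandpass on the continuous recording, epoching,
#' baseline correction, then aRMS outlier channel rejection.
#'
#' @param recording an `eeg_recording` (with impedances in its layout).
#' @param schedule events for this recording.
#' @param session session selector passed to [extract_epochs()].
#' @param l_freq,h_freq bandpass edges in Hz.
#' @param impedance_threshold impedance rejection threshold, kOhm.
#' @return A baseline-corrected `epoch_set` with attribute `reports` (lists
#'   of removed channel names per stage).
#' @export
preprocess_session <- function(recording, schedule, session = NULL,
                               l_freq = 0.5, h_freq = 30,
                               impedance_threshold = 100) {
  rec <- reject_high_impedance(recording, impedance_threshold)
  imp_removed <- attr(rec, "removed")
  spec <- design_bandpass(l_freq, h_freq, rec$fs)
  rec <- apply_filter(rec, spec)
  ep <- baseline_correct(extract_epochs(rec, schedule, session))
  st <- compute_arms(ep)
  keep <- reject_outlier_channels(st)
  ep <- apply_channel_mask(ep, keep)
  attr(ep, "reports") <- list(impedance_removed = imp_removed,
                              arms_removed = attr(keep, "removed"))
  ep
}
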