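#' Synthetic EEG channel layout
#'
#' Builds a schematic high-density cap layout with 10-05-style names arranged
#' in anterior-posterior rows (Fp, AF, F, FC, C, CP, P, PO, O, I) and 2-D
#' scalp positions: `x` in `[-1, 1]` left to right, `y` in `[-1, 1]` back to
#' front. Posterior rows carry the occipital/parietal ("O"/"P") identifiers
#' used by the ERP channel selection. This is a synthetic stand-in layout,
#' not a measured montage.
#'
#' @param n number of channels (default 128).
#' @param impedance default impedance in kOhm assigned to every channel.
#' @return Object of class `channel_layout`: list with `names`, `positions`
#'   (n x 2 matrix, columns `x`, `y`) and `impedances` (kOhm).
#' @export
channel_layout <- function(n = 128L, impedance = 10) {
  prefixes <- c("Fp", "AF", "F", "FC", "C", "CP", "P", "PO", "O", "I")
  ys <- seq(0.9, -0.9, length.out = length(prefixes))
  per_row <- ceiling(n / length(prefixes))
  # odd numbers on the left, even on the right, z on the midline
  mk_row <- function(pref, m) {
    half <- (m - 1) %/% 2
    left <- if (half > 0) sprintf("%s%d", pref, rev(seq_len(half) * 2 - 1))
    right <- if (m - half - 1 > 0)
      sprintf("%s%d", pref, seq_len(m - half - 1) * 2)
    c(left, paste0(pref, "z"), right)
  }
  names <- character(0); xs <- numeric(0); yy <- numeric(0)
  for (i in seq_along(prefixes)) {
    m <- min(per_row, n - length(names))
    if (m <= 0) break
    names <- c(names, mk_row(prefixes[i], m))
    xs <- c(xs, if (m == 1) 0 else seq(-0.9, 0.9, length.out = m))
    yy <- c(yy, rep(ys[i], m))
  }
  stopifnot(!anyDuplicated(names), length(names) == n)
  structure(list(names = names,
                 positions = cbind(x = xs, y = yy),
                 impedances = rep(impedance, n)),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout>", length(x$names), "channels;",
      sum(x$impedances > 100), "above 100 kOhm\n")
  invisible(x)
}

#' ERP effect parameters for the synthetic generator
#'
#' The generator's evoked response is the sum of two Gaussian-windowed
#' components: a negative deflection at 150 ms and a positive deflection at
#' 300 ms after onset (the atypical latencies seen with full-field
#' phosphene-like stimuli, rather than classic N70/P100 peaks). Stimulus
#' features modulate the component amplitudes:
#' positive amplitude grows linearly with lit area, negative amplitude decays
#' exponentially with area, the negative component is scaled up on the scalp
#' hemisphere contralateral to the stimulus centroid and for inferior-field
#' centroids, both components decay with centroid eccentricity, and all
#' amplitudes are weighted toward posterior channels.
#'
#' @param pos_latency,pos_width,pos_base,pos_area_gain positive component:
#'   peak latency (s), Gaussian width (s), base amplitude (uV) and linear
#'   gain (uV per lit cell).
#' @param neg_latency,neg_width,neg_base,neg_area_atten negative component:
#'   latency (s), width (s), base amplitude (uV, given as a positive number)
#'   and exponential attenuation rate per lit cell.
#' @param laterality_gain contralateral scaling of the negative component in
#'   `[0, 1)` per unit of normalized horizontal centroid offset times
#'   normalized channel x-position.
#' @param elevation_gain inferior-field scaling of the negative component per
#'   unit of normalized vertical centroid offset.
#' @param eccentricity_rate amplitude decay rate per grid unit of centroid
#'   distance from the grid centre (foveated-retina surrogate).
#' @param topo_floor fraction of the posterior amplitude retained at the most
#'   frontal channel (posterior channels get weight 1).
#' @return Object of class `erp_params`.
#' @export
erp_params <- function(pos_latency = 0.30, pos_width = 0.06, pos_base = 1.0,
                       pos_area_gain = 0.45, neg_latency = 0.15,
                       neg_width = 0.045, neg_base = 8.0,
                       neg_area_atten = 0.06, laterality_gain = 0.8,
                       elevation_gain = 0.6, eccentricity_rate = 0.18,
                       topo_floor = 0.25) {
  stopifnot(pos_width > 0, neg_width > 0,
            pos_latency > 0, pos_latency < 0.75,
            neg_latency > 0, neg_latency < 0.75,
            laterality_gain >= 0, laterality_gain < 1,
            topo_floor >= 0, topo_floor <= 1)
  structure(as.list(environment()), class = "erp_params")
}

#' Noise parameters for the synthetic generator
#'
#' Background activity is per-channel independent Gaussian noise with a
#' 1/f^alpha amplitude spectrum. Optional ocular artifacts are smooth
#' transients weighted toward frontal channels.
#'
#' @param alpha spectral exponent of the 1/f^alpha power spectrum.
#' @param std per-channel standard deviation in uV.
#' @param ocular_rate artifacts per minute (0 disables them, the default).
#' @param ocular_amplitude artifact peak amplitude in uV at frontal channels.
#' @return Object of class `noise_params`.
#' @export
noise_params <- function(alpha = 1, std = 9, ocular_rate = 0,
                         ocular_amplitude = 80) {
  stopifnot(std > 0, ocular_rate >= 0, alpha >= 0)
  structure(list(alpha = alpha, std = std, ocular_rate = ocular_rate,
                 ocular_amplitude = ocular_amplitude),
            class = "noise_params")
}

#' Per-channel ERP template for one stimulus
#'
#' @param stim a [stimulus()].
#' @param layout a [channel_layout()].
#' @param params an [erp_params()].
#' @param grid the [grid_spec()] of the stimulus.
#' @param fs sampling frequency in Hz.
#' @return Channels x samples matrix covering `[0, 0.75)` s after onset
#'   (`round(0.75 * fs)` samples), in uV.
#' @export
make_erp_template <- function(stim, layout, params = erp_params(),
                              grid = grid_spec(), fs = 1000) {
  n <- round(0.75 * fs)
  t <- (seq_len(n) - 1) / fs
  g <- function(mu, w) exp(-(t - mu)^2 / (2 * w^2))
  mr <- (grid$n_rows - 1) / 2; mc <- (grid$n_cols - 1) / 2
  # normalized centroid offsets: h > 0 right visual field, v > 0 inferior
  h <- (stim$centroid[["col"]] - mc) / max(mc, 1)
  v <- (stim$centroid[["row"]] - mr) / max(mr, 1)
  ecc <- sqrt((stim$centroid[["col"]] - mc)^2 +
              (stim$centroid[["row"]] - mr)^2)
  a <- stim$area
  amp_pos <- params$pos_base + params$pos_area_gain * a
  amp_neg <- params$neg_base * exp(-params$neg_area_atten * (a - 1))
  scale_ecc <- exp(-params$eccentricity_rate * ecc)
  x <- layout$positions[, "x"]; y <- layout$positions[, "y"]
  topo <- params$topo_floor + (1 - params$topo_floor) * (1 - y) / 2
  # contralateral: left-field stimulus (h < 0) boosts right-scalp (x > 0)
  lat <- 1 + params$laterality_gain * (-h) * x
  elev <- 1 + params$elevation_gain * v
  wav_pos <- amp_pos * g(params$pos_latency, params$pos_width)
  wav_neg <- amp_neg * g(params$neg_latency, params$neg_width)
  tpl <- scale_ecc * (outer(topo, wav_pos) -
                      outer(topo * lat * elev, wav_neg))
  rownames(tpl) <- layout$names
  tpl
}

# 1/f^alpha Gaussian noise, one channel, via spectral shaping
pink_noise <- function(n, fs, alpha, std) {
  nf <- (n - 1) %/% 2  # conjugate-paired positive-frequency bins
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  full <- complex(length.out = n)
  full[1 + seq_len(nf)] <- spec
  full[n + 1 - seq_len(nf)] <- Conj(spec)
  if (n %% 2 == 0)  # real-valued Nyquist bin
    full[n / 2 + 1] <- stats::rnorm(1) * (fs / 2)^(-alpha / 2)
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x * (std / s)
}

#' Synthesize a continuous multichannel EEG recording
#'
#' Sums the per-stimulus ERP templates at their scheduled onsets on top of
#' 1/f^alpha background noise (and optional frontal ocular transients). The
#' recording length is rounded up to an integer number of seconds past the
#' last epoch window.
#'
#' @param schedule an [generate_schedule()] result; only events of `session`
#'   are used and their onsets are interpreted relative to this recording.
#' @param registry the stimulus registry the schedule refers to.
#' @param layout a [channel_layout()].
#' @param erp an [erp_params()]; `NULL` gives a noise-only recording.
#' @param noise a [noise_params()]; `NULL` gives a noiseless recording.
#' @param session which session of the schedule to synthesize.
#' @param fs sampling frequency in Hz.
#' @param seed integer seed (noise and artifacts).
#' @return Object of class `eeg_recording`: list with `data` (channels x
#'   samples matrix, uV), `fs`, `layout`.
#' @export
synthesize_recording <- function(schedule, registry, layout,
                                 erp = erp_params(), noise = noise_params(),
                                 session = 1L, fs = 1000, seed = 1L) {
  ev <- schedule[schedule$session == session, , drop = FALSE]
  if (nrow(ev) == 0) stop("schedule has no events for session ", session)
  if (!is.null(erp) && any(!is.finite(unlist(erp))))
    stop("non-finite value in ERP parameters")
  nch <- length(layout$names)
  dur <- ceiling(max(ev$onset) + 1.0)
  n <- dur * fs
  grid <- registry$grid
  data <- matrix(0, nch, n)
  if (!is.null(noise)) {
    data <- with_seed(seed, {
      ocular <- matrix(0, nch, n)
      if (noise$ocular_rate > 0) {
        n_art <- stats::rpois(1, noise$ocular_rate * dur / 60)
        if (n_art > 0) {
          centers <- sort(stats::runif(n_art, 0.2, dur - 0.2))
          frontal <- (1 + layout$positions[, "y"]) / 2
          tt <- (seq_len(n) - 1) / fs
          for (tc in centers) {
            bump <- exp(-(tt - tc)^2 / (2 * 0.05^2))
            ocular <- ocular + noise$ocular_amplitude * outer(frontal, bump)
          }
        }
      }
      bg <- t(vapply(seq_len(nch), function(j)
        pink_noise(n, fs, noise$alpha, noise$std), numeric(n)))
      bg + ocular
    })
  }
  if (!is.null(erp)) {
    tpl_cache <- new.env(parent = emptyenv())
    for (k in seq_len(nrow(ev))) {
      id <- ev$stimulus_id[k]
      tpl <- get0(id, envir = tpl_cache)
      if (is.null(tpl)) {
        tpl <- make_erp_template(get_stimulus(registry, id), layout, erp,
                                 grid, fs)
        assign(id, tpl, envir = tpl_cache)
      }
      i0 <- floor(ev$onset[k] * fs) + 1L
      idx <- i0:(i0 + ncol(tpl) - 1L)
      if (max(idx) > n) stop("event ", k, " extends past the recording end")
      data[, idx] <- data[, idx] + tpl
    }
  }
  rownames(data) <- layout$names
  structure(list(data = data, fs = fs, layout = layout),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording>", nrow(x$data), "channels x", ncol(x$data),
      "samples @", x$fs, "Hz (", round(ncol(x$data) / x$fs, 1), "s )\n")
  invisible(x)
}

#' Simulate electrode impedances
#'
#' Marks exactly `n_bad` randomly chosen channels with an impedance above the
#' 100 kOhm rejection threshold (uniform in 120-200 kOhm); the remaining
#' channels get values uniform in 5-60 kOhm.
#'
#' @param layout a [channel_layout()].
#' @param n_bad number of high-impedance channels.
#' @param seed integer seed.
#' @return The layout with its `impedances` replaced.
#' @export
simulate_impedances <- function(layout, n_bad = 5L, seed = 1L) {
  nch <- length(layout$names)
  if (n_bad > nch) stop("n_bad exceeds the channel count")
  with_seed(seed, {
    imp <- stats::runif(nch, 5, 60)
    if (n_bad > 0) {
      bad <- sample.int(nch, n_bad)
      imp[bad] <- stats::runif(n_bad, 120, 200)
    }
    layout$impedances <- imp
  })
  layout
}
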