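# Minimal continuous-EEG EDF reader/writer (16-bit, 1-second data records).
# Events travel in a sidecar tab-separated file (see write_events); the EDF+
# annotations channel is not used. No installed R package provides EDF I/O,
# so the format subset needed for round-tripping recordings is written here.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a per-channel symmetric physical
#' range with 0.01 percent headroom, so the round-trip error is bounded by
#' `max(abs(x)) * 1.0001 / 32767` per channel. Data records are 1 s long;
#' recordings whose length is not an integer number of seconds are zero-padded
#' to the next full second (with a message).
#'
#' @param recording an `eeg_recording` (see [synthesize_recording()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  fs <- recording$fs
  if (fs != round(fs) || fs <= 0)
    stop("EDF writer supports positive integer sampling rates only, got ", fs)
  nch <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n) {
    message("padding recording with ", n_rec * fs - n,
            " zero samples to fill the last 1 s data record")
    data <- cbind(data, matrix(0, nch, n_rec * fs - n))
  }
  pmax <- apply(abs(data), 1, max) * 1.0001
  pmax[pmax == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nch + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(nch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rownames(data) %||% sprintf("ch%d", seq_len(nch)),
           pad_field, "", width = 16),
    rep(pad_field("", 80), nch),
    rep(pad_field("uV", 8), nch),
    vapply(signif(-pmax, 7), pad_field, "", width = 8),
    vapply(signif(pmax, 7), pad_field, "", width = 8),
    rep(pad_field(-32768, 8), nch),
    rep(pad_field(32767, 8), nch),
    rep(pad_field("", 80), nch),
    rep(pad_field(fs, 8), nch),
    rep(pad_field("", 32), nch))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  # quantize with the exact inverse of the reader's (phys, dig) mapping,
  # using the header's 7-significant-digit physical range
  pmax_hdr <- as.numeric(signif(pmax, 7))
  scale <- 65535 / (2 * pmax_hdr)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round(data[, idx, drop = FALSE] * scale - 0.5)
    if (any(dig > 32767 | dig < -32768))
      stop("sample exceeds the 16-bit digital range after scaling")
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @param layout optional [channel_layout()] to attach (positions/impedances
#'   are not stored in EDF); channel names must match the file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path, layout = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-record sample counts are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = nch * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = nch)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block)
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- data * scale + (pmax - scale * dmax)
  rownames(data) <- labels
  if (!is.null(layout)) {
    if (!identical(layout$names, labels))
      stop("layout channel names do not match the EDF file")
  }
  structure(list(data = data, fs = fs, layout = layout),
            class = "eeg_recording")
}

#' Write / read a full recording (EDF plus events sidecar)
#'
#' Convenience wrappers bundling [write_edf()] with [write_events()]: the
#' events file sits next to the EDF with suffix `_events.tsv`.
#'
#' @param recording an `eeg_recording`.
#' @param events an event schedule data frame.
#' @param path EDF file path (the sidecar path is derived from it).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns `list(recording, events)`.
#' @export
write_recording <- function(recording, events, path) {
  write_edf(recording, path)
  write_events(events, events_path_for(path))
  invisible(path)
}

#' @rdname write_recording
#' @param layout optional layout passed to [read_edf()].
#' @export
read_recording <- function(path, layout = NULL) {
  list(recording = read_edf(path, layout),
       events = read_events(events_path_for(path)))
}

events_path_for <- function(path) paste0(sub("\\.edf$", "", path),
                                         "_events.tsv")
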