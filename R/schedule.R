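#' Generate a presentation schedule
#'
#' Builds the event schedule of the experiment: each session presents every
#' stimulus the same number of times in randomized order, split into
#' sub-sessions of a fixed number of presentations. Each stimulus is flashed
#' for `stimulus_duration` seconds and followed by an inter-stimulus interval
#' drawn uniformly from `isi_range`, so consecutive onsets within a session
#' are separated by `stimulus_duration + ISI`. Onset times restart at
#' `lead_in` for every session (each session is its own continuous
#' recording).
#'
#' The default design is 2 sessions x 30 sub-sessions x 50 presentations over
#' a 60-stimulus registry: 3000 events, 25 repetitions per stimulus per
#' session.
#'
#' @param registry a [build_stimulus_registry()] result (or character vector
#'   of stimulus ids).
#' @param sessions number of sessions.
#' @param subsessions sub-sessions per session.
#' @param presentations presentations per sub-session.
#' @param stimulus_duration stimulus-on time in seconds (default 0.75).
#' @param isi_range length-2 numeric, uniform ISI bounds in seconds
#'   (default `c(1, 1.25)`).
#' @param lead_in seconds of recording before the first onset of a session
#'   (must exceed the epoch baseline of 0.3 s).
#' @param seed integer seed controlling presentation order and ISIs.
#' @return Object of class `event_schedule`: a data frame with columns
#'   `onset`, `duration`, `stimulus_id`, `session`, `subsession`, plus
#'   attributes `stimulus_duration`, `isi_range`.
#' @export
generate_schedule <- function(registry, sessions = 2L, subsessions = 30L,
                              presentations = 50L, stimulus_duration = 0.75,
                              isi_range = c(1.0, 1.25), lead_in = 2,
                              seed = 1L) {
  ids <- if (is.character(registry)) registry else stimulus_ids(registry)
  n_stim <- length(ids)
  per_session <- subsessions * presentations
  if (per_session %% n_stim != 0)
    stop("presentations per session (", per_session,
         ") not divisible by the number of stimuli (", n_stim, ")")
  reps <- per_session %/% n_stim
  stopifnot(lead_in >= 0.3, isi_range[1] <= isi_range[2], isi_range[1] > 0)
  ev <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(sessions), function(s) {
      order_s <- sample(rep(ids, reps))
      gaps <- stimulus_duration +
        stats::runif(per_session, isi_range[1], isi_range[2])
      onsets <- lead_in + c(0, cumsum(gaps[-per_session]))
      data.frame(onset = onsets, duration = stimulus_duration,
                 stimulus_id = order_s, session = s,
                 subsession = rep(seq_len(subsessions),
                                  each = presentations),
                 stringsAsFactors = FALSE)
    }))
  })
  rownames(ev) <- NULL
  structure(ev, stimulus_duration = stimulus_duration, isi_range = isi_range,
            class = c("event_schedule", "data.frame"))
}

#' Write / read a schedule as a tab-separated events file
#'
#' Columns: onset, duration, stimulus_id, session, subsession.
#'
#' @param schedule an [generate_schedule()] result (or compatible data frame).
#' @param path file path.
#' @return `write_events` returns `path` invisibly; `read_events` returns an
#'   `event_schedule` data frame.
#' @export
write_events <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset", "duration", "stimulus_id", "session", "subsession")
  missing <- setdiff(need, names(ev))
  if (length(missing))
    stop("events file lacks column(s): ", paste(missing, collapse = ", "))
  structure(ev, class = c("event_schedule", "data.frame"))
}
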