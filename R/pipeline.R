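#' Simulate a complete scaled study
#'
#' Convenience wrapper: builds (or accepts) a registry, generates a schedule,
#' synthesizes one continuous recording per session with simulated
#' impedances, and runs the preprocessing chain, returning analysis-ready
#' baseline-corrected epochs pooled over sessions.
#'
#' @param registry stimulus registry (default full 60-stimulus registry) or a
#'   character vector of stimulus ids to restrict the schedule to.
#' @param n_channels,fs layout size and sampling rate.
#' @param sessions,subsessions,presentations schedule design.
#' @param erp,noise generator parameter objects (see [erp_params()],
#'   [noise_params()]); `erp = NULL` gives noise-only data.
#' @param n_bad_channels high-impedance channels per session.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param preprocess run the preprocessing chain (`FALSE` returns raw
#'   continuous recordings instead of epochs).
#' @return List with `epochs` (or `recordings`), `schedule`, `registry`,
#'   `layout`, `tasks`.
#' @export
simulate_study <- function(registry = NULL, n_channels = 128, fs = 1000,
                           sessions = 2L, subsessions = 30L,
                           presentations = 50L, erp = erp_params(),
                           noise = noise_params(), n_bad_channels = 5L,
                           seed = 1L, preprocess = TRUE) {
  full <- build_stimulus_registry()
  if (is.null(registry)) registry <- full
  if (is.character(registry)) {
    ids <- registry
    registry <- full
    registry$stimuli <- registry$stimuli[ids]
  }
  tasks <- build_task_registry(full)
  schedule <- generate_schedule(registry, sessions = sessions,
                                subsessions = subsessions,
                                presentations = presentations,
                                seed = seed)
  layout <- channel_layout(n_channels)
  ep_list <- list(); rec_list <- list()
  for (s in seq_len(sessions)) {
    lay_s <- simulate_impedances(layout, n_bad_channels,
                                 seed = seed + 1000L + s)
    rec <- synthesize_recording(schedule, registry, lay_s, erp, noise,
                                session = s, fs = fs,
                                seed = seed + 2000L + s)
    if (!preprocess) { rec_list[[s]] <- rec; next }
    ep_list[[s]] <- preprocess_session(rec, schedule, session = s)
  }
  out <- list(schedule = schedule, registry = registry, layout = layout,
              tasks = tasks)
  if (!preprocess) { out$recordings <- rec_list; return(out) }
  out$epochs <- pool_epochs(ep_list)
  out
}

#' Pool epoch sets from several sessions
#'
#' Concatenates trials, keeping only the channels that survived rejection in
#' every session (channel order of the first set).
#'
#' @param epoch_list list of `epoch_set` objects.
#' @return A single pooled `epoch_set`.
#' @export
pool_epochs <- function(epoch_list) {
  if (length(epoch_list) == 1) return(epoch_list[[1]])
  common <- Reduce(intersect, lapply(epoch_list, `[[`, "channels"))
  if (length(common) == 0) stop("no channel survived in every session")
  eps <- lapply(epoch_list, apply_channel_mask, keep = common)
  out <- eps[[1]]
  out$data <- do.call(abind3, lapply(eps, `[[`, "data"))
  out$stimulus_id <- unlist(lapply(eps, `[[`, "stimulus_id"))
  out
}

# bind 3-d arrays along the first (trial) dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Decode one task end to end
#'
#' Maps trials to task classes, vectorizes, runs cross-validated calibrated
#' decoding, the fold-matched random decoder and the chance-level test.
#'
#' @param epochs an `epoch_set`.
#' @param task a [decoding_task()].
#' @param seed integer seed.
#' @param n_subjects Bonferroni factor for [compare_to_chance()].
#' @param ... passed to [crossval_decode()].
#' @return List: `real` (fold_result), `random` (fold_result), `chance`
#'   (test summary), `task`.
#' @export
decode_task <- function(epochs, task, seed = 1L, n_subjects = 1, ...) {
  feats <- vectorize(epochs)
  labels <- assign_classes(task, epochs$stimulus_id)
  real <- crossval_decode(feats, labels, balanced = task$balanced,
                          seed = seed, ...)
  real$task <- task$name
  rand <- random_decoder(real, seed = seed + 1L)
  list(real = real, random = rand,
       chance = compare_to_chance(real, rand, n_subjects = n_subjects),
       task = task$name)
}
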