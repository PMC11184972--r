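# shared fixtures, built in code at test time

default_registry <- build_stimulus_registry()
default_tasks <- build_task_registry(default_registry)

# small epoch_set with hand-set data for oracle tests
make_epochs <- function(data, stimulus_id = NULL, fs = 100,
                        channels = NULL) {
  d <- dim(data)
  structure(list(
    data = data,
    stimulus_id = stimulus_id %||% paste0("s", seq_len(d[1])),
    fs = fs, window = c(-0.3, 0.75),
    channels = channels %||% paste0("ch", seq_len(d[2])),
    layout = NULL, dropped = integer(0)
  ), class = "epoch_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick toy 2-class feature set: class signal on the first n_signal features
toy_features <- function(n = 60, p = 12, n_signal = 3, effect = 2,
                         seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == "b", seq_len(n_signal)] <- x[y == "b", seq_len(n_signal)] + effect
  list(x = x, y = y)
}
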