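make_rec <- function(data, fs = 1000, impedances = NULL, names = NULL) {
  nch <- nrow(data)
  lay <- channel_layout(nch)
  if (!is.null(names)) lay$names <- names
  if (!is.null(impedances)) lay$impedances <- impedances
  rownames(data) <- lay$names
  structure(list(data = data, fs = fs, layout = lay),
            class = "eeg_recording")
}

test_that("impedance rejection drops exactly the channels above threshold", {
  rec <- make_rec(matrix(rnorm(4 * 100), 4, 100),
                  impedances = c(50, 150, 99, 101))
  out <- reject_high_impedance(rec)
  expect_equal(nrow(out$data), 2)
  expect_setequal(attr(out, "removed"), rec$layout$names[c(2, 4)])

  rec2 <- make_rec(matrix(rnorm(4 * 100), 4, 100), impedances = rep(10, 4))
  expect_length(attr(reject_high_impedance(rec2), "removed"), 0)

  rec3 <- make_rec(matrix(rnorm(2 * 100), 2, 100),
                   impedances = c(150, 200))
  expect_error(reject_high_impedance(rec3), "every channel")

  lay5 <- simulate_impedances(channel_layout(32), 5, seed = 3)
  rec5 <- make_rec(matrix(rnorm(32 * 100), 32, 100),
                   impedances = lay5$impedances)
  expect_length(attr(reject_high_impedance(rec5), "removed"), 5)
})

test_that("bandpass design reproduces the stated transition rule and cutoffs", {
  spec <- design_bandpass(0.5, 30, 1000)
  expect_equal(spec$l_trans, 0.5)    # min(max(0.125, 2), 0.5)
  expect_equal(spec$h_trans, 7.5)    # min(max(7.5, 2), 470)
  expect_equal(spec$half_amp_cutoffs, c(0.25, 33.75))
  expect_equal(spec$n_taps %% 2, 1)
  expect_equal(spec$taps, rev(spec$taps))  # linear phase
  # realized -6 dB points at the design cutoffs
  expect_equal(filter_response(spec, 0.25), 0.5, tolerance = 0.02)
  expect_equal(filter_response(spec, 33.75), 0.5, tolerance = 0.02)
  expect_error(design_bandpass(30, 0.5), "l_freq < h_freq")
})

test_that("zero-phase filtering preserves passband and rejects DC and stopband", {
  fs <- 250
  spec <- design_bandpass(0.5, 30, fs)
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  sine10 <- sin(2 * pi * 10 * t)
  rec <- make_rec(rbind(sine10, rep(5, length(t)),
                        sin(2 * pi * 45 * t)), fs = fs)
  out <- apply_filter(rec, spec)
  mid <- seq(15 * fs, 45 * fs)     # away from edge effects
  expect_equal(max(abs(out$data[1, mid])), 1, tolerance = 0.02)
  # zero phase: peak positions unchanged
  expect_gt(cor(out$data[1, mid], sine10[mid]), 0.9999)
  expect_lt(max(abs(out$data[2, mid])), 0.05)          # DC removed
  expect_lt(max(abs(out$data[3, mid])), 0.05)          # 45 Hz attenuated
  short <- make_rec(matrix(0, 1, 100), fs = fs)
  expect_error(apply_filter(short, spec), "shorter")
})

test_that("epoch extraction follows the floor-index formula", {
  fs <- 1000
  n <- 8000
  ramp <- matrix(seq_len(n) - 1, 1, n)  # sample value = 0-based index
  rec <- make_rec(ramp, fs = fs)
  sch <- data.frame(onset = 5.0, duration = 0.75, stimulus_id = "s",
                    session = 1, subsession = 1)
  ep <- extract_epochs(rec, sch)
  expect_equal(dim(ep$data)[3], 1050)
  expect_equal(ep$data[1, 1, 1], 4700)     # first sample index
  expect_equal(ep$data[1, 1, 1050], 5749)  # last sample index

  rec2 <- make_rec(matrix(rnorm(525 * 2), 1, 1050), fs = 500)
  sch2 <- data.frame(onset = 1.0, duration = 0.75, stimulus_id = "s",
                     session = 1, subsession = 1)
  expect_equal(dim(extract_epochs(rec2, sch2)$data)[3], 525)
})

test_that("truncated epochs are dropped with a warning", {
  rec <- make_rec(matrix(rnorm(2000), 1, 2000), fs = 1000)
  sch <- data.frame(onset = c(0.1, 1.0, 1.9), duration = 0.75,
                    stimulus_id = c("a", "b", "c"), session = 1,
                    subsession = 1)
  expect_warning(ep <- extract_epochs(rec, sch), "truncated")
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(ep$stimulus_id, "b")
  expect_equal(ep$dropped, c(1L, 3L))
})

test_that("baseline correction zeroes the baseline mean per trial and channel", {
  fs <- 100
  ep <- make_epochs(array(7, dim = c(1, 1, 105)), fs = fs)
  out <- baseline_correct(ep)
  expect_true(all(out$data == 0))

  d <- array(0, dim = c(2, 2, 105))
  d[, 1, ] <- 1; d[, 2, ] <- 2
  out2 <- baseline_correct(make_epochs(d, fs = fs))
  expect_true(all(abs(out2$data) < 1e-12))

  set.seed(1)
  d3 <- array(rnorm(3 * 2 * 105), dim = c(3, 2, 105))
  out3 <- baseline_correct(make_epochs(d3, fs = fs))
  bl <- apply(out3$data[, , 1:20, drop = FALSE], c(1, 2), mean)
  expect_true(all(abs(bl) < 1e-12))
})

test_that("aRMS equals the nested-loop mean-of-trial-RMS oracle", {
  ep <- make_epochs(array(2, dim = c(1, 1, 50)))
  expect_equal(unname(compute_arms(ep)$arms), 2)

  d <- array(0, dim = c(2, 1, 50)); d[2, 1, ] <- 2
  expect_equal(unname(compute_arms(make_epochs(d))$arms), 1)  # mean of RMS

  set.seed(7)
  d2 <- array(rnorm(5 * 4 * 30), dim = c(5, 4, 30))
  st <- compute_arms(make_epochs(d2))
  oracle <- numeric(4)
  for (j in 1:4) {
    acc <- 0
    for (n in 1:5) acc <- acc + sqrt(mean(d2[n, j, ]^2))
    oracle[j] <- acc / 5
  }
  expect_equal(unname(st$arms), oracle, tolerance = 1e-14)
  expect_equal(st$iqr, unname(st$q3 - st$q1))
})

test_that("Tukey-fence channel rejection matches direct fence evaluation", {
  mk_stats <- function(arms) {
    d <- array(0, dim = c(1, length(arms), 10))
    for (j in seq_along(arms)) d[1, j, ] <- arms[j]
    compute_arms(make_epochs(d))
  }
  st <- mk_stats(c(10, 11, 12, 13, 12, 40))
  keep <- reject_outlier_channels(st)
  expect_equal(attr(keep, "removed"), "ch6")

  st2 <- mk_stats(rep(3, 6))
  expect_length(attr(reject_outlier_channels(st2), "removed"), 0)

  st3 <- mk_stats(c(0.01, 10, 11, 12, 11, 10, 50))
  expect_setequal(attr(reject_outlier_channels(st3), "removed"),
                  c("ch1", "ch7"))
  expect_error(reject_outlier_channels(mk_stats(c(1, 2, 3))), "at least 4")
})

test_that("rejection never removes channels strictly inside the fences", {
  set.seed(42)
  for (rep in 1:20) {
    arms <- rexp(12, 1 / 10)
    d <- array(0, dim = c(1, 12, 5))
    for (j in 1:12) d[1, j, ] <- arms[j]
    st <- compute_arms(make_epochs(d))
    keep <- reject_outlier_channels(st)
    q <- quantile(arms, c(0.25, 0.75), names = FALSE)
    lo <- q[1] - 1.5 * (q[2] - q[1]); hi <- q[2] + 1.5 * (q[2] - q[1])
    expect_identical(as.logical(keep), arms >= lo & arms <= hi)
  }
})

test_that("filtering then epoching a noiseless recording keeps the template", {
  lay <- channel_layout(8)
  fs <- 250
  sch <- generate_schedule("block3_c", sessions = 1, subsessions = 1,
                           presentations = 10, seed = 2)
  rec <- synthesize_recording(sch, default_registry, lay, noise = NULL,
                              fs = fs, seed = 1)
  spec <- design_bandpass(0.5, 30, fs)
  ep <- baseline_correct(extract_epochs(apply_filter(rec, spec), sch))
  tpl <- make_erp_template(get_stimulus(default_registry, "block3_c"), lay,
                           fs = fs)
  n_pre <- round(0.3 * fs)
  k <- min(ncol(tpl), dim(ep$data)[3] - n_pre)
  for (j in c(1, 8)) {
    got <- ep$data[1, j, n_pre + seq_len(k)]
    expect_gt(cor(got, tpl[j, seq_len(k)]), 0.99)
  }
})

test_that("the preprocessing chain keeps channel bookkeeping consistent", {
  lay <- simulate_impedances(channel_layout(16), 2, seed = 4)
  sch <- generate_schedule(default_registry, sessions = 1, subsessions = 1,
                           presentations = 60, seed = 6)
  rec <- synthesize_recording(sch, default_registry, lay, fs = 250, seed = 6)
  rec$layout <- lay
  ep <- preprocess_session(rec, sch)
  rep <- attr(ep, "reports")
  expect_length(rep$impedance_removed, 2)
  expect_equal(length(ep$channels),
               16 - 2 - length(rep$arms_removed))
  expect_identical(ep$channels,
                   setdiff(lay$names, c(rep$impedance_removed,
                                        rep$arms_removed)))
  expect_true(all(is.finite(ep$data)))
})
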