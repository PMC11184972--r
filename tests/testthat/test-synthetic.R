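test_that("synthetic layout has unique names and posterior O/P rows", {
  lay <- channel_layout(128)
  expect_length(lay$names, 128)
  expect_false(anyDuplicated(lay$names) > 0)
  post <- grepl("^(O|PO|P[0-9z])", lay$names)
  expect_true(all(lay$positions[post, "y"] < 0))
  expect_true(all(is.finite(lay$positions)))
  expect_true(all(lay$impedances >= 0))
})

test_that("positive peak grows with area; negative deflection shrinks", {
  lay <- channel_layout(32)
  ids <- c("single_r2c2", "vbar3_c2", "vbar5_c2", "block3_c")
  tpls <- lapply(ids, function(id)
    make_erp_template(get_stimulus(default_registry, id), lay, fs = 250))
  pos_peaks <- vapply(tpls, max, 0)
  neg_mins <- vapply(tpls, min, 0)
  expect_true(all(diff(pos_peaks) > 0))     # area 1 < 3 < 5 < 9
  expect_true(all(diff(neg_mins) > 0))      # negativity shrinks with area
})

test_that("midline stimuli give mirror-symmetric hemispheres", {
  lay <- channel_layout(64)
  tpl <- make_erp_template(get_stimulus(default_registry, "vbar5_c2"), lay,
                           fs = 250)
  for (pair in list(c("O1", "O2"), c("P1", "P2"), c("F1", "F2")))
    expect_equal(tpl[match(pair[1], lay$names), ],
                 tpl[match(pair[2], lay$names), ])
})

test_that("laterality and elevation modulate the negative component", {
  lay <- channel_layout(64)
  left <- make_erp_template(get_stimulus(default_registry, "vbar5_c0"), lay,
                            fs = 250)
  # left visual field -> larger negativity on the right scalp
  expect_lt(min(left[match("O2", lay$names), ]),
            min(left[match("O1", lay$names), ]))
  sup <- make_erp_template(get_stimulus(default_registry, "single_r0c2"),
                           lay, fs = 250)
  inf <- make_erp_template(get_stimulus(default_registry, "single_r4c2"),
                           lay, fs = 250)
  expect_lt(min(inf), min(sup))
})

test_that("noiseless epochs reproduce the template exactly", {
  lay <- channel_layout(16)
  sch <- generate_schedule(default_registry, sessions = 1, subsessions = 1,
                           presentations = 60, seed = 2)
  rec <- synthesize_recording(sch, default_registry, lay, noise = NULL,
                              fs = 250, seed = 1)
  ep <- extract_epochs(rec, sch)
  expect_equal(dim(ep$data), c(60, 16, 262))
  n_pre <- round(0.3 * 250)
  for (i in c(1, 30)) {
    tpl <- make_erp_template(get_stimulus(default_registry,
                                          sch$stimulus_id[i]), lay,
                             fs = 250)
    expect_equal(max(abs(ep$data[i, , seq_len(n_pre)])), 0)
    k <- min(ncol(tpl), 262 - n_pre)
    expect_equal(ep$data[i, , n_pre + seq_len(k)], tpl[, seq_len(k)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("epoch averaging recovers the template with 1/sqrt(N) error decay", {
  lay <- channel_layout(8)
  sch <- generate_schedule("single_r2c2", sessions = 1, subsessions = 1,
                           presentations = 64, seed = 3)
  rec <- synthesize_recording(sch, default_registry, lay,
                              noise = noise_params(std = 9), fs = 250,
                              seed = 4)
  ep <- extract_epochs(rec, sch)
  tpl <- make_erp_template(get_stimulus(default_registry, "single_r2c2"),
                           lay, fs = 250)
  n_pre <- round(0.3 * 250)
  k <- min(ncol(tpl), 262 - n_pre)
  err_n <- function(n) {
    avg <- apply(ep$data[seq_len(n), , , drop = FALSE], c(2, 3), mean)
    sqrt(mean((avg[, n_pre + seq_len(k)] - tpl[, seq_len(k)])^2))
  }
  e16 <- err_n(16); e64 <- err_n(64)
  expect_lt(e64, e16)            # error shrinks with N
  expect_lt(e64 / e16, 1 / sqrt(4) * 1.8)  # about halved, wide tolerance
})

test_that("recordings are deterministic under seed and 1/f noise has slope -alpha", {
  lay <- channel_layout(4)
  sch <- generate_schedule("single_r2c2", sessions = 1, subsessions = 1,
                           presentations = 8, seed = 5)
  r1 <- synthesize_recording(sch, default_registry, lay, fs = 250, seed = 7)
  r2 <- synthesize_recording(sch, default_registry, lay, fs = 250, seed = 7)
  expect_identical(r1$data, r2$data)
  rn <- synthesize_recording(sch, default_registry, lay, erp = NULL,
                             noise = noise_params(alpha = 1), fs = 250,
                             seed = 8)
  sp <- stats::spec.pgram(stats::ts(rn$data[1, ], frequency = 250),
                          plot = FALSE, taper = 0)
  sel <- sp$freq > 0.5 & sp$freq < 50
  slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~
                                          log(sp$freq[sel])))[2])
  expect_equal(slope, -1, tolerance = 0.15)
})

test_that("zero-effect parameters give identical templates for all stimuli", {
  lay <- channel_layout(8)
  flat <- erp_params(pos_area_gain = 0, neg_area_atten = 0,
                     laterality_gain = 0, elevation_gain = 0,
                     eccentricity_rate = 0)
  t1 <- make_erp_template(get_stimulus(default_registry, "single_r0c0"),
                          lay, flat, fs = 250)
  t2 <- make_erp_template(get_stimulus(default_registry, "block3_br"),
                          lay, flat, fs = 250)
  expect_equal(t1, t2)
})

test_that("simulated impedances mark exactly n_bad channels, reproducibly", {
  lay <- channel_layout(128)
  l5 <- simulate_impedances(lay, 5, seed = 11)
  expect_equal(sum(l5$impedances > 100), 5)
  expect_true(all(l5$impedances[l5$impedances <= 100] < 100))
  l0 <- simulate_impedances(lay, 0, seed = 11)
  expect_equal(sum(l0$impedances > 100), 0)
  expect_identical(simulate_impedances(lay, 5, seed = 11)$impedances,
                   l5$impedances)
  expect_error(simulate_impedances(channel_layout(4), 5), "exceeds")
})

test_that("non-finite ERP parameters are rejected", {
  lay <- channel_layout(4)
  sch <- generate_schedule("single_r2c2", sessions = 1, subsessions = 1,
                           presentations = 8, seed = 5)
  bad <- erp_params(); bad$pos_base <- NaN
  expect_error(synthesize_recording(sch, default_registry, lay, erp = bad,
                                    fs = 250, seed = 1), "non-finite")
})
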