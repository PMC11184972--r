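test_that("vectorization is channel-major and invertible", {
  d <- array(seq_len(2 * 2 * 3), dim = c(2, 2, 3))
  ep <- make_epochs(d, fs = 10)
  x <- vectorize(ep)
  expect_equal(dim(x), c(2, 6))
  # channel-major: features 1:3 from channel 1, 4:6 from channel 2
  expect_equal(unname(x[1, 1:3]), d[1, 1, ])
  expect_equal(unname(x[1, 4:6]), d[1, 2, ])
  expect_equal(feature_coords(x, 4), list(channel = 2L, sample = 1L))
  expect_equal(feature_coords(x, 5), list(channel = 2L, sample = 2L))
  expect_equal(unvectorize(x), d)
  # feature count for the full-scale design
  expect_equal(128L * 1050L, 134400L)
})

test_that("z-scoring pools per channel with the N-1 denominator", {
  set.seed(21)
  d <- array(rnorm(8 * 3 * 5), dim = c(8, 3, 5))
  d[, 2, ] <- d[, 2, ] + 10
  d[, 3, ] <- d[, 3, ] - 10
  x <- vectorize(make_epochs(d))
  zp <- zscore_fit(x)
  xs <- zscore_apply(zp, x)
  map <- attr(x, "map")
  for (j in 1:3) {
    v <- xs[, map == j]
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(as.vector(v)) * sqrt((length(v) - 1) / (length(v) - 1)),
                 1, tolerance = 1e-9)
    # brute-force oracle for the fitted moments
    raw <- as.vector(d[, j, ])
    mu <- sum(raw) / length(raw)
    sig <- sqrt(sum((raw - mu)^2) / (length(raw) - 1))
    expect_equal(zp$mu[j], mu, tolerance = 1e-12)
    expect_equal(zp$sigma[j], sig, tolerance = 1e-12)
  }
  # constant channel -> error naming it
  d0 <- d; d0[, 2, ] <- 4
  x0 <- vectorize(make_epochs(d0))
  expect_error(zscore_fit(x0), "ch2")
})

test_that("test-set standardization reuses training parameters", {
  set.seed(22)
  d <- array(rnorm(10 * 2 * 4), dim = c(10, 2, 4))
  x <- vectorize(make_epochs(d))
  zp <- zscore_fit(x)
  xnew <- matrix(rnorm(3 * 8), 3, 8)
  attr_keep <- attributes(x)
  xn <- xnew
  attributes(xn) <- c(attributes(xnew),
                      attr_keep[c("channels", "n_samples", "map")])
  got <- zscore_apply(zp, xn)
  expect_equal(unname(got[1, 1]),
               (xnew[1, 1] - zp$mu[1]) / zp$sigma[1], tolerance = 1e-12)
})

test_that("calibrated decoder separates a separable toy problem", {
  set.seed(23)
  tf <- toy_features(n = 80, p = 10, effect = 6)
  dec <- fit_calibrated_decoder(tf$x, tf$y)
  expect_s3_class(dec, "calibrated_svm")
  p <- predict(dec, tf$x)
  expect_equal(rowSums(p), rep(1, 80), tolerance = 1e-12)
  expect_true(all(p >= 0))
  pred <- predict(dec, tf$x, type = "class")
  expect_equal(mean(as.character(pred) == tf$y), 1)
  expect_error(fit_calibrated_decoder(tf$x, rep("a", 80)), "single class")
})

test_that("multiclass probabilities live on the simplex and pick the signal", {
  set.seed(24)
  n <- 120; p <- 8
  y <- rep(c("a", "b", "c"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[y == "b", 1] <- x[y == "b", 1] + 4
  x[y == "c", 2] <- x[y == "c", 2] + 4
  dec <- fit_calibrated_decoder(x, y)
  expect_length(dec$machines, 3)
  pr <- predict(dec, x)
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-12)
  expect_gt(mean(predict(dec, x, type = "class") == y), 0.9)
})

test_that("probabilities are roughly calibrated on held-out data", {
  set.seed(25)
  mk <- function(n, seed) {
    set.seed(seed)
    y <- rep(c("a", "b"), length.out = n)
    x <- matrix(rnorm(n * 6), n, 6)
    x[y == "b", 1:2] <- x[y == "b", 1:2] + 1.2
    list(x = x, y = y)
  }
  tr <- mk(400, 26); te <- mk(600, 27)
  dec <- fit_calibrated_decoder(tr$x, tr$y)
  p <- predict(dec, te$x)[, "a"]
  correct_a <- te$y == "a"
  bins <- cut(p, c(0, 0.25, 0.5, 0.75, 1), include.lowest = TRUE)
  centers <- c(0.125, 0.375, 0.625, 0.875)
  for (b in which(table(bins) >= 50)) {
    emp <- mean(correct_a[bins == levels(bins)[b]])
    expect_lt(abs(emp - centers[b]), 0.15)
  }
})

test_that("cross-validation is stratified, leak-free and reproducible", {
  set.seed(27)
  tf <- toy_features(n = 80, p = 10, effect = 2, seed = 31)
  x <- structure(tf$x, map = rep(1:2, each = 5), channels = c("c1", "c2"),
                 n_samples = 5,
                 class = c("feature_matrix", "matrix", "array"))
  r1 <- crossval_decode(x, tf$y, balanced = TRUE, seed = 5)
  r2 <- crossval_decode(x, tf$y, balanced = TRUE, seed = 5)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_length(r1$accuracies, 10)
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 1))
  expect_equal(r1$scheme, "tenfold")
  # stratification: each test fold has both classes
  for (fo in r1$folds) expect_setequal(unique(fo$truth), c("a", "b"))
  # fitted state is untouched by test labels: decoders depend on train only
  expect_identical(lapply(r1$folds, function(f) f$decoder$machines),
                   lapply(r2$folds, function(f) f$decoder$machines))
  r3 <- crossval_decode(x, tf$y, balanced = TRUE, seed = 6)
  expect_false(identical(r1$accuracies, r3$accuracies))
})

test_that("the Monte Carlo resampling scheme balances classes first", {
  set.seed(28)
  n <- 150
  y <- c(rep("big", 110), rep("small", 40))
  x <- matrix(rnorm(n * 6), n, 6)
  x[y == "big", 1] <- x[y == "big", 1] + 1.5
  xf <- structure(x, map = rep(1:2, each = 3), channels = c("c1", "c2"),
                  n_samples = 3,
                  class = c("feature_matrix", "matrix", "array"))
  res <- crossval_decode(xf, y, balanced = FALSE, seed = 9)
  expect_equal(res$scheme, "monte-carlo-resample")
  expect_length(res$accuracies, 10)
  for (fo in res$folds) {
    tab <- table(fo$truth)
    expect_equal(length(tab), 2)
    expect_lte(abs(diff(as.numeric(tab))), 1)  # balanced test split
  }
  expect_error(crossval_decode(xf, c(rep("a", 145), rep("b", 5)),
                               balanced = TRUE), "has 5")
})

test_that("the random decoder matches the binomial chance model", {
  truths <- replicate(10, sample(c("a", "b", "c", "d"), 40, replace = TRUE),
                      simplify = FALSE)
  rd <- random_decoder(truths, levels = c("a", "b", "c", "d"), seed = 2)
  expect_length(rd$accuracies, 10)
  expect_true(all(rd$accuracies >= 0 & rd$accuracies <= 1))
  # many seeds: accuracy distribution ~ Binomial(40, 1/4)/40
  set.seed(3)
  accs <- unlist(lapply(1:200, function(s)
    random_decoder(truths[1], levels = c("a", "b", "c", "d"),
                   seed = s)$accuracies))
  expect_equal(mean(accs), 0.25, tolerance = 0.02)
  expect_equal(sd(accs), sqrt(0.25 * 0.75 / 40), tolerance = 0.08)
  # M = 2 expectation 0.5
  rd2 <- random_decoder(list(rep("a", 5000)), levels = c("a", "b"), seed = 4)
  expect_equal(rd2$accuracies, 0.5, tolerance = 0.03)
})

test_that("chance comparison: Wilcoxon orientation, Bonferroni and reports", {
  same <- rep(0.5, 10)
  out <- compare_to_chance(same, same)
  expect_gte(out$p, 0.5)
  real <- rep(0.9, 10); rand <- rep(0.5, 10)
  out2 <- compare_to_chance(real, rand)
  expect_lt(out2$p, 0.005)   # exact one-sided signed-rank floor ~ 1/1024
  out3 <- compare_to_chance(real, rand, n_subjects = 10)
  expect_equal(out3$p_corrected, min(1, out2$p * 10))
  expect_true(out2$ties)     # identical differences tie
  set.seed(5)
  a <- 0.5 + runif(10, 0, 0.2); b <- 0.5 + runif(10, 0, 0.02)
  out4 <- compare_to_chance(a, b)
  expect_true(is.finite(out4$shapiro_p_real))
  out5 <- compare_to_chance(b, a)
  expect_gt(out5$p, 0.5)     # wrong direction
})
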