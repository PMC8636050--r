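test_that("MAV, WL, ZC match hand computation and symmetry", {
  f <- time_domain_features(c(1, -1, 2, -2))
  expect_equal(unname(f), c(1.5, 9, 3))
  fc <- time_domain_features(rep(3.2, 50))
  expect_equal(unname(fc), c(3.2, 0, 0))
  x <- rnorm(100)
  expect_equal(time_domain_features(x), time_domain_features(-x))
  expect_error(time_domain_features(1), "at least 2")
})

test_that("scalar features agree with brute-force loops on random vectors", {
  brute <- function(x) {
    mav <- 0; wl <- 0; zc <- 0
    for (i in seq_along(x)) mav <- mav + abs(x[i])
    for (i in seq_len(length(x) - 1)) {
      wl <- wl + abs(x[i + 1] - x[i])
      if ((x[i] > 0 && x[i + 1] < 0) || (x[i] < 0 && x[i + 1] > 0)) zc <- zc + 1
    }
    c(mav / length(x), wl, zc)
  }
  set.seed(1)
  for (i in 1:100) {
    x <- rnorm(sample(10:200, 1))
    f <- unname(time_domain_features(x))
    expect_identical(f[3], brute(x)[3])                    # counts: exact
    expect_equal(f[1:2], brute(x)[1:2], tolerance = 1e-12) # sums: 1 ulp
  }
})

test_that("Burg AR recovers a planted AR(2) process and vanishes on white noise", {
  set.seed(42)
  n <- 10000
  e <- rnorm(n + 200)
  x <- numeric(n + 200)
  for (t in 3:(n + 200)) x[t] <- 0.5 * x[t - 1] - 0.3 * x[t - 2] + e[t]
  x <- x[-(1:200)]
  a <- ar_features(x, 6)
  expect_lt(abs(a[1] - 0.5), 0.05)
  expect_lt(abs(a[2] + 0.3), 0.05)
  expect_true(all(abs(a[3:6]) < 0.05))

  w <- rnorm(10000)
  expect_true(all(abs(ar_features(w, 6)) < 0.05))

  # amplitude-scale invariance
  expect_equal(ar_features(x * 10, 6), ar_features(x, 6), tolerance = 1e-10)
  expect_warning(a0 <- ar_features(rep(1, 100)), "constant")
  expect_equal(a0, rep(0, 6))
})

test_that("Welch PSD satisfies the Parseval power check", {
  set.seed(3)
  x <- rnorm(6000)
  w <- welch_psd(x, 1500)
  df <- w$freq[2] - w$freq[1]
  total_power <- sum(w$psd) * df
  expect_lt(abs(total_power - stats::var(x)) / stats::var(x), 0.05)
  # white noise: mean density ~ total power / Nyquist bandwidth
  expect_lt(abs(mean(w$psd) - stats::var(x) / 750) / (stats::var(x) / 750),
            0.1)
})

test_that("in-band mean PSD ranks tones and handles degenerate input", {
  tt <- (0:5999) / 1500
  in_band <- sin(2 * pi * 100 * tt)
  out_band <- sin(2 * pi * 600 * tt)
  expect_gt(psd_mean(in_band, 1500), psd_mean(out_band, 1500))
  expect_equal(psd_mean(rep(0, 1000), 1500), 0)
  expect_error(psd_mean(rnorm(32), 1500), "64")
  expect_error(psd_mean(rnorm(1000), 800), "Nyquist")
})

test_that("feature matrix has documented shape and deterministic row mapping", {
  ws <- tiny_windows()
  sub <- subset_windows(ws, 1:12)
  fm <- build_feature_matrix(sub)
  expect_equal(dim(fm$X), c(12, 12 * 10))
  expect_equal(colnames(fm$X)[1:3], c("ch1_MAV", "ch1_WL", "ch1_ZC"))
  expect_equal(fm$y, sub$labels)

  perm <- c(5, 1, 9, 2)
  fm_p <- build_feature_matrix(subset_windows(sub, perm))
  expect_equal(fm_p$X, fm$X[perm, ])

  zero <- window_set(array(0, c(2, 12, 300)), c(0, 1), rep("S1", 2),
                     rep("z", 2), 1:2)
  fz <- suppressWarnings(build_feature_matrix(zero))
  expect_true(all(fz$X == 0))
})

test_that("baseline configurations carry the documented hyperparameters", {
  expect_error(configure_baseline("XGB"), "LDA")
  rbf <- configure_baseline("RBFSVM")
  expect_equal(rbf$hyperparameters$cost, 1.9)
  expect_equal(rbf$hyperparameters$multiclass, "one-vs-one")
  knn <- configure_baseline("KNN")
  expect_equal(knn$hyperparameters$k, 1)
  expect_equal(knn$hyperparameters$metric, "mahalanobis")
  ann <- configure_baseline("ANN")
  expect_equal(ann$hyperparameters$hidden, 28)
  expect_equal(configure_baseline("LDA", "within")$hyperparameters$covariance,
               "full")
  expect_equal(configure_baseline("LDA", "cross")$hyperparameters$covariance,
               "diagonal")
  expect_equal(configure_baseline("DT")$hyperparameters$max_splits, 100)
  expect_equal(configure_baseline("LSVM")$hyperparameters$cost, 1)
})

test_that("every baseline trains and predicts sensibly on separable features", {
  ws <- tiny_windows()
  fm <- build_feature_matrix(ws)
  tri <- unique(data.frame(tr = ws$trial_ids, y = ws$labels))
  test_trials <- unlist(lapply(split(tri$tr, tri$y), `[`, 1))
  te <- ws$trial_ids %in% test_trials
  for (nm in c("LDA", "DT", "BES", "LSVM", "RBFSVM", "KNN", "ANN")) {
    fit <- train_baseline(configure_baseline(nm), fm$X[!te, ], fm$y[!te],
                          seed = 1)
    acc <- mean(predict(fit, fm$X[te, ]) == fm$y[te])
    expect_gt(acc, 0.5)   # far above the 0.25 chance level
  }
  # RBFSVM specifically beats chance by a wide margin on synergy features
  fit <- train_baseline(configure_baseline("RBFSVM"), fm$X[!te, ], fm$y[!te])
  expect_gt(mean(predict(fit, fm$X[te, ]) == fm$y[te]), 0.8)
})
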