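test_that("NMF factorizes an exact rank-1 non-negative matrix to machine error", {
  set.seed(2)
  w <- runif(12, 0.1, 1)
  h <- runif(200, 0.1, 1)
  X <- w %o% h
  fit <- nmf_factorize(X, 1, max_iter = 2000, tol = 0)
  expect_lt(fit$error, 1e-6)
  # basis proportional to the generating vector
  ratio <- fit$W[, 1] / w
  expect_lt(stats::sd(ratio) / mean(ratio), 1e-3)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_error(nmf_factorize(X - 1, 1), "non-negative")
  expect_error(nmf_factorize(X, 50), "k must be")
})

test_that("dominant channels recover a constructed contribution pattern", {
  # energy concentrated in channels 1, 9, 10, 11 of a 12-channel map
  set.seed(4)
  X <- matrix(abs(rnorm(12 * 300, sd = 0.05)), 12, 300)
  act <- abs(rnorm(300, sd = 1)) + 0.5
  for (ch in c(1, 9, 10, 11)) X[ch, ] <- X[ch, ] + act * runif(1, 0.8, 1.2)
  dec <- channel_contribution_nmf(X, k = 1)
  expect_setequal(dec$dominant_channels, c(1, 9, 10, 11))
  expect_true(all(dec$basis >= 0))
})

test_that("decompositions are seed-reproducible and scale-invariant", {
  set.seed(5)
  X <- matrix(runif(12 * 100), 12, 100)
  d1 <- channel_contribution_nmf(X, seed = 3)
  d2 <- channel_contribution_nmf(X, seed = 3)
  expect_identical(d1$basis, d2$basis)
  d3 <- channel_contribution_nmf(X * 37.5, seed = 3)
  expect_identical(d1$dominant_channels, d3$dominant_channels)
})

test_that("jaccard agreement hits its boundary values", {
  expect_equal(jaccard(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_equal(jaccard(integer(0), integer(0)), 1)
  expect_equal(jaccard(1:2, 2:3), 1 / 3)
})

test_that("information flow follows constructed depthwise weights", {
  cfg <- test_cfg()
  m <- build_model(cfg, seed = 8)
  Wd <- matrix(0, 24, 12)
  Wd[3, c(1, 9)] <- c(2, 1)          # filter 3 reads only channels 1 and 9
  m <- set_param(m, "dw_W", Wd)
  ws <- subset_windows(tiny_windows(), 1:4)
  tr <- trace_information_flow(m, dominant = c(1, 9, 10, 11), ws)
  expect_equal(tr$depthwise_flow, 3)
  expect_true(all(tr$mass_depthwise[-3] == 0))
  expect_length(tr$attention_top, 6)     # top quartile of 24
  expect_gte(tr$agreement, 0)
  expect_lte(tr$agreement, 1)
})

test_that("flow tracing refuses ablated models and names the missing layer", {
  m <- build_model(mcsnet_compact_config(ablate = "attention",
                                         precision = "double"), 1)
  ws <- subset_windows(tiny_windows(), 1:2)
  expect_error(trace_information_flow(m, 1:2, ws), "attention")
  m2 <- build_model(mcsnet_compact_config(ablate = "depthwise",
                                          precision = "double"), 1)
  expect_error(trace_information_flow(m2, 1:2, ws), "depthwise")
})

test_that("input-level NMF recovers the planted synergy channels", {
  # five cohorts, different master seeds; average Jaccard against the
  # generator's planted channel sets
  js <- numeric(0)
  for (seed in 1:5) {
    sim <- sim_config(n_subjects = 1, trials_per_class = c(2, 2, 2, 2),
                      loading_perturbation = 0, seed = seed)
    coh <- generate_cohort(sim)
    ws <- preprocess_recordings(coh$recordings, window_len = 300, step = 300)
    for (k in 0:3) {
      dec <- channel_contribution_nmf(average_input_map(ws, k), k = 1)
      js <- c(js, jaccard(dec$dominant_channels,
                          planted_channels(coh$ground_truth, k)))
    }
  }
  expect_gte(mean(js), 0.75)
})

test_that("layer activation maps keep channel identity and silent channels", {
  loadings <- matrix(0, 12, 4)
  loadings[cbind(c(2, 8, 3, 9), c(1, 1, 2, 2))] <- 1
  loadings[cbind(c(5, 11, 6, 12), c(3, 3, 4, 4))] <- 1
  gt <- synergy_ground_truth(loadings = loadings, symmetric_corr = 0)
  sim <- sim_config(n_subjects = 1, trials_per_class = c(2, 2, 2, 2),
                    mains_amp = 0, noise_floor = 1e-4, symmetric_corr = 0,
                    loading_perturbation = 0)
  coh <- generate_cohort(sim, gt = gt)
  ws <- preprocess_recordings(coh$recordings, spec = NULL,
                              window_len = 300, step = 300)
  m <- build_model(test_cfg(), seed = 2)
  dec_in <- channel_contribution_nmf(average_input_map(ws, 0), k = 1)
  expect_setequal(dec_in$dominant_channels, c(2, 8))

  st_avg <- layer_activation_nmf(m, ws, "lstm", class = 0)
  expect_equal(nrow(st_avg$basis), 12)
  expect_error(layer_activation_nmf(m, subset_windows(ws, integer(0)), "lstm"),
               "no windows")
})
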