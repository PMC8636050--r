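test_that("default configuration produces the full shape chain", {
  cfg <- mcsnet_config(precision = "double")
  m <- cached("default_model", build_model(cfg, seed = 1))
  x <- array(rnorm(2 * 12 * 300), c(2, 12, 300))
  st <- nn_forward(m, x, stages = TRUE)
  expect_equal(dim(st$F_temp), c(12, 300, 2))
  expect_equal(dim(st$F_conv), c(12, 12, 300, 2))
  expect_equal(dim(st$F_dconv), c(24, 300, 2))
  expect_equal(dim(st$F_sepconv), c(24, 300, 2))
  expect_equal(dim(st$F_attended), c(24, 300, 2))
  expect_equal(dim(st$probs), c(2, 4))
  expect_equal(rowSums(st$probs), c(1, 1), tolerance = 1e-6)
  expect_true(all(st$attention > 0 & st$attention < 1))
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(mcsnet_config(C = 5), "even")
  expect_error(mcsnet_config(temporal_kernel = 64), "odd")
  expect_error(mcsnet_config(attention_reduction = 5), "divide")
  expect_error(mcsnet_config(L = 30, lstm_hidden = 30, temporal_kernel = 65),
               "longer")
  expect_error(mcsnet_config(arch = "tcnn", ablate = "attention"), "mcsnet")
})

test_that("block-2 parameter shapes enumerate to the documented counts", {
  cfg <- mcsnet_config(precision = "double")
  lay <- param_layout(cfg)
  count <- function(nm) with(lay[lay$name == nm, ], nrow * ncol)
  expect_equal(count("t_W"), 12 * 65)    # F1 temporal kernels
  expect_equal(count("t_b"), 12)
  expect_equal(count("dw_W"), 2 * 12 * 12)
  expect_equal(count("dw_b"), 24)
  # block total: F1*65 + F1 + D*F1*C + D*F1
  block2 <- count("t_W") + count("t_b") + count("dw_W") + count("dw_b")
  expect_equal(block2, 12 * 65 + 12 + 2 * 12 * 12 + 24)
})

test_that("mirror channels share LSTM parameters and swapping them swaps rows", {
  cfg <- test_cfg()
  m <- build_model(cfg, seed = 3)
  p2 <- lstm_unit_params(m, 2)
  p8 <- lstm_unit_params(m, 8)
  expect_identical(p2$Wx, p8$Wx)
  expect_identical(p2$Wh, p8$Wh)

  x <- matrix(rnorm(12 * 300), 12, 300)
  xs <- x
  xs[c(2, 8), ] <- x[c(8, 2), ]
  f1 <- channel_lstm_forward(m, x)
  f2 <- channel_lstm_forward(m, xs)
  expect_equal(f2[c(8, 2), ], f1[c(2, 8), ], tolerance = 1e-12)
  expect_equal(f2[-c(2, 8), ], f1[-c(2, 8), ], tolerance = 1e-12)
})

test_that("tied pairs stay bit-equal after real Adam training steps", {
  ws <- tiny_windows()
  idx <- which(ws$trial_ids %in% unique(ws$trial_ids)[c(1, 3, 5, 7)])
  train <- subset_windows(ws, idx)   # one trial of every class
  cfg <- mcsnet_compact_config(precision = "single")
  m <- build_model(cfg, seed = 1)
  fit <- suppressWarnings(train_model(m, train, train,
                                      train_config(epochs = 2, seed = 1)))
  for (k in 1:6) {
    a <- lstm_unit_params(fit, k)
    b <- lstm_unit_params(fit, k + 6)
    expect_identical(a$Wx, b$Wx)
    expect_identical(a$Wh, b$Wh)
    expect_identical(a$b, b$b)
  }
})

test_that("attention weights are symmetric at zero input and bounded always", {
  cfg <- test_cfg()
  m <- build_model(cfg, seed = 2)
  z <- matrix(0, 12, 300)
  aw <- channel_attention(m, z)$weights
  expect_true(all(abs(aw - aw[1]) < 1e-12))   # identical across channels
  x <- matrix(rnorm(12 * 300, sd = 5), 12, 300)
  aw2 <- channel_attention(m, x)$weights
  expect_true(all(aw2 > 0 & aw2 < 1))
})

test_that("scaling one separable-output channel moves its attention weight", {
  # constructed: identity pointwise, delta depthwise -> F_sepconv = ELU(F_dconv)
  cfg <- test_cfg()
  m <- build_model(cfg, seed = 4)
  F2 <- cfg$F2
  ks <- cfg$separable_kernel
  delta <- matrix(0, F2, ks); delta[, (ks + 1) / 2] <- 1
  m <- set_param(m, "s_W", delta)
  m <- set_param(m, "s_b1", rep(0, F2))
  m <- set_param(m, "s_P", diag(F2))
  m <- set_param(m, "s_b2", rep(0, F2))
  x <- matrix(rnorm(12 * 300), 12, 300)
  st <- nn_forward(m, x, stages = TRUE)
  dconv <- st$F_dconv[, , 1]
  elu <- function(v) ifelse(v > 0, v, expm1(v))
  expect_equal(st$F_sepconv[, , 1], elu(dconv), tolerance = 1e-10)

  # per-channel locality of the depthwise stage: silencing kernel row j
  # only zeroes output channel j
  m2 <- set_param(m, "s_W", {
    d <- delta; d[3, ] <- 0; d
  })
  st2 <- nn_forward(m2, x, stages = TRUE)
  expect_true(all(st2$F_sepconv[3, , 1] == 0))
  expect_equal(st2$F_sepconv[-3, , 1], st$F_sepconv[-3, , 1],
               tolerance = 1e-12)
})

test_that("softmax head is normalized, deterministic, and rank-preserving", {
  cfg <- test_cfg()
  m <- build_model(cfg, seed = 5)
  x <- array(rnorm(10 * 12 * 300), c(10, 12, 300))
  x[7, , ] <- x[2, , ]                      # duplicated input rows
  p <- classify_forward(m, x)
  expect_equal(dim(p), c(10, 4))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_equal(p[7, ], p[2, ], tolerance = 1e-12)
  expect_equal(predict(m, x), max.col(p) - 1L)
})

test_that("analytic gradients match finite differences on a tiny network", {
  expect_lt(gradient_check(seed = 42), 1e-4)
})

test_that("baseline architectures build, classify, and reload bit-identically", {
  dir <- withr::local_tempdir()
  x <- array(rnorm(10 * 12 * 300), c(10, 12, 300))
  tcnn_cfg <- mcsnet_compact_config(arch = "tcnn", precision = "double")
  cl_cfg <- mcsnet_compact_config(arch = "cnnlstm", precision = "double")
  tcnn <- build_model(tcnn_cfg, seed = 1)
  cl <- build_model(cl_cfg, seed = 1)
  p <- classify_forward(tcnn, x)
  expect_equal(dim(p), c(10, 4))
  expect_equal(rowSums(p), rep(1, 10), tolerance = 1e-6)
  expect_equal(rowSums(classify_forward(cl, x)), rep(1, 10), tolerance = 1e-6)
  # the LSTM-bearing hybrid has strictly more parameters than the pure CNN
  expect_gt(param_count(cl), param_count(tcnn))

  save_model(cl, file.path(dir, "cl.rds"))
  cl2 <- load_model(file.path(dir, "cl.rds"))
  expect_identical(classify_forward(cl2, x), classify_forward(cl, x))
})

test_that("ablated variants drop exactly the targeted computation", {
  x <- array(rnorm(2 * 12 * 300), c(2, 12, 300))
  no_dw <- build_model(mcsnet_compact_config(ablate = "depthwise",
                                             precision = "double"), 1)
  st <- nn_forward(no_dw, x, stages = TRUE)
  expect_equal(dim(st$F_dconv)[1], 12)     # F1 maps, channel-averaged
  # the channel average is parameter-free
  expect_false("dw_W" %in% no_dw$layout$name)
  no_att <- build_model(mcsnet_compact_config(ablate = "attention",
                                              precision = "double"), 1)
  st2 <- nn_forward(no_att, x, stages = TRUE)
  expect_identical(st2$F_attended, st2$F_sepconv)
  no_sep <- build_model(mcsnet_compact_config(ablate = "separable",
                                              precision = "double"), 1)
  st3 <- nn_forward(no_sep, x, stages = TRUE)
  expect_identical(st3$F_sepconv, st3$F_dconv)
})

test_that("weighted loss reduces to unweighted loss on balanced classes", {
  cfg <- test_cfg()
  m <- build_model(cfg, seed = 6)
  x <- array(rnorm(8 * 12 * 300), c(12, 300, 8))
  y <- rep(0:3, 2)
  lw <- synergynet:::cpp_nn_loss_grad(x, y, rep(1, 4), m$theta, cfg, "double")
  p <- synergynet:::cpp_nn_forward(x, m$theta, cfg, FALSE, "double")$probs
  unweighted <- mean(-log(p[cbind(1:8, y + 1)]))
  expect_equal(lw$loss, unweighted, tolerance = 1e-10)
})

test_that("training is reproducible and returns the best checkpoint", {
  ws <- tiny_windows()
  idx <- which(ws$trial_ids %in% unique(ws$trial_ids)[c(1, 3, 5, 7)])
  vidx <- which(ws$trial_ids %in% unique(ws$trial_ids)[c(2, 4, 6, 8)])
  train <- subset_windows(ws, idx)
  val <- subset_windows(ws, vidx)
  cfg <- mcsnet_compact_config()
  tc <- train_config(epochs = 3, seed = 7)
  f1 <- train_model(build_model(cfg, 7), train, val, tc)
  f2 <- train_model(build_model(cfg, 7), train, val, tc)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$history, f2$history)
  expect_equal(f1$history$val_loss[f1$best_epoch],
               min(f1$history$val_loss))
  expect_equal(nrow(f1$history), 3)

  # missing validation class warns but trains
  val_partial <- subset_windows(ws, vidx[ws$labels[vidx] != 3])
  expect_warning(train_model(build_model(cfg, 7), train, val_partial,
                             train_config(epochs = 1, seed = 1)),
                 "missing class")
})
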