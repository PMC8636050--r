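#' Network architecture configuration
#'
#' Hyperparameters of the channel-synergy network and its two reference
#' baselines. The flagship architecture (`arch = "mcsnet"`) chains:
#' per-channel weight-tied LSTMs (block 1), `F1` temporal convolutions of
#' size `(1, temporal_kernel)` followed by a depthwise spatial convolution
#' of size `(C, 1)` with depth multiplier `D` (block 2), a separable
#' convolution of size `(1, separable_kernel)` with `F2 = D * F1` pointwise
#' filters (block 3), a channel-attention module with reduction `r`
#' (block 4), and a dense softmax head. `"tcnn"` keeps only block 2 plus the
#' head; `"cnnlstm"` stacks two LSTM layers and uses the three convolution
#' stages without attention. ELU follows every convolution.
#'
#' Defaults mirror the study configuration `(D, F1, L) = (2, 12, 300)` with
#' LSTM hidden size 300 on 12 channels and 4 classes.
#'
#' @param C channels (even when `tie_symmetric_lstm`).
#' @param L window length in samples.
#' @param lstm_hidden LSTM hidden size (the per-channel feature length).
#' @param F1 number of temporal filters.
#' @param D spatial depth multiplier.
#' @param temporal_kernel,separable_kernel odd kernel lengths.
#' @param attention_reduction attention MLP reduction `r` (must divide
#'   `D * F1`).
#' @param n_classes number of movement classes.
#' @param tie_symmetric_lstm share LSTM weights between mirror channels
#'   `(k, k + C/2)`.
#' @param arch `"mcsnet"`, `"tcnn"`, or `"cnnlstm"`.
#' @param ablate for `"mcsnet"`: remove `"depthwise"` (replaced by a
#'   non-learned channel average), `"separable"`, or `"attention"`;
#'   `"none"` keeps the full network.
#' @param precision `"single"` (training default) or `"double"`.
#' @return Object of class `mcsnet_config`.
#' @export
mcsnet_config <- function(C = 12, L = 300, lstm_hidden = 300, F1 = 12, D = 2,
                          temporal_kernel = 65, separable_kernel = 15,
                          attention_reduction = 4, n_classes = 4,
                          tie_symmetric_lstm = TRUE,
                          arch = c("mcsnet", "tcnn", "cnnlstm"),
                          ablate = c("none", "depthwise", "separable",
                                     "attention"),
                          precision = c("single", "double")) {
  arch <- match.arg(arch)
  ablate <- match.arg(ablate)
  precision <- match.arg(precision)
  if (arch != "mcsnet" && ablate != "none") {
    stop("layer ablation applies to the mcsnet architecture only")
  }
  flags <- switch(arch,
    mcsnet = list(lstm_layers = 1L, has_depthwise = TRUE, has_separable = TRUE,
                  sep_pointwise = TRUE, has_attention = TRUE),
    tcnn = list(lstm_layers = 0L, has_depthwise = TRUE, has_separable = FALSE,
                sep_pointwise = FALSE, has_attention = FALSE),
    cnnlstm = list(lstm_layers = 2L, has_depthwise = TRUE,
                   has_separable = TRUE, sep_pointwise = FALSE,
                   has_attention = FALSE))
  if (ablate == "depthwise") flags$has_depthwise <- FALSE
  if (ablate == "separable") flags$has_separable <- FALSE
  if (ablate == "attention") flags$has_attention <- FALSE
  cfg <- c(list(C = as.integer(C), L = as.integer(L),
                lstm_hidden = as.integer(lstm_hidden),
                F1 = as.integer(F1), D = as.integer(D),
                F2 = as.integer(D * F1),
                temporal_kernel = as.integer(temporal_kernel),
                separable_kernel = as.integer(separable_kernel),
                attention_reduction = as.integer(attention_reduction),
                n_classes = as.integer(n_classes),
                tie_symmetric_lstm = isTRUE(tie_symmetric_lstm),
                arch = arch, ablate = ablate, precision = precision),
           flags)
  class(cfg) <- "mcsnet_config"
  # shape-chain sanity: widths asserted at build time
  lay <- param_layout(cfg)
  stopifnot(nrow(lay) >= 2)
  cfg
}

#' Compact configuration for desk-scale CPU experiments
#'
#' Same architecture, channel count, window length, `F1`, and `D` as the
#' default configuration, but with the per-channel feature width reduced
#' (LSTM hidden 48, temporal kernel 25, separable kernel 9) so whole
#' train/evaluate cycles run in seconds on a single CPU core. Used by the
#' package's synthetic-cohort experiments; see the vignette.
#'
#' @param ... overrides passed to [mcsnet_config()].
#' @return Object of class `mcsnet_config`.
#' @export
mcsnet_compact_config <- function(...) {
  args <- list(...)
  defaults <- list(lstm_hidden = 48, temporal_kernel = 25, separable_kernel = 9)
  defaults[names(args)] <- args
  do.call(mcsnet_config, defaults)
}

cfg_feature_len <- function(cfg) if (cfg$lstm_layers > 0) cfg$lstm_hidden else cfg$L
cfg_width <- function(cfg) if (cfg$has_depthwise) cfg$D * cfg$F1 else cfg$F1

#' Parameter layout of a configuration
#'
#' @param cfg an [mcsnet_config()].
#' @return Data frame with one row per parameter tensor: `name`, `nrow`,
#'   `ncol`, `offset` (0-based into the flat parameter vector).
#' @export
param_layout <- function(cfg) {
  lay <- cpp_param_layout(cfg)
  data.frame(name = as.character(lay$name), nrow = lay$nrow, ncol = lay$ncol,
             offset = lay$offset, stringsAsFactors = FALSE)
}

#' Total trainable parameter count
#'
#' @param x an [mcsnet_config()] or a built/trained model.
#' @return Integer count.
#' @export
param_count <- function(x) {
  cfg <- if (inherits(x, "mcsnet_config")) x else x$cfg
  lay <- param_layout(cfg)
  sum(lay$nrow * lay$ncol)
}

#' Read or replace one named parameter tensor
#'
#' Tensor names follow [param_layout()]; useful for constructing reference
#' models with known weights and for inspecting trained layers.
#'
#' @param model a model.
#' @param name tensor name (e.g. `"dw_W"`, `"l1_u0_Wh"`).
#' @return `get_param` returns the tensor as a matrix; `set_param` returns
#'   the modified model.
#' @export
get_param <- function(model, name) {
  lay <- model$layout
  i <- match(name, lay$name)
  if (is.na(i)) stop("no parameter tensor named ", name)
  matrix(model$theta[(lay$offset[i] + 1):(lay$offset[i] + lay$nrow[i] * lay$ncol[i])],
         lay$nrow[i], lay$ncol[i])
}

#' @rdname get_param
#' @param value replacement values (length `nrow * ncol`).
#' @export
set_param <- function(model, name, value) {
  lay <- model$layout
  i <- match(name, lay$name)
  if (is.na(i)) stop("no parameter tensor named ", name)
  stopifnot(length(value) == lay$nrow[i] * lay$ncol[i])
  model$theta[(lay$offset[i] + 1):(lay$offset[i] + length(value))] <- as.numeric(value)
  model
}

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal <- function(n) {
  qd <- qr(matrix(stats::rnorm(n * n), n, n))
  qr.Q(qd) %*% diag(sign(diag(qr.R(qd))), n)
}

#' Build a model with freshly initialized weights
#'
#' Convolution and dense weights use uniform Glorot initialization; LSTM
#' recurrent matrices are orthogonal per gate with forget-gate bias 1;
#' all other biases start at 0. Fully determined by `seed`.
#'
#' @param cfg an [mcsnet_config()].
#' @param seed integer RNG seed.
#' @return Object of class `mcsnet_model` with elements `cfg`, `theta`,
#'   `layout`, `seed`.
#' @export
build_model <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "mcsnet_config"))
  lay <- param_layout(cfg)
  theta <- numeric(sum(lay$nrow * lay$ncol))
  model <- structure(list(cfg = cfg, theta = theta, layout = lay,
                          seed = as.integer(seed)),
                     class = "mcsnet_model")
  H <- cfg$lstm_hidden
  with_seed(seed, {
    for (i in seq_len(nrow(lay))) {
      nm <- lay$name[i]
      nr <- lay$nrow[i]; nc <- lay$ncol[i]
      val <- if (grepl("_Wx$", nm)) {
        glorot(nr, nc, nc, H)
      } else if (grepl("_Wh$", nm)) {
        do.call(rbind, lapply(1:4, function(g) orthogonal(H)))
      } else if (grepl("_b$", nm) && grepl("^l[0-9]+_", nm)) {
        b <- numeric(nr); b[(H + 1):(2 * H)] <- 1; b   # forget bias 1
      } else if (nm %in% c("t_b", "dw_b", "s_b1", "s_b2", "a_b1", "a_b2", "o_b")) {
        numeric(nr)
      } else {
        glorot(nr, nc, nc, nr)
      }
      model <- set_param(model, nm, val)
    }
  })
  model
}

#' @export
print.mcsnet_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<mcsnet_model> arch=%s%s  C=%d L=%d H=%d F1=%d D=%d  %d params%s\n",
              cfg$arch,
              if (cfg$ablate != "none") paste0(" (-", cfg$ablate, ")") else "",
              cfg$C, cfg$L, cfg$lstm_hidden, cfg$F1, cfg$D, param_count(x),
              if (!is.null(x$history)) sprintf("  trained %d epochs", nrow(x$history)) else ""))
  invisible(x)
}

# windows -> [C, L, B] array for the C++ core
windows_to_array <- function(windows, cfg) {
  if (inherits(windows, "emg_windows")) windows <- windows$windows
  if (is.matrix(windows)) windows <- array(windows, c(1, dim(windows)))
  d <- dim(windows)
  if (d[2] != cfg$C || d[3] != cfg$L) {
    stop("windows are ", d[2], " x ", d[3], " but the model expects ",
         cfg$C, " x ", cfg$L)
  }
  aperm(windows, c(2, 3, 1))
}

#' Forward pass with per-stage activations
#'
#' Runs the network in inference mode and returns class probabilities plus,
#' optionally, the activation of every block: `F_temp` `[C x H]`, `F_conv`
#' `[F1 x C x H]`, `F_dconv`, `F_sepconv`, `F_attended` `[F2 x H]`, and the
#' attention weights.
#'
#' @param model a built or trained model.
#' @param windows an `emg_windows`, an `[N x C x L]` array, or one `C x L`
#'   matrix.
#' @param stages return per-stage activations.
#' @return List with `probs` (`B x N`, rows sum to 1) and, when requested,
#'   one entry per stage shaped `[dim..., B]`.
#' @export
nn_forward <- function(model, windows, stages = FALSE) {
  cfg <- model$cfg
  x <- windows_to_array(windows, cfg)
  out <- cpp_nn_forward(x, model$theta, cfg, stages, cfg$precision)
  if (stages) {
    # F_conv comes back as (F1*C) x FL x B; expose as F1 x C x FL x B
    fc <- out$F_conv
    d <- dim(fc)
    out$F_conv <- array(fc, c(cfg$C, cfg$F1, d[2], d[3]))
    out$F_conv <- aperm(out$F_conv, c(2, 1, 3, 4))
  }
  out
}

#' Class probabilities for a batch of windows
#'
#' @param model a built or trained model.
#' @param windows windows to classify.
#' @return Matrix `B x n_classes`; each row sums to 1.
#' @export
classify_forward <- function(model, windows) {
  nn_forward(model, windows, stages = FALSE)$probs
}

#' Predict class codes
#'
#' @param object a model.
#' @param windows windows to classify.
#' @param ... unused.
#' @return Integer class codes (0-based).
#' @export
predict.mcsnet_model <- function(object, windows, ...) {
  max.col(classify_forward(object, windows)) - 1L
}

#' Per-channel LSTM timing features for one window
#'
#' @param model a model whose architecture includes the LSTM block.
#' @param window one `C x L` matrix (or a window set; first stage of all).
#' @return Matrix `C x lstm_hidden` (`F_temp`).
#' @export
channel_lstm_forward <- function(model, window) {
  if (model$cfg$lstm_layers == 0) stop("this architecture has no LSTM block")
  st <- nn_forward(model, window, stages = TRUE)
  st$F_temp[, , 1]
}

#' Spatiotemporal convolution output for one window
#'
#' @param model a model.
#' @param window one `C x L` matrix.
#' @return `F_dconv` as a `[D*F1, 1, H]` array.
#' @export
spatiotemporal_forward <- function(model, window) {
  st <- nn_forward(model, window, stages = TRUE)
  v <- st$F_dconv[, , 1]
  array(v, c(nrow(v), 1, ncol(v)))
}

#' Separable convolution output for one window
#'
#' @param model a model with the separable block.
#' @param window one `C x L` matrix.
#' @return `F_sepconv` as a `[F2, 1, H]` array.
#' @export
separable_forward <- function(model, window) {
  if (!model$cfg$has_separable) stop("this architecture has no separable block")
  st <- nn_forward(model, window, stages = TRUE)
  v <- st$F_sepconv[, , 1]
  array(v, c(nrow(v), 1, ncol(v)))
}

#' Channel-attention weights and gated features for one window
#'
#' @param model a model with the attention block.
#' @param window one `C x L` matrix.
#' @return List with `weights` (length `F2`, each strictly in (0,1)) and
#'   `F_attended` (`[F2, 1, H]`).
#' @export
channel_attention <- function(model, window) {
  if (!model$cfg$has_attention) stop("this architecture has no attention block")
  st <- nn_forward(model, window, stages = TRUE)
  v <- st$F_attended[, , 1]
  list(weights = st$attention[, 1], F_attended = array(v, c(nrow(v), 1, ncol(v))))
}

#' LSTM parameters serving a given channel
#'
#' With symmetric tying on, mirror channels `k` and `k + C/2` resolve to the
#' same unit, so their parameters are identical by construction (shared
#' storage).
#'
#' @param model a model.
#' @param channel channel index (1-based).
#' @param layer LSTM layer (1 or 2).
#' @return List with `Wx`, `Wh`, `b`.
#' @export
lstm_unit_params <- function(model, channel, layer = 1) {
  cfg <- model$cfg
  if (cfg$lstm_layers < layer) stop("architecture has no LSTM layer ", layer)
  u <- if (cfg$tie_symmetric_lstm) (channel - 1) %% (cfg$C / 2) else channel - 1
  p <- sprintf("l%d_u%d", layer, u)
  list(Wx = get_param(model, paste0(p, "_Wx")),
       Wh = get_param(model, paste0(p, "_Wh")),
       b = get_param(model, paste0(p, "_b")))
}

#' Training configuration
#'
#' Adam with default hyperparameters, class-weighted cross-entropy, batches
#' of `batch` temporally consecutive windows from a single trial (trial
#' order shuffled between epochs, order within a batch preserved), and
#' validation stopping: the returned weights are those of the epoch with
#' minimum validation loss.
#'
#' @param epochs training epochs (study default 1000; reduce for desk-scale
#'   runs).
#' @param batch windows per batch (default 10).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param seed RNG seed for batch shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 1000, batch = 10, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8, seed = 1) {
  stopifnot(epochs >= 1, batch >= 1)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

# consecutive-window batches within each trial
make_batches <- function(ws, batch) {
  idx_by_trial <- split(seq_along(ws$labels), ws$trial_ids)
  batches <- list()
  for (tr in names(idx_by_trial)) {
    idx <- idx_by_trial[[tr]][order(ws$window_order[idx_by_trial[[tr]]])]
    starts <- seq(1, length(idx), by = batch)
    for (s in starts) {
      batches[[length(batches) + 1]] <- idx[s:min(s + batch - 1, length(idx))]
    }
  }
  batches
}

weighted_ce <- function(probs, y, clw) {
  w <- clw[y + 1]
  p <- probs[cbind(seq_along(y), y + 1)]
  sum(-w * log(pmax(p, 1e-12))) / sum(w)
}

#' Train a model
#'
#' @param model a [build_model()] output.
#' @param train,val training and validation [window_set()]s (class weights
#'   are computed on the training labels only).
#' @param tc a [train_config()].
#' @param verbose print a line every 20 epochs.
#' @return The model with `theta` set to the minimum-validation-loss
#'   checkpoint, plus `history` (per-epoch train/val loss and accuracy),
#'   `best_epoch`, and `class_weights`.
#' @export
train_model <- function(model, train, val, tc = train_config(),
                        verbose = FALSE) {
  cfg <- model$cfg
  stopifnot(length(train$labels) > 0, length(val$labels) > 0)
  if (length(setdiff(0:(cfg$n_classes - 1), unique(val$labels))) > 0) {
    warning("validation set is missing class(es): ",
            paste(setdiff(0:(cfg$n_classes - 1), unique(val$labels)),
                  collapse = ", "))
  }
  clw <- compute_class_weights(train$labels, cfg$n_classes)
  Xtr <- windows_to_array(train, cfg)
  Xval <- windows_to_array(val, cfg)
  batches <- make_batches(train, tc$batch)
  theta <- model$theta
  m <- v <- numeric(length(theta))
  step <- 0
  best_loss <- Inf
  best_theta <- theta
  best_epoch <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  with_seed(tc$seed, {
    for (epoch in seq_len(tc$epochs)) {
      order_b <- sample(length(batches))
      tl <- 0
      for (bi in order_b) {
        idx <- batches[[bi]]
        lg <- cpp_nn_loss_grad(Xtr[, , idx, drop = FALSE],
                               train$labels[idx], clw, theta, cfg,
                               cfg$precision)
        step <- step + 1
        g <- lg$grad
        m <- tc$beta1 * m + (1 - tc$beta1) * g
        v <- tc$beta2 * v + (1 - tc$beta2) * g^2
        mh <- m / (1 - tc$beta1^step)
        vh <- v / (1 - tc$beta2^step)
        theta <- theta - tc$lr * mh / (sqrt(vh) + tc$eps)
        tl <- tl + lg$loss
      }
      pv <- cpp_nn_forward(Xval, theta, cfg, FALSE, cfg$precision)$probs
      vl <- weighted_ce(pv, val$labels, clw)
      va <- mean(max.col(pv) - 1L == val$labels)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = tl / length(batches),
                                     val_loss = vl, val_acc = va))
      if (vl < best_loss) {
        best_loss <- vl
        best_theta <- theta
        best_epoch <- epoch
      }
      if (verbose && epoch %% 20 == 0) {
        message(sprintf("epoch %d  train %.4f  val %.4f  acc %.3f",
                        epoch, tl / length(batches), vl, va))
      }
    }
  })
  model$theta <- best_theta
  model$final_theta <- theta
  model$history <- hist
  model$best_epoch <- best_epoch
  model$class_weights <- clw
  model
}

#' Save / load a model
#'
#' @param model a model.
#' @param path file path (RDS).
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Numerical gradient check
#'
#' Compares the analytic gradient with central finite differences on a
#' random subset of coordinates covering every parameter tensor, in double
#' precision.
#'
#' @param cfg configuration (default: a tiny network, `C=2`, `L=16`,
#'   hidden 8, `F1=2`, `D=1`).
#' @param seed RNG seed for weights, data, and coordinate sampling.
#' @param per_slice coordinates checked per parameter tensor.
#' @param eps finite-difference step.
#' @return Maximum relative error over checked coordinates.
#' @export
gradient_check <- function(cfg = NULL, seed = 42, per_slice = 6, eps = 1e-5) {
  if (is.null(cfg)) {
    cfg <- mcsnet_config(C = 2, L = 16, lstm_hidden = 8, F1 = 2, D = 1,
                         temporal_kernel = 5, separable_kernel = 3,
                         attention_reduction = 2, n_classes = 4,
                         precision = "double")
  }
  stopifnot(cfg$precision == "double")
  model <- build_model(cfg, seed = seed)
  with_seed(seed + 1, {
    B <- 4
    x <- array(stats::rnorm(cfg$C * cfg$L * B), c(cfg$C, cfg$L, B))
    y <- sample(0:(cfg$n_classes - 1), B, replace = TRUE)
    clw <- rep(1, cfg$n_classes)
    lg <- cpp_nn_loss_grad(x, y, clw, model$theta, cfg, "double")
    lay <- model$layout
    max_err <- 0
    for (i in seq_len(nrow(lay))) {
      n_i <- lay$nrow[i] * lay$ncol[i]
      coords <- lay$offset[i] + sample(n_i, min(per_slice, n_i))
      for (j in coords) {
        tp <- model$theta; tp[j] <- tp[j] + eps
        tm <- model$theta; tm[j] <- tm[j] - eps
        lp <- cpp_nn_loss_grad(x, y, clw, tp, cfg, "double")$loss
        lm <- cpp_nn_loss_grad(x, y, clw, tm, cfg, "double")$loss
        num <- (lp - lm) / (2 * eps)
        ana <- lg$grad[j]
        err <- abs(num - ana) / max(1e-6, abs(num) + abs(ana))
        max_err <- max(max_err, err)
      }
    }
    max_err
  })
}
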