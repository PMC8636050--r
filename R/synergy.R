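#' Non-negative matrix factorization by multiplicative updates
#'
#' Lee-Seung multiplicative updates minimizing the Frobenius reconstruction
#' error `||X - W H||_F`. The objective is checked to be non-increasing at
#' every iteration (up to numerical slack) and the factorization is
#' deterministic given `seed`.
#'
#' @param X non-negative matrix.
#' @param k number of components.
#' @param max_iter iteration cap (default 500).
#' @param tol relative objective-change convergence tolerance.
#' @param seed RNG seed for initialization.
#' @return List with `W` (`nrow(X) x k`), `H` (`k x ncol(X)`), `error`
#'   (final Frobenius error), and `iterations`.
#' @export
nmf_factorize <- function(X, k, max_iter = 500, tol = 1e-8, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("NMF input must be non-negative")
  if (k < 1 || k > min(dim(X))) stop("k must be in 1..min(dim(X))")
  eps <- 1e-12
  with_seed(seed, {
    W <- matrix(stats::runif(nrow(X) * k, 0.1, 1), nrow(X), k) * sqrt(mean(X) + eps)
    H <- matrix(stats::runif(k * ncol(X), 0.1, 1), k, ncol(X)) * sqrt(mean(X) + eps)
    obj <- norm(X - W %*% H, "F")
    for (it in seq_len(max_iter)) {
      H <- H * (t(W) %*% X) / (t(W) %*% W %*% H + eps)
      W <- W * (X %*% t(H)) / (W %*% H %*% t(H) + eps)
      new_obj <- norm(X - W %*% H, "F")
      if (new_obj > obj * (1 + 1e-9) + 1e-12) {
        stop("NMF objective increased (", obj, " -> ", new_obj,
             "); multiplicative update invariant violated")
      }
      done <- (obj - new_obj) <= tol * max(obj, eps)
      obj <- new_obj
      if (done) break
    }
    list(W = W, H = H, error = obj, iterations = it)
  })
}

#' Dominant-channel analysis of an activation map via NMF
#'
#' Rectifies a channels-by-length activation matrix (absolute value),
#' factorizes it with rank-`k` NMF, and reports the channels whose largest
#' basis loading exceeds `tau` times the overall maximum loading, ranked by
#' loading. This identifies the channels carrying the dominant muscle
#' synergy.
#'
#' @param avg_activation matrix `channels x length` (e.g. the class-average
#'   signal or a layer's class-average output).
#' @param k NMF components (default 1: one dominant synergy per movement).
#' @param tau dominance threshold relative to the largest loading
#'   (default 0.5).
#' @param seed RNG seed for the factorization.
#' @return Object of class `synergy_decomposition`: `basis`, `activations`,
#'   `dominant_channels` (ranked, 1-based), `reconstruction_error`.
#' @export
channel_contribution_nmf <- function(avg_activation, k = 1, tau = 0.5,
                                     seed = 1) {
  X <- abs(as.matrix(avg_activation))
  if (k > nrow(X)) stop("k exceeds the number of channels")
  fit <- nmf_factorize(X, k, seed = seed)
  load <- apply(fit$W, 1, max)
  dominant <- which(load > tau * max(load))
  dominant <- dominant[order(load[dominant], decreasing = TRUE)]
  structure(list(basis = fit$W, activations = fit$H,
                 dominant_channels = dominant, loadings = load,
                 reconstruction_error = fit$error, tau = tau),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat("<synergy_decomposition> k =", ncol(x$basis),
      " dominant channels:", paste(x$dominant_channels, collapse = ", "),
      sprintf(" (error %.3g)\n", x$reconstruction_error))
  invisible(x)
}

#' NMF dominant channels of a layer's class-average activation
#'
#' Averages the chosen layer's activation over all windows of one class,
#' rectifies, and runs the dominant-channel NMF. For `"lstm"` the map is
#' the `C x H` timing-feature output; for `"conv1"` the first convolution's
#' output averaged over its `F1` filter maps (again `C x H`), so channel
#' identity is preserved.
#'
#' @param model a trained model with an LSTM block.
#' @param ws windows to average over (typically filtered to one class).
#' @param layer `"lstm"` or `"conv1"`.
#' @param class class code; `NULL` uses all windows in `ws`.
#' @param ... passed to [channel_contribution_nmf()].
#' @return A `synergy_decomposition`.
#' @export
layer_activation_nmf <- function(model, ws, layer = c("lstm", "conv1"),
                                 class = NULL, ...) {
  layer <- match.arg(layer)
  if (!is.null(class)) ws <- subset_windows(ws, which(ws$labels == class))
  if (length(ws$labels) == 0) stop("no windows to analyse")
  st <- nn_forward(model, ws, stages = TRUE)
  avg <- if (layer == "lstm") {
    apply(st$F_temp, c(1, 2), mean)                 # C x H over windows
  } else {
    apply(st$F_conv, c(2, 3), mean)                 # average filters+windows
  }
  channel_contribution_nmf(avg, ...)
}

#' Trace synergy information flow through the network weights
#'
#' Follows the dominant source channels through the learned weights:
#' each depthwise spatial filter is scored by the fraction of its absolute
#' weight mass on the dominant sEMG channels; filters above the threshold
#' form the spatiotemporal flow set. The same mass screening is applied to
#' the separable pointwise weights to get the final-layer flow set. The
#' attention-selected set is the top quartile of attention weights averaged
#' over `ws`. Agreement is the Jaccard index between the final flow set and
#' the attention set.
#'
#' @param model a trained full network (errors if a traced layer was
#'   ablated).
#' @param dominant dominant source-channel indices (1-based), e.g. from
#'   [channel_contribution_nmf()].
#' @param ws evaluation windows for averaging attention weights.
#' @param theta flow threshold: `"median"` (default: strictly above the
#'   per-layer median mass fraction) or a numeric fraction in (0, 1).
#' @return Object of class `flow_trace` with `depthwise_flow`,
#'   `final_flow`, `attention_top`, `agreement`, and the mass fractions.
#' @export
trace_information_flow <- function(model, dominant, ws, theta = "median") {
  cfg <- model$cfg
  if (!cfg$has_depthwise) stop("model has no depthwise layer (ablated)")
  if (!cfg$has_separable || !cfg$sep_pointwise) {
    stop("model has no separable pointwise layer (ablated)")
  }
  if (!cfg$has_attention) stop("model has no attention layer (ablated)")
  pick <- function(mass) {
    thr <- if (identical(theta, "median")) stats::median(mass) else theta
    which(mass > thr)
  }
  Wd <- abs(get_param(model, "dw_W"))              # (D*F1) x C
  tot <- rowSums(Wd)
  mass_dw <- ifelse(tot > 0, rowSums(Wd[, dominant, drop = FALSE]) / tot, 0)
  flow_dw <- pick(mass_dw)
  P <- abs(get_param(model, "s_P"))                # F2 x F2 (out x in)
  tot2 <- rowSums(P)
  mass_pw <- ifelse(tot2 > 0,
                    rowSums(P[, flow_dw, drop = FALSE]) / tot2, 0)
  flow_final <- pick(mass_pw)
  st <- nn_forward(model, ws, stages = TRUE)
  att <- rowMeans(st$attention)
  attention_top <- which(att >= stats::quantile(att, 0.75))
  structure(list(source_channels = sort(dominant),
                 depthwise_flow = flow_dw, final_flow = flow_final,
                 attention_top = attention_top,
                 mass_depthwise = mass_dw, mass_pointwise = mass_pw,
                 attention_weights = att,
                 agreement = jaccard(flow_final, attention_top)),
            class = "flow_trace")
}

#' @export
print.flow_trace <- function(x, ...) {
  cat("<flow_trace>\n",
      " source channels: ", paste(x$source_channels, collapse = ", "), "\n",
      " depthwise flow:  ", paste(x$depthwise_flow, collapse = ", "), "\n",
      " final flow:      ", paste(x$final_flow, collapse = ", "), "\n",
      " attention top:   ", paste(x$attention_top, collapse = ", "), "\n",
      sprintf("  agreement (Jaccard): %.3f\n", x$agreement), sep = "")
  invisible(x)
}

#' Jaccard set-overlap index
#'
#' @param a,b index vectors.
#' @return `|intersection| / |union|`; 1 when both are empty.
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Class-average rectified input map
#'
#' The channels-by-time average of `|x|` over all windows of one class:
#' the input-level activation map fed to the dominant-channel NMF.
#'
#' @param ws a [window_set()].
#' @param class class code; `NULL` averages all windows.
#' @return Matrix `C x L`.
#' @export
average_input_map <- function(ws, class = NULL) {
  if (!is.null(class)) ws <- subset_windows(ws, which(ws$labels == class))
  if (length(ws$labels) == 0) stop("no windows for the requested class")
  apply(abs(ws$windows), c(2, 3), mean)
}
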