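#' Time-domain window features: MAV, WL, ZC
#'
#' Mean absolute value `mean(|x|)`, waveform length `sum(|diff(x)|)`, and the
#' zero-crossing count: the number of consecutive sample pairs with strictly
#' opposite signs whose amplitudes both exceed the dead-band `zc_eps`
#' (default 0, i.e. no dead band).
#'
#' @param x numeric vector (length >= 2 for WL/ZC).
#' @param zc_eps zero-crossing dead-band threshold.
#' @return Named numeric vector `c(MAV, WL, ZC)`.
#' @export
time_domain_features <- function(x, zc_eps = 0) {
  if (length(x) < 2) stop("need at least 2 samples for WL/ZC")
  d <- diff(x)
  zc <- sum(x[-length(x)] * x[-1] < 0 &
              abs(x[-length(x)]) > zc_eps & abs(x[-1]) > zc_eps)
  c(MAV = mean(abs(x)), WL = sum(abs(d)), ZC = as.numeric(zc))
}

#' Burg autoregressive coefficients
#'
#' Coefficients `a_1..a_order` of the AR model `x_t = sum_j a_j x_(t-j) + e_t`
#' fitted by the Burg method. Coefficients are invariant to amplitude scaling
#' of `x`.
#'
#' @param x numeric vector, longer than `order + 1`, not constant.
#' @param order model order (default 6).
#' @return Numeric vector of `order` coefficients.
#' @export
ar_features <- function(x, order = 6) {
  if (length(x) <= order + 1) stop("need more than order + 1 samples")
  if (stats::sd(x) == 0) {
    warning("constant signal: AR coefficients undefined, returning zeros")
    return(rep(0, order))
  }
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  if (length(a) < order) a <- c(a, rep(0, order - length(a)))
  as.numeric(a)
}

#' Welch power spectral density estimate
#'
#' One-sided PSD by Welch's method: Hann-windowed segments of `nperseg`
#' samples with 50 percent overlap, periodograms averaged and scaled as a
#' density (power per Hz), so the PSD integrated over 0..Nyquist matches the
#' signal's mean square power.
#'
#' @param x numeric vector (length >= `nperseg`).
#' @param rate_hz sampling rate in Hz.
#' @param nperseg segment length (default 128).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, rate_hz, nperseg = 128) {
  n <- length(x)
  if (n < nperseg) stop("signal shorter than one segment (", nperseg, ")")
  step <- nperseg %/% 2
  starts <- seq(1, n - nperseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1))  # Hann
  scale <- 1 / (rate_hz * sum(win^2))
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)] * win
    p <- abs(stats::fft(seg))^2 * scale
    p <- p[1:nfreq]
    p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]   # fold negative frequencies
    acc <- acc + p
  }
  list(freq = (0:(nfreq - 1)) * rate_hz / nperseg, psd = acc / length(starts))
}

#' Mean in-band power spectral density
#'
#' Mean of the Welch PSD estimate over the sEMG analysis band
#' (default 10-450 Hz).
#'
#' @param x numeric vector (length >= 64).
#' @param rate_hz sampling rate in Hz.
#' @param band frequency band `c(low, high)` in Hz.
#' @param nperseg Welch segment length.
#' @return Mean PSD over the band (power per Hz).
#' @export
psd_mean <- function(x, rate_hz, band = c(10, 450), nperseg = 128) {
  if (length(x) < 64) stop("need at least 64 samples")
  if (band[2] >= rate_hz / 2) stop("band upper edge must be below Nyquist")
  w <- welch_psd(x, rate_hz, nperseg)
  sel <- w$freq >= band[1] & w$freq <= band[2]
  mean(w$psd[sel])
}

#' Per-window feature matrix
#'
#' Concatenates, channel by channel, the ten features MAV, WL, ZC, six Burg
#' AR coefficients, and mean in-band Welch PSD, giving `C x 10` columns.
#' Column order is channel-major and recorded in the column names
#' (`ch<k>_<feature>`). Extraction is deterministic.
#'
#' @param ws a [window_set()].
#' @param zc_eps zero-crossing dead band.
#' @param band PSD band in Hz.
#' @return List with `X` (matrix `N x C*10`), `y` (integer labels), and
#'   `feature_names`.
#' @export
build_feature_matrix <- function(ws, zc_eps = 0, band = c(10, 450)) {
  d <- dim(ws$windows)
  if (d[1] == 0) stop("empty window set")
  rate <- if (!is.null(ws$meta$rate_hz)) ws$meta$rate_hz else 1500
  per_ch <- c("MAV", "WL", "ZC", paste0("AR", 1:6), "PSDmean")
  names_out <- as.vector(vapply(seq_len(d[2]),
                                function(c) paste0("ch", c, "_", per_ch),
                                character(10)))
  X <- matrix(0, d[1], d[2] * 10, dimnames = list(NULL, names_out))
  for (i in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      x <- ws$windows[i, c, ]
      td <- time_domain_features(x, zc_eps)
      ar <- if (stats::sd(x) == 0) rep(0, 6) else ar_features(x, 6)
      ps <- if (all(x == 0)) 0 else psd_mean(x, rate, band)
      X[i, ((c - 1) * 10 + 1):(c * 10)] <- c(td, ar, ps)
    }
  }
  list(X = X, y = ws$labels, feature_names = names_out)
}

baseline_names <- c("LDA", "DT", "BES", "LSVM", "RBFSVM", "KNN", "ANN")

#' Classical baseline classifier specification
#'
#' Returns the hyperparameter configuration of one of the seven classical
#' movement-prediction baselines: linear discriminant analysis (full-rank
#' covariance within-subject, diagonal cross-subject), decision tree capped
#' at 100 splits, kernel-density Naive Bayes, linear SVM (C = 1, one-vs-one),
#' RBF SVM (C = 1.9, one-vs-one), 1-nearest-neighbour with Mahalanobis
#' metric, and a single-hidden-layer neural network with 28 units. All
#' honour inverse-frequency class weights during training.
#'
#' @param name one of `"LDA"`, `"DT"`, `"BES"`, `"LSVM"`, `"RBFSVM"`,
#'   `"KNN"`, `"ANN"`.
#' @param protocol `"within"` or `"cross"`; switches the LDA covariance
#'   structure between full-rank and diagonal.
#' @return An object of class `classifier_spec`.
#' @export
configure_baseline <- function(name, protocol = c("within", "cross")) {
  protocol <- match.arg(protocol)
  if (!name %in% baseline_names) {
    stop("unknown baseline '", name, "'; valid names: ",
         paste(baseline_names, collapse = ", "))
  }
  hp <- switch(name,
    LDA = list(covariance = if (protocol == "within") "full" else "diagonal"),
    DT = list(max_splits = 100),
    BES = list(kernel = "gaussian"),
    LSVM = list(kernel = "linear", cost = 1, multiclass = "one-vs-one"),
    RBFSVM = list(kernel = "radial", cost = 1.9, multiclass = "one-vs-one"),
    KNN = list(k = 1, metric = "mahalanobis"),
    ANN = list(hidden = 28))
  structure(list(name = name, protocol = protocol, hyperparameters = hp),
            class = "classifier_spec")
}

# Pooled-diagonal-covariance Gaussian classifier (diagonal LDA).
fit_diag_lda <- function(X, y, prior) {
  classes <- sort(unique(y))
  mu <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(ncol(X))))
  v <- numeric(ncol(X))
  for (k in seq_along(classes)) {
    Xi <- X[y == classes[k], , drop = FALSE]
    v <- v + colSums(sweep(Xi, 2, mu[k, ])^2)
  }
  v <- v / (nrow(X) - length(classes))
  v[v < 1e-12] <- 1e-12
  list(classes = classes, mu = mu, var = v, logprior = log(prior))
}

predict_diag_lda <- function(fit, X) {
  scores <- vapply(seq_along(fit$classes), function(k) {
    -0.5 * colSums((t(X) - fit$mu[k, ])^2 / fit$var) + fit$logprior[k]
  }, numeric(nrow(X)))
  fit$classes[max.col(matrix(scores, nrow(X)))]
}

# Kernel-density Naive Bayes with Gaussian kernels per feature and class.
fit_kde_nb <- function(X, y, prior) {
  classes <- sort(unique(y))
  dens <- lapply(classes, function(k) {
    Xi <- X[y == k, , drop = FALSE]
    lapply(seq_len(ncol(X)), function(j) {
      xj <- Xi[, j]
      bw <- tryCatch(stats::bw.nrd0(xj), error = function(e) 0)
      if (!is.finite(bw) || bw <= 0) bw <- max(1e-6, stats::sd(xj), na.rm = TRUE)
      list(x = xj, bw = bw)
    })
  })
  list(classes = classes, dens = dens, logprior = log(prior))
}

predict_kde_nb <- function(fit, X) {
  n <- nrow(X)
  scores <- matrix(0, n, length(fit$classes))
  for (k in seq_along(fit$classes)) {
    s <- rep(fit$logprior[k], n)
    for (j in seq_len(ncol(X))) {
      d <- fit$dens[[k]][[j]]
      # mean Gaussian kernel over training points, evaluated at X[, j]
      ll <- vapply(X[, j], function(q) {
        mean(stats::dnorm(q, mean = d$x, sd = d$bw))
      }, numeric(1))
      s <- s + log(pmax(ll, 1e-300))
    }
    scores[, k] <- s
  }
  fit$classes[max.col(scores)]
}

# Whitening transform for Mahalanobis 1-NN. The pooled covariance is rank
# deficient whenever n < p, so eigenvalues are floored at a fraction of
# their mean before inversion (standard shrinkage; unregularized whitening
# amplifies null-space noise and destroys the metric).
fit_whitener <- function(X, floor_frac = 0.05) {
  S <- stats::cov(X)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, floor_frac * mean(abs(ev$values)))
  W <- ev$vectors %*% diag(1 / sqrt(lam)) %*% t(ev$vectors)
  list(center = colMeans(X), W = W)
}

apply_whitener <- function(wh, X) sweep(X, 2, wh$center) %*% wh$W

#' Train a classical baseline on a feature matrix
#'
#' @param spec a [configure_baseline()] specification.
#' @param X feature matrix `N x p`.
#' @param y integer class codes.
#' @param class_weights per-class weights (default computed from `y`).
#' @param seed RNG seed (only the neural network baseline is stochastic).
#' @return A fitted model of class `baseline_fit`.
#' @export
train_baseline <- function(spec, X, y, class_weights = NULL, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- as.integer(y)
  if (is.null(class_weights)) class_weights <- compute_class_weights(y)
  case_w <- class_weights[as.character(y)]
  counts <- table(factor(y, levels = sort(unique(y))))
  # inverse-frequency class weights x class counts are equal across classes,
  # so the weighted empirical prior is uniform
  prior <- as.numeric(class_weights[as.character(sort(unique(y)))] * counts)
  prior <- prior / sum(prior)
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    LDA = {
      if (hp$covariance == "full") {
        keep <- apply(X, 2, stats::sd) > 1e-12
        sc <- list(center = colMeans(X[, keep, drop = FALSE]),
                   scale = apply(X[, keep, drop = FALSE], 2, stats::sd))
        Xs <- scale(X[, keep, drop = FALSE], sc$center, sc$scale)
        list(kind = "lda", keep = keep, sc = sc,
             fit = MASS::lda(Xs, grouping = factor(y), prior = prior,
                             tol = 1e-8))
      } else {
        list(kind = "dlda", fit = fit_diag_lda(X, y, prior))
      }
    },
    DT = {
      df <- data.frame(y = factor(y), X)
      full <- rpart::rpart(y ~ ., data = df, weights = case_w, method = "class",
                           control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                          xval = 0))
      cpt <- full$cptable
      ok <- cpt[cpt[, "nsplit"] <= hp$max_splits, "CP"]
      list(kind = "rpart", fit = rpart::prune(full, cp = min(ok)))
    },
    BES = list(kind = "kdenb", fit = fit_kde_nb(X, y, prior)),
    LSVM = list(kind = "svm",
                fit = e1071::svm(X, factor(y), kernel = "linear", cost = 1,
                                 class.weights = stats::setNames(
                                   class_weights, names(class_weights)))),
    RBFSVM = list(kind = "svm",
                  fit = e1071::svm(X, factor(y), kernel = "radial", cost = 1.9,
                                   class.weights = stats::setNames(
                                     class_weights, names(class_weights)))),
    KNN = {
      wh <- fit_whitener(X)
      list(kind = "knn", wh = wh, train = apply_whitener(wh, X), y = y)
    },
    ANN = {
      set.seed(seed)
      sc <- list(center = colMeans(X), scale = pmax(apply(X, 2, stats::sd), 1e-12))
      Xs <- scale(X, sc$center, sc$scale)
      Y <- nnet::class.ind(factor(y))
      list(kind = "nnet", sc = sc,
           fit = nnet::nnet(Xs, Y, size = hp$hidden, softmax = TRUE,
                            weights = case_w, maxit = 300, trace = FALSE,
                            MaxNWts = 20000))
    })
  structure(c(fit, list(spec = spec)), class = "baseline_fit")
}

#' Predict class codes with a fitted baseline
#'
#' @param object a `baseline_fit` from [train_baseline()].
#' @param X feature matrix.
#' @param ... unused.
#' @return Integer class codes.
#' @export
predict.baseline_fit <- function(object, X, ...) {
  out <- switch(object$kind,
    lda = as.integer(as.character(
      stats::predict(object$fit,
                     scale(X[, object$keep, drop = FALSE],
                           object$sc$center, object$sc$scale))$class)),
    dlda = predict_diag_lda(object$fit, X),
    rpart = as.integer(as.character(
      stats::predict(object$fit, data.frame(X), type = "class"))),
    kdenb = predict_kde_nb(object$fit, X),
    svm = as.integer(as.character(stats::predict(object$fit, X))),
    knn = as.integer(as.character(
      class::knn(object$train, apply_whitener(object$wh, X),
                 cl = factor(object$y), k = 1))),
    nnet = {
      Xs <- scale(X, object$sc$center, object$sc$scale)
      p <- stats::predict(object$fit, Xs)
      as.integer(colnames(p)[max.col(p)])
    })
  as.integer(out)
}
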