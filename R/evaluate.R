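#' Evaluation split plan
#'
#' Two protocols, both splitting at the trial level so overlapping windows
#' never leak between train and test:
#' * `"within"`: per subject, a stratified 70/30 train/test split of trials,
#'   with 4-fold cross-validation folds over the training portion (used for
#'   validation stopping / model selection).
#' * `"cross"`: per repetition, `train_subjects` subjects train and
#'   `val_subjects` disjoint subjects evaluate; `reps` repetitions.
#'
#' @param mode `"within"` or `"cross"`.
#' @param seed RNG seed; splits are deterministic given the seed.
#' @param train_frac within-subject training fraction (default 0.7).
#' @param n_folds folds over the training portion (default 4).
#' @param reps cross-subject repetitions (default 10).
#' @param train_subjects,val_subjects subjects per side in cross mode.
#' @return Object of class `split_plan`.
#' @export
split_plan <- function(mode = c("within", "cross"), seed = 1,
                       train_frac = 0.7, n_folds = 4, reps = 10,
                       train_subjects = 3, val_subjects = 2) {
  mode <- match.arg(mode)
  structure(list(mode = mode, seed = as.integer(seed),
                 train_frac = train_frac, n_folds = as.integer(n_folds),
                 reps = as.integer(reps),
                 train_subjects = as.integer(train_subjects),
                 val_subjects = as.integer(val_subjects)),
            class = "split_plan")
}

trial_table <- function(ws) {
  unique(data.frame(subject_id = ws$subject_ids, trial_id = ws$trial_ids,
                    label = ws$labels, stringsAsFactors = FALSE))
}

#' Materialize concrete train/test index sets
#'
#' @param ws a [window_set()] covering the whole dataset.
#' @param plan a [split_plan()].
#' @return For `"within"`: a named list per subject with `train_trials`,
#'   `test_trials`, and `folds` (a partition of the training trials).
#'   For `"cross"`: a list of repetitions with `train_subjects` and
#'   `val_subjects`. All elements are trial/subject identifiers; windows
#'   inherit their trial's side.
#' @export
make_splits <- function(ws, plan) {
  tt <- trial_table(ws)
  with_seed(plan$seed, {
    if (plan$mode == "within") {
      out <- list()
      for (sid in sort(unique(tt$subject_id))) {
        ts <- tt[tt$subject_id == sid, ]
        counts <- table(ts$label)
        if (any(counts < 2)) {
          stop("within-subject split needs at least 2 trials per class per ",
               "subject; subject ", sid, " violates this")
        }
        train_trials <- character()
        test_trials <- character()
        for (k in sort(unique(ts$label))) {
          tr <- sample(ts$trial_id[ts$label == k])
          n_train <- max(1, floor(plan$train_frac * length(tr)))
          n_train <- min(n_train, length(tr) - 1)     # keep >= 1 test trial
          train_trials <- c(train_trials, tr[seq_len(n_train)])
          test_trials <- c(test_trials, tr[-seq_len(n_train)])
        }
        # stratified fold assignment over the training trials; the fold
        # counter runs across classes so folds stay balanced even with
        # few trials per class
        fold_of <- integer(0)
        at <- 0
        for (k in sort(unique(ts$label))) {
          trk <- sample(intersect(train_trials, ts$trial_id[ts$label == k]))
          fold_of[trk] <- (at + seq_along(trk) - 1) %% plan$n_folds + 1
          at <- at + length(trk)
        }
        folds <- lapply(seq_len(plan$n_folds),
                        function(f) names(fold_of)[fold_of == f])
        out[[sid]] <- list(subject = sid, train_trials = sort(train_trials),
                           test_trials = sort(test_trials), folds = folds)
      }
      out
    } else {
      subjects <- sort(unique(tt$subject_id))
      need <- plan$train_subjects + plan$val_subjects
      if (length(subjects) < need) {
        stop("cross-subject protocol needs at least ", need, " subjects, got ",
             length(subjects))
      }
      lapply(seq_len(plan$reps), function(rep) {
        s <- sample(subjects, need)
        list(rep = rep,
             train_subjects = sort(s[seq_len(plan$train_subjects)]),
             val_subjects = sort(s[-seq_len(plan$train_subjects)]))
      })
    }
  })
}

# stable fingerprint of a split (rolling polynomial hash over the
# serialized structure), used to certify identical data across ablation
# conditions
split_hash <- function(splits) {
  s <- utf8ToInt(paste(deparse(splits), collapse = "\n"))
  h <- 0
  for (v in s) h <- (h * 131 + v) %% 2147483647
  h
}

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors.
#' @return Fraction of exact matches in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0) stop("empty prediction vector")
  if (length(pred) != length(truth)) {
    stop("length mismatch: ", length(pred), " predictions vs ",
         length(truth), " labels")
  }
  mean(pred == truth)
}

#' Model specification for protocol runs
#'
#' @param name display name (also selects the classical baseline when
#'   `kind = "classical"`).
#' @param kind `"deep"` (raw windows through the network) or `"classical"`
#'   (handcrafted features through a Table-style baseline).
#' @param cfg an [mcsnet_config()] for deep models.
#' @param tc a [train_config()] for deep models.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, kind = c("deep", "classical"), cfg = NULL,
                       tc = NULL) {
  kind <- match.arg(kind)
  if (kind == "deep" && is.null(cfg)) stop("deep models need a cfg")
  structure(list(name = name, kind = kind, cfg = cfg,
                 tc = if (is.null(tc)) train_config() else tc),
            class = "model_spec")
}

# Train one spec on train windows (with val for deep models) and return
# predicted codes for the test windows. Classical models need no stopping
# set, so they train on train + val (the full 70% side).
fit_and_predict <- function(spec, train, val, test, seed,
                            protocol = "within") {
  if (spec$kind == "deep") {
    model <- build_model(spec$cfg, seed = seed)
    tc <- spec$tc
    tc$seed <- seed
    fit <- train_model(model, train, val, tc)
    predict(fit, test)
  } else {
    cs <- configure_baseline(spec$name, protocol = protocol)
    full <- bind_windows(list(train, val))
    ftr <- build_feature_matrix(full)
    fte <- build_feature_matrix(test)
    fit <- train_baseline(cs, ftr$X, ftr$y, seed = seed)
    predict(fit, fte$X)
  }
}

#' Run an evaluation protocol over a set of models
#'
#' Within-subject: for each subject, each model trains on the 70 percent
#' training trials (deep models use one CV fold as the validation set for
#' stopping) and is scored on the held-out 30 percent. Cross-subject: per
#' repetition, models train on the training subjects' windows (one trial
#' per class held out as validation for deep models) and are scored on the
#' validation subjects.
#'
#' @param models list of [model_spec()]s.
#' @param ws full [window_set()].
#' @param plan a [split_plan()].
#' @param seed base training seed.
#' @return A `results_table`: data frame with one row per model, one
#'   accuracy column per subject (within) or repetition (cross), plus
#'   `mean` and `se2` (two standard errors of the mean across columns).
#' @export
run_protocol <- function(models, ws, plan, seed = 1) {
  splits <- make_splits(ws, plan)
  cols <- if (plan$mode == "within") names(splits) else
    paste0("rep", seq_along(splits))
  acc <- matrix(NA_real_, length(models), length(splits),
                dimnames = list(vapply(models, `[[`, "", "name"), cols))
  for (j in seq_along(splits)) {
    sp <- splits[[j]]
    if (plan$mode == "within") {
      sub_idx <- ws$subject_ids == sp$subject
      val_trials <- sp$folds[[1]]
      train <- subset_windows(ws, which(sub_idx &
                                          ws$trial_ids %in% setdiff(sp$train_trials, val_trials)))
      val <- subset_windows(ws, which(sub_idx & ws$trial_ids %in% val_trials))
      test <- subset_windows(ws, which(sub_idx & ws$trial_ids %in% sp$test_trials))
    } else {
      tr_idx <- ws$subject_ids %in% sp$train_subjects
      tt <- trial_table(subset_windows(ws, which(tr_idx)))
      val_trials <- with_seed(plan$seed + j, {
        unlist(lapply(split(tt$trial_id, tt$label),
                      function(tr) sample(tr, 1)))
      })
      train <- subset_windows(ws, which(tr_idx & !ws$trial_ids %in% val_trials))
      val <- subset_windows(ws, which(tr_idx & ws$trial_ids %in% val_trials))
      test <- subset_windows(ws, which(ws$subject_ids %in% sp$val_subjects))
    }
    for (i in seq_along(models)) {
      acc[i, j] <- tryCatch(
        accuracy(fit_and_predict(models[[i]], train, val, test, seed,
                                 protocol = plan$mode), test$labels),
        error = function(e) {
          warning("model ", models[[i]]$name, " failed on ", cols[j], ": ",
                  conditionMessage(e))
          NA_real_
        })
    }
  }
  out <- data.frame(model = rownames(acc), acc, check.names = FALSE,
                    row.names = NULL)
  out$mean <- rowMeans(acc, na.rm = TRUE)
  out$se2 <- apply(acc, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) return(NA_real_)
    2 * stats::sd(r) / sqrt(length(r))
  })
  class(out) <- c("results_table", class(out))
  attr(out, "plan") <- plan
  out
}

#' Layer-ablation study
#'
#' Trains and evaluates the full network and the three single-layer-removed
#' variants (depthwise replaced by a parameter-free channel average,
#' separable removed, attention removed) on identical cross-subject splits
#' and identical seeds, so accuracy differences isolate the removed
#' computation.
#'
#' @param cfg the full-network [mcsnet_config()].
#' @param ws full [window_set()].
#' @param plan a cross-subject [split_plan()].
#' @param tc a [train_config()].
#' @param seeds training seeds (one run per seed per condition).
#' @return An `ablation_report` data frame: one row per condition
#'   (`none`, `depthwise`, `separable`, `attention`) with mean accuracy and
#'   per-seed columns; attribute `split_hash` certifies shared splits.
#' @export
run_ablation <- function(cfg, ws, plan, tc = train_config(), seeds = 1:3) {
  if (plan$mode != "cross") stop("ablation runs under the cross-subject protocol")
  conditions <- c("none", "depthwise", "separable", "attention")
  res <- matrix(NA_real_, length(conditions), length(seeds),
                dimnames = list(conditions, paste0("seed", seeds)))
  # per-condition fingerprint of the concrete splits each condition saw;
  # columns must be constant for the comparison to be valid
  hashes <- matrix(NA_real_, length(conditions), length(seeds),
                   dimnames = dimnames(res))
  for (si in seq_along(seeds)) {
    plan_s <- plan
    plan_s$seed <- plan$seed + seeds[si]
    splits <- make_splits(ws, plan_s)
    for (cond in conditions) {
      hashes[cond, si] <- split_hash(splits)
      cfg_c <- mcsnet_config(
        C = cfg$C, L = cfg$L, lstm_hidden = cfg$lstm_hidden, F1 = cfg$F1,
        D = cfg$D, temporal_kernel = cfg$temporal_kernel,
        separable_kernel = cfg$separable_kernel,
        attention_reduction = cfg$attention_reduction,
        n_classes = cfg$n_classes,
        tie_symmetric_lstm = cfg$tie_symmetric_lstm, arch = "mcsnet",
        ablate = cond, precision = cfg$precision)
      spec <- model_spec(paste0("mcsnet-", cond), "deep", cfg_c, tc)
      accs <- vapply(splits, function(sp) {
        tr_idx <- ws$subject_ids %in% sp$train_subjects
        tt <- trial_table(subset_windows(ws, which(tr_idx)))
        val_trials <- with_seed(plan_s$seed + sp$rep, {
          unlist(lapply(split(tt$trial_id, tt$label),
                        function(tr) sample(tr, 1)))
        })
        train <- subset_windows(ws, which(tr_idx & !ws$trial_ids %in% val_trials))
        val <- subset_windows(ws, which(tr_idx & ws$trial_ids %in% val_trials))
        test <- subset_windows(ws, which(ws$subject_ids %in% sp$val_subjects))
        accuracy(fit_and_predict(spec, train, val, test, seeds[si]),
                 test$labels)
      }, numeric(1))
      res[cond, si] <- mean(accs)
    }
  }
  out <- data.frame(removed = conditions, res, check.names = FALSE,
                    row.names = NULL)
  out$mean <- rowMeans(res)
  class(out) <- c("ablation_report", class(out))
  attr(out, "split_hash") <- hashes
  out
}

#' Shuffle labels at the trial level
#'
#' Permutes the class labels across trials (windows inherit their trial's
#' new label), preserving the label multiset. Used to build chance-level
#' null controls: a model trained on shuffled labels should score near
#' `1/n_classes`.
#'
#' @param ws a [window_set()].
#' @param seed RNG seed.
#' @return The window set with permuted labels.
#' @export
shuffle_trial_labels <- function(ws, seed = 1) {
  tri <- trial_table(ws)
  with_seed(seed, {
    new_y <- sample(tri$label)
  })
  names(new_y) <- tri$trial_id
  ws$labels <- as.integer(new_y[ws$trial_ids])
  ws
}
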