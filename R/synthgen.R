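# Synthetic sEMG with planted muscle-synergy structure.
#
# Each channel is amplitude-modulated band-limited Gaussian noise (the
# standard interference-pattern surrogate for surface EMG): a non-negative
# per-class channel loading times a trapezoidal activation envelope
# modulates a 20-450 Hz stochastic carrier; left/right mirror channels
# (k, k + C/2) share a correlated carrier component; 50 Hz mains and a white
# noise floor are added. Per-subject multiplicative loading perturbations
# emulate muscle compensation differences between subjects.

# Deterministic substream seeding: every artifact derives its seed from the
# master seed and small integer tags, staying below 2^31.
mix_seed <- function(master, ...) {
  tags <- c(master, ...)
  h <- 0
  for (t in tags) h <- (h * 7919 + (t %% 2147483647) + 1) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Planted synergy ground truth
#'
#' Non-negative per-class channel loadings plus the activation envelope
#' parameters. The default loadings give every class a primary mirror pair
#' (loading 1) and a secondary pair (loading 0.7) on top of a low baseline,
#' so classes differ in which channels carry energy, mirroring the
#' muscle-synergy structure the explainability analysis is meant to recover.
#'
#' @param C number of channels (even, default 12).
#' @param n_classes number of movement classes (default 4).
#' @param loadings optional `C x n_classes` non-negative matrix overriding
#'   the defaults.
#' @param baseline loading given to non-planted channels (default 0.15).
#' @param symmetric_corr carrier correlation between mirror channels, in
#'   `[0, 1]` (default 0.5).
#' @param ramp_s envelope rise/fall time in seconds (default 0.2).
#' @return Object of class `synergy_ground_truth`.
#' @export
synergy_ground_truth <- function(C = 12, n_classes = 4, loadings = NULL,
                                 baseline = 0.15, symmetric_corr = 0.5,
                                 ramp_s = 0.2) {
  if (C %% 2 != 0) stop("C must be even (mirror-pair channel layout)")
  if (is.null(loadings)) {
    half <- C / 2
    primary <- list(c(2, 3), c(3, 6), c(1, 5), c(5, 2))   # left-side indices
    loadings <- matrix(baseline, C, n_classes)
    for (k in seq_len(n_classes)) {
      p <- primary[[(k - 1) %% length(primary) + 1]]
      loadings[c(p[1], p[1] + half), k] <- 1
      loadings[c(p[2], p[2] + half), k] <- 0.7
    }
  }
  loadings <- as.matrix(loadings)
  if (any(loadings < 0)) stop("loadings must be non-negative")
  if (nrow(loadings) != C || ncol(loadings) != n_classes) {
    stop("loadings must be C x n_classes")
  }
  gt <- structure(list(loadings = loadings, symmetric_corr = symmetric_corr,
                       ramp_s = ramp_s, C = C, n_classes = n_classes),
                  class = "synergy_ground_truth")
  planted <- lapply(seq_len(n_classes) - 1L, planted_channels, gt = gt)
  if (all(vapply(planted, length, 1L) == 0)) stop("no planted channels")
  gt$planted <- planted
  gt
}

#' Planted dominant channels for one class
#'
#' The oracle set used by the explainability tests: channels whose loading
#' exceeds half the class maximum.
#'
#' @param gt a [synergy_ground_truth()].
#' @param class class code `0..n_classes-1`.
#' @return Integer vector of channel indices (1-based).
#' @export
planted_channels <- function(gt, class) {
  stopifnot(class >= 0, class < gt$n_classes)
  l <- gt$loadings[, class + 1]
  which(l > 0.5 * max(l))
}

#' Per-subject generation profile
#'
#' @param subject_id subject identifier string.
#' @param loading_perturbation standard deviation of the multiplicative
#'   log-normal perturbation applied to the class loadings (muscle
#'   compensation across subjects).
#' @param gain overall amplitude gain for the subject.
#' @param seed subject seed.
#' @return Object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, loading_perturbation = 0.1,
                            gain = 1, seed = 1) {
  structure(list(subject_id = subject_id,
                 loading_perturbation = loading_perturbation,
                 gain = gain, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Simulation configuration
#'
#' Acquisition-matched defaults: 12 channels at 1500 Hz, a 2 s preparation
#' window, 4 classes with 10 trials each except walking with 20, a 20-450 Hz
#' carrier band, 50 Hz mains, and a white noise floor.
#'
#' @param n_subjects number of subjects.
#' @param C,rate_hz,prep_seconds,n_classes acquisition geometry.
#' @param trials_per_class integer vector (recycled to `n_classes`).
#' @param carrier_band carrier bandpass in Hz.
#' @param mains_amp 50 Hz mains amplitude (signal units).
#' @param noise_floor white-noise standard deviation.
#' @param loading_perturbation across-subject loading jitter (see
#'   [subject_profile()]).
#' @param symmetric_corr mirror-pair carrier correlation.
#' @param seed master seed; all per-subject/per-trial streams derive from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5, C = 12, rate_hz = 1500,
                       prep_seconds = 2, n_classes = 4,
                       trials_per_class = c(10, 10, 20, 10),
                       carrier_band = c(20, 450), mains_amp = 0.2,
                       noise_floor = 0.05, loading_perturbation = 0.1,
                       symmetric_corr = 0.5, seed = 0) {
  if (carrier_band[1] <= 0 || carrier_band[2] >= rate_hz / 2 ||
      carrier_band[2] <= carrier_band[1]) {
    stop("carrier band must satisfy 0 < low < high < Nyquist")
  }
  tpc <- rep_len(trials_per_class, n_classes)
  if (any(tpc < 1)) stop("need at least one trial per class")
  structure(list(n_subjects = n_subjects, C = C, rate_hz = rate_hz,
                 prep_seconds = prep_seconds, n_classes = n_classes,
                 trials_per_class = tpc, carrier_band = carrier_band,
                 mains_amp = mains_amp, noise_floor = noise_floor,
                 loading_perturbation = loading_perturbation,
                 symmetric_corr = symmetric_corr, seed = as.integer(seed)),
            class = "sim_config")
}

# Trapezoidal activation envelope over the preparation window.
activation_envelope <- function(Tn, rate_hz, ramp_s) {
  r <- max(1L, as.integer(round(ramp_s * rate_hz)))
  env <- rep(1, Tn)
  up <- seq_len(min(r, Tn))
  env[up] <- up / r
  down <- seq_len(min(r, Tn))
  env[Tn - down + 1] <- pmin(env[Tn - down + 1], down / r)
  env
}

# Band-limited unit-variance Gaussian carrier.
bandlimited_noise <- function(Tn, rate_hz, band) {
  bp <- signal::butter(2, band / (rate_hz / 2), type = "pass")
  x <- stats::rnorm(Tn + 2000)
  y <- signal::filter(bp, x)[-(1:2000)]           # drop warm-up
  as.numeric(y) / stats::sd(y)
}

#' Generate all trials for one subject
#'
#' Channel `c` of a trial with class `k` is
#' `gain * pert_loading[c, k] * envelope(t) * carrier_c(t) + mains + noise`,
#' where mirror channels share a carrier component with weight
#' `symmetric_corr`. Deterministic given the master seed, the subject seed,
#' and the trial index; the whole span is annotated as the preparation
#' period.
#'
#' @param gt a [synergy_ground_truth()].
#' @param prof a [subject_profile()].
#' @param sim a [sim_config()].
#' @return List of [emg_recording()]s.
#' @export
generate_subject <- function(gt, prof, sim) {
  C <- sim$C
  half <- C / 2
  Tn <- as.integer(sim$prep_seconds * sim$rate_hz)
  pert <- with_seed(mix_seed(sim$seed, prof$seed, 1), {
    gt$loadings * matrix(exp(stats::rnorm(C * gt$n_classes, 0,
                                          prof$loading_perturbation)),
                         C, gt$n_classes)
  })
  tt <- (seq_len(Tn) - 1) / sim$rate_hz
  env <- activation_envelope(Tn, sim$rate_hz, gt$ramp_s)
  recs <- list()
  trial_no <- 0
  for (k in seq_len(sim$n_classes)) {
    for (tr in seq_len(sim$trials_per_class[k])) {
      trial_no <- trial_no + 1
      x <- with_seed(mix_seed(sim$seed, prof$seed, 1000 + trial_no), {
        rho <- sim$symmetric_corr
        shared <- replicate(half, bandlimited_noise(Tn, sim$rate_hz,
                                                    sim$carrier_band))
        own <- replicate(C, bandlimited_noise(Tn, sim$rate_hz, sim$carrier_band))
        m <- matrix(0, C, Tn)
        for (c in seq_len(C)) {
          pair <- if (c <= half) c else c - half
          carrier <- sqrt(1 - rho) * own[, c] + sqrt(rho) * shared[, pair]
          m[c, ] <- prof$gain * pert[c, k] * env * carrier
        }
        phase <- stats::runif(1, 0, 2 * pi)
        mains <- sim$mains_amp * sin(2 * pi * 50 * tt + phase)
        m + rep(1, C) %o% mains +
          matrix(stats::rnorm(C * Tn, 0, sim$noise_floor), C, Tn)
      })
      recs[[trial_no]] <- emg_recording(
        x, rate_hz = sim$rate_hz, subject_id = prof$subject_id,
        trial_id = sprintf("trial%03d", trial_no), label = k - 1L,
        annotations = list(preparation = c(1L, Tn + 1L)))
    }
  }
  recs
}

#' Generate a multi-subject synthetic cohort
#'
#' @param sim a [sim_config()].
#' @param gt optional [synergy_ground_truth()] (default constructed from
#'   `sim`).
#' @param dir if non-NULL, recordings are written as CSV+JSON under `dir`
#'   with a `manifest.json` and a `ground_truth.json`.
#' @return List with `recordings` (named list per subject), `ground_truth`,
#'   `profiles`, and (when written) `manifest` path.
#' @export
generate_cohort <- function(sim = sim_config(), gt = NULL, dir = NULL) {
  if (is.null(gt)) {
    gt <- synergy_ground_truth(C = sim$C, n_classes = sim$n_classes,
                               symmetric_corr = sim$symmetric_corr)
  }
  profiles <- lapply(seq_len(sim$n_subjects), function(s) {
    subject_profile(sprintf("S%02d", s),
                    loading_perturbation = sim$loading_perturbation,
                    seed = s)
  })
  recordings <- list()
  for (p in profiles) recordings[[p$subject_id]] <- generate_subject(gt, p, sim)
  out <- list(recordings = recordings, ground_truth = gt, profiles = profiles)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
      stop("cannot create output directory ", dir)
    }
    rows <- list()
    for (sid in names(recordings)) {
      for (rec in recordings[[sid]]) {
        fn <- sprintf("%s_%s.csv", sid, rec$trial_id)
        write_recording(rec, file.path(dir, fn))
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, path = fn, trial_id = rec$trial_id,
          label = rec$label, stringsAsFactors = FALSE)
      }
    }
    manifest_path <- file.path(dir, "manifest.json")
    write_manifest(do.call(rbind, rows), manifest_path)
    jsonlite::write_json(
      list(loadings = gt$loadings, symmetric_corr = gt$symmetric_corr,
           ramp_s = gt$ramp_s,
           planted = lapply(gt$planted, as.integer)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    out$manifest <- manifest_path
  }
  out
}
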