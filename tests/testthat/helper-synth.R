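# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one-subject, high-SNR cohort: 2 trials per class, no perturbation
tiny_cohort <- function() {
  cached("tiny_cohort", {
    sim <- sim_config(n_subjects = 1, trials_per_class = c(2, 2, 2, 2),
                      loading_perturbation = 0, seed = 11)
    generate_cohort(sim)
  })
}

tiny_windows <- function(step = 300) {
  cached(paste0("tiny_windows_", step), {
    preprocess_recordings(tiny_cohort()$recordings, window_len = 300,
                          step = step)
  })
}

# small synthetic recording: known sinusoids, no randomness
tone_recording <- function(freqs = c(100), amps = c(1), T = 4500, C = 2,
                           rate = 1500) {
  tt <- (0:(T - 1)) / rate
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * tt),
                      numeric(T)))
  emg_recording(matrix(rep(x, each = C), C, T, byrow = FALSE),
                rate_hz = rate, subject_id = "S1", trial_id = "tone",
                label = "SIT",
                annotations = list(preparation = c(1L, T + 1L)))
}

rms <- function(x) sqrt(mean(x^2))

# compact network configuration used across network tests
test_cfg <- function(...) {
  mcsnet_compact_config(precision = "double", ...)
}
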