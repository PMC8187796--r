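# Independent oracles used across the suite. These deliberately use naive
# direct computation (periodograms, literal subsetting, hand loops) so they
# stay independent of the package's implementation paths.

# Periodogram band power of one channel within [low, high] Hz.
bandpower_oracle <- function(x, fs, low, high) {
  n <- length(x)
  sp <- abs(stats::fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sel <- half & freqs >= low & freqs <= high
  sum(sp[sel]) / n
}

# Mean band power of a multichannel recording inside vs outside a set of
# truth intervals (ms), per channel averaged.
bandpower_in_out <- function(samples, fs, truth_ms, low = 50, high = 350) {
  n <- nrow(samples)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(truth_ms))) {
    inside <- inside | (t_ms >= truth_ms$onset_ms[i] &
                          t_ms < truth_ms$offset_ms[i])
  }
  pin <- mean(apply(samples[inside, , drop = FALSE], 2, bandpower_oracle,
                    fs = fs, low = low, high = high))
  pout <- mean(apply(samples[!inside, , drop = FALSE], 2, bandpower_oracle,
                     fs = fs, low = low, high = high))
  c(inside = pin, outside = pout)
}

# Brute-force subject-wise LOO accuracy for one predictor subset: literal
# per-fold subsetting, conditional relative frequencies, 0.5 threshold with
# training-majority tie-break, unweighted mean over held-out participants.
loo_oracle <- function(cases, subset) {
  pids <- unique(cases$participant_id)
  accs <- numeric(0)
  for (pid in pids) {
    train <- cases[cases$participant_id != pid, , drop = FALSE]
    test <- cases[cases$participant_id == pid, , drop = FALSE]
    majority <- mean(train$PB) >= 0.5
    correct <- logical(0)
    for (i in seq_len(nrow(test))) {
      match_rows <- rep(TRUE, nrow(train))
      for (v in subset) {
        match_rows <- match_rows & (train[[v]] == test[[v]][i])
      }
      p <- if (any(match_rows)) mean(train$PB[match_rows]) else mean(train$PB)
      pred <- if (p > 0.5) TRUE else if (p < 0.5) FALSE else majority
      correct <- c(correct, pred == test$PB[i])
    }
    accs <- c(accs, mean(correct))
  }
  mean(accs)
}

# Random small case table for property tests (guaranteed >= 2 participants,
# no participant owning all cases, both PB classes not required).
random_toy_cases <- function(n_cases, n_participants = 3) {
  pid <- sort(rep_len(sprintf("P%d", seq_len(n_participants)), n_cases))
  data.frame(
    participant_id = pid,
    group = "ASD",
    session = 1L,
    situation = "walking",
    S = sample(c(TRUE, FALSE), n_cases, TRUE),
    H = sample(c(TRUE, FALSE), n_cases, TRUE),
    A = FALSE,
    P = sample(c(TRUE, FALSE), n_cases, TRUE),
    PB = sample(c(TRUE, FALSE), n_cases, TRUE)
  )
}

# One trained classifier + its source session, shared by the detector tests
# (training is the slowest step; compute once per test run).
trained_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_emg_config(duration_s = 120, noise_seed = 5,
                                  mixing_seed = 6)
      sim <- generate_emg(cfg)
      filt <- bandpass(sim$recording)
      um <- unmix(filt, seed = 3)
      feats <- rms_envelope(um$components, sim$recording$sample_rate)
      labels <- frame_labels(feats, sim$truth)
      model <- train_smile_classifier(feats, labels, seed = 9,
                                      unmixing = um$unmixing,
                                      center = um$center)
      cache <<- list(config = cfg, sim = sim, features = feats,
                     labels = labels, model = model)
    }
    cache
  }
})

frame_f1 <- function(predicted, truth) {
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  2 * tp / (2 * tp + fp + fn)
}
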