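make_rec <- function(x, fs = 1000) {
  emg_recording(matrix(rep(x, 4), ncol = 4), fs)
}

test_that("band-pass passes the EMG band and rejects artifact frequencies", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)[-1]
  # 5 Hz motion-artifact surrogate: attenuated by >= 40 dB
  slow <- make_rec(sin(2 * pi * 5 * t), fs)
  out <- bandpass(slow)
  atten_db <- 20 * log10(sqrt(mean(out$samples[, 1]^2)) / sqrt(0.5))
  expect_lt(atten_db, -40)
  # 200 Hz in-band tone: passed within 5% (measured away from the edges)
  tone <- make_rec(sin(2 * pi * 200 * t), fs)
  out2 <- bandpass(tone)
  mid <- 2000:8000
  expect_lt(abs(sqrt(mean(out2$samples[mid, 1]^2)) - sqrt(0.5)) / sqrt(0.5),
            0.05)
  expect_identical(out2$band, c(50, 350))
})

test_that("band-pass of all-zero input is all-zero and bad edges error", {
  z <- make_rec(rep(0, 1000))
  expect_true(all(bandpass(z)$samples == 0))
  expect_error(bandpass(z, 50, 600), "Nyquist")
  expect_error(bandpass(z, 0, 350), "0 < low")
})

test_that("the filter is zero-phase: a symmetric pulse stays symmetric", {
  n <- 4001
  # narrow centred Gaussian pulse with substantial in-band energy
  x <- exp(-((seq_len(n) - 2001)^2) / (2 * 3^2))
  out <- bandpass(make_rec(x))$samples[, 1]
  asym <- max(abs(out - rev(out)))
  expect_lt(asym, 1e-9 * max(abs(out)))
})

test_that("ICA recovers independent and mixed super-Gaussian sources", {
  set.seed(4)
  n <- 20000
  src <- matrix(stats::rexp(n * 4) * sample(c(-1, 1), n * 4, TRUE), n, 4)
  # identity mixing: components match inputs up to order and sign
  um_id <- unmix(emg_recording(src, 1000), seed = 2)
  cc <- abs(stats::cor(um_id$components, src))
  expect_true(all(apply(cc, 2, max) >= 0.99))
  # random full mixing: each truth source matched by some component
  A <- matrix(stats::runif(16, 0.2, 1), 4, 4)
  um <- unmix(emg_recording(src %*% t(A), 1000), seed = 2)
  cc2 <- abs(stats::cor(um$components, src))
  expect_true(all(apply(cc2, 2, max) >= 0.95))
  # stored unmixing reproduces the components exactly
  rec <- emg_recording(src %*% t(A), 1000)
  manual <- sweep(rec$samples, 2, um$center) %*% t(um$unmixing)
  expect_equal(unname(manual), unname(um$components), tolerance = 1e-12)
})

test_that("degenerate channels are reported by name", {
  x <- matrix(rnorm(4000), 1000, 4)
  x[, 3] <- 7
  expect_error(unmix(emg_recording(x, 1000)), "ch3")
})

test_that("RMS envelope matches closed forms and brute force", {
  fs <- 1000
  # constant signal: every frame equals |c|
  const <- rms_envelope(matrix(-3, 1000, 1), fs)
  expect_equal(unname(const$values[, 1]), rep(3, 10), tolerance = 1e-12)
  # unit sine with integer periods per frame: RMS = 1/sqrt(2)
  t <- (0:9999) / fs
  sine <- rms_envelope(matrix(sin(2 * pi * 50 * t), ncol = 1), fs)
  expect_true(all(abs(sine$values - 1 / sqrt(2)) < 1e-6))
  # silence then burst, boundary frame by direct summation
  x <- c(rep(0, 950), rnorm(1050))
  env <- rms_envelope(matrix(x, ncol = 1), fs)
  brute <- vapply(seq_len(20), function(i) {
    sqrt(mean(x[((i - 1) * 100 + 1):(i * 100)]^2))
  }, numeric(1))
  expect_equal(unname(env$values[, 1]), brute, tolerance = 1e-12)
  expect_true(all(env$values[1:9, 1] == 0))
  # trailing partial frame discarded
  expect_identical(nrow(rms_envelope(matrix(1, 1050, 1), fs)$values), 10L)
})

test_that("the envelope is scale-equivariant", {
  set.seed(9)
  x <- matrix(rnorm(5000), ncol = 2)
  base <- rms_envelope(x, 1000)$values
  for (k in c(-2, 0.5, 10)) {
    expect_equal(rms_envelope(k * x, 1000)$values, abs(k) * base,
                 tolerance = 1e-12)
  }
})

test_that("training errors on degenerate label sets and tiny data", {
  fx <- trained_fixture()
  all_pos <- rep(TRUE, length(fx$labels))
  expect_error(train_smile_classifier(fx$features, all_pos, seed = 1),
               "both smile and no-smile")
  tiny <- rms_envelope(matrix(rnorm(4000), ncol = 4), 1000) # 10 frames
  expect_error(
    train_smile_classifier(tiny, rep(c(TRUE, FALSE), 5), seed = 1,
                           hidden = 16),
    "hidden units")
  expect_error(train_smile_classifier(fx$features, fx$labels, seed = 1,
                                      threshold = 1), "threshold")
})

test_that("training is deterministic and separable features are learned", {
  fx <- trained_fixture()
  expect_gte(fx$model$training_accuracy, 0.99)
  again <- train_smile_classifier(fx$features, fx$labels, seed = 9,
                                  unmixing = fx$model$unmixing,
                                  center = fx$model$center)
  expect_identical(again$network$wts, fx$model$network$wts)
})

test_that("baseline frames are forced to negative examples", {
  fx <- trained_fixture()
  # pretend the first labelled smile is actually inside the neutral baseline
  lab <- fx$labels
  first_pos <- fx$features$frame_times[which(lab)[1]]
  model <- train_smile_classifier(
    fx$features, lab, baseline_interval = c(first_pos - 5000, first_pos + 5000),
    seed = 9, unmixing = fx$model$unmixing, center = fx$model$center)
  expect_s3_class(model, "smile_classifier")
})

test_that("classification is accurate on frames and empty input is empty", {
  fx <- trained_fixture()
  cl <- classify_frames(fx$model, fx$features)
  expect_true(all(cl$probability >= 0 & cl$probability <= 1))
  expect_gte(frame_f1(cl$smile, fx$labels), 0.95)
  empty <- rms_envelope(matrix(numeric(0), ncol = 4), 1000)
  expect_identical(nrow(classify_frames(fx$model, empty)), 0L)
})

test_that("held-out synthetic session is classified with frame F1 >= 0.90", {
  fx <- trained_fixture()
  cfg2 <- synthetic_emg_config(duration_s = 120, noise_seed = 11,
                               mixing_seed = 6) # same electrode mixing
  sim2 <- generate_emg(cfg2)
  det <- prosmile:::detect_frames(fx$model, sim2$recording)
  truth <- frame_labels(det$features, sim2$truth)
  expect_gte(frame_f1(det$classified$smile, truth), 0.90)
})

test_that("frame flags become smoothed interval tracks", {
  times <- (0:49) * 100
  flags <- rep(FALSE, 50)
  flags[11:15] <- TRUE  # 500 ms
  flags[17:20] <- TRUE  # 100 ms gap -> merged
  flags[40] <- TRUE     # 100 ms blip -> dropped
  tr <- frames_to_intervals(flags, times)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$onset_ms, 1000)
  expect_equal(tr$offset_ms, 2000) # frame 20 covers [1900, 2000)
  expect_identical(nrow(frames_to_intervals(rep(FALSE, 10), (0:9) * 100)), 0L)
})

test_that("unobserved-segment estimation clips, errors and recovers smiles", {
  fx <- trained_fixture()
  sim2 <- generate_emg(synthetic_emg_config(duration_s = 120, noise_seed = 11,
                                            mixing_seed = 6))
  # empty unobservable list -> empty track
  est0 <- estimate_unobserved(fx$model, sim2$recording, smile_track(),
                              data.frame(onset_ms = numeric(0),
                                         offset_ms = numeric(0)))
  expect_identical(nrow(est0), 0L)
  # interval outside the recording -> error
  expect_error(
    estimate_unobserved(fx$model, sim2$recording, smile_track(),
                        data.frame(onset_ms = 0, offset_ms = 200000)),
    "outside")
  # unobservable covering one truth smile: high-overlap recovery
  expect_gt(nrow(sim2$truth), 0)
  tr1 <- as.data.frame(sim2$truth)[1, ]
  unobs <- data.frame(onset_ms = max(0, tr1$onset_ms - 2000),
                      offset_ms = min(120000, tr1$offset_ms + 2000))
  est <- estimate_unobserved(fx$model, sim2$recording, smile_track(), unobs)
  expect_true(all(est$source == "emg"))
  # clipping contract: nothing outside the unobservable region
  expect_true(all(est$onset_ms >= unobs$onset_ms &
                    est$offset_ms <= unobs$offset_ms))
  truth_in <- data.frame(onset_ms = max(tr1$onset_ms, unobs$onset_ms),
                         offset_ms = min(tr1$offset_ms, unobs$offset_ms))
  expect_gte(prosmile:::interval_jaccard(as.data.frame(est), truth_in), 0.8)
})

test_that("end-to-end duration estimate is within 15% of truth at SNR 10", {
  cfg <- synthetic_emg_config(duration_s = 120, snr_db = 10, noise_seed = 5,
                              mixing_seed = 6)
  sim <- generate_emg(cfg)
  filt <- bandpass(sim$recording)
  um <- unmix(filt, seed = 3)
  feats <- rms_envelope(um$components, 1000)
  labels <- frame_labels(feats, sim$truth)
  model <- train_smile_classifier(feats, labels, seed = 9,
                                  unmixing = um$unmixing, center = um$center)
  sim2 <- generate_emg(synthetic_emg_config(duration_s = 120, snr_db = 10,
                                            noise_seed = 12, mixing_seed = 6))
  est <- estimate_unobserved(model, sim2$recording, smile_track(),
                             data.frame(onset_ms = 0, offset_ms = 120000))
  expect_lt(abs(smile_total_s(est) - smile_total_s(sim2$truth)),
            0.15 * smile_total_s(sim2$truth))
})

test_that("classifier JSON round trip preserves predictions", {
  fx <- trained_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(fx$model, path)
  back <- read_classifier(path)
  a <- classify_frames(fx$model, fx$features)
  b <- classify_frames(back, fx$features)
  expect_equal(b$probability, a$probability, tolerance = 1e-8)
  expect_identical(b$smile, a$smile)
  expect_equal(back$unmixing, fx$model$unmixing, tolerance = 1e-12,
               ignore_attr = TRUE)
})
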