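#' Configuration for synthetic facial-EMG generation
#'
#' Describes a simulated four-channel facial surface-EMG recording. The
#' simulator writes each channel as a fixed linear mixture of three latent
#' sources - two smile-muscle sources (orbicularis oculi / zygomaticus
#' major analogues) that are active only inside ground-truth smile
#' intervals, and one always-on tonic background source - plus per-channel
#' broadband sensor noise and occasional high-amplitude low-frequency
#' motion-artifact bursts. Smile-muscle activity is amplitude-modulated
#' band-limited noise confined to `source_band`, the band the downstream
#' detector assumes.
#'
#' @param duration_s recording length in seconds.
#' @param sample_rate sampling rate in Hz; must exceed 700 Hz (and twice
#'   the upper source-band edge).
#' @param n_channels number of electrode pairs; fixed at 4.
#' @param smile_rate expected smiles per minute.
#' @param smile_duration_range min/max smile length in seconds.
#' @param source_band frequency band (Hz) carrying smile-muscle energy.
#' @param artifact_rate motion artifacts per minute.
#' @param artifact_band frequency band (Hz) of motion artifacts; upper edge
#'   must stay below 20 Hz so the band-pass stage can remove them.
#' @param snr_db smile-source amplitude relative to the tonic+sensor
#'   background, in dB.
#' @param mixing_seed seed for the mixing matrix.
#' @param noise_seed seed for all stochastic signal content.
#' @return object of class `synthetic_emg_config`.
#' @export
synthetic_emg_config <- function(duration_s = 60,
                                 sample_rate = 1000,
                                 n_channels = 4,
                                 smile_rate = 4,
                                 smile_duration_range = c(1, 4),
                                 source_band = c(50, 350),
                                 artifact_rate = 3,
                                 artifact_band = c(2, 15),
                                 snr_db = 20,
                                 mixing_seed = 1L,
                                 noise_seed = 2L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (sample_rate <= 700) {
    stop("sample_rate must exceed 700 Hz to carry the 50-350 Hz smile band")
  }
  if (n_channels != 4L) stop("the wearable has 4 electrode pairs; n_channels must be 4")
  if (sample_rate <= 2 * source_band[2]) {
    stop("sample_rate must exceed twice the upper source band edge")
  }
  if (artifact_band[2] >= 20) {
    stop("artifact energy must stay below 20 Hz")
  }
  if (smile_rate < 0 || artifact_rate < 0) stop("rates must be non-negative")
  if (diff(smile_duration_range) < 0 || smile_duration_range[1] <= 0) {
    stop("smile_duration_range must be positive and increasing")
  }
  structure(list(duration_s = duration_s, sample_rate = sample_rate,
                 n_channels = 4L, smile_rate = smile_rate,
                 smile_duration_range = smile_duration_range,
                 source_band = source_band, artifact_rate = artifact_rate,
                 artifact_band = artifact_band, snr_db = snr_db,
                 mixing_seed = as.integer(mixing_seed),
                 noise_seed = as.integer(noise_seed)),
            class = "synthetic_emg_config")
}

# Band-limited Gaussian noise of length n, unit RMS.
bandlimited_noise <- function(n, band, fs) {
  x <- stats::rnorm(n + 2000) # pad to absorb filter transients
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)[1001:(1000 + n)]
  y / sqrt(mean(y^2))
}

# Raised-cosine on/off envelope of length n with ramp_n-sample ramps.
burst_envelope <- function(n, ramp_n) {
  ramp_n <- min(ramp_n, floor(n / 2))
  env <- rep(1, n)
  if (ramp_n > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- r
    env[n + 1 - seq_len(ramp_n)] <- rev(r)
  }
  env
}

# Draw non-overlapping event intervals (seconds) at `rate` per minute.
draw_intervals <- function(duration_s, rate, dur_range) {
  n_ev <- stats::rpois(1, rate * duration_s / 60)
  if (n_ev == 0) {
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  }
  on <- sort(stats::runif(n_ev, 0, duration_s))
  dur <- stats::runif(n_ev, dur_range[1], dur_range[2])
  off <- pmin(on + dur, duration_s)
  iv <- merge_intervals(data.frame(onset_ms = on * 1000, offset_ms = off * 1000))
  data.frame(onset_s = iv$onset_ms / 1000, offset_s = iv$offset_ms / 1000)
}

#' Generate a synthetic EMG recording with ground-truth smile intervals
#'
#' Simulates the recording described by the config and returns both the
#' mixed four-channel trace and the exact smile intervals that drove the
#' smile-muscle sources, for use as ground truth in detector evaluation.
#' The generator is a pure function of the config (including its two
#' seeds): identical configs give bit-identical output.
#'
#' @param config a [synthetic_emg_config()].
#' @param participant_id label stored on the recording.
#' @param truth optional [smile_track()] (ms) of smile intervals to impose
#'   instead of drawing them from `smile_rate`; used when the recording
#'   must match an existing annotated session.
#' @return list with `recording` (an [emg_recording()]) and `truth`
#'   (a [smile_track()] of simulated smile intervals, ms).
#' @export
generate_emg <- function(config, participant_id = "SIM-P1", truth = NULL) {
  if (!inherits(config, "synthetic_emg_config")) {
    stop("config must be a synthetic_emg_config")
  }
  fs <- config$sample_rate
  n <- round(config$duration_s * fs)

  mixing <- with_seed(config$mixing_seed, {
    repeat {
      a <- matrix(stats::runif(12, 0.2, 1), 4, 3)
      # left/right emphasis: each smile source dominates one electrode pair
      a[1:2, 1] <- a[1:2, 1] + 1
      a[3:4, 2] <- a[3:4, 2] + 1
      if (kappa(a, exact = TRUE) < 20) break
    }
    a
  })

  with_seed(config$noise_seed, {
    if (is.null(truth)) {
      smiles <- draw_intervals(config$duration_s, config$smile_rate,
                               config$smile_duration_range)
    } else {
      tiv <- as.data.frame(truth)
      if (nrow(tiv) && (min(tiv$onset_ms) < 0 ||
                        max(tiv$offset_ms) > config$duration_s * 1000)) {
        stop("imposed truth intervals must lie within [0, duration_s]")
      }
      smiles <- data.frame(onset_s = tiv$onset_ms / 1000,
                           offset_s = tiv$offset_ms / 1000)
    }
    # latent sources
    tonic <- bandlimited_noise(n, c(20, fs / 2 * 0.9), fs) # always-on background
    s_amp <- 10^(config$snr_db / 20)
    src <- matrix(0, n, 3)
    src[, 3] <- tonic
    for (k in 1:2) {
      burst <- numeric(n)
      if (nrow(smiles)) {
        for (i in seq_len(nrow(smiles))) {
          i0 <- max(1L, round(smiles$onset_s[i] * fs) + 1L)
          i1 <- min(n, round(smiles$offset_s[i] * fs))
          if (i1 <= i0) next
          len <- i1 - i0 + 1L
          b <- bandlimited_noise(len, config$source_band, fs) *
            burst_envelope(len, round(0.1 * fs)) *
            stats::runif(1, 0.8, 1.2)
          burst[i0:i1] <- b
        }
      }
      src[, k] <- s_amp * burst
    }
    x <- src %*% t(mixing)
    # per-channel sensor noise
    x <- x + matrix(stats::rnorm(n * 4, sd = 0.5), n, 4)
    # low-frequency motion artifact bursts, high amplitude, random channel mix
    arts <- draw_intervals(config$duration_s, config$artifact_rate,
                           c(0.3, 1.2))
    if (nrow(arts)) {
      for (i in seq_len(nrow(arts))) {
        i0 <- max(1L, round(arts$onset_s[i] * fs) + 1L)
        i1 <- min(n, round(arts$offset_s[i] * fs))
        if (i1 <= i0) next
        len <- i1 - i0 + 1L
        a <- bandlimited_noise(len, config$artifact_band, fs) *
          burst_envelope(len, round(0.05 * fs)) * 5 * s_amp
        w <- stats::runif(4, 0.3, 1)
        x[i0:i1, ] <- x[i0:i1, ] + outer(a, w)
      }
    }
    truth <- if (nrow(smiles)) {
      smile_track(round(smiles$onset_s * 1000), round(smiles$offset_s * 1000),
                  source = "video")
    } else {
      smile_track()
    }
    list(recording = emg_recording(x, fs, time_tag_sample = 0,
                                   participant_id = participant_id),
         truth = truth)
  })
}
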