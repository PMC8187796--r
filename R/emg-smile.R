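#' Zero-phase band-pass filter an EMG recording
#'
#' Applies a 4th-order Butterworth band-pass (default 50-350 Hz, the
#' surface-EMG band carrying smile-muscle energy) forward and backward
#' (zero phase), removing low-frequency motion artifacts and
#' out-of-band noise without shifting burst onsets.
#'
#' @param recording an [emg_recording()].
#' @param low,high band edges in Hz; must satisfy
#'   `0 < low < high < sample_rate / 2`.
#' @param order Butterworth order of the underlying one-pass filter.
#' @return a filtered copy of the recording; the band and order are
#'   recorded on the object.
#' @export
bandpass <- function(recording, low = 50, high = 350, order = 4) {
  fs <- recording$sample_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < sample_rate/2 (Nyquist ",
         fs / 2, " Hz)")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- recording
  out$samples <- apply(recording$samples, 2, function(ch) {
    signal::filtfilt(bf, ch)
  })
  colnames(out$samples) <- paste0("ch", 1:4)
  out$band <- c(low, high)
  out$filter_order <- order
  out
}

# Fixed-point (deflation) ICA on pre-whitened data.
# z: whitened n x p matrix (unit covariance). Returns orthogonal p x p W
# with components z %*% t(W) maximally non-Gaussian (tanh contrast).
fastica_deflation <- function(z, seed, tol = 1e-8, maxit = 500) {
  p <- ncol(z)
  w_all <- matrix(0, p, p)
  with_seed(seed, {
    for (i in seq_len(p)) {
      w <- stats::rnorm(p)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(maxit)) {
        wx <- drop(z %*% w)
        g <- tanh(wx)
        gp <- 1 - g^2
        w_new <- colMeans(z * g) - mean(gp) * w
        # deflation: orthogonalize against already-extracted components
        if (i > 1) {
          prev <- w_all[seq_len(i - 1), , drop = FALSE]
          w_new <- w_new - drop(t(prev) %*% (prev %*% w_new))
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        conv <- abs(abs(sum(w_new * w)) - 1)
        w <- w_new
        if (conv < tol) break
      }
      w_all[i, ] <- w
    }
  })
  w_all
}

#' Unmix a filtered EMG recording into independent components
#'
#' Each surface electrode records a superposition of several facial-muscle
#' activities; blind source separation increases the saliency of the
#' individual muscles. The data are centred and whitened, then a
#' deflation-based fixed-point ICA (tanh contrast) with seeded
#' initialization extracts four components. Components are ordered by
#' descending explained variance in the original channels, with signs fixed
#' so each component's skewness is non-negative; the full 4x4 unmixing
#' matrix (whitening included) is returned so exactly the same projection
#' can be reused at classification time.
#'
#' @param recording a (band-passed) [emg_recording()].
#' @param seed seed for the ICA initialization.
#' @return list with `components` (n x 4 matrix), `unmixing` (4 x 4 matrix
#'   `W` such that `components = centred_samples %*% t(W)`), and `center`
#'   (channel means removed before projection).
#' @export
unmix <- function(recording, seed = 1L) {
  x <- recording$samples
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  cv <- stats::cov(xc)
  ev <- eigen(cv, symmetric = TRUE)
  vars <- diag(cv)
  degenerate <- which(vars < 1e-12 * max(vars, 1e-300))
  if (length(degenerate)) {
    stop("rank-deficient covariance: channel(s) ",
         paste(paste0("ch", degenerate), collapse = ", "),
         " carry (near-)constant signal")
  }
  if (min(ev$values) < 1e-10 * max(ev$values)) {
    stop("rank-deficient covariance: channels are collinear")
  }
  wh <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors) # whitening matrix
  z <- xc %*% t(wh)
  w_ica <- fastica_deflation(z, seed)
  unmixing <- w_ica %*% wh
  comps <- xc %*% t(unmixing)
  # order by explained variance in channel space: mixing column norms
  mixing <- solve(unmixing) # components have unit variance after whitening
  expl <- colSums(mixing^2)
  ord <- order(expl, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  comps <- comps[, ord, drop = FALSE]
  # fix signs: non-negative skewness
  sk <- colMeans(comps^3)
  flip <- ifelse(sk < 0, -1, 1)
  comps <- sweep(comps, 2, flip, `*`)
  unmixing <- unmixing * flip
  colnames(comps) <- paste0("ic", 1:4)
  list(components = comps, unmixing = unmixing, center = ctr)
}

#' RMS envelope of component signals over fixed frames
#'
#' Root-mean-square amplitude over non-overlapping frames (default 100 ms),
#' the feature representation fed to the smile classifier. A trailing
#' partial frame is discarded.
#'
#' @param components numeric matrix (samples x components) or vector.
#' @param sample_rate sampling rate in Hz.
#' @param frame_ms frame length in milliseconds.
#' @param t0_ms session time of the first sample (ms), used to stamp frame
#'   times.
#' @return object of class `frame_features`: list with `values`
#'   (n_frames x n_components RMS matrix), `frame_ms`, and `frame_times`
#'   (frame start times, ms).
#' @export
rms_envelope <- function(components, sample_rate, frame_ms = 100,
                         t0_ms = 0) {
  if (frame_ms <= 0) stop("frame_ms must be positive")
  x <- as.matrix(components)
  fl <- round(frame_ms * sample_rate / 1000)
  if (fl < 1) stop("frame shorter than one sample")
  nf <- floor(nrow(x) / fl)
  vals <- matrix(0, nf, ncol(x))
  if (nf > 0) {
    for (j in seq_len(ncol(x))) {
      m <- matrix(x[seq_len(nf * fl), j]^2, nrow = fl)
      vals[, j] <- sqrt(colMeans(m))
    }
  }
  colnames(vals) <- colnames(x)
  structure(list(values = vals, frame_ms = frame_ms,
                 frame_times = t0_ms + (seq_len(nf) - 1) * frame_ms),
            class = "frame_features")
}

#' Per-frame smile labels from an interval track
#'
#' A frame is labelled positive when at least half of it is covered by a
#' smile interval.
#'
#' @param features a [rms_envelope()] result.
#' @param track a [smile_track()] (ms, same clock as `frame_times`).
#' @return logical vector, one element per frame.
#' @export
frame_labels <- function(features, track) {
  iv <- as.data.frame(track)
  fm <- features$frame_ms
  vapply(features$frame_times, function(t0) {
    if (nrow(iv) == 0L) return(FALSE)
    ov <- sum(pmax(0, pmin(iv$offset_ms, t0 + fm) - pmax(iv$onset_ms, t0)))
    ov >= fm / 2
  }, logical(1))
}

#' Train a per-participant smile classifier on RMS features
#'
#' Fits a one-hidden-layer feed-forward network (logistic output) mapping
#' the four RMS component features of each 100-ms frame to the coder's
#' smile label. Frames inside the neutral-baseline interval are forced to
#' negative examples; frames whose broadband power (sum of squared RMS
#' values) exceeds the `noise_quantile` quantile are dropped as
#' noisy/artifactual. Training is deterministic given `seed`: the weight
#' initialization, the 20% validation split and the stopping-point
#' selection (the `maxit` candidate with the lowest validation log-loss)
#' all derive from it.
#'
#' @param features a [rms_envelope()] result for the video-observable part
#'   of the session.
#' @param labels logical per-frame smile labels (coder analysis); `NA`
#'   frames (unobservable) are excluded.
#' @param baseline_interval optional `c(start_ms, end_ms)` of the neutral
#'   baseline recording; frames inside it become negative examples.
#' @param seed integer controlling initialization and the validation split.
#' @param hidden hidden-layer width.
#' @param threshold probability cut for binarization, in (0, 1).
#' @param noise_quantile broadband-power quantile above which frames are
#'   excluded from training.
#' @param unmixing,center,band the projection used to produce `features`,
#'   stored for reuse at classification time.
#' @return object of class `smile_classifier`.
#' @export
train_smile_classifier <- function(features, labels,
                                   baseline_interval = NULL,
                                   seed = 1L, hidden = 16,
                                   threshold = 0.5,
                                   noise_quantile = 0.99,
                                   unmixing = NULL, center = NULL,
                                   band = c(50, 350)) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  x <- features$values
  y <- as.logical(labels)
  if (length(y) != nrow(x)) stop("one label per frame required")
  if (!is.null(baseline_interval)) {
    inb <- features$frame_times >= baseline_interval[1] &
      features$frame_times + features$frame_ms <= baseline_interval[2]
    y[inb] <- FALSE
  }
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  power <- rowSums(x^2)
  keep2 <- power <= stats::quantile(power, noise_quantile)
  x <- x[keep2, , drop = FALSE]
  y <- y[keep2]
  if (length(unique(y)) < 2L) {
    stop("training labels must contain both smile and no-smile frames")
  }
  if (nrow(x) < hidden) {
    stop("fewer training frames (", nrow(x), ") than hidden units (", hidden, ")")
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdv, `/`)

  nwts <- (ncol(xs) + 1) * hidden + (hidden + 1)
  fit <- with_seed(seed, {
    wts0 <- stats::runif(nwts, -0.5, 0.5)
    val <- sample.int(nrow(xs)) <= ceiling(0.2 * nrow(xs))
    candidates <- c(60, 150, 300)
    best <- NULL; best_loss <- Inf; best_maxit <- candidates[1]
    if (sum(val) > 0 && sum(!val) >= hidden) {
      for (m in candidates) {
        net <- nnet::nnet(xs[!val, , drop = FALSE], as.numeric(y[!val]),
                          size = hidden, decay = 1e-3, maxit = m,
                          Wts = wts0, trace = FALSE, entropy = TRUE)
        p <- pmin(pmax(stats::predict(net, xs[val, , drop = FALSE]), 1e-12),
                  1 - 1e-12)
        loss <- -mean(ifelse(y[val], log(p), log(1 - p)))
        if (loss < best_loss) { best_loss <- loss; best_maxit <- m }
      }
    }
    nnet::nnet(xs, as.numeric(y), size = hidden, decay = 1e-3,
               maxit = best_maxit, Wts = wts0, trace = FALSE, entropy = TRUE)
  })
  pr <- drop(stats::predict(fit, xs))
  acc <- mean((pr > threshold) == y)
  structure(list(
    network = fit, hidden = hidden, threshold = threshold,
    feature_center = mu, feature_scale = sdv,
    unmixing = unmixing, center = center, band = band,
    frame_ms = features$frame_ms,
    training_seed = as.integer(seed), training_accuracy = acc,
    n_training_frames = nrow(xs)
  ), class = "smile_classifier")
}

#' @export
print.smile_classifier <- function(x, ...) {
  cat(sprintf(
    "<smile_classifier> %d hidden units, threshold %.2f, trained on %d frames (accuracy %.3f)\n",
    x$hidden, x$threshold, x$n_training_frames, x$training_accuracy))
  invisible(x)
}

#' Classify frames as smile / no smile
#'
#' Applies the trained network to RMS features and binarizes at the model's
#' probability threshold. Interval-level smoothing (flicker suppression) is
#' applied by [frames_to_intervals()].
#'
#' @param model a [train_smile_classifier()] result.
#' @param features a [rms_envelope()] result with matching dimensionality.
#' @return data frame with `frame_time_ms`, `probability`, `smile`.
#' @export
classify_frames <- function(model, features) {
  x <- features$values
  if (nrow(x) == 0L) {
    return(data.frame(frame_time_ms = numeric(0), probability = numeric(0),
                      smile = logical(0)))
  }
  if (ncol(x) != length(model$feature_center)) {
    stop("feature dimensionality does not match the model")
  }
  xs <- sweep(sweep(x, 2, model$feature_center), 2, model$feature_scale, `/`)
  p <- pmin(pmax(drop(stats::predict(model$network, xs)), 0), 1)
  data.frame(frame_time_ms = features$frame_times, probability = p,
             smile = p > model$threshold)
}

#' Convert binary frame flags to smoothed smile intervals
#'
#' Consecutive positive frames become intervals; detections separated by
#' less than `merge_gap_ms` are merged and intervals shorter than
#' `min_duration_ms` are dropped, suppressing frame flicker.
#'
#' @param flags logical per-frame flags.
#' @param frame_times frame start times (ms).
#' @param frame_ms frame length (ms).
#' @param merge_gap_ms gaps shorter than this are bridged.
#' @param min_duration_ms intervals shorter than this are discarded.
#' @param source provenance tag for the returned track.
#' @return a [smile_track()].
#' @export
frames_to_intervals <- function(flags, frame_times, frame_ms = 100,
                                merge_gap_ms = 200, min_duration_ms = 300,
                                source = "emg") {
  if (!any(flags)) return(smile_track(source = source))
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  pos <- which(r$values)
  iv <- data.frame(onset_ms = frame_times[starts[pos]],
                   offset_ms = frame_times[ends[pos]] + frame_ms)
  # bridge short gaps
  if (nrow(iv) > 1L) {
    gap <- iv$onset_ms[-1] - iv$offset_ms[-nrow(iv)]
    iv2 <- iv
    iv2$onset_ms[-1][gap < merge_gap_ms] <- NA
    merged <- list()
    cur_on <- iv2$onset_ms[1]; cur_off <- iv2$offset_ms[1]
    for (i in seq_len(nrow(iv2))[-1]) {
      if (is.na(iv2$onset_ms[i])) {
        cur_off <- iv2$offset_ms[i]
      } else {
        merged[[length(merged) + 1L]] <- c(cur_on, cur_off)
        cur_on <- iv2$onset_ms[i]; cur_off <- iv2$offset_ms[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(cur_on, cur_off)
    iv <- as.data.frame(do.call(rbind, merged))
    names(iv) <- c("onset_ms", "offset_ms")
  }
  iv <- iv[iv$offset_ms - iv$onset_ms >= min_duration_ms, , drop = FALSE]
  if (nrow(iv) == 0L) return(smile_track(source = source))
  smile_track(iv$onset_ms, iv$offset_ms, source = source)
}

# Full detection chain on a raw recording using a trained model's stored
# preprocessing: band-pass -> stored unmixing -> RMS -> network.
detect_frames <- function(model, recording, t0_ms = 0) {
  filt <- bandpass(recording, model$band[1], model$band[2])
  if (is.null(model$unmixing)) {
    stop("model stores no unmixing matrix; train with unmixing = ...")
  }
  xc <- sweep(filt$samples, 2, model$center)
  comps <- xc %*% t(model$unmixing)
  feats <- rms_envelope(comps, recording$sample_rate,
                        frame_ms = model$frame_ms, t0_ms = t0_ms)
  list(features = feats, classified = classify_frames(model, feats))
}

#' Estimate smiles in video-unobservable segments from EMG
#'
#' Runs the stored detection chain (band-pass, the training-time unmixing,
#' RMS envelope, network, smoothing) over the recording and returns the
#' detected smile intervals clipped to the camera-unobservable intervals
#' only; the video-observable part of the session keeps its coder
#' annotation.
#'
#' @param model a [train_smile_classifier()] result (with stored unmixing).
#' @param recording the raw [emg_recording()].
#' @param video_smiles [smile_track()] of coder-annotated smiles; must be
#'   disjoint from `unobservable`.
#' @param unobservable data frame of `onset_ms`/`offset_ms` intervals not
#'   visible on video.
#' @param t0_ms session time of the first EMG sample (from
#'   [synchronize()]).
#' @param merge_gap_ms,min_duration_ms smoothing parameters, see
#'   [frames_to_intervals()].
#' @return a [smile_track()] with `source = "emg"`, contained in
#'   `unobservable`.
#' @export
estimate_unobserved <- function(model, recording, video_smiles, unobservable,
                                t0_ms = 0, merge_gap_ms = 200,
                                min_duration_ms = 300) {
  unobservable <- merge_intervals(as.data.frame(unobservable))
  if (nrow(unobservable) == 0L) return(smile_track(source = "emg"))
  dur_ms <- nrow(recording$samples) / recording$sample_rate * 1000
  if (any(unobservable$onset_ms < t0_ms - 1e-9) ||
      any(unobservable$offset_ms > t0_ms + dur_ms + 1e-9)) {
    stop("unobservable interval outside the recorded session")
  }
  if (nrow(as.data.frame(video_smiles))) {
    ov <- intervals_total_ms(
      intersect_intervals(as.data.frame(video_smiles), unobservable))
    if (ov > 1e-9) {
      stop("video smile intervals must be disjoint from unobservable intervals")
    }
  }
  det <- detect_frames(model, recording, t0_ms = t0_ms)
  track <- frames_to_intervals(det$classified$smile,
                               det$classified$frame_time_ms,
                               frame_ms = model$frame_ms,
                               merge_gap_ms = merge_gap_ms,
                               min_duration_ms = min_duration_ms)
  clipped <- intersect_intervals(as.data.frame(track), unobservable)
  if (nrow(clipped) == 0L) return(smile_track(source = "emg"))
  smile_track(clipped$onset_ms, clipped$offset_ms, source = "emg")
}

#' Serialize a smile classifier to JSON and back
#'
#' Stores the network weights, architecture, feature scaling, unmixing
#' matrix, band and threshold so a trained model can be reloaded without
#' refitting.
#'
#' @param model a [train_smile_classifier()] result.
#' @param path JSON file path.
#' @export
write_classifier <- function(model, path) {
  obj <- list(
    weights = as.numeric(model$network$wts),
    n_inputs = length(model$feature_center),
    hidden = model$hidden, threshold = model$threshold,
    feature_center = model$feature_center, feature_scale = model$feature_scale,
    unmixing = if (is.null(model$unmixing)) NULL else as.numeric(model$unmixing),
    center = model$center, band = model$band, frame_ms = model$frame_ms,
    training_seed = model$training_seed,
    training_accuracy = model$training_accuracy,
    n_training_frames = model$n_training_frames
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- obj$n_inputs
  # rebuild an nnet object carrying the stored weights (0 iterations)
  dummy_x <- matrix(0, max(obj$hidden, k) + 2, k)
  dummy_y <- rep(c(0, 1), length.out = nrow(dummy_x))
  net <- nnet::nnet(dummy_x, dummy_y, size = obj$hidden, maxit = 0,
                    Wts = obj$weights, trace = FALSE, entropy = TRUE)
  net$wts <- obj$weights
  structure(list(
    network = net, hidden = obj$hidden, threshold = obj$threshold,
    feature_center = obj$feature_center, feature_scale = obj$feature_scale,
    unmixing = if (is.null(obj$unmixing)) NULL else matrix(obj$unmixing, 4, 4),
    center = obj$center, band = obj$band, frame_ms = obj$frame_ms,
    training_seed = obj$training_seed,
    training_accuracy = obj$training_accuracy,
    n_training_frames = obj$n_training_frames
  ), class = "smile_classifier")
}
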