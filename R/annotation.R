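#' Controlled vocabulary for behavior annotation labels
#'
#' Interval labels: child behaviors (`smile`, `head_toward_robot`,
#' `approach_robot`, `prosocial_walk`, `prosocial_fall`, `other`), camera
#' visibility (`unobservable_face`) and robot/session anchors
#' (`robot_movement`, `robot_fall_start`, `robot_adjusted`, `session_start`,
#' `prompt`). Anchors and prompts are normally instantaneous events, encoded
#' as zero-length rows in the TSV dialect.
#'
#' @export
timeline_labels <- c(
  "smile", "prosocial_walk", "prosocial_fall", "unobservable_face",
  "robot_movement", "robot_fall_start", "robot_adjusted", "session_start",
  "prompt", "head_toward_robot", "approach_robot", "other"
)

#' Behavioral annotation timeline
#'
#' Holds one coder's labeled intervals and instantaneous events for one
#' therapy session, on a 0-based millisecond clock starting at the session
#' video's first frame. Intervals are half-open `[onset_ms, offset_ms)`;
#' events have `offset_ms == onset_ms`.
#'
#' @param intervals data frame with columns `onset_ms`, `offset_ms`, `label`.
#'   Zero-length rows are treated as events.
#' @param session_id,participant_id opaque identifiers.
#' @param group participant group, `"ASD"` or `"TD"`.
#' @param coder_id annotating coder identifier.
#' @return object of class `annotation_timeline`.
#' @export
annotation_timeline <- function(intervals,
                                session_id = "S1",
                                participant_id = "P1",
                                group = c("ASD", "TD"),
                                coder_id = "coder1") {
  group <- match.arg(group)
  intervals <- as.data.frame(intervals)
  needed <- c("onset_ms", "offset_ms", "label")
  if (!all(needed %in% names(intervals))) {
    stop("timeline intervals need columns onset_ms, offset_ms, label")
  }
  intervals <- intervals[, needed]
  intervals$label <- as.character(intervals$label)
  bad <- which(!(intervals$label %in% timeline_labels))
  if (length(bad)) {
    stop("unknown annotation label(s) in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(intervals$label[bad]), collapse = ", "))
  }
  bad <- which(intervals$onset_ms < 0 | intervals$offset_ms < intervals$onset_ms)
  if (length(bad)) {
    stop("negative times or offset < onset in row(s) ",
         paste(bad, collapse = ", "))
  }
  # same-label true intervals must not overlap (events may coincide)
  spans <- intervals[intervals$offset_ms > intervals$onset_ms, , drop = FALSE]
  for (lab in unique(spans$label)) {
    iv <- spans[spans$label == lab, , drop = FALSE]
    iv <- iv[order(iv$onset_ms), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv$onset_ms[-1] < iv$offset_ms[-nrow(iv)])) {
      stop("overlapping intervals for label '", lab, "'")
    }
  }
  intervals <- intervals[order(intervals$onset_ms, intervals$offset_ms,
                               intervals$label), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(
    list(session_id = session_id, participant_id = participant_id,
         group = group, coder_id = coder_id, intervals = intervals),
    class = "annotation_timeline"
  )
}

#' @export
print.annotation_timeline <- function(x, ...) {
  ev <- sum(x$intervals$offset_ms == x$intervals$onset_ms)
  cat(sprintf(
    "<annotation_timeline> session %s, participant %s (%s), coder %s: %d intervals, %d events\n",
    x$session_id, x$participant_id, x$group, x$coder_id,
    nrow(x$intervals) - ev, ev))
  invisible(x)
}

#' Intervals of a timeline matching a label
#' @param timeline an [annotation_timeline()].
#' @param label label to extract.
#' @param events_only,spans_only restrict to zero-length / positive-length rows.
#' @return data frame with `onset_ms`, `offset_ms`.
#' @export
timeline_label <- function(timeline, label, events_only = FALSE,
                           spans_only = FALSE) {
  iv <- timeline$intervals
  iv <- iv[iv$label == label, , drop = FALSE]
  if (events_only) iv <- iv[iv$offset_ms == iv$onset_ms, , drop = FALSE]
  if (spans_only) iv <- iv[iv$offset_ms > iv$onset_ms, , drop = FALSE]
  rownames(iv) <- NULL
  iv[, c("onset_ms", "offset_ms")]
}

#' Read and write annotation timelines
#'
#' The on-disk dialect is a UTF-8 TSV with header
#' `onset_ms<TAB>offset_ms<TAB>label<TAB>coder`, one file per session per
#' coder; instantaneous events are rows with `offset_ms == onset_ms`.
#' Round-tripping a timeline through `write_timeline()` / `read_timeline()`
#' is lossless for the interval content.
#'
#' @param timeline an [annotation_timeline()].
#' @param path file path.
#' @param session_id,participant_id,group session metadata for the timeline
#'   built on read (the TSV itself carries only rows).
#' @return `read_timeline()` returns an [annotation_timeline()];
#'   `write_timeline()` returns `path`, invisibly.
#' @export
write_timeline <- function(timeline, path) {
  df <- timeline$intervals
  df$coder <- timeline$coder_id
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_timeline
#' @export
read_timeline <- function(path, session_id = "S1", participant_id = "P1",
                          group = c("ASD", "TD")) {
  group <- match.arg(group)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "numeric", "character",
                                         "character"),
                          fileEncoding = "UTF-8")
  if (!identical(names(df), c("onset_ms", "offset_ms", "label", "coder"))) {
    stop("timeline TSV must have header onset_ms, offset_ms, label, coder")
  }
  coder <- unique(df$coder)
  if (length(coder) > 1L) {
    stop("one timeline file holds one coder; found: ",
         paste(coder, collapse = ", "))
  }
  if (length(coder) == 0L) coder <- "coder1"
  annotation_timeline(df[, c("onset_ms", "offset_ms", "label")],
                      session_id = session_id,
                      participant_id = participant_id,
                      group = group, coder_id = coder)
}

#' Align an EMG recording with a session annotation timeline
#'
#' The session start is marked both on the video timeline (a `session_start`
#' event, logged when the therapist opens the intervention-room door) and in
#' the EMG stream (a time-tagged sample from the logger). The returned offset
#' maps EMG sample times onto timeline milliseconds:
#' `timeline_ms = sample_index / sample_rate * 1000 + offset_ms`, so the
#' tagged sample lands exactly on the `session_start` event.
#'
#' @param recording an [emg_recording()] with a `time_tag_sample`.
#' @param timeline an [annotation_timeline()] with exactly one
#'   `session_start` event.
#' @return offset in milliseconds (may be negative).
#' @export
synchronize <- function(recording, timeline) {
  tag <- recording$time_tag_sample
  if (is.null(tag) || is.na(tag)) stop("recording has no time_tag_sample")
  ev <- timeline_label(timeline, "session_start", events_only = TRUE)
  if (nrow(ev) == 0L) stop("timeline has no session_start event")
  if (nrow(ev) > 1L) stop("timeline has ", nrow(ev), " session_start events; expected exactly one")
  ev$onset_ms[1] - tag / recording$sample_rate * 1000
}

#' Fuse video-coded and EMG-estimated smile intervals
#'
#' Video annotation provides smiles wherever the face was visible; the EMG
#' classifier fills the camera-unobservable fragments. Preconditions mirror
#' that split: every EMG interval must lie inside the unobservable set and
#' video smiles must be disjoint from it, which makes the fusion exactly
#' conservative: fused total duration = video total + EMG total.
#'
#' @param video [smile_track()] of coder-annotated smiles.
#' @param emg [smile_track()] of EMG-estimated smiles.
#' @param unobservable data frame of `onset_ms`/`offset_ms` intervals where
#'   the face was not visible on video.
#' @return a [smile_track()]; adjacent video/EMG intervals are merged, and a
#'   merged interval keeps the source of its earliest piece with the total
#'   duration unchanged.
#' @export
fuse_smiles <- function(video, emg, unobservable) {
  unobservable <- merge_intervals(as.data.frame(unobservable))
  v <- as.data.frame(video)
  e <- as.data.frame(emg)
  if (nrow(e)) {
    inside <- intervals_total_ms(intersect_intervals(e, unobservable))
    if (abs(inside - intervals_total_ms(e)) > 1e-9) {
      stop("EMG smile intervals must lie within the unobservable intervals")
    }
  }
  if (nrow(v)) {
    ov <- intervals_total_ms(intersect_intervals(v, unobservable))
    if (ov > 1e-9) {
      stop("video smile intervals must be disjoint from the unobservable intervals")
    }
  }
  both <- rbind(v, e)
  both <- both[order(both$onset_ms), , drop = FALSE]
  if (nrow(both) == 0L) return(smile_track())
  # merge overlap/adjacency but keep provenance of the first piece
  out_on <- both$onset_ms[1]; out_off <- both$offset_ms[1]
  out_src <- both$source[1]
  res <- list()
  for (i in seq_len(nrow(both))[-1]) {
    if (both$onset_ms[i] <= out_off) {
      out_off <- max(out_off, both$offset_ms[i])
    } else {
      res[[length(res) + 1L]] <- data.frame(onset_ms = out_on,
                                            offset_ms = out_off,
                                            source = out_src)
      out_on <- both$onset_ms[i]; out_off <- both$offset_ms[i]
      out_src <- both$source[i]
    }
  }
  res[[length(res) + 1L]] <- data.frame(onset_ms = out_on, offset_ms = out_off,
                                        source = out_src)
  res <- do.call(rbind, res)
  smile_track(res$onset_ms, res$offset_ms, res$source)
}

#' Extract the six timed analysis windows of a session
#'
#' Six segments frame the child-robot interaction: (a) the first minute
#' after entering the intervention room, (b) the minute before and (c) the
#' minute after the onset of prosocial behavior in the walking situation,
#' (d) the minute before the prosocial-behavior onset in the falling
#' situation, (e) the first smile overlapping the robot's fall (possibly of
#' zero length), and (f) the minute after the fallen robot is adjusted. Only
#' the first walking and first falling episode of a session is used. Windows
#' whose anchor events are absent are reported as missing rather than being
#' an error; windows are clipped to the session bounds and clipping is
#' flagged.
#'
#' @param timeline an [annotation_timeline()]; must contain a
#'   `session_start` event.
#' @param smiles optional [smile_track()] used for window (e); defaults to
#'   the timeline's own `smile` intervals.
#' @param session_end_ms session length used for clipping; defaults to the
#'   largest annotated time.
#' @param d_anchor anchor for window (d): `"pb_onset"` (minute before the
#'   falling-situation prosocial behavior, the default) or `"robot_fall"`
#'   (minute before the robot starts falling).
#' @return data frame with one row per window kind a-f: `kind`, `start_ms`,
#'   `end_ms`, `present`, `clipped`, `anchor`.
#' @export
extract_segments <- function(timeline, smiles = NULL, session_end_ms = NULL,
                             d_anchor = c("pb_onset", "robot_fall")) {
  d_anchor <- match.arg(d_anchor)
  start_ev <- timeline_label(timeline, "session_start", events_only = TRUE)
  if (nrow(start_ev) == 0L) stop("timeline has no session_start event")
  t0 <- start_ev$onset_ms[1]
  if (is.null(session_end_ms)) {
    session_end_ms <- max(timeline$intervals$offset_ms, t0 + 60000)
  }
  if (is.null(smiles)) {
    sm <- timeline_label(timeline, "smile", spans_only = TRUE)
  } else {
    sm <- as.data.frame(smiles)
  }
  walk <- timeline_label(timeline, "prosocial_walk", spans_only = TRUE)
  fall_pb <- timeline_label(timeline, "prosocial_fall", spans_only = TRUE)
  fall_start <- timeline_label(timeline, "robot_fall_start")
  adjusted <- timeline_label(timeline, "robot_adjusted")

  win <- function(kind, start, end, anchor) {
    if (is.null(start)) {
      return(data.frame(kind = kind, start_ms = NA_real_, end_ms = NA_real_,
                        present = FALSE, clipped = FALSE, anchor = anchor))
    }
    cs <- max(start, t0); ce <- min(end, session_end_ms)
    data.frame(kind = kind, start_ms = cs, end_ms = max(cs, ce),
               present = TRUE, clipped = (cs != start || ce != end),
               anchor = anchor)
  }
  rows <- list(win("a", t0, t0 + 60000, "session_start"))

  if (nrow(walk)) {
    on <- walk$onset_ms[1] # first walking episode only
    rows <- c(rows, list(win("b", on - 60000, on, "walk_pb_onset"),
                         win("c", on, on + 60000, "walk_pb_onset")))
  } else {
    rows <- c(rows, list(win("b", NULL, NULL, "walk_pb_onset"),
                         win("c", NULL, NULL, "walk_pb_onset")))
  }

  if (d_anchor == "pb_onset") {
    d_on <- if (nrow(fall_pb)) fall_pb$onset_ms[1] else NULL
    rows <- c(rows, list(win("d", if (is.null(d_on)) NULL else d_on - 60000,
                             d_on, "fall_pb_onset")))
  } else {
    d_on <- if (nrow(fall_start)) fall_start$onset_ms[1] else NULL
    rows <- c(rows, list(win("d", if (is.null(d_on)) NULL else d_on - 60000,
                             d_on, "robot_fall_start")))
  }

  if (nrow(fall_start) && nrow(adjusted)) {
    fs <- fall_start$onset_ms[1]; ad <- adjusted$onset_ms[1]
    olap <- sm[sm$offset_ms > fs & sm$onset_ms <= ad, , drop = FALSE]
    if (nrow(olap)) {
      rows <- c(rows, list(win("e", olap$onset_ms[1], olap$offset_ms[1],
                               "first_falling_smile")))
    } else { # no smile during the fall: present with zero duration
      rows <- c(rows, list(win("e", fs, fs, "first_falling_smile")))
    }
    rows <- c(rows, list(win("f", ad, ad + 60000, "robot_adjusted")))
  } else {
    rows <- c(rows, list(win("e", NULL, NULL, "first_falling_smile"),
                         win("f", NULL, NULL, "robot_adjusted")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smile duration inside a window, in seconds
#'
#' Sum of the intersections of the track with `[start_ms, end_ms)`, at
#' millisecond precision.
#'
#' @param track a [smile_track()] (or any onset/offset data frame).
#' @param window one row of [extract_segments()] output, or a list/row with
#'   `start_ms` and `end_ms`.
#' @return duration in seconds.
#' @export
smile_duration_in <- function(track, window) {
  if (is.data.frame(window)) window <- as.list(window[1, ])
  if (isFALSE(window$present)) return(NA_real_)
  cl <- clip_intervals(as.data.frame(track), window$start_ms, window$end_ms)
  intervals_total_ms(cl) / 1000
}

#' Per-second behavior codes over the 10 s before a prosocial behavior
#'
#' Codes head direction, facial expression and body movement for each of the
#' ten 1-s bins preceding `pb_onset_ms`. A second is coded positive for a
#' channel when that channel's intervals overlap the bin by at least
#' `overlap_ms` (default 500 ms). If the onset is less than 10 s after the
#' session start the window is clipped and flagged.
#'
#' @param timeline an [annotation_timeline()].
#' @param pb_onset_ms prosocial-behavior onset (ms).
#' @param smiles optional fused [smile_track()] to code the face channel
#'   from; defaults to the timeline's `smile` intervals.
#' @param overlap_ms minimum overlap for a positive second.
#' @return data frame with one row per second: `second` (-10..-1, bin
#'   `[onset + 1000*second, onset + 1000*(second+1))`), `head`, `face`,
#'   `movement` (logicals) and attribute `clipped`.
#' @export
code_pre_window <- function(timeline, pb_onset_ms, smiles = NULL,
                            overlap_ms = 500) {
  start_ev <- timeline_label(timeline, "session_start", events_only = TRUE)
  t0 <- if (nrow(start_ev)) start_ev$onset_ms[1] else 0
  head_iv <- timeline_label(timeline, "head_toward_robot", spans_only = TRUE)
  move_iv <- timeline_label(timeline, "approach_robot", spans_only = TRUE)
  face_iv <- if (is.null(smiles)) {
    timeline_label(timeline, "smile", spans_only = TRUE)
  } else {
    as.data.frame(smiles)
  }
  secs <- -10:-1
  bin_on <- pb_onset_ms + 1000 * secs
  bin_off <- bin_on + 1000
  clipped <- any(bin_on < t0)
  code <- function(iv, on, off) {
    if (nrow(iv) == 0L) return(FALSE)
    tot <- sum(pmax(0, pmin(iv$offset_ms, off) - pmax(iv$onset_ms, on)))
    tot >= overlap_ms
  }
  out <- data.frame(
    second = secs,
    head = vapply(seq_along(secs), function(i) code(head_iv, bin_on[i], bin_off[i]), logical(1)),
    face = vapply(seq_along(secs), function(i) code(face_iv, bin_on[i], bin_off[i]), logical(1)),
    movement = vapply(seq_along(secs), function(i) code(move_iv, bin_on[i], bin_off[i]), logical(1))
  )
  attr(out, "clipped") <- clipped
  out
}

#' Classify a case into the smile-by-outcome quadrants
#'
#' Case A: smiled and showed prosocial behavior; Case B: neither; Case C:
#' smiled without prosocial behavior; Case D: prosocial behavior without a
#' smile.
#'
#' @param case one case record (list or single data frame row) with binary
#'   fields `S` (smile) and `PB` (prosocial behavior).
#' @return one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
classify_case <- function(case) {
  if (is.data.frame(case)) case <- as.list(case[1, ])
  s <- as.logical(case$S); pb <- as.logical(case$PB)
  if (is.na(s) || is.na(pb)) stop("case must have S and PB set")
  if (s && pb) "A" else if (!s && !pb) "B" else if (s) "C" else "D"
}

#' Two-coder intraclass correlation
#'
#' Single-measure two-way random-effects ICC. The default, absolute
#' agreement (often written ICC(2,1)), treats coder mean differences as
#' disagreement; the consistency form ignores a constant coder offset. The F
#' statistic is MSR/MSE with degrees of freedom (n-1, (n-1)(k-1)), and the
#' 95% confidence interval follows the usual two-way random-effects
#' approximation with a Satterthwaite denominator df for the agreement form.
#'
#' @param ratings numeric matrix or data frame, items in rows, the 2 coders
#'   in columns.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf_level confidence level for the interval.
#' @return object of class `icc_result`: list with `icc`, `type`,
#'   `f_statistic`, `df` (length-2), `ci95`, `n_items`, `n_raters`.
#' @export
icc_two_coders <- function(ratings, type = c("agreement", "consistency"),
                           conf_level = 0.95) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop("ratings must be numeric")
  if (ncol(x) != 2L) stop("exactly two coders are supported")
  if (nrow(x) < 3L) stop("need at least 3 items")
  if (anyNA(x)) stop("ratings must not contain missing values")
  if (stats::var(as.vector(x)) == 0) {
    stop("ratings have zero variance; ICC is undefined")
  }
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
  }
  fstat <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) { # identical columns: perfect agreement
    return(structure(list(icc = 1, type = type, f_statistic = Inf,
                          df = c(df1, df2), ci95 = c(1, 1),
                          n_items = n, n_raters = k),
                     class = "icc_result"))
  }
  if (type == "consistency") {
    fl <- fstat / stats::qf(1 - alpha / 2, df1, df2)
    fu <- fstat * stats::qf(1 - alpha / 2, df2, df1)
    lower <- (fl - 1) / (fl + (k - 1))
    upper <- (fu - 1) / (fu + (k - 1))
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    fu <- stats::qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  structure(list(icc = icc, type = type, f_statistic = fstat,
                 df = c(df1, df2),
                 ci95 = c(max(-1, lower), min(1, upper)),
                 n_items = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC (%s, single measure, two-way random): %.3f\n  F(%d, %d) = %.3f, 95%% CI [%.3f, %.3f], n = %d items\n",
    x$type, x$icc, x$df[1], x$df[2], x$f_statistic, x$ci95[1], x$ci95[2],
    x$n_items))
  invisible(x)
}
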