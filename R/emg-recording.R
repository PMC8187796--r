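#' Multichannel facial surface-EMG recording
#'
#' Container for a four-channel differential facial-EMG trace (orbicularis
#' oculi and zygomaticus major regions, both sides of the face) with a
#' time-tag sample marking the session start for video synchronization.
#'
#' @param samples numeric matrix, samples in rows, 4 channels in columns.
#' @param sample_rate sampling rate in Hz.
#' @param time_tag_sample 0-based index of the tagged sample aligning the
#'   recording to session time zero.
#' @param participant_id opaque participant label.
#' @return object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sample_rate, time_tag_sample = 0,
                          participant_id = "P1") {
  samples <- as.matrix(samples)
  if (ncol(samples) != 4L) {
    stop("an EMG recording has exactly 4 channels, got ", ncol(samples))
  }
  if (!all(is.finite(samples))) stop("EMG samples must be finite")
  if (sample_rate <= 0) stop("sample_rate must be positive")
  if (time_tag_sample < 0 || time_tag_sample >= nrow(samples)) {
    stop("time_tag_sample must lie within the recording")
  }
  colnames(samples) <- paste0("ch", 1:4)
  structure(list(samples = samples, sample_rate = sample_rate,
                 time_tag_sample = time_tag_sample,
                 participant_id = participant_id,
                 band = NULL, filter_order = NULL),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %s: %d samples x 4 channels @ %g Hz (%.1f s)%s\n",
    x$participant_id, nrow(x$samples), x$sample_rate,
    nrow(x$samples) / x$sample_rate,
    if (!is.null(x$band)) sprintf(", band-passed %g-%g Hz", x$band[1], x$band[2])
    else ""))
  invisible(x)
}

#' Write / read an EMG recording as delimited text
#'
#' Tab-separated trace with header `time_s`, `ch1`..`ch4`, plus a JSON
#' sidecar (`<path>.json`) holding sample rate, time tag and participant id.
#'
#' @param recording an [emg_recording()].
#' @param path path of the trace file; the sidecar is `<path>.json`.
#' @export
write_emg <- function(recording, path) {
  n <- nrow(recording$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sample_rate,
                   recording$samples)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(sample_rate = recording$sample_rate,
               time_tag_sample = recording$time_tag_sample,
               participant_id = recording$participant_id,
               band = recording$band, filter_order = recording$filter_order)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_emg
#' @export
read_emg <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  rec <- emg_recording(as.matrix(df[, paste0("ch", 1:4)]),
                       sample_rate = as.numeric(meta$sample_rate),
                       time_tag_sample = as.numeric(meta$time_tag_sample),
                       participant_id = meta$participant_id)
  if (!is.null(meta$band) && length(meta$band) == 2) {
    rec$band <- as.numeric(meta$band)
    rec$filter_order <- meta$filter_order
  }
  rec
}
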