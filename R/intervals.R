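#' Interval utilities
#'
#' All intervals in the package are half-open `[onset_ms, offset_ms)` on a
#' 0-based millisecond session clock. These helpers operate on plain
#' data frames with `onset_ms` / `offset_ms` columns.
#'
#' @name intervals
#' @keywords internal
NULL

#' Sort intervals and merge overlapping or adjacent ones
#'
#' @param iv data frame with `onset_ms`, `offset_ms` columns; extra columns
#'   are dropped on merge.
#' @return data frame of sorted, pairwise-disjoint, non-adjacent intervals.
#' @keywords internal
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  iv <- iv[order(iv$onset_ms, iv$offset_ms), , drop = FALSE]
  on <- iv$onset_ms
  off <- iv$offset_ms
  keep_on <- on[1]
  keep_off <- off[1]
  res_on <- numeric(0)
  res_off <- numeric(0)
  for (i in seq_len(nrow(iv))[-1]) {
    if (on[i] <= keep_off) { # overlap or adjacency
      keep_off <- max(keep_off, off[i])
    } else {
      res_on <- c(res_on, keep_on)
      res_off <- c(res_off, keep_off)
      keep_on <- on[i]
      keep_off <- off[i]
    }
  }
  data.frame(onset_ms = c(res_on, keep_on), offset_ms = c(res_off, keep_off))
}

#' Total length of a set of intervals in milliseconds
#' @keywords internal
intervals_total_ms <- function(iv) {
  if (nrow(iv) == 0L) return(0)
  m <- merge_intervals(iv)
  sum(m$offset_ms - m$onset_ms)
}

#' Intersect intervals with a single window `[start_ms, end_ms)`
#' @keywords internal
clip_intervals <- function(iv, start_ms, end_ms) {
  if (nrow(iv) == 0L) return(iv[0, , drop = FALSE])
  on <- pmax(iv$onset_ms, start_ms)
  off <- pmin(iv$offset_ms, end_ms)
  keep <- off > on
  out <- iv[keep, , drop = FALSE]
  out$onset_ms <- on[keep]
  out$offset_ms <- off[keep]
  rownames(out) <- NULL
  out
}

#' Intersect one interval set with another (both data frames)
#' @keywords internal
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0)))
  }
  pieces <- lapply(seq_len(nrow(b)), function(i) {
    clip_intervals(a[, c("onset_ms", "offset_ms")], b$onset_ms[i], b$offset_ms[i])
  })
  merge_intervals(do.call(rbind, pieces))
}

#' Overlap of a single interval pair in ms
#' @keywords internal
overlap_ms <- function(on1, off1, on2, off2) {
  max(0, min(off1, off2) - max(on1, on2))
}

#' Jaccard index between two interval sets
#'
#' Ratio of the total intersection length to the total union length; used to
#' compare estimated smile intervals with ground truth.
#' @keywords internal
interval_jaccard <- function(a, b) {
  inter <- intervals_total_ms(intersect_intervals(a, b))
  uni <- intervals_total_ms(rbind(
    a[, c("onset_ms", "offset_ms")],
    b[, c("onset_ms", "offset_ms")]
  ))
  if (uni == 0) return(if (inter == 0) 1 else 0)
  inter / uni
}

#' Smile interval tracks
#'
#' A `smile_track` is a sorted, non-overlapping set of half-open smile
#' intervals in session milliseconds, each tagged with its provenance:
#' `"video"` for coder-annotated smiles and `"emg"` for intervals estimated
#' from the wearable-sensor signal in segments where the face was not visible
#' on camera.
#'
#' @param onset_ms,offset_ms numeric vectors of interval bounds (ms).
#' @param source provenance tag, `"video"` or `"emg"`; recycled.
#' @return data frame of class `smile_track` with columns `onset_ms`,
#'   `offset_ms`, `source`.
#' @examples
#' smile_track(c(0, 5000), c(1200, 7000))
#' @export
smile_track <- function(onset_ms = numeric(0), offset_ms = numeric(0),
                        source = "video") {
  if (length(onset_ms) != length(offset_ms)) {
    stop("onset_ms and offset_ms must have the same length")
  }
  source <- rep_len(as.character(source), length(onset_ms))
  if (!all(source %in% c("video", "emg"))) {
    stop("smile track source must be 'video' or 'emg'")
  }
  if (any(offset_ms <= onset_ms)) {
    stop("smile intervals must satisfy onset_ms < offset_ms")
  }
  tr <- data.frame(onset_ms = as.numeric(onset_ms),
                   offset_ms = as.numeric(offset_ms),
                   source = source, stringsAsFactors = FALSE)
  tr <- tr[order(tr$onset_ms), , drop = FALSE]
  if (nrow(tr) > 1L && any(tr$onset_ms[-1] < tr$offset_ms[-nrow(tr)])) {
    stop("smile intervals must be non-overlapping")
  }
  rownames(tr) <- NULL
  class(tr) <- c("smile_track", "data.frame")
  tr
}

#' Total smile duration of a track in seconds
#' @param track a [smile_track()].
#' @return total covered time in seconds.
#' @export
smile_total_s <- function(track) {
  intervals_total_ms(as.data.frame(track)) / 1000
}

#' Read and write smile tracks
#'
#' Tab-separated files with header `onset_ms<TAB>offset_ms<TAB>source`.
#'
#' @param track a [smile_track()].
#' @param path file path.
#' @return `read_smile_track()` returns a [smile_track()];
#'   `write_smile_track()` returns `path` invisibly.
#' @export
write_smile_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_smile_track
#' @export
read_smile_track <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("numeric", "numeric", "character"))
  smile_track(df$onset_ms, df$offset_ms, df$source)
}
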