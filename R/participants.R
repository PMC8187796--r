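#' Study participant roster
#'
#' The twelve children of the reference study: six with autism spectrum
#' disorder (ASD) and six typically developing (TD), with age and the
#' sessions entered into analysis. Shipped as a plain TSV under
#' `inst/extdata`.
#'
#' @return data frame with `participant_id`, `group`, `age`,
#'   `analyzed_sessions`.
#' @export
participant_info <- function() {
  path <- system.file("extdata", "participants.tsv", package = "prosmile")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Per-group age summaries
#'
#' Mean and sample standard deviation (n - 1 denominator) of participant
#' age per group, plus range, in the mean +/- SD format used for
#' demographic tables.
#'
#' @param participants roster data frame; defaults to [participant_info()].
#' @return data frame with `group`, `n`, `mean_age`, `sd_age`, `min_age`,
#'   `max_age`.
#' @export
age_summary <- function(participants = participant_info()) {
  out <- lapply(split(participants, participants$group), function(d) {
    data.frame(group = d$group[1], n = nrow(d),
               mean_age = mean(d$age), sd_age = stats::sd(d$age),
               min_age = min(d$age), max_age = max(d$age))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
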