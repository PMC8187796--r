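#' Pipeline configuration
#'
#' Bundles the stage configurations, seeds and thresholds for a full
#' synthetic run: simulate sessions (and optionally the EMG stream of each
#' session), detect and fuse smiles, extract analysis windows, build the
#' case table and probability tables, and cross-validate the predictors.
#'
#' @param session a [synthetic_session_config()].
#' @param emg a [synthetic_emg_config()] used as a template for per-session
#'   EMG simulation, or `NULL` to skip the EMG stage (video smiles only).
#' @param p_hidden_smile probability that a session hides one true smile
#'   inside its camera-unobservable patch, visible only to the EMG
#'   detector.
#' @param head_seconds,overlap_ms case-coding thresholds, see
#'   [cases_from_timeline()].
#' @param round_decimals rounding of the probability tables' presentation
#'   layer.
#' @param classifier_seed,seed seeds for classifier training and for the
#'   hidden-smile draws.
#' @param out_dir optional directory; when set, the report JSON and the
#'   fused smile tracks (TSV) are written there.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(session = synthetic_session_config(),
                            emg = NULL,
                            p_hidden_smile = 0.5,
                            head_seconds = 8, overlap_ms = 500,
                            round_decimals = 2,
                            classifier_seed = 7L, seed = 1L,
                            out_dir = NULL) {
  structure(list(session = session, emg = emg,
                 p_hidden_smile = p_hidden_smile,
                 head_seconds = head_seconds, overlap_ms = overlap_ms,
                 round_decimals = round_decimals,
                 classifier_seed = as.integer(classifier_seed),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# stage wrapper: any failure aborts naming the stage
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> detect -> fuse -> segment -> tabulate -> model
#' and returns a reproducible report. All randomness flows from the seeds
#' recorded in the config, so two runs with the same config produce
#' identical reports.
#'
#' @param config a [pipeline_config()].
#' @return report list with elements `provenance`, `smiles`,
#'   `segment_durations`, `cases`, `joint`, `loo_cv`, `voluntary`, `notes`.
#'   Written as JSON to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config")
  }
  sessions <- run_stage("simulate", generate_session(config$session))
  session_end <- .session_layout$session_end

  smiles_rows <- list()
  fused_tracks <- list()
  notes <- character(0)

  for (j in seq_along(sessions$timelines)) {
    tl <- sessions$timelines[[j]]
    video <- run_stage("detect", {
      sm <- timeline_label(tl, "smile", spans_only = TRUE)
      if (nrow(sm)) smile_track(sm$onset_ms, sm$offset_ms, "video")
      else smile_track()
    })
    unobs <- timeline_label(tl, "unobservable_face", spans_only = TRUE)

    if (!is.null(config$emg)) {
      fused <- run_stage("detect", {
        hidden <- with_seed(config$seed + 13L * j, {
          if (stats::runif(1) < config$p_hidden_smile) {
            data.frame(onset_ms = 97000, offset_ms = 100500)
          } else {
            NULL
          }
        })
        truth_iv <- rbind(as.data.frame(video)[, c("onset_ms", "offset_ms")],
                          hidden)
        truth_iv <- merge_intervals(truth_iv)
        ecfg <- config$emg
        ecfg$duration_s <- session_end / 1000
        ecfg$mixing_seed <- config$seed + 1000L + j
        ecfg$noise_seed <- config$seed + 2000L + j
        sim <- generate_emg(ecfg, participant_id = tl$participant_id,
                            truth = smile_track(truth_iv$onset_ms,
                                                truth_iv$offset_ms))
        filt <- bandpass(sim$recording)
        um <- unmix(filt, seed = config$classifier_seed)
        feats <- rms_envelope(um$components, sim$recording$sample_rate)
        labels <- frame_labels(feats, video)
        in_unobs <- vapply(feats$frame_times, function(t0) {
          nrow(clip_intervals(unobs, t0, t0 + feats$frame_ms)) > 0
        }, logical(1))
        labels[in_unobs] <- NA
        model <- train_smile_classifier(feats, labels,
                                        seed = config$classifier_seed,
                                        unmixing = um$unmixing,
                                        center = um$center)
        est <- estimate_unobserved(model, sim$recording, video, unobs)
        fuse_smiles(video, est, unobs)
      })
    } else {
      fused <- run_stage("fuse", fuse_smiles(video, smile_track(source = "emg"),
                                             unobs))
    }
    fused_tracks[[tl$session_id]] <- fused
    smiles_rows[[j]] <- data.frame(
      session_id = tl$session_id, participant_id = tl$participant_id,
      group = tl$group,
      video_smile_s = smile_total_s(video),
      emg_smile_s = smile_total_s(fused) - smile_total_s(video),
      fused_smile_s = smile_total_s(fused)
    )
  }
  smiles <- do.call(rbind, smiles_rows)

  # segment windows and their smile durations, Table 2/3 style
  seg_rows <- run_stage("segments", {
    rows <- list()
    for (j in seq_along(sessions$timelines)) {
      tl <- sessions$timelines[[j]]
      segs <- extract_segments(tl, smiles = fused_tracks[[tl$session_id]],
                               session_end_ms = session_end)
      if (!all(segs$present)) {
        notes <- c(notes, paste0(tl$session_id, ": missing window(s) ",
                                  paste(segs$kind[!segs$present],
                                        collapse = ", ")))
      }
      for (i in seq_len(nrow(segs))) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = tl$group, session = sub(".*sess", "", tl$session_id),
          kind = segs$kind[i],
          smile_s = smile_duration_in(fused_tracks[[tl$session_id]],
                                      segs[i, ])
        )
      }
    }
    do.call(rbind, rows)
  })
  seg_summary <- run_stage("segments", {
    agg_m <- stats::aggregate(smile_s ~ group + session + kind, seg_rows,
                              mean, na.action = stats::na.omit)
    agg_s <- stats::aggregate(smile_s ~ group + session + kind, seg_rows,
                              stats::sd, na.action = stats::na.omit)
    names(agg_m)[4] <- "mean_smile_s"
    agg_m$sd_smile_s <- agg_s$smile_s
    agg_m[order(agg_m$group, agg_m$session, agg_m$kind), ]
  })

  cases <- run_stage("cases", {
    cs <- sessions$cases
    cs$case_class <- vapply(seq_len(nrow(cs)),
                            function(i) classify_case(cs[i, ]), character(1))
    cs
  })

  joint <- run_stage("model", {
    jt <- build_joint_table(cases, c("S", "PB"),
                            round_decimals = config$round_decimals)
    list(
      table = jt,
      counts = stats::setNames(jt$cells$count,
                               paste0(ifelse(jt$cells$S, "S", "noS"), "_",
                                      ifelse(jt$cells$PB, "PB", "noPB"))),
      p_smile = marginal_probability(jt, "S"),
      p_pb = marginal_probability(jt, "PB"),
      p_pb_given_smile = list(
        rounded = conditional_probability(jt, "PB", list(S = TRUE), TRUE),
        exact = conditional_probability(jt, "PB", list(S = TRUE), FALSE)),
      p_pb_given_no_smile = list(
        rounded = conditional_probability(jt, "PB", list(S = FALSE), TRUE),
        exact = conditional_probability(jt, "PB", list(S = FALSE), FALSE)),
      smile_share_of_pb_pct = list(
        rounded = smile_share_of_pb(jt, TRUE),
        exact = smile_share_of_pb(jt, FALSE)),
      rounding = sprintf("half-up, %d decimals (exact-count mode reported alongside)",
                         config$round_decimals)
    )
  })

  cv <- run_stage("model", {
    res <- lapply(c("ASD", "TD"), function(g) {
      r <- loo_cv(cases, group_filter = g)
      r$group <- g
      r
    })
    do.call(rbind, res)
  })

  vol <- run_stage("model", voluntary_consistency_check(cases))

  report <- list(
    provenance = list(
      package = "prosmile",
      version = as.character(utils::packageVersion("prosmile")),
      seeds = list(session = config$session$seed,
                   pipeline = config$seed,
                   classifier = config$classifier_seed),
      emg_stage = !is.null(config$emg),
      config_hash = config_hash(config)
    ),
    smiles = smiles,
    segment_durations = seg_summary,
    cases = cases,
    joint = joint[setdiff(names(joint), "table")],
    loo_cv = cv,
    voluntary = vol,
    notes = if (length(notes)) notes else "all windows present"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    for (sid in names(fused_tracks)) {
      write_smile_track(fused_tracks[[sid]],
                        file.path(config$out_dir,
                                  paste0("smiles_", sid, ".tsv")))
    }
  }
  report$fused_tracks <- fused_tracks
  report$joint$table <- joint$table
  invisible(report)
}

# deterministic md5 of the configuration (seeds included)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass_deep(cfg), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Recompute the study's printed quantities from package primitives
#'
#' Rebuilds the 36-case reference table and the participant roster and
#' recomputes every headline number: the rounded joint proportions and
#' marginals, the rounded-mode conditionals, the smile share of prosocial
#' behavior, the design case count, and the per-group age statistics. Each
#' row pairs the expected printed value with the value computed here.
#'
#' @param cases case table to verify against; defaults to
#'   [case_table_fixture()]. Perturbing it makes the corresponding rows
#'   fail.
#' @param participants roster; defaults to [participant_info()].
#' @return data frame with `quantity`, `expected`, `computed`, `pass`;
#'   attribute `all_pass`.
#' @export
verify_paper_numbers <- function(cases = case_table_fixture(),
                                 participants = participant_info()) {
  jt <- build_joint_table(cases, c("S", "PB"))
  cells <- jt$cells
  cell <- function(s, pb) cells$rounded[cells$S == s & cells$PB == pb]
  ages <- age_summary(participants)
  asd <- ages[ages$group == "ASD", ]
  td <- ages[ages$group == "TD", ]
  rows <- data.frame(
    quantity = c(
      "P(PB|S) rounded-mode, %", "P(PB|no S) rounded-mode, %",
      "joint P(S, PB)", "joint P(S, no PB)", "joint P(no S, PB)",
      "joint P(no S, no PB)", "smile share of PB, %",
      "number of cases", "ASD mean age", "ASD age SD",
      "TD mean age", "TD age SD"),
    expected = c(84, 44, 0.42, 0.08, 0.22, 0.28, 66, 36,
                 9.67, 3.50, 9.83, 2.04),
    computed = c(
      100 * conditional_probability(jt, "PB", list(S = TRUE), TRUE),
      100 * conditional_probability(jt, "PB", list(S = FALSE), TRUE),
      cell(TRUE, TRUE), cell(TRUE, FALSE), cell(FALSE, TRUE),
      cell(FALSE, FALSE),
      smile_share_of_pb(jt, TRUE),
      nrow(cases),
      round_half_up(asd$mean_age, 2), round_half_up(asd$sd_age, 2),
      round_half_up(td$mean_age, 2), round_half_up(td$sd_age, 2))
  )
  rows$pass <- abs(rows$expected - rows$computed) < 1e-9
  attr(rows, "all_pass") <- all(rows$pass)
  rows
}
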