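#' Configuration for synthetic therapy-session generation
#'
#' Parameterizes the behavioral event chain observed before prosocial
#' behavior: the robot moves; the child may smile; a smiling (or sometimes a
#' non-smiling) child turns the head toward the robot; a child heading
#' toward the robot may approach it; approach leads to voluntary prosocial
#' behavior; when no smile appears, a therapist or parent may prompt, and
#' prompting may itself elicit (non-voluntary) prosocial behavior. All
#' transitions are Bernoulli draws, one episode per situation per session,
#' with per-second annotation resolution (`step_s = 1`).
#'
#' The defaults are calibrated so the closed-form smile-by-outcome joint
#' distribution equals (0.42, 0.08, 0.22, 0.28) over
#' (S&PB, S&!PB, !S&PB, !S&!PB): P(S) = 0.5, P(PB|S) =
#' 0.875 x 0.96 x 1 = 0.84, and P(PB|!S) = 1 - (1 - 0.25 x 0.96)(1 -
#' 0.5 x 10/19) = 0.44. Approach deterministically yields prosocial behavior
#' (`p_pb_given_approach = 1`): in the observed sessions prosocial behavior
#' always followed once smiling, heading and approaching all occurred.
#'
#' @param n_asd,n_td participants per group.
#' @param asd_sessions,td_sessions analysed sessions per participant.
#' @param situations situations simulated in every session.
#' @param p_smile_given_robot_movement probability the child smiles after
#'   the robot's movement.
#' @param p_head_given_smile,p_head_given_no_smile probability of sustained
#'   heading toward the robot given smiling / not smiling.
#' @param p_approach_given_head probability of approaching given heading.
#' @param p_pb_given_approach probability of prosocial behavior given
#'   approach (the voluntary path).
#' @param p_prompt_given_no_smile probability a therapist/parent prompts
#'   when no smile appeared.
#' @param p_pb_given_prompt probability a prompt elicits prosocial behavior.
#' @param step_s annotation step in seconds (fixed at 1).
#' @param seed integer seed driving every random draw.
#' @return object of class `synthetic_session_config`.
#' @seealso [generate_session()], [session_joint()]
#' @export
synthetic_session_config <- function(n_asd = 6, n_td = 6,
                                     asd_sessions = 2, td_sessions = 1,
                                     situations = c("walking", "falling"),
                                     p_smile_given_robot_movement = 0.5,
                                     p_head_given_smile = 0.875,
                                     p_head_given_no_smile = 0.25,
                                     p_approach_given_head = 0.96,
                                     p_pb_given_approach = 1.0,
                                     p_prompt_given_no_smile = 0.5,
                                     p_pb_given_prompt = 10 / 19,
                                     step_s = 1,
                                     seed = 1L) {
  probs <- c(p_smile_given_robot_movement, p_head_given_smile,
             p_head_given_no_smile, p_approach_given_head,
             p_pb_given_approach, p_prompt_given_no_smile, p_pb_given_prompt)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all chain probabilities must lie in [0, 1]")
  }
  if (n_asd < 0 || n_td < 0 || n_asd + n_td == 0) {
    stop("need at least one participant")
  }
  if (!all(situations %in% c("walking", "falling")) || !length(situations)) {
    stop("situations must be a non-empty subset of walking, falling")
  }
  if (step_s != 1) stop("per-second annotation requires step_s = 1")
  structure(list(
    n_asd = as.integer(n_asd), n_td = as.integer(n_td),
    asd_sessions = as.integer(asd_sessions),
    td_sessions = as.integer(td_sessions),
    situations = situations,
    p_smile_given_robot_movement = p_smile_given_robot_movement,
    p_head_given_smile = p_head_given_smile,
    p_head_given_no_smile = p_head_given_no_smile,
    p_approach_given_head = p_approach_given_head,
    p_pb_given_approach = p_pb_given_approach,
    p_prompt_given_no_smile = p_prompt_given_no_smile,
    p_pb_given_prompt = p_pb_given_prompt,
    step_s = step_s, seed = as.integer(seed)
  ), class = "synthetic_session_config")
}

#' Closed-form smile-by-outcome joint distribution of the event chain
#'
#' The chain admits an exact joint for (smile S, prosocial behavior PB):
#' `P(PB | S) = p_head_given_smile * p_approach_given_head *
#' p_pb_given_approach`; for non-smiling children the voluntary path
#' (`p_head_given_no_smile * p_approach_given_head * p_pb_given_approach`)
#' and the prompting path (`p_prompt_given_no_smile * p_pb_given_prompt`)
#' are independent chances, so
#' `P(PB | !S) = 1 - (1 - voluntary)(1 - prompted)`.
#'
#' @param config a [synthetic_session_config()].
#' @return named numeric of cell probabilities `S_PB`, `S_noPB`, `noS_PB`,
#'   `noS_noPB` (sums to 1).
#' @export
session_joint <- function(config) {
  ps <- config$p_smile_given_robot_movement
  pb_s <- config$p_head_given_smile * config$p_approach_given_head *
    config$p_pb_given_approach
  vol0 <- config$p_head_given_no_smile * config$p_approach_given_head *
    config$p_pb_given_approach
  pr0 <- config$p_prompt_given_no_smile * config$p_pb_given_prompt
  pb_ns <- 1 - (1 - vol0) * (1 - pr0)
  c(S_PB = ps * pb_s,
    S_noPB = ps * (1 - pb_s),
    noS_PB = (1 - ps) * pb_ns,
    noS_noPB = (1 - ps) * (1 - pb_ns))
}

# One chain draw per case; vectorized over n cases. Returns the binary flags.
draw_chain <- function(config, n) {
  s <- stats::runif(n) < config$p_smile_given_robot_movement
  p_head <- ifelse(s, config$p_head_given_smile, config$p_head_given_no_smile)
  h <- stats::runif(n) < p_head
  a <- h & (stats::runif(n) < config$p_approach_given_head)
  pb_vol <- a & (stats::runif(n) < config$p_pb_given_approach)
  p <- (!s) & (stats::runif(n) < config$p_prompt_given_no_smile)
  pb_prompt <- p & (stats::runif(n) < config$p_pb_given_prompt)
  pb <- pb_vol | pb_prompt
  data.frame(S = s, H = h, A = a, P = p, PB = pb,
             voluntary = pb & !p)
}

#' Draw case flags from the event chain without building timelines
#'
#' Fast path used for calibration checks and large-sample experiments: the
#' same Bernoulli chain as [generate_session()], flags only.
#'
#' @param config a [synthetic_session_config()].
#' @param n number of cases.
#' @param seed seed; defaults to the config seed.
#' @return data frame with logical columns `S`, `H`, `A`, `P`, `PB`,
#'   `voluntary`.
#' @export
simulate_chain_cases <- function(config, n, seed = config$seed) {
  with_seed(seed, draw_chain(config, n))
}

# ---- timeline layout constants (ms) -----------------------------------
# One synthetic session: entry at 0, robot's walking movement at 60 s with
# the 10-s observation window [61, 71) s and the (possible) walking
# prosocial behavior at 71 s; the robot falls at 180 s with window
# [181, 191) s, prosocial behavior at 191 s and the robot back on its feet
# at 200 s. A 10-s camera-unobservable patch sits at [95, 105) s, away from
# any annotated smile, so fusion always has work to do.
.session_layout <- list(
  session_end = 260000,
  walk = list(move = 60000, win_on = 61000, pb_on = 71000, pb_off = 91000,
              prompt = 66000),
  fall = list(start = 180000, win_on = 181000, pb_on = 191000,
              pb_off = 199000, prompt = 186000, adjusted = 200000),
  unobservable = c(95000, 105000)
)

# Build annotation rows for one situation episode given drawn flags.
episode_rows <- function(flags, situation) {
  lay <- if (situation == "walking") .session_layout$walk else .session_layout$fall
  rows <- list()
  add <- function(on, off, label) {
    rows[[length(rows) + 1L]] <<- data.frame(onset_ms = on, offset_ms = off,
                                             label = label)
  }
  if (situation == "walking") {
    add(lay$move, lay$move, "robot_movement")
  } else {
    add(lay$start, lay$start, "robot_fall_start")
    add(lay$adjusted, lay$adjusted, "robot_adjusted")
  }
  if (flags$S) {
    on <- lay$win_on + 200 + stats::runif(1, 0, 1800)
    dur <- stats::runif(1, 3000, 6000)
    add(round(on), round(min(on + dur, lay$pb_on - 200)), "smile")
  }
  if (flags$H) {
    add(lay$win_on, lay$pb_on - 500, "head_toward_robot")
  } else {
    add(lay$win_on, lay$win_on + 3000, "head_toward_robot")
  }
  if (flags$A) add(lay$pb_on - 3000, lay$pb_on, "approach_robot")
  if (flags$P) add(lay$prompt, lay$prompt, "prompt")
  if (flags$PB) {
    add(lay$pb_on, lay$pb_off,
        if (situation == "walking") "prosocial_walk" else "prosocial_fall")
  }
  do.call(rbind, rows)
}

#' Generate synthetic session timelines and case records
#'
#' Draws the behavioral event chain once per situation per session per
#' participant, lays the outcomes onto annotated session timelines (entry,
#' robot movement/fall anchors, smile / heading / approach intervals,
#' prompt events, prosocial-behavior onsets, and a camera-unobservable
#' patch), and summarizes each 10-s pre-onset window into a binary case
#' record. The case flags are, by construction, exactly what
#' [cases_from_timeline()] recovers from the emitted timeline.
#'
#' @param config a [synthetic_session_config()].
#' @return list with `timelines` (one [annotation_timeline()] per
#'   participant-session) and `cases` (data frame: `participant_id`,
#'   `group`, `session`, `situation`, `S`, `H`, `A`, `P`, `PB`,
#'   `voluntary`).
#' @export
generate_session <- function(config) {
  if (!inherits(config, "synthetic_session_config")) {
    stop("config must be a synthetic_session_config")
  }
  plan <- list()
  if (config$n_asd > 0 && config$asd_sessions > 0) {
    plan <- c(plan, lapply(seq_len(config$n_asd), function(i) {
      lapply(seq_len(config$asd_sessions), function(s) {
        list(pid = sprintf("ASD-P%d", i), group = "ASD", session = s)
      })
    }))
  }
  if (config$n_td > 0 && config$td_sessions > 0) {
    plan <- c(plan, lapply(seq_len(config$n_td), function(i) {
      lapply(seq_len(config$td_sessions), function(s) {
        list(pid = sprintf("TD-P%d", i), group = "TD", session = s)
      })
    }))
  }
  plan <- unlist(plan, recursive = FALSE)
  if (!length(plan)) stop("need at least one participant with one session")

  with_seed(config$seed, {
    timelines <- vector("list", length(plan))
    case_rows <- list()
    for (j in seq_along(plan)) {
      meta <- plan[[j]]
      rows <- list(data.frame(onset_ms = 0, offset_ms = 0,
                              label = "session_start"),
                   data.frame(onset_ms = .session_layout$unobservable[1],
                              offset_ms = .session_layout$unobservable[2],
                              label = "unobservable_face"))
      for (sit in config$situations) {
        flags <- draw_chain(config, 1)
        rows[[length(rows) + 1L]] <- episode_rows(flags, sit)
        case_rows[[length(case_rows) + 1L]] <- data.frame(
          participant_id = meta$pid, group = meta$group,
          session = meta$session, situation = sit,
          S = flags$S, H = flags$H, A = flags$A, P = flags$P, PB = flags$PB,
          voluntary = flags$voluntary
        )
      }
      timelines[[j]] <- annotation_timeline(
        do.call(rbind, rows),
        session_id = sprintf("%s-sess%d", meta$pid, meta$session),
        participant_id = meta$pid, group = meta$group
      )
    }
    cases <- do.call(rbind, case_rows)
    rownames(cases) <- NULL
    list(timelines = timelines, cases = cases)
  })
}

#' Recover case flags from a session timeline
#'
#' Codes the 10-s window before each situation's prosocial-behavior onset
#' (or, when no prosocial behavior occurred, before the situation's
#' reference time: 11 s after the robot movement / fall start) and derives
#' the binary case flags: `S` if any smile overlaps the window, `H` if at
#' least `head_seconds` of the ten per-second head codes are positive, `A`
#' if any approach interval overlaps the window, `P` if a prompt event falls
#' inside it, and `PB` from the presence of the prosocial interval.
#'
#' @param timeline an [annotation_timeline()].
#' @param smiles optional fused [smile_track()] for the smile channel.
#' @param head_seconds positive seconds required for the heading flag
#'   (default 8 of 10: head direction must be maintained).
#' @param overlap_ms per-second coding threshold, see [code_pre_window()].
#' @return data frame of case rows (one per situation present on the
#'   timeline), same columns as [generate_session()]'s `cases`.
#' @export
cases_from_timeline <- function(timeline, smiles = NULL, head_seconds = 8,
                                overlap_ms = 500) {
  smile_iv <- if (is.null(smiles)) {
    timeline_label(timeline, "smile", spans_only = TRUE)
  } else {
    as.data.frame(smiles)
  }
  out <- list()
  for (sit in c("walking", "falling")) {
    if (sit == "walking") {
      anchor_ev <- timeline_label(timeline, "robot_movement")
      pb_iv <- timeline_label(timeline, "prosocial_walk", spans_only = TRUE)
    } else {
      anchor_ev <- timeline_label(timeline, "robot_fall_start")
      pb_iv <- timeline_label(timeline, "prosocial_fall", spans_only = TRUE)
    }
    if (nrow(anchor_ev) == 0L && nrow(pb_iv) == 0L) next
    pb <- nrow(pb_iv) > 0L
    onset <- if (pb) pb_iv$onset_ms[1] else anchor_ev$onset_ms[1] + 11000
    codes <- code_pre_window(timeline, onset, smiles = smile_iv,
                             overlap_ms = overlap_ms)
    win_on <- onset - 10000
    s <- nrow(clip_intervals(smile_iv, win_on, onset)) > 0L
    appr <- timeline_label(timeline, "approach_robot", spans_only = TRUE)
    a <- nrow(clip_intervals(appr, win_on, onset)) > 0L
    prompts <- timeline_label(timeline, "prompt", events_only = TRUE)
    p <- any(prompts$onset_ms >= win_on & prompts$onset_ms < onset)
    out[[length(out) + 1L]] <- data.frame(
      participant_id = timeline$participant_id, group = timeline$group,
      session = timeline$session_id, situation = sit,
      S = s, H = sum(codes$head) >= head_seconds, A = a, P = p, PB = pb,
      voluntary = pb & !p
    )
  }
  if (!length(out)) {
    return(data.frame(participant_id = character(0), group = character(0),
                      session = character(0), situation = character(0),
                      S = logical(0), H = logical(0), A = logical(0),
                      P = logical(0), PB = logical(0), voluntary = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a case table with exact cell counts from a joint distribution
#'
#' Apportions `n` cases among the four (S, PB) cells by largest-remainder
#' rounding, so counts always sum to `n`, then fills in the remaining flags
#' consistently with the observed behavior chain: smiling cases that acted
#' prosocially did so voluntarily (headed, approached, unprompted), while
#' non-smiling prosocial cases were prompted. Cases are assigned to twelve
#' participants (six per group) round-robin and shuffled by `seed`.
#'
#' @param n number of cases.
#' @param joint length-4 non-negative proportions over
#'   (S&PB, S&!PB, !S&PB, !S&!PB); must sum to 1 within 1e-9.
#' @param seed integer seed for the shuffle.
#' @return data frame of case rows as in [generate_session()].
#' @export
generate_case_table <- function(n, joint, seed = 1L) {
  if (length(joint) != 4L || any(joint < 0)) {
    stop("joint must be 4 non-negative proportions over (S&PB, S&!PB, !S&PB, !S&!PB)")
  }
  if (abs(sum(joint) - 1) > 1e-9) {
    stop("joint proportions must sum to 1 (got ", format(sum(joint)), ")")
  }
  if (n < 1) stop("n must be a positive count")
  counts <- largest_remainder(n, joint)
  cell <- rep(1:4, counts)
  flags <- data.frame(
    S = cell %in% c(1, 2),
    PB = cell %in% c(1, 3)
  )
  flags$H <- cell %in% c(1, 3) # heading maintained whenever PB followed
  flags$A <- cell == 1
  flags$P <- cell == 3 # prompted non-smiling prosocial cases
  flags$voluntary <- flags$PB & !flags$P
  with_seed(seed, {
    ord <- sample.int(length(cell))
    pid_pool <- c(sprintf("ASD-P%d", 1:6), sprintf("TD-P%d", 1:6))
    flags <- flags[ord, , drop = FALSE]
    k <- nrow(flags)
    pid <- rep_len(pid_pool, k)
    data.frame(
      participant_id = pid,
      group = ifelse(startsWith(pid, "ASD"), "ASD", "TD"),
      session = 1L, situation = rep_len(c("walking", "falling"), k),
      S = flags$S, H = flags$H, A = flags$A, P = flags$P, PB = flags$PB,
      voluntary = flags$voluntary, row.names = NULL
    )
  })
}

#' The 36-case reference fixture
#'
#' The study-sized case table: 36 cases (six children per group; two analysed
#' sessions for the ASD group, one for the TD comparison group; walking and
#' falling situation each) whose smile-by-outcome cell counts are
#' (15, 3, 8, 10), the largest-remainder apportionment of the printed joint
#' proportions (0.42, 0.08, 0.22, 0.28) over 36 cases.
#'
#' @param seed shuffle seed (cell counts are unaffected).
#' @return data frame of 36 case rows.
#' @export
case_table_fixture <- function(seed = 1L) {
  generate_case_table(36, c(0.42, 0.08, 0.22, 0.28), seed = seed)
}

#' Write or read a case table TSV
#'
#' Columns: `participant_id`, `group`, `session`, `situation`, `S`, `H`,
#' `A`, `P`, `PB` (0/1 flags); `voluntary` is derived on read.
#' @param cases case data frame.
#' @param path file path.
#' @export
write_case_table <- function(cases, path) {
  df <- cases[, c("participant_id", "group", "session", "situation",
                  "S", "H", "A", "P", "PB")]
  for (col in c("S", "H", "A", "P", "PB")) df[[col]] <- as.integer(df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_case_table
#' @export
read_case_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  for (col in c("S", "H", "A", "P", "PB")) df[[col]] <- as.logical(df[[col]])
  df$voluntary <- df$PB & !df$P
  df
}
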