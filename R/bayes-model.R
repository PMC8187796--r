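#' Build a joint probability table over binary case variables
#'
#' Counts cases in every cell of the cross of the requested binary
#' variables and derives exact proportions plus a rounded presentation
#' layer (half-up, `round_decimals` places) matching how such tables are
#' printed in small-sample reports. Marginals are available in both modes.
#'
#' @param cases case data frame (e.g. from [generate_case_table()]).
#' @param variables character vector of binary case columns (default
#'   smile and prosocial-behavior flags `c("S", "PB")`).
#' @param round_decimals decimals for the rounded layer.
#' @return object of class `joint_prob_table`: list with `variables`,
#'   `cells` (data frame of variable values, `count`, `proportion`,
#'   `rounded`), `n`, `round_decimals`.
#' @export
build_joint_table <- function(cases, variables = c("S", "PB"),
                              round_decimals = 2) {
  if (!is.data.frame(cases) || nrow(cases) == 0L) {
    stop("need at least one case")
  }
  if (!all(variables %in% names(cases))) {
    stop("missing case variable(s): ",
         paste(setdiff(variables, names(cases)), collapse = ", "))
  }
  vals <- lapply(variables, function(v) {
    x <- as.logical(cases[[v]])
    if (anyNA(x)) stop("variable ", v, " must be binary with no missing values")
    x
  })
  names(vals) <- variables
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(variables)))
  names(grid) <- variables
  count <- apply(grid, 1, function(row) {
    m <- rep(TRUE, nrow(cases))
    for (v in variables) m <- m & (vals[[v]] == row[[v]])
    sum(m)
  })
  n <- nrow(cases)
  prop <- count / n
  stopifnot(abs(sum(prop) - 1) < 1e-9)
  cells <- cbind(grid, count = as.integer(count), proportion = prop,
                 rounded = round_half_up(prop, round_decimals))
  structure(list(variables = variables, cells = cells, n = n,
                 round_decimals = round_decimals),
            class = "joint_prob_table")
}

#' @export
print.joint_prob_table <- function(x, ...) {
  cat(sprintf("<joint_prob_table> %s over %d cases (rounded to %d decimals, half-up)\n",
              paste(x$variables, collapse = " x "), x$n, x$round_decimals))
  print(x$cells, row.names = FALSE)
  invisible(x)
}

# Probability of an event {var = value, ...} under a table.
# mode: "rounded" uses the printed proportions, "exact" the counts.
event_probability <- function(table, event, use_rounded = TRUE) {
  cells <- table$cells
  m <- rep(TRUE, nrow(cells))
  for (v in names(event)) {
    if (!v %in% table$variables) stop("unknown variable: ", v)
    m <- m & (cells[[v]] == as.logical(event[[v]]))
  }
  if (use_rounded) sum(cells$rounded[m]) else sum(cells$count[m]) / table$n
}

#' Marginal probability of one variable being TRUE
#' @param table a [build_joint_table()] result.
#' @param variable variable name.
#' @param use_rounded use the rounded presentation layer (default) or the
#'   exact counts.
#' @export
marginal_probability <- function(table, variable, use_rounded = TRUE) {
  ev <- stats::setNames(list(TRUE), variable)
  event_probability(table, ev, use_rounded)
}

#' Conditional probability from a joint table
#'
#' `P(target = TRUE | given)` computed as the ratio of the joint cell mass
#' to the conditioning mass. With `use_rounded = TRUE` (default) the
#' arithmetic runs on the rounded printed proportions, reproducing the
#' worked values of small-sample reports; with `FALSE` it uses exact
#' counts.
#'
#' @param table a [build_joint_table()] result.
#' @param target name of the target variable (probability of it being
#'   TRUE).
#' @param given named list of conditioning values, e.g. `list(S = TRUE)`.
#' @param use_rounded arithmetic mode.
#' @return probability in `[0, 1]`.
#' @export
conditional_probability <- function(table, target, given,
                                    use_rounded = TRUE) {
  p_given <- event_probability(table, given, use_rounded)
  if (p_given <= 0) {
    stop("conditioning event has zero probability")
  }
  joint <- event_probability(table, c(stats::setNames(list(TRUE), target),
                                      given), use_rounded)
  joint / p_given
}

#' Share of prosocial behavior preceded by smiling, in percent
#'
#' `100 * P(S, PB) / P(PB)`, rounded to the nearest whole percent: the
#' fraction of all prosocial-behavior cases in which the child smiled in
#' the 10-s window beforehand.
#'
#' @param table a [build_joint_table()] result over `S` and `PB`.
#' @param use_rounded arithmetic mode as in [conditional_probability()].
#' @return whole-number percentage.
#' @export
smile_share_of_pb <- function(table, use_rounded = TRUE) {
  p_pb <- event_probability(table, list(PB = TRUE), use_rounded)
  if (p_pb <= 0) return(0)
  joint <- event_probability(table, list(S = TRUE, PB = TRUE), use_rounded)
  as.numeric(round_half_up(100 * joint / p_pb, 0))
}

#' Fit a conditional-probability predictor of prosocial behavior
#'
#' Estimates `P(PB | predictor pattern)` by relative frequency over the
#' training cases for every observed pattern of the chosen predictor
#' subset; patterns never seen in training fall back to the training
#' prosocial-behavior rate. With an empty predictor set the model is the
#' base rate everywhere. Optional add-one (Laplace) smoothing is available
#' but off by default, matching plain small-sample arithmetic.
#'
#' @param training_cases case data frame with a `PB` column.
#' @param predictor_set character subset of `c("S", "H", "P")` (possibly
#'   empty).
#' @param smoothing `"none"` (default) or `"add_one"`.
#' @return object of class `predictor_model`.
#' @export
fit_predictor_model <- function(training_cases,
                                predictor_set = c("S"),
                                smoothing = c("none", "add_one")) {
  smoothing <- match.arg(smoothing)
  if (!is.data.frame(training_cases) || nrow(training_cases) == 0L) {
    stop("training cases must be non-empty")
  }
  predictor_set <- as.character(predictor_set)
  if (!all(predictor_set %in% c("S", "H", "P"))) {
    stop("predictors must come from S, H, P")
  }
  pb <- as.logical(training_cases$PB)
  base_rate <- mean(pb)
  if (length(predictor_set) == 0L) {
    tab <- data.frame(p_pb = base_rate, n = length(pb))
  } else {
    key <- do.call(paste, c(lapply(predictor_set, function(v) {
      as.integer(as.logical(training_cases[[v]]))
    }), sep = "|"))
    agg <- tapply(pb, key, function(z) c(sum(z), length(z)))
    tab <- do.call(rbind, agg)
    add <- if (smoothing == "add_one") 1 else 0
    tab <- data.frame(pattern = names(agg),
                      p_pb = (tab[, 1] + add) / (tab[, 2] + 2 * add),
                      n = tab[, 2], row.names = NULL)
  }
  structure(list(predictors = predictor_set, table = tab,
                 fallback = base_rate, threshold = 0.5,
                 n_training = length(pb)),
            class = "predictor_model")
}

#' Predict prosocial behavior for new cases
#'
#' Looks up `P(PB | pattern)` for each case and thresholds at the model's
#' decision threshold (0.5); a probability exactly at the threshold falls
#' back to the training-majority class, as does an unseen pattern's
#' probability lookup (the training PB rate).
#'
#' @param object a [fit_predictor_model()] result.
#' @param newdata case data frame.
#' @param ... unused.
#' @return data frame with `probability` and `prediction` (logical).
#' @export
predict.predictor_model <- function(object, newdata, ...) {
  majority <- object$fallback >= 0.5
  if (length(object$predictors) == 0L) {
    p <- rep(object$fallback, nrow(newdata))
  } else {
    key <- do.call(paste, c(lapply(object$predictors, function(v) {
      as.integer(as.logical(newdata[[v]]))
    }), sep = "|"))
    idx <- match(key, object$table$pattern)
    p <- ifelse(is.na(idx), object$fallback, object$table$p_pb[idx])
  }
  pred <- ifelse(p > object$threshold, TRUE,
                 ifelse(p < object$threshold, FALSE, majority))
  data.frame(probability = p, prediction = as.logical(pred))
}

#' Subject-wise leave-one-out cross-validation of predictor subsets
#'
#' For every predictor subset: hold out all cases of one participant, fit
#' the conditional-probability model on the remaining participants'
#' cases, predict the held-out participant's prosocial behavior, and score
#' that participant's accuracy; the subset's reported accuracy is the
#' unweighted mean over held-out participants (a per-case weighted mean is
#' available via `average = "case"`). When `group_filter` is given, only
#' that group's cases enter the procedure.
#'
#' @param cases case data frame with `participant_id`, `group`, `PB` and
#'   predictor columns.
#' @param predictor_subsets list of character vectors; default: all seven
#'   non-empty subsets of `c("S", "H", "P")`.
#' @param group_filter optional `"ASD"` or `"TD"`.
#' @param average `"participant"` (default) or `"case"`.
#' @param smoothing passed to [fit_predictor_model()].
#' @return data frame with `subset` (label), `accuracy`, `n_participants`,
#'   `n_cases`.
#' @export
loo_cv <- function(cases, predictor_subsets = NULL, group_filter = NULL,
                   average = c("participant", "case"),
                   smoothing = "none") {
  average <- match.arg(average)
  if (!is.null(group_filter)) {
    cases <- cases[cases$group == group_filter, , drop = FALSE]
  }
  if (is.null(predictor_subsets)) {
    predictor_subsets <- list("S", "H", "P", c("S", "H"), c("S", "P"),
                              c("H", "P"), c("S", "H", "P"))
  }
  pids <- unique(cases$participant_id)
  if (length(pids) < 2L) {
    stop("need at least 2 participants",
         if (length(pids) == 1L) " (one participant owns all cases)" else "")
  }
  out <- lapply(predictor_subsets, function(subset) {
    per_part <- vapply(pids, function(pid) {
      test <- cases[cases$participant_id == pid, , drop = FALSE]
      train <- cases[cases$participant_id != pid, , drop = FALSE]
      model <- fit_predictor_model(train, subset, smoothing = smoothing)
      pred <- predict(model, test)
      c(acc = mean(pred$prediction == as.logical(test$PB)),
        n = nrow(test))
    }, numeric(2))
    acc <- if (average == "participant") {
      mean(per_part["acc", ])
    } else {
      sum(per_part["acc", ] * per_part["n", ]) / sum(per_part["n", ])
    }
    data.frame(subset = paste(subset, collapse = "+"),
               accuracy = acc,
               n_participants = length(pids),
               n_cases = nrow(cases))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tabulate support for the voluntary-smile observations
#'
#' Purely descriptive per-group bookkeeping of two qualitative claims
#' about the case set: (1) every smiling child who acted prosocially did
#' so voluntarily (without prompting), and (2) every non-smiling child who
#' acted prosocially was prompted. No test statistic is computed.
#'
#' @param cases case data frame with `group`, `S`, `P`, `PB`, `voluntary`.
#' @return data frame with one row per group and claim: `group`, `claim`,
#'   `supporting`, `violating`, plus attribute `violations` listing the
#'   offending rows.
#' @export
voluntary_consistency_check <- function(cases) {
  rows <- list()
  viol <- list()
  for (g in unique(cases$group)) {
    cg <- cases[cases$group == g, , drop = FALSE]
    s_pb <- cg[as.logical(cg$S) & as.logical(cg$PB), , drop = FALSE]
    ok1 <- as.logical(s_pb$voluntary)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, claim = "smile_implies_voluntary_pb",
      supporting = sum(ok1), violating = sum(!ok1))
    if (any(!ok1)) viol[[length(viol) + 1L]] <- s_pb[!ok1, , drop = FALSE]
    ns_pb <- cg[!as.logical(cg$S) & as.logical(cg$PB), , drop = FALSE]
    ok2 <- as.logical(ns_pb$P)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, claim = "no_smile_pb_implies_prompt",
      supporting = sum(ok2), violating = sum(!ok2))
    if (any(!ok2)) viol[[length(viol) + 1L]] <- ns_pb[!ok2, , drop = FALSE]
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "violations") <- if (length(viol)) do.call(rbind, viol) else NULL
  res
}
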