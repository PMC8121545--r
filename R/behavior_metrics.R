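#' Outlier filtering of behavioral trial records
#'
#' Two-stage rule on the interval-production latency (`response_time`, in
#' seconds): first, whole participants whose mean response time exceeds
#' `participant_mean_max` are removed; then, remaining single trials with
#' response times above `trial_max` are removed.
#'
#' @param records trial table with at least `participant` and
#'   `response_time` columns.
#' @param participant_mean_max participant-level mean RT ceiling (s).
#' @param trial_max trial-level RT ceiling (s).
#' @return List with `records` (kept rows) and `log`: participants removed,
#'   trials removed with them, and single trials removed afterwards.
#' @export
filter_outliers <- function(records, participant_mean_max = 10,
                            trial_max = 6) {
  need <- c("participant", "response_time")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) {
    warning("empty input; nothing to filter")
    return(list(records = records,
                log = list(participants_removed = character(0),
                           trials_removed_with_participants = 0L,
                           trials_removed_rt = 0L)))
  }
  mean_rt <- tapply(records$response_time, records$participant, mean)
  bad_p <- names(mean_rt)[mean_rt > participant_mean_max]
  keep1 <- !(as.character(records$participant) %in% bad_p)
  n_p_trials <- sum(!keep1)
  kept <- records[keep1, , drop = FALSE]
  keep2 <- kept$response_time <= trial_max
  out <- kept[keep2, , drop = FALSE]
  list(records = out,
       log = list(participants_removed = bad_p,
                  trials_removed_with_participants = n_p_trials,
                  trials_removed_rt = sum(!keep2)))
}

#' Trial-level error signals
#'
#' From produced intervals, predictions and feedback (all on a common ms
#' axis) derives:
#' * `signed_error = produced_interval - target`,
#' * `error_magnitude = |signed_error|`,
#' * `spe = |prediction - feedback|` (sensory prediction error),
#' * `rpe = |prediction| - |feedback|` (reward prediction error; positive
#'   when the outcome is better, i.e. closer to the goal, than predicted),
#' * `improvement = error_magnitude[n-1] - error_magnitude[n]` within each
#'   participant-by-block run (positive = performance improved; `NA` on the
#'   first trial of a block).
#'
#' Rows with missing predictions get `NA` prediction-based signals and a
#' `prediction_missing` flag.
#'
#' @param records trial table with `produced_interval`, `prediction`,
#'   `feedback` and (for the improvement column) `participant`, `block`,
#'   `trial`.
#' @param target target interval in ms.
#' @return `records` with the signal columns appended.
#' @export
compute_error_signals <- function(records, target = 1504) {
  need <- c("produced_interval", "prediction", "feedback")
  if (!all(need %in% names(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  out <- records
  out$signed_error <- records$produced_interval - target
  out$error_magnitude <- abs(out$signed_error)
  out$spe <- abs(records$prediction - records$feedback)
  out$rpe <- abs(records$prediction) - abs(records$feedback)
  out$prediction_missing <- !is.finite(records$prediction)
  if (all(c("participant", "block", "trial") %in% names(records))) {
    ord <- order(out$participant, out$block, out$trial)
    em <- out$error_magnitude[ord]
    run <- interaction(out$participant[ord], out$block[ord], drop = TRUE)
    imp <- c(NA_real_, em[-length(em)] - em[-1L])
    first <- !duplicated(run)
    imp[first] <- NA_real_
    out$improvement <- NA_real_
    out$improvement[ord] <- imp
  }
  out
}

#' Trial-to-trial improvement
#'
#' Difference between the previous and the current error magnitude within a
#' block: positive values mean performance improved.  Undefined (missing)
#' on the first trial of a block.
#'
#' @param em_prev,em_curr error magnitudes of consecutive trials.
#' @return `em_prev - em_curr`.
#' @export
improvement <- function(em_prev, em_curr) em_prev - em_curr

#' Per-participant confidence-calibration index
#'
#' For each participant, the partial correlation between trial-wise
#' confidence and the sensory prediction error, controlling for the
#' participant's block-wise mean error magnitude (expanded to trials),
#' computed by double residualization and then sign-reversed so that higher
#' values mean better calibration (more confidence when predictions are
#' more precise).
#'
#' @param trials table with `participant`, `block`, `confidence`, `spe`,
#'   `error_magnitude`.
#' @param min_trials minimum usable trials per participant.
#' @return Data frame with `participant`, `index`, `n`; participants with
#'   too few trials or zero variance get `NA` with a warning.
#' @export
confidence_calibration <- function(trials, min_trials = 10L) {
  need <- c("participant", "block", "confidence", "spe", "error_magnitude")
  if (!all(need %in% names(trials)))
    stop("trials must contain columns: ", paste(need, collapse = ", "))
  res <- lapply(split(trials, trials$participant), function(d) {
    d <- d[stats::complete.cases(d[c("confidence", "spe")]), , drop = FALSE]
    n <- nrow(d)
    if (n < min_trials) {
      warning("participant ", d$participant[1], ": fewer than ",
              min_trials, " usable trials; index undefined")
      return(data.frame(participant = d$participant[1], index = NA_real_,
                        n = n))
    }
    if (stats::sd(d$confidence) == 0 || stats::sd(d$spe) == 0) {
      warning("participant ", d$participant[1],
              ": zero variance in confidence or SPE; index undefined")
      return(data.frame(participant = d$participant[1], index = NA_real_,
                        n = n))
    }
    block_em <- stats::ave(d$error_magnitude, d$block, FUN = mean)
    rc <- stats::resid(stats::lm(d$confidence ~ block_em))
    rs <- stats::resid(stats::lm(d$spe ~ block_em))
    data.frame(participant = d$participant[1],
               index = -stats::cor(rc, rs), n = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Scale and center regression predictors
#'
#' Applies the analysis-ready predictor transformation: `error_magnitude`,
#' `rpe` and `spe` are rescaled from ms to seconds; `confidence` (assumed
#' on \[0, 1\]) and `block` (assumed `1..n_blocks`) are affinely mapped to
#' \[-1, 1\]; `block`, `error_magnitude`, `confidence` and `spe` are then
#' centered on their medians.  `rpe` is *not* centered, since zero (outcome
#' exactly as predicted) is meaningful on its scale.
#'
#' @param table trial table containing the five columns above.
#' @param n_blocks number of blocks spanned by the `block` column.
#' @return The table with transformed columns (same names).
#' @export
scale_predictors <- function(table, n_blocks = 5L) {
  need <- c("error_magnitude", "rpe", "spe", "confidence", "block")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  table$error_magnitude <- table$error_magnitude / 1000
  table$rpe <- table$rpe / 1000
  table$spe <- table$spe / 1000
  table$confidence <- 2 * table$confidence - 1
  table$block <- 2 * (table$block - 1) / (n_blocks - 1) - 1
  for (col in c("block", "error_magnitude", "confidence", "spe"))
    table[[col]] <- table[[col]] - stats::median(table[[col]], na.rm = TRUE)
  table
}

#' Log-transformed error magnitude with a zero guard
#'
#' Natural log of the trial-wise error magnitude (ms); exact zeros are
#' replaced by half the smallest positive value before taking logs.
#'
#' @param em error magnitudes (ms, non-negative).
#' @return `log(em)` with the zero guard applied.
#' @export
log_error_magnitude <- function(em) {
  if (any(em < 0, na.rm = TRUE)) stop("error magnitude must be >= 0")
  pos <- em[em > 0 & is.finite(em)]
  if (length(pos) == 0L) stop("no positive error magnitudes")
  em[em == 0] <- min(pos) / 2
  log(em)
}

#' Fixed-effects trial-level regression
#'
#' Least-squares fit of a model formula on the (scaled) trial table, with
#' an optional per-participant fixed-intercept adjustment.  This is the
#' package's generic regression contract for trial-wise analyses (full
#' random-slope mixed models are out of scope).
#'
#' @param table scaled trial table.
#' @param formula model formula, e.g. `p3a ~ confidence + block + spe +
#'   rpe + error_magnitude`.
#' @param grouping `"none"` or `"participant"` (adds participant
#'   fixed-intercepts).
#' @return List of class `trial_model` with `coefficients` (term, estimate,
#'   se, t, p), `r_squared` and the underlying `lm` fit.
#' @export
fit_trial_model <- function(table, formula,
                            grouping = c("none", "participant")) {
  grouping <- match.arg(grouping)
  if (grouping == "participant") {
    if (!"participant" %in% names(table))
      stop("grouping = 'participant' requires a participant column")
    formula <- stats::update(formula, . ~ . + factor(participant))
  }
  fit <- stats::lm(formula, data = table)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient model; collinear terms: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1],
                              se = sm[, 2], t = sm[, 3], p = sm[, 4],
                              row.names = NULL),
    r_squared = summary(fit)$r.squared,
    fit = fit), class = "trial_model")
}

#' @export
print.trial_model <- function(x, ...) {
  cat("<trial_model> R^2 =", round(x$r_squared, 4), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}
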