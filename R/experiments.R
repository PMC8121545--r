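#' Compare the three agent variants under common random numbers
#'
#' Runs `n_agents` independent agents of each variant (full with a given
#' `cc`, average-confidence, feedback-only) on the same task, reusing the
#' same per-agent noise streams across variants, and summarizes trial-wise
#' learning curves of the absolute target and scale estimation errors.
#'
#' @param n_agents number of agents per variant (>= 2 for SEMs).
#' @param task a [task_config()].
#' @param seed integer master seed; agent seeds are derived from it.
#' @param cc confidence calibration of the full variant.
#' @return An object of class `sim_summary`: list with
#'   `summary` (variant x trial means and SEMs of `target_error` and
#'   `scale_error`), `trajectories` (per-trial records of all runs, with
#'   `em_response = |r - t_true|`), and the call settings.
#' @export
run_model_comparison <- function(n_agents = 200L, task = task_config(),
                                 seed = 1L, cc = 1) {
  if (n_agents < 1L) stop("n_agents must be >= 1")
  if (n_agents < 2L) warning("n_agents < 2: SEMs are undefined")
  set.seed(seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n_agents)
  variants <- c("full", "average_confidence", "feedback_only")
  traj <- vector("list", length(variants) * n_agents)
  idx <- 0L
  for (v in variants) {
    for (a in seq_len(n_agents)) {
      ag <- agent_config(v, cc = cc, sigma_r = task$sigma_r,
                         sigma_c_levels = task$sigma_c_levels,
                         rng_seed = agent_seeds[a])
      d <- run_agent(ag, task)
      d$variant <- v; d$agent <- a
      d$em_response <- abs(d$r - task$t_true)
      idx <- idx + 1L
      traj[[idx]] <- d
    }
  }
  traj <- data.table::rbindlist(traj)
  summ <- traj[, list(mean_target_error = mean(target_error),
                      sem_target_error = .sem(target_error),
                      mean_scale_error = mean(scale_error),
                      sem_scale_error = .sem(scale_error)),
               by = c("variant", "trial")]
  structure(list(summary = as.data.frame(summ),
                 trajectories = as.data.frame(traj),
                 n_agents = n_agents, seed = seed, cc = cc, task = task),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  s <- x$summary
  fin <- s[s$trial == max(s$trial), ]
  cat("<sim_summary>", x$n_agents, "agents x", max(s$trial), "trials\n")
  for (i in seq_len(nrow(fin)))
    cat(sprintf("  %-20s final target error %6.2f  scale error %6.2f\n",
                fin[[1]][i], fin$mean_target_error[i],
                fin$mean_scale_error[i]))
  invisible(x)
}

#' Confidence-calibration sweep of the full agent
#'
#' Runs the full variant at each calibration level under common random
#' numbers and summarizes learning curves, plus the mean absolute response
#' error (`|r - t_true|`) over the final `final_window` trials per level.
#'
#' @param cc_levels calibration probabilities to sweep.
#' @param n_agents agents per level.
#' @param task a [task_config()].
#' @param seed master seed.
#' @param final_window number of trailing trials for the end-state summary.
#' @return A `sim_summary` whose `summary` is keyed by `cc` and which
#'   carries `final_em`: mean response error per calibration level.
#' @export
run_cc_sweep <- function(cc_levels = c(0, 0.75, 1), n_agents = 200L,
                         task = task_config(), seed = 1L,
                         final_window = 50L) {
  set.seed(seed)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n_agents)
  traj <- vector("list", length(cc_levels) * n_agents)
  idx <- 0L
  for (cc in cc_levels) {
    for (a in seq_len(n_agents)) {
      ag <- agent_config("full", cc = cc, sigma_r = task$sigma_r,
                         sigma_c_levels = task$sigma_c_levels,
                         rng_seed = agent_seeds[a])
      d <- run_agent(ag, task)
      d$cc <- cc; d$agent <- a
      d$em_response <- abs(d$r - task$t_true)
      idx <- idx + 1L
      traj[[idx]] <- d
    }
  }
  traj <- data.table::rbindlist(traj)
  summ <- traj[, list(mean_target_error = mean(target_error),
                      sem_target_error = .sem(target_error),
                      mean_scale_error = mean(scale_error),
                      sem_scale_error = .sem(scale_error)),
               by = c("cc", "trial")]
  last <- traj[traj$trial > task$n_trials - final_window, ]
  final_em <- last[, list(mean_em = mean(em_response)), by = "cc"]
  structure(list(summary = as.data.frame(summ),
                 trajectories = as.data.frame(traj),
                 final_em = as.data.frame(final_em),
                 n_agents = n_agents, seed = seed, task = task),
            class = "sim_summary")
}

#' Confidence-conditional coupling of predictions and feedback
#'
#' Ordinary least-squares slope of feedback on predicted outcome within
#' each confidence stratum.  Higher slopes at higher confidence indicate
#' that predictions made with high confidence track actual outcomes more
#' tightly.
#'
#' @param trajectories data frame with columns `po`, `f`, `co`.
#' @return Data frame with one row per confidence level: `co`, `slope`,
#'   `se`, `n`.  Strata with fewer than 3 usable trials are omitted with a
#'   warning.
#' @export
prediction_feedback_coupling <- function(trajectories) {
  need <- c("po", "f", "co")
  if (!all(need %in% names(trajectories)))
    stop("trajectories must contain columns: ", paste(need, collapse = ", "))
  d <- trajectories[stats::complete.cases(trajectories[need]), need]
  out <- lapply(sort(unique(d$co)), function(lvl) {
    di <- d[d$co == lvl, ]
    if (nrow(di) < 3L) {
      warning("confidence level ", lvl, " has < 3 trials; slope omitted")
      return(NULL)
    }
    fit <- stats::lm(f ~ po, data = di)
    data.frame(co = lvl, slope = unname(coef(fit)["po"]),
               se = sqrt(diag(stats::vcov(fit)))[["po"]], n = nrow(di))
  })
  do.call(rbind, out)
}

#' Shannon-surprise grid over prediction errors and predictive precision
#'
#' Surprise about an outcome is its Shannon information under a Gaussian
#' predictive distribution centred on the prediction:
#' `surprise(spe, sigma) = -log N(spe; 0, sigma^2)`.  Narrower predictive
#' distributions (higher confidence) make a given sensory prediction error
#' more surprising.
#'
#' @param spe_axis outcome deviations from the prediction.
#' @param sigma predictive SDs (confidence proxy; smaller = more
#'   confident).  All must be positive.
#' @return Object of class `surprise_grid`: list with the two axes, the
#'   surprise matrix (`length(spe_axis) x length(sigma)`) and the marginal
#'   means along each axis.
#' @export
shannon_surprise_grid <- function(spe_axis = seq(-50, 50, length.out = 101),
                                  sigma = c(5, 10, 20)) {
  if (any(sigma <= 0)) stop("sigma must be > 0")
  surprise <- -vapply(sigma,
                      function(s) stats::dnorm(spe_axis, 0, s, log = TRUE),
                      numeric(length(spe_axis)))
  structure(list(spe_axis = spe_axis, sigma = sigma, surprise = surprise,
                 spe_marginal = rowMeans(surprise),
                 sigma_marginal = colMeans(surprise)),
            class = "surprise_grid")
}

#' @export
print.surprise_grid <- function(x, ...) {
  cat("<surprise_grid>", length(x$spe_axis), "SPE values x",
      length(x$sigma), "precisions; marginal mean by sigma:",
      paste(sprintf("%.2f", x$sigma_marginal), collapse = ", "), "\n")
  invisible(x)
}
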