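#' Time-estimation task configuration
#'
#' Parameters of the simulated time-estimation environment.  The true target
#' interval `t_true` and feedback scale `s_true` are unknown to the learning
#' agent; feedback is the scaled signed deviation of the executed response
#' from the target.  Units are abstract "model units": the defaults place the
#' target at 19 with a feedback scale of 90 and response-noise SD of 10.
#'
#' @param t_true true target interval (model units).
#' @param s_true true feedback scale; must be positive.
#' @param sigma_r response-noise standard deviation.
#' @param sigma_c_levels strictly increasing positive efference-copy noise
#'   SDs; one level is drawn uniformly at random on each trial.
#' @param n_trials number of trials per agent run.
#' @param rng_seed integer seed used by [run_agent()] when the agent config
#'   does not carry one.
#' @return An object of class `task_config`.
#' @export
task_config <- function(t_true = 19, s_true = 90, sigma_r = 10,
                        sigma_c_levels = c(5, 10, 20), n_trials = 250,
                        rng_seed = 1L) {
  stopifnot(is.numeric(t_true), length(t_true) == 1L, is.finite(t_true))
  if (!is.numeric(s_true) || s_true <= 0) stop("s_true must be > 0")
  if (!is.numeric(sigma_r) || sigma_r <= 0) stop("sigma_r must be > 0")
  if (length(sigma_c_levels) < 1L || any(sigma_c_levels <= 0) ||
      is.unsorted(sigma_c_levels, strictly = TRUE))
    stop("sigma_c_levels must be positive and strictly increasing")
  if (n_trials < 1L) stop("n_trials must be >= 1")
  structure(
    list(t_true = t_true, s_true = s_true, sigma_r = sigma_r,
         sigma_c_levels = as.numeric(sigma_c_levels),
         n_trials = as.integer(n_trials), rng_seed = as.integer(rng_seed)),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> target", x$t_true, "| scale", x$s_true,
      "| sigma_r", x$sigma_r,
      "| sigma_c {", paste(x$sigma_c_levels, collapse = ", "), "}",
      "|", x$n_trials, "trials\n")
  invisible(x)
}

#' Feedback from an executed response
#'
#' Feedback is the signed deviation of the executed response `r` from the
#' target `t`, multiplied by the feedback scale `s`: `f = (r - t) * s`.
#' Negative values encode undershoots, positive values overshoots.
#'
#' @param r executed response(s).
#' @param t target interval.
#' @param s feedback scale, positive.
#' @return Feedback value(s), same length as `r`.
#' @export
generate_feedback <- function(r, t, s) {
  .assert_finite(r, "r"); .assert_finite(t, "t"); .assert_finite(s, "s")
  if (any(s <= 0)) stop("feedback scale s must be > 0")
  (r - t) * s
}

#' Sample an executed response
#'
#' One draw per intended response from `Normal(i, sigma_r^2)`.  `sigma_r = 0`
#' is accepted as the degenerate limit (the intention is executed exactly).
#'
#' @param i intended response(s).
#' @param sigma_r response-noise SD, `>= 0`.
#' @return Executed response(s).
#' @export
sample_response <- function(i, sigma_r) {
  if (!is.numeric(sigma_r) || any(sigma_r < 0)) stop("sigma_r must be >= 0")
  .assert_finite(i, "i")
  i + sigma_r * stats::rnorm(length(i))
}

#' Sample an efference copy of an executed response
#'
#' One draw per response from `Normal(r, sigma_c^2)`: the internal, noisy
#' readout of what was actually done.  `sigma_c = 0` gives the perfect-copy
#' limit.
#'
#' @param r executed response(s).
#' @param sigma_c efference-copy noise SD, `>= 0`.
#' @return Efference copy value(s).
#' @export
sample_efference_copy <- function(r, sigma_c) {
  if (!is.numeric(sigma_c) || any(sigma_c < 0)) stop("sigma_c must be >= 0")
  .assert_finite(r, "r")
  r + sigma_c * stats::rnorm(length(r))
}

#' Draw trial-wise efference-copy noise levels
#'
#' Uniform categorical draw over the configured noise levels (each level has
#' probability `1/k`), i.i.d. across trials.
#'
#' @param levels non-empty vector of noise SDs.
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_sigma_c_level <- function(levels, n = 1L) {
  if (length(levels) < 1L) stop("levels must be non-empty")
  levels[sample.int(length(levels), n, replace = TRUE)]
}
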