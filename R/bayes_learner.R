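#' Uniform prior belief over target and scale
#'
#' The agent's belief state is a joint probability table over candidate
#' target intervals `t` and feedback scales `s`, held on a fixed lattice:
#' by default 100 evenly spaced `t` values on \[0, 100\] crossed with 50
#' evenly spaced `s` values on \[0.1, 100\] (endpoints included).  The prior
#' is uniform, weight `1/(n_t * n_s)` per cell.
#'
#' @param n_t,n_s grid sizes for target and scale.
#' @param t_range,s_range inclusive grid spans.
#' @return An object of class `posterior_grid` with elements `t_values`,
#'   `s_values` and the `n_t x n_s` probability matrix `prob`.
#' @export
init_prior <- function(n_t = 100L, n_s = 50L,
                       t_range = c(0, 100), s_range = c(0.1, 100)) {
  stopifnot(n_t >= 2L, n_s >= 2L,
            t_range[2] > t_range[1], s_range[2] > s_range[1])
  grid <- list(
    t_values = seq(t_range[1], t_range[2], length.out = n_t),
    s_values = seq(s_range[1], s_range[2], length.out = n_s),
    prob = matrix(1 / (n_t * n_s), n_t, n_s))
  class(grid) <- "posterior_grid"
  grid
}

#' @export
print.posterior_grid <- function(x, ...) {
  m <- posterior_means(x)
  cat("<posterior_grid>", length(x$t_values), "x", length(x$s_values),
      sprintf("cells | E[t] = %.3f, E[s] = %.3f\n", m["t"], m["s"]))
  invisible(x)
}

.check_grid <- function(grid, tol = 1e-8) {
  if (!inherits(grid, "posterior_grid")) stop("not a posterior_grid")
  if (abs(sum(grid$prob) - 1) > tol)
    stop("posterior grid is not normalized (sum = ", sum(grid$prob), ")")
  invisible(grid)
}

#' Posterior marginals and means
#'
#' @param grid a `posterior_grid`.
#' @return `posterior_marginals()`: list with marginal weight vectors `t`
#'   and `s`.  `posterior_means()`: named vector with expectations of `t`
#'   and `s` under those marginals.
#' @export
posterior_marginals <- function(grid) {
  .check_grid(grid)
  list(t = rowSums(grid$prob), s = colSums(grid$prob))
}

#' @rdname posterior_marginals
#' @export
posterior_means <- function(grid) {
  m <- posterior_marginals(grid)
  c(t = sum(m$t * grid$t_values), s = sum(m$s * grid$s_values))
}

#' Intended response: expected target under the current belief
#'
#' @param grid normalized `posterior_grid`.
#' @return Expectation of the target interval under the `t` marginal.
#' @export
intended_response <- function(grid) {
  unname(posterior_means(grid)["t"])
}

#' Expected feedback scale under the current belief
#'
#' @param grid normalized `posterior_grid`.
#' @return Expectation of the scale under the `s` marginal.
#' @export
expected_scale <- function(grid) {
  unname(posterior_means(grid)["s"])
}

#' Agent configuration
#'
#' Three agent variants are supported: `"full"` (performance monitoring with
#' trial-wise efference-copy precision), `"average_confidence"` (uses the
#' efference copy, but only the average noise level, so all predictions are
#' treated as average-precise) and `"feedback_only"` (ignores the efference
#' copy altogether; expected feedback-generating response is the intention
#' with variance `sigma_r^2`).
#'
#' Confidence calibration `cc` is the probability that, on a given trial,
#' the full agent assumes the *true* efference-copy noise level; with
#' probability `1 - cc` it assumes one of the other levels, uniformly.
#'
#' @param variant one of `"full"`, `"average_confidence"`, `"feedback_only"`.
#' @param cc confidence-calibration probability in \[0, 1\].
#' @param sigma_r response-noise SD assumed (and true) for the agent.
#' @param sigma_c_levels the efference-copy noise levels.
#' @param avg_sigma_c subjective noise SD used by the
#'   `"average_confidence"` variant; default `NULL` means the exact level
#'   mean (`mean(sigma_c_levels)`, i.e. 35/3 for the default levels).  A
#'   rounded value such as 12 may be supplied instead.
#' @param rng_seed integer seed for [run_agent()].
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(variant = c("full", "average_confidence",
                                     "feedback_only"),
                         cc = 1, sigma_r = 10,
                         sigma_c_levels = c(5, 10, 20),
                         avg_sigma_c = NULL, rng_seed = 1L) {
  variant <- match.arg(variant)
  if (!is.numeric(cc) || cc < 0 || cc > 1) stop("cc must lie in [0, 1]")
  if (sigma_r <= 0) stop("sigma_r must be > 0")
  if (any(sigma_c_levels <= 0) ||
      is.unsorted(sigma_c_levels, strictly = TRUE))
    stop("sigma_c_levels must be positive and strictly increasing")
  if (is.null(avg_sigma_c)) avg_sigma_c <- mean(sigma_c_levels)
  if (avg_sigma_c <= 0) stop("avg_sigma_c must be > 0")
  structure(
    list(variant = variant, cc = cc, sigma_r = sigma_r,
         sigma_c_levels = as.numeric(sigma_c_levels),
         avg_sigma_c = avg_sigma_c, rng_seed = as.integer(rng_seed)),
    class = "agent_config")
}

#' @export
print.agent_config <- function(x, ...) {
  cat("<agent_config>", x$variant, "| cc =", x$cc,
      "| sigma_r =", x$sigma_r, "\n")
  invisible(x)
}

# deterministic core of subjective_sigma_c given uniform draws
.subjective_sigma_c <- function(sigma_c_true, cc, levels, u_cal, u_wrong) {
  k <- length(levels)
  if (cc < 1 && k < 2L)
    stop("cc < 1 requires at least two noise levels (no wrong level exists)")
  if (u_cal < cc) return(sigma_c_true)
  others <- levels[levels != sigma_c_true]
  others[ceiling(u_wrong * length(others))]
}

#' Subjectively assumed efference-copy noise level
#'
#' With probability `cc` the agent assumes the true trial-wise noise level;
#' otherwise it assumes one of the other configured levels, drawn uniformly.
#'
#' @param sigma_c_true the true level on this trial (must be in `levels`).
#' @param cc calibration probability in \[0, 1\].
#' @param levels the configured noise levels.
#' @return The subjectively assumed noise SD.
#' @export
subjective_sigma_c <- function(sigma_c_true, cc, levels) {
  if (cc < 0 || cc > 1) stop("cc must lie in [0, 1]")
  if (!sigma_c_true %in% levels) stop("sigma_c_true is not a configured level")
  .subjective_sigma_c(sigma_c_true, cc, levels,
                      stats::runif(1), stats::runif(1))
}

#' Confidence report from the assumed efference-copy precision
#'
#' Confidence is the rank of the assumed precision: the smallest noise level
#' maps to the highest report.  With the default levels `{5, 10, 20}` this is
#' the mapping 5 -> 3, 10 -> 2, 20 -> 1.
#'
#' @param sigma_c_subjective assumed noise SD; must be one of `levels`.
#' @param levels the configured (strictly increasing) noise levels.
#' @return Integer confidence report in `1..length(levels)`.
#' @export
confidence_report <- function(sigma_c_subjective, levels = c(5, 10, 20)) {
  idx <- match(sigma_c_subjective, levels)
  if (anyNA(idx)) stop("sigma_c_subjective outside the level set; ",
                       "confidence mapping undefined")
  length(levels) + 1L - idx
}

#' Predicted outcome on the feedback scale
#'
#' Maps the discrepancy between efference copy and intended response onto
#' the feedback scale using the current expected scale:
#' `po = (c - i) * E[s]`.  Must be computed from the pre-update belief of
#' the current trial.
#'
#' @param c_copy efference copy.
#' @param i intended response.
#' @param grid pre-feedback belief state.
#' @return Predicted outcome in feedback-scale units.
#' @export
predicted_outcome <- function(c_copy, i, grid) {
  (c_copy - i) * expected_scale(grid)
}

#' Precision-weighted fusion of intention and efference copy
#'
#' Combines the intended response `i` (reliability `1/sigma_r^2`) with the
#' efference copy `c_copy` (reliability `1/sigma_c^2`) into the expected
#' feedback-generating response `m` and its variance `v`:
#' `v = 1 / (1/sigma_c^2 + 1/sigma_r^2)`, `m = v * (c/sigma_c^2 + i/sigma_r^2)`.
#'
#' The `"average_confidence"` variant substitutes `avg_sigma_c` for the
#' trial-wise level; the `"feedback_only"` variant ignores the efference
#' copy entirely (`m = i`, `v = sigma_r^2`).
#'
#' @param c_copy efference copy (may be `NA` for `"feedback_only"`).
#' @param i intended response.
#' @param sigma_c trial-wise assumed efference-copy noise SD.
#' @param sigma_r response-noise SD.
#' @param variant agent variant, see [agent_config()].
#' @param avg_sigma_c fixed subjective SD for `"average_confidence"`.
#' @return List with elements `m` and `v`.
#' @export
fuse <- function(c_copy, i, sigma_c, sigma_r, variant = "full",
                 avg_sigma_c = NULL) {
  if (sigma_r <= 0) stop("sigma_r must be > 0")
  if (variant == "feedback_only")
    return(list(m = i, v = sigma_r^2))
  if (variant == "average_confidence") {
    if (is.null(avg_sigma_c)) stop("avg_sigma_c required for this variant")
    sigma_c <- avg_sigma_c
  }
  if (!is.finite(sigma_c) || sigma_c <= 0) stop("sigma_c must be > 0")
  v <- 1 / (1 / sigma_c^2 + 1 / sigma_r^2)
  m <- v * (c_copy / sigma_c^2 + i / sigma_r^2)
  list(m = m, v = v)
}

# log-likelihood of feedback f over all grid cells; cache carries the
# precomputed cell matrices for the hot loop in run_agent()
.loglik_grid <- function(f, m, v, grid, cache = NULL) {
  if (v <= 0) stop("v must be > 0")
  if (is.null(cache)) cache <- .grid_cache(grid)
  mu <- m * cache$S - cache$TS           # per-cell mean (m - t) * s
  -0.5 * (log(2 * pi * v) + cache$logS2 + (f - mu)^2 / (v * cache$S2))
}

.grid_cache <- function(grid) {
  nt <- length(grid$t_values); ns <- length(grid$s_values)
  S <- matrix(grid$s_values, nt, ns, byrow = TRUE)
  list(S = S, S2 = S^2, logS2 = 2 * log(S),
       TS = outer(grid$t_values, grid$s_values))
}

#' Likelihood of observed feedback over the belief grid
#'
#' For each cell `(t, s)`, the density of the feedback under
#' `Normal((m - t) * s, v * s^2)`: since `f = (r - t) * s`, uncertainty `v`
#' about the feedback-generating response scales to variance `v * s^2` on
#' the feedback axis.
#'
#' @param f observed feedback.
#' @param m expected feedback-generating response (from [fuse()]).
#' @param v expected response variance (from [fuse()]).
#' @param grid the belief grid (supplies the cell values).
#' @param log if `TRUE` return log densities.
#' @return Matrix of (log) densities, one entry per grid cell.
#' @export
likelihood_over_grid <- function(f, m, v, grid, log = FALSE) {
  ll <- .loglik_grid(f, m, v, grid)
  if (log) ll else exp(ll)
}

#' Bayesian belief update
#'
#' Cellwise product of prior weights and likelihood, renormalized to sum 1.
#' The likelihood is internally shifted by its maximum before use so that a
#' well-scaled update never underflows; if every cell still underflows the
#' update is degenerate and an error is thrown (callers may retain the prior
#' for that trial, see [run_trial()]).
#'
#' @param grid prior `posterior_grid`.
#' @param likelihood per-cell likelihood weights (natural scale), same shape
#'   as `grid$prob`.
#' @return The updated, normalized `posterior_grid`.
#' @export
update_posterior <- function(grid, likelihood) {
  .check_grid(grid)
  if (!all(dim(likelihood) == dim(grid$prob)))
    stop("likelihood shape does not match the grid")
  if (any(likelihood < 0) || any(!is.finite(likelihood)))
    stop("likelihood must be finite and non-negative")
  mx <- max(likelihood)
  if (mx <= 0) stop("degenerate update: all-zero likelihood")
  w <- grid$prob * (likelihood / mx)
  z <- sum(w)
  if (z <= 0 || !is.finite(z)) stop("degenerate update: posterior underflow")
  grid$prob <- w / z
  grid
}

# same update from log-likelihoods (hot path)
.update_log <- function(grid, loglik) {
  w <- grid$prob * exp(loglik - max(loglik))
  z <- sum(w)
  if (z <= 0 || !is.finite(z)) return(NULL)  # degenerate
  grid$prob <- w / z
  grid
}

#' Simulate one trial of the learning agent
#'
#' Executes, in order: intended response from the current belief; response
#' sampling; efference-copy noise-level draw; efference-copy sampling;
#' subjective noise level (calibration); confidence report; outcome
#' prediction (from the *pre-update* belief); feedback generation from the
#' task truth; precision-weighted fusion; likelihood evaluation; posterior
#' update.  A degenerate update (total underflow) retains the prior and is
#' flagged in the output.
#'
#' @param grid current normalized belief.
#' @param agent an [agent_config()].
#' @param task a [task_config()].
#' @param draws optional list of pre-drawn noise (`z_r`, `lev_idx`, `z_c`,
#'   `u_cal`, `u_wrong`), used by [run_agent()] to give all variants common
#'   random numbers; by default drawn from the current RNG stream.
#' @param cache internal grid cache (precomputed cell matrices).
#' @return List with `output` (named list: `i`, `r`, `c`, `sigma_c_true`,
#'   `sigma_c_subjective`, `co`, `po`, `f`, `t_hat`, `s_hat`,
#'   `target_error`, `scale_error`, `degenerate`) and the updated `grid`.
#' @export
run_trial <- function(grid, agent, task, draws = NULL, cache = NULL) {
  if (is.null(draws)) {
    k <- length(agent$sigma_c_levels)
    draws <- list(z_r = stats::rnorm(1), lev_idx = sample.int(k, 1L),
                  z_c = stats::rnorm(1), u_cal = stats::runif(1),
                  u_wrong = stats::runif(1))
  }
  if (is.null(cache)) cache <- .grid_cache(grid)
  .check_grid(grid)

  pre <- posterior_means(grid)
  i <- unname(pre["t"]); s_hat_pre <- unname(pre["s"])
  r <- i + agent$sigma_r * draws$z_r
  sigma_c_true <- agent$sigma_c_levels[draws$lev_idx]
  c_copy <- r + sigma_c_true * draws$z_c

  variant <- agent$variant
  if (variant == "full") {
    sig_sub <- .subjective_sigma_c(sigma_c_true, agent$cc,
                                   agent$sigma_c_levels,
                                   draws$u_cal, draws$u_wrong)
    co <- confidence_report(sig_sub, agent$sigma_c_levels)
    po <- (c_copy - i) * s_hat_pre
    c_rec <- c_copy
  } else if (variant == "average_confidence") {
    sig_sub <- agent$avg_sigma_c
    co <- NA_integer_                     # no trial-wise confidence
    po <- (c_copy - i) * s_hat_pre
    c_rec <- c_copy
  } else {                                # feedback_only: copy never used
    sig_sub <- NA_real_
    co <- NA_integer_
    po <- NA_real_
    c_rec <- NA_real_
  }

  f <- generate_feedback(r, task$t_true, task$s_true)
  fu <- fuse(c_copy, i, sig_sub, agent$sigma_r, variant = variant,
             avg_sigma_c = agent$avg_sigma_c)
  ll <- .loglik_grid(f, fu$m, fu$v, grid, cache)
  upd <- .update_log(grid, ll)
  degenerate <- is.null(upd)
  if (!degenerate) grid <- upd

  post <- posterior_means(grid)
  list(output = list(
         i = i, r = r, c = c_rec, sigma_c_true = sigma_c_true,
         sigma_c_subjective = sig_sub, co = co, po = po, f = f,
         t_hat = unname(post["t"]), s_hat = unname(post["s"]),
         target_error = abs(post["t"] - task$t_true),
         scale_error = abs(post["s"] - task$s_true),
         degenerate = degenerate),
       grid = grid)
}

#' Simulate a full agent run
#'
#' Runs `task$n_trials` sequential trials with the recursive prior (each
#' trial's posterior is the next trial's prior), starting from the uniform
#' prior of [init_prior()].  All noise streams (response, noise level,
#' efference copy, calibration) are pre-drawn from a single seed in a fixed
#' order, so different agent variants given the same seed experience common
#' random numbers.
#'
#' @param agent an [agent_config()].
#' @param task a [task_config()].
#' @param grid optional starting belief (default: uniform prior).
#' @return A `data.frame` with one row per trial and columns `trial`, `i`,
#'   `r`, `c`, `sigma_c_true`, `sigma_c_subjective`, `co`, `po`, `f`,
#'   `t_hat`, `s_hat`, `target_error`, `scale_error`, `degenerate`.
#' @export
run_agent <- function(agent, task, grid = NULL) {
  n <- task$n_trials
  k <- length(agent$sigma_c_levels)
  seed <- if (!is.null(agent$rng_seed)) agent$rng_seed else task$rng_seed
  set.seed(seed)
  z_r <- stats::rnorm(n)
  lev_idx <- sample.int(k, n, replace = TRUE)
  z_c <- stats::rnorm(n)
  u_cal <- stats::runif(n)
  u_wrong <- stats::runif(n)

  if (is.null(grid)) grid <- init_prior()
  cache <- .grid_cache(grid)
  cols <- c("i", "r", "c", "sigma_c_true", "sigma_c_subjective", "co",
            "po", "f", "t_hat", "s_hat", "target_error", "scale_error",
            "degenerate")
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (tr in seq_len(n)) {
    step <- run_trial(grid, agent, task,
                      draws = list(z_r = z_r[tr], lev_idx = lev_idx[tr],
                                   z_c = z_c[tr], u_cal = u_cal[tr],
                                   u_wrong = u_wrong[tr]),
                      cache = cache)
    grid <- step$grid
    out[tr, ] <- unlist(step$output, use.names = FALSE)
  }
  res <- as.data.frame(out)
  res$degenerate <- as.logical(res$degenerate)
  res$co <- as.integer(res$co)
  cbind(trial = seq_len(n), res)
}
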