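test_that("the uniform prior has the stated cell weights and moments", {
  g <- init_prior()
  expect_equal(dim(g$prob), c(100L, 50L))
  expect_true(all(g$prob == 2e-4))
  expect_equal(posterior_marginals(g)$t, rep(1 / 100, 100))
  expect_equal(intended_response(g), 50)
  expect_equal(range(g$t_values), c(0, 100))
  expect_equal(range(g$s_values), c(0.1, 100))
})

test_that("belief expectations follow the marginals", {
  g2 <- toy_grid(c(10, 30), c(1, 3),
                 prob = matrix(c(0.125, 0.375, 0.125, 0.375), 2, 2))
  expect_equal(intended_response(g2), 25)  # {10: .25, 30: .75}
  pm <- point_mass_grid(c(10, 19, 30), c(50, 90), 19, 90)
  expect_equal(intended_response(pm), 19)
  expect_equal(expected_scale(pm), 90)
  g3 <- toy_grid(5, c(1, 3))
  expect_equal(expected_scale(g3), 2)
  bad <- toy_grid(c(1, 2), c(1, 2)); bad$prob <- bad$prob * 2
  expect_error(intended_response(bad), "not normalized")
})

test_that("calibration controls how often the true noise level is assumed", {
  levels <- c(5, 10, 20)
  set.seed(21)
  expect_identical(subjective_sigma_c(10, 1, levels), 10)
  none_true <- replicate(200, subjective_sigma_c(10, 0, levels))
  expect_false(any(none_true == 10))
  expect_true(all(none_true %in% c(5, 20)))
  hits <- replicate(1e5, subjective_sigma_c(5, 0.75, levels) == 5)
  expect_lt(abs(mean(hits) - 0.75), 0.01)
  expect_error(subjective_sigma_c(10, 0.5, levels = 10), "at least two")
  expect_error(subjective_sigma_c(7, 1, levels), "not a configured level")
})

test_that("confidence is the rank of the assumed precision", {
  expect_identical(confidence_report(5), 3L)
  expect_identical(confidence_report(10), 2L)
  expect_identical(confidence_report(20), 1L)
  expect_error(confidence_report(12), "undefined")
})

test_that("the predicted outcome maps the copy-intention gap to the scale", {
  pm <- point_mass_grid(c(10, 19, 30), c(50, 90), 19, 90)
  expect_equal(predicted_outcome(25, 20, pm), 450)
  expect_equal(predicted_outcome(20, 20, pm), 0)
  g1 <- point_mass_grid(c(10, 20), c(1, 2), 20, 1)
  expect_equal(predicted_outcome(18, 20, g1), -2)
})

test_that("fusion is precision weighting with the documented variants", {
  fu <- fuse(30, 20, 10, 10)
  expect_equal(fu$m, 25)
  expect_equal(fu$v, 50)
  # sigma_c -> 0 limit: copy dominates
  fu0 <- fuse(30, 20, 1e-6, 10)
  expect_lt(abs(fu0$m - 30), 1e-9)
  expect_lt(fu0$v, 1e-11)
  # feedback-only ignores the copy entirely
  fb <- fuse(NA, 20, NA, 10, variant = "feedback_only")
  expect_equal(fb$m, 20)
  expect_equal(fb$v, 100)
  # average-confidence substitutes the level mean
  av <- fuse(30, 20, 5, 10, variant = "average_confidence",
             avg_sigma_c = 35 / 3)
  expect_equal(av$v, 1 / (1 / (35 / 3)^2 + 1 / 100))
  expect_error(fuse(30, 20, -1, 10), "sigma_c")
  expect_error(fuse(30, 20, 10, 0), "sigma_r")
})

test_that("fusion is consistent: v bounded by both precisions, m between", {
  set.seed(5)
  for (k in 1:50) {
    cc <- rnorm(1, 20, 15); ii <- rnorm(1, 20, 15)
    sc <- runif(1, 0.5, 30); sr <- runif(1, 0.5, 30)
    fu <- fuse(cc, ii, sc, sr)
    expect_lte(fu$v, min(sc^2, sr^2) + 1e-12)
    expect_gte(fu$m, min(cc, ii) - 1e-12)
    expect_lte(fu$m, max(cc, ii) + 1e-12)
  }
})

test_that("the grid likelihood matches the per-cell Gaussian density", {
  g <- toy_grid(c(18, 19, 20), c(80, 90))
  lik <- likelihood_over_grid(90, m = 20, v = 50, g)
  # cell (t = 19, s = 90): Normal(mean 90, var 50 * 90^2) at f = 90
  expect_equal(lik[2, 2], 1 / sqrt(2 * pi * 405000), tolerance = 1e-12)
  expect_equal(lik[2, 2], 6.266e-4, tolerance = 1e-3)
  # f at the cell mean maximizes the likelihood over f
  f_axis <- seq(0, 200, by = 5)
  dens <- vapply(f_axis, function(f)
    likelihood_over_grid(f, 20, 50, g)[2, 2], numeric(1))
  expect_equal(f_axis[which.max(dens)], 90)
  # doubling s at fixed (m - t) rescales mean and SD: density halves
  gs <- toy_grid(19, c(45, 90))
  d1 <- likelihood_over_grid(45 * 1, 20, 50, gs)[1, 1]
  d2 <- likelihood_over_grid(90 * 1, 20, 50, gs)[1, 2]
  expect_equal(d2, d1 / 2, tolerance = 1e-12)
  expect_error(likelihood_over_grid(90, 20, -1, g), "v must be > 0")
})

test_that("the posterior update is Bayes' rule, renormalized", {
  g <- toy_grid(c(1, 2, 3), 1)
  lik <- matrix(c(2, 1, 1), 3, 1)
  post <- update_posterior(g, lik)
  expect_equal(as.numeric(post$prob), c(0.5, 0.25, 0.25))
  # uninformative likelihood leaves the prior untouched
  g2 <- toy_grid(c(1, 2), c(1, 2), prob = matrix(c(1, 2, 3, 4), 2, 2))
  post2 <- update_posterior(g2, matrix(0.3, 2, 2))
  expect_equal(post2$prob, g2$prob)
  expect_error(update_posterior(g, matrix(0, 3, 1)), "degenerate")
  expect_error(update_posterior(g, matrix(1, 2, 1)), "shape")
})

test_that("sequential updates equal the brute-force enumerated posterior", {
  set.seed(42)
  g <- toy_grid(seq(10, 30, length.out = 5), seq(50, 120, length.out = 4))
  trials <- data.frame(f = rnorm(5, 60, 40), m = rnorm(5, 20, 3),
                       v = runif(5, 20, 80))
  seq_grid <- g
  for (k in seq_len(nrow(trials))) {
    lik <- likelihood_over_grid(trials$f[k], trials$m[k], trials$v[k],
                                seq_grid)
    seq_grid <- update_posterior(seq_grid, lik)
  }
  expect_equal(seq_grid$prob, oracle_posterior(g, trials),
               tolerance = 1e-12)
})

test_that("run_trial respects ordering and normalization contracts", {
  task <- task_config(n_trials = 10)
  agent <- agent_config("full", cc = 1)
  grid <- init_prior()
  set.seed(9)
  for (k in 1:15) {  # posterior stays normalized after every trial
    step <- run_trial(grid, agent, task)
    grid <- step$grid
    expect_lt(abs(sum(grid$prob) - 1), 1e-12)
  }
  # po is computed from the pre-update grid
  draws <- list(z_r = 0.5, lev_idx = 1L, z_c = -0.3, u_cal = 0.1,
                u_wrong = 0.9)
  s1 <- run_trial(init_prior(), agent, task, draws = draws)
  s2 <- run_trial(s1$grid, agent, task, draws = draws)
  pre_s_hat <- expected_scale(init_prior())
  expect_equal(s1$output$po, (s1$output$c - s1$output$i) * pre_s_hat)
  expect_false(isTRUE(all.equal(s1$output$po, s2$output$po)))
})

test_that("agent runs are reproducible and learn under low noise", {
  task <- task_config(n_trials = 25)
  a <- run_agent(agent_config("full", rng_seed = 77), task)
  b <- run_agent(agent_config("full", rng_seed = 77), task)
  expect_identical(a, b)
  expect_equal(nrow(a), 25L)
  # near-noiseless: the target estimate converges within one grid step
  quiet <- task_config(sigma_r = 0.05, sigma_c_levels = c(0.05, 0.1, 0.2),
                       n_trials = 50)
  qa <- agent_config("full", cc = 1, sigma_r = 0.05,
                     sigma_c_levels = c(0.05, 0.1, 0.2), rng_seed = 3)
  d <- run_agent(qa, quiet)
  expect_lt(abs(d$t_hat[50] - 19), 100 / 99 + 1e-9)
})

test_that("the feedback-only trajectory ignores the efference-copy stream", {
  n <- 40
  t1 <- task_config(sigma_c_levels = c(5, 10, 20), n_trials = n)
  t2 <- task_config(sigma_c_levels = c(1, 2, 3), n_trials = n)
  d1 <- run_agent(agent_config("feedback_only", sigma_c_levels = c(5, 10, 20),
                               rng_seed = 5), t1)
  d2 <- run_agent(agent_config("feedback_only", sigma_c_levels = c(1, 2, 3),
                               rng_seed = 5), t2)
  expect_equal(d1$t_hat, d2$t_hat)
  expect_equal(d1$f, d2$f)
  expect_true(all(is.na(d1$po)))
  expect_true(all(is.na(d1$co)))
})

test_that("agent_config validates variant, cc and levels", {
  expect_error(agent_config("full", cc = 1.2), "cc")
  expect_error(agent_config("nope"), "arg")
  expect_equal(agent_config("average_confidence")$avg_sigma_c, 35 / 3)
  expect_equal(agent_config("average_confidence",
                            avg_sigma_c = 12)$avg_sigma_c, 12)
})
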