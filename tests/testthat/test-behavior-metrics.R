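# small trial table builder
make_trials <- function(n_per = 20, participants = c("A", "B"), rt = 2) {
  do.call(rbind, lapply(participants, function(p) {
    data.frame(participant = p, block = rep(1:2, each = n_per / 2),
               trial = rep(seq_len(n_per / 2), 2),
               produced_interval = 1504 + seq(-200, 200,
                                              length.out = n_per),
               response_time = rt,
               prediction = seq(-150, 150, length.out = n_per),
               confidence = seq(0.1, 0.9, length.out = n_per))
  }))
}

test_that("outlier filtering applies the participant and trial RT rules", {
  d <- make_trials()
  d$feedback <- d$produced_interval - 1504
  d$response_time[d$participant == "A"] <- 10.5   # mean RT > 10 s
  d$response_time[d$participant == "B"][1] <- 6.2 # one slow trial
  d$response_time[d$participant == "B"][2] <- 5.9 # below threshold
  out <- filter_outliers(d)
  expect_identical(out$log$participants_removed, "A")
  expect_equal(out$log$trials_removed_with_participants, 20L)
  expect_equal(out$log$trials_removed_rt, 1L)
  expect_true(all(out$records$participant == "B"))
  expect_equal(nrow(out$records), 19)
  expect_true(all(out$records$response_time <= 6))
  expect_warning(filter_outliers(d[0, ]), "empty")
})

test_that("error signals follow their defining formulas", {
  d <- data.frame(produced_interval = c(1804, 1504, 1204),
                  prediction = c(200, -300, 0),
                  feedback = c(-300, -300, -250))
  s <- compute_error_signals(d)
  expect_equal(s$signed_error, c(300, 0, -300))
  expect_equal(s$error_magnitude, c(300, 0, 300))
  expect_equal(s$spe[1], 500)   # |200 - (-300)|
  expect_equal(s$rpe[1], -100)  # |200| - |-300|
  expect_equal(s$spe[2], 0)     # perfectly predicted error
  expect_equal(s$rpe[2], 0)
  # zero prediction: spe collapses to |feedback|, rpe to -|feedback|
  expect_equal(s$spe[3], 250)
  expect_equal(s$rpe[3], -250)
})

test_that("spe is symmetric and rpe antisymmetric in its arguments", {
  set.seed(12)
  p <- rnorm(50, 0, 200); f <- rnorm(50, 0, 200)
  a <- compute_error_signals(data.frame(produced_interval = 1504,
                                        prediction = p, feedback = f))
  b <- compute_error_signals(data.frame(produced_interval = 1504,
                                        prediction = f, feedback = p))
  expect_equal(a$spe, b$spe)
  expect_equal(a$rpe, -b$rpe)
})

test_that("improvement is previous minus current error, NA at block starts", {
  expect_equal(improvement(400, 250), 150)
  expect_equal(improvement(250, 250), 0)
  d <- data.frame(participant = "A", block = rep(1:2, each = 3),
                  trial = rep(1:3, 2),
                  produced_interval = 1504 + c(400, 250, 250, 100, 50, 80),
                  prediction = 0, feedback = 0)
  s <- compute_error_signals(d)
  expect_equal(s$improvement, c(NA, 150, 0, NA, 50, -30))
})

test_that("missing predictions are flagged with NA prediction signals", {
  d <- data.frame(produced_interval = 1604, prediction = c(NA, 100),
                  feedback = 100)
  s <- compute_error_signals(d)
  expect_true(s$prediction_missing[1])
  expect_true(is.na(s$spe[1]))
  expect_false(is.na(s$error_magnitude[1]))
})

test_that("the calibration index recovers constructed relationships", {
  set.seed(33)
  n <- 250
  base <- data.frame(participant = "S1", block = rep(1:5, each = n / 5),
                     spe = abs(rnorm(n, 0, 150)),
                     error_magnitude = abs(rnorm(n, 200, 80)))
  # well calibrated: confidence falls with SPE
  good <- base
  good$confidence <- 1 - 0.003 * base$spe + rnorm(n, 0, 0.05)
  expect_gt(confidence_calibration(good)$index, 0.5)
  # shuffled confidence: no relationship
  shuf <- good
  shuf$confidence <- sample(good$confidence)
  expect_lt(abs(confidence_calibration(shuf)$index), 0.1)
  # anti-calibrated: confidence equal to SPE
  anti <- base
  anti$confidence <- base$spe
  expect_lt(confidence_calibration(anti)$index, -0.99)
})

test_that("the calibration index is affine-invariant in confidence", {
  set.seed(34)
  d <- data.frame(participant = "S1", block = rep(1:5, each = 50),
                  spe = abs(rnorm(250, 0, 150)),
                  error_magnitude = abs(rnorm(250, 200, 80)))
  d$confidence <- 1 - 0.003 * d$spe + rnorm(250, 0, 0.05)
  i0 <- confidence_calibration(d)$index
  d2 <- d; d2$confidence <- 5 + 3 * d$confidence
  expect_equal(confidence_calibration(d2)$index, i0, tolerance = 1e-12)
  d3 <- d; d3$confidence <- -2 * d$confidence
  expect_equal(confidence_calibration(d3)$index, -i0, tolerance = 1e-12)
})

test_that("degenerate calibration inputs are flagged", {
  few <- data.frame(participant = "S1", block = 1, spe = 1:5,
                    error_magnitude = 1:5, confidence = 1:5 / 5)
  expect_warning(out <- confidence_calibration(few), "fewer than")
  expect_true(is.na(out$index))
  flat <- data.frame(participant = "S1", block = 1, spe = 1:20,
                     error_magnitude = 1:20, confidence = 0.5)
  expect_warning(out2 <- confidence_calibration(flat), "zero variance")
  expect_true(is.na(out2$index))
})

test_that("predictor scaling converts units and centers as documented", {
  d <- data.frame(error_magnitude = c(500, 300, 100),
                  rpe = c(-100, 0, 250), spe = c(500, 200, 100),
                  confidence = c(0, 0.5, 1), block = c(1, 3, 5))
  s <- scale_predictors(d)
  # block 1..5 -> {-1, 0, 1} here; median center at block 3 is a no-op
  expect_equal(s$block, c(-1, 0, 1))
  # confidence mapped to [-1, 1] then median-centered
  expect_equal(s$confidence, c(-1, 0, 1))
  # ms -> s plus median centering for error magnitude and spe
  expect_equal(s$error_magnitude, c(0.5, 0.3, 0.1) - 0.3)
  expect_equal(s$spe, c(0.5, 0.2, 0.1) - 0.2)
  # rpe scaled but NOT centered
  expect_equal(s$rpe, c(-0.1, 0, 0.25))
  expect_error(scale_predictors(d[-1]), "missing columns")
})

test_that("the log transform guards exact zeros", {
  em <- c(0, 10, 100)
  le <- log_error_magnitude(em)
  expect_equal(le, log(c(5, 10, 100)))
  expect_error(log_error_magnitude(-1), ">= 0")
})

test_that("the regression contract estimates and flags as specified", {
  set.seed(55)
  n <- 400
  d <- data.frame(prediction = rnorm(n), confidence = rnorm(n),
                  participant = rep(c("A", "B"), n / 2))
  d$y <- 1 + 2 * d$prediction + 0.5 * d$confidence +
    1.5 * d$prediction * d$confidence + rnorm(n, 0, 0.8)
  m <- fit_trial_model(d, y ~ prediction * confidence)
  cf <- m$coefficients
  ia <- cf[cf$term == "prediction:confidence", ]
  expect_gt(ia$estimate, 0)
  expect_lt(abs(ia$estimate - 1.5), 2 * ia$se)
  # outcome identical to a predictor
  d$y2 <- d$prediction
  m2 <- suppressWarnings(fit_trial_model(d, y2 ~ prediction + confidence))
  cf2 <- m2$coefficients
  expect_equal(cf2$estimate[cf2$term == "prediction"], 1, tolerance = 1e-10)
  expect_equal(m2$r_squared, 1)
  # intercept-only model returns the mean
  m3 <- fit_trial_model(d, y ~ 1)
  expect_equal(m3$coefficients$estimate, mean(d$y))
  # collinear terms are named in the error
  d$dup <- d$prediction
  expect_error(fit_trial_model(d, y ~ prediction + dup), "collinear.*dup")
  # per-participant fixed intercepts
  m4 <- fit_trial_model(d, y ~ prediction, grouping = "participant")
  expect_true(any(grepl("participant", m4$coefficients$term)))
})
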