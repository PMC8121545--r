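#' Configuration for the synthetic behavioral generator
#'
#' Each synthetic participant is a full-variant Bayesian learner with an
#' individual confidence-calibration probability; the agent runs in model
#' units (target 19, scale 90) and its responses are mapped to milliseconds
#' around the 1504 ms target with `ms_per_unit` ms per model unit (the
#' default 25 gives a 250 ms response SD, a realistic coefficient of
#' variation for supra-second interval production).
#'
#' @param n_participants number of participants.
#' @param blocks,trials_per_block session layout (5 x 50 by default).
#' @param target target interval in ms.
#' @param ms_per_unit ms per agent model unit.
#' @param cc_dist function `n -> n` calibration probabilities in \[0, 1\];
#'   default `Beta(2, 1)` (most participants reasonably calibrated, broad
#'   spread).
#' @param sigma_r,sigma_c_levels agent noise parameters (model units).
#' @param rt_meanlog,rt_sdlog lognormal decision-latency component (s)
#'   added to the produced interval to form the response time.
#' @param rt_contam_rate probability of a slow contaminant trial (RT drawn
#'   uniformly from 6.5-9 s) so outlier rules are exercised.
#' @param rng_seed integer seed.
#' @return Object of class `behavior_gen_config`.
#' @export
behavior_gen_config <- function(n_participants = 40L, blocks = 5L,
                                trials_per_block = 50L, target = 1504,
                                ms_per_unit = 25,
                                cc_dist = function(n) stats::rbeta(n, 2, 1),
                                sigma_r = 10, sigma_c_levels = c(5, 10, 20),
                                rt_meanlog = log(0.45), rt_sdlog = 0.35,
                                rt_contam_rate = 0.004, rng_seed = 1L) {
  stopifnot(n_participants >= 1L, blocks >= 1L, trials_per_block >= 1L,
            target > 0, ms_per_unit > 0, sigma_r > 0,
            all(sigma_c_levels > 0), rt_contam_rate >= 0,
            rt_contam_rate <= 1)
  structure(as.list(environment()), class = "behavior_gen_config")
}

#' Generate a synthetic behavioral trial table
#'
#' Simulates each participant as a full-variant agent with their own
#' calibration probability, then maps model units to the task's ms axes:
#' `produced_interval = target + (r - t_true) * ms_per_unit`, feedback is
#' the signed production error in ms, and the prediction is the agent's
#' predicted outcome converted from feedback-scale units to ms.  The
#' ternary confidence report is mapped to \{0.17, 0.5, 0.83\} plus small
#' Gaussian jitter (clamped to \[0, 1\]) to emulate a continuous rating
#' scale.  Response times are the produced interval plus a lognormal
#' latency, with rare slow contaminants.
#'
#' @param config a [behavior_gen_config()].
#' @return Data frame with columns `participant`, `block`, `trial`,
#'   `produced_interval`, `response_time`, `prediction`, `confidence`,
#'   `feedback`, plus generator-truth columns `cc_true` and `co_raw`.
#'   The per-participant calibration draw is also attached as attribute
#'   `"cc"`.
#' @export
generate_behavior <- function(config = behavior_gen_config()) {
  if (!inherits(config, "behavior_gen_config")) stop("invalid config")
  set.seed(config$rng_seed)
  n_p <- config$n_participants
  cc <- pmin(pmax(config$cc_dist(n_p), 0), 1)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n_p)
  n_trials <- config$blocks * config$trials_per_block
  task <- task_config(sigma_r = config$sigma_r,
                      sigma_c_levels = config$sigma_c_levels,
                      n_trials = n_trials)
  kappa <- config$ms_per_unit
  rows <- vector("list", n_p)
  for (p in seq_len(n_p)) {
    ag <- agent_config("full", cc = cc[p], sigma_r = config$sigma_r,
                       sigma_c_levels = config$sigma_c_levels,
                       rng_seed = agent_seeds[p])
    d <- run_agent(ag, task)
    produced <- config$target + (d$r - task$t_true) * kappa
    # rating-scale jitter and response times use the post-run RNG stream
    conf <- c(0.17, 0.5, 0.83)[d$co] + stats::rnorm(n_trials, 0, 0.05)
    rt <- produced / 1000 +
      stats::rlnorm(n_trials, config$rt_meanlog, config$rt_sdlog)
    contam <- stats::runif(n_trials) < config$rt_contam_rate
    rt[contam] <- stats::runif(sum(contam), 6.5, 9)
    rows[[p]] <- data.frame(
      participant = sprintf("P%02d", p),
      block = rep(seq_len(config$blocks), each = config$trials_per_block),
      trial = rep(seq_len(config$trials_per_block), config$blocks),
      produced_interval = produced,
      response_time = rt,
      prediction = d$po * kappa / task$s_true,
      confidence = pmin(pmax(conf, 0), 1),
      feedback = (produced - config$target),
      cc_true = cc[p],
      co_raw = d$co)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cc") <- stats::setNames(cc, sprintf("P%02d", seq_len(n_p)))
  out
}

#' Configuration for the synthetic EEG epoch generator
#'
#' Epochs are a sum of temporally autocorrelated, band-limited noise and
#' three Gaussian-shaped components (an FRN-like fronto-central negativity,
#' a fronto-central P3a and a parietal P3b) whose single-trial amplitudes
#' are linear in the trial's error signals.  Effect coefficients are in
#' microvolts per second of RPE/SPE/error magnitude and per unit of
#' confidence on the \[-1, 1\] scale; their signs follow the component
#' physiology (less negative FRN for better-than-expected outcomes, larger
#' P3a for surprising outcomes and high confidence, larger P3b for large
#' SPE and small errors).
#'
#' @param channels channel labels (must cover FCz, Pz and both ROIs).
#' @param srate,t0,n_samples epoch layout.
#' @param components list of component templates; each has `latency` and
#'   `width` (ms), a named `topo` weight vector, `base` amplitude and a
#'   named `betas` vector over `rpe`, `spe`, `em`, `confidence`.
#' @param noise_sd marginal noise SD per channel (microvolts, pre-filter).
#' @param ar_rho first-order autocorrelation of the noise.
#' @param band band-pass limits in Hz applied to the noise.
#' @param artifact_rate fraction of epochs receiving an injected amplitude
#'   spike or gradient step.
#' @param rng_seed integer seed.
#' @return Object of class `erp_gen_config`.
#' @export
erp_gen_config <- function(channels = c("F1", "Fz", "F2", "FC1", "FCz",
                                        "FC2", "C1", "Cz", "C2", "CP1",
                                        "CPz", "CP2", "P1", "Pz", "P2",
                                        "PO3", "POz", "PO4"),
                           srate = 500, t0 = -200, n_samples = 500L,
                           components = NULL, noise_sd = 8, ar_rho = 0.95,
                           band = c(0.5, 40), artifact_rate = 0.02,
                           rng_seed = 1L) {
  stopifnot(noise_sd > 0, ar_rho >= 0, ar_rho < 1,
            artifact_rate >= 0, artifact_rate <= 1)
  if (is.null(components)) {
    fc <- c(F1 = 0.5, Fz = 0.7, F2 = 0.5, FC1 = 0.7, FCz = 1, FC2 = 0.7,
            C1 = 0.5, Cz = 0.7, C2 = 0.5, CP1 = 0.2, CPz = 0.2, CP2 = 0.2,
            P1 = 0.15, Pz = 0.15, P2 = 0.15, PO3 = 0.1, POz = 0.1,
            PO4 = 0.1)
    par <- c(F1 = 0.15, Fz = 0.15, F2 = 0.15, FC1 = 0.3, FCz = 0.3,
             FC2 = 0.3, C1 = 0.5, Cz = 0.5, C2 = 0.5, CP1 = 0.8,
             CPz = 0.9, CP2 = 0.8, P1 = 0.9, Pz = 1, P2 = 0.9,
             PO3 = 0.6, POz = 0.6, PO4 = 0.6)
    components <- list(
      frn = list(latency = 250, width = 20, topo = fc, base = -12,
                 betas = c(rpe = 8)),
      p3a = list(latency = 380, width = 30, topo = fc, base = 4,
                 betas = c(spe = 4, confidence = 1.5)),
      p3b = list(latency = 466, width = 35, topo = par, base = 4,
                 betas = c(spe = 3, em = -4, rpe = -2)))
  }
  lat <- vapply(components, `[[`, numeric(1), "latency")
  span <- c(t0, t0 + (n_samples - 1) * 1000 / srate)
  if (any(lat < span[1] | lat > span[2]))
    stop("component latencies must lie within the epoch span")
  structure(list(channels = channels, srate = srate, t0 = t0,
                 n_samples = as.integer(n_samples),
                 components = components, noise_sd = noise_sd,
                 ar_rho = ar_rho, band = band,
                 artifact_rate = artifact_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "erp_gen_config")
}

# temporal kernel of a component on the epoch time axis (unit peak)
.component_kernel <- function(comp, times) {
  exp(-0.5 * ((times - comp$latency) / comp$width)^2)
}

# scaled per-trial regressors used by the generator (seconds / [-1, 1])
.epoch_regressors <- function(trials) {
  need <- c("rpe", "spe", "error_magnitude", "confidence")
  if (!all(need %in% names(trials)))
    stop("trials must carry error signals (run compute_error_signals) ",
         "and confidence")
  list(rpe = trials$rpe / 1000, spe = trials$spe / 1000,
       em = trials$error_magnitude / 1000,
       confidence = 2 * trials$confidence - 1)
}

#' Generate synthetic feedback-locked EEG epochs
#'
#' One epoch per trial row.  Component amplitudes are
#' `base + sum(betas * regressors)` with regressors RPE/SPE/error magnitude
#' in seconds and confidence on \[-1, 1\]; each component is its amplitude
#' times a Gaussian temporal kernel times its scalp topography.  Noise is
#' an AR(1) process band-passed to the configured band, independent across
#' channels and epochs.  A configurable fraction of epochs receives an
#' injected artifact (amplitude spike or step-like gradient jump).
#'
#' The exact linear mapping from regressors to the package's ERP features
#' (window means; FRN peak approximated by the FCz kernel peak) is attached
#' as attribute `"expected_effects"` for recovery tests.
#'
#' @param trials trial table including error-signal columns (see
#'   [compute_error_signals()]) and `confidence`.
#' @param config an [erp_gen_config()].
#' @return An [epoch_array()] with attributes `"expected_effects"` and
#'   `"artifact"` (logical injection mask).
#' @export
generate_epochs <- function(trials, config = erp_gen_config()) {
  if (!inherits(config, "erp_gen_config")) stop("invalid config")
  n <- nrow(trials)
  if (n < 1L) stop("no trials supplied")
  set.seed(config$rng_seed)
  ns <- config$n_samples
  nc <- length(config$channels)
  times <- config$t0 + (seq_len(ns) - 1L) * 1000 / config$srate
  reg <- .epoch_regressors(trials)

  # band-limited AR(1) noise, channels/epochs independent
  innov_sd <- config$noise_sd * sqrt(1 - config$ar_rho^2)
  x <- matrix(0, ns, n * nc)
  x[1L, ] <- stats::rnorm(n * nc, 0, config$noise_sd)
  for (t in 2:ns)
    x[t, ] <- config$ar_rho * x[t - 1L, ] +
      stats::rnorm(n * nc, 0, innov_sd)
  freq <- (seq_len(ns) - 1L) * config$srate / ns
  freq <- pmin(freq, config$srate - freq)         # two-sided spectrum
  keep <- freq >= config$band[1] & freq <= config$band[2]
  x <- Re(stats::mvfft(stats::mvfft(x) * keep, inverse = TRUE)) / ns
  data <- aperm(array(x, c(ns, n, nc)), c(2, 3, 1))

  for (comp in config$components) {
    amp <- rep(comp$base, n)
    for (term in names(comp$betas))
      amp <- amp + comp$betas[[term]] * reg[[term]]
    topo <- comp$topo[config$channels]
    if (anyNA(topo)) stop("component topography missing channels")
    kern <- .component_kernel(comp, times)
    data <- data + amp %o% (unname(topo) %o% kern)
  }

  # artifact injection: alternating amplitude spikes and gradient steps
  art <- stats::runif(n) < config$artifact_rate
  art_idx <- which(art)
  for (k in seq_along(art_idx)) {
    e <- art_idx[k]
    ch <- sample.int(nc, 1L)
    pos <- sample(seq(20L, ns - 20L), 1L)
    sign <- sample(c(-1, 1), 1L)
    if (k %% 2L == 1L) {
      data[e, ch, pos:(pos + 2L)] <-
        data[e, ch, pos:(pos + 2L)] + sign * stats::runif(1, 180, 280)
    } else {
      data[e, ch, pos:ns] <-
        data[e, ch, pos:ns] + sign * stats::runif(1, 70, 120)
    }
  }

  epochs <- epoch_array(data, config$channels, config$srate, config$t0)
  attr(epochs, "expected_effects") <- .expected_effects(config, times)
  attr(epochs, "artifact") <- art
  epochs
}

# expected regression coefficients of each feature on each regressor.
# Exact for the window means (linear); for the FRN peak-to-peak feature the
# min/max extremum picking under noise compresses the slope toward zero, so
# the frn entry is a noise-free upper bound (exact only as noise_sd -> 0).
.expected_effects <- function(config, times) {
  rois <- default_rois()
  windows <- list(p3a = c(330, 430), p3b = c(416, 516))
  frn_lat <- if (!is.null(config$components$frn))
    config$components$frn$latency else 250
  gain <- function(comp, feature) {
    if (feature == "frn")                       # kernel value at the FRN peak
      return(comp$topo[["FCz"]] * .component_kernel(comp, frn_lat))
    roi <- rois[[feature]]$channels
    idx <- times >= windows[[feature]][1] & times < windows[[feature]][2]
    mean(comp$topo[roi]) * mean(.component_kernel(comp, times)[idx])
  }
  out <- list()
  for (feature in c("frn", "p3a", "p3b")) {
    beta <- c(rpe = 0, spe = 0, em = 0, confidence = 0)
    for (comp in config$components)
      for (term in names(comp$betas))
        beta[term] <- beta[term] + gain(comp, feature) * comp$betas[[term]]
    out[[feature]] <- beta
  }
  out
}

#' Write a self-contained synthetic fixture bundle
#'
#' Generates a behavioral table and matching epochs and writes them to
#' `out_dir`: `trials.csv`, `epochs_data.csv` (one row per epoch x channel,
#' one column per sample), `epochs_meta.json` (channel names, srate, t0,
#' epoch count and the trial keys, i.e. an HDF5-style sidecar in plain
#' text) and `config.json`.  Deterministic for a given pair of seeds.
#'
#' @param behavior_config a [behavior_gen_config()].
#' @param erp_config an [erp_gen_config()].
#' @param out_dir output directory (created if needed).
#' @param n_epochs number of epochs; if smaller than the number of trials,
#'   an evenly strided subset of trials is used.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture_bundle <- function(behavior_config = behavior_gen_config(),
                                 erp_config = erp_gen_config(),
                                 out_dir, n_epochs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trials <- generate_behavior(behavior_config)
  trials <- compute_error_signals(trials, target = behavior_config$target)
  if (!is.null(n_epochs) && n_epochs < nrow(trials)) {
    pick <- round(seq(1L, nrow(trials), length.out = n_epochs))
    etrials <- trials[pick, , drop = FALSE]
  } else etrials <- trials
  epochs <- generate_epochs(etrials, erp_config)

  paths <- c(trials = file.path(out_dir, "trials.csv"),
             epochs = file.path(out_dir, "epochs_data.csv"),
             meta = file.path(out_dir, "epochs_meta.json"),
             config = file.path(out_dir, "config.json"))
  data.table::fwrite(trials, paths["trials"])
  write_epochs(epochs, paths["epochs"], paths["meta"],
               trial_keys = etrials[c("participant", "block", "trial")])
  jsonlite::write_json(
    list(behavior = behavior_config[setdiff(names(behavior_config),
                                            "cc_dist")],
         erp = list(noise_sd = erp_config$noise_sd,
                    ar_rho = erp_config$ar_rho,
                    artifact_rate = erp_config$artifact_rate,
                    rng_seed = erp_config$rng_seed)),
    paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Epoch serialization (plain-text CSV + JSON sidecar)
#'
#' `write_epochs()` stores the voltage array as a wide CSV (columns
#' `epoch`, `channel`, then one column per sample) and a JSON sidecar with
#' the layout metadata; `read_epochs()` restores the [epoch_array()].
#'
#' @param epochs an [epoch_array()].
#' @param data_path,meta_path file paths for the CSV and sidecar.
#' @param trial_keys optional data frame of per-epoch trial identifiers
#'   stored in the sidecar.
#' @return `write_epochs()`: invisibly the two paths; `read_epochs()`: an
#'   `epoch_array` with attribute `"trial_keys"` when present.
#' @export
write_epochs <- function(epochs, data_path, meta_path,
                         trial_keys = NULL) {
  d <- epochs$data
  n <- dim(d)[1]; nc <- dim(d)[2]; ns <- dim(d)[3]
  flat <- matrix(aperm(d, c(2, 1, 3)), n * nc, ns)
  df <- data.table::data.table(
    epoch = rep(seq_len(n), each = nc),
    channel = rep(epochs$channels, n))
  df <- cbind(df, data.table::as.data.table(flat))
  data.table::fwrite(df, data_path)
  meta <- list(channels = epochs$channels, srate = epochs$srate,
               t0 = epochs$t0, n_epochs = n, n_samples = ns)
  if (!is.null(trial_keys)) meta$trial_keys <- trial_keys
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, meta_path))
}

#' @rdname write_epochs
#' @export
read_epochs <- function(data_path, meta_path) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- data.table::fread(data_path)
  n <- meta$n_epochs; nc <- length(meta$channels); ns <- meta$n_samples
  flat <- as.matrix(df[, -(1:2)])
  d <- aperm(array(flat, c(nc, n, ns)), c(2, 1, 3))
  out <- epoch_array(d, meta$channels, meta$srate, meta$t0)
  if (!is.null(meta$trial_keys))
    attr(out, "trial_keys") <- as.data.frame(meta$trial_keys)
  out
}
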