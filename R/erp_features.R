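#' Epoched EEG container
#'
#' Voltage array of feedback-locked epochs with named channels.  Sample
#' times run from `t0` in steps of `1000/srate` ms; the default layout is
#' 500 samples at 500 Hz spanning -200..798 ms (left-closed sample bins
#' covering -200..800 ms around feedback onset).
#'
#' @param data numeric array, `epochs x channels x samples`, in microvolts.
#' @param channels unique channel labels, one per array row dimension 2.
#' @param srate sampling rate in Hz.
#' @param t0 time of the first sample in ms relative to feedback onset.
#' @return Object of class `epoch_array` with a `times` vector attached.
#' @export
epoch_array <- function(data, channels, srate = 500, t0 = -200) {
  if (length(dim(data)) != 3L) stop("data must be epochs x channels x samples")
  if (dim(data)[2] != length(channels))
    stop("channel count does not match data")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (srate <= 0) stop("srate must be > 0")
  structure(list(data = data, channels = as.character(channels),
                 srate = srate, t0 = t0,
                 times = t0 + (seq_len(dim(data)[3]) - 1L) * 1000 / srate),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array>", d[1], "epochs x", d[2], "channels x", d[3],
      sprintf("samples | %g Hz | %g..%g ms\n", x$srate,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Region-of-interest specification
#'
#' @param name ROI label.
#' @param channels channel labels forming the ROI.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(name, channels) {
  structure(list(name = name, channels = as.character(channels)),
            class = "roi_spec")
}

#' Default analysis ROIs
#'
#' The fronto-central ROI used for the P3a and the parietal ROI used for
#' the P3b.
#'
#' @return Named list of [roi_spec()] objects `p3a` and `p3b`.
#' @export
default_rois <- function() {
  list(p3a = roi_spec("p3a", c("F1", "Fz", "F2", "FC1", "FCz", "FC2",
                               "C1", "Cz", "C2")),
       p3b = roi_spec("p3b", c("CP1", "CPz", "CP2", "P1", "Pz", "P2",
                               "PO3", "POz", "PO4")))
}

.chan_idx <- function(epochs, channels) {
  idx <- match(channels, epochs$channels)
  if (anyNA(idx))
    stop("channels missing from epochs: ",
         paste(channels[is.na(idx)], collapse = ", "))
  idx
}

#' Baseline correction
#'
#' Subtracts, per epoch and channel, the mean voltage over the pre-stimulus
#' interval (default \[-200, 0) ms; left-closed, right-open).  Idempotent.
#'
#' @param epochs an [epoch_array()].
#' @param window baseline interval in ms.
#' @return Baseline-corrected `epoch_array`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  idx <- epochs$times >= window[1] & epochs$times < window[2]
  if (!any(idx) || epochs$times[1] > window[1])
    stop("epoch does not cover the baseline interval")
  base <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(base, dim(epochs$data))
  epochs
}

#' Artifact rejection mask
#'
#' Flags an epoch if, on any channel, any sample's absolute voltage exceeds
#' `amp_max` or any absolute difference between adjacent samples exceeds
#' `grad_max`.
#'
#' @param epochs a (baseline-corrected) [epoch_array()].
#' @param amp_max amplitude threshold in microvolts.
#' @param grad_max adjacent-sample gradient threshold in microvolts.
#' @return Logical vector, `TRUE` = rejected.
#' @export
reject_artifacts <- function(epochs, amp_max = 150, grad_max = 50) {
  d <- epochs$data
  n <- dim(d)[1]
  flat <- matrix(abs(d), n)
  amp <- apply(flat, 1L, max)
  ns <- dim(d)[3]
  grad <- matrix(abs(d[, , -1L, drop = FALSE] -
                     d[, , -ns, drop = FALSE]), n)
  gmx <- apply(grad, 1L, max)
  amp > amp_max | gmx > grad_max
}

#' Single-trial FRN peak-to-peak amplitude
#'
#' Locates the minimum voltage in the 200-300 ms post-feedback window
#' (inclusive) on the given channel, then the maximum in the 100 ms window
#' ending at the detected negative peak, and returns their difference
#' `frn = V_min - V_max` (negative-going) together with the negative-peak
#' latency.  Ties resolve to the earliest sample.
#'
#' @param epochs an [epoch_array()].
#' @param channel channel label (default `"FCz"`).
#' @param neg_window search window for the negative peak, ms.
#' @param pre_width width of the preceding maximum window, ms.
#' @return Data frame with `frn` and `neg_peak_latency`, one row per epoch.
#' @export
frn_peak_to_peak <- function(epochs, channel = "FCz",
                             neg_window = c(200, 300), pre_width = 100) {
  ch <- .chan_idx(epochs, channel)
  tm <- epochs$times
  widx <- which(tm >= neg_window[1] & tm <= neg_window[2])
  if (!length(widx)) stop("negative-peak window is not sampled")
  mat <- epochs$data[, ch, widx, drop = FALSE]
  dim(mat) <- c(dim(epochs$data)[1], length(widx))
  jl <- max.col(-mat, ties.method = "first")
  vmin <- mat[cbind(seq_len(nrow(mat)), jl)]
  lat <- tm[widx[jl]]
  vmax <- numeric(nrow(mat))
  for (e in seq_len(nrow(mat))) {
    pidx <- tm >= lat[e] - pre_width & tm <= lat[e]
    vmax[e] <- max(epochs$data[e, ch, pidx])
  }
  data.frame(frn = vmin - vmax, neg_peak_latency = lat)
}

#' Mean voltage over an ROI and time window
#'
#' Averages over all ROI channels and all samples in the window
#' (left-closed, right-open in sample space).  Linear in the input.
#'
#' @param epochs an [epoch_array()].
#' @param roi a [roi_spec()] or character vector of channels.
#' @param window time window in ms, within the epoch span.
#' @return Numeric vector, one mean per epoch.
#' @export
window_mean <- function(epochs, roi, window) {
  channels <- if (inherits(roi, "roi_spec")) roi$channels else roi
  ch <- .chan_idx(epochs, channels)
  tm <- epochs$times
  step <- 1000 / epochs$srate
  if (window[1] < tm[1] || window[2] > tm[length(tm)] + step)
    stop("window lies outside the epoch span")
  idx <- tm >= window[1] & tm < window[2]
  if (!any(idx)) stop("window contains no samples")
  rowMeans(epochs$data[, ch, idx, drop = FALSE], dims = 1)
}

#' Subject-wise component window
#'
#' Averages the subject's (non-rejected) epochs, finds the positive peak
#' latency within the search span on the given channel, and returns the
#' window of width `width` centred on it.  Ties resolve to the earliest
#' latency (with a message).
#'
#' @param epochs an [epoch_array()].
#' @param channel channel to search (e.g. `"FCz"` for P3a, `"Pz"` for P3b).
#' @param span inclusive search span in ms.
#' @param width window width in ms.
#' @param reject optional logical rejection mask; rejected epochs are
#'   excluded from the average.
#' @return Numeric `c(start, end)` window in ms.
#' @export
subject_window <- function(epochs, channel, span, width = 100,
                           reject = NULL) {
  ch <- .chan_idx(epochs, channel)
  keep <- if (is.null(reject)) rep(TRUE, dim(epochs$data)[1]) else !reject
  if (!any(keep)) stop("no surviving epochs")
  avg <- colMeans(epochs$data[keep, ch, , drop = FALSE], dims = 2)
  avg <- as.numeric(avg)
  tm <- epochs$times
  sidx <- which(tm >= span[1] & tm <= span[2])
  if (!length(sidx)) stop("search span is not sampled")
  seg <- avg[sidx]
  mx <- max(seg)
  hits <- which(seg == mx)
  if (length(hits) > 1L)
    message("tied peak latencies; taking the earliest")
  lat <- tm[sidx[hits[1L]]]
  c(lat - width / 2, lat + width / 2)
}

#' Extract the standard single-trial ERP feature set
#'
#' Convenience pipeline: baseline correction, artifact rejection, FRN
#' peak-to-peak at FCz, and P3a/P3b ROI window means.  Features of rejected
#' epochs are set to `NA`.  By default the common printed windows
#' (330-430 ms and 416-516 ms) are used for all epochs; set
#' `subject_windows = TRUE` to re-derive 100 ms windows from the positive
#' peak of this subject's average at FCz / Pz.
#'
#' @param epochs an [epoch_array()].
#' @param rois list with `p3a` and `p3b` [roi_spec()]s.
#' @param p3a_window,p3b_window common component windows, ms.
#' @param subject_windows derive windows from the subject average instead.
#' @return Data frame with `epoch`, `rejected`, `frn`,
#'   `frn_neg_peak_latency`, `p3a`, `p3b`.
#' @export
extract_erp_features <- function(epochs, rois = default_rois(),
                                 p3a_window = c(330, 430),
                                 p3b_window = c(416, 516),
                                 subject_windows = FALSE) {
  epochs <- baseline_correct(epochs)
  rejected <- reject_artifacts(epochs)
  if (subject_windows) {
    p3a_window <- subject_window(epochs, "FCz", c(250, 500),
                                 reject = rejected)
    p3b_window <- subject_window(epochs, "Pz", c(300, 600),
                                 reject = rejected)
  }
  frn <- frn_peak_to_peak(epochs)
  out <- data.frame(epoch = seq_len(dim(epochs$data)[1]),
                    rejected = rejected,
                    frn = frn$frn,
                    frn_neg_peak_latency = frn$neg_peak_latency,
                    p3a = window_mean(epochs, rois$p3a, p3a_window),
                    p3b = window_mean(epochs, rois$p3b, p3b_window))
  out[rejected, c("frn", "frn_neg_peak_latency", "p3a", "p3b")] <- NA_real_
  out
}
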