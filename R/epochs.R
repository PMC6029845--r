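#' Epoched multichannel recording
#'
#' The unit of all decoding: a `trials x channels x time` array with one
#' condition label per trial and a time axis in ms relative to target onset.
#' Field-strength units (fT) for real MEG, arbitrary units for synthetic
#' data.
#'
#' @param data Numeric array `trials x channels x timepoints`.
#' @param labels Character or factor vector of condition ids, one per trial.
#' @param time Numeric time axis in ms; length must equal `dim(data)[3]`.
#' @param sampling_rate Sampling rate, Hz.
#' @param baseline Baseline window `c(start, end)` in ms; must lie within the
#'   time axis.
#' @param category_of Optional named vector mapping condition id to category
#'   label.
#' @param processing Character vector logging the preprocessing steps already
#'   applied (maintained by the preprocessing functions).
#' @return An object of class `meg_epochs`.
#' @export
meg_epochs <- function(data, labels, time, sampling_rate,
                       baseline = c(min(time), 0), category_of = NULL,
                       processing = character()) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(time) != dim(data)[3])
    stop("time axis length must equal the data's third extent")
  if (length(labels) != dim(data)[1])
    stop("labels length must equal the trial count")
  stopifnot(length(baseline) == 2, baseline[1] <= baseline[2])
  if (baseline[1] < min(time) || baseline[2] > max(time))
    stop("baseline window must lie within the time axis")
  structure(list(data = data, labels = as.character(labels),
                 time = as.numeric(time), sampling_rate = sampling_rate,
                 baseline = as.numeric(baseline), category_of = category_of,
                 processing = processing),
            class = "meg_epochs")
}

#' @export
print.meg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<meg_epochs> %d trials x %d channels x %d timepoints\n",
              d[1], d[2], d[3]))
  cat(sprintf("  time %g..%g ms @ %g Hz, %d conditions\n",
              min(x$time), max(x$time), x$sampling_rate,
              length(unique(x$labels))))
  if (length(x$processing))
    cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, for every trial and channel, the mean over the baseline window
#' so that the baseline mean becomes zero; all other samples are shifted by
#' the same amount.
#'
#' @param epochs A [meg_epochs].
#' @param window Baseline window `c(start, end)` in ms; defaults to the
#'   epochs' stored baseline.
#' @return A baseline-corrected [meg_epochs].
#' @export
baseline_correct <- function(epochs, window = epochs$baseline) {
  stopifnot(inherits(epochs, "meg_epochs"))
  idx <- which(epochs$time >= window[1] & epochs$time <= window[2])
  if (length(idx) == 0) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over the 3rd extent
  epochs$processing <- c(epochs$processing, "baseline_correct")
  epochs
}

#' Reject trials by peak-to-peak amplitude
#'
#' A trial is removed iff the max-minus-min span over *any* channel strictly
#' exceeds `threshold`; a trial spanning exactly the threshold is kept. The
#' order of surviving trials is preserved. The default threshold is the
#' 6000 fT criterion standard for MEG artifact screening.
#'
#' @param epochs A [meg_epochs].
#' @param threshold Positive peak-to-peak rejection threshold, field-strength
#'   units.
#' @return List with `epochs` (survivors) and `rejected`, a data frame of
#'   rejected trial indices with the offending channel and its span.
#' @export
reject_by_peak_to_peak <- function(epochs, threshold = 6000) {
  stopifnot(inherits(epochs, "meg_epochs"))
  if (threshold <= 0) stop("threshold must be > 0")
  spans <- apply(epochs$data, c(1, 2), function(v) max(v) - min(v))
  spans <- matrix(spans, nrow = dim(epochs$data)[1])
  worst <- apply(spans, 1, max)
  bad <- which(worst > threshold)
  if (length(bad) == dim(epochs$data)[1])
    stop(sprintf("all trials exceed the %g peak-to-peak threshold", threshold))
  rejected <- data.frame(
    trial = bad,
    channel = if (length(bad)) apply(spans[bad, , drop = FALSE], 1, which.max)
              else integer(),
    span = worst[bad]
  )
  if (length(bad)) {
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
    epochs$labels <- epochs$labels[-bad]
  }
  epochs$processing <- c(epochs$processing,
                         sprintf("reject_by_peak_to_peak(%g)", threshold))
  list(epochs = epochs, rejected = rejected)
}

# zero-phase 4th-order Butterworth, forward-backward, with odd reflection
# padding of one filter length to avoid edge transients
lowpass_vector <- function(x, flt, npad) {
  n <- length(x)
  p <- min(npad, n - 1)
  if (p > 0) {
    head_pad <- 2 * x[1] - x[(p + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- signal::filtfilt(flt, xp)
  y[(p + 1):(p + n)]
}

#' Zero-phase low-pass filter
#'
#' Smooths every trial and channel with a zero-phase (forward-backward)
#' 4th-order Butterworth low-pass filter, the 20 Hz smoothing conventionally
#' applied to evoked MEG before decoding. Zero-phase filtering leaves the
#' latency of symmetric transients untouched, which matters because peak and
#' onset latencies are the quantities of interest downstream.
#'
#' @param epochs A [meg_epochs].
#' @param cutoff Cutoff frequency, Hz; must be below the Nyquist frequency.
#' @return A filtered [meg_epochs].
#' @export
lowpass <- function(epochs, cutoff = 20) {
  stopifnot(inherits(epochs, "meg_epochs"))
  nyq <- epochs$sampling_rate / 2
  if (cutoff >= nyq)
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff, nyq))
  flt <- signal::butter(4, cutoff / nyq, type = "low")
  npad <- ceiling(6 * epochs$sampling_rate / cutoff)   # > filter settling time
  d <- dim(epochs$data)
  for (tr in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      epochs$data[tr, ch, ] <- lowpass_vector(epochs$data[tr, ch, ], flt, npad)
  epochs$processing <- c(epochs$processing, sprintf("lowpass(%g)", cutoff))
  epochs
}

#' Standard preprocessing chain
#'
#' Applies baseline correction, peak-to-peak rejection, and zero-phase
#' low-pass filtering in that order (the default order, recorded in the
#' output's processing log).
#'
#' @param epochs A [meg_epochs].
#' @param threshold Peak-to-peak rejection threshold.
#' @param cutoff Low-pass cutoff, Hz.
#' @return List with `epochs` and `rejected` as in [reject_by_peak_to_peak()].
#' @export
preprocess_epochs <- function(epochs, threshold = 6000, cutoff = 20) {
  out <- reject_by_peak_to_peak(baseline_correct(epochs), threshold)
  out$epochs <- lowpass(out$epochs, cutoff)
  out
}
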