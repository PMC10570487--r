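# Deterministic signal conditioning: band-pass filtering, downsampling,
# mean-mastoid re-referencing and stimulus-locked epoching. Component-based
# artifact cleaning (ASR, ICA/ICLabel) is not reimplemented here; a
# pre-cleaning hook accepts externally cleaned signals, and synthetic data
# is generated clean.

#' Re-reference EEG to mean mastoids
#'
#' Subtracts the average of TP9 and TP10 from every channel, sample-wise.
#' After this reference TP9 and TP10 are algebraically degenerate
#' (TP9 = -TP10 = half their original difference); the returned matrix
#' carries a `"mastoid_degenerate"` attribute flagging this. The operation
#' is idempotent.
#'
#' @param eeg Numeric matrix, channels x samples.
#' @param labels Channel labels (defaults to the row names); must contain
#'   TP9 and TP10.
#' @return The re-referenced matrix.
#' @export
rereference_mastoids <- function(eeg, labels = rownames(eeg)) {
  if (is.null(labels)) stop("channel labels required")
  i9 <- match("TP9", labels); i10 <- match("TP10", labels)
  if (is.na(i9) || is.na(i10)) stop("mastoid channel TP9/TP10 missing")
  ref <- (eeg[i9, ] + eeg[i10, ]) / 2
  out <- eeg - rep(ref, each = nrow(eeg))
  dimnames(out) <- dimnames(eeg)
  attr(out, "mastoid_degenerate") <- c("TP9", "TP10")
  out
}

#' Segment a recording into stimulus-locked epochs
#'
#' Extracts one epoch per `stimulus_onset` event over the half-open window
#' `[tmin, tmax)` relative to the stimulus, so each epoch has exactly
#' `(tmax - tmin) * fs` samples. Trials whose window crosses a recording
#' edge are dropped (the count is reported via the `"dropped"` attribute
#' and a message). Each epoch inherits the mode/run/trial labels of its
#' stimulus event.
#'
#' @param eeg Numeric matrix, channels x samples.
#' @param events Event data frame with `time` and `code` (and optionally
#'   `mode`, `run`, `trial`).
#' @param tmin,tmax Epoch window in seconds relative to stimulus onset
#'   (default `[-3, 10)`).
#' @param fs Sampling rate (Hz).
#' @return An object of class `epoch_set`: `data` (trials x channels x
#'   samples), `times` (s relative to stimulus), `fs`, `labels` (per-trial
#'   data frame), `channels`.
#' @export
segment_epochs <- function(eeg, events, tmin = -3, tmax = 10, fs) {
  stopifnot(tmin < tmax)
  stim <- events[events$code == "stimulus_onset", , drop = FALSE]
  if (!nrow(stim)) stop("no stimulus_onset events: zero epochs extractable")
  n <- ncol(eeg)
  n_ep <- as.integer(round((tmax - tmin) * fs))
  off <- as.integer(round(tmin * fs))
  stim_samp <- as.integer(round(stim$time * fs)) + 1L
  first <- stim_samp + off
  last <- first + n_ep - 1L
  ok <- first >= 1L & last <= n
  if (!all(ok))
    message(sum(!ok), " trial(s) dropped: epoch window crosses recording edge")
  stim <- stim[ok, , drop = FALSE]
  first <- first[ok]
  if (!nrow(stim)) stop("zero epochs extractable within the recording")
  nt <- nrow(stim)
  data <- array(0, c(nt, nrow(eeg), n_ep))
  for (k in seq_len(nt))
    data[k, , ] <- eeg[, first[k]:(first[k] + n_ep - 1L)]
  labels <- data.frame(
    trial = stim$trial %||% seq_len(nt),
    mode = stim$mode %||% NA_character_,
    run = stim$run %||% NA_integer_,
    stringsAsFactors = FALSE
  )
  structure(list(
    data = data,
    times = tmin + (seq_len(n_ep) - 1L) / fs,
    fs = fs,
    labels = labels,
    channels = rownames(eeg) %||% paste0("ch", seq_len(nrow(eeg)))
  ), class = "epoch_set", dropped = sum(!ok))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t in [%g, %g)\n",
              d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)] + 1 / x$fs))
  if (!all(is.na(x$labels$mode)))
    print(table(x$labels$mode))
  invisible(x)
}

#' Condition a dyad recording and epoch both participants
#'
#' The deterministic conditioning chain: optional user-supplied cleaning
#' hook (for externally artifact-corrected signals), 1-50 Hz zero-phase
#' FIR band-pass, optional downsampling to `fs_target`, mean-mastoid
#' re-referencing, and stimulus-locked epoching over `[tmin, tmax)`.
#' Identical input yields bit-identical output.
#'
#' @param rec A `dyad_recording`.
#' @param lo,hi Broadband filter edges (Hz).
#' @param fs_target Target sampling rate (Hz); the recording is
#'   downsampled when its rate is higher.
#' @param tmin,tmax Epoch window (s) relative to stimulus onset.
#' @param reref Re-reference to mean mastoids (default TRUE).
#' @param clean_hook Optional `function(eeg_matrix, fs, labels)` applied to
#'   each participant's raw EEG before filtering.
#' @return List with `epochs_a` and `epochs_b` (class `epoch_set`).
#' @export
preprocess_recording <- function(rec, lo = 1, hi = 50, fs_target = 250,
                                 tmin = -3, tmax = 10, reref = TRUE,
                                 clean_hook = NULL) {
  stopifnot(inherits(rec, "dyad_recording"))
  one <- function(eeg) {
    if (!is.null(clean_hook)) eeg <- clean_hook(eeg, rec$fs, rec$labels)
    fs <- rec$fs
    if (fs > fs_target) {
      eeg <- resample_to(bandpass_fir(eeg, lo, hi, fs), fs, fs_target)
      fs <- fs_target
    } else {
      eeg <- bandpass_fir(eeg, lo, hi, fs)
    }
    if (reref) eeg <- rereference_mastoids(eeg, rec$labels)
    segment_epochs(eeg, rec$events, tmin, tmax, fs)
  }
  list(epochs_a = one(rec$eeg_a), epochs_b = one(rec$eeg_b))
}
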