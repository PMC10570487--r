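# Band-wise analytic-signal extraction and cross-brain phase-synchrony
# measures. PLV is the modulus of the trial-averaged unit phasor of the
# phase difference (0 = no phase relation, 1 = perfect locking); ciPLV
# discounts the real (zero-lag) part of the mean phasor; wPLI weights
# phase-difference signs by the magnitude of the imaginary cross-spectrum.

#' Band-limit epochs and take the analytic signal
#'
#' For each trial and channel the epoch is band-pass filtered with the
#' zero-phase FIR of [bandpass_fir()] and extended by mirror reflection
#' before the Hilbert/analytic construction, suppressing edge transients.
#' The instantaneous phase is the argument of the analytic value, in
#' (-pi, pi].
#'
#' @param epochs An `epoch_set`.
#' @param band Band name (one of [band_specs()]) or a list/row with
#'   `name`, `lo`, `hi`.
#' @return An object of class `analytic_tensor`: complex `values`
#'   (trials x channels x samples), `times`, `fs`, `band`, `labels`.
#' @export
analytic_band <- function(epochs, band) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(band)) band <- band_spec(band)
  if (band$hi >= epochs$fs / 2) stop("band exceeds the Nyquist frequency")
  d <- dim(epochs$data)
  nt <- d[1]; nc <- d[2]; ns <- d[3]
  kernel <- fir_bandpass_kernel(band$lo, band$hi, epochs$fs)
  if (ns < length(kernel) / 3)
    stop("epoch shorter than a third of the filter length for band ", band$name)
  pad <- min(ns - 1L, as.integer(epochs$fs))
  out <- array(complex(real = 0), d)
  idx_front <- (pad + 1L):2L
  idx_back <- (ns - 1L):(ns - pad)
  for (k in seq_len(nt)) {
    x <- t(epochs$data[k, , , drop = TRUE])        # samples x channels
    if (nc == 1L) x <- matrix(epochs$data[k, 1L, ], ncol = 1L)
    xf <- fft_filter_cols(x, kernel)
    xp <- rbind(xf[idx_front, , drop = FALSE], xf, xf[idx_back, , drop = FALSE])
    a <- analytic_cols(xp)[(pad + 1L):(pad + ns), , drop = FALSE]
    out[k, , ] <- t(a)
  }
  structure(list(values = out, times = epochs$times, fs = epochs$fs,
                 band = band$name, labels = epochs$labels,
                 channels = epochs$channels),
            class = "analytic_tensor")
}

#' Instantaneous phase of an analytic tensor
#'
#' @param at An `analytic_tensor`.
#' @return Array of phases (radians, in (-pi, pi]) with the tensor's shape.
#' @export
instantaneous_phase <- function(at) Arg(at$values)

#' Cross-brain pairwise connectivity
#'
#' Computes, for every channel pair (i from A, j from B) and time sample,
#' a phase-synchrony measure across the N trials. With
#' `m(t) = mean_n exp(1i * (phi_Ai,n(t) - phi_Bj,n(t)))` and cross-spectrum
#' `S_n(t) = a_n(t) * Conj(b_n(t))`:
#' \itemize{
#'   \item `plv`: `|m(t)|`
#'   \item `ciplv`: `|Im m(t)| / sqrt(1 - Re(m(t))^2)`
#'   \item `wpli`: `|sum_n Im S_n| / sum_n |Im S_n|`, defined as 0 when the
#'     denominator is 0 (zero-lag dependence carries no lag information).
#' }
#' With `time_resolved = FALSE` the phasor average runs over time within
#' each trial and then across trials (a trial-resolved variant).
#'
#' @param A,B `analytic_tensor`s with identical trials, samples and band.
#' @param measure `"plv"`, `"ciplv"` or `"wpli"`.
#' @param time_resolved Average across trials per time sample (default) or
#'   across time within trial first.
#' @return Object of class `pair_connectivity`: `values`
#'   (channels_A x channels_B x time, or x 1), `measure`, `band`, `times`,
#'   `fs`, `n_trials`, `baseline_corrected`.
#' @export
pair_connectivity <- function(A, B, measure = c("plv", "ciplv", "wpli"),
                              time_resolved = TRUE) {
  measure <- match.arg(measure)
  stopifnot(inherits(A, "analytic_tensor"), inherits(B, "analytic_tensor"))
  da <- dim(A$values); db <- dim(B$values)
  if (da[1] != db[1] || da[3] != db[3])
    stop("A and B must share trial count and sample count")
  if (!identical(A$band, B$band)) stop("A and B must share the band")
  if (da[1] < 2L) stop("need at least 2 trials")
  nt <- da[1]; na <- da[2]; nb <- db[2]; ns <- da[3]

  if (time_resolved) {
    t_idx <- seq_len(ns)
    vals <- conn_at_times(A$values, B$values, t_idx, measure)
    times <- A$times
  } else {
    vals <- array(0, c(na, nb, 1L))
    ua <- A$values / Mod(A$values)
    ub <- B$values / Mod(B$values)
    for (i in seq_len(na)) {
      ai <- ua[, i, , drop = TRUE]
      if (nt == 1L) ai <- matrix(ai, 1L)
      for (j in seq_len(nb)) {
        bj <- ub[, j, , drop = TRUE]
        if (nt == 1L) bj <- matrix(bj, 1L)
        z <- rowMeans(ai * Conj(bj))   # per-trial time-averaged phasor
        vals[i, j, 1L] <- summarise_phasor(mean(z), measure = measure)
      }
    }
    if (measure == "wpli") stop("wpli has no trial-resolved variant")
    times <- NA_real_
  }
  structure(list(values = vals, measure = measure, band = A$band,
                 times = times, fs = A$fs, n_trials = nt,
                 channels_a = A$channels, channels_b = B$channels,
                 baseline_corrected = FALSE),
            class = "pair_connectivity")
}

summarise_phasor <- function(m, measure) {
  if (measure == "plv") Mod(m)
  else if (measure == "ciplv") {
    den <- sqrt(pmax(1 - Re(m)^2, .Machine$double.eps))
    abs(Im(m)) / den
  } else stop("unsupported")
}

# core kernel: measure at the requested time indices for all channel pairs
conn_at_times <- function(av, bv, t_idx, measure) {
  d <- dim(av)
  nt <- d[1]; na <- d[2]; nb <- dim(bv)[2]
  out <- array(0, c(na, nb, length(t_idx)))
  if (measure %in% c("plv", "ciplv")) {
    ua <- av / Mod(av)
    ub <- bv / Mod(bv)
    for (k in seq_along(t_idx)) {
      tt <- t_idx[k]
      Ua <- matrix(ua[, , tt], nt, na)
      Ub <- matrix(ub[, , tt], nt, nb)
      m <- crossprod(Ua, Conj(Ub)) / nt   # t(Ua) %*% Conj(Ub)
      out[, , k] <- if (measure == "plv") Mod(m) else {
        den <- sqrt(pmax(1 - Re(m)^2, .Machine$double.eps))
        abs(Im(m)) / den
      }
    }
  } else {  # wpli: needs per-trial imaginary cross-spectra
    for (i in seq_len(na)) {
      ai <- matrix(av[, i, t_idx], nt)
      for (j in seq_len(nb)) {
        bj <- matrix(bv[, j, t_idx], nt)
        imS <- Im(ai * Conj(bj))
        num <- abs(.colSums(imS, nt, ncol(imS)))
        den <- .colSums(abs(imS), nt, ncol(imS))
        w <- ifelse(den > 0, num / den, 0)
        out[i, j, ] <- w
      }
    }
  }
  out
}

#' @export
print.pair_connectivity <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pair_connectivity> %s, %s band: %d x %d pairs x %d time points, %d trials%s\n",
              x$measure, x$band, d[1], d[2], d[3], x$n_trials,
              if (x$baseline_corrected) " (baseline-corrected)" else ""))
  invisible(x)
}

#' Baseline-correct connectivity time courses
#'
#' Subtracts, per channel pair, the mean over the baseline window
#' (default `[-3, 0)` s, half-open) from the whole time course.
#'
#' @param pc A time-resolved `pair_connectivity`.
#' @param window Baseline window `c(from, to)` in seconds (half-open).
#' @return The corrected `pair_connectivity` (flag set).
#' @export
baseline_correct <- function(pc, window = c(-3, 0)) {
  stopifnot(inherits(pc, "pair_connectivity"))
  idx <- which(pc$times >= window[1] & pc$times < window[2])
  if (!length(idx)) stop("baseline window outside the time axis")
  base <- apply(pc$values[, , idx, drop = FALSE], c(1, 2), mean)
  pc$values <- sweep(pc$values, c(1, 2), base, "-")
  pc$baseline_corrected <- TRUE
  pc
}

#' Event-window mean connectivity
#'
#' Averages each pair's time course over the event window (default
#' 200-500 ms post-stimulus, endpoints inclusive at sample resolution).
#'
#' @param pc A time-resolved `pair_connectivity`.
#' @param window `c(from, to)` in seconds, inclusive.
#' @return A channels_A x channels_B matrix.
#' @export
event_window_mean <- function(pc, window = c(0.2, 0.5)) {
  stopifnot(inherits(pc, "pair_connectivity"))
  eps <- 1e-9
  idx <- which(pc$times >= window[1] - eps & pc$times <= window[2] + eps)
  if (!length(idx)) stop("event window empty after discretisation")
  out <- apply(pc$values[, , idx, drop = FALSE], c(1, 2), mean)
  dimnames(out) <- list(pc$channels_a, pc$channels_b)
  out
}

#' Aggregate a channel-pair matrix into region pairs
#'
#' Region-pair value = mean over member channel pairs, so the pair-count
#' weighted mean of the 5 x 5 region matrix equals the grand mean of the
#' 32 x 32 input.
#'
#' @param mat Channels_A x channels_B matrix with channel-label dimnames.
#' @param map Named region vector, as from [region_map()].
#' @return 5 x 5 region matrix (rows = participant A regions).
#' @export
aggregate_by_region <- function(mat, map = region_map()) {
  regions <- c("frontal", "central", "temporal", "parietal", "occipital")
  ra <- map[rownames(mat)]; rb <- map[colnames(mat)]
  if (any(is.na(ra)) || any(is.na(rb)))
    stop("unmapped channel(s): ",
         paste(unique(c(rownames(mat)[is.na(ra)], colnames(mat)[is.na(rb)])),
               collapse = ", "))
  fa <- factor(ra, regions); fb <- factor(rb, regions)
  sums <- rowsum(t(rowsum(mat, fa)), fb)      # occupancy sums, then transpose back
  counts <- table(fa) %o% table(fb)
  out <- t(sums) / counts
  dimnames(out) <- list(regions, regions)
  out
}
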