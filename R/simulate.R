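# Synthetic dyad generator: paired 32-channel EEG with controllable
# interbrain phase coupling, paired gaze trajectories with mode-dependent
# attraction/repulsion, and the full trial/event structure of the
# shared-gaze visual search paradigm (3-s fixation, 300-ms auditory
# stimulus, 10-s search, 13-s trials, three task modes).

default_coupling <- function() {
  # wrapped-normal phase-noise SDs (radians): c(sigma_base, sigma_event).
  # Coupling is concentrated in the slow bands, strongest in cooperation,
  # intermediate in competition, weakest in single-player mode, and tighter
  # inside the post-stimulus event window than at baseline.
  list(
    single = list(delta = c(2.2, 1.6), theta = c(2.2, 1.6),
                  alpha = c(2.5, 2.2), beta = c(3.0, 3.0), gamma = c(3.0, 3.0)),
    cooperation = list(delta = c(1.6, 0.8), theta = c(1.6, 0.8),
                       alpha = c(2.2, 1.8), beta = c(3.0, 3.0), gamma = c(3.0, 3.0)),
    competition = list(delta = c(1.8, 1.1), theta = c(1.8, 1.1),
                       alpha = c(2.3, 2.0), beta = c(3.0, 3.0), gamma = c(3.0, 3.0))
  )
}

default_sim_bands <- function() {
  bs <- band_specs()
  bs$amplitude <- c(20, 10, 15, 5, 2)  # microvolts
  bs
}

#' Simulation configuration
#'
#' Builds the configuration for the synthetic dyad generator. Defaults
#' reproduce the study paradigm: 29 dyads, 250 Hz EEG, 13-s trials
#' (3-s fixation, 300-ms auditory stimulus, 10-s search that begins at
#' stimulus onset), 40 trials per mode (20 per run, two runs) in three
#' modes (single-player, cooperation, competition), five oscillatory bands
#' plus 1/f background noise, wrapped-normal cross-brain phase coupling
#' whose strength differs between baseline and the post-stimulus event
#' window, and gaze attraction coefficients of +0.8 (cooperation), -0.8
#' (competition) and 0 (single-player).
#'
#' @param n_dyads Number of dyads.
#' @param fs EEG sampling rate (Hz).
#' @param n_trials_per_mode Trials per mode (both runs together).
#' @param bands Data frame `name, lo, hi, amplitude` of simulated oscillators.
#' @param coupling Per-mode, per-band list of `c(sigma_base, sigma_event)`
#'   wrapped-normal phase-noise SDs in radians (`Inf` = uncoupled), or
#'   `NULL` for fully uncoupled participants.
#' @param phase_lag Constant cross-brain phase offset in radians, or
#'   `"random"` to draw one per dyad and band.
#' @param coupling_event_window Post-stimulus window (s, relative to
#'   stimulus onset) in which `sigma_event` applies.
#' @param mixing Optional 64 x 64 instantaneous mixing matrix (two stacked
#'   32-channel blocks; cross-participant blocks must be zero).
#' @param noise_amp RMS amplitude (microvolts) of the per-channel 1/f
#'   background noise.
#' @param gaze_fs Gaze sampling rate (Hz); consumer eye-tracker class.
#' @param gaze_coupling Named attraction coefficients in `[-1, 1]` per mode.
#' @param grid Screen/target geometry: `width`, `height` (px), `cells`
#'   (per side of the target matrix) and `cell_px`.
#' @param simulate_gaze Generate gaze tracks and gaze-derived lock events
#'   (disable to generate EEG-only recordings faster).
#' @param seed Integer root seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_dyads = 29L,
                       fs = 250,
                       n_trials_per_mode = 40L,
                       bands = default_sim_bands(),
                       coupling = default_coupling(),
                       phase_lag = "random",
                       coupling_event_window = c(0, 0.5),
                       mixing = NULL,
                       noise_amp = 5,
                       gaze_fs = 30,
                       gaze_coupling = c(single = 0, cooperation = 0.8,
                                         competition = -0.8),
                       grid = list(width = 1920, height = 1080,
                                   cells = 4L, cell_px = 150),
                       simulate_gaze = TRUE,
                       seed = 1L) {
  layout <- list(fixation_s = 3, stimulus_s = 0.3, search_s = 10, trial_s = 13)
  if (any(bands$hi * 2 >= fs)) stop("fs must exceed twice the highest band edge")
  if (!is.null(coupling)) {
    sig <- unlist(coupling)
    if (any(sig < 0)) stop("sigma values must be non-negative")
  }
  if (any(abs(gaze_coupling) > 1)) stop("attraction coefficients must lie in [-1, 1]")
  if (!is.null(mixing)) check_mixing(mixing)
  if (n_trials_per_mode %% 2L != 0L)
    stop("n_trials_per_mode must be even (two runs)")
  structure(list(
    n_dyads = as.integer(n_dyads), fs = fs, trial_layout = layout,
    n_trials_per_mode = as.integer(n_trials_per_mode),
    modes = c("single", "cooperation", "competition"),
    bands = bands, coupling = coupling, phase_lag = phase_lag,
    coupling_event_window = coupling_event_window,
    mixing = mixing, noise_amp = noise_amp, gaze_fs = gaze_fs,
    gaze_coupling = gaze_coupling, grid = grid,
    simulate_gaze = isTRUE(simulate_gaze), seed = as.integer(seed)
  ), class = "sim_config")
}

check_mixing <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(64L, 64L)))
    stop("mixing matrix must be 64 x 64 (two stacked 32-channel blocks)")
  off1 <- M[1:32, 33:64]; off2 <- M[33:64, 1:32]
  if (any(off1 != 0) || any(off2 != 0))
    stop("cross-participant mixing blocks must be zero (mixing never crosses heads)")
  invisible(TRUE)
}

mode_schedule <- function(config, dyad_index) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  ord <- config$modes[perms[[(dyad_index - 1L) %% 6L + 1L]]]
  blocks <- data.frame(
    block = 1:6,
    mode = c(ord, rev(ord)),
    run = rep(1:2, each = 3),
    stringsAsFactors = FALSE
  )
  per_block <- config$n_trials_per_mode %/% 2L
  trials <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
    data.frame(block = b, mode = blocks$mode[b], run = blocks$run[b],
               trial_in_block = seq_len(per_block), stringsAsFactors = FALSE)
  }))
  trials$trial <- seq_len(nrow(trials))
  trials$t0 <- (trials$trial - 1) * config$trial_layout$trial_s
  trials$stim_time <- trials$t0 + config$trial_layout$fixation_s
  trials
}

gender_composition <- function(dyad_index, n_dyads) {
  # study-like mixture: about 62% female-female, one male-male dyad, the
  # rest female-male
  n_ff <- max(1L, round(0.62 * n_dyads))
  n_mm <- if (n_dyads >= 3L) 1L else 0L
  if (dyad_index <= n_ff) "FF" else if (dyad_index > n_dyads - n_mm) "MM" else "FM"
}

# AR(1) instantaneous-frequency jitter around a band's centre frequency
phase_ramp <- function(n, f_centre, f_sd, fs) {
  e <- stats::rnorm(n, 0, f_sd * sqrt(1 - 0.995^2))
  jitter <- as.numeric(stats::filter(e, 0.995, method = "recursive"))
  phi0 <- stats::runif(1, 0, 2 * pi)
  phi0 + cumsum(2 * pi * (f_centre + jitter) / fs)
}

one_over_f_noise <- function(n, rms) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  half <- (nfft - 1L) %/% 2L          # positive non-Nyquist frequencies
  mag <- 1 / sqrt(seq_len(half))
  pos <- complex(real = stats::rnorm(half), imaginary = stats::rnorm(half)) * mag
  full <- if (nfft %% 2L == 0L)
    c(0, pos, stats::rnorm(1) / sqrt(half + 1), Conj(rev(pos)))
  else c(0, pos, Conj(rev(pos)))
  x <- Re(stats::fft(full, inverse = TRUE))[1:n]
  x * rms / stats::sd(x)
}

#' Simulate one dyad recording
#'
#' Generates a paired EEG + gaze recording for one dyad under the
#' configured paradigm. Each band is an oscillator whose phase ramps with
#' AR(1) frequency jitter in participant A; participant B's band phase is
#' A's phase plus a constant offset plus wrapped-normal noise drawn once
#' per trial and window (`sigma_event` inside the post-stimulus coupling
#' window, `sigma_base` elsewhere; `Inf` yields an independent oscillator).
#' Channels share the participant's band oscillators up to fixed
#' channel-specific phase offsets; independent 1/f background noise is
#' added per channel. Gaze tracks and gaze-derived target-lock events come
#' from [simulate_gaze_pair()]. The recording is deterministic given the
#' configuration seed and dyad index.
#'
#' @param config A [sim_config()] object.
#' @param dyad_index Dyad number in `1:n_dyads`.
#' @return A list with components `recording` (class `dyad_recording`) and
#'   `truth` (ground-truth coupling parameters, expected asymptotic PLV
#'   `exp(-sigma^2/2)` per mode and band, the trial/target schedule, and
#'   per-trial lock onsets).
#' @export
simulate_dyad <- function(config, dyad_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (dyad_index < 1L || dyad_index > config$n_dyads)
    stop("dyad_index must lie in 1:n_dyads")
  fs <- config$fs
  layout <- config$trial_layout
  trials <- mode_schedule(config, dyad_index)
  n_trials <- nrow(trials)
  spt <- as.integer(round(layout$trial_s * fs))  # samples per trial
  n_samp <- n_trials * spt
  labels <- eeg_montage()

  seed_d <- derive_seed(config$seed, dyad_index)
  rec <- with_seed(seed_d, {
    # per-trial target schedule
    per_block <- config$n_trials_per_mode %/% 2L
    n_targets <- unlist(lapply(unique(trials$block), function(b)
      sample(rep_len(c(1L, 3L, 5L), per_block))))
    trials$n_targets <- n_targets
    n_cells <- config$grid$cells^2
    targets <- lapply(n_targets, function(k) sort(sample.int(n_cells, k)))

    bands <- config$bands
    nb <- nrow(bands)
    t_in_trial <- rep(seq(0, layout$trial_s - 1 / fs, by = 1 / fs), n_trials)
    in_event <- t_in_trial >= layout$fixation_s + config$coupling_event_window[1] &
      t_in_trial <= layout$fixation_s + config$coupling_event_window[2]
    trial_of_sample <- rep(seq_len(n_trials), each = spt)

    phases_a <- matrix(0, n_samp, nb)
    phases_b <- matrix(0, n_samp, nb)
    truth_rows <- list()
    for (bi in seq_len(nb)) {
      f_c <- (bands$lo[bi] + bands$hi[bi]) / 2
      f_sd <- 0.05 * (bands$hi[bi] - bands$lo[bi])
      phi_a <- phase_ramp(n_samp, f_c, f_sd, fs)
      offset <- if (identical(config$phase_lag, "random"))
        stats::runif(1, 0, 2 * pi) else config$phase_lag
      band_name <- bands$name[bi]
      sig <- vapply(config$modes, function(m) {
        s <- config$coupling[[m]][[band_name]]
        if (is.null(s)) c(Inf, Inf) else s
      }, numeric(2))
      if (is.null(config$coupling) || all(is.infinite(sig))) {
        phi_b <- phase_ramp(n_samp, f_c, f_sd, fs)
      } else {
        sb <- sig[1, trials$mode[trial_of_sample]]
        se <- sig[2, trials$mode[trial_of_sample]]
        eps_base <- stats::rnorm(n_trials)[trial_of_sample] * sb
        eps_event <- stats::rnorm(n_trials)[trial_of_sample] * se
        eps <- ifelse(in_event, eps_event, eps_base)
        phi_b <- phi_a + offset + eps
        # any Inf sigma in some mode: replace those stretches with an
        # independent ramp
        if (any(is.infinite(eps))) {
          indep <- phase_ramp(n_samp, f_c, f_sd, fs)
          bad <- is.infinite(eps)
          phi_b[bad] <- indep[bad]
        }
      }
      phases_a[, bi] <- phi_a
      phases_b[, bi] <- phi_b
      for (m in config$modes) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          dyad = dyad_index, mode = m, band = band_name,
          sigma_base = sig[1, m], sigma_event = sig[2, m],
          plv_base = exp(-sig[1, m]^2 / 2),
          plv_event = exp(-sig[2, m]^2 / 2),
          phase_lag = offset, stringsAsFactors = FALSE)
      }
    }

    build_eeg <- function(phases) {
      eeg <- matrix(0, 32L, n_samp, dimnames = list(labels, NULL))
      ch_off <- matrix(stats::runif(32L * nb, 0, 2 * pi), 32L, nb)
      for (ch in 1:32) {
        s <- numeric(n_samp)
        for (bi in seq_len(nb))
          s <- s + config$bands$amplitude[bi] * sin(phases[, bi] + ch_off[ch, bi])
        if (config$noise_amp > 0)
          s <- s + one_over_f_noise(n_samp, config$noise_amp)
        eeg[ch, ] <- s
      }
      eeg
    }
    eeg_a <- build_eeg(phases_a)
    eeg_b <- build_eeg(phases_b)

    # events and gaze
    ev <- list()
    gaze_a <- gaze_b <- list()
    lock_rows <- list()
    for (k in seq_len(n_trials)) {
      t0 <- trials$t0[k]
      ev[[length(ev) + 1L]] <- data.frame(
        time = c(t0, trials$stim_time[k], t0 + layout$trial_s),
        code = c("fixation_onset", "stimulus_onset", "trial_end"),
        participant = NA_character_, cell = NA_integer_,
        mode = trials$mode[k], run = trials$run[k], trial = k,
        stringsAsFactors = FALSE)
      if (config$simulate_gaze) {
        gp <- simulate_gaze_pair(
          mode = trials$mode[k], targets = targets[[k]],
          attraction = unname(config$gaze_coupling[trials$mode[k]]),
          grid = config$grid, gaze_fs = config$gaze_fs,
          trial_layout = layout, seed = derive_seed(seed_d, 1000L + k))
        ga <- gp$a; gb <- gp$b
        ga$t <- ga$t + t0; gb$t <- gb$t + t0
        gaze_a[[k]] <- ga; gaze_b[[k]] <- gb
        if (nrow(gp$idents)) {
          id <- gp$idents
          id$time <- id$time + t0
          ev[[length(ev) + 1L]] <- data.frame(
            time = id$time, code = "ident", participant = id$participant,
            cell = id$cell, mode = trials$mode[k], run = trials$run[k],
            trial = k, stringsAsFactors = FALSE)
          lock_rows[[length(lock_rows) + 1L]] <-
            cbind(id, trial = k, onset = id$time - 0.7)
        }
      }
    }
    events <- do.call(rbind, ev)
    events <- events[order(events$time, method = "radix"), ]
    rownames(events) <- NULL

    gaze_a <- if (length(gaze_a)) do.call(rbind, gaze_a) else
      data.frame(t = numeric(0), x = numeric(0), y = numeric(0), valid = logical(0))
    gaze_b <- if (length(gaze_b)) do.call(rbind, gaze_b) else gaze_a

    rec <- dyad_recording(
      eeg_a = eeg_a, eeg_b = eeg_b, fs = fs, labels = labels,
      gaze_a = gaze_a, gaze_b = gaze_b, events = events,
      meta = list(dyad_id = dyad_index,
                  gender = gender_composition(dyad_index, config$n_dyads),
                  schedule = trials, seed = seed_d))
    truth <- list(
      coupling = do.call(rbind, truth_rows),
      trials = cbind(trials, n_targets = trials$n_targets),
      targets = targets,
      locks = if (length(lock_rows)) do.call(rbind, lock_rows) else NULL)
    list(recording = rec, truth = truth)
  })
  if (!is.null(config$mixing))
    rec$recording <- apply_mixing(rec$recording, config$mixing)
  rec
}

#' Apply an instantaneous within-head mixing matrix
#'
#' Replaces every stacked 64-channel sample vector (participant A's 32
#' channels over participant B's) by `M %*% vector`. Cross-participant
#' blocks of `M` must be zero: instantaneous mixing models volume
#' conduction, which never crosses heads. Useful for studying how zero-lag
#' mixing inflates PLV while ciPLV and wPLI stay at their null levels.
#'
#' @param rec A `dyad_recording`.
#' @param M A 64 x 64 mixing matrix with zero off-head blocks.
#' @return The mixed `dyad_recording`.
#' @export
apply_mixing <- function(rec, M) {
  stopifnot(inherits(rec, "dyad_recording"))
  check_mixing(M)
  stacked <- rbind(rec$eeg_a, rec$eeg_b)
  mixed <- M %*% stacked
  rec$eeg_a <- mixed[1:32, , drop = FALSE]
  rec$eeg_b <- mixed[33:64, , drop = FALSE]
  rownames(rec$eeg_a) <- rownames(rec$eeg_b) <- rec$labels
  rec$meta$mixed <- TRUE
  rec
}

#' Expected asymptotic PLV under wrapped-normal phase noise
#'
#' Closed form for the phase locking value of a coupled pair whose
#' per-trial phase difference is constant plus wrapped-normal noise of
#' standard deviation `sigma`: `exp(-sigma^2 / 2)`.
#'
#' @param sigma Phase-noise SD in radians (vectorised).
#' @return Expected PLV in `[0, 1]`.
#' @export
plv_expected <- function(sigma) exp(-sigma^2 / 2)

#' Monte-Carlo small-sample PLV oracle
#'
#' Expected finite-trial PLV estimate under wrapped-normal phase noise:
#' the mean (and SD) over `reps` replicates of the resultant length of
#' `n_trials` unit phasors `exp(1i * eps)`, `eps ~ N(0, sigma^2)`.
#' `sigma = Inf` gives the uniform-phase null (use for the no-coupling
#' floor). Serves as the independent oracle against which estimated PLV is
#' compared: with few trials the estimate is biased upward relative to the
#' asymptotic `exp(-sigma^2/2)`.
#'
#' @param sigma Phase-noise SD in radians.
#' @param n_trials Number of trials averaged by the estimator.
#' @param reps Monte-Carlo replicates.
#' @param seed Seed.
#' @return List with `mean`, `sd` (per-estimate SD) and `se` (of the mean).
#' @export
plv_small_sample <- function(sigma, n_trials, reps = 1e5, seed = 1L) {
  with_seed(seed, {
    eps <- if (is.infinite(sigma))
      matrix(stats::runif(reps * n_trials, 0, 2 * pi), reps)
    else matrix(stats::rnorm(reps * n_trials, 0, sigma), reps)
    r <- Mod(rowMeans(exp(1i * eps)))
    list(mean = mean(r), sd = stats::sd(r), se = stats::sd(r) / sqrt(reps))
  })
}
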