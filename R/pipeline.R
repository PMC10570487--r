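# End-to-end orchestration: simulate (or load) dyad recordings, condition
# and epoch them, extract band-wise analytic signals, compute true-dyad
# and shuffled-pair connectivity, run the bootstrap null tests, derive the
# behavioral tables, and fit the condition-contrast models. Every stage is
# an exported function; run_pipeline() only sequences them.

#' Pipeline configuration
#'
#' Collects every knob of [run_pipeline()] with validated defaults. The
#' default problem size (2 bands, PLV, all 32 channels in the null stage)
#' is chosen so a full synthetic run stays tractable on one core; real
#' studies can widen `bands` and `n_boot` freely.
#'
#' @param sim A [sim_config()] describing the synthetic cohort, or `NULL`
#'   when `recordings` are passed to [run_pipeline()] directly.
#' @param bands Band names to analyse (subset of `band_specs()$name`).
#' @param measure Connectivity measure: `"plv"`, `"ciplv"` or `"wpli"`.
#' @param fs_target Analysis sampling rate (Hz).
#' @param tmin,tmax Epoch window (s) relative to stimulus onset.
#' @param baseline_window Half-open baseline window (s).
#' @param event_window Inclusive event window (s).
#' @param n_boot,m Bootstrap null parameters (means of draws).
#' @param q FDR level for the null tests and mode contrasts.
#' @param baseline_step Baseline decimation step for the event-level
#'   connectivity (the synchrony time course is smooth on the sample
#'   scale, so a stride of 10 changes baselines negligibly; see the
#'   methods vignette).
#' @param null_channels Channel labels entering the null stage (default
#'   all montage channels; restrict to bound memory and time).
#' @param heatmap List `nx`, `ny`, `sigma` for gaze heatmaps.
#' @param run_null,run_behavior,run_stats Stage switches.
#' @param out_dir Directory for CSV artifacts, or `NULL` to skip writing.
#' @param seed Root seed for the bootstrap stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), bands = c("delta", "theta"),
                       measure = c("plv", "ciplv", "wpli"),
                       fs_target = 250, tmin = -3, tmax = 10,
                       baseline_window = c(-3, 0), event_window = c(0.2, 0.5),
                       n_boot = 1000L, m = 200L, q = 0.05,
                       baseline_step = 10L, null_channels = NULL,
                       heatmap = list(nx = 96L, ny = 54L, sigma = 1.5),
                       run_null = TRUE, run_behavior = TRUE, run_stats = TRUE,
                       out_dir = NULL, seed = 1L) {
  measure <- match.arg(measure)
  known <- band_specs()$name
  if (!all(bands %in% known))
    stop("unknown band(s): ", paste(setdiff(bands, known), collapse = ", "))
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, bands = bands, measure = measure,
                 fs_target = fs_target, tmin = tmin, tmax = tmax,
                 baseline_window = baseline_window,
                 event_window = event_window,
                 n_boot = as.integer(n_boot), m = as.integer(m), q = q,
                 baseline_step = as.integer(baseline_step),
                 null_channels = null_channels, heatmap = heatmap,
                 run_null = run_null, run_behavior = run_behavior,
                 run_stats = run_stats, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

subset_trials_tensor <- function(at, mask) {
  at$values <- at$values[mask, , , drop = FALSE]
  at
}

subset_times_tensor <- function(at, idx) {
  at$values <- at$values[, , idx, drop = FALSE]
  at$times <- at$times[idx]
  at
}

subset_channels_tensor <- function(at, labels) {
  idx <- match(labels, at$channels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  at$values <- at$values[, idx, , drop = FALSE]
  at$channels <- at$channels[idx]
  at
}

# indices kept for the event-level stage: decimated baseline + event window
reduced_time_index <- function(times, event_window, baseline_window, step) {
  eps <- 1e-9
  ev <- which(times >= event_window[1] - eps & times <= event_window[2] + eps)
  bs <- which(times >= baseline_window[1] & times < baseline_window[2])
  bs <- bs[seq(1L, length(bs), by = step)]
  sort(unique(c(bs, ev)))
}

# search windows of one task mode: [stimulus, stimulus + search_s] per trial
mode_windows <- function(events, mode, search_s = 10) {
  st <- events[events$code == "stimulus_onset" & events$mode == mode, ]
  cbind(from = st$time, to = st$time + search_s, trial = st$trial)
}

in_any_window <- function(t, win) {
  if (!nrow(win)) return(rep(FALSE, length(t)))
  i <- findInterval(t, win[, "from"])
  i > 0 & t <= win[i, "to"]
}

#' Run the full dyadic-synchrony pipeline
#'
#' Stages: simulate or accept recordings; condition + epoch; band-wise
#' analytic signals; per-mode connectivity time courses and
#' baseline-corrected event means; shuffled-pair bootstrap null tests with
#' FDR; behavioral tables (target-searching times, inter-gaze distance,
#' heatmap similarity); repeated-measures and mixed-design contrasts.
#' Deterministic given the configuration.
#'
#' @param config A [run_config()].
#' @param recordings Optional list of `dyad_recording`s (e.g. from
#'   [read_xdf()]); overrides `config$sim`.
#' @return Object of class `ibs_pipeline`; see the elements `timecourses`,
#'   `event_means`, `mode_contrasts`, `null_tests`, `behavior`, `stats`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, recordings = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()

  ## 1. data
  truths <- NULL
  if (is.null(recordings)) {
    if (is.null(config$sim)) stop("either config$sim or recordings required")
    sims <- lapply(seq_len(config$sim$n_dyads),
                   function(d) simulate_dyad(config$sim, d))
    recordings <- lapply(sims, `[[`, "recording")
    truths <- lapply(sims, `[[`, "truth")
    rm(sims)
  }
  n_dyads <- length(recordings)
  if (n_dyads < 1L) stop("no recordings")
  modes <- sort(unique(recordings[[1]]$events$mode[
    recordings[[1]]$events$code == "stimulus_onset"]))

  ## 2-4. per-dyad conditioning, analytic signals, connectivity
  tc_rows <- list()
  event_means <- list()   # [[band]][[mode]]: dyads x chA x chB
  red_tensors <- list()   # [[band]][[participant]]: reduced analytic_tensor
  trial_modes <- vector("list", n_dyads)
  for (d in seq_len(n_dyads)) {
    ep <- preprocess_recording(recordings[[d]], fs_target = config$fs_target,
                               tmin = config$tmin, tmax = config$tmax)
    trial_modes[[d]] <- ep$epochs_a$labels$mode
    for (band in config$bands) {
      ta <- analytic_band(ep$epochs_a, band)
      tb <- analytic_band(ep$epochs_b, band)
      if (!is.null(config$null_channels)) {
        ta <- subset_channels_tensor(ta, config$null_channels)
        tb <- subset_channels_tensor(tb, config$null_channels)
      }
      for (mo in modes) {
        mask <- trial_modes[[d]] == mo
        if (sum(mask) < 2L) next
        pc <- pair_connectivity(subset_trials_tensor(ta, mask),
                                subset_trials_tensor(tb, mask),
                                measure = config$measure)
        pc <- baseline_correct(pc, config$baseline_window)
        tc_rows[[length(tc_rows) + 1L]] <- data.frame(
          dyad = d, band = band, mode = mo, time = pc$times,
          value = apply(pc$values, 3, mean), stringsAsFactors = FALSE)
        em <- event_window_mean(pc, config$event_window)
        if (is.null(event_means[[band]])) event_means[[band]] <- list()
        if (is.null(event_means[[band]][[mo]]))
          event_means[[band]][[mo]] <- array(
            NA_real_, c(n_dyads, nrow(em), ncol(em)),
            dimnames = c(list(NULL), dimnames(em)))
        event_means[[band]][[mo]][d, , ] <- em
      }
      ridx <- reduced_time_index(ta$times, config$event_window,
                                 config$baseline_window, config$baseline_step)
      if (is.null(red_tensors[[band]])) red_tensors[[band]] <- list()
      red_tensors[[band]][[paste0("d", d, ".a")]] <- subset_times_tensor(ta, ridx)
      red_tensors[[band]][[paste0("d", d, ".b")]] <- subset_times_tensor(tb, ridx)
    }
  }
  timecourses <- do.call(rbind, tc_rows)

  ## 5. mode contrasts per channel pair (paired t across dyads, BH-FDR)
  mode_contrasts <- NULL
  if (length(modes) >= 2L && n_dyads >= 3L) {
    mc <- list()
    combos <- utils::combn(modes, 2L)
    for (band in config$bands) for (k in seq_len(ncol(combos))) {
      m1 <- combos[1, k]; m2 <- combos[2, k]
      a1 <- event_means[[band]][[m1]]; a2 <- event_means[[band]][[m2]]
      if (is.null(a1) || is.null(a2)) next
      dn <- dimnames(a1)
      x1 <- matrix(a1, n_dyads); x2 <- matrix(a2, n_dyads)
      ok <- stats::complete.cases(x1) & stats::complete.cases(x2)
      if (sum(ok) < 3L) next
      dmat <- x1[ok, , drop = FALSE] - x2[ok, , drop = FALSE]
      mu <- colMeans(dmat)
      se <- apply(dmat, 2, stats::sd) / sqrt(sum(ok))
      tval <- ifelse(se > 0, mu / se, sign(mu) * Inf)
      p <- 2 * stats::pt(abs(tval), df = sum(ok) - 1, lower.tail = FALSE)
      grid <- expand.grid(chan_a = dn[[2]], chan_b = dn[[3]],
                          stringsAsFactors = FALSE)
      mc[[length(mc) + 1L]] <- data.frame(
        band = band, contrast = paste(m1, "vs", m2),
        chan_a = grid$chan_a, chan_b = grid$chan_b,
        diff = mu, t = tval, p = p, stringsAsFactors = FALSE)
    }
    if (length(mc)) {
      mode_contrasts <- do.call(rbind, mc)
      fdr <- fdr_bh(pmin(mode_contrasts$p, 1), config$q)
      mode_contrasts$q_value <- fdr$adjusted
      mode_contrasts$reject <- fdr$reject
      rownames(mode_contrasts) <- NULL
    }
  }

  ## 6. shuffled-pair bootstrap null per band x mode
  null_tests <- NULL
  if (config$run_null && n_dyads >= 2L) {
    dyad_table <- data.frame(a = paste0("d", seq_len(n_dyads), ".a"),
                             b = paste0("d", seq_len(n_dyads), ".b"))
    pseudo <- enumerate_shuffled_pairs(dyad_table)
    null_tests <- list()
    for (band in config$bands) for (mo in modes) {
      tens <- lapply(seq_len(n_dyads), function(d) {
        mask <- trial_modes[[d]] == mo
        list(a = subset_trials_tensor(red_tensors[[band]][[paste0("d", d, ".a")]], mask),
             b = subset_trials_tensor(red_tensors[[band]][[paste0("d", d, ".b")]], mask))
      })
      tl <- c(lapply(tens, `[[`, "a"), lapply(tens, `[[`, "b"))
      names(tl) <- c(dyad_table$a, dyad_table$b)
      true_arr <- NULL
      for (d in seq_len(n_dyads)) {
        ec <- event_connectivity(tl[[dyad_table$a[d]]], tl[[dyad_table$b[d]]],
                                 measure = config$measure,
                                 event_window = config$event_window,
                                 baseline_window = config$baseline_window,
                                 baseline_step = 1L)
        if (is.null(true_arr))
          true_arr <- array(NA_real_, c(n_dyads, nrow(ec), ncol(ec)),
                            dimnames = c(list(NULL), dimnames(ec)))
        true_arr[d, , ] <- ec
      }
      shuf <- shuffled_connectivity(tl, pseudo, measure = config$measure,
                                    event_window = config$event_window,
                                    baseline_window = config$baseline_window,
                                    baseline_step = 1L)
      null_tests[[paste(band, mo, sep = ".")]] <- ibs_null_test(
        true_arr, shuf, n_boot = config$n_boot, m = config$m, q = config$q,
        seed = derive_seed(config$seed, match(band, config$bands),
                           match(mo, modes)))
    }
  }
  rm(red_tensors)

  ## 7. behavior
  behavior <- NULL
  if (config$run_behavior && nrow(recordings[[1]]$gaze_a)) {
    tst_rows <- list(); tst_tables <- list(); gaze_rows <- list()
    for (d in seq_len(n_dyads)) {
      rec <- recordings[[d]]
      sched <- rec$meta$schedule
      if (is.null(sched)) {
        st <- rec$events[rec$events$code == "stimulus_onset", ]
        sched <- data.frame(trial = st$trial, mode = st$mode, run = st$run,
                            n_targets = NA_integer_)
      }
      tt <- tst_table(rec$events, sched, dyad = d)
      tst_tables[[d]] <- tt
      if (nrow(tt$table)) tst_rows[[d]] <- tt$table
      for (mo in modes) {
        win <- mode_windows(rec$events, mo)
        # per-trial metrics over the search window, then averaged: per-trial
        # footprints preserve scan-order differences that pooling would blur
        per_trial <- lapply(seq_len(nrow(win)), function(k) {
          sel_a <- rec$gaze_a$t >= win[k, "from"] & rec$gaze_a$t <= win[k, "to"]
          sel_b <- rec$gaze_b$t >= win[k, "from"] & rec$gaze_b$t <= win[k, "to"]
          dist <- tryCatch(gaze_distance(rec$gaze_a[sel_a, ], rec$gaze_b[sel_b, ]),
                           error = function(e) NA_real_)
          sim <- tryCatch({
            ha <- gaze_heatmap(rec$gaze_a[sel_a, ], nx = config$heatmap$nx,
                               ny = config$heatmap$ny, sigma = config$heatmap$sigma)
            hb <- gaze_heatmap(rec$gaze_b[sel_b, ], nx = config$heatmap$nx,
                               ny = config$heatmap$ny, sigma = config$heatmap$sigma)
            heatmap_similarity(ha, hb)
          }, error = function(e) list(pearson = NA_real_, ssim = NA_real_,
                                      jaccard = NA_real_))
          c(dist = dist, pearson = sim$pearson, ssim = sim$ssim,
            jaccard = as.numeric(sim$jaccard))
        })
        pt <- do.call(rbind, per_trial)
        avg <- colMeans(pt, na.rm = TRUE)
        gaze_rows[[length(gaze_rows) + 1L]] <- data.frame(
          dyad = d, mode = mo, dist = avg[["dist"]],
          pearson = avg[["pearson"]], ssim = avg[["ssim"]],
          jaccard = avg[["jaccard"]], stringsAsFactors = FALSE)
      }
    }
    behavior <- list(tst = if (length(tst_rows)) do.call(rbind, tst_rows) else NULL,
                     tst_tables = tst_tables,
                     gaze = do.call(rbind, gaze_rows))
  }

  ## 8. group statistics on the behavioral summaries
  stats_out <- NULL
  if (config$run_stats && !is.null(behavior)) {
    stats_out <- list()
    safe <- function(expr) tryCatch(expr, error = function(e) {
      message("stats stage: ", conditionMessage(e)); NULL
    })
    g <- behavior$gaze
    for (metric in c("dist", "jaccard")) {
      dd <- data.frame(subject = g$dyad, level = g$mode, value = g[[metric]])
      dd <- dd[is.finite(dd$value), ]
      stats_out[[paste0("rm_", metric)]] <-
        safe(rm_anova(dd, subject = "subject", level = "level", value = "value"))
    }
    if (!is.null(behavior$tst)) {
      tt <- behavior$tst[behavior$tst$k == 1L, ]
      agg <- stats::aggregate(tst ~ dyad + participant + mode, tt,
                              function(v) as.numeric(trimmed_mean(v)))
      agg$subject <- paste0(agg$dyad, ".", agg$participant)
      stats_out$rm_tst_first <- safe(rm_anova(
        agg, subject = "subject", level = "mode", value = "tst"))
      gender <- vapply(recordings, function(r) r$meta$gender %||% NA_character_, "")
      if (!all(is.na(gender))) {
        agg$group <- gender[agg$dyad]
        sizes <- table(unique(agg[, c("subject", "group")])$group)
        keep <- names(sizes)[sizes >= 2L]
        if (length(keep) < length(sizes))
          message("mixed model: excluding singleton group(s): ",
                  paste(setdiff(names(sizes), keep), collapse = ", "))
        agg2 <- agg[agg$group %in% keep, ]
        stats_out$mixed_tst_first <- safe(mixed_anova(
          agg2, subject = "subject", within = "mode", between = "group",
          value = "tst"))
      }
    }
  }

  out <- structure(list(
    config = config, n_dyads = n_dyads, modes = modes,
    timecourses = timecourses, event_means = event_means,
    mode_contrasts = mode_contrasts, null_tests = null_tests,
    behavior = behavior, stats = stats_out, truths = truths,
    manifest = pipeline_manifest(config, t_start)
  ), class = "ibs_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

pipeline_manifest <- function(config, t_start) {
  cfg <- config
  cfg$out_dir <- NULL                       # location-independent hash
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp, version = 2, compress = FALSE)
  list(config_hash = unname(tools::md5sum(tmp)),
       seed = config$seed,
       package_version = as.character(utils::packageVersion("dyadsync")),
       started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"))
}

write_pipeline_artifacts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(x$timecourses, "timecourses.csv")
  em <- list()
  for (band in names(x$event_means)) for (mo in names(x$event_means[[band]])) {
    a <- x$event_means[[band]][[mo]]
    em[[length(em) + 1L]] <- data.frame(
      band = band, mode = mo, dyad = seq_len(dim(a)[1]),
      mean_value = apply(a, 1, mean), stringsAsFactors = FALSE)
  }
  if (length(em)) w(do.call(rbind, em), "event_means.csv")
  w(x$mode_contrasts, "mode_contrasts.csv")
  if (!is.null(x$null_tests)) {
    nt <- do.call(rbind, lapply(names(x$null_tests), function(nm) {
      r <- x$null_tests[[nm]]$results
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      cbind(band = parts[1], mode = parts[2], r)
    }))
    w(nt, "null_tests.csv")
  }
  if (!is.null(x$behavior)) {
    w(x$behavior$tst, "tst.csv")
    w(x$behavior$gaze, "gaze_metrics.csv")
  }
  if (!is.null(x$stats)) {
    st <- do.call(rbind, lapply(names(x$stats), function(nm) {
      s <- x$stats[[nm]]
      if (is.null(s)) return(NULL)
      cbind(model = nm, s$effects)
    }))
    w(st, "stats.csv")
  }
  writeLines(jsonlite::toJSON(x$manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(NULL)
}

#' @export
print.ibs_pipeline <- function(x, ...) {
  cat(sprintf("<ibs_pipeline> %d dyads, modes: %s; bands: %s; measure: %s\n",
              x$n_dyads, paste(x$modes, collapse = "/"),
              paste(x$config$bands, collapse = "/"), x$config$measure))
  if (!is.null(x$null_tests))
    for (nm in names(x$null_tests)) {
      r <- x$null_tests[[nm]]$results
      cat(sprintf("  null [%s]: %d/%d pairs rejected (FDR q = %g)\n",
                  nm, sum(r$reject), nrow(r), x$config$q))
    }
  if (!is.null(x$behavior)) {
    g <- stats::aggregate(cbind(dist, jaccard) ~ mode, x$behavior$gaze, mean)
    for (k in seq_len(nrow(g)))
      cat(sprintf("  gaze [%s]: dist = %.1f px, jaccard = %.3f\n",
                  g$mode[k], g$dist[k], g$jaccard[k]))
  }
  cat("  config hash:", x$manifest$config_hash, "\n")
  invisible(x)
}
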