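# Behavioral metrics: target-search times derived from the 700-ms lock
# rule, inter-gaze Euclidean distance, gaze occupancy heatmaps and their
# similarity coefficients (Pearson r, SSIM, Jaccard).

#' Target-lock onsets per trial
#'
#' The lock onset is defined as 0.7 s before target identification. For
#' each trial, identification events (`code == "ident"`) are converted to
#' onsets relative to the trial's stimulus; onsets that would precede the
#' stimulus are clamped to it and flagged.
#'
#' @param events Event data frame (`time`, `code`, `participant`, `cell`,
#'   `mode`, `run`, `trial`).
#' @param participant Optional participant filter (`"a"` or `"b"`).
#' @return Data frame `trial`, `mode`, `run`, `participant`, `cell`,
#'   `onset` (s after stimulus, ordered within trial), `clamped`.
#' @export
lock_onsets <- function(events, participant = NULL) {
  stim <- events[events$code == "stimulus_onset", c("trial", "time")]
  ids <- events[events$code == "ident", , drop = FALSE]
  if (!is.null(participant)) ids <- ids[ids$participant %in% participant, ]
  if (!nrow(ids))
    return(data.frame(trial = integer(0), mode = character(0),
                      run = integer(0), participant = character(0),
                      cell = integer(0), onset = numeric(0),
                      clamped = logical(0)))
  stim_time <- stim$time[match(ids$trial, stim$trial)]
  onset <- ids$time - 0.7 - stim_time
  clamped <- onset < 0
  onset[clamped] <- 0
  out <- data.frame(trial = ids$trial, mode = ids$mode, run = ids$run,
                    participant = ids$participant, cell = ids$cell,
                    onset = onset, clamped = clamped,
                    stringsAsFactors = FALSE)
  out[order(out$trial, out$onset), ]
}

#' Target-searching times from ordered lock onsets
#'
#' The first TST is the time from the stimulus to the first lock onset;
#' each remaining TST is the time between consecutive lock onsets, so the
#' TSTs telescope to the last onset.
#'
#' @param onsets Sorted lock-onset times (s after stimulus).
#' @param stimulus Stimulus time on the same clock (default 0).
#' @return Numeric vector of TSTs (one per onset).
#' @export
tst_sequence <- function(onsets, stimulus = 0) {
  if (is.unsorted(onsets)) stop("onsets must be sorted")
  if (!length(onsets)) return(numeric(0))
  diff(c(stimulus, onsets))
}

#' Trimmed mean with 10% outlier removal
#'
#' Removes `ceiling(0.05 * n)` smallest and largest values (5% per tail
#' for the default 10% total trim) and averages the rest. If trimming
#' would empty the vector the median is returned instead, flagged via the
#' `"fallback"` attribute.
#'
#' @param values Non-empty numeric vector.
#' @param trim Total trim fraction (default 0.10).
#' @return Scalar mean (with `"fallback"` attribute when the median path
#'   was used).
#' @export
trimmed_mean <- function(values, trim = 0.10) {
  if (!length(values)) stop("empty input")
  n <- length(values)
  k <- ceiling(trim / 2 * n)
  if (2 * k >= n) {
    out <- stats::median(values)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  s <- sort(values)
  mean(s[(k + 1):(n - k)])
}

#' Per-trial target-searching-time table
#'
#' Builds the TST table (one row per identified target) and trimmed-mean
#' summaries per participant, mode, target-count condition and target
#' order.
#'
#' @param events Event table of one dyad recording.
#' @param schedule Trial schedule with `trial` and `n_targets`.
#' @param dyad Dyad identifier stored in the output.
#' @return List with `table` (trial-level rows: `participant`, `mode`,
#'   `run`, `trial`, `n_targets`, `k` (target order), `tst`) and `summary`
#'   (trimmed means per participant x mode x n_targets x k).
#' @export
tst_table <- function(events, schedule, dyad = NA) {
  lo <- lock_onsets(events)
  if (!nrow(lo))
    return(list(table = data.frame(), summary = data.frame()))
  lo$n_targets <- schedule$n_targets[match(lo$trial, schedule$trial)]
  rows <- do.call(rbind, lapply(split(lo, list(lo$trial, lo$participant),
                                      drop = TRUE), function(d) {
    d <- d[order(d$onset), ]
    data.frame(dyad = dyad, participant = d$participant[1], mode = d$mode[1],
               run = d$run[1], trial = d$trial[1], n_targets = d$n_targets[1],
               k = seq_len(nrow(d)), tst = tst_sequence(d$onset),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  smry <- stats::aggregate(tst ~ participant + mode + n_targets + k, rows,
                           function(v) as.numeric(trimmed_mean(v)))
  smry$dyad <- dyad
  list(table = rows, summary = smry)
}

#' Mean inter-gaze distance
#'
#' Interpolates both tracks onto a common uniform clock within the window
#' and averages the per-sample Euclidean distance where both tracks are
#' valid (a resampled point is valid only if both neighbouring source
#' samples are).
#'
#' @param a,b Gaze tracks (`t`, `x`, `y`, `valid`).
#' @param window `c(from, to)` in seconds on the common clock, or `NULL`
#'   for the full overlap.
#' @param fs Resampling rate (Hz).
#' @return Mean distance in pixels.
#' @export
gaze_distance <- function(a, b, window = NULL, fs = 30) {
  t0 <- max(min(a$t), min(b$t))
  t1 <- min(max(a$t), max(b$t))
  if (!is.null(window)) {
    t0 <- max(t0, window[1]); t1 <- min(t1, window[2])
  }
  if (t1 <= t0) stop("no jointly covered time range")
  tt <- seq(t0, t1, by = 1 / fs)
  interp <- function(g) {
    x <- stats::approx(g$t, g$x, xout = tt)$y
    y <- stats::approx(g$t, g$y, xout = tt)$y
    v <- stats::approx(g$t, as.numeric(g$valid), xout = tt)$y >= 1
    list(x = x, y = y, v = v & !is.na(x))
  }
  ia <- interp(a); ib <- interp(b)
  ok <- ia$v & ib$v
  if (!any(ok)) stop("no jointly valid samples in the window")
  mean(sqrt((ia$x[ok] - ib$x[ok])^2 + (ia$y[ok] - ib$y[ok])^2))
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

convolve_rows <- function(m, k) {
  # same-size 1-D convolution along rows, zero padding
  t(apply(m, 1, function(v) {
    full <- stats::convolve(v, rev(k), type = "open")
    r <- (length(k) - 1) / 2
    full[(r + 1):(r + length(v))]
  }))
}

#' Gaze occupancy heatmap
#'
#' 2-D histogram of valid gaze samples over a regular grid spanning the
#' screen, optionally Gaussian-smoothed (separable kernel, sigma in
#' cells), renormalised to total mass 1.
#'
#' @param track Gaze track (`t`, `x`, `y`, `valid`), or a data frame
#'   binding several trials' tracks.
#' @param nx,ny Grid size (default 96 x 54: 20-px cells on a 1920 x 1080
#'   screen).
#' @param extent Screen extent `c(width, height)` in pixels.
#' @param sigma Smoothing SD in cells (0 = none).
#' @return Object of class `gaze_heatmap`: `grid` (ny x nx matrix of
#'   occupancy probabilities, rows = y), `extent`, `sigma`.
#' @export
gaze_heatmap <- function(track, nx = 96L, ny = 54L, extent = c(1920, 1080),
                         sigma = 1.5) {
  ok <- track$valid & !is.na(track$x) & !is.na(track$y)
  if (!any(ok)) stop("zero valid gaze samples")
  x <- pmin(pmax(track$x[ok], 0), extent[1] - 1e-9)
  y <- pmin(pmax(track$y[ok], 0), extent[2] - 1e-9)
  ix <- floor(x / extent[1] * nx) + 1
  iy <- floor(y / extent[2] * ny) + 1
  grid <- matrix(0, ny, nx)
  counts <- table(factor((ix - 1) * ny + iy, levels = seq_len(nx * ny)))
  grid[] <- as.numeric(counts)
  if (sigma > 0) {
    k <- gaussian_kernel_1d(sigma)
    grid <- convolve_rows(t(convolve_rows(grid, k)), k)
    grid <- t(grid)
    grid[grid < 0] <- 0   # numerical fuzz from FFT convolution
  }
  grid <- grid / sum(grid)
  structure(list(grid = grid, extent = extent, sigma = sigma),
            class = "gaze_heatmap")
}

box_window_stats <- function(m, w) {
  # sliding w x w window mean via separable box filter; "valid" region only
  box1 <- function(mat) {
    cs <- apply(mat, 2, cumsum)
    cs <- rbind(0, cs)
    (cs[(w + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]) / w
  }
  t(box1(t(box1(m))))
}

#' Similarity between two gaze heatmaps
#'
#' Three coefficients on identically gridded heatmaps:
#' \itemize{
#'   \item Pearson r of the flattened cells (NA if either map has zero
#'     variance);
#'   \item SSIM: mean structural similarity over sliding `ssim_window`
#'     windows (cells rescaled to `[0, 1]` by their joint maximum;
#'     stabilising constants `C1 = 0.01^2`, `C2 = 0.03^2`);
#'   \item Jaccard: `|A & B| / |A | B|` after binarising at
#'     `threshold` (default above-uniform occupancy, `1 / n_cells`).
#' }
#'
#' @param A,B `gaze_heatmap`s on the same grid.
#' @param ssim_window Sliding window side (cells, default 7).
#' @param threshold Binarisation threshold for Jaccard; default
#'   `1 / (nx * ny)`.
#' @return List `pearson`, `ssim`, `jaccard` (with the threshold used as
#'   attribute `"threshold"` on `jaccard`).
#' @export
heatmap_similarity <- function(A, B, ssim_window = 7L, threshold = NULL) {
  ga <- A$grid; gb <- B$grid
  if (!all(dim(ga) == dim(gb))) stop("heatmap grids differ")
  pearson <- if (stats::sd(ga) == 0 || stats::sd(gb) == 0) NA_real_
  else stats::cor(as.vector(ga), as.vector(gb))

  mx <- max(ga, gb)
  xa <- ga / mx; xb <- gb / mx
  w <- min(ssim_window, dim(ga))
  mu_a <- box_window_stats(xa, w); mu_b <- box_window_stats(xb, w)
  va <- box_window_stats(xa^2, w) - mu_a^2
  vb <- box_window_stats(xb^2, w) - mu_b^2
  vab <- box_window_stats(xa * xb, w) - mu_a * mu_b
  c1 <- 0.01^2; c2 <- 0.03^2
  ssim_map <- ((2 * mu_a * mu_b + c1) * (2 * vab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  ssim <- mean(ssim_map)

  thr <- threshold %||% (1 / length(ga))
  ba <- ga > thr; bb <- gb > thr
  uni <- sum(ba | bb)
  jac <- if (uni == 0) 0 else sum(ba & bb) / uni
  attr(jac, "threshold") <- thr
  list(pearson = pearson, ssim = ssim, jaccard = jac)
}
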