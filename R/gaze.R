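# Paired gaze-trajectory simulation for one trial of the visual search
# paradigm. The player scans the 4 x 4 target matrix cell by cell; target
# identification follows the lock rule (continuous within-cell dwell
# strictly greater than 700 ms; the lock onset is 700 ms before
# identification). The partner's dynamics depend on the task mode through
# an attraction coefficient: positive values draw its gaze toward the
# player's (cooperation), negative values repel it (competition), zero
# leaves it in free drift (the single-player observer).

cell_centres <- function(grid) {
  k <- grid$cells
  span <- k * grid$cell_px
  x0 <- (grid$width - span) / 2
  y0 <- (grid$height - span) / 2
  centres <- expand.grid(col = seq_len(k), row = seq_len(k))
  cbind(x = x0 + (centres$col - 0.5) * grid$cell_px,
        y = y0 + (centres$row - 0.5) * grid$cell_px)
}

cell_of_point <- function(x, y, grid) {
  k <- grid$cells
  span <- k * grid$cell_px
  x0 <- (grid$width - span) / 2
  y0 <- (grid$height - span) / 2
  col <- floor((x - x0) / grid$cell_px) + 1
  row <- floor((y - y0) / grid$cell_px) + 1
  idx <- (row - 1) * k + col
  idx[col < 1 | col > k | row < 1 | row > k] <- NA_integer_
  as.integer(idx)
}

# piecewise-constant goal sequence for a searching agent: scan the cells
# in random order, dwell long on targets, and after the search rest on
# the last target found (gaze lingers on the completed find; agents with
# different scan orders therefore rest on different cells)
search_goal_track <- function(n, targets, grid, gaze_fs, trial_layout) {
  centre <- c(grid$width / 2, grid$height / 2)
  centres <- cell_centres(grid)
  n_cells <- nrow(centres)
  goal <- matrix(rep(centre, each = n), n, 2)
  fix_end <- trial_layout$fixation_s + stats::runif(1, 0.15, 0.35)
  i <- as.integer(ceiling(fix_end * gaze_fs)) + 1L
  order_cells <- sample.int(n_cells)
  remaining <- length(targets)
  rest <- centre
  for (cell in order_cells) {
    if (i > n) break
    is_target <- cell %in% targets
    dwell <- if (is_target) 0.95 else stats::runif(1, 0.08, 0.18)
    len <- max(1L, as.integer(round(dwell * gaze_fs)))
    j <- min(n, i + len - 1L)
    goal[i:j, 1] <- centres[cell, 1]
    goal[i:j, 2] <- centres[cell, 2]
    i <- j + 1L
    if (is_target) {
      remaining <- remaining - 1L
      rest <- centres[cell, ]
    }
    if (remaining == 0L) break
  }
  if (i <= n) {
    goal[i:n, 1] <- rest[1]
    goal[i:n, 2] <- rest[2]
  }
  goal
}

# exponential approach to a moving goal with white positional jitter
approach_track <- function(goal, beta, jitter_sd, start) {
  n <- nrow(goal)
  drive_x <- beta * goal[, 1] + stats::rnorm(n, 0, jitter_sd)
  drive_y <- beta * goal[, 2] + stats::rnorm(n, 0, jitter_sd)
  x <- as.numeric(stats::filter(drive_x, 1 - beta, method = "recursive",
                                init = start[1]))
  y <- as.numeric(stats::filter(drive_y, 1 - beta, method = "recursive",
                                init = start[2]))
  cbind(x, y)
}

# detect identification events: continuous dwell inside a target cell
# strictly longer than `threshold` seconds; identification occurs
# `threshold` seconds into the dwell, once per cell
detect_idents <- function(track_xy, t, targets, grid, gaze_fs, threshold = 0.7) {
  cells <- cell_of_point(track_xy[, 1], track_xy[, 2], grid)
  idents <- list()
  for (tc in targets) {
    inside <- !is.na(cells) & cells == tc
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      dur <- r$lengths[k] / gaze_fs
      if (dur > threshold) {
        idents[[length(idents) + 1L]] <-
          data.frame(time = t[starts[k]] + threshold, cell = tc)
        break
      }
    }
  }
  if (length(idents)) do.call(rbind, idents) else
    data.frame(time = numeric(0), cell = integer(0))
}

add_dropout <- function(n, p_start = 0.004) {
  valid <- rep(TRUE, n)
  starts <- which(stats::runif(n) < p_start)
  for (s in starts) valid[s:min(n, s + sample(2:4, 1))] <- FALSE
  valid
}

#' Simulate a paired gaze trajectory for one trial
#'
#' Produces timestamped (x, y) pixel tracks for both participants over one
#' 13-s trial, plus the target-identification events implied by the lock
#' rule (continuous within-cell dwell strictly greater than 0.7 s;
#' identification 0.7 s into the dwell). Agent A searches the target
#' matrix; agent B's step blends its own search drift with
#' `attraction` times the direction toward A's concurrent gaze (negative
#' values repel). In single-player mode B is a free-drifting observer and
#' only A produces identifications; in competition each target is credited
#' to whichever participant locks it first.
#'
#' @param mode One of `"single"`, `"cooperation"`, `"competition"`.
#' @param targets Non-empty vector of target cell indices within the grid.
#' @param attraction Coefficient in `[-1, 1]`.
#' @param grid Screen/target geometry (see [sim_config()]).
#' @param gaze_fs Gaze sampling rate (Hz).
#' @param trial_layout List with `fixation_s` and `trial_s` (seconds).
#' @param jitter_sd SD (px) of the white positional jitter added to every
#'   step; set to 0 for noise-free trajectories.
#' @param seed Integer seed.
#' @return List with gaze tracks `a` and `b` (data frames `t`, `x`, `y`,
#'   `valid`; `t` in seconds from trial onset) and `idents`
#'   (`time`, `participant`, `cell`).
#' @export
simulate_gaze_pair <- function(mode, targets, attraction,
                               grid = list(width = 1920, height = 1080,
                                           cells = 4L, cell_px = 150),
                               gaze_fs = 30,
                               trial_layout = list(fixation_s = 3, trial_s = 13),
                               jitter_sd = 8,
                               seed = 1L) {
  if (!mode %in% c("single", "cooperation", "competition"))
    stop("mode must be single, cooperation or competition")
  if (length(targets) == 0L) stop("targets must be non-empty")
  n_cells <- grid$cells^2
  if (any(targets < 1L | targets > n_cells))
    stop("target cells must lie within the ", grid$cells, "x", grid$cells, " grid")
  if (abs(attraction) > 1) stop("attraction must lie in [-1, 1]")

  with_seed(seed, {
    n <- as.integer(round(trial_layout$trial_s * gaze_fs))
    t <- (seq_len(n) - 1) / gaze_fs
    centre <- c(grid$width / 2, grid$height / 2)
    beta <- 0.5

    goal_a <- search_goal_track(n, targets, grid, gaze_fs, trial_layout)
    pa <- approach_track(goal_a, beta, jitter_sd, centre)

    search_phase <- t >= trial_layout$fixation_s
    if (mode == "single") {
      # free-drifting observer: wide Ornstein-Uhlenbeck wander about centre
      theta <- 0.02
      eta_sd <- 55
      pb <- matrix(0, n, 2)
      p <- centre + stats::rnorm(2, 0, 150)
      for (i in seq_len(n)) {
        p <- p + theta * (centre - p) + stats::rnorm(2, 0, eta_sd)
        p[1] <- min(max(p[1], 0), grid$width)
        p[2] <- min(max(p[2], 0), grid$height)
        pb[i, ] <- p
      }
    } else {
      goal_b <- search_goal_track(n, targets, grid, gaze_fs, trial_layout)
      pb <- matrix(0, n, 2)
      p <- centre
      a <- attraction
      for (i in seq_len(n)) {
        step <- beta * (goal_b[i, ] - p)
        if (search_phase[i]) {
          if (a > 0) {
            step <- (1 - a) * step + a * 0.5 * (pa[i, ] - p)
          } else if (a < 0) {
            d <- pa[i, ] - p
            dist <- sqrt(sum(d^2))
            step <- step - a * 45 * (-d / (dist + 1)) * exp(-dist / 300)
          }
        }
        p <- p + step + stats::rnorm(2, 0, jitter_sd)
        p[1] <- min(max(p[1], 0), grid$width)
        p[2] <- min(max(p[2], 0), grid$height)
        pb[i, ] <- p
      }
    }

    id_a <- detect_idents(pa, t, targets, grid, gaze_fs)
    if (nrow(id_a)) id_a$participant <- "a"
    if (mode == "single") {
      idents <- id_a
    } else {
      id_b <- detect_idents(pb, t, targets, grid, gaze_fs)
      if (nrow(id_b)) id_b$participant <- "b"
      idents <- rbind(id_a, id_b)
      if (mode == "competition" && nrow(idents)) {
        # each target can be marked only once: first lock wins
        idents <- idents[order(idents$time), ]
        idents <- idents[!duplicated(idents$cell), ]
      }
    }
    if (nrow(idents)) {
      idents <- idents[order(idents$time), c("time", "participant", "cell")]
      rownames(idents) <- NULL
    } else {
      idents <- data.frame(time = numeric(0), participant = character(0),
                           cell = integer(0))
    }

    list(
      a = data.frame(t = t, x = pa[, 1], y = pa[, 2], valid = add_dropout(n)),
      b = data.frame(t = t, x = pb[, 1], y = pb[, 2], valid = add_dropout(n)),
      idents = idents
    )
  })
}
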