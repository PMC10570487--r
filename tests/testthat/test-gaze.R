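grid4 <- list(width = 1920, height = 1080, cells = 4L, cell_px = 150)

test_that("cell lookup inverts the cell centres and rejects off-grid points", {
  centres <- dyadsync:::cell_centres(grid4)
  got <- dyadsync:::cell_of_point(centres[, "x"], centres[, "y"], grid4)
  expect_equal(got, 1:16)
  expect_true(is.na(dyadsync:::cell_of_point(5, 5, grid4)))
  expect_true(is.na(dyadsync:::cell_of_point(1915, 540, grid4)))
})

test_that("lock rule requires a dwell strictly longer than 0.7 s", {
  gaze_fs <- 30
  centres <- dyadsync:::cell_centres(grid4)
  mk_track <- function(dwell_samples) {
    n <- 120
    xy <- matrix(c(5, 5), n, 2, byrow = TRUE)   # off-grid elsewhere
    xy[31:(30 + dwell_samples), 1] <- centres[6, "x"]
    xy[31:(30 + dwell_samples), 2] <- centres[6, "y"]
    xy
  }
  t <- (seq_len(120) - 1) / gaze_fs
  # 21 samples at 30 Hz = 0.7 s exactly: NOT strictly greater -> no ident
  none <- dyadsync:::detect_idents(mk_track(21), t, targets = 6L, grid4, gaze_fs)
  expect_equal(nrow(none), 0L)
  # 22 samples = 0.733 s: ident at dwell start + 0.7
  one <- dyadsync:::detect_idents(mk_track(22), t, targets = 6L, grid4, gaze_fs)
  expect_equal(nrow(one), 1L)
  expect_equal(one$cell, 6L)
  expect_equal(one$time, t[31] + 0.7)
})

test_that("paired gaze simulation is deterministic and well-formed", {
  g1 <- simulate_gaze_pair("cooperation", targets = c(2L, 9L),
                           attraction = 0.8, seed = 31L)
  g2 <- simulate_gaze_pair("cooperation", targets = c(2L, 9L),
                           attraction = 0.8, seed = 31L)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$a), 13 * 30)
  expect_true(all(g1$a$x >= 0 & g1$a$x <= 1920))
  expect_true(all(g1$b$y >= 0 & g1$b$y <= 1080))
  expect_true(all(g1$idents$cell %in% c(2L, 9L)))
})

test_that("competition credits each target to the first locker only", {
  g <- simulate_gaze_pair("competition", targets = c(3L, 8L, 14L),
                          attraction = -0.8, seed = 17L)
  expect_false(anyDuplicated(g$idents$cell) > 0)
})

test_that("attraction pulls the partner: cooperative gaze tracks the searcher", {
  d_coop <- d_single <- numeric(5)
  for (s in 1:5) {
    co <- simulate_gaze_pair("cooperation", targets = 7L, attraction = 0.8,
                             seed = 40L + s)
    si <- simulate_gaze_pair("single", targets = 7L, attraction = 0,
                             seed = 40L + s)
    search <- co$a$t >= 3
    d_coop[s] <- mean(sqrt((co$a$x - co$b$x)^2 + (co$a$y - co$b$y)^2)[search])
    d_single[s] <- mean(sqrt((si$a$x - si$b$x)^2 + (si$a$y - si$b$y)^2)[search])
  }
  expect_lt(mean(d_coop), mean(d_single))
})

test_that("single mode yields identifications by the searcher only", {
  g <- simulate_gaze_pair("single", targets = c(1L, 16L), attraction = 0,
                          seed = 9L)
  if (nrow(g$idents)) expect_true(all(g$idents$participant == "a"))
  expect_error(simulate_gaze_pair("single", targets = integer(0),
                                  attraction = 0), "non-empty")
  expect_error(simulate_gaze_pair("duet", targets = 1L, attraction = 0),
               "mode")
})
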