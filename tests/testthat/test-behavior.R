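test_that("lock onsets are 0.7 s before identification, clamped at stimulus", {
  events <- data.frame(
    time = c(3, 4.0, 3.5, 16, 18.2),
    code = c("stimulus_onset", "ident", "ident", "stimulus_onset", "ident"),
    participant = c(NA, "a", "b", NA, "a"),
    cell = c(NA, 5L, 9L, NA, 2L),
    mode = "cooperation", run = 1L,
    trial = c(1L, 1L, 1L, 2L, 2L))
  lo <- lock_onsets(events)
  expect_equal(nrow(lo), 3L)
  t1 <- lo[lo$trial == 1L, ]
  expect_equal(t1$onset, c(0, 0.3))           # 3.5 - 0.7 - 3 < 0 -> clamped
  expect_equal(t1$clamped, c(TRUE, FALSE))
  expect_equal(lo$onset[lo$trial == 2L], 18.2 - 0.7 - 16)
  only_a <- lock_onsets(events, participant = "a")
  expect_true(all(only_a$participant == "a"))
})

test_that("TSTs telescope: first from stimulus, rest between onsets", {
  expect_equal(tst_sequence(c(1.2, 2.0, 3.5)), c(1.2, 0.8, 1.5))
  expect_equal(sum(tst_sequence(c(1.2, 2.0, 3.5))), 3.5)
  expect_equal(tst_sequence(numeric(0)), numeric(0))
  expect_error(tst_sequence(c(2, 1)), "sorted")
})

test_that("trimmed mean removes ceiling(0.05 n) per tail, median fallback", {
  expect_equal(trimmed_mean(c(1, 2, 3, 4, 100)), 3)     # drops 1 and 100
  expect_equal(trimmed_mean(1:20), mean(2:19))
  one <- trimmed_mean(5)
  expect_equal(as.numeric(one), 5)
  expect_true(isTRUE(attr(one, "fallback")))
  two <- trimmed_mean(c(3, 9))
  expect_equal(as.numeric(two), 6)                      # median fallback
  expect_error(trimmed_mean(numeric(0)), "empty")
})

test_that("gaze distance interpolates to a common clock", {
  a <- data.frame(t = seq(0, 1, 0.1), x = 0, y = 0, valid = TRUE)
  b <- data.frame(t = seq(0, 1, 0.1), x = 30, y = 40, valid = TRUE)
  expect_equal(gaze_distance(a, b, fs = 30), 50)
  # invalid stretches are excluded
  b2 <- b
  b2$x[1:6] <- 1e6
  b2$valid[1:6] <- FALSE
  d <- gaze_distance(a, b2, fs = 30)
  expect_equal(d, 50)
  expect_error(gaze_distance(a, data.frame(t = 5 + a$t, x = 1, y = 1,
                                           valid = TRUE)),
               "jointly")
})

test_that("heatmaps are unit-mass histograms in screen orientation", {
  tr <- data.frame(t = 1:100 / 30,
                   x = rep(100, 100), y = rep(1000, 100), valid = TRUE)
  h <- gaze_heatmap(tr, nx = 96, ny = 54, sigma = 0)
  expect_equal(sum(h$grid), 1)
  hit <- which(h$grid > 0, arr.ind = TRUE)
  expect_equal(nrow(hit), 1L)
  expect_equal(unname(hit[1, ]), c(51L, 6L))  # row = y cell 51, col = x cell 6
  hs <- gaze_heatmap(tr, nx = 96, ny = 54, sigma = 1.5)
  expect_equal(sum(hs$grid), 1)
  expect_gt(sum(hs$grid > 1e-8), 9)           # smoothing spreads the mass
  expect_error(gaze_heatmap(data.frame(t = 1, x = 1, y = 1, valid = FALSE)),
               "valid")
})

test_that("similarity coefficients hit their boundary values", {
  tr1 <- data.frame(t = 1:200 / 30, x = stats::runif(200, 0, 500),
                    y = stats::runif(200, 0, 500), valid = TRUE)
  tr2 <- data.frame(t = 1:200 / 30, x = stats::runif(200, 1400, 1900),
                    y = stats::runif(200, 600, 1060), valid = TRUE)
  h1 <- gaze_heatmap(tr1); h2 <- gaze_heatmap(tr2)
  same <- heatmap_similarity(h1, h1)
  expect_equal(same$pearson, 1)
  expect_equal(same$ssim, 1, tolerance = 1e-6)
  expect_equal(as.numeric(same$jaccard), 1)
  disjoint <- heatmap_similarity(h1, h2)
  expect_equal(as.numeric(disjoint$jaccard), 0)
  expect_lt(disjoint$pearson, 0.1)
  expect_lt(disjoint$ssim, same$ssim)
  expect_error(heatmap_similarity(h1, gaze_heatmap(tr1, nx = 10, ny = 10)),
               "differ")
})

test_that("per-trial TST table orders targets and summarises by condition", {
  events <- data.frame(
    time = c(3, 4.5, 6.0, 16, 17.1),
    code = c("stimulus_onset", "ident", "ident", "stimulus_onset", "ident"),
    participant = c(NA, "a", "a", NA, "a"),
    cell = c(NA, 5L, 9L, NA, 3L),
    mode = c("single", "single", "single", "cooperation", "cooperation"),
    run = 1L, trial = c(1L, 1L, 1L, 2L, 2L))
  sched <- data.frame(trial = 1:2, n_targets = c(2L, 1L))
  tt <- tst_table(events, sched, dyad = 7)
  expect_equal(nrow(tt$table), 3L)
  t1 <- tt$table[tt$table$trial == 1L, ]
  expect_equal(t1$k, 1:2)
  expect_equal(t1$tst, c(4.5 - 0.7 - 3, 6.0 - 4.5))
  expect_equal(t1$n_targets, c(2L, 2L))
  expect_true(all(tt$summary$dyad == 7))
})
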