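test_that("simulation is deterministic given the seed and dyad index", {
  cfg <- tiny_sim(seed = 12)
  a <- simulate_dyad(cfg, 1)
  b <- simulate_dyad(cfg, 1)
  expect_identical(a$recording$eeg_a, b$recording$eeg_a)
  expect_identical(a$recording$gaze_b, b$recording$gaze_b)
  expect_identical(a$truth$coupling, b$truth$coupling)
  # a different dyad index gives different data from the same config
  c2 <- simulate_dyad(tiny_sim(seed = 12, n_dyads = 2), 2)
  expect_false(identical(a$recording$eeg_a[1, 1:100],
                         c2$recording$eeg_a[1, 1:100]))
})

test_that("recording dimensions and event counts match the paradigm", {
  cfg <- tiny_sim(seed = 3, n_trials_per_mode = 4)
  rec <- simulate_dyad(cfg, 1)$recording
  n_trials <- 3 * 4
  expect_equal(dim(rec$eeg_a), c(32L, n_trials * 13 * cfg$fs))
  expect_equal(rownames(rec$eeg_a), eeg_montage())
  expect_equal(sum(rec$events$code == "stimulus_onset"), n_trials)
  expect_equal(sum(rec$events$code == "fixation_onset"), n_trials)
  st <- rec$events[rec$events$code == "stimulus_onset", ]
  # stimulus 3 s after each trial onset, trials 13 s long
  expect_equal(st$time, (seq_len(n_trials) - 1) * 13 + 3)
  expect_equal(unname(table(st$mode)[cfg$modes]), rep(4L, 3), ignore_attr = TRUE)
})

test_that("mode schedule is blocked and counterbalanced across two runs", {
  cfg <- tiny_sim(seed = 5, n_dyads = 6, n_trials_per_mode = 4)
  for (d in 1:3) {
    sched <- simulate_dyad(cfg, d)$recording$meta$schedule
    expect_equal(unname(table(sched$run)), c(6L, 6L), ignore_attr = TRUE)
    per <- table(sched$mode, sched$run)
    expect_true(all(per == 2L))         # each mode twice per run
    blocks <- tapply(sched$mode, sched$block, function(m) unique(m))
    expect_true(all(lengths(blocks) == 1L))  # trials blocked by mode
  }
})

test_that("ground-truth PLV equals exp(-sigma^2/2) and orders the modes", {
  tr <- simulate_dyad(tiny_sim(seed = 2), 1)$truth$coupling
  expect_equal(tr$plv_event, exp(-tr$sigma_event^2 / 2))
  th <- tr[tr$band == "theta", ]
  coop <- th$plv_event[th$mode == "cooperation"]
  comp <- th$plv_event[th$mode == "competition"]
  sing <- th$plv_event[th$mode == "single"]
  expect_true(coop > comp && comp > sing)
  expect_true(all(tr$plv_event >= tr$plv_base))
})

test_that("1/f noise generator has no parity artefacts and unit-set RMS", {
  noise <- dyadsync:::one_over_f_noise
  for (n in c(620L, 1024L, 1250L)) {   # nextn odd (625), even, even (1250)
    x <- with_seed(8L, noise(n, 5))
    expect_false(anyNA(x))
    expect_equal(stats::sd(x), 5, tolerance = 1e-9)
  }
})

test_that("gender composition is FF-dominant with exactly one MM dyad", {
  g <- vapply(1:29, function(d) dyadsync:::gender_composition(d, 29L), "")
  expect_equal(sum(g == "MM"), 1L)
  expect_gt(sum(g == "FF"), sum(g == "FM"))
  expect_equal(length(g), 29L)
})

test_that("small-sample PLV oracle is consistent and inflated at small N", {
  o40 <- plv_small_sample(0.5, 40, reps = 500, seed = 4)
  expect_gt(o40$mean, exp(-0.5^2 / 2) - 3 * o40$se)
  # uncoupled phases at N = 40 still yield positive PLV near sqrt(pi/160)
  oinf <- plv_small_sample(Inf, 40, reps = 500, seed = 4)
  expect_equal(oinf$mean, sqrt(pi / 160), tolerance = 4 * oinf$se + 0.01)
  expect_equal(plv_expected(0), 1)
  expect_lt(plv_expected(2), plv_expected(1))
})
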