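test_that("mastoid re-referencing is exact, flagged and idempotent", {
  set.seed(2)
  labels <- eeg_montage()
  eeg <- matrix(stats::rnorm(32 * 100), 32, dimnames = list(labels, NULL))
  ref <- rereference_mastoids(eeg)
  i9 <- match("TP9", labels); i10 <- match("TP10", labels)
  expect_equal(ref[5, ], eeg[5, ] - (eeg[i9, ] + eeg[i10, ]) / 2)
  # mastoids become mirror images after re-referencing
  expect_equal(ref[i9, ], -ref[i10, ])
  expect_equal(attr(ref, "mastoid_degenerate"), c("TP9", "TP10"))
  again <- rereference_mastoids(ref)
  expect_equal(unclass(again)[, ], unclass(ref)[, ])
  expect_error(rereference_mastoids(eeg[1:5, ]), "TP9")
})

test_that("epochs have exactly (tmax - tmin) * fs samples, half-open", {
  fs <- 100
  eeg <- matrix(seq_len(2 * fs * 30), 2, byrow = TRUE)
  rownames(eeg) <- c("A", "B")
  events <- data.frame(time = c(5, 15), code = "stimulus_onset",
                       mode = "single", run = 1L, trial = 1:2)
  ep <- segment_epochs(eeg, events, tmin = -1, tmax = 2, fs = fs)
  expect_equal(dim(ep$data), c(2L, 2L, 300L))
  expect_equal(ep$times[1], -1)
  expect_equal(ep$times[300], 2 - 1 / fs)    # tmax itself excluded
  # first epoch of channel A starts at sample (5 - 1) * fs + 1
  expect_equal(ep$data[1, 1, 1], unname(eeg[1, 4 * fs + 1]))
  expect_equal(ep$data[1, 1, 300], unname(eeg[1, 4 * fs + 300]))
})

test_that("trials crossing the recording edge are dropped with a message", {
  fs <- 100
  eeg <- matrix(stats::rnorm(2 * fs * 10), 2,
                dimnames = list(c("A", "B"), NULL))
  events <- data.frame(time = c(0.5, 5, 9.8), code = "stimulus_onset",
                       mode = "single", run = 1L, trial = 1:3)
  expect_message(ep <- segment_epochs(eeg, events, tmin = -1, tmax = 2,
                                      fs = fs),
                 "dropped")
  expect_equal(dim(ep$data)[1], 1L)
  expect_equal(attr(ep, "dropped"), 2L)
  expect_equal(ep$labels$trial, 2L)
  # all trials out of range is an error, not an empty object
  far <- data.frame(time = 100, code = "stimulus_onset")
  expect_error(segment_epochs(eeg, far, tmin = -1, tmax = 2, fs = fs),
               "zero epochs")
})

test_that("the conditioning chain is deterministic and correctly shaped", {
  rec <- simulate_dyad(tiny_sim(seed = 10, fs = 500, n_trials_per_mode = 2),
                       1)$recording
  e1 <- preprocess_recording(rec)
  e2 <- preprocess_recording(rec)
  expect_identical(e1$epochs_a$data, e2$epochs_a$data)
  expect_equal(dim(e1$epochs_a$data), c(6L, 32L, 3250L))
  expect_equal(e1$epochs_a$fs, 250)
  expect_equal(e1$epochs_a$times[1], -3)
  expect_equal(e1$epochs_b$labels$mode, e1$epochs_a$labels$mode)
})

test_that("the cleaning hook is applied before filtering", {
  rec <- simulate_dyad(tiny_sim(seed = 10, n_trials_per_mode = 2),
                       1)$recording
  zero_hook <- function(eeg, fs, labels) eeg * 0
  ep <- preprocess_recording(rec, clean_hook = zero_hook)
  expect_true(all(ep$epochs_a$data == 0))
})
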