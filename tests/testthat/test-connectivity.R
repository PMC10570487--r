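# brute-force oracles for the synchrony measures, written independently
# of the package kernels
oracle_plv <- function(pa, pb) {          # pa, pb: trials x samples phases
  Mod(colMeans(exp(1i * (pa - pb))))
}
oracle_ciplv <- function(pa, pb) {
  m <- colMeans(exp(1i * (pa - pb)))
  abs(Im(m)) / sqrt(pmax(1 - Re(m)^2, .Machine$double.eps))
}
oracle_wpli <- function(za, zb) {         # za, zb: trials x samples complex
  s <- Im(za * Conj(zb))
  num <- abs(colSums(s)); den <- colSums(abs(s))
  ifelse(den > 0, num / den, 0)
}

test_that("PLV is exactly 1 for a constant phase offset", {
  set.seed(1)
  ph <- array(stats::runif(20 * 1 * 50, 0, 2 * pi), c(20, 1, 50))
  A <- phase_tensor(ph)
  B <- phase_tensor(ph + 0.9)
  pc <- pair_connectivity(A, B, measure = "plv")
  expect_equal(as.vector(pc$values), rep(1, 50))
})

test_that("all three measures match brute-force oracles on random data", {
  set.seed(5)
  nt <- 15; ns <- 30
  pa <- array(stats::runif(nt * 2 * ns, 0, 2 * pi), c(nt, 2, ns))
  pb <- array(stats::runif(nt * 3 * ns, 0, 2 * pi), c(nt, 3, ns))
  A <- phase_tensor(pa); B <- phase_tensor(pb)
  # modulate amplitudes for wpli (unit phasors would be a degenerate check)
  A$values <- A$values * array(stats::rexp(nt * 2 * ns) + 0.1, c(nt, 2, ns))
  B$values <- B$values * array(stats::rexp(nt * 3 * ns) + 0.1, c(nt, 3, ns))
  for (meas in c("plv", "ciplv", "wpli")) {
    pc <- pair_connectivity(A, B, measure = meas)
    for (i in 1:2) for (j in 1:3) {
      expected <- switch(meas,
        plv = oracle_plv(pa[, i, ], pb[, j, ]),
        ciplv = oracle_ciplv(pa[, i, ], pb[, j, ]),
        wpli = oracle_wpli(A$values[, i, ], B$values[, j, ]))
      expect_equal(pc$values[i, j, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("ciPLV is blind to pure zero-lag locking, wPLI maps 0/0 to 0", {
  set.seed(6)
  ph <- array(stats::runif(30 * 1 * 20, 0, 2 * pi), c(30, 1, 20))
  A <- phase_tensor(ph); B <- phase_tensor(ph)        # identical phases
  expect_equal(as.vector(pair_connectivity(A, B, "ciplv")$values),
               rep(0, 20))
  expect_equal(as.vector(pair_connectivity(A, B, "wpli")$values),
               rep(0, 20))                            # Im S = 0 everywhere
  # constant positive lag: wPLI = 1
  Bq <- phase_tensor(ph + pi / 4)
  expect_equal(as.vector(pair_connectivity(A, Bq, "wpli")$values),
               rep(1, 20))
})

test_that("baseline correction zeroes the baseline mean per pair", {
  set.seed(7)
  ph <- array(stats::runif(10 * 2 * 40, 0, 2 * pi), c(10, 2, 40))
  A <- phase_tensor(ph, fs = 10, tmin = -2)
  B <- phase_tensor(ph[, 2:1, , drop = FALSE] + 0.3, fs = 10, tmin = -2)
  pc <- baseline_correct(pair_connectivity(A, B, "plv"), window = c(-2, 0))
  idx <- which(pc$times >= -2 & pc$times < 0)
  for (i in 1:2) for (j in 1:2)
    expect_equal(mean(pc$values[i, j, idx]), 0, tolerance = 1e-12)
  expect_true(pc$baseline_corrected)
})

test_that("event-window mean includes both endpoints at sample resolution", {
  vals <- array(0, c(1, 1, 10))
  vals[1, 1, ] <- 1:10
  pc <- structure(list(values = vals, measure = "plv", band = "theta",
                       times = seq(0, 0.9, by = 0.1), fs = 10, n_trials = 5,
                       channels_a = "x", channels_b = "y",
                       baseline_corrected = FALSE),
                  class = "pair_connectivity")
  # window [0.2, 0.5] covers samples 3:6
  expect_equal(as.numeric(event_window_mean(pc, c(0.2, 0.5))), mean(3:6))
})

test_that("region aggregation preserves the pair-count weighted mean", {
  set.seed(8)
  labels <- eeg_montage()
  mat <- matrix(stats::rnorm(1024), 32, 32, dimnames = list(labels, labels))
  reg <- aggregate_by_region(mat)
  expect_equal(dim(reg), c(5L, 5L))
  counts <- table(factor(region_map()[labels],
                         levels = rownames(reg)))
  weighted <- sum(reg * (as.numeric(counts) %o% as.numeric(counts)))
  expect_equal(weighted / 1024, mean(mat))
  # one region pair checked by hand
  f <- names(region_map())[region_map() == "occipital"]
  expect_equal(reg["occipital", "occipital"], mean(mat[f, f]))
})

test_that("event connectivity trims unequal trial counts with a message", {
  set.seed(9)
  pa <- array(stats::runif(12 * 1 * 30, 0, 2 * pi), c(12, 1, 30))
  A <- phase_tensor(pa, fs = 10, tmin = -1)
  B <- phase_tensor(pa[1:10, , , drop = FALSE] + 0.4, fs = 10, tmin = -1)
  expect_message(
    ec <- event_connectivity(A, B, event_window = c(0.2, 0.5),
                             baseline_window = c(-1, 0)),
    "trimmed")
  expect_equal(dim(ec), c(1L, 1L))
  expect_true(is.finite(ec[1, 1]))
})
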