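test_that("pseudo-dyad enumeration matches choose(2D, 2) - D", {
  for (D in c(2L, 3L, 5L, 29L)) {
    dyads <- data.frame(a = paste0("p", seq_len(D), "L"),
                        b = paste0("p", seq_len(D), "R"))
    ps <- enumerate_shuffled_pairs(dyads)
    expect_equal(nrow(ps), choose(2 * D, 2) - D)
    # no true pair sneaks in
    key <- paste(pmin(ps$a, ps$b), pmax(ps$a, ps$b))
    true_key <- paste(pmin(dyads$a, dyads$b), pmax(dyads$a, dyads$b))
    expect_length(intersect(key, true_key), 0L)
    expect_false(anyDuplicated(key) > 0)
  }
  expect_error(enumerate_shuffled_pairs(data.frame(a = c("x", "y"),
                                                   b = c("z", "x"))),
               "duplicated")
})

test_that("bootstrap null is deterministic and centred on the source mean", {
  set.seed(3)
  v <- stats::rnorm(300, mean = 2, sd = 1)
  b1 <- bootstrap_null(v, n_boot = 500, m = 100, seed = 7)
  b2 <- bootstrap_null(v, n_boot = 500, m = 100, seed = 7)
  expect_identical(b1, b2)
  expect_length(b1, 500L)
  expect_equal(mean(b1), mean(v), tolerance = 0.02)
  # sd of a mean of m draws ~ sd(v)/sqrt(m)
  expect_equal(stats::sd(b1), stats::sd(v) / sqrt(100), tolerance = 0.25)
})

test_that("z and percentile p follow their definitions", {
  boot <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  r <- true_vs_null(10, boot)
  expect_equal(r$z, (10 - mean(boot)) / stats::sd(boot))
  # r = 9 bootstrap means below 10 -> p = 2 * min(10, 1) / 10
  expect_equal(r$p, 2 * 1 / 10)
  r2 <- true_vs_null(0, boot)                 # all above -> same p, z < 0
  expect_equal(r2$p, 2 * 1 / 10)
  expect_lt(r2$z, 0)
  # degenerate null
  r3 <- true_vs_null(5, rep(2, 10))
  expect_identical(r3$z, Inf)
  expect_identical(true_vs_null(2, rep(2, 10))$z, 0)
})

test_that("BH adjustment matches a brute-force step-up computation", {
  set.seed(4)
  p <- stats::runif(40)^2
  got <- fdr_bh(p, q = 0.1)
  n <- length(p)
  o <- order(p)
  raw <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(raw)))
  brute <- numeric(n); brute[o] <- pmin(adj, 1)
  expect_equal(got$adjusted, brute)
  expect_equal(got$reject, brute <= 0.1)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("the null test flags a genuine shift with positive z", {
  set.seed(5)
  shuffled <- matrix(stats::rnorm(200 * 3, 0, 0.1), 200, 3)
  true_vals <- matrix(stats::rnorm(10 * 3, 0, 0.1), 10, 3)
  true_vals[, 2] <- true_vals[, 2] + 0.5       # only pair 2 coupled
  colnames(shuffled) <- colnames(true_vals) <- c("p1", "p2", "p3")
  nt <- ibs_null_test(true_vals, shuffled, n_boot = 500, m = 50, seed = 2)
  r <- nt$results
  expect_true(r$reject[2])
  expect_gt(r$z[2], 5)
  expect_equal(r$mean_true, unname(colMeans(true_vals)))
  # deterministic given the seed
  nt2 <- ibs_null_test(true_vals, shuffled, n_boot = 500, m = 50, seed = 2)
  expect_identical(nt$results, nt2$results)
})
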