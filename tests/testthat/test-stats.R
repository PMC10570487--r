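# brute-force classical within-subject decomposition, independent of aov()
brute_rm_F <- function(wide) {
  n <- nrow(wide); a <- ncol(wide)
  y <- as.matrix(wide)
  grand <- mean(y)
  ss_level <- n * sum((colMeans(y) - grand)^2)
  ss_subj <- a * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  df1 <- a - 1; df2 <- (a - 1) * (n - 1)
  F <- (ss_level / df1) / (ss_err / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

test_that("repeated-measures F matches the brute-force decomposition", {
  set.seed(11)
  wide <- data.frame(m1 = stats::rnorm(8, 10), m2 = stats::rnorm(8, 11),
                     m3 = stats::rnorm(8, 10.5))
  res <- rm_anova(wide)
  oracle <- brute_rm_F(wide)
  expect_equal(res$effects$F, oracle$F)
  expect_equal(res$effects$df1, oracle$df1)
  expect_equal(res$effects$df2, oracle$df2)
  expect_equal(res$effects$p, oracle$p)
})

test_that("long input, subject dropping and input guards work", {
  set.seed(12)
  long <- expand.grid(subject = paste0("s", 1:6), level = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  long$value <- stats::rnorm(nrow(long))
  full <- rm_anova(long)
  expect_equal(full$n_subjects, 6L)
  incomplete <- long[-1, ]                      # s1 misses level a
  expect_message(res <- rm_anova(incomplete), "dropped")
  expect_equal(res$n_subjects, 5L)
  expect_equal(res$dropped, 1L)
  expect_error(rm_anova(long[long$level == "a", ]), "2 factor levels")
  expect_error(rm_anova(long[long$subject %in% c("s1", "s2"), ]),
               "3 complete subjects")
})

test_that("Holm post hocs reproduce the worked adjustment example", {
  # paired t-tests constructed to give raw p ~ (0.01, 0.03, 0.04) ordering:
  # check against p.adjust directly through the public interface
  set.seed(13)
  wide <- data.frame(x = stats::rnorm(10), y = stats::rnorm(10, 0.8),
                     z = stats::rnorm(10, 1.2))
  res <- rm_anova(wide)
  raw <- res$posthoc$p
  expect_equal(res$posthoc$p_adjusted, stats::p.adjust(raw, "holm"))
  # and the canonical example: 0.01, 0.03, 0.04 -> 0.03, 0.06, 0.06
  expect_equal(stats::p.adjust(c(0.01, 0.03, 0.04), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(res$posthoc$direction,
               ifelse(res$posthoc$diff > 0, ">", "<"))
})

test_that("zero residual variance yields the NA sentinel, not nonsense", {
  wide <- data.frame(a = c(1, 2, 3), b = c(2, 3, 4))   # perfectly additive
  res <- suppressWarnings(rm_anova(wide, posthoc = FALSE))
  expect_true(is.na(res$effects$F))
  expect_true(is.na(res$effects$p))
})

test_that("mixed ANOVA matches aov's split-plot decomposition by hand", {
  set.seed(14)
  d <- expand.grid(subject = paste0("s", 1:12), mode = c("m1", "m2", "m3"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 6, "g1", "g2")
  d$value <- stats::rnorm(nrow(d)) +
    ifelse(d$group == "g1", 0.5, 0) + ifelse(d$mode == "m2", 0.7, 0)
  res <- mixed_anova(d, subject = "subject", within = "mode",
                     between = "group", value = "value")
  # independent recomputation with aov on fresh factors
  fit <- stats::aov(value ~ mode * group + Error(factor(subject)), data = d)
  s <- summary(fit)
  bt <- s[["Error: factor(subject)"]][[1]]
  wt <- s[["Error: Within"]][[1]]
  rownames(bt) <- trimws(rownames(bt))
  rownames(wt) <- trimws(rownames(wt))
  expect_equal(res$effects$F[res$effects$effect == "between"],
               bt["group", "F value"], ignore_attr = TRUE)
  expect_equal(res$effects$F[res$effects$effect == "within"],
               wt["mode", "F value"], ignore_attr = TRUE)
  expect_equal(res$effects$F[res$effects$effect == "within:between"],
               wt["mode:group", "F value"], ignore_attr = TRUE)
  expect_equal(res$effects$df2[1], 10)      # N - groups = 12 - 2
  expect_equal(res$effects$df2[2], 20)      # (a-1)(N-g) = 2 * 10
})

test_that("singleton groups error; constant between degenerates gracefully", {
  d <- expand.grid(subject = paste0("s", 1:5), mode = c("m1", "m2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$subject == "s5", "solo", "main")
  d$value <- stats::rnorm(nrow(d))
  expect_error(mixed_anova(d, within = "mode", value = "value"),
               "singleton")
  d$group <- "all"
  res <- mixed_anova(d, within = "mode", value = "value")
  expect_true(is.na(res$effects$F[res$effects$effect == "between"]))
  expect_match(res$note, "constant")
  rm_ref <- rm_anova(d, subject = "subject", level = "mode", value = "value",
                     posthoc = FALSE)
  expect_equal(res$effects$F[res$effects$effect == "within"],
               rm_ref$effects$F)
})
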