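# Shuffled-team bootstrap null model: enumerate pseudo-dyads (all
# participant pairs that were never a real team), compute their
# connectivity exactly as for true dyads, build bootstrap distributions of
# shuffled-mean connectivity, z-score and test the true-dyad mean, and
# control the false discovery rate across channel pairs.

#' Enumerate pseudo-dyads from true team labels
#'
#' All unordered participant pairs that are not true dyads; for D dyads
#' (2D participants) that is `choose(2D, 2) - D` pseudo-dyads (29 dyads
#' give 1624).
#'
#' @param dyads Two-column matrix or data frame of participant identifiers,
#'   one row per true dyad; every participant must appear exactly once.
#' @return Data frame `a`, `b` of pseudo-dyad members.
#' @export
enumerate_shuffled_pairs <- function(dyads) {
  dyads <- as.data.frame(dyads)
  if (ncol(dyads) < 2L) stop("dyads needs two participant columns")
  members <- c(as.character(dyads[[1]]), as.character(dyads[[2]]))
  if (anyDuplicated(members))
    stop("duplicated participant: each may appear in exactly one true dyad")
  if (nrow(dyads) < 2L)
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  all_pairs <- t(utils::combn(sort(members), 2L))
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  true_keys <- key(as.character(dyads[[1]]), as.character(dyads[[2]]))
  keep <- !(key(all_pairs[, 1], all_pairs[, 2]) %in% true_keys)
  data.frame(a = all_pairs[keep, 1], b = all_pairs[keep, 2],
             stringsAsFactors = FALSE)
}

#' Baseline-corrected event-window connectivity for one participant pair
#'
#' The scalar-per-channel-pair summary fed to the null model: the measure
#' is evaluated per time sample across trials, averaged over the event
#' window (inclusive), and the mean over the baseline window (half-open,
#' optionally decimated by `baseline_step` for speed; the time course is
#' smooth on the sample scale) is subtracted.
#'
#' @param A,B `analytic_tensor`s of the two participants (same band and
#'   trial structure; unequal trial counts are trimmed to the common
#'   minimum with a message).
#' @param measure `"plv"`, `"ciplv"` or `"wpli"`.
#' @param event_window Inclusive event window (s).
#' @param baseline_window Half-open baseline window (s), or `NULL` to skip
#'   baseline correction.
#' @param baseline_step Use every `baseline_step`-th baseline sample.
#' @return channels_A x channels_B matrix.
#' @export
event_connectivity <- function(A, B, measure = "plv",
                               event_window = c(0.2, 0.5),
                               baseline_window = c(-3, 0),
                               baseline_step = 1L) {
  stopifnot(inherits(A, "analytic_tensor"), inherits(B, "analytic_tensor"))
  na_t <- dim(A$values)[1]; nb_t <- dim(B$values)[1]
  if (na_t != nb_t) {
    n <- min(na_t, nb_t)
    message("trial counts differ (", na_t, " vs ", nb_t, "): trimmed to ", n)
    A$values <- A$values[seq_len(n), , , drop = FALSE]
    B$values <- B$values[seq_len(n), , , drop = FALSE]
  }
  eps <- 1e-9
  ev_idx <- which(A$times >= event_window[1] - eps & A$times <= event_window[2] + eps)
  if (!length(ev_idx)) stop("event window empty")
  ev <- conn_at_times(A$values, B$values, ev_idx, measure)
  out <- apply(ev, c(1, 2), mean)
  if (!is.null(baseline_window)) {
    b_idx <- which(A$times >= baseline_window[1] & A$times < baseline_window[2])
    if (!length(b_idx)) stop("baseline window outside the time axis")
    b_idx <- b_idx[seq(1L, length(b_idx), by = as.integer(baseline_step))]
    bs <- conn_at_times(A$values, B$values, b_idx, measure)
    out <- out - apply(bs, c(1, 2), mean)
  }
  dimnames(out) <- list(A$channels, B$channels)
  out
}

#' Connectivity of pseudo-dyads
#'
#' Applies [event_connectivity()] to every listed pseudo-dyad, pairing
#' trials by position (all dyads saw the identical stimulus sequence, so
#' positional matching within the schedule is meaningful). Deterministic:
#' no randomness is involved in this step.
#'
#' @param tensors Named list of `analytic_tensor`s, one per participant.
#' @param pairs Data frame `a`, `b` of participant names (as from
#'   [enumerate_shuffled_pairs()]).
#' @param ... Passed to [event_connectivity()].
#' @return 3-d array: pseudo-dyads x channels_A x channels_B.
#' @export
shuffled_connectivity <- function(tensors, pairs, ...) {
  stopifnot(all(c(pairs$a, pairs$b) %in% names(tensors)))
  np <- nrow(pairs)
  first <- event_connectivity(tensors[[pairs$a[1]]], tensors[[pairs$b[1]]], ...)
  out <- array(0, c(np, nrow(first), ncol(first)),
               dimnames = c(list(NULL), dimnames(first)))
  out[1, , ] <- first
  for (k in seq_len(np)[-1])
    out[k, , ] <- event_connectivity(tensors[[pairs$a[k]]],
                                     tensors[[pairs$b[k]]], ...)
  out
}

#' Bootstrap distribution of shuffled means
#'
#' `n_boot` bootstrap sample means, each the mean of `m` draws with
#' replacement from the shuffled values. Deterministic given the seed.
#'
#' @param shuffled Numeric vector of shuffled-pair values.
#' @param n_boot Number of bootstrap means (default 1000).
#' @param m Draws per mean (default 200).
#' @param seed Integer seed.
#' @return Numeric vector of `n_boot` bootstrap means.
#' @export
bootstrap_null <- function(shuffled, n_boot = 1000L, m = 200L, seed = 1L) {
  if (!length(shuffled)) stop("shuffled values must be non-empty")
  if (m <= 0L) stop("m must be positive")
  with_seed(seed, {
    idx <- sample.int(length(shuffled), n_boot * m, replace = TRUE)
    .rowMeans(shuffled[idx], n_boot, m)
  })
}

#' z and two-sided bootstrap-percentile p for true versus null
#'
#' `z = (mean(true) - mean(boot)) / sd(boot)`: the number of null standard
#' deviations the true-team mean lies from the shuffled-mean distribution
#' (positive = coupling, negative = decoupling). The p-value is the
#' two-sided percentile position with add-one correction,
#' `p = 2 * min(r + 1, n_boot + 1 - r) / (n_boot + 1)` with `r` the number
#' of bootstrap means below `mean(true)` (capped at 1). A degenerate null
#' (`sd = 0`) yields an infinite z sentinel.
#'
#' @param true_values Per-true-dyad values.
#' @param boot_means Bootstrap means from [bootstrap_null()].
#' @return List with `z`, `p`, `mean_true`, `mean_null`, `sd_null`.
#' @export
true_vs_null <- function(true_values, boot_means) {
  if (!length(true_values) || !length(boot_means)) stop("empty inputs")
  mt <- mean(true_values)
  mn <- mean(boot_means)
  sn <- stats::sd(boot_means)
  z <- if (sn > 0) (mt - mn) / sn else if (mt == mn) 0 else sign(mt - mn) * Inf
  n_boot <- length(boot_means)
  r <- sum(boot_means < mt)
  p <- min(1, 2 * min(r + 1, n_boot + 1 - r) / (n_boot + 1))
  list(z = z, p = p, mean_true = mt, mean_null = mn, sd_null = sn)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (monotone by construction) and the rejection
#' mask at level `q`.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and `reject`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adjusted, reject = !is.na(adjusted) & adjusted <= q)
}

#' Test true-dyad connectivity against the shuffled-team null
#'
#' For every channel pair, compares the mean connectivity of the true
#' dyads with a bootstrap distribution of shuffled-pair means
#' (`n_boot` means of `m` draws with replacement), yielding a z map and
#' two-sided percentile p-values, FDR-corrected across channel pairs.
#' Per-(pair) bootstrap seeds derive deterministically from `seed`.
#'
#' @param true_values Array: true dyads x channels_A x channels_B (or a
#'   dyads x pairs matrix).
#' @param shuffled_values Array: pseudo-dyads x channels_A x channels_B
#'   (or matrix), channel dimensions matching `true_values`.
#' @param n_boot,m Bootstrap parameters (defaults 1000 and 200).
#' @param q FDR level.
#' @param seed Integer root seed.
#' @return Object of class `ibs_null` with a `results` data frame
#'   (`chan_a`, `chan_b`, `mean_true`, `mean_null`, `sd_null`, `z`, `p`,
#'   `q_value`, `reject`) and the parameters.
#' @export
ibs_null_test <- function(true_values, shuffled_values, n_boot = 1000L,
                          m = 200L, q = 0.05, seed = 1L) {
  as_mat <- function(x) {
    if (length(dim(x)) == 3L) {
      dn <- dimnames(x)
      ca <- dn[[2]] %||% paste0("a", seq_len(dim(x)[2]))
      cb <- dn[[3]] %||% paste0("b", seq_len(dim(x)[3]))
      grid <- expand.grid(chan_a = ca, chan_b = cb, stringsAsFactors = FALSE)
      list(m = matrix(x, dim(x)[1]), pairs = grid)
    } else {
      x <- as.matrix(x)
      list(m = x, pairs = data.frame(
        chan_a = colnames(x) %||% paste0("p", seq_len(ncol(x))),
        chan_b = NA_character_, stringsAsFactors = FALSE))
    }
  }
  tv <- as_mat(true_values)
  sv <- as_mat(shuffled_values)
  if (ncol(tv$m) != ncol(sv$m))
    stop("true and shuffled channel-pair spaces differ")
  np <- ncol(tv$m)
  res <- tv$pairs
  res$mean_true <- res$mean_null <- res$sd_null <- res$z <- res$p <- NA_real_
  for (k in seq_len(np)) {
    boots <- bootstrap_null(sv$m[, k], n_boot, m, seed = derive_seed(seed, k))
    tn <- true_vs_null(tv$m[, k], boots)
    res$mean_true[k] <- tn$mean_true
    res$mean_null[k] <- tn$mean_null
    res$sd_null[k] <- tn$sd_null
    res$z[k] <- tn$z
    res$p[k] <- tn$p
  }
  fdr <- fdr_bh(res$p, q)
  res$q_value <- fdr$adjusted
  res$reject <- fdr$reject
  structure(list(results = res,
                 params = list(n_boot = n_boot, m = m, q = q, seed = seed,
                               n_true = nrow(tv$m), n_shuffled = nrow(sv$m))),
            class = "ibs_null")
}

#' @export
print.ibs_null <- function(x, ...) {
  r <- x$results
  cat(sprintf("<ibs_null> %d channel pairs; %d true dyads vs %d pseudo-dyads\n",
              nrow(r), x$params$n_true, x$params$n_shuffled))
  cat(sprintf("  bootstrap: %d means of %d draws; FDR q = %g\n",
              x$params$n_boot, x$params$m, x$params$q))
  cat(sprintf("  rejected: %d (%0.1f%%) [%d coupling z>0, %d decoupling z<0]\n",
              sum(r$reject), 100 * mean(r$reject),
              sum(r$reject & r$z > 0), sum(r$reject & r$z < 0)))
  invisible(x)
}

#' @export
summary.ibs_null <- function(object, ...) {
  r <- object$results
  print(object)
  cat("\nz distribution:\n")
  print(summary(r$z))
  top <- r[order(r$q_value), ][seq_len(min(10L, nrow(r))), ]
  cat("\nstrongest pairs:\n")
  print(top, row.names = FALSE)
  invisible(object)
}
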