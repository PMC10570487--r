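# Condition contrasts: one-way repeated-measures ANOVA with
# Holm-Bonferroni post hoc tests, and the mixed factorial design (within
# task mode x between gender composition). The sums-of-squares numerics
# are delegated to the classical aov() decomposition; this module's
# contract is the interface, the balanced-design handling and the post
# hoc adjustment.

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition
#' (`F = MS_factor / MS_(factor x subject)`) on a complete subjects x
#' levels table, with Holm-Bonferroni adjusted paired post hoc t tests.
#' Subjects with missing levels are dropped (reported by message and in
#' the result). No sphericity correction is applied by default, matching
#' the classical uncorrected degrees of freedom.
#'
#' @param x Either a numeric matrix/data frame with one row per subject
#'   and one column per factor level, or a long data frame with the
#'   columns named by `subject`, `level`, `value`.
#' @param subject,level,value Column names for long input.
#' @param posthoc Run pairwise paired t tests (default TRUE).
#' @return Object of class `stat_result`: `effects` data frame (`effect`,
#'   `F`, `df1`, `df2`, `p`), `posthoc` (`contrast`, `diff`, `p`,
#'   `p_adjusted`, `direction`), `n_subjects`, `dropped`.
#' @export
rm_anova <- function(x, subject = "subject", level = "level", value = "value",
                     posthoc = TRUE) {
  wide <- as_wide_table(x, subject, level, value)
  dropped <- sum(!stats::complete.cases(wide))
  if (dropped > 0) {
    message(dropped, " subject(s) dropped (incomplete levels)")
    wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  }
  n <- nrow(wide); a <- ncol(wide)
  if (a < 2L) stop("need at least 2 factor levels")
  if (n < 3L) stop("need at least 3 complete subjects")

  long <- data.frame(
    y = as.vector(as.matrix(wide)),
    level = factor(rep(colnames(wide), each = n)),
    subject = factor(rep(rownames(wide) %||% seq_len(n), a))
  )
  fit <- stats::aov(y ~ level + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  fval <- tab["level", "F value"]
  p <- tab["level", "Pr(>F)"]
  ms_err <- tab["Residuals", "Mean Sq"]
  ms_lvl <- tab["level", "Mean Sq"]
  # zero residual variance (perfectly additive data): F is undefined
  if (!is.finite(fval) || ms_err <= 1e-10 * (ms_lvl + ms_err)) {
    fval <- NA_real_; p <- NA_real_
  }
  effects <- data.frame(effect = "level", F = fval,
                        df1 = tab["level", "Df"],
                        df2 = tab["Residuals", "Df"], p = p,
                        stringsAsFactors = FALSE)

  ph <- NULL
  if (posthoc && a >= 2L) {
    combos <- utils::combn(colnames(wide), 2L)
    ph <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
      l1 <- combos[1, k]; l2 <- combos[2, k]
      d <- wide[[l1]] - wide[[l2]]
      tt <- stats::t.test(d)
      data.frame(contrast = paste(l1, "vs", l2), diff = mean(d),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
    ph$p_adjusted <- stats::p.adjust(ph$p, method = "holm")
    ph$direction <- ifelse(ph$diff > 0, ">", ifelse(ph$diff < 0, "<", "="))
  }
  structure(list(effects = effects, posthoc = ph, n_subjects = n,
                 dropped = dropped),
            class = "stat_result")
}

as_wide_table <- function(x, subject, level, value) {
  if (is.matrix(x)) return(as.data.frame(x))
  x <- as.data.frame(x)
  if (all(c(subject, level, value) %in% names(x))) {
    wide <- stats::reshape(x[, c(subject, level, value)],
                           idvar = subject, timevar = level,
                           direction = "wide")
    rownames(wide) <- wide[[subject]]
    wide[[subject]] <- NULL
    names(wide) <- sub(paste0("^", value, "\\."), "", names(wide))
    wide
  } else x  # already wide
}

#' Mixed factorial ANOVA (within x between)
#'
#' Split-plot decomposition with one within-subject factor and one
#' between-subject grouping factor: between main effect tested against
#' subjects-within-groups, within main effect and interaction tested
#' against the within-subject residual. Groups with a single subject must
#' be excluded by the caller (an informative error is raised otherwise).
#' A constant between factor degenerates to the one-way repeated-measures
#' analysis; the between effect is then flagged as untestable.
#'
#' @param data Long data frame.
#' @param subject,within,between,value Column names.
#' @return Object of class `stat_result` with three effects (between,
#'   within, interaction).
#' @export
mixed_anova <- function(data, subject = "subject", within = "mode",
                        between = "group", value = "value") {
  d <- data.frame(
    y = data[[value]],
    subject = factor(data[[subject]]),
    within = factor(data[[within]]),
    between = factor(data[[between]])
  )
  d <- d[stats::complete.cases(d), ]
  grp_of <- tapply(as.character(d$between), d$subject, function(v) v[1])
  sizes <- table(grp_of)
  if (nlevels(droplevels(d$between)) < 2L) {
    res <- rm_anova(d, subject = "subject", level = "within", value = "y",
                    posthoc = FALSE)
    res$effects$effect <- "within"
    res$effects <- rbind(
      data.frame(effect = "between", F = NA_real_, df1 = NA_real_,
                 df2 = NA_real_, p = NA_real_, stringsAsFactors = FALSE),
      res$effects)
    res$note <- "between factor constant: between effect untestable (df = 0)"
    return(res)
  }
  if (any(sizes < 2L))
    stop("group(s) with a single subject: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "),
         "; exclude singleton groups before calling mixed_anova")

  fit <- stats::aov(y ~ within * between + Error(subject), data = d)
  s <- summary(fit)
  btab <- s[["Error: subject"]][[1]]
  wtab <- s[["Error: Within"]][[1]]
  grab <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    if (is.na(i)) return(c(NA, NA, NA))
    c(tab[i, "F value"], tab[i, "Df"], tab[i, "Pr(>F)"])
  }
  b <- grab(btab, "between")
  w <- grab(wtab, "within")
  i <- grab(wtab, "within:between")
  df2b <- btab[trimws(rownames(btab)) == "Residuals", "Df"]
  df2w <- wtab[trimws(rownames(wtab)) == "Residuals", "Df"]
  if (!length(df2b)) df2b <- NA_real_
  if (!length(df2w)) df2w <- NA_real_
  effects <- data.frame(
    effect = c("between", "within", "within:between"),
    F = c(b[1], w[1], i[1]),
    df1 = c(b[2], w[2], i[2]),
    df2 = c(df2b, df2w, df2w),
    p = c(b[3], w[3], i[3]),
    stringsAsFactors = FALSE
  )
  structure(list(effects = effects, posthoc = NULL,
                 n_subjects = nlevels(droplevels(d$subject)),
                 group_sizes = sizes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat("<stat_result>", x$n_subjects, "subjects\n")
  e <- x$effects
  for (k in seq_len(nrow(e)))
    cat(sprintf("  %s: F(%s, %s) = %s, p = %s\n", e$effect[k],
                format(e$df1[k]), format(e$df2[k]),
                format(round(e$F[k], 3)), format.pval(e$p[k], digits = 3)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Holm):\n")
    ph <- x$posthoc
    for (k in seq_len(nrow(ph)))
      cat(sprintf("    %s (%s): p_adj = %s\n", ph$contrast[k],
                  ph$direction[k], format.pval(ph$p_adjusted[k], digits = 3)))
  }
  invisible(x)
}
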