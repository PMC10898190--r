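#' Clinical cohort table: abscess-wall optical properties at 665 nm
#'
#' Per-subject optical properties at 665 nm, oxygen saturation and
#' methylene blue concentration for the 13-subject abscess-PDT spectroscopy
#' cohort, before (pre) and after (post) MB administration, as published.
#' Post-MB data were not of sufficient quality for subject 1 (`NA` row).
#'
#' @return `data.frame` with columns `subject`, `mua665_pre`,
#'   `musp665_pre`, `so2_pre`, `mua665_post`, `musp665_post`, `so2_post`,
#'   `mb` (uM).
#' @export
abscess_cohort <- function() {
  data.frame(
    subject = 1:13,
    mua665_pre = c(0.32, 0.03, 0.09, 0.14, 0.11, 0.09, 0.21, 0.36, 0.14,
                   0.20, 0.06, 0.11, 0.04),
    musp665_pre = c(6.7, 10.6, 5.5, 7.1, 8.6, 4.8, 8.7, 13.2, 10.4, 7.2,
                    7.6, 11.3, 8.0),
    so2_pre = c(100.0, 56.5, 100.0, 81.1, 81.4, 87.7, 17.4, 48.7, 100.0,
                8.4, 54.2, 5.6, 23.8),
    mua665_post = c(NA, 9.6, 0.28, 10.1, 3.1, 49.4, 0.08, 2.9, 5.0, 3.6,
                    41.5, 0.86, 1.76),
    musp665_post = c(NA, 9.8, 6.6, 4.0, 1.6, 3.4, 9.9, 6.8, 4.1, 3.5, 4.5,
                     6.5, 3.2),
    so2_post = c(NA, 7.6, 76.4, 45.5, 45.1, 36.3, 72.4, 29.9, 23.7, 40.0,
                 20.3, 0.0001, 37.7),
    mb = c(NA, 58.2, 0.8, 59.4, 1.7e-6, 311, 0, 8.0, 13.2, 17.1, 227, 4.3,
           7.0))
}

#' Cohort summaries: mean, sample SD and range per quantity
#'
#' Summarizes each numeric column across subjects as mean, standard
#' deviation (n - 1 denominator), minimum, maximum and the number of
#' non-missing values; all-missing columns are omitted with a note.
#'
#' @param records `data.frame` with one row per subject (see
#'   [abscess_cohort()] for the expected shape); non-numeric columns are
#'   ignored.
#' @return `data.frame` with one row per summarized quantity.
#' @export
summarize_cohort <- function(records) {
  if (nrow(records) < 2L) stop("need at least 2 subjects", call. = FALSE)
  num <- names(records)[vapply(records, is.numeric, TRUE)]
  num <- setdiff(num, "subject")
  rows <- lapply(num, function(q) {
    x <- records[[q]]
    n <- sum(is.finite(x))
    if (n == 0L) {
      message("quantity ", q, " is all missing; omitted")
      return(NULL)
    }
    data.frame(quantity = q, mean = mean(x, na.rm = TRUE),
               sd = stats::sd(x, na.rm = TRUE), min = min(x, na.rm = TRUE),
               max = max(x, na.rm = TRUE), n = n)
  })
  do.call(rbind, rows)
}

# exact null distribution of the signed-rank statistic over doubled
# (integer) midranks, by polynomial convolution
signed_rank_null <- function(ranks2) {
  probs <- c(1)
  for (r in ranks2) {
    nxt <- c(probs, numeric(r)) / 2
    nxt[(r + 1):(r + length(probs))] <-
      nxt[(r + 1):(r + length(probs))] + probs / 2
    probs <- nxt
  }
  probs  # probs[k + 1] = P(2 * W+ = k)
}

#' Exact Wilcoxon signed-rank test for paired measurements
#'
#' Two-sided paired signed-rank test with midranks for tied absolute
#' differences.  Zero differences are dropped before ranking (the common
#' convention).  For up to `exact_max` informative pairs the p-value comes
#' from the exact null distribution (computed by convolution over the
#' doubled ranks); above that, a tie-corrected normal approximation with
#' continuity correction is used.  Missing pairs are dropped.
#'
#' @param pre,post Paired measurement vectors.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (W+, sum of positive ranks), `p.value`,
#'   `n` (informative pairs), and `method`.  With no informative pairs the
#'   p-value is 1 (no evidence against the null).
#' @export
paired_wilcoxon <- function(pre, post, exact_max = 25L) {
  keep <- is.finite(pre) & is.finite(post)
  d <- post[keep] - pre[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = 1, n = 0L,
                method = "no informative pairs"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n < 3L) {
    warning(warningCondition(
      "fewer than 3 informative pairs: signed-rank test is uninformative",
      class = "drsfit_degenerate_test"))
  }
  if (n <= exact_max) {
    probs <- signed_rank_null(as.integer(round(2 * r)))
    k <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(k + 1L)])
    p_ge <- sum(probs[(k + 1L):length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (midranks)"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie^3 - tie) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie and continuity corrected"
  }
  list(statistic = W, p.value = p, n = n, method = method)
}

#' Spearman rank correlation test
#'
#' Midranks for ties; two-sided p-value (exact when tie-free and n small,
#' via [stats::cor.test()], otherwise the t approximation).
#'
#' @param x,y Paired observations; incomplete pairs dropped.
#' @return List with `rho`, `p.value`, `n`.
#' @export
correlation_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop(errorCondition("need at least 3 complete pairs",
                        class = "drsfit_degenerate_test"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(errorCondition("constant input: correlation undefined",
                        class = "drsfit_degenerate_test"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Two-group and k-group rank comparisons
#'
#' With two groups, the Mann-Whitney (Wilcoxon rank-sum) test; with more,
#' the Kruskal-Wallis test accompanied by Dunn's pairwise z tests on mean
#' ranks (tie-corrected).  Dunn p-values are reported raw by default; a
#' multiplicity adjustment can be requested via `p_adjust`.
#'
#' @param values Numeric observations.
#' @param labels Group labels (coerced to factor).
#' @param p_adjust Adjustment method for Dunn p-values (see
#'   [stats::p.adjust()]); `"none"` by default.
#' @return For two groups: list with `statistic`, `p.value`, `method`.
#'   For k > 2: that plus a `pairwise` data.frame of Dunn comparisons with
#'   raw and adjusted p-values.
#' @export
group_test <- function(values, labels, p_adjust = "none") {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- factor(labels[keep])
  labels <- droplevels(labels)
  if (length(values) < 3L || nlevels(labels) < 2L) {
    stop(errorCondition("need >= 3 observations in >= 2 groups",
                        class = "drsfit_degenerate_test"))
  }
  if (stats::sd(values) == 0) {
    stop(errorCondition("constant input: rank test undefined",
                        class = "drsfit_degenerate_test"))
  }
  if (nlevels(labels) == 2L) {
    wt <- suppressWarnings(
      stats::wilcox.test(values ~ labels, exact = TRUE))
    return(list(statistic = unname(wt$statistic), p.value = wt$p.value,
                method = "Mann-Whitney"))
  }
  kw <- stats::kruskal.test(values, labels)
  N <- length(values)
  r <- rank(values)
  tie <- table(values)
  tie_term <- sum(tie^3 - tie) / (12 * (N - 1))
  rbar <- tapply(r, labels, mean)
  ns <- tapply(r, labels, length)
  lev <- levels(labels)
  cmb <- utils::combn(lev, 2)
  pw <- apply(cmb, 2, function(pair) {
    j <- pair[1]; k <- pair[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[j]] + 1 / ns[[k]]))
    z <- (rbar[[j]] - rbar[[k]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                         z = pw["z", ], p.value = pw["p", ],
                         p.adjusted = stats::p.adjust(pw["p", ],
                                                      method = p_adjust))
  list(statistic = unname(kw$statistic), p.value = kw$p.value,
       method = "Kruskal-Wallis + Dunn", pairwise = pairwise)
}

#' Full cohort report: summaries, paired tests and correlation
#'
#' Reproduces the cohort-level analysis on a per-subject table of fitted
#' optical properties: mean/SD/range summaries per quantity and condition,
#' paired signed-rank tests of the 665 nm optical properties and SO2
#' between pre- and post-MB conditions, and the Spearman correlation
#' between MB concentration and the pre-to-post SO2 change.
#'
#' @param records Table shaped like [abscess_cohort()].
#' @return Object of class `cohort_report`.
#' @export
cohort_report <- function(records) {
  summaries <- summarize_cohort(records)
  paired <- list(
    mua665 = paired_wilcoxon(records$mua665_pre, records$mua665_post),
    musp665 = paired_wilcoxon(records$musp665_pre, records$musp665_post),
    so2 = paired_wilcoxon(records$so2_pre, records$so2_post))
  dso2 <- records$so2_post - records$so2_pre
  corr <- correlation_test(records$mb, dso2)
  structure(list(summaries = summaries, paired = paired,
                 mb_vs_dso2 = corr, n_subjects = nrow(records)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cohort report (%d subjects)\n\n", x$n_subjects))
  s <- x$summaries
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.4g +/- %.4g (range: %.4g to %.4g), n = %d\n",
                s$quantity[i], s$mean[i], s$sd[i], s$min[i], s$max[i],
                s$n[i]))
  }
  cat("\nPaired pre/post signed-rank tests:\n")
  for (q in names(x$paired)) {
    t <- x$paired[[q]]
    cat(sprintf("  %-8s W = %g, p = %.4g (n = %d, %s)\n", q, t$statistic,
                t$p.value, t$n, t$method))
  }
  cat(sprintf("\nSpearman [MB] vs delta-SO2: rho = %.3f, p = %.3g (n = %d)\n",
              x$mb_vs_dso2$rho, x$mb_vs_dso2$p.value, x$mb_vs_dso2$n))
  invisible(x)
}
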