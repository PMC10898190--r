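test_that("cohort summaries compute mean/SD/range and handle degeneracy", {
  d <- data.frame(subject = 1:4, x = c(2, 4, 6, 8), y = rep(5, 4),
                  z = rep(NA_real_, 4))
  expect_message(s <- summarize_cohort(d), "all missing")
  expect_equal(s$mean[s$quantity == "x"], 5)
  expect_equal(s$sd[s$quantity == "x"], sd(c(2, 4, 6, 8)))
  expect_equal(s$min[s$quantity == "x"], 2)
  expect_equal(s$max[s$quantity == "x"], 8)
  expect_equal(s$sd[s$quantity == "y"], 0)          # repeated value
  expect_false("z" %in% s$quantity)
  expect_error(summarize_cohort(d[1, ]), "2 subjects")
})

test_that("signed-rank test: exact null against full enumeration", {
  # brute-force two-sided p over all 2^n sign assignments
  brute_p <- function(d) {
    d <- d[d != 0]; n <- length(d)
    r <- rank(abs(d))
    W_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.numeric(signs %*% r)
    mu <- sum(r) / 2
    min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
  }
  set.seed(17)
  for (rep in 1:5) {
    d <- round(rnorm(8), 1)
    got <- paired_wilcoxon(rep(0, length(d)), d)
    expect_equal(got$p.value, brute_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank test matches wilcox.test in the tie-free exact case", {
  set.seed(5)
  pre <- rnorm(12); post <- pre + rnorm(12, 0.4)
  ours <- paired_wilcoxon(pre, post)
  ref <- wilcox.test(post, pre, paired = TRUE, exact = TRUE)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  expect_equal(unname(ours$statistic), unname(ref$statistic))
})

test_that("signed-rank edge cases follow the zero-difference policy", {
  x <- c(1, 2, 3, 4)
  expect_equal(paired_wilcoxon(x, x)$p.value, 1)
  expect_equal(paired_wilcoxon(x, x)$n, 0)
  expect_warning(paired_wilcoxon(c(1, 2), c(3, 1)),
                 class = "drsfit_degenerate_test")
  # a uniform positive shift over 12 pairs is maximally significant
  set.seed(2)
  pre <- rnorm(12)
  got <- paired_wilcoxon(pre, pre + 5)
  expect_lt(got$p.value, 0.01)
  expect_equal(got$p.value, 2 / 2^12, tolerance = 1e-12)
})

test_that("Spearman correlation: monotone behavior and degeneracy", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- x^3 + 2
  expect_equal(correlation_test(x, y)$rho, 1)
  z <- c(2, 7, 1, 8, 2.8, 1.8, 2.9)
  base <- correlation_test(x, z)
  trans <- correlation_test(exp(x), log(z))   # strictly monotone maps
  expect_equal(base$rho, trans$rho)
  expect_equal(base$p.value, trans$p.value)
  expect_error(correlation_test(c(1, 1, 1), c(1, 2, 3)),
               class = "drsfit_degenerate_test")
  expect_error(correlation_test(c(1, 2), c(1, 2)),
               class = "drsfit_degenerate_test")
})

test_that("two-group and k-group rank tests behave", {
  v <- c(1, 2, 3, 4, 5, 6)
  g2 <- rep(c("a", "b"), 3)
  got <- group_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(got$p.value, 1)                # identical groups
  expect_equal(got$method, "Mann-Whitney")
  set.seed(8)
  v3 <- rnorm(30); g3 <- rep(c("a", "b", "c"), 10)
  kg <- group_test(v3, g3)
  expect_equal(kg$method, "Kruskal-Wallis + Dunn")
  expect_equal(nrow(kg$pairwise), 3)
  expect_gt(kg$p.value, 0.05)                 # same distribution
  kg_adj <- group_test(v3, g3, p_adjust = "bonferroni")
  expect_true(all(kg_adj$pairwise$p.adjusted >= kg_adj$pairwise$p.value))
  expect_error(group_test(rep(1, 6), g2), class = "drsfit_degenerate_test")
})

test_that("cohort_report assembles summaries, paired tests and correlation", {
  rep_ <- cohort_report(abscess_cohort())
  expect_s3_class(rep_, "cohort_report")
  expect_named(rep_$paired, c("mua665", "musp665", "so2"))
  expect_equal(rep_$paired$mua665$n, 12)      # subject 1 post missing
  expect_equal(rep_$mb_vs_dso2$n, 12)
  expect_output(print(rep_), "Spearman")
})
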