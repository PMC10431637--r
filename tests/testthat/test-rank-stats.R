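table1_ranks <- c(NSCT = 6.67, `PCNN-NSCT` = 6.36, `NSCT-SR` = 6.08,
                  `m-PCNN` = 5.92, `SCM-F` = 5.44, `SCM-M` = 4.64,
                  `Nabla-PCA` = 3.53, `Nabla-weighted` = 3.28,
                  `Nabla-max` = 3.08)

test_that("within-row ranking respects orientation and ties", {
  s <- score_matrix(rbind(c(0.9, 0.5, 0.7), c(0.9, 0.9, 0.1)))
  r <- rank_rows(s)
  expect_equal(r$r[1, ], c(M1 = 1, M2 = 3, M3 = 2))
  expect_equal(r$r[2, ], c(M1 = 1.5, M2 = 1.5, M3 = 3))
  # lower_better flips the direction
  s2 <- score_matrix(rbind(c(1, 2, 3), c(3, 2, 1)),
                     orientation = c("lower_better", "higher_better"))
  expect_equal(unname(rank_rows(s2)$r), rbind(c(1, 2, 3), c(1, 2, 3)))
  # all-identical row: every rank (k+1)/2
  s3 <- score_matrix(rbind(c(2, 2, 2), c(1, 2, 3)))
  expect_equal(unname(rank_rows(s3)$r[1, ]), rep(2, 3))
  expect_error(score_matrix(rbind(c(1, NA), c(1, 2))), "non-finite")
})

test_that("row rank sums and grand mean are invariant", {
  set.seed(61)
  for (i in 1:20) {
    N <- sample(2:30, 1); k <- sample(2:12, 1)
    r <- rank_rows(score_matrix(matrix(rnorm(N * k), N, k)))
    expect_equal(unname(rowSums(r$r)), rep(k * (k + 1) / 2, N))
    expect_equal(r$grand_mean, (k + 1) / 2)
  }
})

test_that("Friedman chi-square reproduces printed and hand values", {
  # printed mean ranks, N = 36, k = 9
  expect_equal(friedman_chi2(table1_ranks, N = 36), 75.74, tolerance = 0.01 / 75.74)
  # all methods tied: statistic 0
  expect_equal(friedman_chi2(rep(2.5, 4), N = 10), 0)
  # two methods, two rows, method 1 always best:
  # 12*2/(2*3) * [(1 + 4) - 2*9/4] = 2
  s <- score_matrix(rbind(c(2, 1), c(5, 3)))
  expect_equal(friedman_chi2(rank_rows(s)), 2)
  expect_error(friedman_chi2(3.5, N = NULL), "required")
})

test_that("F form follows from the chi-square", {
  chi1 <- friedman_chi2(table1_ranks, N = 36)
  expect_equal(friedman_F(chi1, 36, 9), 12.49, tolerance = 0.01 / 12.49)
  expect_equal(friedman_F(81.75, 36, 8), 16.81, tolerance = 0.01 / 16.81)
  expect_equal(friedman_F(0, 36, 9), 0)
  expect_error(friedman_F(36 * 8, 36, 9), "degenerate")
})

test_that("Q = SSt/SSe equals the chi-square form without ties", {
  set.seed(62)
  for (i in 1:10) {
    N <- sample(5:25, 1); k <- sample(3:8, 1)
    r <- rank_rows(score_matrix(matrix(rnorm(N * k), N, k)))
    q <- friedman_Q(r)
    expect_equal(q$Q, friedman_chi2(r), tolerance = 1e-10)
    expect_equal(q$p_value, pchisq(q$Q, k - 1, lower.tail = FALSE))
  }
  # all methods identical in every row: every rank is tied, SSe = 0
  expect_error(friedman_Q(score_matrix(matrix(5, 4, 3))), "degenerate")
  # hand case: N = 2, k = 2, method 1 always best -> Q = 2
  expect_equal(friedman_Q(rank_rows(score_matrix(rbind(c(2, 1), c(5, 3)))))$Q, 2)
})

test_that("standard error and critical differences reproduce the printed reference chain", {
  expect_equal(standard_error(9, 36), 0.646, tolerance = 0.001 / 0.646)
  expect_equal(standard_error(2, 1), 1)
  expect_equal(standard_error(5, 40), standard_error(5, 10) / 2)
  # Bonferroni-Dunn q = 2.95 -> CD = 1.9
  expect_equal(cd_critical_difference(9, 36, 2.95), 1.9, tolerance = 0.01 / 1.9)
  expect_equal(critical_value_bonferroni_dunn(9, 36), 2.95, tolerance = 0.01)
  # two-comparison-corrected normal quantile -> CD ~ 2.064
  cd <- cd_critical_difference(9, 36, critical_value_normal(9))
  expect_equal(cd, 2.064, tolerance = 0.01)
  expect_equal(cd_critical_difference(9, 36, 0), 0)
})

test_that("pairwise decisions use a strict CD threshold", {
  d <- pairwise_decisions(table1_ranks, 2.064)
  expect_true(d["Nabla-PCA", "m-PCNN"])       # |3.53 - 5.92| = 2.39 > CD
  expect_false(d["Nabla-PCA", "SCM-M"])       # |3.53 - 4.64| = 1.11 < CD
  expect_true(isSymmetric(d))
  expect_false(any(diag(d)))
  # CD above the whole spread: nothing significant
  expect_false(any(pairwise_decisions(table1_ranks, 10)))
  # CD = 0 with strict ">": any nonzero difference is significant
  expect_true(all(pairwise_decisions(c(1, 2), 0)[1, 2]))
})

test_that("p-values against the best method follow the two-sided normal", {
  # printed standardized differences map to the corresponding p-values
  expect_lt(abs(2 * (1 - pnorm(0.3012)) - 0.763), 0.001)
  expect_lt(abs(2 * (1 - pnorm(0.6885)) - 0.4911), 0.001)
  expect_lt(abs(2 * (1 - pnorm(2.4099)) - 0.0160), 0.001)
  tab <- p_vs_best(table1_ranks, N = 36)
  expect_identical(attr(tab, "best"), "Nabla-max")
  expect_equal(attr(tab, "SE"), standard_error(9, 36))
  expect_identical(tab$method[1], "NSCT")              # weakest first
  expect_identical(tab$method[8], "Nabla-weighted")
  expect_false(is.unsorted(tab$p))
  # a method tied with the best gets p = 1
  tied <- p_vs_best(c(A = 2, B = 2, C = 3), N = 10)
  expect_equal(tied$p[tied$method == "B"], 1)
})

table2_p <- c(0.0000, 0.0000, 0.0000, 0.0000, 0.0003, 0.0160, 0.4911, 0.7632)
table2_methods <- c("NSCT", "PCNN-NSCT", "NSCT-SR", "m-PCNN", "SCM-F",
                    "SCM-M", "Nabla-PCA", "Nabla-weighted")

test_that("Holm and Hochberg reproduce the printed rejection sets", {
  h <- holm(table2_p, alpha = 0.05, labels = table2_methods)
  expect_equal(h$thresholds,
               c(0.0063, 0.0071, 0.0083, 0.01, 0.0125, 0.0167, 0.025, 0.05),
               tolerance = 1e-2)
  expect_identical(h$labels[h$rejected],
                   c("NSCT", "PCNN-NSCT", "NSCT-SR", "m-PCNN", "SCM-F",
                     "SCM-M"))
  expect_identical(h$labels[!h$rejected], c("Nabla-PCA", "Nabla-weighted"))
  hb <- hochberg(table2_p, alpha = 0.05, labels = table2_methods)
  expect_identical(hb$rejected, h$rejected)
})

test_that("stepwise procedures handle edge cases and nest correctly", {
  expect_false(any(holm(rep(1, 5))$rejected))
  expect_false(any(hochberg(rep(1, 5))$rejected))
  expect_true(all(holm(rep(0, 5))$rejected))
  expect_true(all(hochberg(rep(0, 5))$rejected))
  # hand-enumerated: p = (.02, .04), k = 3 -> both procedures reject both
  expect_true(all(holm(c(0.02, 0.04))$rejected))
  expect_true(all(hochberg(c(0.02, 0.04))$rejected))
  expect_error(holm(c(0.5, 0.1)), "sorted")
  expect_error(hochberg(c(0.2, 0.1)), "sorted")
  # Hochberg rejections are a superset of Holm's on random p-vectors
  set.seed(63)
  for (i in 1:50) {
    p <- sort(runif(sample(2:9, 1)))
    expect_true(all(holm(p)$rejected <= hochberg(p)$rejected))
  }
})

test_that("the protocol is equivariant and rank-monotone", {
  set.seed(64)
  m <- matrix(rnorm(20 * 5), 20, 5)
  base <- friedman_test(score_matrix(m))
  perm <- c(4, 2, 5, 1, 3)
  permd <- friedman_test(score_matrix(m[, perm]))
  expect_equal(unname(permd$mean_ranks), unname(base$mean_ranks[perm]))
  expect_equal(permd$chi2, base$chi2)
  expect_equal(permd$F, base$F)
  # boosting one column can only improve (lower) its mean rank
  m2 <- m; m2[, 3] <- m2[, 3] + 2
  expect_lte(friedman_test(score_matrix(m2))$mean_ranks[3],
             base$mean_ranks[3])
})

test_that("compare_methods runs the whole chain from scores or mean ranks", {
  cmp <- compare_methods(table1_ranks, N = 36)
  expect_equal(cmp$friedman$chi2, 75.74, tolerance = 1e-3)
  expect_equal(cmp$friedman$F, 12.49, tolerance = 1e-3)
  expect_identical(cmp$holm$labels[cmp$holm$rejected],
                   c("NSCT", "PCNN-NSCT", "NSCT-SR", "m-PCNN", "SCM-F",
                     "SCM-M"))
  expect_identical(cmp$hochberg$labels[cmp$hochberg$rejected],
                   cmp$holm$labels[cmp$holm$rejected])
  s <- make_score_matrix(12, 4, planted_mean_ranks = c(1, 2, 3, 4),
                         noise = 0.3, seed = 9)
  cmp2 <- compare_methods(s)
  expect_s3_class(cmp2$friedman, "friedman_result")
  expect_output(print(cmp2), "Friedman")
})
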