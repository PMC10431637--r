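# Friedman-test protocol for comparing k fusion methods over N samples
# (each sample = one metric on one experiment). Convention throughout:
# rank 1 = best within a sample, so the best method has the LOWEST mean rank.

#' Construct a score matrix
#'
#' Wraps an N-by-k table of metric values (N samples as rows, k methods as
#' columns) together with method names and each row's orientation, i.e.
#' whether larger values are better for that sample's metric.
#'
#' @param values numeric N-by-k matrix, all finite, N >= 2, k >= 2.
#' @param methods character vector of k method names (default: column names
#'   or `M1..Mk`).
#' @param orientation `"higher_better"` (default) or `"lower_better"`,
#'   length 1 or N (recycled per row).
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values, methods = NULL,
                         orientation = "higher_better") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 samples and 2 methods", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries", call. = FALSE)
  k <- ncol(values)
  if (is.null(methods)) methods <- colnames(values)
  if (is.null(methods)) methods <- paste0("M", seq_len(k))
  if (length(methods) != k) stop("need one method name per column",
                                 call. = FALSE)
  if (!all(orientation %in% c("higher_better", "lower_better")))
    stop("orientation must be 'higher_better' or 'lower_better'",
         call. = FALSE)
  orientation <- rep_len(orientation, nrow(values))
  colnames(values) <- methods
  structure(list(values = values, methods = methods,
                 orientation = orientation),
            class = "score_matrix")
}

#' Within-sample ranks of a score matrix
#'
#' Ranks methods within each row, rank 1 = best per that row's orientation,
#' ties receiving average ranks (which keeps each row sum at k(k+1)/2).
#'
#' @param scores a [score_matrix] (or plain matrix, treated as
#'   higher-is-better).
#' @return An object of class `rank_matrix`: list with the N-by-k rank matrix
#'   `r`, `mean_ranks`, `grand_mean`, `N` and `k`.
#' @export
rank_rows <- function(scores) {
  if (is.matrix(scores)) scores <- score_matrix(scores)
  if (!inherits(scores, "score_matrix"))
    stop("`scores` must be a score_matrix", call. = FALSE)
  v <- scores$values
  r <- t(vapply(seq_len(nrow(v)), function(i) {
    x <- v[i, ]
    if (scores$orientation[i] == "higher_better") x <- -x
    rank(x, ties.method = "average")
  }, numeric(ncol(v))))
  colnames(r) <- scores$methods
  structure(list(r = r, mean_ranks = colMeans(r),
                 grand_mean = mean(r), N = nrow(r), k = ncol(r)),
            class = "rank_matrix")
}

as_mean_ranks <- function(x, N) {
  if (inherits(x, "rank_matrix"))
    return(list(mr = x$mean_ranks, N = x$N, k = x$k))
  if (inherits(x, "score_matrix")) return(as_mean_ranks(rank_rows(x), N))
  if (is.matrix(x)) return(as_mean_ranks(rank_rows(score_matrix(x)), N))
  if (is.numeric(x)) {
    if (is.null(N)) stop("`N` is required when mean ranks are supplied directly",
                         call. = FALSE)
    return(list(mr = x, N = N, k = length(x)))
  }
  stop("cannot interpret `x` as ranks or mean ranks", call. = FALSE)
}

#' Friedman chi-square statistic
#'
#' \deqn{\chi^2_F = \frac{12N}{k(k+1)}\Big[\sum_j \bar r_j^2 -
#'       \frac{k(k+1)^2}{4}\Big]}
#' from the column mean ranks. Accepts a [rank_matrix], a [score_matrix], a
#' plain score matrix, or a numeric vector of externally supplied mean ranks
#' (then `N` must be given).
#'
#' @param x ranks, scores, or a numeric vector of k mean ranks.
#' @param N number of samples; only needed when `x` is a plain mean-rank
#'   vector.
#' @return The chi-square statistic (k-1 degrees of freedom).
#' @export
friedman_chi2 <- function(x, N = NULL) {
  d <- as_mean_ranks(x, N)
  if (d$k < 2L) stop("need k >= 2 methods", call. = FALSE)
  12 * d$N / (d$k * (d$k + 1)) * (sum(d$mr^2) - d$k * (d$k + 1)^2 / 4)
}

#' F-form of the Friedman statistic
#'
#' \deqn{F_F = \frac{(N-1)\,\chi^2_F}{N(k-1) - \chi^2_F}} with
#' (k-1) and (k-1)(N-1) degrees of freedom; the less conservative form used
#' against F critical-value tables.
#'
#' @param chi2 the Friedman chi-square statistic.
#' @param N number of samples.
#' @param k number of methods.
#' @return The F statistic.
#' @export
friedman_F <- function(chi2, N, k) {
  if (chi2 < 0) stop("`chi2` must be >= 0", call. = FALSE)
  if (chi2 >= N * (k - 1))
    stop("degenerate statistic: chi2 must be < N(k-1)", call. = FALSE)
  (N - 1) * chi2 / (N * (k - 1) - chi2)
}

#' Friedman statistic as a ratio of sums of squares
#'
#' \eqn{Q = SS_t / SS_e} with
#' \eqn{SS_t = N \sum_j (\bar r_{.j} - \bar r)^2} and
#' \eqn{SS_e = \frac{1}{N(k-1)} \sum_{ij} (r_{ij} - \bar r)^2}. Without ties
#' Q equals the chi-square form to round-off.
#'
#' @param ranks a [rank_matrix] (or scores coercible to one).
#' @return List with `Q`, `SSt`, `SSe`, `df` (= k-1) and `p_value` from the
#'   chi-square approximation.
#' @export
friedman_Q <- function(ranks) {
  if (!inherits(ranks, "rank_matrix")) ranks <- rank_rows(ranks)
  SSt <- ranks$N * sum((ranks$mean_ranks - ranks$grand_mean)^2)
  SSe <- sum((ranks$r - ranks$grand_mean)^2) / (ranks$N * (ranks$k - 1))
  if (SSe == 0)
    stop("degenerate statistic: SSe is zero (all rows identically ranked)",
         call. = FALSE)
  Q <- SSt / SSe
  list(Q = Q, SSt = SSt, SSe = SSe, df = ranks$k - 1L,
       p_value = stats::pchisq(Q, ranks$k - 1L, lower.tail = FALSE))
}

#' Friedman test of a score matrix
#'
#' Runs the whole chain: within-row ranks, mean ranks, the chi-square and F
#' statistics with their p-values (chi-square on k-1 df; F on (k-1),
#' (k-1)(N-1) df). A perfectly consistent ordering reaches the chi-square
#' ceiling N(k-1), where the F form degenerates; it is reported as `Inf`
#' with p-value 0 rather than an error.
#'
#' @param scores a [score_matrix] or plain matrix.
#' @return Object of class `friedman_result`.
#' @export
friedman_test <- function(scores) {
  ranks <- rank_rows(scores)
  chi2 <- friedman_chi2(ranks)
  FF <- friedman_F_safe(chi2, ranks$N, ranks$k)
  structure(list(
    mean_ranks = ranks$mean_ranks, N = ranks$N, k = ranks$k,
    chi2 = chi2, df_chi2 = ranks$k - 1L,
    p_chi2 = stats::pchisq(chi2, ranks$k - 1L, lower.tail = FALSE),
    F = FF, df_F = c(ranks$k - 1L, (ranks$k - 1L) * (ranks$N - 1L)),
    p_F = if (is.finite(FF))
      stats::pf(FF, ranks$k - 1L, (ranks$k - 1L) * (ranks$N - 1L),
                lower.tail = FALSE) else 0,
    ranks = ranks), class = "friedman_result")
}

friedman_F_safe <- function(chi2, N, k) {
  if (chi2 >= N * (k - 1)) Inf else friedman_F(chi2, N, k)
}

#' @export
print.friedman_result <- function(x, ...) {
  cat("Friedman test:", x$N, "samples x", x$k, "methods\n")
  cat("Mean ranks (1 = best):\n")
  print(round(sort(x$mean_ranks), 2))
  cat(sprintf("chi^2_F = %.4g on %d df, p = %.4g\n", x$chi2, x$df_chi2,
              x$p_chi2))
  cat(sprintf("F_F = %.4g on (%d, %d) df, p = %.4g\n", x$F, x$df_F[1],
              x$df_F[2], x$p_F))
  invisible(x)
}

#' Standard error of a mean-rank difference
#'
#' \eqn{SE = \sqrt{k(k+1)/(6N)}}.
#'
#' @param k number of methods (>= 2).
#' @param N number of samples (>= 1).
#' @return Positive real.
#' @export
standard_error <- function(k, N) {
  if (k < 2 || N < 1) stop("need k >= 2 and N >= 1", call. = FALSE)
  sqrt(k * (k + 1) / (6 * N))
}

#' Critical values for critical-difference post hocs
#'
#' `critical_value_normal()` gives the Siegel-Castellan (Kruskal-Wallis style)
#' value: the upper-tail normal quantile at \eqn{\alpha/(k(k-1))}, i.e. the
#' two-comparison-corrected z. `critical_value_bonferroni_dunn()` gives the
#' two-tailed Bonferroni-Dunn value, computed as the Student-t quantile
#' \eqn{t_{1-\alpha/(2k),\,N-1}} (the closed form behind the usual printed
#' Bonferroni tables; for k = 9, N = 36, alpha = 0.05 it is 2.955).
#'
#' @param k number of methods.
#' @param N number of samples (Bonferroni-Dunn only).
#' @param alpha family significance level (default 0.05).
#' @return Positive critical value.
#' @export
critical_value_normal <- function(k, alpha = 0.05) {
  if (k < 2) stop("need k >= 2", call. = FALSE)
  stats::qnorm(1 - alpha / (k * (k - 1)))
}

#' @rdname critical_value_normal
#' @export
critical_value_bonferroni_dunn <- function(k, N, alpha = 0.05) {
  if (k < 2 || N < 2) stop("need k >= 2 and N >= 2", call. = FALSE)
  stats::qt(1 - alpha / (2 * k), df = N - 1)
}

#' Critical difference for mean ranks
#'
#' `CD = critical_value * standard_error(k, N)`; two mean ranks further apart
#' than CD are declared significantly different.
#'
#' @inheritParams standard_error
#' @param critical_value a z or q value, e.g. from
#'   [critical_value_normal()] or [critical_value_bonferroni_dunn()].
#' @return Nonnegative real.
#' @export
cd_critical_difference <- function(k, N, critical_value) {
  if (critical_value < 0) stop("`critical_value` must be >= 0", call. = FALSE)
  critical_value * standard_error(k, N)
}

#' Pairwise significance decisions from mean ranks
#'
#' Entry (u, v) is `TRUE` iff `|mean_rank_u - mean_rank_v| > CD` (strictly
#' "bigger than"); the diagonal is `FALSE`.
#'
#' @param mean_ranks numeric vector of k mean ranks (names kept).
#' @param CD nonnegative critical difference.
#' @return Symmetric k-by-k logical matrix.
#' @export
pairwise_decisions <- function(mean_ranks, CD) {
  if (CD < 0) stop("`CD` must be >= 0", call. = FALSE)
  d <- abs(outer(mean_ranks, mean_ranks, `-`)) > CD
  diag(d) <- FALSE
  dimnames(d) <- list(names(mean_ranks), names(mean_ranks))
  d
}

#' P-values of each method against the best-ranked one
#'
#' Identifies the best (lowest mean rank) method and, for every other method,
#' computes the two-sided normal p-value of the standardized mean-rank
#' difference, \eqn{p_i = 2(1 - \Phi(|R_i - R_{best}|/SE))}. Hypotheses are
#' returned ordered from smallest p (weakest method) to largest, ready for
#' [holm()] / [hochberg()].
#'
#' @param mean_ranks numeric vector of k mean ranks, named if possible.
#' @param N number of samples.
#' @return A `data.frame` with columns `method`, `mean_rank`, `z`
#'   (standardized difference) and `p`, ordered by ascending `p`, with
#'   attributes `best` (method name or index) and `SE`.
#' @export
p_vs_best <- function(mean_ranks, N) {
  k <- length(mean_ranks)
  if (k < 2) stop("need k >= 2", call. = FALSE)
  if (is.null(names(mean_ranks)))
    names(mean_ranks) <- paste0("M", seq_len(k))
  SE <- standard_error(k, N)
  best <- which.min(mean_ranks)
  others <- setdiff(seq_len(k), best)
  z <- (mean_ranks[others] - mean_ranks[best]) / SE
  p <- 2 * (1 - stats::pnorm(abs(z)))
  out <- data.frame(method = names(mean_ranks)[others],
                    mean_rank = unname(mean_ranks[others]),
                    z = unname(z), p = unname(p))
  out <- out[order(out$p, -out$z), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best") <- names(mean_ranks)[best]
  attr(out, "SE") <- SE
  out
}

check_stepwise_input <- function(p, alpha, labels, k) {
  if (!is.numeric(p) || length(p) < 1L || any(!is.finite(p)) ||
      any(p < 0 | p > 1))
    stop("`p` must be p-values in [0, 1]", call. = FALSE)
  if (is.unsorted(p))
    stop("`p` must be sorted ascending (weakest method first)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (is.null(labels)) labels <- paste0("H", seq_along(p))
  if (length(labels) != length(p))
    stop("need one label per p-value", call. = FALSE)
  if (is.null(k)) k <- length(p) + 1L
  if (k != length(p) + 1L)
    stop("`k` must equal length(p) + 1 (comparisons against the best method)",
         call. = FALSE)
  list(labels = labels, k = k)
}

stepwise_result <- function(procedure, p, labels, alpha, k, rejected) {
  structure(list(procedure = procedure, p = p, labels = labels,
                 alpha = alpha, k = k,
                 thresholds = alpha / (k - seq_along(p)),
                 rejected = rejected),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("%s procedure, alpha = %g (k = %d methods)\n",
              tools::toTitleCase(x$procedure), x$alpha, x$k))
  print(data.frame(hypothesis = x$labels, p = x$p,
                   threshold = x$thresholds, rejected = x$rejected))
  invisible(x)
}

#' Holm step-down procedure against the best method
#'
#' With p-values sorted ascending over the k-1 comparisons against the best
#' method, finds the minimal index j with \eqn{P_j > \alpha/(k-j)} and rejects
#' hypotheses 1..j-1 (all, if no such j exists).
#'
#' @param p p-values sorted ascending.
#' @param alpha family-wise error level (default 0.05).
#' @param labels optional hypothesis labels (method names).
#' @param k total number of methods; defaults to `length(p) + 1`.
#' @return A `stepwise_result` with a logical `rejected` vector.
#' @export
holm <- function(p, alpha = 0.05, labels = NULL, k = NULL) {
  chk <- check_stepwise_input(p, alpha, labels, k)
  thresholds <- alpha / (chk$k - seq_along(p))
  stop_at <- which(p > thresholds)
  rejected <- if (length(stop_at) == 0L) rep(TRUE, length(p))
              else seq_along(p) < min(stop_at)
  stepwise_result("holm", p, chk$labels, alpha, chk$k, rejected)
}

#' Hochberg step-up procedure against the best method
#'
#' Finds the maximal index j with \eqn{P_j \le \alpha/(k-j)} and rejects
#' hypotheses 1..j (none, if no such j exists). Rejects a superset of
#' [holm()] on any input.
#'
#' @inheritParams holm
#' @return A `stepwise_result` with a logical `rejected` vector.
#' @export
hochberg <- function(p, alpha = 0.05, labels = NULL, k = NULL) {
  chk <- check_stepwise_input(p, alpha, labels, k)
  thresholds <- alpha / (chk$k - seq_along(p))
  ok <- which(p <= thresholds)
  rejected <- if (length(ok) == 0L) rep(FALSE, length(p))
              else seq_along(p) <= max(ok)
  stepwise_result("hochberg", p, chk$labels, alpha, chk$k, rejected)
}

#' Complete method-comparison protocol
#'
#' Friedman test, critical-difference post hoc (both critical values) and the
#' Holm and Hochberg step procedures against the best-ranked method, from a
#' score matrix or from externally supplied mean ranks.
#'
#' @param scores a [score_matrix], or a named numeric vector of mean ranks
#'   (then `N` is required).
#' @param N number of samples when `scores` is a mean-rank vector.
#' @param alpha significance level (default 0.05).
#' @return Object of class `method_comparison` with elements `friedman`
#'   (either a full `friedman_result` or the chi-square/F chain from mean
#'   ranks), `cd` (critical differences and pairwise decision matrices),
#'   `p_table`, `holm`, `hochberg`.
#' @export
compare_methods <- function(scores, N = NULL, alpha = 0.05) {
  if (is.numeric(scores) && !is.matrix(scores)) {
    mr <- scores
    if (is.null(N)) stop("`N` is required with mean-rank input", call. = FALSE)
    k <- length(mr)
    chi2 <- friedman_chi2(mr, N)
    FF <- friedman_F_safe(chi2, N, k)
    fr <- list(mean_ranks = mr, N = N, k = k, chi2 = chi2,
               df_chi2 = k - 1L,
               p_chi2 = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
               F = FF,
               df_F = c(k - 1L, (k - 1L) * (N - 1L)),
               p_F = if (is.finite(FF))
                 stats::pf(FF, k - 1L, (k - 1L) * (N - 1L),
                           lower.tail = FALSE) else 0)
  } else {
    fr <- friedman_test(scores)
    mr <- fr$mean_ranks
    N <- fr$N; k <- fr$k
  }
  cd_sc <- cd_critical_difference(k, N, critical_value_normal(k, alpha))
  cd_bd <- cd_critical_difference(k, N,
                                  critical_value_bonferroni_dunn(k, N, alpha))
  ptab <- p_vs_best(mr, N)
  structure(list(
    friedman = fr, alpha = alpha,
    cd = list(siegel_castellan = cd_sc, bonferroni_dunn = cd_bd,
              decisions_siegel_castellan = pairwise_decisions(mr, cd_sc),
              decisions_bonferroni_dunn = pairwise_decisions(mr, cd_bd)),
    p_table = ptab,
    holm = holm(ptab$p, alpha, labels = ptab$method, k = k),
    hochberg = hochberg(ptab$p, alpha, labels = ptab$method, k = k)),
    class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  fr <- x$friedman
  cat("== Friedman ==\n")
  cat("Mean ranks (1 = best):\n")
  print(round(sort(fr$mean_ranks), 2))
  cat(sprintf("chi^2_F = %.4g (p = %.4g), F_F = %.4g (p = %.4g)\n",
              fr$chi2, fr$p_chi2, fr$F, fr$p_F))
  cat("\n== Critical differences ==\n")
  cat(sprintf("Siegel-Castellan CD = %.4g, Bonferroni-Dunn CD = %.4g\n",
              x$cd$siegel_castellan, x$cd$bonferroni_dunn))
  cat(sprintf("\n== Comparisons vs best (%s) ==\n", attr(x$p_table, "best")))
  print(x$p_table)
  cat("\n")
  print(x$holm)
  cat("\n")
  print(x$hochberg)
  invisible(x)
}
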