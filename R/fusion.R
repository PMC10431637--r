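check_fields <- function(fields) {
  if (!is.list(fields) || length(fields) < 1L)
    stop("`fields` must be a non-empty list of vector fields", call. = FALSE)
  if (!all(vapply(fields, inherits, logical(1), "vector_field")))
    stop("every element of `fields` must be a vector_field", call. = FALSE)
  d <- dim(fields[[1L]])
  if (!all(vapply(fields, function(f) identical(dim(f), d), logical(1))))
    stop("all vector fields must share the same shape", call. = FALSE)
  invisible(fields)
}

#' Weighted-averaging fusion of vector fields
#'
#' Fuses n co-registered vector fields pixelwise into
#' \deqn{\bar P = \sum_i w_i P_i / \sum_i w_i, \quad
#'       \bar Q = \sum_i w_i Q_i / \sum_i w_i.}
#' Weights must be nonnegative with at least one strictly positive.
#'
#' @param fields list of [vector_field] objects of identical shape.
#' @param weights numeric vector, one nonnegative weight per field
#'   (default: equal weights).
#' @return The fused [vector_field].
#' @export
fuse_weighted <- function(fields, weights = rep(1, length(fields))) {
  check_fields(fields)
  n <- length(fields)
  if (!is.numeric(weights) || length(weights) != n || !all(is.finite(weights)))
    stop("`weights` must be a finite numeric vector of length ", n,
         call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative with at least one positive weight",
         call. = FALSE)
  w <- weights / sum(weights)
  P <- Reduce(`+`, Map(function(f, wi) wi * f$P, fields, w))
  Q <- Reduce(`+`, Map(function(f, wi) wi * f$Q, fields, w))
  vector_field(P, Q)
}

#' Pointwise-maximum fusion of vector fields
#'
#' In `signed` mode (the default, the literal rule) each fused component is
#' the pointwise maximum of the source components. In `magnitude` mode the
#' component with the largest absolute value is kept with its sign, ties going
#' to the lowest source index; this variant preserves strong negative
#' gradients that the signed maximum discards.
#'
#' @inheritParams fuse_weighted
#' @param mode `"signed"` (default) or `"magnitude"`.
#' @return The fused [vector_field].
#' @export
fuse_max <- function(fields, mode = c("signed", "magnitude")) {
  mode <- match.arg(mode)
  check_fields(fields)
  pick <- function(comp) {
    if (mode == "signed")
      return(Reduce(pmax, lapply(fields, `[[`, comp)))
    best <- fields[[1L]][[comp]]
    for (f in fields[-1L]) {
      cand <- f[[comp]]
      swap <- abs(cand) > abs(best)  # strict: ties keep the earlier source
      best[swap] <- cand[swap]
    }
    best
  }
  vector_field(pick("P"), pick("Q"))
}

#' PCA-weighted fusion of vector fields
#'
#' For each component (P and Q separately) the n component grids are flattened
#' into columns of a pixels-by-n matrix, its n-by-n covariance is estimated
#' (mean-centered, denominator pixels−1), and the eigenvector of the largest
#' eigenvalue is taken as the weight vector. Eigenvectors are sign- and
#' scale-ambiguous, so absolute values are taken and normalized to sum 1,
#' which makes the weights valid for the weighted-averaging rule. The two
#' components are then fused with their respective weight vectors.
#'
#' A degenerate covariance (all component grids essentially zero) falls back
#' to equal weights with a warning.
#'
#' @inheritParams fuse_weighted
#' @return A list with elements `field` (the fused [vector_field]),
#'   `weights_P` and `weights_Q` (the normalized weight vectors).
#' @export
fuse_pca <- function(fields) {
  check_fields(fields)
  n <- length(fields)
  if (n == 1L)
    return(list(field = fields[[1L]], weights_P = 1, weights_Q = 1))
  pca_weights <- function(comp) {
    X <- vapply(fields, function(f) as.vector(f[[comp]]),
                numeric(length(fields[[1L]]$P)))
    C <- stats::cov(X)
    if (!all(is.finite(C)) || max(abs(C)) < .Machine$double.eps * 100) {
      warning("degenerate covariance in PCA fusion (", comp,
              " component); falling back to equal weights", call. = FALSE)
      return(rep(1 / n, n))
    }
    v <- eigen(C, symmetric = TRUE)$vectors[, 1L]
    w <- abs(v)
    w / sum(w)
  }
  wP <- pca_weights("P")
  wQ <- pca_weights("Q")
  P <- Reduce(`+`, Map(function(f, wi) wi * f$P, fields, wP))
  Q <- Reduce(`+`, Map(function(f, wi) wi * f$Q, fields, wQ))
  list(field = vector_field(P, Q), weights_P = wP, weights_Q = wQ)
}
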