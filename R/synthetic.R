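# Deterministic, seedable generators for all test inputs. The phantom pair
# stands in for real co-registered CT/MR acquisitions: one image carries a
# bright bone-like ring plus sparse compact high-contrast shapes, the other a
# smooth soft-tissue-like texture plus shapes placed in the opposite half of
# the anatomy, so each source contributes structures absent from the other.
# The outer margin is exactly constant so zero-Dirichlet Poisson
# reconstruction is well posed up to a DC offset.

#' Generate a complementary CT-like / MR-like phantom pair
#'
#' Returns two co-registered images with complementary content on a constant
#' background, plus logical masks recording which compact structures belong
#' to which source (disjoint by construction: source A's shapes are placed in
#' angular sectors disjoint from source B's). Identical seeds give
#' bit-identical output.
#'
#' @param size square image side in pixels (default 64 for tests; the demo
#'   scale is 256).
#' @param kind `"ct_mr"` (default), `"blobs"` (two disjoint sets of smooth
#'   blobs) or `"ramps"` (smooth bilinear shading plus disjoint bumps).
#' @param seed integer RNG seed (default 20230816, the repository's pinned
#'   fixture seed).
#' @param margin width in pixels of the constant-background border band
#'   (default 8).
#' @return A list with `A`, `B` (matrices in \[0, 1\]), `mask_A`, `mask_B`
#'   (logical matrices) and the `spec` used.
#' @export
make_phantom_pair <- function(size = 64L, kind = c("ct_mr", "blobs", "ramps"),
                              seed = 20230816L, margin = 8L) {
  kind <- match.arg(kind)
  if (size < 4L * margin)
    stop("`size` must be at least 4 * margin", call. = FALSE)
  with_seed(seed, {
    ctr <- (size + 1) / 2
    row <- matrix(seq_len(size), size, size)
    col <- matrix(seq_len(size), size, size, byrow = TRUE)
    d <- sqrt((row - ctr)^2 + (col - ctr)^2)
    theta <- atan2(row - ctr, col - ctr)  # (-pi, pi]
    brain_R <- size / 2 - margin - 2
    inside <- d <= brain_R
    bg <- 0.02

    disc_set <- function(n_shapes, theta_lo, theta_hi) {
      mask <- matrix(FALSE, size, size)
      for (i in seq_len(n_shapes)) {
        ang <- stats::runif(1, theta_lo, theta_hi)
        rad <- stats::runif(1, 0.25, 0.65) * brain_R
        cy <- ctr + rad * sin(ang)
        cx <- ctr + rad * cos(ang)
        rr <- stats::runif(1, 0.08, 0.16) * brain_R
        mask <- mask | (sqrt((row - cy)^2 + (col - cx)^2) <= rr & inside)
      }
      mask
    }

    if (kind == "ct_mr") {
      # A: "CT" — bright skull ring + sparse compact dense shapes
      ring <- 0.85 * exp(-((d - (brain_R - 1)) / 1.4)^2)
      mask_A <- disc_set(3L, 0, pi)            # upper half sectors
      A <- bg + inside * (ring + 0.9 * mask_A)
      # B: "MR" — smooth tissue + low-frequency texture + disjoint shapes
      mask_B <- disc_set(3L, -pi, 0)           # lower half sectors
      tissue <- 0.55 * exp(-(d / (brain_R / 1.4))^2)
      texture <- 0.08 * sin(2 * pi * 3 * row / size) *
        cos(2 * pi * 2 * col / size)
      B <- bg + inside * (tissue + texture) + 0.35 * mask_B
    } else if (kind == "blobs") {
      gauss_set <- function(n, theta_lo, theta_hi) {
        g <- matrix(0, size, size); m <- matrix(FALSE, size, size)
        for (i in seq_len(n)) {
          ang <- stats::runif(1, theta_lo, theta_hi)
          rad <- stats::runif(1, 0.2, 0.6) * brain_R
          cy <- ctr + rad * sin(ang); cx <- ctr + rad * cos(ang)
          s <- stats::runif(1, 0.12, 0.2) * brain_R
          bump <- exp(-((row - cy)^2 + (col - cx)^2) / (2 * s^2))
          g <- g + stats::runif(1, 0.4, 0.7) * bump
          m <- m | bump > 0.3
        }
        list(g = g, m = m)
      }
      a <- gauss_set(3L, 0, pi); b <- gauss_set(3L, -pi, 0)
      A <- bg + inside * a$g; mask_A <- a$m & inside
      B <- bg + inside * b$g; mask_B <- b$m & inside
    } else { # ramps
      A <- bg + inside * (0.3 + 0.4 * col / size)
      B <- bg + inside * (0.3 + 0.4 * row / size)
      mask_A <- disc_set(2L, 0, pi)
      mask_B <- disc_set(2L, -pi, 0)
      A <- A + 0.3 * mask_A
      B <- B + 0.3 * mask_B
    }
    list(A = clip01(A), B = clip01(B),
         mask_A = mask_A, mask_B = mask_B,
         spec = list(size = size, kind = kind, seed = seed, margin = margin))
  })
}

#' Generate an exact gradient round-trip case
#'
#' Returns a smooth image with near-zero boundary together with its exact
#' Nabla transform, for reconstruct-and-compare tests. `gaussian_bump` is a
#' centered Gaussian (amplitude 0.8, sd size/8, negligible at the border);
#' `bilinear` is a product of linear ramps, whose second differences vanish
#' so the divergence of its field is identically zero on the interior.
#'
#' @param size square image side, >= 8.
#' @param kind `"gaussian_bump"` (default) or `"bilinear"`.
#' @return List with `image` and `field` (= `nabla_transform(image)`).
#' @export
make_gradient_case <- function(size = 64L,
                               kind = c("gaussian_bump", "bilinear")) {
  kind <- match.arg(kind)
  if (size < 8L) stop("`size` must be >= 8", call. = FALSE)
  ctr <- (size + 1) / 2
  row <- matrix(seq_len(size), size, size)
  col <- matrix(seq_len(size), size, size, byrow = TRUE)
  U <- switch(kind,
    gaussian_bump = 0.8 * exp(-((row - ctr)^2 + (col - ctr)^2) /
                                (2 * (size / 8)^2)),
    bilinear = 0.02 * (1 + 2 * col / size) * (1 + 1.5 * row / size))
  list(image = U, field = nabla_transform(U))
}

#' Generate a score matrix with a planted method ordering
#'
#' Each cell is `base_j + noise * rnorm(1)` where the base score realizes the
#' planted mean rank of method j under a higher-is-better orientation
#' (`base_j = k + 1 - planted_j`). With `noise = 0` and a strict planted
#' ordering, within-row ranks equal the planted ranks exactly.
#'
#' @param N number of samples (rows), >= 2.
#' @param k number of methods (columns), >= 2.
#' @param planted_mean_ranks numeric vector of k target mean ranks in
#'   \[1, k\], or `NULL` for all-equal (no planted differences).
#' @param noise standard deviation of the additive Gaussian noise
#'   (default 0.5; the rank-gap unit is 1).
#' @param seed integer RNG seed.
#' @param methods optional method names.
#' @return A [score_matrix].
#' @export
make_score_matrix <- function(N, k, planted_mean_ranks = NULL, noise = 0.5,
                              seed = 1L, methods = NULL) {
  if (N < 2L || k < 2L) stop("need N >= 2 and k >= 2", call. = FALSE)
  if (is.null(planted_mean_ranks)) planted_mean_ranks <- rep((k + 1) / 2, k)
  if (length(planted_mean_ranks) != k ||
      any(planted_mean_ranks < 1 | planted_mean_ranks > k))
    stop("`planted_mean_ranks` must be k values in [1, k]", call. = FALSE)
  if (noise < 0) stop("`noise` must be >= 0", call. = FALSE)
  with_seed(seed, {
    base <- k + 1 - planted_mean_ranks
    values <- matrix(rep(base, each = N), N, k) +
      noise * matrix(stats::rnorm(N * k), N, k)
    score_matrix(values, methods = methods, orientation = "higher_better")
  })
}
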