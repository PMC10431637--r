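# Objective fusion-quality metrics. Conventions pinned here once:
# intensities in [0,1]; histograms use `bins` equal-width bins over [0,1];
# edge operators are 3x3 Sobel kernels with replicate borders; SSIM uses a
# uniform (box) window, population moments, K1 = 0.01, K2 = 0.03, L = 1;
# Qabf uses the edge-transfer model with its customary sigmoid parameters.

hist_counts <- function(img, bins) {
  idx <- pmin(pmax(floor(clip01(img) * bins) + 1L, 1L), bins)
  tabulate(idx, nbins = bins)
}

#' Shannon entropy of an image histogram
#'
#' \eqn{-\sum p \log_2 p} over the nonempty bins of the intensity histogram
#' (`bins` equal-width bins over \[0, 1\]). Higher entropy indicates a richer
#' intensity distribution in the fused image.
#'
#' @param img numeric matrix with intensities in \[0, 1\].
#' @param bins number of histogram bins (default 256).
#' @return Entropy in bits, >= 0.
#' @export
img_entropy <- function(img, bins = 256L) {
  check_image(img)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  p <- hist_counts(img, bins) / length(img)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Standard deviation of image intensities
#'
#' Population standard deviation (denominator n) of all pixel values.
#'
#' @inheritParams img_entropy
#' @return Nonnegative real.
#' @export
img_std <- function(img) {
  check_image(img)
  sqrt(mean((img - mean(img))^2))
}

#' Average gradient of an image
#'
#' Mean over interior pixels of \eqn{\sqrt{(g_x^2 + g_y^2)/2}} with central
#' differences; a sharpness measure.
#'
#' @inheritParams img_entropy
#' @return Nonnegative real.
#' @export
average_gradient <- function(img) {
  check_image(img)
  H <- nrow(img); W <- ncol(img)
  r <- 2:(H - 1L); c <- 2:(W - 1L)
  gx <- (img[r, c + 1L] - img[r, c - 1L]) / 2
  gy <- (img[r + 1L, c] - img[r - 1L, c]) / 2
  mean(sqrt((gx^2 + gy^2) / 2))
}

#' Edge intensity of an image
#'
#' Mean Sobel gradient magnitude over all pixels (replicate borders).
#'
#' @inheritParams img_entropy
#' @return Nonnegative real.
#' @export
edge_intensity <- function(img) {
  check_image(img)
  g <- sobel_components(img)
  mean(sqrt(g$gx^2 + g$gy^2))
}

mi_pair <- function(x, y, bins) {
  ix <- pmin(pmax(floor(clip01(x) * bins) + 1L, 1L), bins)
  iy <- pmin(pmax(floor(clip01(y) * bins) + 1L, 1L), bins)
  joint <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins),
                  bins, bins) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- which(joint > 0, arr.ind = TRUE)
  p <- joint[nz]
  sum(p * log2(p / (px[nz[, 1L]] * py[nz[, 2L]])))
}

#' Mutual information between a fused image and its sources
#'
#' Sum over sources of \eqn{I(F; S_i)} computed from joint intensity
#' histograms (`bins` x `bins` over \[0, 1\]), in bits. Measures how much
#' source information the fused image retains.
#'
#' @param fused numeric matrix in \[0, 1\].
#' @param sources a single matrix or list of matrices conforming to `fused`.
#' @param bins histogram bins per axis (default 256).
#' @return Nonnegative real (bits).
#' @export
mutual_information <- function(fused, sources, bins = 256L) {
  check_image(fused, "fused")
  if (is.matrix(sources)) sources <- list(sources)
  for (s in sources) {
    check_image(s, "source")
    if (!identical(dim(s), dim(fused)))
      stop("sources must match the shape of `fused`", call. = FALSE)
  }
  sum(vapply(sources, function(s) mi_pair(fused, s, bins), numeric(1)))
}

# Mean local SSIM between two images over all fully-interior box windows.
ssim_pair <- function(x, y, window, k1, k2, L) {
  n <- window^2
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  mx <- box_sum(x, window) / n
  my <- box_sum(y, window) / n
  vx <- box_sum(x^2, window) / n - mx^2
  vy <- box_sum(y^2, window) / n - my^2
  cxy <- box_sum(x * y, window) / n - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Mean structural similarity to the source images
#'
#' Local SSIM maps between the fused image and each source (uniform square
#' window, population moments, standard constants, dynamic range 1), averaged
#' over the valid window positions and then over the sources.
#'
#' @inheritParams mutual_information
#' @param window odd window side (default 7).
#' @param k1,k2 SSIM stabilizing constants (defaults 0.01 and 0.03).
#' @return Real in \[-1, 1\]; 1 iff fused matches every source exactly.
#' @export
ssim_avg <- function(fused, sources, window = 7L, k1 = 0.01, k2 = 0.03) {
  check_image(fused, "fused")
  if (is.matrix(sources)) sources <- list(sources)
  if (window %% 2L != 1L || window < 3L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  vals <- vapply(sources, function(s) {
    if (!identical(dim(s), dim(fused)))
      stop("sources must match the shape of `fused`", call. = FALSE)
    ssim_pair(fused, s, window, k1, k2, L = 1)
  }, numeric(1))
  mean(vals)
}

# Sobel strength and orientation; alpha = atan(gy/gx) in [-pi/2, pi/2],
# defined as 0 where both components vanish.
edge_strength_orientation <- function(img) {
  g <- sobel_components(img)
  strength <- sqrt(g$gx^2 + g$gy^2)
  alpha <- atan(ifelse(g$gx == 0,
                       ifelse(g$gy == 0, 0, sign(g$gy) * Inf),
                       g$gy / g$gx))
  list(g = strength, a = alpha)
}

qabf_preservation <- function(src, fus,
                              Gg = 0.9994, kg = -15, sg = 0.5,
                              Ga = 0.9879, ka = -22, sa = 0.8) {
  # relative strength: ratio of the smaller to the larger gradient magnitude
  G <- ifelse(src$g > fus$g, fus$g / src$g,
              ifelse(fus$g > 0, src$g / fus$g, 0))
  # orientation difference folded mod pi (edge direction is axial), so the
  # agreement score lies in [0, 1] and is transpose-invariant
  d <- abs(src$a - fus$a)
  d <- pmin(d, pi - d)
  A <- 1 - d / (pi / 2)
  Qg <- Gg / (1 + exp(kg * (G - sg)))
  Qa <- Ga / (1 + exp(ka * (A - sa)))
  Qg * Qa
}

#' Edge-information transfer measure Qabf
#'
#' The gradient-based fusion performance measure: Sobel edge strength and
#' orientation are extracted from both sources and the fused image; per-pixel
#' edge-preservation scores between each source and the fused image (sigmoid
#' maps of relative strength and orientation agreement) are averaged with the
#' source edge strengths as weights. Values lie in \[0, 1\]; 1 means all
#' source edge information reached the fused image.
#'
#' @param fused,sourceA,sourceB conforming numeric matrices in \[0, 1\].
#' @return Real in \[0, 1\]. If both sources are edge-free the measure is
#'   defined as 0, with a warning.
#' @export
qabf <- function(fused, sourceA, sourceB) {
  check_image(fused, "fused")
  check_image(sourceA, "sourceA"); check_image(sourceB, "sourceB")
  if (!identical(dim(fused), dim(sourceA)) ||
      !identical(dim(fused), dim(sourceB)))
    stop("`fused`, `sourceA`, `sourceB` must have identical shape",
         call. = FALSE)
  eA <- edge_strength_orientation(sourceA)
  eB <- edge_strength_orientation(sourceB)
  eF <- edge_strength_orientation(fused)
  wA <- eA$g; wB <- eB$g
  denom <- sum(wA + wB)
  if (denom == 0) {
    warning("both sources are edge-free; Qabf defined as 0", call. = FALSE)
    return(0)
  }
  QAF <- qabf_preservation(eA, eF)
  QBF <- qabf_preservation(eB, eF)
  sum(QAF * wA + QBF * wB) / denom
}

#' Full metric report for a fused image
#'
#' Computes the objective quality metrics for a fused image against its
#' sources and returns a tidy table with each metric's orientation
#' (all are higher-is-better).
#'
#' @inheritParams mutual_information
#' @param metrics character vector choosing a subset of
#'   `c("entropy", "std", "average_gradient", "edge_intensity",
#'      "mutual_information", "ssim", "qabf")`.
#' @return A `data.frame` with columns `metric`, `value`, `orientation`.
#' @export
evaluate_fusion <- function(fused, sources,
                            metrics = c("entropy", "std", "average_gradient",
                                        "edge_intensity", "mutual_information",
                                        "ssim", "qabf")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.matrix(sources)) sources <- list(sources)
  vals <- vapply(metrics, function(m) {
    switch(m,
      entropy = img_entropy(fused),
      std = img_std(fused),
      average_gradient = average_gradient(fused),
      edge_intensity = edge_intensity(fused),
      mutual_information = mutual_information(fused, sources),
      ssim = ssim_avg(fused, sources),
      qabf = {
        if (length(sources) != 2L)
          stop("qabf requires exactly two sources", call. = FALSE)
        qabf(fused, sources[[1L]], sources[[2L]])
      })
  }, numeric(1))
  data.frame(metric = metrics, value = unname(vals),
             orientation = "higher_better", row.names = NULL)
}
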