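#' @keywords internal
"_PACKAGE"

# Coordinate convention, fixed package-wide: images are numeric matrices with
# rows = y (height H) and columns = x (width W). The derivative "along x" acts
# across columns, the one "along y" across rows. 0 <= intensity <= 1 is assumed
# for metrics but not enforced for intermediate fields.

check_image <- function(U, arg = "img", min_dim = 3L) {
  if (!is.matrix(U) || !is.numeric(U))
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  if (nrow(U) < min_dim || ncol(U) < min_dim)
    stop(sprintf("`%s` must be at least %dx%d (got %dx%d)",
                 arg, min_dim, min_dim, nrow(U), ncol(U)), call. = FALSE)
  if (!all(is.finite(U)))
    stop(sprintf("`%s` contains non-finite values", arg), call. = FALSE)
  invisible(U)
}

# Shifted copy of a matrix: result[r, c] = U[r + dr, c + dc], with out-of-grid
# reads resolved by the padding rule. `replicate` clamps to the nearest edge,
# `reflect` mirrors about the edge pixel, `zero` reads 0.
shift_mat <- function(U, dr, dc, boundary = "replicate") {
  H <- nrow(U); W <- ncol(U)
  ri <- seq_len(H) + dr
  ci <- seq_len(W) + dc
  if (boundary == "zero") {
    out <- matrix(0, H, W)
    rok <- ri >= 1L & ri <= H
    cok <- ci >= 1L & ci <= W
    out[rok, cok] <- U[ri[rok], ci[cok]]
    return(out)
  }
  map_idx <- function(i, n) {
    if (boundary == "replicate") return(pmin(pmax(i, 1L), n))
    # reflect about the border pixel: 0 -> 2, n+1 -> n-1
    i[i < 1L] <- 2L - i[i < 1L]
    i[i > n] <- 2L * n - i[i > n]
    pmin(pmax(i, 1L), n)
  }
  U[map_idx(ri, H), map_idx(ci, W), drop = FALSE]
}

# Sobel derivative components with replicate borders; x = columns, y = rows.
sobel_components <- function(U) {
  s <- function(dr, dc) shift_mat(U, dr, dc, "replicate")
  gx <- (s(-1, 1) + 2 * s(0, 1) + s(1, 1)) -
        (s(-1, -1) + 2 * s(0, -1) + s(1, -1))
  gy <- (s(1, -1) + 2 * s(1, 0) + s(1, 1)) -
        (s(-1, -1) + 2 * s(-1, 0) + s(-1, 1))
  list(gx = gx, gy = gy)
}

# Sums over all w x w windows fully inside U ("valid" region), via a
# summed-area table. Returns an (H-w+1) x (W-w+1) matrix.
box_sum <- function(U, w) {
  H <- nrow(U); W <- ncol(U)
  if (w > H || w > W) stop("window larger than image", call. = FALSE)
  S <- rbind(0, apply(U, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  r2 <- (w + 1L):(H + 1L); r1 <- r2 - w
  c2 <- (w + 1L):(W + 1L); c1 <- c2 - w
  S[r2, c2] - S[r1, c2] - S[r2, c1] + S[r1, c1]
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
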