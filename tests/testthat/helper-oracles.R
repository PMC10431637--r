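# Independent, deliberately slow loop-based oracles. These never call the
# implementation paths they check.

# clamped index for replicate padding
.clampi <- function(i, n) min(max(i, 1L), n)

# central-difference gradient with replicate borders, pixel by pixel
oracle_gradient <- function(U) {
  H <- nrow(U); W <- ncol(U)
  P <- Q <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    P[r, c] <- (U[r, .clampi(c + 1L, W)] - U[r, .clampi(c - 1L, W)]) / 2
    Q[r, c] <- (U[.clampi(r + 1L, H), c] - U[.clampi(r - 1L, H), c]) / 2
  }
  list(P = P, Q = Q)
}

# one synchronous Jacobi sweep, loop form; band of width `s` pinned at 0
oracle_jacobi_step <- function(U, b, s = 2L) {
  H <- nrow(U); W <- ncol(U)
  U1 <- matrix(0, H, W)
  for (r in (s + 1L):(H - s)) for (c in (s + 1L):(W - s)) {
    U1[r, c] <- (U[r - s, c] + U[r + s, c] + U[r, c - s] + U[r, c + s] +
                   b[r, c]) / 4
  }
  U1
}

# dense assembly of the stride-s system 4U - sum(neighbors) = b over interior
# unknowns (border band of width s fixed at 0), solved directly
oracle_direct_solve <- function(b, s = 2L) {
  H <- nrow(b); W <- ncol(b)
  rs <- (s + 1L):(H - s); cs <- (s + 1L):(W - s)
  cells <- expand.grid(r = rs, c = cs)
  idx <- matrix(0L, H, W)
  idx[as.matrix(cells)] <- seq_len(nrow(cells))
  n <- nrow(cells)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (i in seq_len(n)) {
    r <- cells$r[i]; c <- cells$c[i]
    A[i, i] <- 4
    for (d in list(c(-s, 0L), c(s, 0L), c(0L, -s), c(0L, s))) {
      j <- idx[r + d[1L], c + d[2L]]
      if (j > 0L) A[i, j] <- A[i, j] - 1
    }
    rhs[i] <- b[r, c]
  }
  x <- solve(A, rhs)
  U <- matrix(0, H, W)
  U[as.matrix(cells)] <- x
  U
}

# Sobel strength/orientation + edge-transfer measure, loop form
oracle_qabf <- function(F, A, B) {
  sob <- function(U) {
    H <- nrow(U); W <- ncol(U)
    gx <- gy <- matrix(0, H, W)
    at <- function(r, c) U[.clampi(r, H), .clampi(c, W)]
    for (r in seq_len(H)) for (c in seq_len(W)) {
      gx[r, c] <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
                  (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
      gy[r, c] <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
                  (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
    }
    g <- sqrt(gx^2 + gy^2)
    a <- matrix(0, H, W)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      a[r, c] <- if (gx[r, c] == 0) {
        if (gy[r, c] == 0) 0 else sign(gy[r, c]) * pi / 2
      } else atan(gy[r, c] / gx[r, c])
    }
    list(g = g, a = a)
  }
  pres <- function(s, f) {
    H <- nrow(s$g); W <- ncol(s$g)
    Q <- matrix(0, H, W)
    for (r in seq_len(H)) for (c in seq_len(W)) {
      gs <- s$g[r, c]; gf <- f$g[r, c]
      G <- if (gs > gf) gf / gs else if (gf > 0) gs / gf else 0
      dlt <- abs(s$a[r, c] - f$a[r, c])
      dlt <- min(dlt, pi - dlt)
      Aor <- 1 - dlt / (pi / 2)
      Qg <- 0.9994 / (1 + exp(-15 * (G - 0.5)))
      Qa <- 0.9879 / (1 + exp(-22 * (Aor - 0.8)))
      Q[r, c] <- Qg * Qa
    }
    Q
  }
  eA <- sob(A); eB <- sob(B); eF <- sob(F)
  num <- 0; den <- 0
  QAF <- pres(eA, eF); QBF <- pres(eB, eF)
  for (r in seq_len(nrow(F))) for (c in seq_len(ncol(F))) {
    num <- num + QAF[r, c] * eA$g[r, c] + QBF[r, c] * eB$g[r, c]
    den <- den + eA$g[r, c] + eB$g[r, c]
  }
  num / den
}

rmse <- function(x, y) sqrt(mean((x - y)^2))

random_image <- function(H, W = H) matrix(stats::runif(H * W), H, W)
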