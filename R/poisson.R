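# The discrete system solved here is, per pixel,
#   4 U(i,j) - U(i-2,j) - U(i+2,j) - U(i,j-2) - U(i,j+2) = b(i,j)
# (stride-2 stencil, from composing two central differences), or the usual
# 5-point form with +/-1 neighbors. Pixels closer than the stencil stride to
# the border lack neighbors and are held at the Dirichlet value (0) during
# iteration: a fixed band of width 2 (stride-2) or 1 (5-point).

stencil_stride <- function(stencil) if (stencil == "paper_stride2") 2L else 1L

neighbor_sum <- function(U, s) {
  shift_mat(U, -s, 0, "zero") + shift_mat(U, s, 0, "zero") +
    shift_mat(U, 0, -s, "zero") + shift_mat(U, 0, s, "zero")
}

interior_mask <- function(H, W, s) {
  list(r = (s + 1L):(H - s), c = (s + 1L):(W - s))
}

#' Divergence of a vector field (Poisson right-hand side)
#'
#' Applies the same central-difference operator used by [nabla_transform()]
#' to the components of a fused field:
#' \deqn{f(x,y) = (\bar P(x+1,y) - \bar P(x-1,y))/2 +
#'               (\bar Q(x,y+1) - \bar Q(x,y-1))/2.}
#' When the field is exactly the Nabla transform of an image U, `f` equals the
#' stride-2 discrete Laplacian of U, \eqn{(U(i-2)-2U(i)+U(i+2))/4} summed over
#' both axes, at every pixel whose 1-neighborhood is in-grid.
#'
#' @param field a [vector_field].
#' @param boundary padding rule for the border differences (default
#'   `"replicate"`).
#' @return Numeric matrix `f` of the field's shape.
#' @export
divergence_rhs <- function(field, boundary = "replicate") {
  if (!inherits(field, "vector_field"))
    stop("`field` must be a vector_field", call. = FALSE)
  (shift_mat(field$P, 0, 1, boundary) - shift_mat(field$P, 0, -1, boundary)) / 2 +
    (shift_mat(field$Q, 1, 0, boundary) - shift_mat(field$Q, -1, 0, boundary)) / 2
}

#' Assemble the Poisson right-hand side b from f
#'
#' The stride-2 stencil arises from \eqn{\nabla^2 U = f} scaled by 4, so
#' `b = 4 f`; the standard 5-point stencil uses `b = f` unscaled.
#'
#' @param f numeric matrix (divergence of the fused field).
#' @param stencil `"paper_stride2"` (default) or `"standard_5point"`.
#' @return Numeric matrix `b` of the same shape.
#' @export
assemble_b <- function(f, stencil = c("paper_stride2", "standard_5point")) {
  stencil <- match.arg(stencil)
  if (!is.matrix(f) || !all(is.finite(f)))
    stop("`f` must be a finite numeric matrix", call. = FALSE)
  if (stencil == "paper_stride2") 4 * f else f
}

#' Poisson solver state
#'
#' Bundles the right-hand side `b`, the current iterate `U`, the Dirichlet
#' boundary value and the iteration counter for use with [jacobi_step()].
#'
#' @param b numeric matrix, right-hand side.
#' @param U0 starting iterate (default: all zeros).
#' @param boundary_value Dirichlet value held fixed on the border band
#'   (default 0).
#' @param stencil `"paper_stride2"` (default) or `"standard_5point"`.
#' @return An object of class `poisson_system`.
#' @export
poisson_system <- function(b, U0 = NULL,
                           boundary_value = 0,
                           stencil = c("paper_stride2", "standard_5point")) {
  stencil <- match.arg(stencil)
  if (!is.matrix(b) || !all(is.finite(b)))
    stop("`b` must be a finite numeric matrix", call. = FALSE)
  s <- stencil_stride(stencil)
  if (nrow(b) < 2L * s + 1L || ncol(b) < 2L * s + 1L)
    stop("grid too small for the ", stencil, " stencil", call. = FALSE)
  if (is.null(U0)) U0 <- matrix(boundary_value, nrow(b), ncol(b))
  if (!identical(dim(U0), dim(b)))
    stop("U0 must match the shape of b", call. = FALSE)
  structure(list(b = b, U = U0, boundary_value = boundary_value,
                 stencil = stencil, m = 0L),
            class = "poisson_system")
}

#' One synchronous Jacobi sweep
#'
#' Replaces every interior pixel by
#' \eqn{U^{(m+1)} = (U_{i-s,j} + U_{i+s,j} + U_{i,j-s} + U_{i,j+s} + b)/4}
#' using the previous iterate only (true Jacobi, not Gauss-Seidel), where the
#' stride s is 2 for the default stencil and 1 for the 5-point one. The border
#' band of width s stays at the Dirichlet value.
#'
#' @param sys a [poisson_system].
#' @return The updated `poisson_system` with `m` incremented.
#' @export
jacobi_step <- function(sys) {
  if (!inherits(sys, "poisson_system"))
    stop("`sys` must be a poisson_system", call. = FALSE)
  s <- stencil_stride(sys$stencil)
  H <- nrow(sys$b); W <- ncol(sys$b)
  upd <- (neighbor_sum(sys$U, s) + sys$b) / 4
  U1 <- matrix(sys$boundary_value, H, W)
  idx <- interior_mask(H, W, s)
  U1[idx$r, idx$c] <- upd[idx$r, idx$c]
  sys$U <- U1
  sys$m <- sys$m + 1L
  sys
}

# Relative residual: max-norm of (4U - neighbor sum - b) over the interior,
# divided by the max-norm of b (or 1 when b is identically zero).
jacobi_residual <- function(sys) {
  s <- stencil_stride(sys$stencil)
  idx <- interior_mask(nrow(sys$b), ncol(sys$b), s)
  res <- 4 * sys$U - neighbor_sum(sys$U, s) - sys$b
  denom <- max(abs(sys$b))
  if (denom == 0) denom <- 1
  max(abs(res[idx$r, idx$c])) / denom
}

#' Jacobi contraction factor
#'
#' Asymptotic error-decrease factor of Jacobi iteration on an n-by-n grid:
#' \eqn{cf(n) = \cos(\pi/(n+1))}, which is 0 at n = 1 and increases toward 1.
#'
#' @param n grid side, integer >= 1.
#' @return `cos(pi/(n+1))`.
#' @export
convergence_factor <- function(n) {
  if (!is.numeric(n) || any(n < 1) || any(n != floor(n)))
    stop("`n` must be an integer >= 1", call. = FALSE)
  cos(pi / (n + 1))
}

#' A-priori Jacobi iteration bound
#'
#' Least integer strictly greater than \eqn{2(1-\alpha)((n+1)/\pi)^2}: the
#' number of sweeps after which the error-decrease rate reaches the target
#' \eqn{\alpha \in (0,1)} under the contraction-factor bound, in the
#' large-grid linearization.
#'
#' @param n grid side, integer >= 1.
#' @param alpha target error-decrease rate in (0, 1).
#' @return Integer iteration count.
#' @export
iteration_bound <- function(n, alpha) {
  if (!is.numeric(n) || any(n < 1) || any(n != floor(n)))
    stop("`n` must be an integer >= 1", call. = FALSE)
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1))
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  as.integer(floor(2 * (1 - alpha) * ((n + 1) / pi)^2) + 1)
}

#' Solve the discrete Poisson system by Jacobi iteration
#'
#' Iterates [jacobi_step()] from `U0` (default: all zeros, matching the zero
#' Dirichlet data) until the relative residual falls below `tol` or `max_iter`
#' sweeps have run. The default `max_iter` is [iteration_bound()] at
#' alpha = 0.01 for the larger grid side; tight tolerances on large grids may
#' need more.
#'
#' @param b numeric matrix, right-hand side of the 4U − neighbors = b system.
#' @param tol relative-residual stopping tolerance (default 1e-6).
#' @param max_iter sweep cap (default `iteration_bound(max(dim(b)), 0.01)`).
#' @param U0 starting iterate (default zeros).
#' @inheritParams poisson_system
#' @return A list: `U` (solution matrix) and `info`, itself a list with
#'   `converged`, `iterations`, `residuals` (history including the initial
#'   residual), `tol`, `cf` (contraction factor of the grid) and `m_bound`.
#'   Non-convergence raises a warning of class
#'   `nablafuse_nonconvergence`, not an error.
#' @export
jacobi_solve <- function(b, tol = 1e-6, max_iter = NULL, U0 = NULL,
                         stencil = c("paper_stride2", "standard_5point"),
                         boundary_value = 0) {
  stencil <- match.arg(stencil)
  if (!is.numeric(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  n <- max(dim(b))
  m_bound <- iteration_bound(n, 0.01)
  if (is.null(max_iter)) max_iter <- m_bound
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  sys <- poisson_system(b, U0 = U0, boundary_value = boundary_value,
                        stencil = stencil)
  residuals <- jacobi_residual(sys)
  while (residuals[length(residuals)] > tol && sys$m < max_iter) {
    sys <- jacobi_step(sys)
    residuals <- c(residuals, jacobi_residual(sys))
  }
  converged <- residuals[length(residuals)] <= tol
  if (!converged)
    warning(structure(
      class = c("nablafuse_nonconvergence", "warning", "condition"),
      list(message = sprintf(
        "Jacobi iteration stopped at max_iter = %d with relative residual %.3g > tol = %.3g",
        max_iter, residuals[length(residuals)], tol),
        call = NULL)))
  list(U = sys$U,
       info = list(converged = converged, iterations = sys$m,
                   residuals = residuals, tol = tol,
                   cf = convergence_factor(n), m_bound = m_bound))
}

#' Reconstruct a scalar image from a (fused) vector field
#'
#' Runs the inverse-transform pipeline: divergence of the field, right-hand
#' side assembly, Jacobi solve under zero Dirichlet boundaries, then DC
#' restoration. Differentiation destroys the overall intensity offset, so a
#' convention is needed to place the result: `match_mean` (default) shifts the
#' solution so its mean equals `dc_reference`; `minmax` affinely maps it onto
#' \[0, 1\]. The output is clipped to \[0, 1\].
#'
#' Note on signs: the second-difference identity gives
#' \eqn{\Sigma_{nbr} U - 4U = b} for `b = 4f`, while the Jacobi update solves
#' \eqn{4U - \Sigma_{nbr} U = b}; the solver is therefore fed `-b`, which is
#' what makes reconstruction invert [nabla_transform()].
#'
#' @param field a [vector_field] to invert.
#' @inheritParams jacobi_solve
#' @param dc_mode `"match_mean"` (default) or `"minmax"`.
#' @param dc_reference target mean intensity for `match_mean` (default 0.5;
#'   pipeline wrappers pass the weighted mean of the source images).
#' @return Numeric matrix in \[0, 1\] with attribute `"solver"` carrying the
#'   `info` list of [jacobi_solve()].
#' @export
reconstruct <- function(field,
                        stencil = c("paper_stride2", "standard_5point"),
                        dc_mode = c("match_mean", "minmax"),
                        dc_reference = 0.5,
                        tol = 1e-6, max_iter = NULL) {
  stencil <- match.arg(stencil)
  dc_mode <- match.arg(dc_mode)
  f <- divergence_rhs(field)
  b <- assemble_b(f, stencil)
  sol <- jacobi_solve(-b, tol = tol, max_iter = max_iter, stencil = stencil)
  U <- sol$U
  U <- switch(dc_mode,
    match_mean = U + (dc_reference - mean(U)),
    minmax = {
      rng <- range(U)
      if (diff(rng) == 0) matrix(dc_reference, nrow(U), ncol(U))
      else (U - rng[1L]) / diff(rng)
    })
  structure(clip01(U), solver = sol$info)
}
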