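#' Construct a vector field
#'
#' A vector field is the pair of component grids \eqn{(P, Q)} produced by
#' differentiating a scalar image: `P` holds the derivative along x (columns),
#' `Q` the derivative along y (rows). Both components must be finite matrices
#' of identical shape.
#'
#' @param P numeric matrix, derivative along x.
#' @param Q numeric matrix, derivative along y, same shape as `P`.
#' @return An object of class `vector_field`: a list with elements `P` and `Q`.
#' @examples
#' vf <- vector_field(matrix(0, 4, 4), matrix(0, 4, 4))
#' @export
vector_field <- function(P, Q) {
  if (!is.matrix(P) || !is.matrix(Q) || !is.numeric(P) || !is.numeric(Q))
    stop("P and Q must be numeric matrices", call. = FALSE)
  if (!identical(dim(P), dim(Q)))
    stop("P and Q must have identical shape", call. = FALSE)
  if (!all(is.finite(P)) || !all(is.finite(Q)))
    stop("vector field components must be finite", call. = FALSE)
  structure(list(P = P, Q = Q), class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field %dx%d>  |P| in [%.4g, %.4g], |Q| in [%.4g, %.4g]\n",
              nrow(x$P), ncol(x$P),
              min(abs(x$P)), max(abs(x$P)), min(abs(x$Q)), max(abs(x$Q))))
  invisible(x)
}

#' @export
dim.vector_field <- function(x) dim(x$P)

#' Discrete Nabla transform of a scalar image
#'
#' Maps an image \eqn{U(x, y)} to the vector field \eqn{(P, Q)} of its finite
#' differences. With the default central scheme and unit grid step,
#' \deqn{P(x,y) = (U(x+1,y) - U(x-1,y))/2, \quad
#'       Q(x,y) = (U(x,y+1) - U(x,y-1))/2,}
#' where x indexes columns and y indexes rows. Forward/backward schemes use
#' one-sided differences with unit step. Pixels whose stencil reaches outside
#' the grid use the chosen padding rule; `replicate` (the default) repeats the
#' border value, which keeps border gradients near zero for smooth images.
#'
#' The transform is linear: \eqn{\nabla(aA + bB) = a\nabla A + b\nabla B}, and
#' annihilates constants.
#'
#' @param img numeric matrix, at least 3x3, all values finite.
#' @param scheme finite-difference scheme: `"central"` (default), `"forward"`
#'   or `"backward"`.
#' @param boundary padding rule for border pixels: `"replicate"` (default),
#'   `"reflect"` or `"zero"`.
#' @return A [vector_field] with the same shape as `img`.
#' @examples
#' U <- matrix(rep(1:8, each = 8) / 8, 8, 8)  # ramp along x
#' vf <- nabla_transform(U)
#' vf$P[4, 4] * 8  # interior slope = 1 in pixel units
#' @seealso [reconstruct()] for the inverse operation.
#' @export
nabla_transform <- function(img,
                            scheme = c("central", "forward", "backward"),
                            boundary = c("replicate", "reflect", "zero")) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  check_image(img)
  s <- function(dr, dc) shift_mat(img, dr, dc, boundary)
  switch(scheme,
    central = vector_field(P = (s(0, 1) - s(0, -1)) / 2,
                           Q = (s(1, 0) - s(-1, 0)) / 2),
    forward = vector_field(P = s(0, 1) - img, Q = s(1, 0) - img),
    backward = vector_field(P = img - s(0, -1), Q = img - s(-1, 0))
  )
}

#' Check linearity of the Nabla transform
#'
#' Computes the maximum absolute deviation of \eqn{\nabla(aA + bB)} from
#' \eqn{a\nabla A + b\nabla B} over both components. Exact linearity of finite
#' differences means the result is zero up to floating round-off.
#'
#' @param a,b real coefficients.
#' @param imgA,imgB conforming numeric matrices.
#' @inheritParams nabla_transform
#' @return A nonnegative scalar.
#' @export
check_linearity <- function(a, imgA, b, imgB,
                            scheme = "central", boundary = "replicate") {
  check_image(imgA, "imgA"); check_image(imgB, "imgB")
  if (!identical(dim(imgA), dim(imgB)))
    stop("imgA and imgB must have the same shape", call. = FALSE)
  lhs <- nabla_transform(a * imgA + b * imgB, scheme, boundary)
  fa <- nabla_transform(imgA, scheme, boundary)
  fb <- nabla_transform(imgB, scheme, boundary)
  max(abs(lhs$P - (a * fa$P + b * fb$P)),
      abs(lhs$Q - (a * fa$Q + b * fb$Q)))
}
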