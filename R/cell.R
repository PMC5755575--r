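#' Construct a unit cell
#'
#' Builds a \linkS4class{UnitCell} with its derived metric tensors,
#' orthogonalization matrix and volume. The orthogonalization convention puts
#' \eqn{a} along Cartesian x and \eqn{b} in the xy plane.
#'
#' @param a,b,c cell lengths in Angstrom
#' @param alpha,beta,gamma cell angles in degrees
#' @return a \code{UnitCell}
#' @examples
#' unitCell(4.265, 12.796, 7.490, 90, 100.77, 90)
#' @export
unitCell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (!is.finite(v2) || v2 <= 0 || a <= 0 || b <= 0 || c <= 0)
    stop("degenerate cell: volume is not positive")
  v <- sqrt(v2)
  M <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0,      c * v / sg),
              nrow = 3, byrow = TRUE)
  Minv <- solve(M)
  G <- t(M) %*% M
  Gstar <- solve(G)
  new("UnitCell", a = a, b = b, c = c, alpha = alpha, beta = beta,
      gamma = gamma, M = M, Minv = Minv, G = G, Gstar = Gstar,
      astar = sqrt(diag(Gstar)), volume = a * b * c * v)
}

#' Fractional/Cartesian transform pair
#'
#' Returns the pair of linear maps between fractional and Cartesian
#' coordinates for a cell. Both act on n x 3 matrices (or length-3 vectors).
#'
#' @param cell a \code{UnitCell}
#' @return list with functions \code{toCartesian} and \code{toFractional}
#' @export
orthogonalize <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  M <- cell@M; Minv <- cell@Minv
  asMat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 3)
  list(
    toCartesian  = function(x) asMat(x) %*% t(M),
    toFractional = function(x) asMat(x) %*% t(Minv)
  )
}

fracToCart <- function(cell, x) {
  (if (is.matrix(x)) x else matrix(x, ncol = 3)) %*% t(cell@M)
}

cartToFrac <- function(cell, x) {
  (if (is.matrix(x)) x else matrix(x, ncol = 3)) %*% t(cell@Minv)
}

#' Reciprocal-lattice vectors in Cartesian coordinates
#'
#' Maps integer Miller indices to Cartesian reciprocal vectors
#' (\eqn{\AA^{-1}}, no \eqn{2\pi}), so that \code{sqrt(rowSums(x^2))} is
#' \eqn{1/d}.
#'
#' @param cell a \code{UnitCell}
#' @param hkl n x 3 matrix of Miller indices
#' @return n x 3 matrix of Cartesian reciprocal vectors
#' @export
reciprocalVectors <- function(cell, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  hkl %*% cell@Minv
}

#' Resolution of reflections
#'
#' @param cell a \code{UnitCell}
#' @param hkl n x 3 Miller index matrix
#' @return \eqn{\sin\theta/\lambda = 1/(2d)} per reflection (\eqn{\AA^{-1}})
#' @export
sinThetaOverLambda <- function(cell, hkl) {
  hs <- reciprocalVectors(cell, hkl)
  sqrt(rowSums(hs^2)) / 2
}
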