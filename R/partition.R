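#' Stockholder (Hirshfeld) weights
#'
#' Weight of each fragment atom at each point,
#' \eqn{w_A(r) = \rho^0_A(|r - R_A|) / \sum_B \rho^0_B(|r - R_B|)}, built
#' from spherical reference-atom densities. Rows sum to one exactly by
#' construction; the promolecule is strictly positive at finite distances.
#'
#' @param points n x 3 Cartesian coordinates (Angstrom)
#' @param fragment a \code{MoleculeFragment}
#' @param provider optional \code{DensityProvider} supplying the references
#' @return n x nAtoms matrix of weights in [0, 1]
#' @export
hirshfeldWeights <- function(points, fragment, provider = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  a <- fragment@atoms
  W <- matrix(0, nrow(points), nrow(a))
  for (i in seq_len(nrow(a))) {
    r <- sqrt((points[, 1] - a$x[i])^2 + (points[, 2] - a$y[i])^2 +
                (points[, 3] - a$z[i])^2)
    rho0 <- if (is.null(provider)) {
      evalRadialDensity(freeAtomDensity(a$element[i]), r)
    } else provider@reference(i, r)
    W[, i] <- a$occ[i] * rho0
  }
  tot <- rowSums(W)
  tot[tot <= 0] <- .Machine$double.xmin
  W / tot
}

#' Hirshfeld atomic charges and dipoles
#'
#' Stockholder-partitioned monopoles and atom-centred dipoles of a molecular
#' density: \eqn{q_A = Z_A - \int w_A \rho \, dV} and
#' \eqn{\mu_A = -\int w_A \rho (r - R_A) \, dV} (electron-only moments; the
#' nuclear contribution vanishes at the expansion centre). These feed the
#' point-charge/dipole crystal-field model.
#'
#' @param fragment a \code{MoleculeFragment}
#' @param provider a \code{DensityProvider} for the molecular density
#' @param grid a \code{QuadratureGrid} over the fragment
#' @param Z optional nuclear charges per fragment atom (defaults to the
#'   element's atomic number)
#' @return data.frame: atom, element, q (e), mux, muy, muz (e Angstrom)
#' @export
atomicMultipoles <- function(fragment, provider, grid, Z = NULL) {
  a <- fragment@atoms
  if (is.null(Z)) Z <- ATOMIC_NUMBERS[a$element]
  rho <- provider@density(grid@points)
  Ne <- sum(a$occ * Z) - fragment@netCharge
  tot <- sum(grid@w * rho)
  if (abs(tot - Ne) > 0.01 * max(1, Ne))
    stop(sprintf(paste0("grid integral of the density (%.4f e) deviates from ",
                        "the expected electron count (%.4f e); refine the grid"),
                 tot, Ne))
  W <- hirshfeldWeights(grid@points, fragment, provider)
  out <- data.frame(atom = seq_len(nrow(a)), element = a$element,
                    q = numeric(nrow(a)), mux = numeric(nrow(a)),
                    muy = numeric(nrow(a)), muz = numeric(nrow(a)))
  for (i in seq_len(nrow(a))) {
    vi <- grid@w * W[, i] * rho
    pop <- sum(vi)
    out$q[i] <- a$occ[i] * Z[i] - pop
    out$mux[i] <- -sum(vi * (grid@points[, 1] - a$x[i]))
    out$muy[i] <- -sum(vi * (grid@points[, 2] - a$y[i]))
    out$muz[i] <- -sum(vi * (grid@points[, 3] - a$z[i]))
  }
  out
}
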