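
hklKeys <- function(hkl) paste(hkl[, 1], hkl[, 2], hkl[, 3])

# All distinct rotated indices R_s^T h needed to assemble symmetry copies.
expandHklBySymmetry <- function(symops, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  all <- do.call(rbind, lapply(symops, function(op) hkl %*% op@R))
  storage.mode(all) <- "integer"
  all[!duplicated(hklKeys(all)), , drop = FALSE]
}

#' Hirshfeld atom form factors
#'
#' Numerical Fourier transform of the stockholder-partitioned atomic
#' densities:
#' \eqn{f_A(h) = \sum_g w_g \, w_A(r_g) \rho(r_g)
#'   \exp(2\pi i \, h^* \cdot (r_g - R_A))},
#' with \eqn{h^*} the Cartesian reciprocal vector. The phase is referenced
#' to the nucleus, so positional parameters carry the lattice phases in the
#' structure-factor sum. Only asymmetric-unit (core) atoms receive form
#' factors; all fragment atoms contribute density and weights. The index
#' set is expanded over the space group so rotated copies can be retrieved
#' analytically.
#'
#' @param structure the \code{CrystalStructure} (cell + symmetry)
#' @param fragment the grown \code{MoleculeFragment}
#' @param provider a \code{DensityProvider}
#' @param grid a \code{QuadratureGrid} over the fragment
#' @param hkl unique Miller indices (n x 3)
#' @param expandSymmetry expand the index set over the space group
#' @return a \linkS4class{FormFactorSet}
#' @export
hirshfeldFormFactors <- function(structure, fragment, provider, grid, hkl,
                                 expandSymmetry = TRUE) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  idx <- if (expandSymmetry) expandHklBySymmetry(structure@symops, hkl)
         else { storage.mode(hkl) <- "integer"; hkl[!duplicated(hklKeys(hkl)), , drop = FALSE] }
  a <- fragment@atoms
  core <- which(a$symop == 1L & a$tx == 0 & a$ty == 0 & a$tz == 0)
  rho <- provider@density(grid@points)
  W <- hirshfeldWeights(grid@points, fragment, provider)
  if (!is.null(provider@meta$Ne)) {
    tot <- sum(grid@w * rho)
    if (abs(tot - provider@meta$Ne) > 0.01 * max(1, provider@meta$Ne))
      stop(sprintf(paste0("grid population check failed: integrated density ",
                          "%.4f e vs expected %.4f e; refine the grid"),
                   tot, provider@meta$Ne))
  }
  hstar <- reciprocalVectors(structure@cell, idx)
  V <- W[, core, drop = FALSE] * (grid@w * rho)
  coreXYZ <- t(as.matrix(a[core, c("x", "y", "z")]))
  f <- matrix(0 + 0i, length(core), nrow(idx))
  chunk <- 64L
  for (j0 in seq(1L, nrow(idx), by = chunk)) {
    j1 <- min(j0 + chunk - 1L, nrow(idx))
    hs <- hstar[j0:j1, , drop = FALSE]
    E <- exp(2i * pi * (grid@points %*% t(hs)))
    B <- crossprod(E, V)                       # chunk x nCore, no conjugation
    shift <- exp(-2i * pi * (hs %*% coreXYZ))  # phase to each nucleus
    f[, j0:j1] <- t(B * shift)
  }
  new("FormFactorSet", f = f, hkl = idx, siteIndex = as.integer(a$site[core]),
      labels = structure@sites$label[a$site[core]],
      dispersionApplied = FALSE,
      meta = list(gridLevel = grid@level, provenance = provider@meta,
                  route = "hirshfeld"))
}

#' Spherical (IAM) form-factor set
#'
#' Form factors from spherical reference densities only: the independent
#' atom model route. References come from the provider when given (toy
#' models) and from the free-atom tables otherwise.
#'
#' @inheritParams hirshfeldFormFactors
#' @return a \code{FormFactorSet} (real-valued, stored as complex)
#' @export
iamFormFactorSet <- function(structure, fragment, provider = NULL, hkl,
                             expandSymmetry = TRUE, nQuad = 400) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  idx <- if (expandSymmetry) expandHklBySymmetry(structure@symops, hkl)
         else { storage.mode(hkl) <- "integer"; hkl[!duplicated(hklKeys(hkl)), , drop = FALSE] }
  a <- fragment@atoms
  core <- which(a$symop == 1L & a$tx == 0 & a$ty == 0 & a$tz == 0)
  s <- sinThetaOverLambda(structure@cell, idx)
  f <- matrix(0 + 0i, length(core), nrow(idx))
  for (ci in seq_along(core)) {
    A <- core[ci]
    fv <- if (is.null(provider)) {
      iamFormFactor(a$element[A], s, nQuad = nQuad)
    } else {
      # radial transform of the provider's spherical reference
      rad <- taRadial(nQuad)
      r <- rad$r; wr <- rad$w
      rho <- provider@reference(A, r)
      vapply(s, function(si) {
        if (si < 1e-12) return(4 * pi * sum(wr * rho * r^2))
        q <- 4 * pi * si
        4 * pi * sum(wr * rho * r^2 * sin(q * r) / (q * r))
      }, numeric(1))
    }
    f[ci, ] <- fv + 0i
  }
  new("FormFactorSet", f = f, hkl = idx, siteIndex = as.integer(a$site[core]),
      labels = structure@sites$label[a$site[core]],
      dispersionApplied = FALSE,
      meta = list(gridLevel = "radial", provenance = list(kind = "iam"),
                  route = "iam"))
}

#' Retrieve a form factor for a symmetry copy
#'
#' Hirshfeld atoms are aspherical, so the copy of atom A generated by
#' operation s scatters with \eqn{f_A(R_s^T h)}. The value is looked up on
#' the symmetry-expanded index set; when dispersion has not been applied the
#' Friedel relation \eqn{f(-h) = \overline{f(h)}} is used as a fallback.
#'
#' @param fset a \code{FormFactorSet}
#' @param atom row index into the set (asymmetric-unit atom)
#' @param symop a \code{SymOp}
#' @param hkl length-3 Miller index (or n x 3 matrix)
#' @return complex form-factor value(s)
#' @export
symmetryFormFactor <- function(fset, atom, symop, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  g <- hkl %*% symop@R
  lut <- stats::setNames(seq_len(nrow(fset@hkl)), hklKeys(fset@hkl))
  j <- lut[hklKeys(g)]
  out <- complex(nrow(g))
  miss <- is.na(j)
  out[!miss] <- fset@f[atom, j[!miss]]
  if (any(miss)) {
    if (fset@dispersionApplied)
      stop("rotated index missing from the form-factor set; evaluate form ",
           "factors on the symmetry-expanded index set")
    jm <- lut[hklKeys(-g[miss, , drop = FALSE])]
    if (anyNA(jm))
      stop("rotated index missing from the form-factor set; evaluate form ",
           "factors on the symmetry-expanded index set")
    out[miss] <- Conj(fset@f[atom, jm])
  }
  out
}

#' Apply anomalous-dispersion corrections
#'
#' Adds the wavelength-dependent terms once: f <- f + f' + i f''. Elements
#' without entries pass through unchanged. A second application is rejected.
#'
#' @param fset a \code{FormFactorSet}
#' @param terms named list: element -> c(fp, fpp), or NULL for none
#' @param elements element symbol per row of the set (defaults from labels)
#' @return the corrected \code{FormFactorSet}
#' @export
applyDispersion <- function(fset, terms, elements = NULL) {
  if (is.null(terms) || !length(terms)) return(fset)
  if (fset@dispersionApplied)
    stop("dispersion terms have already been applied to this form-factor set")
  if (is.null(elements))
    elements <- vapply(fset@labels, elementFromLabel, character(1),
                       USE.NAMES = FALSE)
  for (i in seq_len(nrow(fset@f))) {
    tr <- terms[[elements[i]]]
    if (!is.null(tr))
      fset@f[i, ] <- fset@f[i, ] + complex(real = tr[1], imaginary = tr[2])
  }
  fset@dispersionApplied <- TRUE
  fset
}
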