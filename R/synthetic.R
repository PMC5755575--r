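#' Analytic Gaussian-atom toy crystals
#'
#' Named presets of small P1/P-1 crystals whose static electron density is a
#' sum of atom-centred Gaussian shells, so every quantity downstream --
#' atomic form factors, structure factors, populations -- has a closed
#' form. The presets exercise the engine's failure modes separately:
#' \describe{
#'   \item{one_atom_P1}{single pseudo-carbon, U_iso = 0.01 \eqn{\AA^2}}
#'   \item{diatomic_P1}{homonuclear pair in a centrosymmetric arrangement}
#'   \item{polar_XH_P1}{an O-H-like pair whose hydrogen density centroid is
#'     displaced 0.10 \eqn{\AA} along the bond towards the heavy atom,
#'     emulating the bond-density asphericity that makes spherical-atom
#'     refinement foreshorten X-H distances by about 0.1 \eqn{\AA}}
#'   \item{ionic_P1}{a +1/-1 ion pair for crystal-field environment tests}
#'   \item{diatomic_P1bar}{centrosymmetric diatomic in P-1 with the atom in
#'     a general position (Z' = 1/2), for fragment-growth invariants}
#'   \item{mirror_site}{an SO2-like molecule on a crystallographic mirror,
#'     for special-position constraint tests}
#' }
#'
#' @param preset preset name
#' @return list(structure = CrystalStructure, model = GaussianAtomModel,
#'   provider = DensityProvider)
#' @export
makeToyCrystal <- function(preset) {
  presets <- c("one_atom_P1", "diatomic_P1", "polar_XH_P1", "ionic_P1",
               "diatomic_P1bar", "mirror_site")
  if (!preset %in% presets)
    stop("unknown preset '", preset, "'; available: ",
         paste(presets, collapse = ", "))
  p1 <- list(parseSymOp("x, y, z"))
  p1bar <- list(parseSymOp("x, y, z"), parseSymOp("-x, -y, -z"))
  shell <- function(ne, alpha, offType = "none", partner = NA, dist = 0)
    data.frame(ne = ne, alpha = alpha, offType = offType,
               ox = 0, oy = 0, oz = 0, partner = partner, dist = dist,
               stringsAsFactors = FALSE)
  aniso <- function(u11, u22, u33, u12 = 0, u13 = 0, u23 = 0)
    list(adpType = "ani", u11 = u11, u22 = u22, u33 = u33,
         u12 = u12, u13 = u13, u23 = u23)
  def <- switch(preset,
    one_atom_P1 = list(
      cell = unitCell(5, 5, 5),
      symops = p1, sg = "P 1",
      atoms = data.frame(label = "C1", element = "C",
                         x = 0.30, y = 0.40, z = 0.35, Z = 6, occ = 1,
                         adpType = "iso", uiso = 0.01,
                         u11 = 0, u22 = 0, u33 = 0, u12 = 0, u13 = 0, u23 = 0),
      shells = list(rbind(shell(2, 30), shell(4, 4)))),
    diatomic_P1 = list(
      cell = unitCell(6, 5, 4.5),
      symops = p1, sg = "P 1",
      atoms = data.frame(label = c("N1", "N2"), element = "N",
                         x = 0.5 + c(-1, 1) * 0.55 / 6, y = 0.5, z = 0.5,
                         Z = 7, occ = 1, adpType = "ani", uiso = 0,
                         u11 = 0.012, u22 = 0.010, u33 = 0.008,
                         u12 = 0, u13 = 0, u23 = 0),
      shells = rep(list(rbind(shell(2, 35), shell(5, 4.5))), 2)),
    polar_XH_P1 = list(
      cell = unitCell(6, 5, 4.5),
      symops = p1, sg = "P 1",
      atoms = data.frame(label = c("O1", "H1"), element = c("O", "H"),
                         x = c(0.35, 0.35 + 1.00 / 6), y = 0.5, z = 0.5,
                         Z = c(8, 1), occ = 1, adpType = "ani", uiso = 0,
                         u11 = c(0.008, 0.025), u22 = c(0.010, 0.022),
                         u33 = c(0.009, 0.020), u12 = 0, u13 = 0, u23 = 0),
      shells = list(rbind(shell(2, 45), shell(6, 5)),
                    # two bond-directed shells: density centroid 0.10 A
                    # towards O, but not reducible to one displaced sphere
                    rbind(shell(0.5, 3.2, offType = "bond", partner = "O1",
                                dist = 0.16),
                          shell(0.5, 2.2, offType = "bond", partner = "O1",
                                dist = 0.04)))),
    ionic_P1 = list(
      cell = unitCell(5.5, 5.5, 5.5),
      symops = p1, sg = "P 1",
      atoms = data.frame(label = c("K1", "Cl1"), element = c("K", "Cl"),
                         x = c(0.25, 0.75), y = c(0.25, 0.75),
                         z = c(0.25, 0.75), Z = c(19, 17), occ = 1,
                         adpType = "ani", uiso = 0,
                         u11 = 0.010, u22 = 0.010, u33 = 0.010,
                         u12 = 0, u13 = 0, u23 = 0),
      shells = list(rbind(shell(10, 60), shell(8, 7)),
                    rbind(shell(10, 50), shell(8, 4.5)))),
    diatomic_P1bar = list(
      cell = unitCell(6, 5, 4.5),
      symops = p1bar, sg = "P -1",
      atoms = data.frame(label = "N1", element = "N",
                         x = 0.5 * 1.10 / 6, y = 0.02, z = 0.03,
                         Z = 7, occ = 1, adpType = "ani", uiso = 0,
                         u11 = 0.012, u22 = 0.010, u33 = 0.008,
                         u12 = 0.001, u13 = 0, u23 = 0),
      shells = list(rbind(shell(2, 35), shell(5, 4.5)))),
    mirror_site = list(
      cell = unitCell(6, 5, 4.5),
      symops = list(parseSymOp("x, y, z"), parseSymOp("x, -y, z")),
      sg = "P m",
      atoms = data.frame(label = c("S1", "O1"), element = c("S", "O"),
                         x = c(0.30, 0.45), y = c(0.00, 0.22),
                         z = c(0.40, 0.40), Z = c(16, 8), occ = 1,
                         adpType = "ani", uiso = 0,
                         u11 = c(0.010, 0.011), u22 = c(0.012, 0.009),
                         u33 = c(0.009, 0.010),
                         u12 = 0, u13 = c(0.001, 0.0015), u23 = 0),
      shells = list(rbind(shell(10, 40), shell(6, 4)),
                    rbind(shell(2, 45), shell(6, 5)))))
  structure <- crystalStructure(def$cell, def$symops, def$atoms,
                                spaceGroupName = def$sg)
  model <- new("GaussianAtomModel", cell = def$cell, symops = def$symops,
               atoms = def$atoms, shells = def$shells)
  list(structure = structure, model = model,
       provider = gaussianDensityProvider(model, structure))
}

# Resolve shell offsets (Cartesian) for an atom placed at `center`, given the
# positions of all fragment atoms (bond-directed offsets point towards the
# nearest image of the partner site).
resolveOffsets <- function(sh, center, fragAtoms, siteLabels) {
  off <- matrix(0, nrow(sh), 3)
  for (j in seq_len(nrow(sh))) {
    if (sh$offType[j] == "fixed") {
      off[j, ] <- c(sh$ox[j], sh$oy[j], sh$oz[j])
    } else if (sh$offType[j] == "bond") {
      pIdx <- which(siteLabels[fragAtoms$site] == sh$partner[j])
      if (!length(pIdx)) stop("offset partner not in fragment: ", sh$partner[j])
      pPos <- as.matrix(fragAtoms[pIdx, c("x", "y", "z"), drop = FALSE])
      d <- sweep(pPos, 2, center)
      k <- which.min(rowSums(d^2))
      u <- d[k, ] / sqrt(sum(d[k, ]^2))
      off[j, ] <- sh$dist[j] * u
    }
  }
  off
}

#' Analytic density provider for a Gaussian-atom model
#'
#' Evaluates the model density at arbitrary points and exposes closed-form
#' atomic form factors
#' \eqn{f_A(h) = \sum_j n_j \exp(-\pi^2 |h^*|^2/\alpha_j)
#'   \exp(2\pi i h^*\cdot d_j)} for oracle use. Rebuilding at a new
#' geometry recomputes shell centres (and bond-directed offsets) from the
#' fragment, which is how the outer refinement loop keeps density and
#' geometry consistent.
#'
#' @param model a \code{GaussianAtomModel}
#' @param structure the companion \code{CrystalStructure}
#' @param fragment optional grown fragment (defaults to complete molecules)
#' @return a \linkS4class{DensityProvider}
#' @export
gaussianDensityProvider <- function(model, structure, fragment = NULL) {
  if (is.null(fragment))
    fragment <- growFragment(structure, "complete_molecules")
  a <- fragment@atoms
  labels <- structure@sites$label
  shellsOf <- lapply(seq_len(nrow(a)), function(i) model@shells[[a$site[i]]])
  # rotate fixed offsets by the generating operation; bond offsets follow
  # the local geometry directly
  offsets <- lapply(seq_len(nrow(a)), function(i)
    resolveOffsets(shellsOf[[i]], as.numeric(a[i, c("x", "y", "z")]), a, labels))
  NeTot <- sum(vapply(seq_len(nrow(a)), function(i)
    a$occ[i] * sum(shellsOf[[i]]$ne), numeric(1)))
  densityFun <- function(points) {
    if (!is.matrix(points)) points <- matrix(points, ncol = 3)
    out <- numeric(nrow(points))
    for (i in seq_len(nrow(a))) {
      sh <- shellsOf[[i]]
      for (j in seq_len(nrow(sh))) {
        cJ <- as.numeric(a[i, c("x", "y", "z")]) + offsets[[i]][j, ]
        r2 <- (points[, 1] - cJ[1])^2 + (points[, 2] - cJ[2])^2 +
          (points[, 3] - cJ[3])^2
        out <- out + a$occ[i] * sh$ne[j] * (sh$alpha[j] / pi)^1.5 *
          exp(-sh$alpha[j] * r2)
      }
    }
    out
  }
  referenceFun <- function(atomIndex, r) {
    sh <- shellsOf[[atomIndex]]
    out <- numeric(length(r))
    for (j in seq_len(nrow(sh)))
      out <- out + sh$ne[j] * (sh$alpha[j] / pi)^1.5 * exp(-sh$alpha[j] * r^2)
    out
  }
  ffFun <- function(atomIndex, hstar) {
    if (!is.matrix(hstar)) hstar <- matrix(hstar, ncol = 3)
    sh <- shellsOf[[atomIndex]]
    h2 <- rowSums(hstar^2)
    out <- complex(nrow(hstar))
    for (j in seq_len(nrow(sh)))
      out <- out + sh$ne[j] * exp(-pi^2 * h2 / sh$alpha[j]) *
        exp(2i * pi * as.vector(hstar %*% offsets[[atomIndex]][j, ]))
    out
  }
  new("DensityProvider", density = densityFun, reference = referenceFun,
      rebuild = function(fragment, structure)
        gaussianDensityProvider(model, structure, fragment),
      formFactor = ffFun, fragment = fragment,
      meta = list(kind = "gaussian", Ne = NeTot))
}

#' Closed-form structure factors of a Gaussian-atom crystal
#'
#' Direct analytic sum over symmetry copies of the model atoms with
#' Debye-Waller smearing from the companion structure's ADPs; independent of
#' the quadrature/assembly route and therefore usable as its oracle.
#'
#' @param model a \code{GaussianAtomModel}
#' @param structure the companion \code{CrystalStructure} (ADPs, occupancies)
#' @param hkl n x 3 Miller indices
#' @return complex structure factors
#' @export
oracleStructureFactors <- function(model, structure, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  cell <- structure@cell
  s <- structure@sites
  frag <- growFragment(structure, "complete_molecules")
  prov <- gaussianDensityProvider(model, structure, frag)
  a <- frag@atoms
  core <- which(a$symop == 1L & a$tx == 0 & a$ty == 0 & a$tz == 0)
  F <- complex(nrow(hkl))
  s2 <- sinThetaOverLambda(cell, hkl)^2
  for (ci in core) {
    A <- a$site[ci]
    orb <- siteOrbit(structure, c(s$x[A], s$y[A], s$z[A]))
    for (oi in seq_along(orb$symop)) {
      op <- structure@symops[[orb$symop[oi]]]
      g <- hkl %*% op@R
      fv <- prov@formFactor(ci, g %*% cell@Minv)
      ph <- exp(2i * pi * as.vector(hkl %*% applySymOp(op, c(s$x[A], s$y[A], s$z[A]))))
      Tdw <- if (s$adpType[A] == "ani") {
        u6 <- as.numeric(s[A, c("u11", "u22", "u33", "u12", "u13", "u23")])
        exp(-2 * pi^2 * as.vector(dwDesign(cell, g) %*% u6))
      } else exp(-8 * pi^2 * s$uiso[A] * s2)
      F <- F + s$occ[A] * fv * Tdw * ph
    }
  }
  F
}

#' Complete unique reflection list to a resolution limit
#'
#' @param structure a \code{CrystalStructure}
#' @param resolution maximum \eqn{\sin\theta/\lambda} (\eqn{\AA^{-1}})
#' @return n x 3 integer matrix of Laue-unique indices
#' @export
uniqueHklTo <- function(structure, resolution) {
  cell <- structure@cell
  hmax <- ceiling(2 * resolution / cell@astar)
  H <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  H <- H[rowSums(abs(H)) > 0, , drop = FALSE]
  H <- H[sinThetaOverLambda(cell, H) <= resolution, , drop = FALSE]
  cano <- canonicalHkl(structure@symops, H)
  self <- paste(H[, 1], H[, 2], H[, 3])
  keep <- cano == self            # exactly one orbit member is self-canonical
  H <- H[keep, , drop = FALSE]
  H <- H[!duplicated(cano[keep]), , drop = FALSE]
  storage.mode(H) <- "integer"
  H
}

#' Simulate a reflection data set
#'
#' Computes the complete Laue-unique index set to the resolution limit,
#' evaluates the closed-form structure factors of the model, and applies
#' relative Gaussian noise on |F| (matching the refinement target):
#' |F_obs| = |F|(1 + e), e ~ N(0, noiseFraction), sigma = noiseFraction |F|.
#' With \code{noiseFraction = 0} the data are exact and carry a small
#' constant nominal sigma (1e-4 of the mean |F|) so that least-squares
#' weights remain finite.
#'
#' @param structure a \code{CrystalStructure}
#' @param model the \code{GaussianAtomModel} generating the data
#' @param resolution maximum \eqn{\sin\theta/\lambda} (\eqn{\AA^{-1}})
#' @param noiseFraction relative noise level
#' @param seed RNG seed (recorded in the dialect tag)
#' @return a \code{ReflectionSet}
#' @export
simulateReflections <- function(structure, model, resolution = 0.7,
                                noiseFraction = 0, seed = 1) {
  if (resolution > 1.5) stop("resolution limit above 1.5 1/Angstrom")
  H <- uniqueHklTo(structure, resolution)
  nPar <- 1 + 9 * nrow(structure@sites)
  if (nrow(H) < 5 * nPar)
    warning("fewer than 5 reflections per parameter (", nrow(H), " for ",
            nPar, ")")
  Ftrue <- Mod(oracleStructureFactors(model, structure, H))
  if (noiseFraction > 0) {
    set.seed(seed)
    eps <- stats::rnorm(length(Ftrue), 0, noiseFraction)
    fo <- Ftrue * (1 + eps)
    sig <- noiseFraction * Ftrue
  } else {
    fo <- Ftrue
    sig <- rep(1e-4 * mean(Ftrue), length(Ftrue))
  }
  sig <- pmax(sig, 1e-12)
  reflectionSet(H, pmax(fo, 0), sig,
                dialect = sprintf("simulated(noise=%g,seed=%d)",
                                  noiseFraction, seed))
}

#' Randomly perturb a starting model
#'
#' Displaces coordinates by uniform random Cartesian shifts within
#' \code{magnitudeXyz} per component and the diagonal displacement
#' parameters within \code{magnitudeU}, respecting special-position
#' constraints. Shifts along floating-origin (polar) directions are removed
#' with the same weighting used to fix the origin in refinement, so the
#' perturbed model refines back onto the generating coordinates.
#'
#' @param structure a \code{CrystalStructure}
#' @param magnitudeXyz maximum Cartesian component shift (\eqn{\AA})
#' @param magnitudeU maximum diagonal U shift (\eqn{\AA^2})
#' @param seed RNG seed
#' @return the perturbed structure
#' @export
perturbModel <- function(structure, magnitudeXyz = 0.05, magnitudeU = 0.005,
                         seed = 1) {
  set.seed(seed)
  s <- structure@sites
  cell <- structure@cell
  shifts <- matrix(0, nrow(s), 3)
  for (A in seq_len(nrow(s))) {
    con <- sitePositionConstraints(structure, A)
    dCart <- stats::runif(3, -magnitudeXyz, magnitudeXyz)
    dFrac <- as.vector(cartToFrac(cell, dCart))
    if (ncol(con$xyz) < 3)
      dFrac <- as.vector(con$xyz %*% (t(con$xyz) %*% dFrac))
    shifts[A, ] <- dFrac
    if (magnitudeU > 0) {
      dU <- c(stats::runif(3, -magnitudeU, magnitudeU), 0, 0, 0)
      if (s$adpType[A] == "ani") {
        if (ncol(con$u) < 6) dU <- as.vector(con$u %*% (t(con$u) %*% dU))
        u6 <- as.numeric(s[A, uColumns]) + dU
        s[A, uColumns] <- as.list(u6)
      } else {
        s$uiso[A] <- abs(s$uiso[A] + dU[1])
      }
    }
  }
  # remove the net shift along polar directions (weighted as in refinement)
  stack <- do.call(rbind, lapply(structure@symops, function(o) o@R - diag(3)))
  polar <- nullBasis(stack)
  if (ncol(polar)) {
    wA <- ATOMIC_NUMBERS[s$element] * s$occ * s$mult
    for (pd in seq_len(ncol(polar))) {
      v <- polar[, pd]
      net <- sum((shifts %*% v) * wA) / sum(wA * sum(v^2))
      shifts <- shifts - outer(rep(net, nrow(s)), v)
    }
  }
  s$x <- (s$x + shifts[, 1]) %% 1
  s$y <- (s$y + shifts[, 2]) %% 1
  s$z <- (s$z + shifts[, 3]) %% 1
  structure@sites <- s
  clampAdps(structure)$structure
}

#' Write a synthetic fixture to disk
#'
#' Emits the CIF and a SHELX-format hkl file for a toy preset, embedding the
#' preset name, resolution, noise level and seed in comments.
#'
#' @param preset toy preset name
#' @param dir output directory (created if needed)
#' @param resolution,noiseFraction,seed passed to
#'   \code{\link{simulateReflections}}
#' @return invisibly, the two file paths
#' @export
simulateToFiles <- function(preset, dir, resolution = 0.7,
                            noiseFraction = 0.02, seed = 1) {
  toy <- makeToyCrystal(preset)
  refl <- simulateReflections(toy$structure, toy$model, resolution,
                              noiseFraction, seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  provenance <- sprintf("# synthetic fixture: preset=%s resolution=%g noise=%g seed=%d",
                        preset, resolution, noiseFraction, seed)
  cifPath <- file.path(dir, paste0(preset, ".cif"))
  writeLines(c(provenance, writeCif(toy$structure)), cifPath)
  hklPath <- file.path(dir, paste0(preset, ".hkl"))
  # fixed-width SHELX files conventionally carry F^2, matching auto-detection
  writeLines(writeHkl(refl, squared = TRUE), hklPath)
  invisible(c(cif = cifPath, hkl = hklPath))
}
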