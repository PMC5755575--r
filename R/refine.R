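#' Refinement options
#'
#' Collects every user-facing knob of a refinement run. The default is a
#' minimal run: no crystal-field cluster (radius 0 disables it), hydrogens
#' refined freely and anisotropically, reflections pruned at F > 3 sigma(F),
#' no dispersion.
#'
#' @param method electronic-structure method label for the density provider
#' @param basis basis-set label
#' @param clusterRadius crystal-field radius in Angstrom; 0 disables
#' @param environmentKind "none", "charges_dipoles" or "explicit_cluster"
#' @param hAdpMode hydrogen ADPs: "anisotropic", "isotropic" or "fixed"
#' @param pruneSigma observation cutoff F > pruneSigma * sigma
#' @param dispersion named list element -> c(fp, fpp), or NULL
#' @param gridLevel quadrature preset ("test", "standard", "fine")
#' @param maxOuterCycles,maxInnerCycles cycle limits
#' @param convergenceShiftOverSu convergence threshold on max |shift|/su
#' @return a \linkS4class{RefinementOptions}
#' @export
refinementOptions <- function(method = "rhf", basis = "def2-SVP",
                              clusterRadius = 0, environmentKind = "none",
                              hAdpMode = "anisotropic", pruneSigma = 3,
                              dispersion = NULL, gridLevel = "standard",
                              maxOuterCycles = 15, maxInnerCycles = 20,
                              convergenceShiftOverSu = 0.01) {
  new("RefinementOptions", method = method, basis = basis,
      clusterRadius = clusterRadius, environmentKind = environmentKind,
      hAdpMode = hAdpMode, pruneSigma = pruneSigma, dispersion = dispersion,
      gridLevel = gridLevel, maxOuterCycles = maxOuterCycles,
      maxInnerCycles = maxInnerCycles,
      convergenceShiftOverSu = convergenceShiftOverSu)
}

# --- displacement-parameter conversions ----------------------------------

dMat <- function(cell) diag(cell@astar)

#' Convert CIF U tensors to Cartesian
#'
#' @param cell a \code{UnitCell}
#' @param u6 six-vector (U11, U22, U33, U12, U13, U23), CIF convention
#' @return 3x3 Cartesian tensor (\eqn{\AA^2})
#' @export
uCifToCart <- function(cell, u6) {
  MD <- cell@M %*% dMat(cell)
  MD %*% uSixToMat(u6) %*% t(MD)
}

#' Convert a Cartesian U tensor to the CIF convention
#'
#' @param cell a \code{UnitCell}
#' @param ucart 3x3 Cartesian tensor
#' @return six-vector (U11, U22, U33, U12, U13, U23)
#' @export
uCartToCif <- function(cell, ucart) {
  MDi <- solve(cell@M %*% dMat(cell))
  uMatToSix(MDi %*% ucart %*% t(MDi))
}

#' Isotropic-equivalent CIF U tensor
#'
#' The CIF-basis tensor whose Cartesian image is uiso times the identity.
#'
#' @param cell a \code{UnitCell}
#' @param uiso isotropic displacement parameter (\eqn{\AA^2})
#' @return six-vector in the CIF convention
#' @export
isoToUCif <- function(cell, uiso) {
  Di <- solve(dMat(cell))
  uMatToSix(uiso * (Di %*% cell@Gstar %*% Di))
}

#' Debye-Waller factor
#'
#' Thermal smearing factor in (0, 1]:
#' \deqn{T(h) = \exp(-2\pi^2 \sum_{ij} h_i h_j a^*_i a^*_j U^{ij})}
#' (CIF U convention); the isotropic case reduces to
#' \eqn{\exp(-8\pi^2 U s^2)} with \eqn{s = \sin\theta/\lambda}.
#'
#' @param cell a \code{UnitCell}
#' @param hkl n x 3 Miller indices
#' @param u either a single U_iso or a six-vector U^ij
#' @return n values in (0, 1]
#' @export
debyeWaller <- function(cell, hkl, u) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  if (length(u) == 1) {
    s2 <- sinThetaOverLambda(cell, hkl)^2
    return(exp(-8 * pi^2 * u * s2))
  }
  q <- dwDesign(cell, hkl)
  exp(-2 * pi^2 * as.vector(q %*% u))
}

# design matrix of the quadratic form: T = exp(-2 pi^2 (design %*% u6))
dwDesign <- function(cell, g) {
  as_ <- cell@astar
  cbind(g[, 1]^2 * as_[1]^2, g[, 2]^2 * as_[2]^2, g[, 3]^2 * as_[3]^2,
        2 * g[, 1] * g[, 2] * as_[1] * as_[2],
        2 * g[, 1] * g[, 3] * as_[1] * as_[3],
        2 * g[, 2] * g[, 3] * as_[2] * as_[3])
}

# --- structure-factor assembly -------------------------------------------

# F(h) and (optionally) analytic derivatives w.r.t. the native parameters of
# each asymmetric-unit site. Symmetry copies use rotated indices g = R^T h
# for both the aspherical form factor and the displacement tensor.
structureFactorCore <- function(structure, fset, hkl, deriv = FALSE) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  cell <- structure@cell
  s <- structure@sites
  n <- nrow(hkl)
  lut <- stats::setNames(seq_len(nrow(fset@hkl)), hklKeys(fset@hkl))
  rowOf <- match(seq_len(nrow(s)), fset@siteIndex)
  F <- complex(n)
  dX <- if (deriv) lapply(seq_len(nrow(s)), function(i) matrix(0i, n, 3))
  dU <- if (deriv) lapply(seq_len(nrow(s)), function(i)
    matrix(0i, n, if (s$adpType[i] == "ani") 6 else 1))
  s2 <- sinThetaOverLambda(cell, hkl)^2
  for (A in seq_len(nrow(s))) {
    if (is.na(rowOf[A]))
      stop("no form factors for site ", s$label[A], "; index mismatch")
    orb <- siteOrbit(structure, c(s$x[A], s$y[A], s$z[A]))
    for (oi in seq_along(orb$symop)) {
      op <- structure@symops[[orb$symop[oi]]]
      g <- hkl %*% op@R
      j <- lut[hklKeys(g)]
      if (anyNA(j))
        stop("form-factor set does not cover the symmetry-expanded indices")
      fv <- fset@f[rowOf[A], j]
      ph <- exp(2i * pi * as.vector(hkl %*% applySymOp(op, c(s$x[A], s$y[A], s$z[A]))))
      if (s$adpType[A] == "ani") {
        u6 <- as.numeric(s[A, c("u11", "u22", "u33", "u12", "u13", "u23")])
        q <- dwDesign(cell, g)
        Tdw <- exp(-2 * pi^2 * as.vector(q %*% u6))
      } else {
        Tdw <- exp(-8 * pi^2 * s$uiso[A] * s2)
      }
      contrib <- s$occ[A] * fv * Tdw * ph
      F <- F + contrib
      if (deriv) {
        dX[[A]] <- dX[[A]] + (2i * pi) * contrib * g
        if (s$adpType[A] == "ani") {
          dU[[A]] <- dU[[A]] + contrib * (-2 * pi^2) * q
        } else {
          dU[[A]] <- dU[[A]] + contrib * (-8 * pi^2) * s2
        }
      }
    }
  }
  list(F = F, dX = dX, dU = dU)
}

#' Calculated structure factors
#'
#' Assembles \eqn{F_c(h)} from a form-factor set over all symmetry copies of
#' the asymmetric-unit sites, with Debye-Waller smearing and site
#' occupancies (special positions enter once per distinct copy, so
#' multiplicity is handled without double counting).
#'
#' @param structure a \code{CrystalStructure}
#' @param fset a \code{FormFactorSet} covering the expanded index set
#' @param hkl n x 3 Miller indices
#' @param scale overall scale factor applied to |F|
#' @return complex vector of \eqn{k F_c(h)}
#' @export
structureFactors <- function(structure, fset, hkl, scale = 1) {
  scale * structureFactorCore(structure, fset, hkl, deriv = FALSE)$F
}

#' Optimal scale factor
#'
#' Closed-form minimizer of \eqn{\sum_h w_h (|F_o| - k |F_c|)^2}:
#' \eqn{k = \sum w |F_o||F_c| / \sum w |F_c|^2}.
#'
#' @param fo,fc observed and calculated magnitudes
#' @param w weights (default unit)
#' @return the scale k
#' @export
optimalScale <- function(fo, fc, w = rep(1, length(fo))) {
  fc <- abs(fc)
  denom <- sum(w * fc^2)
  if (denom <= 0) stop("cannot scale: all |F_calc| are zero")
  sum(w * fo * fc) / denom
}

# --- parameterization ----------------------------------------------------

# Builds the linear map from free least-squares parameters to native
# parameter shifts, honouring special-position constraints, the hydrogen
# ADP mode and floating-origin fixing in polar space groups.
buildParameterization <- function(structure, hAdpMode = "anisotropic") {
  s <- structure@sites
  blocks <- list()
  names_ <- character(0)
  for (A in seq_len(nrow(s))) {
    con <- sitePositionConstraints(structure, A)
    xyzB <- con$xyz
    isH <- s$element[A] == "H"
    uB <- NULL; uKind <- "none"
    if (s$adpType[A] == "ani") {
      if (!isH || hAdpMode == "anisotropic") { uB <- con$u; uKind <- "ani" }
      else if (hAdpMode == "isotropic") {
        # one isotropic degree of freedom expressed in the U^ij basis
        uB <- matrix(isoToUCif(structure@cell, 1), ncol = 1); uKind <- "ani"
      }
    } else {
      if (!isH || hAdpMode %in% c("anisotropic", "isotropic")) {
        uB <- matrix(1, 1, 1); uKind <- "iso"
      }
    }
    if (isH && hAdpMode == "fixed") { uB <- NULL; uKind <- "none" }
    nx <- ncol(xyzB); nu <- if (is.null(uB)) 0 else ncol(uB)
    if (nx) names_ <- c(names_, paste0(s$label[A], ".x", seq_len(nx)))
    if (nu) names_ <- c(names_, paste0(s$label[A], ".u", seq_len(nu)))
    blocks[[A]] <- list(xyz = xyzB, u = uB, uKind = uKind)
  }
  nFree <- 1L + sum(vapply(blocks, function(b)
    ncol(b$xyz) + if (is.null(b$u)) 0L else ncol(b$u), integer(1)))
  # floating-origin directions: v with R v = v for every operation
  stack <- do.call(rbind, lapply(structure@symops, function(o) o@R - diag(3)))
  polar <- nullBasis(stack)
  list(blocks = blocks, nFree = nFree, polar = polar,
       names = c("scale", names_))
}

# Jacobian of k|Fc| w.r.t. the free parameters, plus |Fc| and phases.
assembleJacobian <- function(structure, param, fset, hkl, k) {
  sf <- structureFactorCore(structure, fset, hkl, deriv = TRUE)
  Fc <- sf$F
  aF <- pmax(Mod(Fc), 1e-300)
  u <- Conj(Fc) / aF
  J <- matrix(0, length(aF), param$nFree)
  J[, 1] <- aF                       # d(k|Fc|)/dk
  col <- 2L
  for (A in seq_along(param$blocks)) {
    b <- param$blocks[[A]]
    if (ncol(b$xyz)) {
      dAbs <- Re(u * sf$dX[[A]])     # n x 3, d|Fc|/dx
      J[, col:(col + ncol(b$xyz) - 1L)] <- k * (dAbs %*% b$xyz)
      col <- col + ncol(b$xyz)
    }
    if (!is.null(b$u)) {
      dAbs <- Re(u * sf$dU[[A]])
      J[, col:(col + ncol(b$u) - 1L)] <- k * (dAbs %*% b$u)
      col <- col + ncol(b$u)
    }
  }
  list(J = J, aF = aF, Fc = Fc)
}

applyShift <- function(structure, param, delta) {
  s <- structure@sites
  col <- 2L
  for (A in seq_along(param$blocks)) {
    b <- param$blocks[[A]]
    if (ncol(b$xyz)) {
      d <- b$xyz %*% delta[col:(col + ncol(b$xyz) - 1L)]
      s$x[A] <- s$x[A] + d[1]; s$y[A] <- s$y[A] + d[2]; s$z[A] <- s$z[A] + d[3]
      col <- col + ncol(b$xyz)
    }
    if (!is.null(b$u)) {
      du <- b$u %*% delta[col:(col + ncol(b$u) - 1L)]
      if (b$uKind == "ani") {
        u6 <- as.numeric(s[A, c("u11", "u22", "u33", "u12", "u13", "u23")]) + du
        s[A, c("u11", "u22", "u33", "u12", "u13", "u23")] <- as.list(u6)
      } else {
        s$uiso[A] <- s$uiso[A] + du
      }
      col <- col + ncol(b$u)
    }
  }
  structure@sites <- s
  structure
}

# Eigenvalue-clamp non-positive-definite ADPs (Cartesian floor 1e-5 A^2).
clampAdps <- function(structure, floorEv = 1e-5) {
  s <- structure@sites
  flagged <- character(0)
  for (A in which(s$adpType == "ani")) {
    u6 <- as.numeric(s[A, c("u11", "u22", "u33", "u12", "u13", "u23")])
    uc <- uCifToCart(structure@cell, u6)
    ev <- eigen(uc, symmetric = TRUE)
    if (min(ev$values) < floorEv) {
      flagged <- c(flagged, s$label[A])
      ev$values <- pmax(ev$values, floorEv)
      uc2 <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
      s[A, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
        as.list(uCartToCif(structure@cell, uc2))
    }
  }
  for (A in which(s$adpType == "iso")) {
    if (s$uiso[A] < floorEv) { flagged <- c(flagged, s$label[A]); s$uiso[A] <- floorEv }
  }
  structure@sites <- s
  list(structure = structure, flagged = flagged)
}

# Null-space reduction for floating origins: the occupancy- and
# Z-weighted centre of the structure is fixed along each polar direction.
originReduction <- function(structure, param) {
  if (!ncol(param$polar)) return(NULL)
  s <- structure@sites
  wA <- ATOMIC_NUMBERS[s$element] * s$occ * s$mult
  C <- matrix(0, ncol(param$polar), param$nFree)
  for (pd in seq_len(ncol(param$polar))) {
    v <- param$polar[, pd]
    col <- 2L
    for (A in seq_along(param$blocks)) {
      b <- param$blocks[[A]]
      if (ncol(b$xyz)) {
        C[pd, col:(col + ncol(b$xyz) - 1L)] <- wA[A] * as.vector(v %*% b$xyz)
        col <- col + ncol(b$xyz)
      }
      if (!is.null(b$u)) col <- col + ncol(b$u)
    }
  }
  C <- C[rowSums(abs(C)) > 1e-12, , drop = FALSE]
  if (!nrow(C)) return(NULL)
  nullBasis(t(C) %*% C)              # basis of the allowed subspace
}

#' One weighted least-squares cycle
#'
#' Minimizes \eqn{\sum_h w_h (|F_o| - k|F_c|)^2} (weights \eqn{1/\sigma^2})
#' with analytic derivatives of |F_c| with respect to coordinates and
#' displacement parameters at fixed form factors. Shifts come from the
#' constrained normal equations (special positions and, in polar space
#' groups, the floating origin); standard uncertainties from the inverse
#' normal matrix scaled by the goodness of fit. Large shifts are damped,
#' and the step is halved (up to 8 times) if the weighted residual would
#' otherwise increase.
#'
#' @param state refinement state from \code{\link{refinementState}}
#' @return updated state (fields: structure, k, r1, wr2, gof, su,
#'   maxShiftOverSu, maxShift, cycle)
#' @export
lsqCycle <- function(state) {
  structure <- state$structure; param <- state$param
  jb <- assembleJacobian(structure, param, state$fset, state$hkl, state$k)
  w <- state$w; fo <- state$fo
  r <- fo - state$k * jb$aF
  red <- state$reduction
  J <- if (is.null(red)) jb$J else jb$J %*% red
  A <- crossprod(J, w * J)
  bvec <- crossprod(J, w * r)
  ev <- eigen(A, symmetric = TRUE)
  tolEv <- max(ev$values) * 1e-12
  if (min(ev$values) < tolEv) {
    bad <- which(abs(ev$vectors[, which.min(ev$values)]) > 0.3)
    nm <- if (is.null(red)) param$names[bad] else paste0("reduced#", bad)
    stop("singular normal matrix; unconstrained or degenerate parameter(s): ",
         paste(nm, collapse = ", "))
  }
  Ainv <- ev$vectors %*% (t(ev$vectors) / ev$values)
  delta <- as.vector(Ainv %*% bvec)
  nObs <- length(fo); nPar <- ncol(J)
  gof <- sqrt(sum(w * r^2) / max(1, nObs - nPar))
  su <- sqrt(pmax(diag(Ainv), 0)) * max(gof, 1e-300)
  # damp runaway steps, then backtrack if the weighted residual would rise
  damp <- min(1, 0.5 / max(max(abs(delta)), .Machine$double.eps))
  wr2old <- sqrt(sum(w * r^2) / sum(w * fo^2))
  wr2new <- wr2old
  usedDamp <- damp
  for (try in 0:8) {
    step <- delta * damp / 2^try
    full <- if (is.null(red)) step else as.vector(red %*% step)
    cand <- applyShift(structure, param, full)   # index 1 (scale) is skipped
    candK <- state$k + full[1]
    aFnew <- Mod(structureFactorCore(cand, state$fset, state$hkl)$F)
    kUse <- if (candK > 0) candK else optimalScale(fo, aFnew, w)
    rNew <- fo - kUse * aFnew
    wr2new <- sqrt(sum(w * rNew^2) / sum(w * fo^2))
    if (wr2new <= wr2old * (1 + 1e-12) || try == 8) {
      usedDamp <- damp / 2^try
      state$structure <- cand
      state$k <- kUse
      clamped <- clampAdps(state$structure)
      if (length(clamped$flagged)) {
        warning("non-positive-definite ADPs clamped: ",
                paste(unique(clamped$flagged), collapse = ", "))
        state$structure <- clamped$structure
        state$flags$nonPositiveDefinite <-
          unique(c(state$flags$nonPositiveDefinite, clamped$flagged))
      }
      break
    }
  }
  fullSu <- if (is.null(red)) su else
    sqrt(pmax(diag(red %*% Ainv %*% t(red)), 0)) * max(gof, 1e-300)
  state$su <- fullSu
  state$nPar <- nPar
  state$gof <- gof
  state$r1 <- sum(abs(r)) / sum(fo)
  state$wr2 <- wr2new
  state$maxShiftOverSu <- max(abs(delta) / pmax(su, 1e-300)) * usedDamp
  state$maxShift <- max(abs(delta)) * usedDamp
  state$cycle <- state$cycle + 1L
  state
}

#' Initialize a least-squares refinement state
#'
#' @param structure starting \code{CrystalStructure}
#' @param reflections pruned \code{ReflectionSet}
#' @param fset a \code{FormFactorSet} covering the expanded index set
#' @param hAdpMode hydrogen ADP treatment
#' @return a state list consumed by \code{\link{lsqCycle}}
#' @export
refinementState <- function(structure, reflections, fset,
                            hAdpMode = "anisotropic") {
  obs <- reflections@observed
  hkl <- reflections@hkl[obs, , drop = FALSE]
  fo <- reflections@fo[obs]
  w <- 1 / reflections@sigma[obs]^2
  param <- buildParameterization(structure, hAdpMode)
  state <- list(structure = structure, param = param, fset = fset,
                hkl = hkl, fo = fo, w = w, k = 1, cycle = 0L,
                flags = list(), su = NULL, gof = NA_real_)
  state$reduction <- originReduction(structure, param)
  aF <- Mod(structureFactorCore(structure, fset, hkl)$F)
  state$k <- optimalScale(fo, aF, w)
  state
}

runInnerCycles <- function(state, maxCycles, tol) {
  for (i in seq_len(maxCycles)) {
    state <- lsqCycle(state)
    if (state$maxShiftOverSu < tol || state$maxShift < 1e-10) break
  }
  state
}

# write su values and refined parameters back into the site table
attachUncertainties <- function(state) {
  structure <- state$structure; param <- state$param
  s <- structure@sites
  su <- state$su
  col <- 2L
  for (A in seq_along(param$blocks)) {
    b <- param$blocks[[A]]
    if (ncol(b$xyz)) {
      cov <- b$xyz %*% diag(su[col:(col + ncol(b$xyz) - 1L)]^2,
                            ncol(b$xyz)) %*% t(b$xyz)
      s$su_x[A] <- sqrt(cov[1, 1]); s$su_y[A] <- sqrt(cov[2, 2])
      s$su_z[A] <- sqrt(cov[3, 3])
      col <- col + ncol(b$xyz)
    }
    if (!is.null(b$u)) {
      cov <- b$u %*% diag(su[col:(col + ncol(b$u) - 1L)]^2,
                          ncol(b$u)) %*% t(b$u)
      if (b$uKind == "ani") {
        s[A, paste0("su_", c("u11", "u22", "u33", "u12", "u13", "u23"))] <-
          as.list(sqrt(pmax(diag(cov), 0)))
      } else {
        s$su_uiso[A] <- sqrt(cov[1, 1])
      }
      col <- col + ncol(b$u)
    }
  }
  structure@sites <- s
  structure
}

# --- the outer loop ------------------------------------------------------

#' Hirshfeld atom refinement
#'
#' The two-step engine: (1) evaluate the molecular density at the current
#' geometry (rebuilding the provider fragment), partition it into Hirshfeld
#' atoms and Fourier-transform them into aspherical form factors; (2) refine
#' coordinates, ADPs and the scale against |F_obs| by weighted least squares
#' at fixed form factors. The two steps alternate until the largest
#' parameter shift falls below \code{convergenceShiftOverSu} (in s.u. units)
#' or \code{maxOuterCycles} is reached.
#'
#' @param structure starting \code{CrystalStructure}
#' @param reflections a \code{ReflectionSet}
#' @param options a \code{RefinementOptions}
#' @param provider a \code{DensityProvider} for the molecular density
#' @return a \linkS4class{RefinementResult}
#' @export
harRefine <- function(structure, reflections, options = refinementOptions(),
                      provider) {
  refineEngine(structure, reflections, options, provider, route = "har")
}

#' Independent-atom-model refinement
#'
#' Identical least-squares machinery with spherical free-atom form factors;
#' the classical reference against which the aspherical route is compared.
#'
#' @inheritParams harRefine
#' @param provider optional provider supplying spherical references for toy
#'   models; free-atom tables are used when NULL
#' @return a \linkS4class{RefinementResult}
#' @export
iamRefine <- function(structure, reflections, options = refinementOptions(),
                      provider = NULL) {
  refineEngine(structure, reflections, options, provider, route = "iam")
}

refineEngine <- function(structure, reflections, options, provider, route) {
  if (options@hAdpMode == "anisotropic")
    structure <- convertHydrogensToAnisotropic(structure)
  reflections <- pruneReflections(reflections, sigmaCut = options@pruneSigma)
  hklObs <- reflections@hkl[reflections@observed, , drop = FALSE]
  environment <- NULL
  cycleLog <- data.frame(outer = integer(0), inner = integer(0),
                         r1 = numeric(0), wr2 = numeric(0),
                         maxShiftOverSu = numeric(0))
  flags <- list()
  converged <- FALSE
  state <- NULL
  prevPar <- NULL
  for (outer in seq_len(options@maxOuterCycles)) {
    growMode <- if (route == "har" &&
                    options@environmentKind == "explicit_cluster" &&
                    options@clusterRadius > 0) "radius_cluster"
                else "complete_molecules"
    fragment <- growFragment(structure, growMode,
                             radius = options@clusterRadius)
    if (route == "har") {
      prov <- if (!is.null(provider@rebuild))
        provider@rebuild(fragment, structure) else provider
      grid <- molecularGrid(fragment, options@gridLevel)
      if (options@environmentKind == "charges_dipoles" &&
          options@clusterRadius > 0) {
        mp <- atomicMultipoles(fragment, prov, grid)
        environment <- buildEnvironment(structure, fragment, options, mp)
      }
      fset <- hirshfeldFormFactors(structure, fragment, prov, grid, hklObs)
    } else {
      prov <- if (!is.null(provider) && !is.null(provider@rebuild))
        provider@rebuild(fragment, structure) else provider
      fset <- iamFormFactorSet(structure, fragment, prov, hklObs)
    }
    if (!is.null(options@dispersion))
      fset <- applyDispersion(fset, options@dispersion,
                              elements = structure@sites$element[fset@siteIndex])
    state0 <- refinementState(structure, reflections, fset, options@hAdpMode)
    if (!is.null(state)) state0$k <- state$k
    state <- runInnerCycles(state0, options@maxInnerCycles,
                            options@convergenceShiftOverSu)
    cycleLog <- rbind(cycleLog, data.frame(outer = outer, inner = state$cycle,
                                           r1 = state$r1, wr2 = state$wr2,
                                           maxShiftOverSu = state$maxShiftOverSu))
    flags <- utils::modifyList(flags, state$flags)
    newPar <- parameterSnapshot(state$structure, state$k)
    if (!is.null(prevPar)) {
      outerShift <- max(abs(newPar - prevPar))
      if (outerShift < 1e-6 &&
          state$maxShiftOverSu < options@convergenceShiftOverSu) {
        converged <- TRUE
        structure <- state$structure
        break
      }
    }
    prevPar <- newPar
    structure <- state$structure
  }
  structure <- attachUncertainties(state)
  rf <- rFactors(state$fo, Mod(structureFactorCore(structure, state$fset,
                                                   state$hkl)$F),
                 state$k, state$w, nParam = state$nPar)
  suK <- state$su[1]
  new("RefinementResult", structure = structure, k = state$k, suK = suK,
      r1 = rf[["R1"]], wr2 = rf[["wR2"]], gof = rf[["GOF"]],
      nObs = length(state$fo), nParam = state$nPar,
      cycleLog = cycleLog, converged = converged, flags = flags)
}

parameterSnapshot <- function(structure, k) {
  s <- structure@sites
  c(k, s$x, s$y, s$z, s$uiso, s$u11, s$u22, s$u33, s$u12, s$u13, s$u23)
}

#' Promote isotropic hydrogens to anisotropic parameterization
#'
#' Replaces U_iso on hydrogen sites by the equivalent U^ij tensor so the six
#' components can be refined freely.
#'
#' @param structure a \code{CrystalStructure}
#' @return the converted structure
#' @export
convertHydrogensToAnisotropic <- function(structure) {
  s <- structure@sites
  idx <- which(s$element == "H" & s$adpType == "iso")
  for (A in idx) {
    s[A, c("u11", "u22", "u33", "u12", "u13", "u23")] <-
      as.list(isoToUCif(structure@cell, s$uiso[A]))
    s$adpType[A] <- "ani"
  }
  structure@sites <- s
  structure
}

# --- crystal-field environment -------------------------------------------

#' Build the crystal-field environment
#'
#' Collects every whole neighbouring molecule or ion with any atom within
#' \code{clusterRadius} of the fragment and attaches stockholder charges
#' and dipoles (rotated by the generating operation) at its atomic sites,
#' or returns the atoms themselves for an explicit cluster. The environment
#' is iterated with the density until the multipoles are stationary
#' (max |dq| < 1e-3 e and max |dmu| < 1e-3 e Angstrom, at most 10 cycles)
#' when a responsive \code{multipoleFun} is supplied.
#'
#' @param structure a \code{CrystalStructure}
#' @param fragment the core \code{MoleculeFragment}
#' @param options a \code{RefinementOptions} (radius and kind)
#' @param multipoles data.frame from \code{\link{atomicMultipoles}} for the
#'   fragment atoms
#' @param multipoleFun optional function(environment) -> updated multipoles,
#'   for densities that respond to the crystal field
#' @return an \linkS4class{EnvironmentModel}
#' @export
buildEnvironment <- function(structure, fragment, options, multipoles,
                             multipoleFun = NULL) {
  kind <- options@environmentKind
  radius <- options@clusterRadius
  emptyEntries <- data.frame(element = character(0), x = numeric(0),
                             y = numeric(0), z = numeric(0), q = numeric(0),
                             mux = numeric(0), muy = numeric(0),
                             muz = numeric(0), site = integer(0),
                             symop = integer(0))
  if (kind == "none" || radius <= 0)
    return(new("EnvironmentModel", kind = "none", entries = emptyEntries,
               radius = radius, log = list()))
  neigh <- neighbourMolecules(structure, fragment, radius)
  if (!nrow(neigh)) {
    warning("no neighbouring molecules within ", radius, " Angstrom")
    return(new("EnvironmentModel", kind = kind, entries = emptyEntries,
               radius = radius, log = list()))
  }
  M <- structure@cell@M; Minv <- structure@cell@Minv
  scLog <- list()
  mp <- multipoles
  for (cycle in 1:10) {
    q <- mp$q[match(neigh$site, mp$atom)]
    mu <- as.matrix(mp[match(neigh$site, mp$atom), c("mux", "muy", "muz")])
    for (i in seq_len(nrow(neigh))) {
      Rc <- M %*% structure@symops[[neigh$symop[i]]]@R %*% Minv
      mu[i, ] <- as.vector(Rc %*% mu[i, ])
    }
    entries <- data.frame(element = neigh$element, x = neigh$x, y = neigh$y,
                          z = neigh$z,
                          q = if (kind == "charges_dipoles") q else 0,
                          mux = if (kind == "charges_dipoles") mu[, 1] else 0,
                          muy = if (kind == "charges_dipoles") mu[, 2] else 0,
                          muz = if (kind == "charges_dipoles") mu[, 3] else 0,
                          site = neigh$site, symop = neigh$symop)
    scLog[[cycle]] <- c(maxQ = max(abs(entries$q)), n = nrow(entries))
    if (is.null(multipoleFun)) break
    mpNew <- multipoleFun(entries)
    dq <- max(abs(mpNew$q - mp$q))
    dmu <- max(abs(as.matrix(mpNew[, c("mux", "muy", "muz")]) -
                     as.matrix(mp[, c("mux", "muy", "muz")])))
    mp <- mpNew
    if (dq < 1e-3 && dmu < 1e-3) break
  }
  fragPts <- as.matrix(fragment@atoms[, c("x", "y", "z")])
  entPts <- as.matrix(entries[, c("x", "y", "z")])
  d2 <- outer(rowSums(entPts^2), rowSums(fragPts^2), "+") -
    2 * entPts %*% t(fragPts)
  if (any(d2 < 0.25))
    stop("environment entry within 0.5 Angstrom of a fragment atom")
  new("EnvironmentModel", kind = kind, entries = entries, radius = radius,
      log = scLog)
}

# whole molecules (symmetry + translation images) with any atom within
# `radius` of the fragment, excluding the fragment's own atoms
neighbourMolecules <- function(structure, fragment, radius) {
  u <- expandUniverse(structure, tmax = 2L)
  u <- u[u$occ > 1e-8, , drop = FALSE]
  cart <- as.matrix(u[, c("x", "y", "z")])
  key <- paste(round(cart[, 1] / 0.05), round(cart[, 2] / 0.05),
               round(cart[, 3] / 0.05))
  pref <- order(u$symop != 1L | u$tx != 0 | u$ty != 0 | u$tz != 0)
  u <- u[pref, ][!duplicated(key[pref]), , drop = FALSE]
  cart <- as.matrix(u[, c("x", "y", "z")])
  pr <- bondPairs(u$element, cart)
  comp <- connectedComponents(nrow(u), pr)
  fragPts <- as.matrix(fragment@atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(cart^2), rowSums(fragPts^2), "+") - 2 * cart %*% t(fragPts)
  dmin <- sqrt(pmax(apply(d2, 1, min), 0))
  inFrag <- dmin < 1e-3
  nearComp <- unique(comp[dmin < radius & !inFrag])
  fragComp <- unique(comp[inFrag])
  # a component counts as fragment only if fully coincident with it
  fullFrag <- fragComp[vapply(fragComp, function(cpd)
    all(inFrag[comp == cpd]), logical(1))]
  sel <- comp %in% setdiff(nearComp, fullFrag) & !inFrag
  u[sel, c("element", "x", "y", "z", "site", "symop"), drop = FALSE]
}
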