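#' Crystallographic agreement factors
#'
#' \deqn{R_1 = \sum ||F_o| - k|F_c|| / \sum |F_o|}
#' \deqn{wR_2 = \sqrt{\sum w (|F_o| - k|F_c|)^2 / \sum w |F_o|^2}}
#' \deqn{GOF = \sqrt{\sum w (|F_o| - k|F_c|)^2 / (N_{obs} - N_{param})}}
#'
#' @param fo,fc observed and calculated |F|
#' @param k scale factor
#' @param w weights (default 1)
#' @param nParam number of refined parameters (for GOF)
#' @return named vector c(R1, wR2, GOF)
#' @export
rFactors <- function(fo, fc, k = 1, w = rep(1, length(fo)), nParam = 0) {
  if (!length(fo)) stop("empty reflection set")
  fc <- abs(fc)
  d <- fo - k * fc
  c(R1 = sum(abs(d)) / sum(fo),
    wR2 = sqrt(sum(w * d^2) / sum(w * fo^2)),
    GOF = sqrt(sum(w * d^2) / max(1, length(fo) - nParam)))
}

#' Residual density map
#'
#' Difference Fourier synthesis on a uniform unit-cell grid:
#' \deqn{\Delta\rho(r) = \frac{1}{V} \sum_h (|F_o|/k - |F_c|)
#'   e^{i\varphi_c(h)} e^{-2\pi i h\cdot r},}
#' summed over the observed reflections expanded by the space-group
#' operations and Friedel mates. The F(000) term is excluded, so the map
#' mean is zero.
#'
#' @param structure a \code{CrystalStructure}
#' @param reflections a \code{ReflectionSet} (observed flags honoured)
#' @param fcalc complex calculated structure factors for the reflection list
#' @param k scale factor
#' @param gridStep target grid step in Angstrom (must be <= 0.3)
#' @return a \linkS4class{ResidualMap}
#' @export
residualMap <- function(structure, reflections, fcalc, k = 1,
                        gridStep = 0.25) {
  if (gridStep > 0.3)
    stop("gridStep > 0.3 Angstrom would alias the residual features")
  cell <- structure@cell
  obs <- reflections@observed
  hkl <- reflections@hkl[obs, , drop = FALSE]
  fo <- reflections@fo[obs]
  fc <- fcalc[obs]
  dF <- (fo / k - Mod(fc)) * exp(1i * Arg(fc))
  # expand over the space group and Friedel pairs
  seen <- new.env(parent = emptyenv())
  H <- matrix(0L, 0, 3); coef <- complex(0)
  for (op in structure@symops) {
    g <- hkl %*% op@R
    ph <- exp(-2i * pi * as.vector(hkl %*% op@t))
    for (sgn in c(1, -1)) {
      gg <- sgn * g
      cc <- if (sgn == 1) dF * ph else Conj(dF * ph)
      keys <- hklKeys(gg)
      newIdx <- which(!vapply(keys, function(kk)
        exists(kk, envir = seen, inherits = FALSE), logical(1)))
      for (kk in keys[newIdx]) assign(kk, TRUE, envir = seen)
      H <- rbind(H, gg[newIdx, , drop = FALSE])
      coef <- c(coef, cc[newIdx])
    }
  }
  n <- pmax(4L, 2L * ceiling(c(cell@a, cell@b, cell@c) / (2 * gridStep)))
  arr <- array(0i, dim = n)
  idx <- sweep(H, 2, n, "%%") + 1L
  for (i in seq_len(nrow(idx)))
    arr[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      arr[idx[i, 1], idx[i, 2], idx[i, 3]] + coef[i]
  map <- Re(fft(arr)) / cell@volume
  new("ResidualMap", values = map, cell = cell, step = gridStep,
      reflHash = paste0("n", nrow(hkl), "_", format(sum(fo), digits = 10)))
}

#' Fractal-dimension curve of a residual map
#'
#' For each density level in a uniform scan of [min, max], the voxels whose
#' value falls within half a bin of the level are counted on the full grid
#' and on subsampled copies (every 2nd, 4th, 8th voxel per axis); the
#' box-counting dimension is the negative log-log slope of the count versus
#' the subsampling factor. A featureless noise map peaks at
#' df(0) close to 3; a flat (self-consistent) map has no definable levels
#' and returns an empty curve with a flag.
#'
#' @param map a \code{ResidualMap} or a numeric 3-d array
#' @param nLevels number of density levels (default 101)
#' @return data.frame(rho0, df) with attribute "degenerate" for flat maps
#' @export
fractalDimensionCurve <- function(map, nLevels = 101) {
  v <- if (is(map, "ResidualMap")) map@values else map
  rng <- range(v)
  if (diff(rng) < 1e-12) {
    out <- data.frame(rho0 = numeric(0), df = numeric(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  levels <- seq(rng[1], rng[2], length.out = nLevels)
  halfBin <- (levels[2] - levels[1]) / 2
  dims <- dim(v)
  decim <- c(1L, 2L, 4L, 8L)
  decim <- decim[decim < min(dims)]
  subs <- lapply(decim, function(b)
    v[seq(1, dims[1], by = b), seq(1, dims[2], by = b), seq(1, dims[3], by = b)])
  df <- vapply(levels, function(l0) {
    counts <- vapply(subs, function(sv) sum(abs(sv - l0) < halfBin), numeric(1))
    if (any(counts == 0)) return(NA_real_)
    -stats::coef(stats::lm(log(counts) ~ log(decim)))[[2]]
  }, numeric(1))
  out <- data.frame(rho0 = levels, df = df)
  attr(out, "degenerate") <- FALSE
  out
}

#' Error-weighted root-mean-square difference
#'
#' \deqn{wRMSD = \sqrt{\frac{1}{N}\sum_i \frac{(v_{X,i} - v_{N,i})^2}
#'   {\sigma_{X,i}^2 + \sigma_{N,i}^2}}}
#' The combined standard uncertainty weights two independent determinations
#' of the same quantities; a value of 1 indicates statistical agreement.
#' Components whose two s.u.s are both zero are excluded with a warning.
#'
#' @param valuesX,valuesN matched component lists
#' @param suX,suN their standard uncertainties
#' @return the scalar wRMSD
#' @export
wrmsd <- function(valuesX, valuesN, suX, suN) {
  stopifnot(length(valuesX) == length(valuesN),
            length(suX) == length(valuesX), length(suN) == length(valuesX))
  csu2 <- suX^2 + suN^2
  bad <- csu2 <= 0
  if (any(bad)) {
    warning(sum(bad), " component(s) with zero combined s.u. excluded")
    valuesX <- valuesX[!bad]; valuesN <- valuesN[!bad]; csu2 <- csu2[!bad]
  }
  if (!length(valuesX)) return(NaN)
  sqrt(mean((valuesX - valuesN)^2 / csu2))
}

uColumns <- c("u11", "u22", "u33", "u12", "u13", "u23")

#' ADP agreement statistics between two models
#'
#' Compares the anisotropic displacement parameters of two refinements of
#' the same structure (e.g. X-ray versus neutron), matched by site label:
#' the mean ratio of diagonal components, the mean absolute differences of
#' diagonal and off-diagonal components (with sample standard deviations),
#' and the wRMSD over all six components weighted by the combined s.u.s.
#' Statistics are reported for hydrogen and non-hydrogen sites separately
#' and are computed on U^ij in the crystal (CIF) basis by default.
#'
#' @param modelX,modelN two \code{CrystalStructure}s with matched labels
#' @param pooling "components" pools all components before averaging;
#'   "atoms" averages per atom first
#' @param basis "cif" or "cartesian"
#' @return list with data.frame \code{summary} and the per-atom differences
#' @export
adpRatioStats <- function(modelX, modelN, pooling = c("components", "atoms"),
                          basis = c("cif", "cartesian")) {
  pooling <- match.arg(pooling); basis <- match.arg(basis)
  sX <- modelX@sites; sN <- modelN@sites
  idx <- match(sX$label, sN$label)
  if (anyNA(idx))
    stop("unmatched site label(s): ",
         paste(sX$label[is.na(idx)], collapse = ", "))
  sN <- sN[idx, ]
  keep <- sX$adpType == "ani" & sN$adpType == "ani"
  sX <- sX[keep, ]; sN <- sN[keep, ]
  getU <- function(s, m) {
    u <- as.matrix(s[, uColumns])
    if (basis == "cartesian") {
      cellOf <- if (identical(m, "X")) modelX@cell else modelN@cell
      u <- t(apply(u, 1, function(r) uMatToSix(uCifToCart(cellOf, r))))
      colnames(u) <- uColumns
    }
    u
  }
  uX <- getU(sX, "X"); uN <- getU(sN, "N")
  suXm <- as.matrix(sX[, paste0("su_", uColumns)])
  suNm <- as.matrix(sN[, paste0("su_", uColumns)])
  classOf <- ifelse(sX$element == "H", "hydrogen", "non-hydrogen")
  blocks <- lapply(split(seq_len(nrow(sX)), classOf), function(ii) {
    dDiag <- abs(uX[ii, 1:3, drop = FALSE] - uN[ii, 1:3, drop = FALSE])
    dOff <- abs(uX[ii, 4:6, drop = FALSE] - uN[ii, 4:6, drop = FALSE])
    ratios <- uX[ii, 1:3, drop = FALSE] / uN[ii, 1:3, drop = FALSE]
    if (pooling == "atoms") {
      ratios <- rowMeans(ratios); dDiag <- rowMeans(dDiag); dOff <- rowMeans(dOff)
    }
    wr <- wrmsd(as.vector(uX[ii, , drop = FALSE]),
                as.vector(uN[ii, , drop = FALSE]),
                as.vector(suXm[ii, , drop = FALSE]),
                as.vector(suNm[ii, , drop = FALSE]))
    data.frame(nAtoms = length(ii),
               ratioMean = mean(ratios), ratioSd = stats::sd(as.vector(ratios)),
               dDiagMean = mean(dDiag), dDiagSd = stats::sd(as.vector(dDiag)),
               dOffMean = mean(dOff), dOffSd = stats::sd(as.vector(dOff)),
               wrmsd = wr)
  })
  summary <- do.call(rbind, blocks)
  summary <- cbind(class = rownames(summary), summary)
  rownames(summary) <- NULL
  list(summary = summary,
       perAtom = data.frame(label = sX$label, element = sX$element,
                            uX - uN, check.names = FALSE))
}

#' Rigid-bond (DMSDA) test
#'
#' For each bond the difference of the two atoms' mean-square displacement
#' amplitudes along the bond direction,
#' \eqn{\Delta_{AB} = \hat u^T U_A^{cart} \hat u - \hat u^T U_B^{cart} \hat u}.
#' Rigid covalent bonds between non-hydrogen atoms should stay below about
#' 0.001 square Angstrom. Bonds with an isotropic-only end are skipped with
#' a warning.
#'
#' @param structure a \code{CrystalStructure} with anisotropic ADPs
#' @param bonds optional data.frame(labelA, labelB); defaults to the
#'   covalent bond list
#' @return list(perBond = data.frame, byClass = data.frame)
#' @export
dmsda <- function(structure, bonds = NULL) {
  if (is.null(bonds)) bonds <- bondList(structure)
  s <- structure@sites
  cell <- structure@cell
  frag <- growFragment(structure, "complete_molecules")
  a <- frag@atoms
  res <- list()
  for (i in seq_len(nrow(bonds))) {
    iA <- match(bonds$labelA[i], s$label); iB <- match(bonds$labelB[i], s$label)
    if (is.na(iA) || is.na(iB))
      stop("bond refers to unknown label: ", bonds$labelA[i], "-", bonds$labelB[i])
    if (s$adpType[iA] != "ani" || s$adpType[iB] != "ani") {
      warning("skipping bond ", bonds$labelA[i], "-", bonds$labelB[i],
              ": isotropic-only atom")
      next
    }
    # bond vector from the fragment geometry (nearest image pair)
    cA <- which(a$site == iA)[1]
    cB <- which(a$site == iB)
    pB <- as.matrix(a[cB, c("x", "y", "z")])
    dAll <- sweep(pB, 2, as.numeric(a[cA, c("x", "y", "z")]))
    cB <- cB[which.min(rowSums(dAll^2))]
    u <- as.numeric(a[cB, c("x", "y", "z")]) - as.numeric(a[cA, c("x", "y", "z")])
    u <- u / sqrt(sum(u^2))
    # transform U to the frames of the generating operations
    rotU <- function(idx, atomRow) {
      op <- structure@symops[[a$symop[atomRow]]]
      Rc <- cell@M %*% op@R %*% cell@Minv
      Rc %*% uCifToCart(cell, as.numeric(s[idx, uColumns])) %*% t(Rc)
    }
    zA <- as.numeric(u %*% rotU(iA, cA) %*% u)
    zB <- as.numeric(u %*% rotU(iB, cB) %*% u)
    res[[length(res) + 1L]] <- data.frame(
      labelA = bonds$labelA[i], labelB = bonds$labelB[i],
      class = if ("H" %in% c(s$element[iA], s$element[iB])) "X-H" else "X-X",
      dist = sqrt(sum((as.numeric(a[cB, c("x", "y", "z")]) -
                         as.numeric(a[cA, c("x", "y", "z")]))^2)),
      delta = zA - zB)
  }
  perBond <- if (length(res)) do.call(rbind, res) else
    data.frame(labelA = character(0), labelB = character(0),
               class = character(0), dist = numeric(0), delta = numeric(0))
  byClass <- do.call(rbind, lapply(split(perBond, perBond$class), function(d)
    data.frame(class = d$class[1], n = nrow(d),
               meanAbs = mean(abs(d$delta)), sd = stats::sd(abs(d$delta)))))
  rownames(byClass) <- NULL
  list(perBond = perBond, byClass = byClass)
}

#' Bond-length comparison statistics
#'
#' Compares matched bonds (by atom labels) between two models of the same
#' structure: the mean bond length, mean ratio, mean absolute difference
#' (each with sample standard deviation) and the wRMSD from the bond s.u.s
#' (propagated from the coordinate s.u.s), reported per bond class (e.g.
#' C-H, N-H, O-H).
#'
#' @param modelX,modelN two \code{CrystalStructure}s with matched labels
#' @param classes optional subset of bond classes ("C-H", "X-X", ...)
#' @return data.frame of per-class statistics
#' @export
bondComparison <- function(modelX, modelN, classes = NULL) {
  bX <- bondGeometry(modelX)
  bN <- bondGeometry(modelN)
  key <- function(b) paste(pmin(b$labelA, b$labelB), pmax(b$labelA, b$labelB))
  idx <- match(key(bX), key(bN))
  if (anyNA(idx)) bX <- bX[!is.na(idx), , drop = FALSE]
  bN <- bN[idx[!is.na(idx)], , drop = FALSE]
  cls <- bX$class
  if (!is.null(classes)) { sel <- cls %in% classes; bX <- bX[sel, ]; bN <- bN[sel, ]; cls <- cls[sel] }
  out <- lapply(split(seq_len(nrow(bX)), cls), function(ii) {
    rX <- bX$dist[ii]; rN <- bN$dist[ii]
    wr <- if (length(ii) > 0) wrmsd(rX, rN, bX$su[ii], bN$su[ii]) else NA_real_
    data.frame(class = cls[ii][1], n = length(ii),
               meanX = mean(rX), sdX = stats::sd(rX),
               ratioMean = mean(rX / rN), ratioSd = stats::sd(rX / rN),
               dAbsMean = mean(abs(rX - rN)), dAbsSd = stats::sd(abs(rX - rN)),
               wrmsd = wr)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# bond list with distances and propagated s.u.s, classed by element pair
bondGeometry <- function(structure) {
  b <- bondList(structure)
  s <- structure@sites
  cell <- structure@cell
  su <- numeric(nrow(b)); cls <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    iA <- match(b$labelA[i], s$label); iB <- match(b$labelB[i], s$label)
    suA <- fracToCart(cell, c(s$su_x[iA], s$su_y[iA], s$su_z[iA]))
    suB <- fracToCart(cell, c(s$su_x[iB], s$su_y[iB], s$su_z[iB]))
    su[i] <- sqrt(sum(suA^2) / 3 + sum(suB^2) / 3)
    pair <- c(b$elementA[i], b$elementB[i])
    cls[i] <- if ("H" %in% pair) paste0(setdiff(pair, "H")[1], "-H")
              else "X-X"
    if (all(pair == "H")) cls[i] <- "H-H"
  }
  b$su <- pmax(su, 1e-12)
  b$class <- cls
  b
}
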