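
# Covalent radii (Angstrom), H-Kr
COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71,
  O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11,
  P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Sc = 1.70,
  Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39, Fe = 1.32, Co = 1.26, Ni = 1.24,
  Cu = 1.32, Zn = 1.22, Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20,
  Br = 1.20, Kr = 1.16)

ATOMIC_NUMBERS <- stats::setNames(seq_along(ELEMENTS), ELEMENTS)

# Expand the asymmetric unit over symops and lattice translations.
expandUniverse <- function(structure, tmax = 2L) {
  s <- structure@sites
  nops <- length(structure@symops)
  cells <- as.matrix(expand.grid(tx = -tmax:tmax, ty = -tmax:tmax, tz = -tmax:tmax))
  rows <- list()
  for (i in seq_len(nrow(s))) {
    orb <- siteOrbit(structure, c(s$x[i], s$y[i], s$z[i]))
    for (j in seq_along(orb$symop)) {
      base <- orb$xyz[j, ] %% 1
      frac <- sweep(cells, 2, base, "+")
      rows[[length(rows) + 1L]] <- data.frame(
        element = s$element[i], fx = frac[, 1], fy = frac[, 2], fz = frac[, 3],
        site = i, symop = orb$symop[j],
        tx = cells[, 1], ty = cells[, 2], tz = cells[, 3],
        occ = s$occ[i], stringsAsFactors = FALSE)
    }
  }
  u <- do.call(rbind, rows)
  cart <- fracToCart(structure@cell, as.matrix(u[, c("fx", "fy", "fz")]))
  u$x <- cart[, 1]; u$y <- cart[, 2]; u$z <- cart[, 3]
  u
}

# Alkali and alkaline-earth cations are treated as isolated ions: their
# contacts to O/N are ionic, and the covalent criterion with their large
# radii would otherwise fuse salt networks into one unbounded "molecule".
IONIC_ELEMENTS <- c("Li", "Na", "K", "Mg", "Ca")

# Bond adjacency under the covalent criterion; hydrogen keeps only its
# shortest contact (at most one bond).
bondPairs <- function(elements, cart, factor = 1.15) {
  n <- nrow(cart)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  rad <- COVALENT_RADII[elements]
  rad[elements %in% IONIC_ELEMENTS] <- 0
  maxCut <- factor * 2 * max(rad)
  pairs <- list()
  block <- 2000L
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(i0 + block - 1L, n)
    d2 <- outer(rowSums(cart[i0:i1, , drop = FALSE]^2), rowSums(cart^2), "+") -
      2 * cart[i0:i1, , drop = FALSE] %*% t(cart)
    cut <- outer(rad[i0:i1], rad, "+") * factor
    hit <- which(d2 < cut^2 & d2 > 1e-6, arr.ind = TRUE)
    if (nrow(hit)) {
      a <- hit[, 1] + i0 - 1L; b <- hit[, 2]
      keep <- a < b
      pairs[[length(pairs) + 1L]] <-
        cbind(a[keep], b[keep], sqrt(d2[hit[keep, , drop = FALSE]]))
    }
  }
  if (!length(pairs)) return(matrix(integer(0), ncol = 2))
  pr <- do.call(rbind, pairs)
  # enforce <= 1 bond per hydrogen: keep the shortest
  isH <- elements == "H"
  for (hi in which(isH)) {
    inv <- which(pr[, 1] == hi | pr[, 2] == hi)
    if (length(inv) > 1) {
      drop <- inv[-which.min(pr[inv, 3])]
      pr <- pr[-drop, , drop = FALSE]
    }
  }
  pr[, 1:2, drop = FALSE]
}

#' Grow a molecular fragment from the asymmetric unit
#'
#' Applies space-group operations and lattice translations until every
#' molecule containing an asymmetric-unit atom is complete
#' (\code{"complete_molecules"}); \code{"radius_cluster"} additionally adds
#' every whole molecule or ion that has any atom within \code{radius} of the
#' core fragment. Bond detection uses distance < 1.15 x (covalent radius
#' sum) with at most one bond per hydrogen. Each added atom records its
#' parent site, generating operation and lattice translation.
#'
#' @param structure a \code{CrystalStructure}
#' @param mode "complete_molecules" or "radius_cluster"
#' @param radius cluster radius in Angstrom (radius_cluster mode)
#' @param netCharge,spinMultiplicity fragment electronic state labels
#' @param maxAtoms growth guard
#' @return a \code{MoleculeFragment}; core (asymmetric-unit) atoms come first
#' @export
growFragment <- function(structure,
                         mode = c("complete_molecules", "radius_cluster"),
                         radius = 0, netCharge = 0, spinMultiplicity = 1,
                         maxAtoms = 1e4) {
  mode <- match.arg(mode)
  if (mode == "radius_cluster" && radius < 0) stop("radius must be >= 0")
  s <- structure@sites
  zero <- s$occ <= 1e-8
  if (any(zero)) warning("excluding zero-occupancy site(s): ",
                         paste(s$label[zero], collapse = ", "))
  nops <- length(structure@symops)
  tmax <- if (nrow(s) * nops > 60) 1L else 2L
  u <- expandUniverse(structure, tmax = tmax)
  u <- u[u$occ > 1e-8, , drop = FALSE]
  # deduplicate coincident images (special positions)
  cart <- as.matrix(u[, c("x", "y", "z")])
  key <- paste(round(cart[, 1] / 0.05), round(cart[, 2] / 0.05),
               round(cart[, 3] / 0.05))
  # prefer the identity image in the home cell as representative
  pref <- order(u$symop != 1L | u$tx != 0 | u$ty != 0 | u$tz != 0)
  u <- u[pref, ][!duplicated(key[pref]), , drop = FALSE]
  cart <- as.matrix(u[, c("x", "y", "z")])
  if (nrow(u) > maxAtoms * 5)
    stop("symmetry expansion produced too many candidate atoms; ",
         "consider a smaller radius")
  pr <- bondPairs(u$element, cart)
  comp <- connectedComponents(nrow(u), pr)
  core <- which(u$symop == 1L & u$tx == 0 & u$ty == 0 & u$tz == 0)
  keepComp <- unique(comp[core])
  if (mode == "radius_cluster" && radius > 0) {
    corePts <- cart[comp %in% keepComp, , drop = FALSE]
    d2 <- outer(rowSums(cart^2), rowSums(corePts^2), "+") -
      2 * cart %*% t(corePts)
    near <- apply(d2, 1, min) < radius^2 + 1e-9
    keepComp <- unique(c(keepComp, comp[near]))
  }
  sel <- comp %in% keepComp
  if (sum(sel) > maxAtoms)
    stop("fragment growth produced more than ", maxAtoms,
         " atoms; consider a smaller radius")
  u <- u[sel, , drop = FALSE]
  # core atoms first, in site order
  isCore <- u$symop == 1L & u$tx == 0 & u$ty == 0 & u$tz == 0
  u <- u[order(!isCore, u$site), , drop = FALSE]
  missing <- setdiff(seq_len(nrow(s))[!zero], unique(u$site))
  if (length(missing))
    stop("internal error: site(s) not represented in the fragment: ",
         paste(s$label[missing], collapse = ", "))
  atoms <- data.frame(element = u$element, x = u$x, y = u$y, z = u$z,
                      site = u$site, symop = u$symop,
                      tx = u$tx, ty = u$ty, tz = u$tz, occ = u$occ,
                      stringsAsFactors = FALSE)
  new("MoleculeFragment", atoms = atoms, netCharge = netCharge,
      spinMultiplicity = spinMultiplicity)
}

connectedComponents <- function(n, pairs) {
  parent <- seq_len(n)
  storage.mode(pairs) <- "integer"
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Covalent bond list of the asymmetric unit
#'
#' Bonds between asymmetric-unit sites (through the complete-molecule
#' fragment, so bonds across the asymmetric-unit boundary are found), as
#' pairs of site labels with distances.
#'
#' @param structure a \code{CrystalStructure}
#' @return data.frame: labelA, labelB, elementA, elementB, dist
#' @export
bondList <- function(structure) {
  frag <- growFragment(structure, "complete_molecules")
  a <- frag@atoms
  cart <- as.matrix(a[, c("x", "y", "z")])
  pr <- bondPairs(a$element, cart)
  if (!nrow(pr))
    return(data.frame(labelA = character(0), labelB = character(0),
                      elementA = character(0), elementB = character(0),
                      dist = numeric(0)))
  lab <- structure@sites$label
  out <- data.frame(
    labelA = lab[a$site[pr[, 1]]], labelB = lab[a$site[pr[, 2]]],
    elementA = a$element[pr[, 1]], elementB = a$element[pr[, 2]],
    dist = sqrt(rowSums((cart[pr[, 1], , drop = FALSE] -
                           cart[pr[, 2], , drop = FALSE])^2)))
  # keep one entry per unique site pair (shortest)
  key <- paste(pmin(out$labelA, out$labelB), pmax(out$labelA, out$labelB),
               sep = "~")
  ord <- order(out$dist)
  out <- out[ord, , drop = FALSE]
  out[!duplicated(key[ord]), , drop = FALSE]
}
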