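#' Parse a symmetry operation string
#'
#' Converts a CIF-style "x, y, z" triplet (e.g. \code{"-x, y+1/2, -z+1/2"})
#' into a \linkS4class{SymOp}. The rotation part is extracted by evaluating
#' the triplet at unit fractional displacements; translations are reduced
#' into [0, 1).
#'
#' @param s the triplet string
#' @return a \code{SymOp}
#' @examples
#' parseSymOp("-x, y+1/2, -z+1/2")
#' @export
parseSymOp <- function(s) {
  parts <- strsplit(gsub("[ '\"]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3)
    stop("symmetry operation must have three comma-separated components: ", s)
  evalAt <- function(x, y, z) {
    env <- list2env(list(x = x, y = y, z = z))
    vapply(parts, function(p) {
      v <- tryCatch(eval(parse(text = p), envir = env),
                    error = function(e) NA_real_)
      if (!is.finite(v)) stop("cannot parse symmetry component: ", p)
      v
    }, numeric(1), USE.NAMES = FALSE)
  }
  t0 <- evalAt(0, 0, 0)
  R <- cbind(evalAt(1, 0, 0) - t0, evalAt(0, 1, 0) - t0, evalAt(0, 0, 1) - t0)
  new("SymOp", R = round(R), t = t0 %% 1)
}

#' Format a symmetry operation as a CIF triplet
#'
#' @param op a \code{SymOp}
#' @return string like \code{"-x, y+1/2, -z+1/2"}
#' @export
symOpToString <- function(op) {
  ax <- c("x", "y", "z")
  fmtFrac <- function(v) {
    if (abs(v) < 1e-9) return("")
    fr <- c(`1/2` = 1/2, `1/3` = 1/3, `2/3` = 2/3, `1/4` = 1/4, `3/4` = 3/4,
            `1/6` = 1/6, `5/6` = 5/6)
    i <- which(abs(fr - (v %% 1)) < 1e-9)
    if (length(i)) paste0("+", names(fr)[i[1]]) else sprintf("%+g", v)
  }
  comp <- vapply(1:3, function(i) {
    s <- ""
    for (j in 1:3) {
      r <- op@R[i, j]
      if (r == 0) next
      s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else "",
                  if (abs(r) != 1) paste0(abs(r), "*") else "", ax[j])
    }
    if (!nzchar(s)) s <- "0"
    paste0(s, fmtFrac(op@t[i]))
  }, character(1))
  paste(comp, collapse = ", ")
}

#' Apply a symmetry operation to fractional coordinates
#'
#' @param op a \code{SymOp}
#' @param x length-3 vector or n x 3 matrix of fractional coordinates
#' @return transformed coordinates (not reduced mod 1)
#' @export
applySymOp <- function(op, x) {
  if (is.matrix(x)) sweep(x %*% t(op@R), 2, op@t, "+")
  else as.numeric(op@R %*% x + op@t)
}

composeSymOps <- function(a, b) {
  # returns a after b: x -> a(b(x))
  new("SymOp", R = a@R %*% b@R, t = (as.numeric(a@R %*% b@t) + a@t) %% 1)
}

symOpKey <- function(op) {
  paste(c(as.integer(op@R), round(op@t * 12)), collapse = ",")
}

#' Check group closure of a symmetry-operation list
#'
#' Verifies that the set is closed under composition modulo lattice
#' translations and contains the identity.
#'
#' @param ops list of \code{SymOp}
#' @return TRUE, or a character message describing the violation
#' @export
checkSymOpClosure <- function(ops) {
  keys <- vapply(ops, symOpKey, character(1))
  idKey <- symOpKey(new("SymOp", R = diag(3), t = c(0, 0, 0)))
  if (!idKey %in% keys) return("identity operation missing")
  for (a in ops) for (b in ops) {
    if (!symOpKey(composeSymOps(a, b)) %in% keys)
      return(sprintf("set not closed under composition: (%s) o (%s)",
                     symOpToString(a), symOpToString(b)))
  }
  TRUE
}

#' Site-symmetry stabilizer
#'
#' Operations leaving a fractional position invariant modulo lattice
#' translations. Drives special-position detection, multiplicities and the
#' refinement constraints.
#'
#' @param structure a \code{CrystalStructure}
#' @param xyz fractional position (length 3)
#' @param tol coincidence tolerance in Angstrom
#' @return integer indices into \code{symmetryOps(structure)}
#' @export
siteStabilizer <- function(structure, xyz, tol = 0.05) {
  cell <- structure@cell
  which(vapply(structure@symops, function(op) {
    d <- (applySymOp(op, xyz) - xyz) %% 1
    d <- pmin(d, 1 - d)
    sqrt(sum((fracToCart(cell, d))^2)) < tol
  }, logical(1)))
}

#' Special-position constraint matrices
#'
#' For a site with a non-trivial stabilizer, returns orthonormal bases for
#' the symmetry-allowed directions of the fractional coordinates and of the
#' six-component U tensor (CIF convention). U is transported through the
#' dimensionless beta representation (beta_ij = U_ij a*_i a*_j) where
#' rotations act as R beta R^T.
#'
#' @param structure a \code{CrystalStructure}
#' @param siteIndex row of \code{atomSites(structure)}
#' @return list(xyz = 3 x k matrix, u = 6 x m matrix, multiplicity = integer)
#' @export
sitePositionConstraints <- function(structure, siteIndex) {
  st <- structure@sites[siteIndex, ]
  stab <- siteStabilizer(structure, c(st$x, st$y, st$z))
  ops <- structure@symops[stab]
  astar <- structure@cell@astar
  # xyz: average of rotation parts projects onto the invariant subspace
  P <- Reduce(`+`, lapply(ops, function(o) o@R)) / length(ops)
  xyzBasis <- nullBasis(P - diag(3))
  # U: group-average the 6-vector action in the beta basis
  A <- vapply(1:6, function(j) {
    u <- numeric(6); u[j] <- 1
    b <- uSixToMat(u * outer6(astar))
    bAvg <- Reduce(`+`, lapply(ops, function(o) o@R %*% b %*% t(o@R))) / length(ops)
    uMatToSix(bAvg) / outer6(astar)
  }, numeric(6))
  uBasis <- nullBasis(A - diag(6))
  list(xyz = xyzBasis, u = uBasis,
       multiplicity = length(structure@symops) / length(ops))
}

outer6 <- function(astar) {
  c(astar[1]^2, astar[2]^2, astar[3]^2,
    astar[1] * astar[2], astar[1] * astar[3], astar[2] * astar[3])
}

uSixToMat <- function(u) {
  matrix(c(u[1], u[4], u[5],
           u[4], u[2], u[6],
           u[5], u[6], u[3]), 3, 3)
}

uMatToSix <- function(m) c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

nullBasis <- function(A, tol = 1e-8) {
  s <- svd(A, nu = 0)
  keep <- s$d < tol * max(1, s$d[1])
  if (!any(keep)) return(matrix(numeric(0), nrow = nrow(s$v), ncol = 0))
  s$v[, keep, drop = FALSE]
}

#' Symmetry-expanded orbit of a site
#'
#' Distinct images of a fractional position under the space group, reduced
#' into [0, 1). Used for structure-factor sums and fragment growth.
#'
#' @param structure a \code{CrystalStructure}
#' @param xyz fractional position
#' @param tol coincidence tolerance (Angstrom)
#' @return list(xyz = n x 3 matrix (not reduced), symop = generating indices)
#' @export
siteOrbit <- function(structure, xyz, tol = 0.05) {
  cell <- structure@cell
  pos <- matrix(numeric(0), ncol = 3)
  opIdx <- integer(0)
  for (i in seq_along(structure@symops)) {
    p <- applySymOp(structure@symops[[i]], xyz)
    pm <- p %% 1
    dup <- FALSE
    if (nrow(pos)) {
      d <- sweep(pos %% 1, 2, pm)
      d <- d - round(d)
      if (any(sqrt(rowSums(fracToCart(cell, d)^2)) < tol)) dup <- TRUE
    }
    if (!dup) { pos <- rbind(pos, p); opIdx <- c(opIdx, i) }
  }
  list(xyz = pos, symop = opIdx)
}

#' Reduce reflections to the Laue-unique set
#'
#' Canonical representatives under the Laue group (point operations plus
#' Friedel inversion): each orbit keeps its lexicographically largest member.
#'
#' @param structure a \code{CrystalStructure} (or anything with symops)
#' @param hkl n x 3 integer matrix
#' @return logical vector marking the unique representatives
#' @export
laueUnique <- function(structure, hkl) {
  reps <- canonicalHkl(structure@symops, hkl)
  !duplicated(reps)
}

canonicalHkl <- function(symops, hkl) {
  if (!is.matrix(hkl)) hkl <- matrix(hkl, ncol = 3)
  n <- nrow(hkl)
  best <- matrix(-Inf, n, 3)
  for (op in symops) for (sgn in c(1, -1)) {
    g <- sgn * (hkl %*% op@R)      # rows: R^T h
    better <- (g[, 1] > best[, 1]) |
      (g[, 1] == best[, 1] & g[, 2] > best[, 2]) |
      (g[, 1] == best[, 1] & g[, 2] == best[, 2] & g[, 3] > best[, 3])
    best[better, ] <- g[better, , drop = FALSE]
  }
  paste(best[, 1], best[, 2], best[, 3])
}
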