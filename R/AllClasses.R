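#' @import methods
NULL

ELEMENTS <- c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na",
              "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti",
              "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge",
              "As", "Se", "Br", "Kr")

elementFromLabel <- function(label) {
  lead <- sub("^([A-Za-z]+).*$", "\\1", label)
  two <- paste0(toupper(substr(lead, 1, 1)), tolower(substr(lead, 2, 2)))
  if (nchar(lead) >= 2 && two %in% ELEMENTS) return(two)
  one <- toupper(substr(lead, 1, 1))
  if (one %in% ELEMENTS) return(one)
  NA_character_
}

#' Unit cell
#'
#' Holds the direct cell parameters together with derived quantities: the
#' metric tensor \code{G} (\eqn{\AA^2}), its reciprocal \code{Gstar}
#' (\eqn{\AA^{-2}}), the orthogonalization matrix \code{M} mapping fractional
#' coordinates to Cartesian \eqn{\AA}, the reciprocal cell lengths
#' \code{astar}, and the cell volume. Reciprocal vectors follow the
#' crystallographic convention without a factor \eqn{2\pi}, so
#' \eqn{|h^*| = 1/d}.
#'
#' @slot a,b,c direct cell lengths (\eqn{\AA})
#' @slot alpha,beta,gamma cell angles (degrees)
#' @slot M 3x3 fractional-to-Cartesian matrix (\eqn{\AA})
#' @slot Minv inverse of \code{M}
#' @slot G,Gstar direct and reciprocal metric tensors
#' @slot astar reciprocal cell lengths (\eqn{\AA^{-1}})
#' @slot volume cell volume (\eqn{\AA^3})
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 M = "matrix", Minv = "matrix", G = "matrix",
                 Gstar = "matrix", astar = "numeric", volume = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!isTRUE(object@volume > 0)) msg <- c(msg, "cell volume must be positive")
    if (max(abs(object@G %*% object@Gstar - diag(3))) > 1e-10)
      msg <- c(msg, "metric tensors are not mutually inverse")
    if (abs(det(object@M)) < 1e-12)
      msg <- c(msg, "orthogonalization matrix is singular")
    if (length(msg)) msg else TRUE
  })

#' Symmetry operation
#'
#' A space-group operation x' = R x + t acting on fractional coordinates.
#' Rotation parts are integer matrices with det(R) = +/-1; translations are
#' reduced into [0, 1).
#'
#' @slot R 3x3 rotation part (fractional basis)
#' @slot t translation vector (fractional)
#' @exportClass SymOp
setClass("SymOp", representation(R = "matrix", t = "numeric"),
  validity = function(object) {
    d <- round(det(object@R))
    if (!d %in% c(-1, 1)) return("det(R) must be +1 or -1")
    if (max(abs(object@R - round(object@R))) > 1e-8)
      return("rotation part must be integral in the fractional basis")
    TRUE
  })

#' Crystal structure
#'
#' The refinable model: unit cell, space-group operations, and the
#' asymmetric-unit atom sites. Sites are kept in a data frame with fractional
#' coordinates, occupancies, displacement parameters (either \code{uiso} or
#' the six \code{u11..u23} components, CIF convention, \eqn{\AA^2}), their
#' standard uncertainties (\code{su*} columns), and site multiplicities.
#'
#' @slot cell a \code{UnitCell}
#' @slot symops list of \code{SymOp}
#' @slot sites data.frame of atom sites
#' @slot spaceGroupName Hermann-Mauguin symbol (informational)
#' @slot Z formula units per cell
#' @exportClass CrystalStructure
setClass("CrystalStructure",
  representation(cell = "UnitCell", symops = "list", sites = "data.frame",
                 spaceGroupName = "character", Z = "numeric"),
  validity = function(object) {
    need <- c("label", "element", "x", "y", "z", "occ", "adpType", "uiso",
              "u11", "u22", "u33", "u12", "u13", "u23")
    miss <- setdiff(need, names(object@sites))
    if (length(miss))
      return(paste("sites is missing columns:", paste(miss, collapse = ", ")))
    if (any(object@sites$occ <= 0 | object@sites$occ > 1 + 1e-8))
      return("occupancies must lie in (0, 1]")
    if (anyDuplicated(object@sites$label))
      return("site labels must be unique")
    if (!all(vapply(object@symops, is, TRUE, "SymOp")))
      return("symops must be a list of SymOp")
    TRUE
  })

#' Reflection set
#'
#' Miller indices with structure-factor magnitudes |F| (electrons), their
#' standard uncertainties, and observed flags. The refinement target is
#' always |F|; squared-dialect input files are converted on reading.
#'
#' @slot hkl integer matrix (n x 3)
#' @slot fo |F_obs| per reflection
#' @slot sigma s.u. of |F_obs|
#' @slot observed logical flag (set by pruning)
#' @slot dialect source dialect of the reflection file
#' @exportClass ReflectionSet
setClass("ReflectionSet",
  representation(hkl = "matrix", fo = "numeric", sigma = "numeric",
                 observed = "logical", dialect = "character"),
  validity = function(object) {
    n <- nrow(object@hkl)
    if (ncol(object@hkl) != 3) return("hkl must have three columns")
    if (length(object@fo) != n || length(object@sigma) != n ||
        length(object@observed) != n)
      return("fo, sigma and observed must match nrow(hkl)")
    if (any(rowSums(abs(object@hkl)) == 0))
      return("the (0,0,0) reflection is not allowed")
    if (any(object@sigma <= 0))
      return("all sigmas must be positive after dialect conversion")
    TRUE
  })

#' Molecular fragment
#'
#' Symmetry-expanded set of atoms (Cartesian \eqn{\AA}) used for the density
#' calculation. Every atom records its parent asymmetric-unit site, the
#' generating symmetry operation and lattice translation.
#'
#' @slot atoms data.frame: element, x, y, z, site, symop, tx, ty, tz, occ
#' @slot netCharge integer total charge
#' @slot spinMultiplicity integer
#' @exportClass MoleculeFragment
setClass("MoleculeFragment",
  representation(atoms = "data.frame", netCharge = "numeric",
                 spinMultiplicity = "numeric"),
  validity = function(object) {
    need <- c("element", "x", "y", "z", "site", "symop", "tx", "ty", "tz")
    miss <- setdiff(need, names(object@atoms))
    if (length(miss))
      return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
    TRUE
  })

#' Spherically averaged free-atom density
#'
#' Radial electron density of a free (neutral) atom, the promolecule
#' ingredient of the stockholder partition. Densities are carried as sums of
#' Gaussian terms (electron counts \code{ne} and real-space exponents
#' \code{alpha}, \eqn{\AA^{-2}}) plus a tabulation on a logarithmic mesh for
#' export and interpolation.
#'
#' @slot element element symbol
#' @slot chargeState integer (0 = neutral; the only supported state)
#' @slot rKnots radii of the tabulation mesh (\eqn{\AA})
#' @slot rho density at the knots (e \eqn{\AA^{-3}})
#' @slot Ne electron count
#' @slot terms data.frame(ne, alpha) Gaussian expansion
#' @exportClass RadialDensity
setClass("RadialDensity",
  representation(element = "character", chargeState = "numeric",
                 rKnots = "numeric", rho = "numeric", Ne = "numeric",
                 terms = "data.frame"),
  validity = function(object) {
    if (any(object@rho < -1e-12)) return("rho must be non-negative")
    if (any(object@terms$alpha <= 0)) return("Gaussian exponents must be positive")
    TRUE
  })

#' Molecular quadrature grid
#'
#' Atom-centred radial x angular product grid with smooth (Becke) cell
#' weights, used for all volume integrals: populations, multipoles and the
#' Fourier transforms of the Hirshfeld atoms.
#'
#' @slot points Cartesian coordinates (n x 3, \eqn{\AA})
#' @slot w quadrature weights (\eqn{\AA^3})
#' @slot owner owning atom index per point
#' @slot level preset name
#' @exportClass QuadratureGrid
setClass("QuadratureGrid",
  representation(points = "matrix", w = "numeric", owner = "integer",
                 level = "character"),
  validity = function(object) {
    if (any(object@w <= 0)) return("all weights must be positive")
    if (nrow(object@points) != length(object@w)) return("points/w mismatch")
    TRUE
  })

#' Density provider
#'
#' Contract that returns total electron-density values at arbitrary Cartesian
#' points for a molecular fragment, plus the spherical per-atom reference
#' densities used by the stockholder weights. Providers can be rebuilt at a
#' new geometry (the outer refinement loop) and may expose closed-form atomic
#' form factors for oracle use.
#'
#' @slot density function(points) -> density values
#' @slot reference function(atomIndex, r) -> spherical reference density
#' @slot rebuild function(fragment, structure) -> new provider, or NULL
#' @slot formFactor function(atomIndex, hstar) -> complex values, or NULL
#' @slot fragment the fragment the provider was built for
#' @slot meta provenance list
#' @exportClass DensityProvider
setClass("DensityProvider",
  representation(density = "function", reference = "function",
                 rebuild = "ANY", formFactor = "ANY",
                 fragment = "MoleculeFragment", meta = "list"))

#' Aspherical form-factor set
#'
#' Complex scattering factor per (asymmetric-unit atom, reflection), the
#' bridge from the partitioned density to the least-squares refinement. The
#' index set is the symmetry-expanded unique reflection list; rotated copies
#' are retrieved through \code{\link{symmetryFormFactor}}.
#'
#' @slot f complex matrix (atoms x reflections), electrons
#' @slot hkl integer index matrix (reflections x 3)
#' @slot siteIndex asymmetric-unit site index per row of \code{f}
#' @slot labels site labels
#' @slot dispersionApplied logical
#' @slot meta grid level and density provenance
#' @exportClass FormFactorSet
setClass("FormFactorSet",
  representation(f = "matrix", hkl = "matrix", siteIndex = "integer",
                 labels = "character", dispersionApplied = "logical",
                 meta = "list"))

#' Crystal-field environment model
#'
#' Point charges and dipoles (or explicit atoms) at the sites of neighbouring
#' molecules, simulating the crystal field around the refined fragment.
#'
#' @slot kind one of "none", "charges_dipoles", "explicit_cluster"
#' @slot entries data.frame: element, x, y, z, q, mux, muy, muz, site, symop
#' @slot radius generation radius (\eqn{\AA})
#' @slot log self-consistency log
#' @exportClass EnvironmentModel
setClass("EnvironmentModel",
  representation(kind = "character", entries = "data.frame",
                 radius = "numeric", log = "list"))

#' Refinement options
#'
#' @slot method electronic-structure method label passed to the provider
#' @slot basis basis-set label
#' @slot clusterRadius crystal-field radius (\eqn{\AA}; 0 disables)
#' @slot environmentKind "none", "charges_dipoles" or "explicit_cluster"
#' @slot hAdpMode hydrogen ADP treatment: "anisotropic", "isotropic", "fixed"
#' @slot pruneSigma observation cutoff: keep F > pruneSigma * sigma(F)
#' @slot dispersion named list element -> c(fp, fpp), or NULL
#' @slot gridLevel quadrature preset
#' @slot maxOuterCycles,maxInnerCycles cycle limits
#' @slot convergenceShiftOverSu outer convergence threshold on max |shift|/su
#' @exportClass RefinementOptions
setClass("RefinementOptions",
  representation(method = "character", basis = "character",
                 clusterRadius = "numeric", environmentKind = "character",
                 hAdpMode = "character", pruneSigma = "numeric",
                 dispersion = "ANY", gridLevel = "character",
                 maxOuterCycles = "numeric", maxInnerCycles = "numeric",
                 convergenceShiftOverSu = "numeric"),
  validity = function(object) {
    basisSets <- c("STO-3G", "def2-SVP", "cc-pVDZ", "def2-TZVP", "cc-pVTZ",
                   "def2-TZVPP", "cc-pVQZ")
    if (!object@basis %in% basisSets)
      return(paste("basis must be one of:", paste(basisSets, collapse = ", ")))
    if (object@clusterRadius < 0) return("clusterRadius must be >= 0")
    if (!object@hAdpMode %in% c("anisotropic", "isotropic", "fixed"))
      return("hAdpMode must be anisotropic, isotropic or fixed")
    if (!object@environmentKind %in% c("none", "charges_dipoles", "explicit_cluster"))
      return("unknown environmentKind")
    TRUE
  })

#' Refinement result
#'
#' @slot structure refined \code{CrystalStructure} carrying s.u. columns
#' @slot k overall scale factor
#' @slot suK s.u. of the scale
#' @slot r1,wr2,gof agreement factors
#' @slot nObs,nParam observation and parameter counts
#' @slot cycleLog per-cycle data.frame (outer, inner, r1, wr2, maxShiftOverSu)
#' @slot converged logical
#' @slot flags quality flags (e.g. non-positive-definite ADPs)
#' @exportClass RefinementResult
setClass("RefinementResult",
  representation(structure = "CrystalStructure", k = "numeric",
                 suK = "numeric", r1 = "numeric", wr2 = "numeric",
                 gof = "numeric", nObs = "numeric", nParam = "numeric",
                 cycleLog = "data.frame", converged = "logical",
                 flags = "list"),
  validity = function(object) {
    if (object@r1 < 0) return("R1 must be non-negative")
    if (object@nObs <= object@nParam)
      return("refinement requires more observations than parameters")
    TRUE
  })

#' Residual density map
#'
#' Difference Fourier synthesis (Fobs/k - Fcalc with calculated phases) on a
#' uniform unit-cell grid, in e \eqn{\AA^{-3}}. The F(000) term is excluded,
#' so the map mean is zero.
#'
#' @slot values 3-d array over the unit cell
#' @slot cell the \code{UnitCell}
#' @slot step requested grid step (\eqn{\AA})
#' @slot reflHash hash of the generating reflection list
#' @exportClass ResidualMap
setClass("ResidualMap",
  representation(values = "array", cell = "UnitCell", step = "numeric",
                 reflHash = "character"))

#' Analytic Gaussian-atom crystal model
#'
#' Toy crystal whose static density is a sum of atom-centred Gaussian shells.
#' Shells may carry a fixed Cartesian offset or a bond-directed offset
#' (mimicking bonding asphericity); form factors and structure factors have
#' closed forms, making the model the analytic oracle for the whole Fourier
#' and refinement machinery.
#'
#' @slot cell a \code{UnitCell}
#' @slot symops list of \code{SymOp}
#' @slot atoms data.frame: label, element, x, y, z (fractional), Z, occ
#' @slot shells list (one data.frame per atom): ne, alpha, offType
#'   ("none"/"fixed"/"bond"), ox, oy, oz, partner, dist
#' @exportClass GaussianAtomModel
setClass("GaussianAtomModel",
  representation(cell = "UnitCell", symops = "list", atoms = "data.frame",
                 shells = "list"),
  validity = function(object) {
    if (nrow(object@atoms) != length(object@shells))
      return("one shell table per atom is required")
    for (sh in object@shells) {
      if (any(sh$alpha <= 0)) return("shell exponents must be positive")
    }
    TRUE
  })
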