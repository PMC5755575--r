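#' Accessors
#'
#' Small accessor generics for the package classes. Slots are never accessed
#' directly by user code.
#'
#' @param x an object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("crystalCell", function(x) standardGeneric("crystalCell"))
#' @rdname accessors
#' @export
setGeneric("atomSites", function(x) standardGeneric("atomSites"))
#' @rdname accessors
#' @export
setGeneric("symmetryOps", function(x) standardGeneric("symmetryOps"))
#' @rdname accessors
#' @export
setGeneric("millerIndices", function(x) standardGeneric("millerIndices"))
#' @rdname accessors
#' @export
setGeneric("fObs", function(x) standardGeneric("fObs"))
#' @rdname accessors
#' @export
setGeneric("fSigma", function(x) standardGeneric("fSigma"))
#' @rdname accessors
#' @export
setGeneric("fragmentAtoms", function(x) standardGeneric("fragmentAtoms"))
#' @rdname accessors
#' @export
setGeneric("refinedStructure", function(x) standardGeneric("refinedStructure"))
#' @rdname accessors
#' @export
setGeneric("rFactor1", function(x) standardGeneric("rFactor1"))
#' @rdname accessors
#' @export
setGeneric("wRFactor2", function(x) standardGeneric("wRFactor2"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("cycleLog", function(x) standardGeneric("cycleLog"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
setMethod("crystalCell", "CrystalStructure", function(x) x@cell)
#' @rdname accessors
setMethod("crystalCell", "GaussianAtomModel", function(x) x@cell)
#' @rdname accessors
setMethod("atomSites", "CrystalStructure", function(x) x@sites)
#' @rdname accessors
setMethod("symmetryOps", "CrystalStructure", function(x) x@symops)
#' @rdname accessors
setMethod("symmetryOps", "GaussianAtomModel", function(x) x@symops)
#' @rdname accessors
setMethod("millerIndices", "ReflectionSet", function(x) x@hkl)
#' @rdname accessors
setMethod("fObs", "ReflectionSet", function(x) x@fo)
#' @rdname accessors
setMethod("fSigma", "ReflectionSet", function(x) x@sigma)
#' @rdname accessors
setMethod("fragmentAtoms", "MoleculeFragment", function(x) x@atoms)
#' @rdname accessors
setMethod("refinedStructure", "RefinementResult", function(x) x@structure)
#' @rdname accessors
setMethod("rFactor1", "RefinementResult", function(x) x@r1)
#' @rdname accessors
setMethod("wRFactor2", "RefinementResult", function(x) x@wr2)
#' @rdname accessors
setMethod("scaleFactor", "RefinementResult", function(x) x@k)
#' @rdname accessors
setMethod("cycleLog", "RefinementResult", function(x) x@cycleLog)
#' @rdname accessors
setMethod("mapValues", "ResidualMap", function(x) x@values)

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              object@a, object@b, object@c, object@alpha, object@beta,
              object@gamma, object@volume))
})

setMethod("show", "CrystalStructure", function(object) {
  cat(sprintf("CrystalStructure: %s, %d symmetry operation(s), %d site(s), Z=%g\n",
              if (nzchar(object@spaceGroupName)) object@spaceGroupName else "?",
              length(object@symops), nrow(object@sites), object@Z))
  show(object@cell)
  el <- table(object@sites$element)
  cat("  sites:", paste(sprintf("%s%d", names(el), as.integer(el)), collapse = " "), "\n")
})

setMethod("show", "ReflectionSet", function(object) {
  cat(sprintf("ReflectionSet: %d reflections (%d observed), dialect '%s', <|F|>=%.3f\n",
              nrow(object@hkl), sum(object@observed), object@dialect,
              mean(object@fo)))
})

setMethod("show", "MoleculeFragment", function(object) {
  el <- table(object@atoms$element)
  cat(sprintf("MoleculeFragment: %d atoms (%s), net charge %+d\n",
              nrow(object@atoms),
              paste(sprintf("%s%d", names(el), as.integer(el)), collapse = " "),
              as.integer(object@netCharge)))
})

setMethod("show", "FormFactorSet", function(object) {
  cat(sprintf("FormFactorSet: %d atom(s) x %d reflection(s), grid '%s', dispersion %s\n",
              nrow(object@f), ncol(object@f),
              if (!is.null(object@meta$gridLevel)) object@meta$gridLevel else "?",
              if (object@dispersionApplied) "applied" else "not applied"))
})

setMethod("show", "RefinementResult", function(object) {
  cat(sprintf("RefinementResult: %s after %d outer cycle(s)\n",
              if (object@converged) "converged" else "NOT converged",
              max(object@cycleLog$outer, 0)))
  cat(sprintf("  R1 = %.5f  wR2 = %.5f  GOF = %.3f  k = %.5f(%d)\n",
              object@r1, object@wr2, object@gof, object@k,
              as.integer(round(object@suK * 1e5))))
  cat(sprintf("  N_obs = %d  N_param = %d\n", as.integer(object@nObs),
              as.integer(object@nParam)))
})

setMethod("show", "ResidualMap", function(object) {
  v <- object@values
  cat(sprintf("ResidualMap: %d x %d x %d grid, min %.4f / max %.4f e A^-3\n",
              dim(v)[1], dim(v)[2], dim(v)[3], min(v), max(v)))
})

setMethod("show", "GaussianAtomModel", function(object) {
  cat(sprintf("GaussianAtomModel: %d atom(s), %d symmetry operation(s)\n",
              nrow(object@atoms), length(object@symops)))
  show(object@cell)
})
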