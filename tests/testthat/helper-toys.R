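# cached toy crystals shared across test files
.toyCache <- new.env(parent = emptyenv())

getToy <- function(preset) {
  if (is.null(.toyCache[[preset]]))
    .toyCache[[preset]] <- makeToyCrystal(preset)
  .toyCache[[preset]]
}

uCols <- c("u11", "u22", "u33", "u12", "u13", "u23")

# largest Cartesian coordinate deviation between two site tables (Angstrom)
maxCoordDev <- function(cell, a, b) {
  d <- as.matrix(a[, c("x", "y", "z")]) - as.matrix(b[, c("x", "y", "z")])
  d <- d - round(d)
  tr <- orthogonalize(cell)
  max(abs(tr$toCartesian(d)))
}

maxUDev <- function(a, b) {
  max(abs(as.matrix(a[, uCols]) - as.matrix(b[, uCols])),
      abs(a$uiso - b$uiso))
}

bondLength <- function(structure, labelA, labelB) {
  frag <- growFragment(structure, "complete_molecules")
  a <- fragmentAtoms(frag)
  s <- atomSites(structure)
  iA <- which(a$site == match(labelA, s$label))[1]
  iB <- which(a$site == match(labelB, s$label))
  pA <- as.numeric(a[iA, c("x", "y", "z")])
  pB <- as.matrix(a[iB, c("x", "y", "z")])
  min(sqrt(rowSums(sweep(pB, 2, pA)^2)))
}

khoxFixture <- function() system.file("extdata", "khox_synthetic.cif",
                                      package = "qcrefine")
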