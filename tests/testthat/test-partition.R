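test_that("stockholder weights normalize pointwise by construction", {
  toy <- getToy("polar_XH_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  set.seed(5)
  pts <- matrix(runif(3e4, -3, 8), ncol = 3)
  W <- hirshfeldWeights(pts, frag, toy$provider)
  expect_true(all(W >= 0 & W <= 1))
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
})

test_that("single-atom fragments take the whole density", {
  toy <- getToy("one_atom_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  W <- hirshfeldWeights(matrix(runif(30, 0, 5), ncol = 3), frag,
                        toy$provider)
  expect_true(all(W == 1))
})

test_that("homonuclear weights split evenly at the bond midpoint", {
  toy <- getToy("diatomic_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  a <- fragmentAtoms(frag)
  mid <- matrix(colMeans(as.matrix(a[, c("x", "y", "z")])), 1)
  W <- hirshfeldWeights(mid, frag, toy$provider)
  expect_equal(as.numeric(W), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("partitioned charges conserve the fragment charge", {
  toy <- getToy("ionic_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  mp <- atomicMultipoles(frag, toy$provider, grid,
                         Z = toy$model@atoms$Z)
  expect_equal(sum(mp$q), 0, tolerance = 1e-3)        # K(+1) + Cl(-1)
  expect_equal(mp$q, c(1, -1), tolerance = 1e-3)
  expect_true(all(abs(mp$q) < c(19, 17)))             # bounded by Z
})

test_that("neutral homonuclear atoms carry zero charge and dipole", {
  toy <- getToy("diatomic_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  mp <- atomicMultipoles(frag, toy$provider, grid)
  expect_lt(max(abs(mp$q)), 1e-3)
  # dipoles are equal and opposite along the bond by symmetry
  expect_equal(mp$mux[1], -mp$mux[2], tolerance = 1e-6)
  expect_lt(max(abs(mp[, c("muy", "muz")])), 1e-6)
})

test_that("a spherical one-atom density has zero dipole", {
  toy <- getToy("one_atom_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  mp <- atomicMultipoles(frag, toy$provider, grid)
  expect_lt(max(abs(mp[, c("mux", "muy", "muz")])), 1e-6)
  expect_lt(abs(mp$q), 1e-6)
})

test_that("dipoles rotate with the fragment", {
  # one atom with a fixed off-centre shell, oriented along x and then z
  mk <- function(axis) {
    off <- c(0, 0, 0); off[axis] <- 0.2
    atoms <- data.frame(label = "C1", element = "C", x = 0.5, y = 0.5,
                        z = 0.5, Z = 6, occ = 1)
    shells <- list(data.frame(ne = 6, alpha = 5, offType = "fixed",
                              ox = off[1], oy = off[2], oz = off[3],
                              partner = NA, dist = 0))
    cell <- unitCell(8, 8, 8)
    model <- new("GaussianAtomModel", cell = cell,
                 symops = list(parseSymOp("x, y, z")), atoms = atoms,
                 shells = shells)
    st <- crystalStructure(cell, sites = cbind(atoms, adpType = "iso",
                                               uiso = 0.01))
    frag <- growFragment(st, "complete_molecules")
    prov <- gaussianDensityProvider(model, st, frag)
    grid <- molecularGrid(frag, "standard")
    atomicMultipoles(frag, prov, grid, Z = 6)
  }
  mx <- mk(1); mz <- mk(3)
  expect_equal(mx$mux, mz$muz, tolerance = 1e-8)
  expect_lt(abs(mx$muy) + abs(mx$muz) + abs(mz$mux) + abs(mz$muy), 1e-8)
  expect_equal(mx$mux, -6 * 0.2, tolerance = 1e-4)   # electron-only moment
})

test_that("a bad grid is detected through the population check", {
  toy <- getToy("diatomic_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  grid <- molecularGrid(frag, "test")
  grid@w <- grid@w * 0.9   # corrupt the quadrature
  expect_error(atomicMultipoles(frag, toy$provider, grid), "deviates")
})
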