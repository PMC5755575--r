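test_that("quadrature form factors match the analytic Gaussian transform", {
  toy <- getToy("one_atom_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  grid <- molecularGrid(frag, "fine")
  hkl <- uniqueHklTo(st, 0.7)                 # |h*| up to 1.4 1/Angstrom
  fs <- hirshfeldFormFactors(st, frag, toy$provider, grid, hkl)
  fan <- toy$provider@formFactor(1, reciprocalVectors(crystalCell(st),
                                                      fs@hkl))
  expect_lt(max(Mod(fs@f[1, ] - fan)) / max(Mod(fan)), 1e-6)
  # spherical density referenced to its nucleus transforms real
  expect_lt(max(abs(Im(fs@f[1, ]))), 1e-8)
})

test_that("the zero-frequency limit is the Hirshfeld population", {
  toy <- getToy("polar_XH_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  fs <- hirshfeldFormFactors(st, frag, toy$provider, grid,
                             rbind(c(0, 0, 0), c(1, 0, 0)),
                             expandSymmetry = FALSE)
  pops <- Re(fs@f[, 1])
  expect_lt(max(abs(Im(fs@f[, 1]))), 1e-10)
  expect_true(all(pops > 0))
  expect_equal(sum(pops), 9, tolerance = 0.01)  # O(8e) + H(1e)
})

test_that("doubling the grid level changes |f| by less than 1e-4", {
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  hkl <- uniqueHklTo(st, 0.7)
  f1 <- hirshfeldFormFactors(st, frag, toy$provider,
                             molecularGrid(frag, "standard"), hkl)
  f2 <- hirshfeldFormFactors(st, frag, toy$provider,
                             molecularGrid(frag, "fine"), hkl)
  expect_lt(max(Mod(f1@f - f2@f)), 1e-4)
})

test_that("Hirshfeld and spherical routes agree for promolecule densities", {
  # the diatomic's density is an exact superposition of spherical atoms,
  # so its stockholder atoms are the free atoms themselves
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  hkl <- uniqueHklTo(st, 0.7)
  fH <- hirshfeldFormFactors(st, frag, toy$provider,
                             molecularGrid(frag, "fine"), hkl)
  fI <- iamFormFactorSet(st, frag, toy$provider, hkl)
  expect_lt(max(Mod(fH@f - fI@f)), 1e-4)
})

test_that("symmetry lookups honour rotation, identity and Friedel", {
  toy <- getToy("polar_XH_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  hkl <- rbind(c(1, 2, 1), c(2, -1, 3), c(0, 1, 2))
  c2 <- parseSymOp("-x, -y, z")
  fs <- hirshfeldFormFactors(st, frag, toy$provider, grid,
                             rbind(hkl, hkl %*% c2@R, -hkl),
                             expandSymmetry = FALSE)
  idOp <- parseSymOp("x, y, z")
  expect_equal(symmetryFormFactor(fs, 2, idOp, hkl),
               fs@f[2, 1:3])
  inv <- parseSymOp("-x, -y, -z")
  expect_equal(symmetryFormFactor(fs, 2, inv, hkl),
               Conj(fs@f[2, 1:3]), tolerance = 1e-12)
  # brute-force recomputation of the rotated integral
  v2 <- symmetryFormFactor(fs, 2, c2, hkl)
  hstar <- reciprocalVectors(crystalCell(st), hkl %*% c2@R)
  W <- hirshfeldWeights(grid@points, frag, toy$provider)
  rho <- toy$provider@density(grid@points)
  vA <- grid@w * W[, 2] * rho
  ctr <- as.numeric(fragmentAtoms(frag)[2, c("x", "y", "z")])
  brute <- vapply(seq_len(nrow(hstar)), function(j)
    sum(vA * exp(2i * pi * as.vector(sweep(grid@points, 2, ctr) %*%
                                       hstar[j, ]))), complex(1))
  expect_lt(max(Mod(v2 - brute)), 1e-8)
  # a rotated index outside the set demands expansion
  fsSmall <- hirshfeldFormFactors(st, frag, toy$provider, grid, hkl,
                                  expandSymmetry = FALSE)
  expect_error(symmetryFormFactor(fsSmall, 1, c2, rbind(c(1, 2, 1))),
               "symmetry-expanded")
})

test_that("dispersion terms add once and exactly once", {
  toy <- getToy("polar_XH_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  fs <- iamFormFactorSet(st, frag, toy$provider, rbind(c(1, 0, 0)))
  f0 <- fs@f[1, 1]
  # terms absent: identity
  expect_identical(applyDispersion(fs, NULL)@f, fs@f)
  terms <- list(O = c(0.1, 0.2))
  fs2 <- applyDispersion(fs, terms, elements = c("O", "H"))
  expect_equal(fs2@f[1, 1], f0 + complex(real = 0.1, imaginary = 0.2))
  expect_equal(fs2@f[2, 1], fs@f[2, 1])      # H untouched
  expect_error(applyDispersion(fs2, terms, elements = c("O", "H")),
               "already")
})

test_that("form factors at h = 0 sum to the fragment electron count", {
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  fs <- hirshfeldFormFactors(st, frag, toy$provider, grid,
                             rbind(c(0, 0, 0)), expandSymmetry = FALSE)
  expect_equal(sum(Re(fs@f[, 1])), 14, tolerance = 0.01)
})
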