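test_that("unknown presets are rejected with the available list", {
  expect_error(makeToyCrystal("nope"), "one_atom_P1")
})

test_that("presets define the documented starting points", {
  one <- getToy("one_atom_P1")
  expect_equal(nrow(atomSites(one$structure)), 1)
  expect_equal(length(symmetryOps(one$structure)), 1)
  expect_equal(atomSites(one$structure)$uiso, 0.01)
  xh <- getToy("polar_XH_P1")
  expect_equal(atomSites(xh$structure)$element, c("O", "H"))
  expect_equal(bondLength(xh$structure, "O1", "H1"), 1.00, tolerance = 1e-6)
})

test_that("model densities are non-negative and integrate to the electron count", {
  toy <- getToy("polar_XH_P1")
  set.seed(13)
  pts <- matrix(runif(3e5, -4, 10), ncol = 3)
  expect_true(all(toy$provider@density(pts) >= 0))
  frag <- growFragment(toy$structure, "complete_molecules")
  g <- molecularGrid(frag, "fine")
  tot <- gridIntegrate(g, toy$provider@density)
  expect_equal(tot, 9, tolerance = 1e-8)
})

test_that("centrosymmetric arrangements give real structure factors", {
  toy <- getToy("diatomic_P1bar")
  H <- uniqueHklTo(toy$structure, 0.6)
  F <- oracleStructureFactors(toy$model, toy$structure, H)
  phases <- Arg(F) %% pi
  expect_true(all(pmin(phases, pi - phases) < 1e-8))
})

test_that("simulated reflections are exact at zero noise and reproducible", {
  toy <- getToy("diatomic_P1")
  r0 <- simulateReflections(toy$structure, toy$model, 0.6, 0, 1)
  Ft <- Mod(oracleStructureFactors(toy$model, toy$structure,
                                   millerIndices(r0)))
  expect_identical(fObs(r0), Ft)
  ra <- simulateReflections(toy$structure, toy$model, 0.6, 0.02, 5)
  rb <- simulateReflections(toy$structure, toy$model, 0.6, 0.02, 5)
  expect_identical(fObs(ra), fObs(rb))
  rc <- simulateReflections(toy$structure, toy$model, 0.6, 0.02, 6)
  expect_false(identical(fObs(ra), fObs(rc)))
})

test_that("the applied noise has the requested relative spread", {
  toy <- getToy("diatomic_P1")
  H <- uniqueHklTo(toy$structure, 0.7)
  Ft <- Mod(oracleStructureFactors(toy$model, toy$structure, H))
  eps <- unlist(lapply(1:15, function(sd) {
    r <- simulateReflections(toy$structure, toy$model, 0.7, 0.02, sd)
    fObs(r) / Ft - 1
  }))
  expect_gt(length(eps), 1e4)
  expect_gt(stats::sd(eps), 0.019)
  expect_lt(stats::sd(eps), 0.021)
  r <- simulateReflections(toy$structure, toy$model, 0.7, 0.02, 1)
  expect_equal(fSigma(r), 0.02 * Ft)
})

test_that("perturbation respects magnitudes, seeds and constraints", {
  toy <- getToy("mirror_site")
  st <- toy$structure
  expect_equal(atomSites(perturbModel(st, 0, 0, 1)),
               atomSites(st))
  p1 <- perturbModel(st, 0.05, 0.005, seed = 7)
  p2 <- perturbModel(st, 0.05, 0.005, seed = 7)
  expect_identical(atomSites(p1), atomSites(p2))
  # displacement bound, checked where no floating-origin correction applies
  tb <- getToy("diatomic_P1bar")
  pb <- perturbModel(tb$structure, 0.05, 0.005, seed = 8)
  expect_lt(maxCoordDev(crystalCell(tb$structure), atomSites(pb),
                        atomSites(tb$structure)), 0.05 * sqrt(3) + 1e-9)
  # the mirror site stays on its plane, forbidden U components stay zero
  s1 <- atomSites(p1)
  expect_equal(s1$y[1], 0)
  expect_equal(s1$u12[1], 0)
  expect_equal(s1$u23[1], 0)
})

test_that("fixtures written to disk parse back and carry provenance", {
  dir <- tempfile("fixtures")
  paths <- simulateToFiles("diatomic_P1", dir, resolution = 0.5,
                           noiseFraction = 0.02, seed = 3)
  expect_true(all(file.exists(paths)))
  first <- readLines(paths[["cif"]], n = 1)
  expect_match(first, "preset=diatomic_P1")
  expect_match(first, "seed=3")
  st <- parseCif(paths[["cif"]])
  expect_equal(nrow(atomSites(st)), 2)
  refl <- parseHkl(paths[["hkl"]])   # auto-detects the F^2 fixed format
  expect_gt(nrow(millerIndices(refl)), 50)
  unlink(dir, recursive = TRUE)
})
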