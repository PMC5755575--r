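test_that("free-atom densities normalize to the electron count", {
  for (el in c("H", "C", "N", "O", "K")) {
    rd <- freeAtomDensity(el)
    f0 <- iamFormFactor(rd, 0)
    expect_equal(f0, rd@Ne, tolerance = 1e-4)
  }
})

test_that("densities decay monotonically away from the nucleus", {
  rd <- freeAtomDensity("C")
  rho <- evalRadialDensity(rd, c(0, 1))
  expect_true(is.finite(rho[1]))
  expect_gt(rho[1], rho[2])
  r <- seq(0.05, 4, by = 0.05)
  expect_true(all(diff(evalRadialDensity(rd, r)) < 0))
})

test_that("quadrature form factors match the published expansion", {
  # independent oracle: the tabulated 4-Gaussian scattering formula
  cm <- function(s, a, b, cc) sum(a * exp(-b * s^2)) + cc
  fC <- iamFormFactor("C", 0.5)
  ref <- cm(0.5, c(2.3100, 1.0200, 1.5886, 0.8650),
            c(20.8439, 10.2075, 0.5687, 51.6512), 0.2156)
  expect_lt(abs(fC - ref) / ref, 0.02)
  expect_lt(iamFormFactor("H", 1.4), 0.02)   # near-vanishing at 1.4 1/A
})

test_that("unsupported elements and charge states are refused", {
  expect_error(freeAtomDensity("U"), "H-Kr")
  expect_error(freeAtomDensity("C", chargeState = 1), "neutral")
})

test_that("knot interpolation reproduces the exact expansion", {
  rd <- freeAtomDensity("O")
  set.seed(2)
  r <- exp(runif(200, log(2e-4), log(5)))   # off-knot radii
  exact <- evalRadialDensity(rd, r, "terms")
  interp <- evalRadialDensity(rd, r, "spline")
  sel <- exact > 1e-8 * max(exact)
  expect_lt(max(abs(interp[sel] - exact[sel]) / exact[sel]), 1e-6)
})

test_that("molecular grids integrate reference densities accurately", {
  frag <- new("MoleculeFragment",
              atoms = data.frame(element = "H", x = 0, y = 0, z = 0,
                                 site = 1L, symop = 1L, tx = 0, ty = 0,
                                 tz = 0, occ = 1),
              netCharge = 0, spinMultiplicity = 2)
  g <- molecularGrid(frag, "standard")
  hyd <- gridIntegrate(g, function(p) exp(-2 * sqrt(rowSums(p^2))) / pi)
  expect_equal(hyd, 1, tolerance = 1e-6)
  gau <- gridIntegrate(g, function(p) (4 / pi)^1.5 * exp(-4 * rowSums(p^2)))
  expect_equal(gau, 1, tolerance = 1e-8)
  # refinement property: finer preset changes the integral by < 1e-7
  gf <- molecularGrid(frag, "fine")
  gau2 <- gridIntegrate(gf, function(p) (4 / pi)^1.5 * exp(-4 * rowSums(p^2)))
  expect_lt(abs(gau2 - gau), 1e-7)
})

test_that("overlapping nuclei are rejected", {
  frag <- new("MoleculeFragment",
              atoms = data.frame(element = c("C", "C"),
                                 x = c(0, 0.1), y = 0, z = 0,
                                 site = 1:2, symop = 1L, tx = 0, ty = 0,
                                 tz = 0, occ = 1),
              netCharge = 0, spinMultiplicity = 1)
  expect_error(molecularGrid(frag), "verlapping")
})

test_that("promolecule density superposes spherical atoms", {
  toy <- getToy("diatomic_P1")
  frag <- growFragment(toy$structure, "complete_molecules")
  a <- fragmentAtoms(frag)
  mid <- colMeans(as.matrix(a[, c("x", "y", "z")]))
  half <- sqrt(sum((as.numeric(a[1, c("x", "y", "z")]) - mid)^2))
  atMid <- promoleculeDensity(matrix(mid, 1), frag, toy$provider)
  single <- toy$provider@reference(1, half)
  expect_equal(atMid, 2 * single, tolerance = 1e-12)
  # one-atom promolecule equals the radial density itself
  frag1 <- new("MoleculeFragment", atoms = a[1, ], netCharge = 0,
               spinMultiplicity = 1)
  p <- as.numeric(a[1, c("x", "y", "z")]) + c(0.7, 0, 0)
  expect_equal(promoleculeDensity(matrix(p, 1), frag1, toy$provider),
               toy$provider@reference(1, 0.7), tolerance = 1e-12)
  # two pseudo-atoms integrate to the full electron count
  g <- molecularGrid(frag, "standard")
  tot <- gridIntegrate(g, promoleculeDensity(g@points, frag, toy$provider))
  expect_equal(tot, 14, tolerance = 1e-4)
})
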