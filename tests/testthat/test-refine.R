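test_that("Debye-Waller factors follow the closed forms", {
  cl <- unitCell(10, 10, 10)
  expect_equal(debyeWaller(cl, c(1, 0, 0), 0), 1)
  # cubic a = 10, h = (1,0,0), U_iso = 0.01: s = 0.05 1/A
  expect_equal(debyeWaller(cl, c(1, 0, 0), 0.01), exp(-0.019739 / 10),
               tolerance = 1e-4)
  # isotropic U as an equivalent tensor in a monoclinic cell
  clm <- unitCell(4.265, 12.796, 7.49, 90, 100.77, 90)
  hkl <- rbind(c(1, 2, 3), c(-2, 1, 4), c(3, 0, -2), c(0, 5, 1))
  expect_equal(debyeWaller(clm, hkl, 0.015),
               debyeWaller(clm, hkl, isoToUCif(clm, 0.015)),
               tolerance = 1e-12)
  expect_true(all(debyeWaller(clm, hkl, 0.02) > 0 &
                    debyeWaller(clm, hkl, 0.02) <= 1))
})

test_that("U tensor conversions invert each other", {
  cl <- unitCell(6.1, 7.3, 9.2, 81.2, 95.7, 103.4)
  u6 <- c(0.012, 0.010, 0.015, 0.002, -0.001, 0.003)
  expect_equal(uCartToCif(cl, uCifToCart(cl, u6)), u6, tolerance = 1e-12)
  expect_equal(uCifToCart(cl, isoToUCif(cl, 0.02)), 0.02 * diag(3),
               tolerance = 1e-12)
})

test_that("structure-factor sums obey elementary limits", {
  # one atom at the origin in P1: |F| = |f| T
  cell <- unitCell(8, 8, 8)
  atoms <- data.frame(label = "C1", element = "C", x = 0, y = 0, z = 0,
                      Z = 6, occ = 1)
  shells <- list(data.frame(ne = 6, alpha = 5, offType = "none",
                            ox = 0, oy = 0, oz = 0, partner = NA, dist = 0))
  model <- new("GaussianAtomModel", cell = cell,
               symops = list(parseSymOp("x, y, z")), atoms = atoms,
               shells = shells)
  st <- crystalStructure(cell, sites = cbind(atoms, adpType = "iso",
                                             uiso = 0))
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 1, 2))
  F <- oracleStructureFactors(model, st, hkl)
  hstar <- reciprocalVectors(cell, hkl)
  expect_equal(Mod(F), Mod(6 * exp(-pi^2 * rowSums(hstar^2) / 5)),
               tolerance = 1e-12)
  # two identical atoms at +/- 1/4 along x: F(1,0,0) = 0 by interference
  atoms2 <- data.frame(label = c("C1", "C2"), element = "C",
                       x = c(0.25, 0.75), y = 0, z = 0, Z = 6, occ = 1)
  model2 <- new("GaussianAtomModel", cell = cell,
                symops = list(parseSymOp("x, y, z")), atoms = atoms2,
                shells = rep(shells, 2))
  st2 <- crystalStructure(cell, sites = cbind(atoms2, adpType = "iso",
                                              uiso = 0))
  F2 <- oracleStructureFactors(model2, st2, rbind(c(1, 0, 0), c(2, 0, 0)))
  expect_lt(Mod(F2[1]), 1e-12)
  expect_gt(Mod(F2[2]), 1)
})

test_that("assembled structure factors match the analytic oracle", {
  toy <- getToy("mirror_site")     # exercises symmetry copies and rotated U
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  hkl <- uniqueHklTo(st, 0.6)
  fs <- hirshfeldFormFactors(st, frag, toy$provider,
                             molecularGrid(frag, "standard"), hkl)
  Fq <- structureFactors(st, fs, hkl)
  Fo <- oracleStructureFactors(toy$model, st, hkl)
  expect_lt(max(Mod(Fq - Fo)) / max(Mod(Fo)), 1e-5)
})

test_that("the closed-form scale minimizes the weighted residual", {
  expect_equal(optimalScale(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(optimalScale(c(2, 4, 6), c(1, 2, 3), w = c(3, 1, 7)), 2)
  set.seed(3)
  fo <- runif(50, 1, 10); fc <- fo * 0.5 + rnorm(50, 0, 0.3)
  w <- runif(50, 0.5, 2)
  kNum <- stats::optimize(function(k) sum(w * (fo - k * abs(fc))^2),
                          c(0, 10), tol = 1e-12)$minimum
  expect_equal(optimalScale(fo, fc, w), kNum, tolerance = 1e-8)
  expect_error(optimalScale(c(1, 2), c(0, 0)), "zero")
})

test_that("least squares is stationary at the generating truth", {
  toy <- getToy("one_atom_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.7, 0, 1)
  fs <- iamFormFactorSet(st, growFragment(st, "complete_molecules"),
                         toy$provider, millerIndices(refl))
  state <- refinementState(st, refl, fs, "anisotropic")
  state <- lsqCycle(state)
  expect_lt(state$maxShift, 1e-8)
})

test_that("cycles reduce the weighted residual monotonically", {
  toy <- getToy("one_atom_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.7, 0, 1)
  disp <- st
  disp@sites$uiso[1] <- disp@sites$uiso[1] + 0.004
  fs <- iamFormFactorSet(disp, growFragment(disp, "complete_molecules"),
                         toy$provider, millerIndices(refl))
  state <- refinementState(disp, refl, fs, "anisotropic")
  wr2 <- Inf
  for (i in 1:6) {
    state <- lsqCycle(state)
    expect_lte(state$wr2, wr2 * (1 + 1e-12))
    wr2 <- state$wr2
  }
  expect_lt(state$maxShift, 1e-6)
})

test_that("standard uncertainties track the noise-driven spread", {
  toy <- getToy("one_atom_P1")
  st <- toy$structure
  opts <- refinementOptions(gridLevel = "test")
  u <- numeric(60); su <- numeric(60)
  for (sd in 1:60) {
    refl <- simulateReflections(st, toy$model, 0.7, 0.02, seed = sd)
    r <- iamRefine(st, refl, opts, toy$provider)
    s1 <- atomSites(refinedStructure(r))
    u[sd] <- s1$uiso[1]; su[sd] <- s1$su_uiso[1]
  }
  expect_lt(abs(stats::sd(u) / mean(su) - 1), 0.3)
})

test_that("hydrogen ADP modes constrain exactly as requested", {
  toy <- getToy("polar_XH_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.6, 0, 1)
  pert <- perturbModel(st, 0.02, 0.002, seed = 6)
  u0 <- as.numeric(atomSites(pert)[2, uCols])
  res <- harRefine(pert, refl,
                   refinementOptions(gridLevel = "test", hAdpMode = "fixed"),
                   toy$provider)
  s1 <- atomSites(refinedStructure(res))
  expect_equal(as.numeric(s1[2, uCols]), u0, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(s1$x[2], atomSites(pert)$x[2])))
})

test_that("spherical densities make the aspherical route collapse onto IAM", {
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.5, 0.02, 9)
  pert <- perturbModel(st, 0.01, 0.001, seed = 4)
  opts <- refinementOptions(gridLevel = "fine")
  # an early cycle transiently clamps one ADP in both routes alike
  rH <- suppressWarnings(harRefine(pert, refl, opts, toy$provider))
  rI <- suppressWarnings(iamRefine(pert, refl, opts, toy$provider))
  sH <- atomSites(refinedStructure(rH)); sI <- atomSites(refinedStructure(rI))
  cols <- c("x", "y", "z", uCols)
  expect_lt(max(abs(as.matrix(sH[, cols]) - as.matrix(sI[, cols]))), 1e-6)
})

test_that("singular problems are reported with parameter names", {
  # a diatomic started exactly at its pseudo-symmetric truth has a
  # transverse degree of freedom with identically zero gradient
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.5, 0.02, 2)
  fs <- iamFormFactorSet(st, growFragment(st, "complete_molecules"),
                         toy$provider, millerIndices(refl))
  state <- refinementState(st, refl, fs, "anisotropic")
  expect_error(lsqCycle(state), "degenerate|unconstrained")
})

test_that("crystal-field environments enumerate whole neighbour molecules", {
  toy <- getToy("ionic_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  mp <- atomicMultipoles(frag, toy$provider, grid, Z = toy$model@atoms$Z)
  # radius zero disables the cluster
  opts0 <- refinementOptions(clusterRadius = 0,
                             environmentKind = "charges_dipoles")
  env0 <- buildEnvironment(st, frag, opts0, mp)
  expect_equal(nrow(env0@entries), 0)
  # 8 A cluster: entry count equals brute-force supercell enumeration
  opts8 <- refinementOptions(clusterRadius = 8,
                             environmentKind = "charges_dipoles")
  env8 <- buildEnvironment(st, frag, opts8, mp)
  cl <- crystalCell(st)
  cells <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  s <- atomSites(st)
  allf <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    sweep(as.matrix(s[, c("x", "y", "z")]), 2, cells[i, ], "+")))
  tr <- orthogonalize(cl)
  allc <- tr$toCartesian(allf)
  fragc <- as.matrix(fragmentAtoms(frag)[, c("x", "y", "z")])
  d <- sqrt(pmax(outer(rowSums(allc^2), rowSums(fragc^2), "+") -
                   2 * allc %*% t(fragc), 0))
  dmin <- apply(d, 1, min)
  expect_equal(nrow(env8@entries), sum(dmin < 8 & dmin > 1e-3))
  # charges carried over from the stockholder monopoles
  expect_equal(sort(unique(round(env8@entries$q, 2))), c(-1, 1))
})

test_that("neutral molecular crystals give a neutral environment", {
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  frag <- growFragment(st, "complete_molecules")
  grid <- molecularGrid(frag, "standard")
  mp <- atomicMultipoles(frag, toy$provider, grid)
  opts <- refinementOptions(clusterRadius = 7,
                            environmentKind = "charges_dipoles")
  env <- buildEnvironment(st, frag, opts, mp)
  expect_gt(nrow(env@entries), 0)
  expect_lt(abs(sum(env@entries$q)), 1e-3)
})
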