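test_that("R factors follow their definitions", {
  expect_equal(unname(rFactors(c(5, 7), c(5, 7))[c("R1", "wR2")]), c(0, 0))
  rf <- rFactors(c(10, 10), c(9, 11))
  expect_equal(rf[["R1"]], 0.1)
  expect_equal(rf[["wR2"]], sqrt(2 / 200))
  # halving sigma leaves R1, doubles GOF
  fo <- c(10, 12, 9); fc <- c(9.5, 12.5, 9.2); sg <- c(0.5, 0.4, 0.6)
  a <- rFactors(fo, fc, w = 1 / sg^2)
  b <- rFactors(fo, fc, w = 1 / (sg / 2)^2)
  expect_equal(a[["R1"]], b[["R1"]])
  expect_equal(b[["GOF"]], 2 * a[["GOF"]], tolerance = 1e-12)
  expect_error(rFactors(numeric(0), numeric(0)), "empty")
})

test_that("wRMSD matches hand arithmetic and is scale invariant", {
  expect_equal(wrmsd(c(1, 2, 3), c(1, 2, 3), rep(1, 3), rep(1, 3)), 0)
  expect_equal(wrmsd(1, 0, 0.6, 0.8), 1)            # |delta| = csu
  expect_equal(wrmsd(c(1, 2, 2), c(0, 0, 0), c(1, 1, 2), c(0, 0, 0)),
               sqrt(2), tolerance = 1e-12)
  set.seed(4)
  vX <- rnorm(20); vN <- rnorm(20); sX <- runif(20, .1, 1); sN <- runif(20, .1, 1)
  expect_equal(wrmsd(vX, vN, sX, sN), wrmsd(5 * vX, 5 * vN, 5 * sX, 5 * sN),
               tolerance = 1e-12)
  expect_warning(w <- wrmsd(c(1, 2), c(1, 1), c(1, 0), c(1, 0)), "excluded")
  expect_equal(w, 0)
})

test_that("ADP comparison statistics match independent recomputation", {
  st <- parseCif(khoxFixture())
  expect_identical(atomSites(st)$adpType[atomSites(st)$element != "H"],
                   rep("ani", 7))
  same <- adpRatioStats(st, st)
  expect_true(all(abs(same$summary$ratioMean - 1) < 1e-12))
  expect_true(all(same$summary$dDiagMean == 0))
  expect_true(all(same$summary$wrmsd == 0))
  # uniform 10% inflation
  st2 <- st
  st2@sites[, uCols] <- st@sites[, uCols] * 1.1
  infl <- adpRatioStats(st2, st)
  nh <- infl$summary[infl$summary$class == "non-hydrogen", ]
  expect_equal(nh$ratioMean, 1.1, tolerance = 1e-12)
  expect_equal(nh$ratioSd, 0, tolerance = 1e-12)
  # randomized pair against a direct spreadsheet-style recomputation
  set.seed(9)
  stA <- st
  stA@sites[, uCols] <- st@sites[, uCols] + matrix(rnorm(48, 0, 5e-4), 8)
  stA@sites[, paste0("su_", uCols)] <- matrix(runif(48, 1e-4, 5e-4), 8)
  stats <- adpRatioStats(stA, st)
  ani <- which(atomSites(st)$adpType == "ani")
  uA <- as.matrix(stA@sites[ani, uCols]); uB <- as.matrix(st@sites[ani, uCols])
  suA <- as.matrix(stA@sites[ani, paste0("su_", uCols)])
  suB <- as.matrix(st@sites[ani, paste0("su_", uCols)])
  isH <- atomSites(st)$element[ani] == "H"
  manual <- c(mean(uA[!isH, 1:3] / uB[!isH, 1:3]),
              mean(abs(uA[!isH, 1:3] - uB[!isH, 1:3])),
              mean(abs(uA[!isH, 4:6] - uB[!isH, 4:6])),
              sqrt(mean((uA[!isH, ] - uB[!isH, ])^2 /
                          (suA[!isH, ]^2 + suB[!isH, ]^2))))
  got <- stats$summary[stats$summary$class == "non-hydrogen", ]
  expect_equal(c(got$ratioMean, got$dDiagMean, got$dOffMean, got$wrmsd),
               manual, tolerance = 1e-12)
  # unmatched labels are reported
  stBad <- st
  stBad@sites$label[1] <- "Zz9"
  expect_error(adpRatioStats(stBad, st), "Zz9")
})

test_that("the rigid-bond test projects displacements along bonds", {
  cl <- unitCell(10, 10, 10)
  s2 <- data.frame(label = c("A1", "A2"), element = "C",
                   x = c(0.3, 0.45), y = 0.3, z = 0.3, occ = 1,
                   adpType = "ani", uiso = 0,
                   u11 = c(0.02, 0.01), u22 = 0.01, u33 = 0.01,
                   u12 = 0, u13 = 0, u23 = 0)
  st <- crystalStructure(cl, sites = s2)
  d <- dmsda(st, data.frame(labelA = "A1", labelB = "A2"))
  expect_equal(d$perBond$delta, 0.01, tolerance = 1e-12)
  # antisymmetry under swapping the bond ends
  d2 <- dmsda(st, data.frame(labelA = "A2", labelB = "A1"))
  expect_equal(d2$perBond$delta, -0.01, tolerance = 1e-12)
  # identical tensors: zero
  s2$u11 <- 0.01
  d3 <- dmsda(crystalStructure(cl, sites = s2),
              data.frame(labelA = "A1", labelB = "A2"))
  expect_equal(d3$perBond$delta, 0, tolerance = 1e-15)
})

test_that("rigid-body (TLS) displacement fields pass the rigid-bond test", {
  cl <- unitCell(8, 9, 10)
  frac <- rbind(C1 = c(.30, .30, .30), C2 = c(.42, .34, .31),
                O1 = c(.50, .26, .35), N1 = c(.38, .44, .27))
  sites <- data.frame(label = rownames(frac), element = c("C", "C", "O", "N"),
                      x = frac[, 1], y = frac[, 2], z = frac[, 3], occ = 1,
                      adpType = "ani", uiso = 0)
  Tt <- matrix(c(0.010, 0.002, 0.001, 0.002, 0.012, 0.0015,
                 0.001, 0.0015, 0.009), 3, 3)
  L <- matrix(c(0.004, 0.001, 0.0005, 0.001, 0.003, 0.0008,
                0.0005, 0.0008, 0.005), 3, 3)
  tr <- orthogonalize(cl)
  cart <- tr$toCartesian(frac)
  ctr <- colMeans(cart)
  skew <- function(v) matrix(c(0, -v[3], v[2], v[3], 0, -v[1],
                               -v[2], v[1], 0), 3, 3, byrow = TRUE)
  for (i in 1:4) {
    K <- skew(cart[i, ] - ctr)
    sites[i, uCols] <- as.list(uCartToCif(cl, Tt + K %*% L %*% t(K)))
  }
  st <- crystalStructure(cl, sites = sites)
  bonds <- data.frame(labelA = "C1", labelB = c("C2", "O1", "N1"))
  d <- dmsda(st, bonds)
  expect_lt(max(abs(d$perBond$delta)), 1e-6)
  # invariance under rigid rotation of the whole structure (swap axes)
  fracR <- frac[, c(2, 3, 1)]
  clR <- unitCell(9, 10, 8)
  trR <- orthogonalize(clR)
  sitesR <- sites
  sitesR$x <- fracR[, 1]; sitesR$y <- fracR[, 2]; sitesR$z <- fracR[, 3]
  P <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3, byrow = TRUE)
  for (i in 1:4) {
    U <- uCifToCart(cl, as.numeric(sites[i, uCols]))
    sitesR[i, uCols] <- as.list(uCartToCif(clR, P %*% U %*% t(P)))
  }
  dR <- dmsda(crystalStructure(clR, sites = sitesR), bonds)
  expect_equal(dR$perBond$delta, d$perBond$delta, tolerance = 1e-10)
})

test_that("bond-length comparison mirrors direct recomputation", {
  st <- parseCif(khoxFixture())
  same <- bondComparison(st, st)
  expect_true(all(abs(same$ratioMean - 1) < 1e-12))
  expect_true(all(same$dAbsMean == 0))
  # X-ray bonds uniformly 10% shorter
  st2 <- st
  ctr <- colMeans(as.matrix(st@sites[, c("x", "y", "z")]))
  st2@sites[, c("x", "y", "z")] <-
    sweep(sweep(as.matrix(st@sites[, c("x", "y", "z")]), 2, ctr), 1, 0.9,
          "*") + matrix(ctr, 8, 3, byrow = TRUE)
  shr <- bondComparison(st2, st)
  expect_equal(shr$ratioMean, rep(0.9, nrow(shr)), tolerance = 1e-6)
})

test_that("residual maps vanish for self-consistent models", {
  toy <- getToy("diatomic_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.6, 0, 1)
  Fc <- oracleStructureFactors(toy$model, st, millerIndices(refl))
  m <- residualMap(st, refl, Fc, k = 1, gridStep = 0.25)
  expect_lt(max(abs(mapValues(m))), 1e-10)
  expect_lt(abs(mean(mapValues(m))), 1e-6)
  expect_error(residualMap(st, refl, Fc, 1, gridStep = 0.5), "alias")
})

test_that("an unmodelled atom shows up at its site in the residual map", {
  toy <- getToy("one_atom_P1")
  st <- toy$structure
  refl <- simulateReflections(st, toy$model, 0.7, 0, 1)
  hkl <- millerIndices(refl)
  hs <- reciprocalVectors(crystalCell(st), hkl)
  site <- c(0.7, 0.2, 0.6)
  fex <- 2 * exp(-pi^2 * rowSums(hs^2) / 8) *
    exp(2i * pi * as.vector(hkl %*% site))
  Fc <- oracleStructureFactors(toy$model, st, hkl)
  reflMod <- reflectionSet(hkl, Mod(Fc + fex), fSigma(refl))
  m <- residualMap(st, reflMod, Fc, 1, 0.2)
  v <- mapValues(m)
  peak <- which(v == max(v), arr.ind = TRUE)[1, ]
  expFrac <- site * dim(v)
  wrap <- function(d, n) pmin(abs(d), n - abs(d))
  expect_true(all(wrap(peak - 1 - expFrac, dim(v)) <= 1.5))
  expect_lt(abs(mean(v)), 1e-6)
})

test_that("white-noise maps have fractal dimension 3 at zero residual", {
  set.seed(11)
  v <- array(rnorm(64^3), dim = c(64, 64, 64))
  fd <- fractalDimensionCurve(v)
  expect_false(attr(fd, "degenerate"))
  ord <- order(abs(fd$rho0))
  expect_equal(mean(fd$df[ord[1:5]], na.rm = TRUE), 3, tolerance = 0.15)
  # iid noise is scale-free at every level: a broad plateau near 3 that
  # only collapses where the level sets become too sparse to count
  mid <- abs(fd$rho0) < stats::sd(v)
  expect_gt(mean(fd$df[mid], na.rm = TRUE), 2.7)
  # scaling the map rescales the level axis, not the dimensions
  fd2 <- fractalDimensionCurve(2 * v)
  expect_equal(fd2$df, fd$df, tolerance = 1e-12)
  expect_equal(fd2$rho0, 2 * fd$rho0, tolerance = 1e-12)
  # flat maps are degenerate
  flat <- fractalDimensionCurve(array(0, dim = c(8, 8, 8)))
  expect_true(attr(flat, "degenerate"))
  expect_equal(nrow(flat), 0)
})

test_that("a strong unmodelled feature skews the curve to positive levels", {
  set.seed(12)
  v <- array(rnorm(32^3, sd = 0.1), dim = c(32, 32, 32))
  # positive blob (unmodelled density)
  idx <- as.matrix(expand.grid(1:32, 1:32, 1:32))
  d2 <- rowSums(sweep(idx, 2, c(16, 16, 16))^2)
  v <- v + array(1.5 * exp(-d2 / 18), dim = dim(v))
  fd <- fractalDimensionCurve(v)
  ok <- fd$rho0[!is.na(fd$df)]
  expect_gt(max(ok), -min(ok))   # support extends further on the positive side
})
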