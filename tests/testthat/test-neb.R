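# Path interpolation, NEB relaxation and barrier extraction.

doubleWell <- function(x) (x[1L]^2 - 1)^2 + 5 * x[2L]^2
doubleWellGrad <- function(x) c(4 * x[1L] * (x[1L]^2 - 1), 10 * x[2L])

test_that("NEB recovers the analytic saddle of a 2-D double well", {
  ## bowed initial band between the two minima
  t <- seq(0, 1, length.out = 11L)
  X0 <- cbind(-1 + 2 * t, 0.4 * sin(pi * t))
  r <- nebRelaxGeneric(X0, doubleWell, doubleWellGrad, springK = 1,
                       tol = 1e-4)
  expect_true(r$converged)
  expect_lt(abs(max(r$energies) - 1), 0.01)
  ## endpoints never move
  expect_identical(r$X[1L, ], X0[1L, ])
  expect_identical(r$X[11L, ], X0[11L, ])
  ## image refinement leaves the barrier estimate stable
  t2 <- seq(0, 1, length.out = 21L)
  X02 <- cbind(-1 + 2 * t2, 0.4 * sin(pi * t2))
  r2 <- nebRelaxGeneric(X02, doubleWell, doubleWellGrad, springK = 1,
                        tol = 1e-4)
  expect_lt(abs(max(r2$energies) - max(r$energies)), 0.01)
  ## finite-difference gradient fallback agrees
  r3 <- nebRelaxGeneric(X0, doubleWell, springK = 1, tol = 1e-3,
                        maxIter = 2000L)
  expect_lt(abs(max(r3$energies) - 1), 0.02)
})

test_that("a band on a flat potential converges immediately", {
  X0 <- cbind(seq(0, 1, length.out = 5L), seq(0, 2, length.out = 5L))
  r <- nebRelaxGeneric(X0, function(x) 7, function(x) c(0, 0))
  expect_true(r$converged)
  expect_identical(unique(r$energies), 7)
  expect_identical(r$iterations, 1L)
})

test_that("barrier arithmetic follows its definitions exactly", {
  b <- barrierReport(c(0, 0.5, 0.3))
  expect_equal(b$barrierTwistedToFlat, 0.2)
  expect_equal(b$barrierFlatToTwisted, 0.5)
  expect_equal(b$endothermicEnergy, 0.3)
  expect_identical(b$topIndex, 2L)
  mono <- barrierReport(c(0, 0.1, 0.2))
  expect_equal(mono$barrierTwistedToFlat, 0)
  flat <- barrierReport(c(1, 1, 1))
  expect_equal(flat$barrierTwistedToFlat, 0)
  expect_equal(flat$barrierFlatToTwisted, 0)
  expect_equal(flat$endothermicEnergy, 0)
  expect_error(barrierReport(numeric(0)), "empty")
  ## the two barriers always differ by the endothermic energy
  set.seed(21L)
  for (k in 1:25) {
    b <- barrierReport(stats::rnorm(sample(3:12, 1L)))
    expect_identical(b$barrierFlatToTwisted - b$barrierTwistedToFlat,
                     b$endothermicEnergy)
  }
})

test_that("dihedral interpolation preserves covalent geometry; cartesian does not", {
  d <- buildParallelDimer(builderParams(sequence = "GAGA", startPosition = 1L))
  ax <- enumerateAxes(d, 3L)[[2L]]
  tw <- applyTorsion(d, ax, 120)@structure
  bl <- function(s) {
    b <- covalentBonds(s); X <- atomCoords(s)
    sqrt(rowSums((X[b[, 1L], ] - X[b[, 2L], ])^2))
  }
  ref <- bl(d)
  pDih <- interpolatePath(d, tw, ax, nImages = 6L, mode = "dihedral")
  devDih <- max(vapply(pathImages(pDih), function(im) max(abs(bl(im) - ref)),
                       numeric(1L)))
  expect_lt(devDih, 1e-6)
  pCar <- interpolatePath(d, tw, ax, nImages = 6L, mode = "cartesian")
  devCar <- max(vapply(pathImages(pCar), function(im) max(abs(bl(im) - ref)),
                       numeric(1L)))
  expect_gt(devCar, 0.01)
  ## endpoints exactly preserved in both modes
  for (p in list(pDih, pCar)) {
    expect_identical(atomCoords(pathImages(p)[[1L]]), atomCoords(d))
    expect_identical(atomCoords(pathImages(p)[[6L]]), atomCoords(tw))
  }
  ## three images: the middle image carries the mean dihedral
  p3 <- interpolatePath(d, tw, ax, nImages = 3L)
  d0 <- measureDihedral(d, 3L, "psi")
  d1 <- measureDihedral(tw, 3L, "psi")
  dm <- measureDihedral(pathImages(p3)[[2L]], 3L, "psi")
  half <- BetaTwist:::.wrapAngle(d1 - d0) / 2
  expect_lt(abs(BetaTwist:::.wrapAngle(dm - d0) - half), 1e-6)
  ## identical endpoints give identical images
  pSame <- interpolatePath(d, d, ax, nImages = 4L)
  for (im in pathImages(pSame))
    expect_lt(max(abs(atomCoords(im) - atomCoords(d))), 1e-9)
})

test_that("molecular NEB keeps endpoints fixed and lowers the initial band", {
  d <- buildParallelDimer(builderParams(sequence = "GAGA", startPosition = 1L))
  flat <- minimizeStructure(d, maxIter = 400L, tol = 0.05)$structure
  ax <- enumerateAxes(flat, 3L)[[2L]]
  tw <- generateTwisted(flat, ax, maxIter = 200L)
  p0 <- interpolatePath(flat, tw@structure, ax, nImages = 6L)
  model <- BetaTwist:::.energyModel(flat, energyParams())
  e0 <- vapply(pathImages(p0), function(s)
    BetaTwist:::.modelEnergy(model, atomCoords(s)), numeric(1L))
  rp <- nebRelax(p0, tol = 0.05, maxIter = 250L)
  expect_identical(atomCoords(pathImages(rp)[[1L]]), atomCoords(flat))
  expect_identical(atomCoords(pathImages(rp)[[6L]]), atomCoords(tw@structure))
  expect_lte(max(pathEnergies(rp)), max(e0) + 1e-9)
  b <- barrierReport(rp)
  expect_gte(b$barrierTwistedToFlat, 0)
  expect_identical(b$barrierFlatToTwisted - b$barrierTwistedToFlat,
                   b$endothermicEnergy)
})
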