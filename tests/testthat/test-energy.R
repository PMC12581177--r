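# Surrogate energy: term behaviour, invariances, gradient, minimisation.

test_that("well-separated fragments are exactly additive", {
  mono <- buildStrand(builderParams(sequence = "GASG", startPosition = 1L))
  d <- buildParallelDimer(builderParams(sequence = "GASG", startPosition = 1L,
                                        layerSeparation = 50))
  p <- energyParams()
  a <- atomRecords(d)
  eDim <- surrogateEnergy(d, p, reference = d)
  eMono <- surrogateEnergy(mono, p, reference = mono)
  expect_lt(abs(eDim - 2 * eMono), 1e-6)
})

test_that("energy is invariant under rigid motion and finite under overlap", {
  s <- buildParallelDimer(builderParams(sequence = "GAG", startPosition = 1L))
  p <- energyParams()
  e0 <- surrogateEnergy(s, p)
  xyz <- atomCoords(s)
  s2 <- s
  atomCoords(s2) <- sweep(BetaTwist:::.rotateAboutAxis(xyz, c(0, 1, 2),
                                                       c(1, -1, 2), 33),
                          2L, c(5, 5, -2), "+")
  expect_lt(abs(surrogateEnergy(s2, p, reference = s) - e0), 1e-9)
  ## overlapping atoms: large but finite penalty
  s3 <- s
  xyz[2L, ] <- xyz[1L, ] + c(0.05, 0, 0)
  atomCoords(s3) <- xyz
  e3 <- surrogateEnergy(s3, p, reference = s)
  expect_true(is.finite(e3))
  expect_gt(e3, e0 + 100)
})

test_that("breaking one ideal bond costs the well depth", {
  ## negligible steric term isolates the closed-form bond well
  p <- energyParams(ljEpsilon = c(H = 1e-12, C = 1e-12, N = 1e-12,
                                  O = 1e-12, S = 1e-12))
  ## ideal geometry: distance factor 1, angle factor 1
  sIdeal <- microHBStructure(p$hbDistance0, 180)
  sBroken <- microHBStructure(p$hbDistance0, 60)  # hydrogen swung off axis
  dE <- surrogateEnergy(sBroken, p, reference = sBroken) -
    surrogateEnergy(sIdeal, p, reference = sIdeal)
  expect_lt(abs(dE - p$hbWellDepth), 0.1 * p$hbWellDepth)
})

test_that("the analytic gradient matches finite differences", {
  set.seed(12L)
  s <- buildParallelDimer(builderParams(sequence = "SG", startPosition = 1L))
  p <- energyParams()
  model <- BetaTwist:::.energyModel(s, p)
  X <- atomCoords(s) + matrix(stats::rnorm(3L * nAtoms(s), sd = 0.04),
                              ncol = 3L)
  G <- BetaTwist:::.modelGradient(model, X)
  h <- 1e-6
  for (k in sample(length(X), 10L)) {
    Xp <- X; Xp[k] <- Xp[k] + h
    Xm <- X; Xm[k] <- Xm[k] - h
    num <- (BetaTwist:::.modelEnergy(model, Xp) -
              BetaTwist:::.modelEnergy(model, Xm)) / (2 * h)
    expect_lt(abs(num - G[k]), 1e-5 * max(1, abs(G[k])))
  }
})

test_that("minimisation descends and honours an already-minimal input", {
  p <- energyParams()
  s <- buildParallelDimer(builderParams(sequence = "GAG", startPosition = 1L))
  r0 <- minimizeStructure(s, p, maxIter = 400L, tol = 0.05)
  ## minimal input returns unchanged
  r1 <- minimizeStructure(r0$structure, p, reference = s, tol = 1,
                          maxIter = 400L)
  expect_identical(atomCoords(r1$structure), atomCoords(r0$structure))
  ## jittered start strictly decreases
  set.seed(4L)
  sj <- r0$structure
  atomCoords(sj) <- atomCoords(sj) + matrix(
    stats::rnorm(3L * nAtoms(sj), sd = 0.05), ncol = 3L)
  model <- BetaTwist:::.energyModel(s, p)
  eStart <- BetaTwist:::.modelEnergy(model, atomCoords(sj))
  r2 <- minimizeStructure(sj, p, reference = s, maxIter = 400L, tol = 0.05)
  expect_lt(r2$energy, eStart)
  expect_error(minimizeStructure(s, p, reference = s, maxIter = 0L), NA)
})

test_that("a harmonic-only system converges to its analytic minimum", {
  ## with negligible steric and bond-well terms the surrogate is a pure
  ## quadratic in the 1-2/1-3 distances, minimised at the reference geometry
  p <- energyParams(ljEpsilon = c(H = 1e-12, C = 1e-12, N = 1e-12,
                                  O = 1e-12, S = 1e-12),
                    hbWellDepth = 1e-12)
  s <- buildStrand(builderParams(sequence = "AG", startPosition = 1L))
  set.seed(8L)
  sj <- s
  atomCoords(sj) <- atomCoords(s) + matrix(
    stats::rnorm(3L * nAtoms(s), sd = 0.03), ncol = 3L)
  r <- minimizeStructure(sj, p, reference = s, tol = 1e-4, maxIter = 3000L)
  expect_true(r$converged)
  expect_lt(abs(r$energy), 1e-6)
  ## all restrained distances back at their reference values
  b <- covalentBonds(s)
  X <- atomCoords(r$structure); X0 <- atomCoords(s)
  dr <- sqrt(rowSums((X[b[, 1L], ] - X[b[, 2L], ])^2))
  d0 <- sqrt(rowSums((X0[b[, 1L], ] - X0[b[, 2L], ])^2))
  expect_lt(max(abs(dr - d0)), 1e-3)
})
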