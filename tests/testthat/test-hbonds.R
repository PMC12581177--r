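# Hydrogen-bond detection, ledgers and structural observables.

test_that("criteria boundaries are inclusive exactly as defined", {
  ## collinear N-H...O at the distance boundary
  expect_identical(nrow(detectHBonds(microHBStructure(3.6, 180))), 1L)
  expect_identical(nrow(detectHBonds(microHBStructure(3.7, 180))), 0L)
  ## angle boundary
  expect_identical(nrow(detectHBonds(microHBStructure(3.0, 120))), 1L)
  expect_identical(nrow(detectHBonds(microHBStructure(3.0, 119))), 0L)
  ## criteria are parameters, not constants
  strict <- hbCriteria(maxDistance = 2.5, minAngle = 150)
  expect_identical(nrow(detectHBonds(microHBStructure(3.0, 160), strict)), 0L)
  expect_identical(nrow(detectHBonds(microHBStructure(2.4, 160), strict)), 1L)
})

test_that("detection equals the brute-force oracle on random fixtures", {
  for (k in 1:20) {
    s <- randomPeptideDimer(500L + k)
    crit <- hbCriteria(maxDistance = stats::runif(1L, 2.8, 4.2),
                       minAngle = stats::runif(1L, 100, 150))
    mine <- sort(BetaTwist:::.hbKey(detectHBonds(s, crit)))
    expect_identical(mine, oracleHBonds(s, crit$maxDistance, crit$minAngle))
  }
})

test_that("detection is invariant under isometries and atom reordering", {
  s <- makeHbFixture(5L)
  k0 <- sort(BetaTwist:::.hbKey(detectHBonds(s)))
  ## rigid rotation + translation
  xyz <- atomCoords(s)
  rot <- BetaTwist:::.rotateAboutAxis(xyz, c(2, -1, 3), c(1, 2, 0.5), 77)
  s2 <- s
  atomCoords(s2) <- sweep(rot, 2L, c(10, -4, 6), "+")
  expect_identical(sort(BetaTwist:::.hbKey(detectHBonds(s2))), k0)
  ## shuffle atoms within residues
  a <- atomRecords(s)
  set.seed(9L)
  perm <- unlist(lapply(split(seq_len(nrow(a)), paste(a$monomer, a$resno)),
                        sample))
  s3 <- BetaTwist:::.makeStructure(a[perm, ])
  expect_identical(sort(BetaTwist:::.hbKey(detectHBonds(s3))), k0)
})

test_that("tightening either criterion never increases the count", {
  s <- buildParallelDimer(builderParams(jitterSigma = 0.05, seed = 3L))
  base <- nrow(detectHBonds(s, hbCriteria(3.6, 120)))
  for (dmax in c(3.6, 3.2, 2.9)) for (amin in c(120, 140, 160)) {
    n <- nrow(detectHBonds(s, hbCriteria(dmax, amin)))
    expect_lte(n, base)
    if (dmax < 3.6 || amin > 120)
      expect_lte(n, nrow(detectHBonds(s, hbCriteria(3.6, amin))))
  }
})

test_that("structures without hydrogens are rejected", {
  s <- buildStrand(builderParams(sequence = "AG", startPosition = 1L))
  a <- atomRecords(s)
  bare <- BetaTwist:::.makeStructure(a[a$elesy != "H", ])
  expect_error(detectHBonds(bare), "hydrogen")
})

test_that("the broken/formed ledger is antisymmetric and identity-stable", {
  s <- makeHbFixture(6L)
  z <- deltaHB(s, s)
  expect_identical(z$deltaNHB, 0L)
  expect_identical(nrow(z$broken) + nrow(z$formed), 0L)
  s2 <- makeHbFixture(2L)  # same topology, four bonds spoiled
  ab <- deltaHB(s, s2)
  ba <- deltaHB(s2, s)
  expect_identical(sort(BetaTwist:::.hbKey(ab$broken)),
                   sort(BetaTwist:::.hbKey(ba$formed)))
  expect_identical(sort(BetaTwist:::.hbKey(ab$formed)),
                   sort(BetaTwist:::.hbKey(ba$broken)))
  ## topology mismatch is refused
  expect_error(deltaHB(s, buildStrand(builderParams())), "topolog")
})

test_that("interlayer distance equals construction and brute force", {
  d <- buildParallelDimer(builderParams(layerSeparation = 5.2))
  expect_equal(interlayerDistance(d), 5.2, tolerance = 1e-9)
  j <- buildParallelDimer(builderParams(layerSeparation = 4.8,
                                        jitterSigma = 0.1, seed = 17L))
  expect_equal(interlayerDistance(j), oracleInterlayer(j), tolerance = 1e-9)
  ## unequal residue counts are refused
  a <- atomRecords(d)
  trunc <- a[!(a$monomer == 2L & a$resno == 34L), ]
  expect_error(interlayerDistance(BetaTwist:::.makeStructure(trunc)),
               "unequal")
})

test_that("segment carbonyl O-O distances track the layer separation", {
  d <- buildParallelDimer(builderParams(layerSeparation = 4.8))
  for (i in c(22L, 25L, 28L))
    expect_lt(abs(segmentOODistance(d, i) - 4.8), 0.2)
  expect_error(segmentOODistance(d, 34L), "segment")
})

test_that("contact tables report minimal near-axis distances at both images", {
  d <- buildParallelDimer(builderParams())
  ax25 <- enumerateAxes(d, 25L)[[2L]]         # psi G25 -> H-H class
  tw <- applyTorsion(d, ax25, 100)@structure
  ct <- contactTable(list(d, tw), ax25, barrierIndex = 1L, minimumIndex = 2L)
  expect_identical(unique(ct$pairType), "H-H")
  expect_setequal(ct$atom, c("HA1", "HA2"))
  ## brute-force minimum over the specified atom classes
  a <- atomRecords(d)
  up <- unique(a$monomer[a$layer == "upper"])
  xyz <- atomCoords(d)
  loH <- xyz[a$monomer != up & a$elesy == "H", ]
  for (r in seq_len(nrow(ct))) {
    i <- which(a$monomer == up & a$resno == 25L & a$elety == ct$atom[r])
    expect_equal(ct$barrierTop[r],
                 min(sqrt(rowSums(sweep(loH, 2L, xyz[i, ])^2))),
                 tolerance = 1e-9)
  }
  ## aspartate near the axis switches to the carboxyl-O class
  ax24 <- enumerateAxes(d, 24L)[[1L]]          # phi V24 -> neighbour D23
  ctd <- contactTable(list(d, tw), ax24, 1L, 2L)
  expect_identical(unique(ctd$pairType), "O-O")
  expect_setequal(ctd$atom, c("OD1", "OD2"))
  ## a far-lifted segment reports long distances
  far <- applyTorsion(d, ax25, 140)@structure
  xyzf <- atomCoords(far)
  lift <- far
  X <- xyzf
  X[ax25@movingSet, 3L] <- X[ax25@movingSet, 3L] + 30
  atomCoords(lift) <- X
  ctf <- contactTable(list(lift, lift), ax25, 1L, 2L)
  expect_true(all(ctf$barrierTop > 10))
})
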