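# Torsion-axis enumeration, rigid rotation, clash screening and twisted-state
# generation.

flatDimer <- buildParallelDimer(builderParams())

test_that("axis enumeration covers the studied axes in deterministic order", {
  axes <- enumerateAxes(flatDimer, 22:26)
  labs <- vapply(axes, function(a) sprintf("%d:%s", a@residue, a@kind), "")
  for (want in c("22:psi", "23:phi", "23:psi", "24:phi", "25:psi", "26:phi"))
    expect_true(want %in% labs)
  ## N-to-C, phi before psi
  expect_identical(labs[1:4], c("22:phi", "22:psi", "23:phi", "23:psi"))
  expect_length(enumerateAxes(flatDimer, 24L), 2L)
  ## the monomer's N-terminal residue offers only psi
  labs20 <- vapply(enumerateAxes(flatDimer, 20L),
                   function(a) a@kind, "")
  expect_identical(labs20, "psi")
  expect_error(enumerateAxes(flatDimer, integer(0)), "empty")
})

test_that("moving sets follow bond connectivity for phi and psi", {
  a <- atomRecords(flatDimer)
  up <- unique(a$monomer[a$layer == "upper"])
  axPsi <- enumerateAxes(flatDimer, 25L)[[2L]]
  axPhi <- enumerateAxes(flatDimer, 25L)[[1L]]
  ## psi moves the pivot's sidechain; phi only its amide group
  inMv <- function(ax, elety) {
    idx <- which(a$monomer == up & a$resno == 25L & a$elety == elety)
    idx %in% ax@movingSet
  }
  expect_true(inMv(axPsi, "HA2"))   # glycine sidechain hydrogen
  expect_true(inMv(axPsi, "N"))
  expect_false(inMv(axPsi, "O"))
  expect_true(inMv(axPhi, "N"))
  expect_true(inMv(axPhi, "H"))
  expect_false(inMv(axPhi, "HA2"))
  ## all atoms of N-terminal residues move in both cases
  expect_true(all(which(a$monomer == up & a$resno < 25L) %in%
                    axPsi@movingSet))
})

test_that("applyTorsion is rigid, composable, invertible and exact in angle", {
  ax <- enumerateAxes(flatDimer, 23L)[[2L]]
  X0 <- atomCoords(flatDimer)
  ## identity and full turn
  expect_identical(atomCoords(applyTorsion(flatDimer, ax, 0)@structure), X0)
  expect_lt(max(abs(atomCoords(applyTorsion(flatDimer, ax, 360)@structure) -
                      X0)), 1e-6)
  ## exact dihedral change, independent oracle
  a <- atomRecords(flatDimer)
  up <- unique(a$monomer[a$layer == "upper"])
  pget <- function(s, r, n) atomCoords(s)[
    which(a$monomer == up & a$resno == r & a$elety == n), ]
  for (delta in c(-120, -45, 30, 90)) {
    tw <- applyTorsion(flatDimer, ax, delta)@structure
    d0 <- oracleDihedral(pget(flatDimer, 23L, "N"), pget(flatDimer, 23L, "CA"),
                         pget(flatDimer, 23L, "C"), pget(flatDimer, 24L, "N"))
    d1 <- oracleDihedral(pget(tw, 23L, "N"), pget(tw, 23L, "CA"),
                         pget(tw, 23L, "C"), pget(tw, 24L, "N"))
    dd <- (d1 - d0 - delta) %% 360
    expect_lt(min(dd, 360 - dd), 1e-6)
  }
  ## rigid-body property on both sets
  tw <- applyTorsion(flatDimer, ax, 70)@structure
  mv <- ax@movingSet
  fx <- setdiff(seq_len(nAtoms(flatDimer)), mv)
  dmat <- function(M) as.matrix(stats::dist(M))
  expect_lt(max(abs(dmat(atomCoords(tw)[mv, ]) - dmat(X0[mv, ]))), 1e-9)
  expect_lt(max(abs(dmat(atomCoords(tw)[fx, ]) - dmat(X0[fx, ]))), 1e-9)
  ## composition and inverse
  s1 <- applyTorsion(applyTorsion(flatDimer, ax, 25)@structure, ax, 40)@structure
  s2 <- applyTorsion(flatDimer, ax, 65)@structure
  expect_lt(max(abs(atomCoords(s1) - atomCoords(s2))), 1e-6)
  s3 <- applyTorsion(applyTorsion(flatDimer, ax, 50)@structure, ax, -50)@structure
  expect_lt(max(abs(atomCoords(s3) - X0)), 1e-6)
})

test_that("small torsions leave C-terminal hydrogen bonds untouched", {
  ax <- enumerateAxes(flatDimer, 25L)[[2L]]
  hb0 <- detectHBonds(flatDimer)
  cterm0 <- hb0[hb0$donorResno > 25L & hb0$acceptorResno > 25L, ]
  for (delta in c(-4, 3)) {
    hb <- detectHBonds(applyTorsion(flatDimer, ax, delta)@structure)
    cterm <- hb[hb$donorResno > 25L & hb$acceptorResno > 25L, ]
    expect_setequal(BetaTwist:::.hbKey(cterm), BetaTwist:::.hbKey(cterm0))
  }
})

test_that("clash counting excludes bonded relations and matches brute force", {
  s <- buildStrand(builderParams(sequence = "GA", startPosition = 1L))
  ## covalently bonded pair at 1.0 A does not count
  expect_identical(clashCount(s, 1.2), oracleClashCount(s, 1.2))
  set.seed(31L)
  for (k in 1:5) {
    r <- randomPeptideDimer(100L + k)
    cutoff <- stats::runif(1L, 1.5, 2.6)
    expect_identical(clashCount(r, cutoff), oracleClashCount(r, cutoff))
    expect_identical(clashCount(r, cutoff, atoms = "heavy"),
                     oracleClashCount(r, cutoff, heavyOnly = TRUE))
  }
})

test_that("twisted-state generation detaches the lifted segment deterministically", {
  flat <- minimizeStructure(flatDimer, maxIter = 600L, tol = 0.05)$structure
  ax <- enumerateAxes(flat, 25L)[[2L]]
  tw1 <- generateTwisted(flat, ax, maxIter = 150L)
  tw2 <- generateTwisted(flat, ax, maxIter = 150L)
  expect_identical(atomCoords(tw1@structure), atomCoords(tw2@structure))
  expect_identical(tw1@appliedAngle, tw2@appliedAngle)
  ## the torsion breaks the moving segment's intermolecular mainchain bonds
  led <- deltaHB(flat, tw1@structure)
  expect_gt(led$deltaNHB, 0L)
  hb <- detectHBonds(tw1@structure)
  hb <- hb[hb$scope == "intermolecular" & hb$class == "mainchain", ]
  ## the C-terminal ladder persists
  expect_gt(nrow(hb), 0L)
  expect_true(all(hb$donorResno >= 23L & hb$acceptorResno >= 23L))
  ## a dimer with no interlayer contact stays unchanged in its bond ledger
  far <- buildParallelDimer(builderParams(sequence = "GAGA",
                                          startPosition = 1L,
                                          layerSeparation = 20))
  axf <- enumerateAxes(far, 3L)[[2L]]
  twf <- generateTwisted(far, axf, maxIter = 150L)
  expect_identical(deltaHB(far, twf@structure)$deltaNHB, 0L)
})
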