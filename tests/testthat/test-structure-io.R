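# Reading, writing, topology inference and layer assignment.

test_that("PDB round trip preserves coordinates, counts and residue numbering", {
  d <- buildParallelDimer(builderParams())
  f <- tempfile(fileext = ".pdb")
  writeStructure(d, f, format = "pdb")
  d2 <- readStructure(f, format = "pdb")
  expect_identical(nAtoms(d2), nAtoms(d))
  expect_lt(max(abs(atomCoords(d2) - atomCoords(d))), 1e-3)
  expect_identical(sort(unique(atomRecords(d2)$resno)), 20:34)
  ## two chain identifiers on disk
  lines <- readLines(f)
  chains <- unique(substr(grep("^ATOM", lines, value = TRUE), 22L, 22L))
  expect_setequal(chains, c("A", "B"))
  ## layers re-derived geometrically agree with the original labels
  expect_identical(atomRecords(d2)$layer, atomRecords(d)$layer)
})

test_that("XYZ round trip works against a topology template", {
  s <- buildStrand(builderParams(sequence = "SAG", startPosition = 1L))
  f <- tempfile(fileext = ".xyz")
  writeStructure(s, f, format = "xyz")
  s2 <- readStructure(f, format = "xyz", template = s)
  expect_lt(max(abs(atomCoords(s2) - atomCoords(s))), 1e-5)
  expect_error(readStructure(f, format = "xyz"), "template")
})

test_that("degenerate and malformed inputs give format/topology errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(readStructure(f, format = "pdb"), "format error|ATOM")
  ## drop one backbone atom -> topology error naming the residue
  d <- buildStrand(builderParams(sequence = "GA", startPosition = 1L))
  a <- atomRecords(d)
  a <- a[!(a$resno == 2L & a$elety == "O"), ]
  expect_error(BetaTwist:::.makeStructure(a), "residue 2.*O")
  expect_error(BetaTwist:::.makeStructure(a[0, ]), "no atoms")
})

test_that("sequence restriction of the amyloid-beta fragment is honoured", {
  d <- buildParallelDimer(builderParams())
  a <- atomRecords(d)
  one <- bio3d::aa321(a$resid[!duplicated(paste(a$monomer, a$resno))])
  expect_identical(paste(one[1:15], collapse = ""), "FAEDVGSNKGAIIGL")
  expect_identical(ABETA_20_34, "FAEDVGSNKGAIIGL")
  expect_identical(range(a$resno), c(20L, 34L))
})

test_that("topology inference is idempotent and partitions cover every atom once", {
  s <- buildStrand(builderParams(sequence = "NKI", startPosition = 5L))
  a <- atomRecords(s)
  expect_true(all(a$chainclass %in% c("mainchain", "sidechain")))
  s2 <- BetaTwist:::.makeStructure(a)
  expect_identical(atomRecords(s2)$chainclass, a$chainclass)
  expect_identical(covalentBonds(s2), covalentBonds(s))
  ## glycine's alpha hydrogens split across the partition
  g <- buildStrand(builderParams(sequence = "AGA", startPosition = 1L))
  ga <- atomRecords(g)
  expect_identical(ga$chainclass[ga$resno == 2L & ga$elety == "HA1"],
                   "mainchain")
  expect_identical(ga$chainclass[ga$resno == 2L & ga$elety == "HA2"],
                   "sidechain")
})

test_that("multi-model paths read back in order with consistent atoms", {
  d <- buildParallelDimer(builderParams(sequence = "GAG", startPosition = 1L))
  ax <- enumerateAxes(d, 2L)[[2L]]
  imgs <- lapply(c(0, 30, 60, 90, 120, 150, 179), function(ang)
    applyTorsion(d, ax, ang)@structure)
  f <- tempfile(fileext = ".pdb")
  writePath(imgs, f, format = "pdb")
  back <- readPath(f, format = "pdb")
  expect_length(back, 7L)
  for (k in c(1L, 4L, 7L))
    expect_lt(max(abs(atomCoords(back[[k]]) - atomCoords(imgs[[k]]))), 1e-3)
  ## xyz trajectory dialect
  fx <- tempfile(fileext = ".xyz")
  writePath(imgs, fx, format = "xyz")
  backx <- readPath(fx, format = "xyz", template = d)
  expect_length(backx, 7L)
  expect_lt(max(abs(atomCoords(backx[[3L]]) - atomCoords(imgs[[3L]]))), 1e-5)
  ## a single model is not a path
  f1 <- tempfile(fileext = ".pdb")
  writeStructure(d, f1)
  expect_error(readPath(f1, format = "pdb"), ">= 2 images")
})

test_that("layer assignment is geometric, order-invariant and guards degeneracy", {
  d <- buildParallelDimer(builderParams(sequence = "AGAG", startPosition = 1L,
                                        layerSeparation = 5.0))
  a <- atomRecords(d)
  ## builder's translated copy (monomer 2) is the upper layer
  expect_identical(unique(a$layer[a$monomer == 2L]), "upper")
  ## swapping monomer input order does not change the labelling
  sw <- a
  sw$monomer <- 3L - sw$monomer
  sw$layer <- NA_character_
  d2 <- assignLayers(BetaTwist:::.makeStructure(sw))
  a2 <- atomRecords(d2)
  m_upper <- unique(a2$monomer[a2$layer == "upper"])
  up1 <- atomCoords(d)[a$layer == "upper", ]
  up2 <- atomCoords(d2)[a2$monomer == m_upper, ]
  expect_equal(sort(up1[, 3L]), sort(up2[, 3L]), tolerance = 1e-9)
  ## coincident layers cannot be labelled
  co <- a
  co$z[co$monomer == 2L] <- co$z[co$monomer == 2L] - 5.0
  expect_error(assignLayers(BetaTwist:::.makeStructure(co, checkChain = FALSE)),
               "degenerate|clash", ignore.case = TRUE)
  ## monomers cannot be layered
  expect_error(assignLayers(buildStrand(builderParams())), "dimer")
})
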