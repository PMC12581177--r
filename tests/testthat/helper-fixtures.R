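# Programmatic fixtures shared across the suite.

## small random peptide dimers (<= 100 atoms) with varied backbone geometry
randomPeptideDimer <- function(seed) {
  set.seed(seed)
  nres <- sample(2:3, 1L)
  seqch <- paste(sample(c("G", "A", "S", "V"), nres, replace = TRUE),
                 collapse = "")
  p <- builderParams(sequence = seqch,
                     phi = stats::runif(1, -150, -90),
                     psi = stats::runif(1, 100, 150),
                     layerSeparation = stats::runif(1, 4.4, 6.0),
                     jitterSigma = stats::runif(1, 0, 0.12),
                     seed = seed, startPosition = 1L)
  buildParallelDimer(p)
}

## hand-built two-residue dimer with a single candidate N-H...O=C triple at
## exactly the requested donor-acceptor distance and D-H...A angle
microHBStructure <- function(dDA, dhaAngle) {
  ## lower residue: carbonyl O points up (+z)
  low <- rbind(
    CA = c(0, 0, 0),
    C = c(1.52, 0, 0),
    O = c(1.52, 0, 1.23),
    N = c(-0.58, 1.33, 0),
    H = c(-0.28, 1.84, -0.80))
  acc <- low["O", ]
  don <- acc + c(0, 0, dDA)
  ## hydrogen on the donor sphere, tilted to realise the requested angle
  tiltAngleOf <- function(alpha) {
    h <- don + 1.01 * c(sin(alpha), 0, -cos(alpha))
    u <- don - h
    v <- acc - h
    acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  }
  alpha <- if (abs(tiltAngleOf(0) - dhaAngle) < 1e-9) 0 else
    stats::uniroot(function(a) tiltAngleOf(a) - dhaAngle,
                   c(0, pi * 0.95), tol = 1e-12)$root
  h <- don + 1.01 * c(sin(alpha), 0, -cos(alpha))
  up <- rbind(
    N = don,
    H = h,
    CA = don + c(-1.02, 1.02, 0.3),
    C = don + c(-0.5, 2.2, 1.0),
    O = don + c(-0.5, 2.2, 2.23))
  mk <- function(m, xyz) data.frame(
    eleno = seq_len(nrow(xyz)), elety = rownames(xyz),
    elesy = substr(rownames(xyz), 1L, 1L), resno = 1L, resid = "GLY",
    monomer = m, layer = NA_character_, chainclass = "mainchain",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)
  BetaTwist:::.makeStructure(rbind(mk(1L, low), mk(2L, up)),
                             provenance = "micro HB fixture")
}

## matched-pair fixture for the steric-barrier comparison: identical
## full-size double layers except for the sidechain at the torsional pivot
## (wild-type glycine 25 vs a valine substitution)
twistBarrier <- function(seqch, residue = 25L) {
  d <- buildParallelDimer(builderParams(sequence = seqch))
  flat <- minimizeStructure(d, maxIter = 1200L, tol = 0.05)$structure
  ax <- BetaTwist:::.makeAxis(flat, residue, "psi")
  tw <- generateTwisted(flat, ax, maxIter = 300L)
  path <- interpolatePath(flat, tw@structure, ax, nImages = 7L)
  rp <- nebRelax(path, tol = 0.05, maxIter = 300L)
  barrierReport(rp)$barrierTwistedToFlat
}
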