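# Backbone torsion kinematics: axis enumeration, rigid rotation of the
# N-terminal segment of the upper monomer, clash screening, and generation of
# relaxed twisted conformations.

#' TwistResult: a twisted conformation and how it was produced
#'
#' @slot structure the twisted \linkS4class{PeptideStructure}.
#' @slot axis the \linkS4class{TorsionAxis} used.
#' @slot appliedAngle applied torsion angle, degrees, in (-180, 180].
#' @slot relaxed whether surrogate-energy relaxation converged.
#' @slot clashCount non-bonded heavy-atom contacts below the covalent-clash
#'   cutoff in the final structure.
#' @export
setClass("TwistResult",
  representation(structure = "PeptideStructure", axis = "TorsionAxis",
                 appliedAngle = "numeric", relaxed = "logical",
                 clashCount = "integer"))

setMethod("show", "TwistResult", function(object) {
  cat(sprintf("TwistResult: %s torsion at residue %d, applied %.1f deg, %s, %d clashes\n",
              object@axis@kind, object@axis@residue, object@appliedAngle,
              if (object@relaxed) "relaxed" else "unrelaxed",
              object@clashCount))
})

## row indices of one atom in (monomer, resno, elety); error if absent
.atomIdx <- function(a, monomer, resno, elety, required = TRUE) {
  i <- which(a$monomer == monomer & a$resno == resno & a$elety == elety)
  if (required && length(i) != 1L)
    stop(sprintf("atom %s of residue %d (monomer %d) not found/unique",
                 elety, resno, monomer))
  i
}

.upperMonomer <- function(s) {
  a <- s@atoms
  if (nMonomers(s) == 1L) return(unique(a$monomer))
  if (!any(!is.na(a$layer))) s <- assignLayers(s)
  unique(s@atoms$monomer[s@atoms$layer == "upper"])
}

## construct the TorsionAxis object for (residue, kind) on the upper monomer
.makeAxis <- function(s, residue, kind) {
  a <- s@atoms
  m <- .upperMonomer(s)
  pos <- unique(a$resno[a$monomer == m])
  if (!(residue %in% pos)) stop("residue ", residue, " not in the upper monomer")
  first <- min(pos)
  if (kind == "phi" && residue == first)
    stop("phi axis undefined at the N-terminal residue (nothing to lift)")
  nter <- which(a$monomer == m & a$resno < residue)
  resSel <- a$monomer == m & a$resno == residue
  if (kind == "psi") {
    ax <- c(.atomIdx(a, m, residue, "CA"), .atomIdx(a, m, residue, "C"))
    ## pivot residue: everything but its carbonyl (and C-terminal carboxyl)
    own <- which(resSel & !a$elety %in% c("C", "O", "OXT", "HXT"))
  } else {
    ax <- c(.atomIdx(a, m, residue, "N"), .atomIdx(a, m, residue, "CA"))
    own <- which(resSel & a$elety %in% c("N", "H", "H1", "H2"))
  }
  new("TorsionAxis", residue = as.integer(residue), kind = kind,
      monomer = as.integer(m), axisAtoms = as.integer(ax),
      movingSet = sort(as.integer(c(nter, own))))
}

#' Enumerate backbone torsion axes of the upper monomer
#'
#' For each residue position in \code{residueRange}, yields the phi and psi
#' axes whose rotation lifts the chain N-terminal of the axis off the lower
#' layer. The phi axis of the monomer's N-terminal residue is omitted (there
#' is no chain N-terminal of it to lift). Order is deterministic: N-to-C,
#' phi before psi within a residue.
#'
#' @param s a dimeric \linkS4class{PeptideStructure} with layers assigned
#'   (or a monomer).
#' @param residueRange integer vector of residue positions.
#' @return list of \linkS4class{TorsionAxis}.
#' @export
enumerateAxes <- function(s, residueRange) {
  stopifnot(is(s, "PeptideStructure"))
  if (!length(residueRange)) stop("empty residue range")
  if (nMonomers(s) == 2L && !any(!is.na(s@atoms$layer))) s <- assignLayers(s)
  m <- .upperMonomer(s)
  pos <- unique(s@atoms$resno[s@atoms$monomer == m])
  first <- min(pos)
  axes <- list()
  for (r in sort(unique(as.integer(residueRange)))) {
    if (!(r %in% pos)) next
    if (r > first)
      axes[[length(axes) + 1L]] <- .makeAxis(s, r, "phi")
    axes[[length(axes) + 1L]] <- .makeAxis(s, r, "psi")
  }
  axes
}

#' Measure a backbone dihedral
#'
#' @param s a \linkS4class{PeptideStructure}.
#' @param residue residue position.
#' @param kind \code{"psi"} (N-CA-C-N') or \code{"phi"} (C'-N-CA-C).
#' @param monomer monomer index; defaults to the upper monomer.
#' @return dihedral in degrees, (-180, 180].
#' @export
measureDihedral <- function(s, residue, kind = c("psi", "phi"),
                            monomer = NULL) {
  kind <- match.arg(kind)
  a <- s@atoms
  m <- if (is.null(monomer)) .upperMonomer(s) else monomer
  xyz <- atomCoords(s)
  p <- function(elety, resno) xyz[.atomIdx(a, m, resno, elety), ]
  if (kind == "psi") {
    dihedralAngle(p("N", residue), p("CA", residue), p("C", residue),
                  p("N", residue + 1L))
  } else {
    dihedralAngle(p("C", residue - 1L), p("N", residue), p("CA", residue),
                  p("C", residue))
  }
}

#' Apply a rigid backbone torsion
#'
#' Rotates the axis' moving set rigidly about the bond line so that the
#' measured backbone dihedral changes by exactly \code{delta} (modulo 360).
#' All distances within the moving set and within its complement are
#' preserved; only distances across the two sets change.
#'
#' @param s a \linkS4class{PeptideStructure}.
#' @param axis a \linkS4class{TorsionAxis} belonging to \code{s}.
#' @param delta torsion increment, degrees.
#' @return a \linkS4class{TwistResult} (unrelaxed).
#' @export
applyTorsion <- function(s, axis, delta) {
  stopifnot(is(s, "PeptideStructure"), is(axis, "TorsionAxis"))
  xyz <- atomCoords(s)
  a1 <- xyz[axis@axisAtoms[1L], ]
  a2 <- xyz[axis@axisAtoms[2L], ]
  u <- a2 - a1
  if (.vnorm(u) < 1e-6) stop("zero-length torsion axis")
  mv <- axis@movingSet
  ## the moving set holds the first atom of the measured dihedral, so a
  ## rotation of -delta about the N->C axis vector raises the dihedral by
  ## +delta
  xyz[mv, ] <- .rotateAboutAxis(xyz[mv, , drop = FALSE], a1, u, -delta)
  out <- s
  atomCoords(out) <- xyz
  new("TwistResult", structure = out, axis = axis,
      appliedAngle = .wrapAngle(delta), relaxed = FALSE,
      clashCount = clashCount(out, 1.8, atoms = "heavy"))
}

#' Count non-bonded close contacts
#'
#' Number of atom pairs closer than \code{cutoff}, excluding covalently
#' bonded (1-2) and geminal (1-3) pairs.
#'
#' @param s a \linkS4class{PeptideStructure}.
#' @param cutoff distance cutoff, Angstrom.
#' @param atoms \code{"all"} or \code{"heavy"} (exclude hydrogens).
#' @return integer count.
#' @export
clashCount <- function(s, cutoff, atoms = c("all", "heavy")) {
  atoms <- match.arg(atoms)
  stopifnot(cutoff > 0)
  a <- s@atoms
  keep <- if (atoms == "heavy") which(a$elesy != "H") else seq_len(nrow(a))
  xyz <- atomCoords(s)[keep, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  close <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (!nrow(close)) return(0L)
  ## map back to atom indices and drop 1-2/1-3 pairs
  i <- keep[close[, 1L]]
  j <- keep[close[, 2L]]
  excl <- .excludedPairKeys(s)
  n <- nAtoms(s)
  keys <- pmin(i, j) * (n + 1L) + pmax(i, j)
  sum(!(keys %in% excl))
}

## integer keys of all pairs within `through` bonds (2 = exclude 1-2/1-3,
## 3 = additionally exclude 1-4)
.excludedPairKeys <- function(s, through = 2L) {
  n <- nAtoms(s)
  adj <- .bondAdjacency(s@bonds, n)
  keys <- integer(0)
  for (i in seq_len(n)) {
    shell <- adj[[i]]
    part <- shell
    for (k in seq_len(through - 1L)) {
      shell <- setdiff(unique(unlist(adj[shell])), c(i, part))
      part <- c(part, shell)
    }
    part <- part[part > i]
    if (length(part)) keys <- c(keys, i * (n + 1L) + part)
  }
  unique(keys)
}

#' Generate an optimised twisted conformation
#'
#' Performs a driven torsion scan about the axis: the moving segment is
#' rotated in grid-sized stages (lifting direction chosen automatically as
#' the sign that moves the lifted chain away from the lower layer), and after
#' every stage the structure is briefly relaxed with a step-capped descent so
#' that transiently obstructing atoms can move aside - a rigid sweep of a
#' long tail about a tilted bond axis would otherwise jam almost immediately
#' for near-terminal axes. Stages whose relaxed geometry retains covalent
#' heavy-atom clashes (non-bonded contacts < 1.8 Angstrom) are rejected. The
#' selected twisted candidate is the lowest-energy stage that (a) has broken
#' every intermolecular mainchain hydrogen bond of the moving segment and
#' (b) lies in a basin separated from the flat state (the staged energy
#' profile has already descended from a preceding maximum by at least the
#' bond-well depth); it is then relaxed to a local minimum.
#'
#' @param s flat reference \linkS4class{PeptideStructure} (dimer).
#' @param axis a \linkS4class{TorsionAxis}.
#' @param angleGrid nominal cumulative angles scanned, degrees; default
#'   10-degree steps over (0, 180].
#' @param params an \code{\link{energyParams}} object.
#' @param relax logical; relax the selected candidate.
#' @param maxIter final-relaxation iteration budget.
#' @param stageIter per-stage relaxation budget of the driven scan.
#' @return a \linkS4class{TwistResult}.
#' @export
generateTwisted <- function(s, axis, angleGrid = seq(10, 180, by = 10),
                            params = NULL, relax = TRUE,
                            maxIter = 300L, stageIter = 40L) {
  stopifnot(is(s, "PeptideStructure"), is(axis, "TorsionAxis"))
  if (is.null(params)) params <- energyParams()
  a <- s@atoms
  lowSel <- if (nMonomers(s) == 2L) {
    if (!any(!is.na(a$layer))) { s <- assignLayers(s); a <- s@atoms }
    a$monomer == unique(a$monomer[a$layer == "lower"])
  } else rep(FALSE, nrow(a))
  ## lifting direction: the rotation sign that raises the moving segment
  ## above the lower-monomer plane
  sgn <- 1
  if (any(lowSel)) {
    caLow <- atomCoords(s)[lowSel & a$elety == "CA", , drop = FALSE]
    nrm <- .stackingAxis(caLow, a)
    ctr <- colMeans(caLow)
    upSel <- !lowSel & a$elety == "CA"
    if (mean(atomCoords(s)[upSel, , drop = FALSE] %*% nrm) < sum(ctr * nrm))
      nrm <- -nrm
    lift <- function(stru) {
      xyz <- atomCoords(stru)[axis@movingSet, , drop = FALSE]
      mean(xyz %*% nrm) - sum(ctr * nrm)
    }
    probe <- 30
    sgn <- if (lift(applyTorsion(s, axis, probe)@structure) >=
               lift(applyTorsion(s, axis, -probe)@structure)) 1 else -1
  }
  ## reference bonds carried by the moving segment
  refHB <- detectHBonds(s)
  refHB <- refHB[refHB$scope == "intermolecular" & refHB$class == "mainchain", ]
  mvBond <- (refHB$donor %in% axis@movingSet) |
    (refHB$acceptor %in% axis@movingSet)
  refKeys <- .hbKey(refHB[mvBond, , drop = FALSE])
  model <- .energyModel(s, params)
  eFlat <- .modelEnergy(model, atomCoords(s))
  ## driven scan: rotate stage by stage, relaxing briefly in between
  grid <- sort(abs(angleGrid))
  steps <- diff(c(0, grid))
  cur <- s
  cand <- list()
  for (k in seq_along(grid)) {
    ## recompute the axis line from the current geometry (the fixed-set
    ## pivot atoms may have relaxed slightly)
    cur <- applyTorsion(cur, axis, sgn * steps[k])@structure
    rel <- .fireMinimize(model, atomCoords(cur), tol = 0.05,
                         maxIter = as.integer(stageIter))
    atomCoords(cur) <- rel$X
    stru <- cur
    viable <- clashCount(stru, 1.8, atoms = "heavy") == 0L
    hb <- detectHBonds(stru)
    cand[[k]] <- list(structure = stru, angle = sgn * grid[k],
                      energy = rel$energy, viable = viable,
                      detached = !any(.hbKey(hb) %in% refKeys))
    ## stop early once the scan has wandered far uphill with no prospect
    if (rel$energy > eFlat + 60 * params$hbWellDepth) break
  }
  E <- vapply(cand, `[[`, 0, "energy")
  viable <- vapply(cand, `[[`, FALSE, "viable")
  detached <- vapply(cand, `[[`, FALSE, "detached")
  if (!any(viable))
    stop("no viable twist: every grid angle produces covalent clashes")
  ## basin-separated selection (see above)
  margin <- params$hbWellDepth
  runPeak <- cummax(c(-Inf, E[-length(E)]))
  separated <- E < runPeak - margin
  pool <- which(separated & detached & viable)
  if (!length(pool)) pool <- which(detached & viable)
  if (!length(pool)) pool <- which(viable)
  sel <- pool[which.min(E[pool])]
  best <- new("TwistResult", structure = cand[[sel]]$structure, axis = axis,
              appliedAngle = .wrapAngle(cand[[sel]]$angle), relaxed = FALSE,
              clashCount = clashCount(cand[[sel]]$structure, 1.8,
                                      atoms = "heavy"))
  if (relax) {
    rel <- .fireMinimize(model, atomCoords(best@structure), tol = 0.05,
                         maxIter = as.integer(maxIter))
    stru <- best@structure
    atomCoords(stru) <- rel$X
    best@structure <- stru
    best@relaxed <- rel$converged
    best@clashCount <- clashCount(stru, 1.8, atoms = "heavy")
  }
  best
}
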