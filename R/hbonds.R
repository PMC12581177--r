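# Geometric hydrogen-bond detection and the structural observables of the
# double-layer analysis: broken-bond ledgers, interlayer distance, segment
# carbonyl O-O distances and near-axis contact tables.

#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is counted when the donor-acceptor distance is at most
#' \code{maxDistance} and the D-H...A angle is at least \code{minAngle}; both
#' boundaries are inclusive.
#'
#' @param maxDistance donor-acceptor cutoff, Angstrom (default 3.6).
#' @param minAngle minimum D-H...A angle, degrees (default 120).
#' @return a parameter list of class \code{"HBCriteria"}.
#' @export
hbCriteria <- function(maxDistance = 3.6, minAngle = 120) {
  stopifnot(maxDistance > 0, minAngle >= 0, minAngle <= 180)
  structure(list(maxDistance = maxDistance, minAngle = minAngle),
            class = "HBCriteria")
}

## donor heavy atoms (N or O bearing >= 1 H), their hydrogens, and acceptors
## (any O; N with no bonded hydrogen). Sulfur is excluded (no Cys/Met in the
## 20-34 fragment).
.hbTopology <- function(s) {
  a <- s@atoms
  adj <- .bondAdjacency(s@bonds, nrow(a))
  isH <- a$elesy == "H"
  donors <- integer(0); hydros <- integer(0)
  for (i in which(a$elesy %in% c("N", "O"))) {
    hs <- adj[[i]][isH[adj[[i]]]]
    if (length(hs)) {
      donors <- c(donors, rep.int(i, length(hs)))
      hydros <- c(hydros, hs)
    }
  }
  accN <- which(a$elesy == "N")
  accN <- accN[!vapply(adj[accN], function(nb) any(isH[nb]), logical(1L))]
  acceptors <- sort(c(which(a$elesy == "O"), accN))
  list(donors = donors, hydros = hydros, acceptors = acceptors, adj = adj)
}

## atoms within two bonds of i (inclusive of i)
.within13 <- function(adj, i) {
  nb1 <- adj[[i]]
  unique(c(i, nb1, unlist(adj[nb1])))
}

#' Detect hydrogen bonds
#'
#' Enumerates every donor-H...acceptor triple satisfying the geometric
#' criteria. Donors are N or O atoms covalently bearing at least one hydrogen;
#' acceptors are any O plus imine-like N (no bonded hydrogen). Triples with
#' donor and acceptor in the same residue, or with the acceptor within two
#' covalent bonds of the donor, are excluded.
#'
#' @param s a \linkS4class{PeptideStructure} with hydrogens present.
#' @param criteria a \code{\link{hbCriteria}} object.
#' @return data.frame with one row per bond: indices, names and residues of
#'   donor/hydrogen/acceptor, \code{daDistance} (Angstrom), \code{dhaAngle}
#'   (degrees), \code{scope} (\code{intermolecular}/\code{intramolecular}) and
#'   \code{class} (\code{mainchain} if both heavy partners are mainchain,
#'   otherwise \code{sidechain}).
#' @export
detectHBonds <- function(s, criteria = hbCriteria()) {
  stopifnot(is(s, "PeptideStructure"), inherits(criteria, "HBCriteria"))
  a <- s@atoms
  if (!any(a$elesy == "H"))
    stop("structure has no hydrogens; hydrogen bonds cannot be inferred")
  topo <- .hbTopology(s)
  xyz <- atomCoords(s)
  out <- list()
  resKey <- paste(a$monomer, a$resno)
  for (k in seq_along(topo$donors)) {
    d <- topo$donors[k]; h <- topo$hydros[k]
    excl <- .within13(topo$adj, d)
    acc <- setdiff(topo$acceptors, excl)
    acc <- acc[resKey[acc] != resKey[d]]
    if (!length(acc)) next
    dv <- sweep(xyz[acc, , drop = FALSE], 2L, xyz[d, ])
    dd <- sqrt(rowSums(dv^2))
    acc <- acc[dd <= criteria$maxDistance]
    dd <- dd[dd <= criteria$maxDistance]
    if (!length(acc)) next
    u <- sweep(xyz[acc, , drop = FALSE], 2L, xyz[h, ])
    v <- xyz[d, ] - xyz[h, ]
    cosang <- (u %*% v) / (sqrt(rowSums(u^2)) * .vnorm(v))
    ang <- .rad2deg(acos(pmax(-1, pmin(1, cosang))))
    keep <- ang >= criteria$minAngle
    if (!any(keep)) next
    acc <- acc[keep]; dd <- dd[keep]; ang <- ang[keep]
    out[[length(out) + 1L]] <- data.frame(
      donor = d, hydrogen = h, acceptor = acc,
      donorName = a$elety[d], acceptorName = a$elety[acc],
      donorResno = a$resno[d], acceptorResno = a$resno[acc],
      donorMonomer = a$monomer[d], acceptorMonomer = a$monomer[acc],
      daDistance = dd, dhaAngle = as.numeric(ang),
      scope = ifelse(a$monomer[acc] == a$monomer[d],
                     "intramolecular", "intermolecular"),
      class = ifelse(a$chainclass[d] == "mainchain" &
                       a$chainclass[acc] == "mainchain",
                     "mainchain", "sidechain"),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donorName = character(0),
                      acceptorName = character(0), donorResno = integer(0),
                      acceptorResno = integer(0), donorMonomer = integer(0),
                      acceptorMonomer = integer(0), daDistance = numeric(0),
                      dhaAngle = numeric(0), scope = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count hydrogen bonds after scope/class filtering
#'
#' @param s a \linkS4class{PeptideStructure}.
#' @param scope \code{"any"}, \code{"intermolecular"} or
#'   \code{"intramolecular"}.
#' @param classFilter \code{"any"}, \code{"mainchain"} or \code{"sidechain"}.
#' @param criteria a \code{\link{hbCriteria}} object.
#' @return integer count.
#' @export
countHBonds <- function(s, scope = c("any", "intermolecular", "intramolecular"),
                        classFilter = c("any", "mainchain", "sidechain"),
                        criteria = hbCriteria()) {
  scope <- match.arg(scope)
  classFilter <- match.arg(classFilter)
  if (scope == "intermolecular" && nMonomers(s) < 2L)
    stop("intermolecular scope needs a dimer")
  hb <- detectHBonds(s, criteria)
  if (scope != "any") hb <- hb[hb$scope == scope, , drop = FALSE]
  if (classFilter != "any") hb <- hb[hb$class == classFilter, , drop = FALSE]
  nrow(hb)
}

## identity key of a bond: donor and acceptor atom identities
.hbKey <- function(hb) {
  if (NROW(hb) == 0L) return(character(0))
  paste(hb$donorMonomer, hb$donorResno, hb$donorName, "->",
        hb$acceptorMonomer, hb$acceptorResno, hb$acceptorName)
}

#' Broken/formed hydrogen-bond ledger between two conformations
#'
#' Compares the hydrogen-bond sets of a reference and a comparison structure
#' (same topology), keyed by donor/acceptor atom identity. The headline count
#' \code{deltaNHB} is the number of intermolecular mainchain bonds present in
#' the reference and absent in the comparison, matching the broken-bond count
#' used to rationalise torsional endothermicity.
#'
#' @param reference,comparison \linkS4class{PeptideStructure} objects with
#'   identical topology.
#' @param criteria a \code{\link{hbCriteria}} object.
#' @return list of class \code{"HBChangeReport"} with elements
#'   \code{deltaNHB}, \code{broken}, \code{formed} (data.frames as returned by
#'   \code{\link{detectHBonds}}).
#' @export
deltaHB <- function(reference, comparison, criteria = hbCriteria()) {
  stopifnot(is(reference, "PeptideStructure"),
            is(comparison, "PeptideStructure"))
  ar <- reference@atoms; ac <- comparison@atoms
  if (nrow(ar) != nrow(ac) || !all(ar$elety == ac$elety) ||
      !all(ar$resno == ac$resno) || !all(ar$monomer == ac$monomer))
    stop("mismatched topologies")
  hbr <- detectHBonds(reference, criteria)
  hbc <- detectHBonds(comparison, criteria)
  kr <- .hbKey(hbr); kc <- .hbKey(hbc)
  broken <- hbr[!(kr %in% kc), , drop = FALSE]
  formed <- hbc[!(kc %in% kr), , drop = FALSE]
  deltaNHB <- sum(broken$scope == "intermolecular" &
                    broken$class == "mainchain")
  structure(list(deltaNHB = as.integer(deltaNHB), broken = broken,
                 formed = formed),
            class = "HBChangeReport")
}

#' @export
print.HBChangeReport <- function(x, ...) {
  cat("HBChangeReport: deltaNHB =", x$deltaNHB,
      sprintf("(%d broken, %d formed overall)\n", nrow(x$broken),
              nrow(x$formed)))
  invisible(x)
}

#' Interlayer distance of an in-register dimer
#'
#' Mean over residue positions of the distance between corresponding upper and
#' lower Calpha atoms.
#'
#' @param s a dimeric \linkS4class{PeptideStructure}.
#' @return distance in Angstrom.
#' @export
interlayerDistance <- function(s) {
  stopifnot(is(s, "PeptideStructure"))
  a <- s@atoms
  if (length(unique(a$monomer)) != 2L) stop("interlayer distance needs a dimer")
  ms <- sort(unique(a$monomer))
  ca1 <- a[a$monomer == ms[1L] & a$elety == "CA", ]
  ca2 <- a[a$monomer == ms[2L] & a$elety == "CA", ]
  if (nrow(ca1) != nrow(ca2)) stop("unequal residue counts between monomers")
  d <- sqrt(rowSums((as.matrix(ca1[, c("x", "y", "z")]) -
                     as.matrix(ca2[, c("x", "y", "z")]))^2))
  mean(d)
}

#' Carbonyl oxygen separation of an i - i+1 segment
#'
#' Distance between the mainchain carbonyl oxygen of residue \code{i} in the
#' upper monomer and the same atom in the lower monomer; the carbonyl of
#' segment i - i+1 is the C=O of residue i.
#'
#' @param s a dimeric \linkS4class{PeptideStructure} with layers assigned.
#' @param i residue position opening the segment.
#' @return distance in Angstrom.
#' @export
segmentOODistance <- function(s, i) {
  stopifnot(is(s, "PeptideStructure"))
  a <- s@atoms
  if (!any(!is.na(a$layer))) s <- assignLayers(s)
  a <- s@atoms
  up <- which(a$layer == "upper" & a$resno == i & a$elety == "O")
  lo <- which(a$layer == "lower" & a$resno == i & a$elety == "O")
  if (length(up) != 1L || length(lo) != 1L)
    stop(sprintf("missing mainchain O for segment %d-%d", i, i + 1L))
  if (!any(a$resno == i + 1L))
    stop(sprintf("segment %d-%d does not exist", i, i + 1L))
  sqrt(sum((as.numeric(a[up, c("x", "y", "z")]) -
            as.numeric(a[lo, c("x", "y", "z")]))^2))
}

## the residue whose sidechain sits against the torsional axis: the pivot
## residue itself for a psi torsion (its sidechain moves with the lifted
## chain), the preceding residue for a phi torsion
.nearAxisResidue <- function(axis) {
  if (axis@kind == "psi") axis@residue else axis@residue - 1L
}

#' Near-axis steric contact distances along a pathway
#'
#' For the residue adjacent to the torsional axis, reports the minimal
#' distances between its characteristic upper-monomer atoms and the lower
#' monomer, at the barrier-top image and at the local-minimum image. The atom
#' classes follow the steric analysis of twisted-to-flat transitions: for an
#' aspartate neighbour the sidechain carboxyl oxygens against lower-monomer
#' mainchain carbonyl oxygens; for glycine its alpha-hydrogens against lower
#' hydrogens; otherwise all sidechain hydrogens against lower hydrogens.
#'
#' @param path a \linkS4class{ReactionPath} or list of structures.
#' @param axis a \linkS4class{TorsionAxis}.
#' @param barrierIndex,minimumIndex image indices (1-based).
#' @return data.frame of class \code{"ContactReport"}: one row per
#'   upper-monomer atom, columns \code{atom}, \code{pairType},
#'   \code{barrierTop}, \code{localMinimum} (Angstrom), sorted by
#'   \code{barrierTop}.
#' @export
contactTable <- function(path, axis, barrierIndex, minimumIndex) {
  imgs <- if (is(path, "ReactionPath")) path@images else path
  stopifnot(is(axis, "TorsionAxis"))
  if (barrierIndex < 1L || barrierIndex > length(imgs) ||
      minimumIndex < 1L || minimumIndex > length(imgs))
    stop("image index out of range")
  resi <- .nearAxisResidue(axis)
  s <- imgs[[barrierIndex]]
  a <- s@atoms
  if (!any(!is.na(a$layer))) stop("contact table needs layer labels")
  code <- a$resid[a$layer == "upper" & a$resno == resi][1L]
  if (is.na(code)) stop("near-axis residue not present in the upper monomer")
  upSel <- a$layer == "upper" & a$resno == resi
  if (code == "ASP") {
    upAtoms <- which(upSel & a$chainclass == "sidechain" & a$elesy == "O")
    loSel <- a$layer == "lower" & a$elety == "O"
    pairType <- "O-O"
  } else if (code == "GLY") {
    upAtoms <- which(upSel & a$elesy == "H" & grepl("^HA", a$elety))
    loSel <- a$layer == "lower" & a$elesy == "H"
    pairType <- "H-H"
  } else {
    upAtoms <- which(upSel & a$chainclass == "sidechain" & a$elesy == "H")
    loSel <- a$layer == "lower" & a$elesy == "H"
    pairType <- "H-H"
  }
  if (!length(upAtoms))
    stop(sprintf("residue %d (%s) lacks the contact atom class", resi, code))
  minDist <- function(img) {
    xyz <- atomCoords(img)
    lo <- xyz[which(loSel), , drop = FALSE]
    vapply(upAtoms, function(i)
      min(sqrt(rowSums(sweep(lo, 2L, xyz[i, ])^2))), numeric(1L))
  }
  res <- data.frame(atom = a$elety[upAtoms], pairType = pairType,
                    barrierTop = minDist(imgs[[barrierIndex]]),
                    localMinimum = minDist(imgs[[minimumIndex]]),
                    stringsAsFactors = FALSE)
  res <- res[order(res$barrierTop), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("ContactReport", class(res))
  res
}
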