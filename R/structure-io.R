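# Reading, writing and topology inference for peptide structures and
# pathway ensembles. PDB parsing is delegated to bio3d; the PDB writer and the
# concatenated-XYZ trajectory dialect are implemented here.

## covalent radii (Angstrom) for the elements occurring in peptides
.COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

.BOND_SCALE <- 1.2  # bond if d < .BOND_SCALE * (r1 + r2)

## mainchain atom names; glycine's second alpha-hydrogen (HA2) is classed as
## its sidechain (the glycine "sidechain" is that single hydrogen atom)
.MAINCHAIN_NAMES <- c("N", "CA", "C", "O", "H", "HA", "H1", "H2",
                      "OXT", "HXT", "HA1")

.elementFromName <- function(name) {
  toupper(substr(gsub("^[0-9]+", "", name), 1L, 1L))
}

.classifyAtom <- function(elety, resid) {
  cls <- ifelse(elety %in% .MAINCHAIN_NAMES, "mainchain", "sidechain")
  ## non-glycine residues name their alpha hydrogen HA (mainchain); a glycine
  ## HA2 falls through to sidechain because it is not in the mainchain list
  cls
}

## split atom row indices by residue, in monomer/resno order
.residueIndex <- function(a) {
  key <- paste(a$monomer, a$resno, sep = ":")
  split(seq_len(nrow(a)), factor(key, levels = unique(key)))
}

## infer covalent bonds within each monomer by covalent-radius cutoff
.inferBonds <- function(a) {
  out <- vector("list", length(unique(a$monomer)))
  k <- 0L
  for (m in sort(unique(a$monomer))) {
    idx <- which(a$monomer == m)
    xyz <- as.matrix(a[idx, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    r <- .COVALENT_RADII[a$elesy[idx]]
    if (anyNA(r)) stop("unknown element for bond inference: ",
                       paste(unique(a$elesy[idx][is.na(r)]), collapse = ", "))
    cut <- .BOND_SCALE * outer(r, r, "+")
    hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
    ## never bond two hydrogens
    hh <- a$elesy[idx[hit[, 1L]]] == "H" & a$elesy[idx[hit[, 2L]]] == "H"
    hit <- hit[!hh, , drop = FALSE]
    k <- k + 1L
    out[[k]] <- cbind(idx[hit[, 1L]], idx[hit[, 2L]])
  }
  bonds <- do.call(rbind, out)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0L, 2L)
  storage.mode(bonds) <- "integer"
  bonds
}

## adjacency list from a bond matrix
.bondAdjacency <- function(bonds, n) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1L]; j <- bonds[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

## assemble a PeptideStructure from a raw atom table, inferring topology
.makeStructure <- function(a, provenance = "", checkChain = TRUE) {
  if (nrow(a) == 0L) stop("format error: structure has no atoms")
  a$elesy <- .elementFromName(a$elety)
  a <- a[order(a$monomer, a$resno), , drop = FALSE]
  rownames(a) <- NULL
  a$eleno <- seq_len(nrow(a))
  a$chainclass <- .classifyAtom(a$elety, a$resid)
  if (is.null(a$layer)) a$layer <- NA_character_
  ## topology error naming the residue, before S4 validity
  for (m in unique(a$monomer)) {
    for (r in unique(a$resno[a$monomer == m])) {
      nm <- a$elety[a$monomer == m & a$resno == r]
      miss <- setdiff(c("N", "CA", "C", "O"), nm)
      if (length(miss))
        stop(sprintf("topology error: residue %d (monomer %d) lacks backbone atom(s) %s",
                     r, m, paste(miss, collapse = ",")))
    }
  }
  bonds <- .inferBonds(a)
  s <- new("PeptideStructure", atoms = a, bonds = bonds,
           provenance = as.character(provenance))
  validObject(s)
  if (checkChain) .checkPeptideChain(s)
  s
}

## peptide-bond connectivity C(i)-N(i+1) < 2.0 A within each monomer
.checkPeptideChain <- function(s) {
  a <- s@atoms
  for (m in unique(a$monomer)) {
    pos <- unique(a$resno[a$monomer == m])
    if (length(pos) < 2L) next
    for (k in seq_len(length(pos) - 1L)) {
      ci <- which(a$monomer == m & a$resno == pos[k] & a$elety == "C")
      ni <- which(a$monomer == m & a$resno == pos[k + 1L] & a$elety == "N")
      d <- sqrt(sum((as.numeric(a[ci, c("x", "y", "z")]) -
                     as.numeric(a[ni, c("x", "y", "z")]))^2))
      if (d >= 2.0)
        stop(sprintf("topology error: broken peptide bond %d-%d (monomer %d), C-N = %.2f A",
                     pos[k], pos[k + 1L], m, d))
    }
  }
  invisible(TRUE)
}

#' Read a peptide structure from PDB or XYZ
#'
#' Parses a single-structure file, infers topology (covalent bonds,
#' mainchain/sidechain partition) and, for dimers, assigns upper/lower layer
#' labels geometrically (chain identifiers are not trusted). The XYZ format
#' carries no residue information, so reading it requires a \code{template}
#' structure providing the topology in matching atom order.
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"xyz"}.
#' @param template a \linkS4class{PeptideStructure} supplying topology when
#'   \code{format = "xyz"}; ignored for PDB.
#' @return a \linkS4class{PeptideStructure}.
#' @export
readStructure <- function(path, format = c("pdb", "xyz"), template = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                    error = function(e) stop("format error: unparseable PDB (",
                                             conditionMessage(e), ")"))
    at <- pdb$atom
    if (is.null(at) || nrow(at) == 0L) stop("format error: no ATOM records")
    chain <- at$chain
    chain[is.na(chain) | chain == ""] <- "A"
    mono <- match(chain, unique(chain))
    a <- data.frame(eleno = seq_len(nrow(at)), elety = at$elety,
                    elesy = .elementFromName(at$elety),
                    resno = as.integer(at$resno), resid = at$resid,
                    monomer = as.integer(mono), layer = NA_character_,
                    chainclass = "sidechain",
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
    s <- .makeStructure(a, provenance = path)
  } else {
    fr <- .readXyzFrames(path)
    if (length(fr) == 0L) stop("format error: no XYZ frames")
    if (is.null(template))
      stop("reading XYZ needs a 'template' structure supplying the topology")
    s <- .applyFrame(template, fr[[1L]], provenance = path)
  }
  if (nMonomers(s) == 2L) s <- assignLayers(s) else s
}

## map one xyz frame (element + coords) onto a template topology
.applyFrame <- function(template, frame, provenance = "") {
  stopifnot(is(template, "PeptideStructure"))
  if (nrow(frame$xyz) != nAtoms(template))
    stop("format error: frame atom count does not match template")
  if (!all(toupper(frame$el) == template@atoms$elesy))
    stop("format error: frame element order does not match template")
  s <- template
  atomCoords(s) <- frame$xyz
  s@provenance <- as.character(provenance)
  s
}

## parse concatenated XYZ frames: n / comment / n lines of "El x y z"
.readXyzFrames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0L) stop("format error: bad XYZ frame header at line ", i)
    if (i + 1L + n > length(lines)) stop("format error: truncated XYZ frame")
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(trimws(body), "\\s+")
    if (any(lengths(tok) < 4L)) stop("format error: malformed XYZ atom line")
    el <- vapply(tok, `[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3L)))
    if (!all(is.finite(xyz))) stop("format error: non-numeric XYZ coordinates")
    frames[[length(frames) + 1L]] <- list(el = el, xyz = xyz)
    i <- i + 2L + n
  }
  frames
}

#' Write a peptide structure to PDB or XYZ
#'
#' PDB output uses chain A for the upper monomer and chain B for the lower
#' (monomer order when layers are unassigned); coordinates are written at PDB
#' precision (0.001 Angstrom).
#'
#' @param s a \linkS4class{PeptideStructure}.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"xyz"}.
#' @return invisibly, \code{path}.
#' @export
writeStructure <- function(s, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(is(s, "PeptideStructure"))
  lines <- if (format == "pdb") .pdbLines(s) else .xyzLines(s)
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write to ", path)
  invisible(path)
}

.chainOf <- function(a) {
  if (all(is.na(a$layer))) {
    c("A", "B")[a$monomer]
  } else {
    ifelse(a$layer == "upper", "A", "B")
  }
}

.pdbLines <- function(s, modelNo = NA) {
  a <- s@atoms
  chain <- .chainOf(a)
  lines <- character(0L)
  if (!is.na(modelNo)) lines <- sprintf("MODEL     %4d", modelNo)
  serial <- 0L
  for (m in sort(unique(a$monomer))) {
    rows <- which(a$monomer == m)
    for (i in rows) {
      serial <- serial + 1L
      nm <- a$elety[i]
      namefld <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namefld, a$resid[i], chain[i], a$resno[i],
        a$x[i], a$y[i], a$z[i], 1, 0, a$elesy[i]))
    }
    serial <- serial + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %-3s %s%4d",
                              serial, a$resid[last], chain[last], a$resno[last]))
  }
  c(lines, if (!is.na(modelNo)) "ENDMDL" else "END")
}

.xyzLines <- function(s, comment = "BetaTwist structure") {
  a <- s@atoms
  c(sprintf("%d", nrow(a)), comment,
    sprintf("%-2s %14.6f %14.6f %14.6f", a$elesy, a$x, a$y, a$z))
}

#' Read a pathway ensemble (ordered list of structures)
#'
#' Accepts a multi-model PDB file, a concatenated-XYZ trajectory, or a
#' directory of single-model PDB files (lexicographic order). All models must
#' share atom count and ordering.
#'
#' @param path file or directory path.
#' @param format \code{"pdb"} or \code{"xyz"} (ignored for directories).
#' @param template topology template, required for XYZ input.
#' @return list of \linkS4class{PeptideStructure}, in path order.
#' @export
readPath <- function(path, format = c("pdb", "xyz"), template = NULL) {
  format <- match.arg(format)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
    if (length(files) < 2L) stop("a path needs >= 2 images")
    imgs <- lapply(files, readStructure, format = "pdb")
  } else if (format == "pdb") {
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("format error: unparseable multi-model PDB (",
                               conditionMessage(e), ")"))
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || nmod < 2L) stop("a path needs >= 2 images")
    first <- readStructure(path, format = "pdb")
    ## bio3d returns models as rows of an xyz matrix in original atom order;
    ## re-apply the ordering used by .makeStructure
    at <- pdb$atom
    chain <- at$chain; chain[is.na(chain) | chain == ""] <- "A"
    mono <- match(chain, unique(chain))
    ord <- order(mono, as.integer(at$resno))
    imgs <- lapply(seq_len(nmod), function(k) {
      xyz <- matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE)[ord, , drop = FALSE]
      s <- first
      atomCoords(s) <- xyz
      s@provenance <- sprintf("%s [model %d]", path, k)
      s
    })
  } else {
    fr <- .readXyzFrames(path)
    if (length(fr) < 2L) stop("a path needs >= 2 images")
    if (is.null(template))
      stop("reading an XYZ trajectory needs a 'template' structure")
    imgs <- lapply(seq_along(fr), function(k)
      .applyFrame(template, fr[[k]],
                  provenance = sprintf("%s [frame %d]", path, k)))
  }
  n <- vapply(imgs, nAtoms, integer(1L))
  if (length(unique(n)) != 1L)
    stop("inconsistent atom counts across path images")
  imgs
}

#' Write a pathway ensemble
#'
#' @param images list of \linkS4class{PeptideStructure} sharing one topology,
#'   or a \linkS4class{ReactionPath}.
#' @param path output file.
#' @param format \code{"pdb"} (multi-model) or \code{"xyz"} (concatenated).
#' @return invisibly, \code{path}.
#' @export
writePath <- function(images, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (is(images, "ReactionPath")) images <- images@images
  stopifnot(length(images) >= 2L)
  lines <- unlist(lapply(seq_along(images), function(k) {
    if (format == "pdb") .pdbLines(images[[k]], modelNo = k)
    else .xyzLines(images[[k]], comment = sprintf("frame %d", k))
  }))
  if (format == "pdb") lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' Assign upper/lower layer labels to a dimer
#'
#' The stacking axis is the normal of the least-squares plane through the
#' Calpha atoms of one monomer (equivalent for exact translates); the monomer
#' with the greater mean projection onto that axis is labelled \code{upper}.
#' The normal's sign is fixed deterministically (largest-magnitude component
#' made positive), so the labelling is invariant under monomer input order.
#'
#' @param s a dimeric \linkS4class{PeptideStructure}.
#' @return the structure with \code{layer} labels set.
#' @export
assignLayers <- function(s) {
  stopifnot(is(s, "PeptideStructure"))
  a <- s@atoms
  if (length(unique(a$monomer)) != 2L)
    stop("layer assignment needs a dimer")
  m1 <- min(a$monomer)
  ca <- a[a$monomer == m1 & a$elety == "CA", c("x", "y", "z")]
  n <- .stackingAxis(as.matrix(ca), a)
  proj <- vapply(sort(unique(a$monomer)), function(m) {
    sel <- a$monomer == m & a$elety == "CA"
    mean(as.matrix(a[sel, c("x", "y", "z")]) %*% n)
  }, numeric(1L))
  if (abs(diff(proj)) < 1e-3)
    stop("degenerate geometry: monomer centroids coincide along the stacking axis")
  upper <- sort(unique(a$monomer))[which.max(proj)]
  a$layer <- ifelse(a$monomer == upper, "upper", "lower")
  s@atoms <- a
  validObject(s)
  s
}

## unit normal of the least-squares plane through points (n x 3), sign fixed
.planeNormal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2L, ctr), nv = 3L)
  n <- sv$v[, 3L]
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  n
}

## stacking axis for layer assignment: the lower-monomer Calpha plane normal
## when the plane is well conditioned, otherwise (few or collinear Calpha
## atoms) the inter-monomer centroid direction; sign fixed deterministically
.stackingAxis <- function(ca, a) {
  if (nrow(ca) >= 3L) {
    sv <- svd(sweep(ca, 2L, colMeans(ca)), nv = 3L)
    if (sv$d[2L] > 0.1) {
      n <- sv$v[, 3L]
      k <- which.max(abs(n))
      return(if (n[k] < 0) -n else n)
    }
  }
  ms <- sort(unique(a$monomer))
  c1 <- colMeans(as.matrix(a[a$monomer == ms[1L], c("x", "y", "z")]))
  c2 <- colMeans(as.matrix(a[a$monomer == ms[2L], c("x", "y", "z")]))
  d <- c2 - c1
  if (.vnorm(d) < 1e-6)
    stop("degenerate geometry: monomer centroids coincide along the stacking axis")
  n <- d / .vnorm(d)
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  n
}
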