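#' @import methods
NULL

#' PeptideStructure: atoms, topology and layer labels of a peptide (dimer)
#'
#' The universal carrier for all analyses in the package. Atoms are stored as a
#' data frame (one row per atom) holding the PDB-style atom name, element,
#' residue number in amyloid-beta(1-42) numbering, three-letter residue code,
#' monomer index, layer label (\code{"upper"}/\code{"lower"} once assigned),
#' mainchain/sidechain class and Cartesian coordinates in Angstrom. Covalent
#' bonds (inferred by covalent-radius cutoff) are stored as a two-column index
#' matrix.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety},
#'   \code{elesy}, \code{resno}, \code{resid}, \code{monomer}, \code{layer},
#'   \code{chainclass}, \code{x}, \code{y}, \code{z}.
#' @slot bonds integer matrix, two columns of atom row indices.
#' @slot provenance free-text origin of the coordinates.
#' @export
setClass("PeptideStructure",
  representation(atoms = "data.frame", bonds = "matrix",
                 provenance = "character"))

setValidity("PeptideStructure", function(object) {
  a <- object@atoms
  need <- c("eleno", "elety", "elesy", "resno", "resid", "monomer", "layer",
            "chainclass", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atom table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("non-finite coordinates")
  pre <- substr(gsub("[^A-Za-z].*$", "", a$elety), 1L, 1L)
  if (!all(toupper(pre) == toupper(a$elesy)))
    return("element symbol inconsistent with atom-name prefix")
  if (!all(a$chainclass %in% c("mainchain", "sidechain")))
    return("chainclass must be 'mainchain' or 'sidechain'")
  if (!all(a$monomer %in% c(1L, 2L)))
    return("monomer index must be 1 or 2")
  ## residue positions strictly increasing within each monomer
  for (m in unique(a$monomer)) {
    rp <- unique(a$resno[a$monomer == m])
    if (any(diff(rp) <= 0L))
      return("residue positions not strictly increasing within a monomer")
    ## every residue has the core mainchain atoms
    for (r in rp) {
      nm <- a$elety[a$monomer == m & a$resno == r]
      if (!all(c("N", "CA", "C", "O") %in% nm))
        return(sprintf("residue %d (monomer %d) lacks backbone atoms", r, m))
    }
  }
  lay <- unique(a$layer[!is.na(a$layer)])
  if (length(lay) && length(unique(a$monomer)) == 2L) {
    if (!setequal(lay, c("upper", "lower")))
      return("a labelled dimer needs exactly one upper and one lower monomer")
    bym <- tapply(a$layer, a$monomer, function(z) unique(z))
    if (any(lengths(bym) != 1L))
      return("layer label must be constant within a monomer")
  }
  TRUE
})

#' TorsionAxis: a backbone phi/psi rotation axis plus its moving set
#'
#' Describes rotation about the N-Calpha (phi) or Calpha-C (psi) bond of one
#' residue of the upper monomer. \code{axisAtoms} are the two atom row indices
#' spanning the bond, ordered N-to-C; \code{movingSet} are the atom row indices
#' that rotate (the chain N-terminal of the axis, lifted off the lower layer).
#'
#' @slot residue residue position (amyloid-beta numbering).
#' @slot kind \code{"psi"} or \code{"phi"}.
#' @slot monomer monomer index the axis belongs to.
#' @slot axisAtoms integer(2), atom row indices of the bond, N-side first.
#' @slot movingSet integer vector of rotated atom row indices.
#' @export
setClass("TorsionAxis",
  representation(residue = "integer", kind = "character", monomer = "integer",
                 axisAtoms = "integer", movingSet = "integer"))

setValidity("TorsionAxis", function(object) {
  if (!object@kind %in% c("psi", "phi")) return("kind must be 'psi' or 'phi'")
  if (length(object@axisAtoms) != 2L) return("axisAtoms must have length 2")
  TRUE
})

#' ReactionPath: an ordered chain of structures with surrogate energies
#'
#' The minimum-energy-path object: an ordered list of images sharing one
#' topology, the per-image surrogate energy, the band spring constant and a
#' convergence flag. The first image is the flat reference, the last the
#' twisted endpoint.
#'
#' @slot images list of \linkS4class{PeptideStructure} with identical topology.
#' @slot energies numeric vector parallel to \code{images} (surrogate units).
#' @slot springK band spring constant (surrogate unit per Angstrom squared).
#' @slot converged logical convergence flag of the last relaxation.
#' @export
setClass("ReactionPath",
  representation(images = "list", energies = "numeric", springK = "numeric",
                 converged = "logical"))

setValidity("ReactionPath", function(object) {
  if (length(object@images) < 2L) return("a path needs at least 2 images")
  if (length(object@energies) &&
      length(object@energies) != length(object@images))
    return("energies must parallel images")
  n <- vapply(object@images, nAtoms, integer(1L))
  if (length(unique(n)) != 1L) return("images differ in atom count")
  TRUE
})

## ---- accessors -------------------------------------------------------------

#' @describeIn PeptideStructure-accessors atom table of a structure
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @describeIn PeptideStructure-accessors coordinate matrix (n x 3, Angstrom)
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @describeIn PeptideStructure-accessors replace the coordinate matrix
#' @export
setGeneric("atomCoords<-", function(x, value) standardGeneric("atomCoords<-"))

#' @describeIn PeptideStructure-accessors number of atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn PeptideStructure-accessors covalent bond index matrix
#' @export
setGeneric("covalentBonds", function(x) standardGeneric("covalentBonds"))

#' @describeIn PeptideStructure-accessors number of monomers (1 or 2)
#' @export
setGeneric("nMonomers", function(x) standardGeneric("nMonomers"))

#' Accessors for PeptideStructure
#' @name PeptideStructure-accessors
#' @param x a \linkS4class{PeptideStructure}.
#' @param value replacement n x 3 coordinate matrix.
NULL

#' @export
setMethod("atomRecords", "PeptideStructure", function(x) x@atoms)

#' @export
setMethod("atomCoords", "PeptideStructure", function(x)
  unname(as.matrix(x@atoms[, c("x", "y", "z")])))

#' @export
setMethod("atomCoords<-", "PeptideStructure", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1L]
  x@atoms$y <- value[, 2L]
  x@atoms$z <- value[, 3L]
  x
})

#' @export
setMethod("nAtoms", "PeptideStructure", function(x) nrow(x@atoms))

#' @export
setMethod("covalentBonds", "PeptideStructure", function(x) x@bonds)

#' @export
setMethod("nMonomers", "PeptideStructure", function(x)
  length(unique(x@atoms$monomer)))

#' @export
setGeneric("pathImages", function(x) standardGeneric("pathImages"))

#' @describeIn ReactionPath-accessors list of images
#' @export
setMethod("pathImages", "ReactionPath", function(x) x@images)

#' @export
setGeneric("pathEnergies", function(x) standardGeneric("pathEnergies"))

#' Accessors for ReactionPath
#' @name ReactionPath-accessors
#' @param x a \linkS4class{ReactionPath}.
NULL

#' @describeIn ReactionPath-accessors per-image surrogate energies
#' @export
setMethod("pathEnergies", "ReactionPath", function(x) x@energies)

#' @export
setGeneric("axisLabel", function(x) standardGeneric("axisLabel"))

#' @describeIn TorsionAxis-class compact label such as \code{"G25:psi"}
#' @export
setMethod("axisLabel", "TorsionAxis", function(x) {
  ## one-letter code of the pivot residue is resolved lazily by callers that
  ## hold the structure; here the numeric label is enough
  sprintf("%d:%s", x@residue, x@kind)
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "PeptideStructure", function(object) {
  a <- object@atoms
  nres <- length(unique(paste(a$monomer, a$resno)))
  cat("PeptideStructure:", nrow(a), "atoms,", nres, "residues,",
      length(unique(a$monomer)), "monomer(s)\n")
  if (any(!is.na(a$layer)))
    cat("  layers assigned (upper/lower)\n")
  for (m in sort(unique(a$monomer))) {
    rr <- a[a$monomer == m, ]
    pos <- unique(rr$resno)
    cat(sprintf("  monomer %d: residues %d-%d (%s)\n", m, min(pos), max(pos),
                paste(bio3d::aa321(rr$resid[!duplicated(rr$resno)]),
                      collapse = "")))
  }
  if (nzchar(object@provenance[1L]))
    cat("  provenance:", object@provenance[1L], "\n")
})

setMethod("show", "TorsionAxis", function(object) {
  cat(sprintf("TorsionAxis: %s torsion at residue %d (monomer %d), %d moving atoms\n",
              object@kind, object@residue, object@monomer,
              length(object@movingSet)))
})

setMethod("show", "ReactionPath", function(object) {
  cat("ReactionPath:", length(object@images), "images")
  if (length(object@energies)) {
    rel <- object@energies - object@energies[1L]
    cat(sprintf(", barrier (rel. units) %.4f", max(rel)))
  }
  cat(if (isTRUE(object@converged)) ", converged\n" else ", not converged\n")
})
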