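# Nudged-elastic-band relaxation of flat-to-twisted pathways, with a generic
# core usable on any differentiable potential, path interpolation, and
# activation-barrier extraction.

#' Interpolate a path between flat and twisted conformations
#'
#' \code{mode = "dihedral"} sweeps the torsion angle of \code{axis} linearly
#' between the endpoint values (shortest arc), applying a rigid torsion to the
#' flat structure for each interior image; covalent bond lengths are preserved
#' exactly along such a path. \code{mode = "cartesian"} interpolates
#' coordinates linearly (bond lengths contract through the sweep). Endpoints
#' are kept exactly as supplied.
#'
#' @param flat,twisted endpoint \linkS4class{PeptideStructure}s sharing one
#'   topology.
#' @param axis \linkS4class{TorsionAxis} (required for dihedral mode).
#' @param nImages total number of images (>= 3).
#' @param mode \code{"dihedral"} or \code{"cartesian"}.
#' @return a \linkS4class{ReactionPath} (energies not yet computed).
#' @export
interpolatePath <- function(flat, twisted, axis = NULL, nImages = 8L,
                            mode = c("dihedral", "cartesian")) {
  mode <- match.arg(mode)
  stopifnot(is(flat, "PeptideStructure"), is(twisted, "PeptideStructure"))
  if (nImages < 3L) stop("a path needs at least 3 images")
  af <- flat@atoms; at <- twisted@atoms
  if (nrow(af) != nrow(at) || !all(af$elety == at$elety) ||
      !all(af$resno == at$resno))
    stop("mismatched topologies between endpoints")
  frac <- seq(0, 1, length.out = nImages)
  imgs <- vector("list", nImages)
  imgs[[1L]] <- flat
  imgs[[nImages]] <- twisted
  if (mode == "dihedral") {
    if (is.null(axis)) stop("dihedral mode needs a torsion axis")
    d0 <- measureDihedral(flat, axis@residue, axis@kind)
    d1 <- measureDihedral(twisted, axis@residue, axis@kind)
    sweepAngle <- .wrapAngle(d1 - d0)
    for (k in 2:(nImages - 1L))
      imgs[[k]] <- applyTorsion(flat, axis, frac[k] * sweepAngle)@structure
  } else {
    X0 <- atomCoords(flat); X1 <- atomCoords(twisted)
    for (k in 2:(nImages - 1L)) {
      s <- flat
      atomCoords(s) <- (1 - frac[k]) * X0 + frac[k] * X1
      imgs[[k]] <- s
    }
  }
  new("ReactionPath", images = imgs, energies = numeric(0), springK = 1.0,
      converged = FALSE)
}

## improved (energy-weighted) tangent of interior image i (Henkelman-Jonsson)
.nebTangent <- function(X, E, i) {
  tp <- X[i + 1L, ] - X[i, ]
  tm <- X[i, ] - X[i - 1L, ]
  if (E[i + 1L] > E[i] && E[i] > E[i - 1L]) {
    tau <- tp
  } else if (E[i + 1L] < E[i] && E[i] < E[i - 1L]) {
    tau <- tm
  } else {
    dmax <- max(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
    dmin <- min(abs(E[i + 1L] - E[i]), abs(E[i - 1L] - E[i]))
    tau <- if (E[i + 1L] > E[i - 1L]) tp * dmax + tm * dmin
           else tp * dmin + tm * dmax
  }
  n <- sqrt(sum(tau^2))
  if (n < 1e-12) tau else tau / n
}

## generic NEB relaxation with a FIRE optimizer.
## X: nImages x ndof matrix of row-vector images; efun/gfun take one vector.
.nebCore <- function(X, efun, gfun, springK = 1.0, climbing = FALSE,
                     tol = 1e-3, maxIter = 5000L) {
  m <- nrow(X)
  if (m < 3L) stop("NEB needs at least 3 images")
  interior <- 2:(m - 1L)
  V <- matrix(0, m, ncol(X))          # FIRE velocities (interior rows used)
  dt <- 0.05; dtMax <- 0.5
  alpha0 <- 0.1; alpha <- alpha0
  nUp <- 0L
  converged <- FALSE
  E <- apply(X, 1L, efun)
  if (!all(is.finite(E))) stop("non-finite energy on an initial image")
  for (iter in seq_len(maxIter)) {
    G <- t(vapply(interior, function(i) gfun(X[i, ]), numeric(ncol(X))))
    top <- which.max(E)
    Fmat <- matrix(0, m, ncol(X))
    for (r in seq_along(interior)) {
      i <- interior[r]
      tau <- .nebTangent(X, E, i)
      Ftrue <- -G[r, ]
      if (climbing && i == top) {
        Fmat[i, ] <- Ftrue - 2 * sum(Ftrue * tau) * tau
      } else {
        Fperp <- Ftrue - sum(Ftrue * tau) * tau
        Fspr <- springK * (sqrt(sum((X[i + 1L, ] - X[i, ])^2)) -
                           sqrt(sum((X[i, ] - X[i - 1L, ])^2))) * tau
        Fmat[i, ] <- Fperp + Fspr
      }
    }
    fmax <- max(abs(Fmat[interior, ]))
    if (fmax <= tol) { converged <- TRUE; break }
    ## FIRE update on the interior images
    P <- sum(V[interior, ] * Fmat[interior, ])
    if (P > 0) {
      nUp <- nUp + 1L
      if (nUp > 5L) { dt <- min(dt * 1.1, dtMax); alpha <- alpha * 0.99 }
      vn <- sqrt(sum(V[interior, ]^2)); fn <- sqrt(sum(Fmat[interior, ]^2))
      if (fn > 0)
        V[interior, ] <- (1 - alpha) * V[interior, ] +
          alpha * vn * Fmat[interior, ] / fn
    } else {
      V[interior, ] <- 0
      dt <- dt * 0.5
      alpha <- alpha0
      nUp <- 0L
    }
    V[interior, ] <- V[interior, ] + dt * Fmat[interior, ]
    step <- dt * V[interior, , drop = FALSE]
    ## cap the per-coordinate displacement for stability
    step[step > 0.2] <- 0.2; step[step < -0.2] <- -0.2
    X[interior, ] <- X[interior, , drop = FALSE] + step
    E[interior] <- apply(X[interior, , drop = FALSE], 1L, efun)
    if (!all(is.finite(E))) stop("non-finite energy during NEB relaxation")
  }
  list(X = X, energies = E, converged = converged, iterations = iter)
}

#' NEB relaxation on an arbitrary potential
#'
#' Generic interface to the nudged-elastic-band core: images are rows of a
#' matrix, the potential is an R function of one coordinate vector. Intended
#' for analytic test surfaces and custom systems.
#'
#' @param images nImages x ndof matrix; first and last rows are the fixed
#'   endpoints.
#' @param energyFn function(x) -> scalar.
#' @param gradFn function(x) -> gradient vector; if \code{NULL}, a central
#'   finite difference is used.
#' @param springK band spring constant.
#' @param climbing use a climbing highest image.
#' @param tol maximum force component for convergence.
#' @param maxIter iteration budget.
#' @return list with \code{images}, \code{energies}, \code{converged},
#'   \code{iterations}.
#' @export
nebRelaxGeneric <- function(images, energyFn, gradFn = NULL, springK = 1.0,
                            climbing = FALSE, tol = 1e-3, maxIter = 5000L) {
  stopifnot(is.matrix(images))
  if (is.null(gradFn)) {
    h <- 1e-6
    gradFn <- function(x) {
      vapply(seq_along(x), function(k) {
        xp <- x; xp[k] <- xp[k] + h
        xm <- x; xm[k] <- xm[k] - h
        (energyFn(xp) - energyFn(xm)) / (2 * h)
      }, numeric(1L))
    }
  }
  .nebCore(images, energyFn, gradFn, springK, climbing, tol, maxIter)
}

#' Relax a molecular reaction path with the nudged elastic band
#'
#' Relaxes the interior images of a flat-to-twisted path under the surrogate
#' energy. The endpoints are never moved. The surrogate model (pair lists and
#' covalent-restraint targets) is built once from the first (flat) image.
#'
#' @param path a \linkS4class{ReactionPath}.
#' @param params an \code{\link{energyParams}} object.
#' @param springK band spring constant (surrogate unit per Angstrom squared).
#' @param climbing use a climbing highest image (off by default).
#' @param tol maximum force component for convergence, surrogate unit per
#'   Angstrom.
#' @param maxIter iteration budget.
#' @return the relaxed \linkS4class{ReactionPath} with per-image energies.
#' @export
nebRelax <- function(path, params = energyParams(), springK = 1.0,
                     climbing = FALSE, tol = 1e-3, maxIter = 5000L) {
  stopifnot(is(path, "ReactionPath"))
  imgs <- path@images
  if (length(imgs) < 3L) stop("NEB needs at least 3 images")
  model <- .energyModel(imgs[[1L]], params)
  X <- t(vapply(imgs, function(s) as.vector(atomCoords(s)),
                numeric(3L * nAtoms(imgs[[1L]]))))
  efun <- function(x) .modelEnergy(model, matrix(x, ncol = 3L))
  gfun <- function(x) as.vector(.modelGradient(model, matrix(x, ncol = 3L)))
  res <- .nebCore(X, efun, gfun, springK, climbing, tol, maxIter)
  out <- imgs
  for (k in seq_along(out)) {
    s <- out[[k]]
    atomCoords(s) <- matrix(res$X[k, ], ncol = 3L)
    out[[k]] <- s
  }
  new("ReactionPath", images = out, energies = res$energies,
      springK = springK, converged = res$converged)
}

#' Activation barriers of a reaction path
#'
#' The barrier top is the image of maximum energy. The twisted-to-flat barrier
#' is E(top) - E(last image), the flat-to-twisted barrier E(top) - E(first
#' image), and the endothermic energy E(last) - E(first); by construction
#' \code{barrierFlatToTwisted - barrierTwistedToFlat = endothermicEnergy}
#' exactly.
#'
#' @param path a \linkS4class{ReactionPath} with energies, or a numeric
#'   energy vector.
#' @return list of class \code{"BarrierReport"}: \code{barrierTwistedToFlat},
#'   \code{barrierFlatToTwisted}, \code{topIndex}, \code{endothermicEnergy}.
#' @export
barrierReport <- function(path) {
  E <- if (is(path, "ReactionPath")) path@energies else as.numeric(path)
  if (!length(E)) stop("empty path / energies not computed")
  top <- which.max(E)
  b_tf <- E[top] - E[length(E)]
  b_ft <- E[top] - E[1L]
  structure(list(
    barrierTwistedToFlat = b_tf,
    barrierFlatToTwisted = b_ft,
    topIndex = as.integer(top),
    ## computed as the barrier difference so the defining identity
    ## barrierFlatToTwisted - barrierTwistedToFlat = endothermic is exact
    ## in floating point as well
    endothermicEnergy = b_ft - b_tf),
    class = "BarrierReport")
}

#' @export
print.BarrierReport <- function(x, ...) {
  cat(sprintf("BarrierReport: twisted->flat %.4f, flat->twisted %.4f, endothermic %.4f (top image %d)\n",
              x$barrierTwistedToFlat, x$barrierFlatToTwisted,
              x$endothermicEnergy, x$topIndex))
  invisible(x)
}
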