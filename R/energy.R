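# Coarse surrogate energy for peptide dimers: a 12-6 steric term, a smooth
# hydrogen-bond well factored into donor-acceptor distance and D-H...A angle
# parts, and harmonic covalent restraints to a reference topology. The
# surrogate reproduces the qualitative drivers of beta-sheet stability
# (hydrogen bonding, van der Waals packing, steric repulsion); its absolute
# numbers are in arbitrary units and are not comparable to first-principles
# energies.

#' Surrogate energy parameters
#'
#' @param ljEpsilon named per-element 12-6 well depths (surrogate units).
#' @param ljSigma named per-element 12-6 radii, Angstrom. Defaults are
#'   deliberately compact so that ideal beta-sheet packing (4.8 Angstrom
#'   stacking) sits near the steric minimum; the surrogate has no
#'   electrostatic attraction to offset a harder wall.
#' @param ljCutoff pair cutoff, Angstrom; the 12-6 term is shifted to zero at
#'   the cutoff so that well-separated fragments are exactly additive.
#' @param hbWellDepth depth of the hydrogen-bond well, surrogate units.
#' @param hbDistance0 ideal donor-acceptor distance, Angstrom.
#' @param hbDistanceWidth Gaussian width of the distance factor, Angstrom.
#' @param hbAnglePower exponent of the angular factor
#'   \code{max(0, -cos(DHA))^power}.
#' @param restraintKBond harmonic constant tying 1-2 distances to the
#'   reference, surrogate unit per Angstrom squared.
#' @param restraintKAngle harmonic constant tying 1-3 (geminal) distances to
#'   the reference (a distance-based stand-in for bond-angle restraints).
#' @return a parameter list of class \code{"EnergyParams"}.
#' @export
energyParams <- function(ljEpsilon = c(H = 0.02, C = 0.06, N = 0.07, O = 0.08,
                                       S = 0.09),
                         ljSigma = c(H = 2.3, C = 3.2, N = 3.05, O = 2.95,
                                     S = 3.3),
                         ljCutoff = 12,
                         hbWellDepth = 2.0, hbDistance0 = 2.9,
                         hbDistanceWidth = 0.35, hbAnglePower = 4,
                         restraintKBond = 100, restraintKAngle = 30) {
  stopifnot(all(ljEpsilon > 0), all(ljSigma > 0), ljCutoff > 0,
            hbWellDepth > 0, hbDistanceWidth > 0, hbAnglePower > 0,
            restraintKBond > 0, restraintKAngle > 0)
  structure(list(ljEpsilon = ljEpsilon, ljSigma = ljSigma,
                 ljCutoff = ljCutoff, hbWellDepth = hbWellDepth,
                 hbDistance0 = hbDistance0, hbDistanceWidth = hbDistanceWidth,
                 hbAnglePower = hbAnglePower, restraintKBond = restraintKBond,
                 restraintKAngle = restraintKAngle),
            class = "EnergyParams")
}

## distance clamp below which the 12-6 term goes flat: keeps overlapping
## atoms at a large, finite, non-overflowing penalty
.LJ_CLAMP <- 0.8

## precompute pair/triple lists and reference geometry for fast re-evaluation
.energyModel <- function(reference, params) {
  stopifnot(is(reference, "PeptideStructure"),
            inherits(params, "EnergyParams"))
  a <- reference@atoms
  n <- nrow(a)
  xyz <- atomCoords(reference)
  ## non-bonded pairs: everything except 1-2, 1-3 and 1-4 (torsional
  ## neighbours are handled by the restraint terms, not sterics)
  excl <- .excludedPairKeys(reference, through = 3L)
  all <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keys <- all[, 1L] * (n + 1L) + all[, 2L]
  nb <- all[!(keys %in% excl), , drop = FALSE]
  el <- a$elesy
  if (!all(el %in% names(params$ljSigma)))
    stop("ljSigma lacks element(s): ",
         paste(setdiff(unique(el), names(params$ljSigma)), collapse = ", "))
  sig <- (params$ljSigma[el[nb[, 1L]]] + params$ljSigma[el[nb[, 2L]]]) / 2
  eps <- sqrt(params$ljEpsilon[el[nb[, 1L]]] * params$ljEpsilon[el[nb[, 2L]]])
  ## covalent restraints: 1-2 and 1-3 reference distances
  bonds <- reference@bonds
  adj <- .bondAdjacency(bonds, n)
  g13 <- list()
  for (i in seq_len(n)) {
    two <- setdiff(unique(unlist(adj[adj[[i]]])), c(i, adj[[i]]))
    two <- two[two > i]
    if (length(two)) g13[[length(g13) + 1L]] <- cbind(i, two)
  }
  g13 <- if (length(g13)) do.call(rbind, g13) else matrix(integer(0), 0L, 2L)
  dref <- function(p) sqrt(rowSums((xyz[p[, 1L], , drop = FALSE] -
                                    xyz[p[, 2L], , drop = FALSE])^2))
  ## hydrogen-bond triples: donor-H against all acceptors outside the donor's
  ## residue and 1-3 neighbourhood (same exclusions as detection)
  topo <- .hbTopology(reference)
  resKey <- paste(a$monomer, a$resno)
  trip <- list()
  for (k in seq_along(topo$donors)) {
    d <- topo$donors[k]; h <- topo$hydros[k]
    acc <- setdiff(topo$acceptors, .within13(adj = topo$adj, i = d))
    acc <- acc[resKey[acc] != resKey[d]]
    if (length(acc)) trip[[length(trip) + 1L]] <- cbind(d, h, acc)
  }
  trip <- if (length(trip)) do.call(rbind, trip) else matrix(integer(0), 0L, 3L)
  list(n = n, params = params,
       nbI = nb[, 1L], nbJ = nb[, 2L], sig = unname(sig), eps = unname(eps),
       bondI = bonds[, 1L], bondJ = bonds[, 2L], bondRef = dref(bonds),
       angI = g13[, 1L], angJ = g13[, 2L],
       angRef = if (nrow(g13)) dref(g13) else numeric(0),
       hbD = trip[, 1L], hbH = trip[, 2L], hbA = trip[, 3L])
}

## pair distances for index vectors
.pairDist <- function(X, i, j) {
  dx <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  list(dx = dx, r = sqrt(rowSums(dx^2)))
}

.modelEnergy <- function(model, X) {
  p <- model$params
  e <- 0
  ## 12-6 steric term, cutoff-shifted
  pd <- .pairDist(X, model$nbI, model$nbJ)
  r <- pmax(pd$r, .LJ_CLAMP)
  inR <- r < p$ljCutoff
  if (any(inR)) {
    sr6 <- (model$sig[inR] / r[inR])^6
    src6 <- (model$sig[inR] / p$ljCutoff)^6
    e <- e + sum(4 * model$eps[inR] * (sr6^2 - sr6 - src6^2 + src6))
  }
  ## hydrogen-bond well
  if (length(model$hbD)) {
    da <- .pairDist(X, model$hbD, model$hbA)
    f <- exp(-(da$r - p$hbDistance0)^2 / (2 * p$hbDistanceWidth^2))
    u <- X[model$hbD, , drop = FALSE] - X[model$hbH, , drop = FALSE]
    v <- X[model$hbA, , drop = FALSE] - X[model$hbH, , drop = FALSE]
    cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    g <- pmax(0, -cosang)^p$hbAnglePower
    e <- e - p$hbWellDepth * sum(f * g)
  }
  ## covalent restraints
  rb <- .pairDist(X, model$bondI, model$bondJ)$r
  e <- e + p$restraintKBond * sum((rb - model$bondRef)^2)
  if (length(model$angI)) {
    ra <- .pairDist(X, model$angI, model$angJ)$r
    e <- e + p$restraintKAngle * sum((ra - model$angRef)^2)
  }
  e
}

.modelGradient <- function(model, X) {
  p <- model$params
  G <- matrix(0, nrow(X), 3L)
  add <- function(i, vals) {
    gi <- rowsum(vals, i)
    idx <- as.integer(rownames(gi))
    G[idx, ] <<- G[idx, , drop = FALSE] + gi
    invisible(NULL)
  }
  ## 12-6
  pd <- .pairDist(X, model$nbI, model$nbJ)
  r0 <- pd$r
  r <- pmax(r0, .LJ_CLAMP)
  sel <- which(r < p$ljCutoff & r0 > .LJ_CLAMP)
  if (length(sel)) {
    rs <- r[sel]
    sr6 <- (model$sig[sel] / rs)^6
    dEdr <- 4 * model$eps[sel] * (-12 * sr6^2 + 6 * sr6) / rs
    w <- dEdr / rs
    contrib <- pd$dx[sel, , drop = FALSE] * w
    add(model$nbI[sel], contrib)
    add(model$nbJ[sel], -contrib)
  }
  ## hydrogen-bond well
  if (length(model$hbD)) {
    da <- .pairDist(X, model$hbD, model$hbA)
    f <- exp(-(da$r - p$hbDistance0)^2 / (2 * p$hbDistanceWidth^2))
    u <- X[model$hbD, , drop = FALSE] - X[model$hbH, , drop = FALSE]
    v <- X[model$hbA, , drop = FALSE] - X[model$hbH, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cosang <- rowSums(u * v) / (nu * nv)
    act <- which(f > 1e-12 & cosang < 0)
    if (length(act)) {
      fa <- f[act]; ca <- cosang[act]
      ga <- (-ca)^p$hbAnglePower
      ## distance part: dE/d(da) = -D0 * f' * g
      fp <- fa * (-(da$r[act] - p$hbDistance0) / p$hbDistanceWidth^2)
      dEdr <- -p$hbWellDepth * fp * ga
      w <- dEdr / da$r[act]
      contrib <- da$dx[act, , drop = FALSE] * w
      add(model$hbD[act], contrib)
      add(model$hbA[act], -contrib)
      ## angle part: dE/dcos = -D0 * f * g'(cos), g' = -p*(-cos)^(p-1)
      gp <- -p$hbAnglePower * (-ca)^(p$hbAnglePower - 1)
      dEdc <- -p$hbWellDepth * fa * gp
      ua <- u[act, , drop = FALSE]; va <- v[act, , drop = FALSE]
      nua <- nu[act]; nva <- nv[act]
      dcdu <- va / (nua * nva) - ua * (ca / nua^2)
      dcdv <- ua / (nua * nva) - va * (ca / nva^2)
      add(model$hbD[act], dcdu * dEdc)
      add(model$hbA[act], dcdv * dEdc)
      add(model$hbH[act], -(dcdu + dcdv) * dEdc)
    }
  }
  ## restraints
  for (part in list(list(i = model$bondI, j = model$bondJ,
                         ref = model$bondRef, k = p$restraintKBond),
                    list(i = model$angI, j = model$angJ,
                         ref = model$angRef, k = p$restraintKAngle))) {
    if (!length(part$i)) next
    pd <- .pairDist(X, part$i, part$j)
    dEdr <- 2 * part$k * (pd$r - part$ref)
    contrib <- pd$dx * (dEdr / pd$r)
    add(part$i, contrib)
    add(part$j, -contrib)
  }
  G
}

#' Surrogate energy of a structure
#'
#' Evaluates the coarse surrogate energy: cutoff-shifted 12-6 steric term over
#' non-bonded pairs, a hydrogen-bond well (Gaussian in donor-acceptor
#' distance, \code{max(0, -cos)^p} in the D-H...A angle, minimised at ideal
#' geometry) and harmonic restraints tying 1-2/1-3 distances to the
#' \code{reference} topology. Invariant under rigid rotation and translation;
#' overlapping atoms are penalised by a large finite value.
#'
#' @param s a \linkS4class{PeptideStructure}.
#' @param params an \code{\link{energyParams}} object.
#' @param reference structure supplying topology and restraint targets
#'   (default: \code{s} itself, making the restraint terms zero).
#' @return scalar energy, surrogate units.
#' @export
surrogateEnergy <- function(s, params = energyParams(), reference = s) {
  model <- .energyModel(reference, params)
  .modelEnergy(model, atomCoords(s))
}

#' Relax a structure to a local minimum of the surrogate energy
#'
#' Limited-memory BFGS minimisation with the analytic gradient. Convergence is
#' declared when the largest gradient component is at most \code{tol}.
#'
#' @param s starting \linkS4class{PeptideStructure}.
#' @param params an \code{\link{energyParams}} object.
#' @param reference restraint/topology reference (default \code{s}).
#' @param tol gradient tolerance, surrogate unit per Angstrom.
#' @param maxIter iteration budget.
#' @return list with \code{structure}, \code{energy}, \code{converged},
#'   \code{gradMax}.
#' @export
minimizeStructure <- function(s, params = energyParams(), reference = s,
                              tol = 1e-3, maxIter = 500L) {
  model <- .energyModel(reference, params)
  x0 <- as.vector(atomCoords(s))
  e0 <- .modelEnergy(model, matrix(x0, ncol = 3L))
  if (!is.finite(e0)) stop("non-finite energy at the starting structure")
  g0 <- .modelGradient(model, matrix(x0, ncol = 3L))
  if (max(abs(g0)) <= tol) {
    return(list(structure = s, energy = e0, converged = TRUE,
                gradMax = max(abs(g0))))
  }
  fn <- function(x) .modelEnergy(model, matrix(x, ncol = 3L))
  gr <- function(x) as.vector(.modelGradient(model, matrix(x, ncol = 3L)))
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = as.integer(maxIter),
                                     factr = 1e4))
  X <- matrix(opt$par, ncol = 3L)
  gmax <- max(abs(.modelGradient(model, X)))
  out <- s
  atomCoords(out) <- X
  list(structure = out, energy = opt$value, converged = gmax <= tol,
       gradMax = gmax)
}

## step-capped FIRE descent: a conservative local minimiser that cannot hop
## out of the starting basin the way a quasi-Newton line search can; used to
## relax twisted candidates, which sit in shallow basins next to the much
## deeper flat minimum
.fireMinimize <- function(model, X, tol = 0.05, maxIter = 500L, cap = 0.15) {
  V <- matrix(0, nrow(X), 3L)
  dt <- 0.05; dtMax <- 0.4; alpha0 <- 0.1; alpha <- alpha0; nUp <- 0L
  gmax <- Inf
  for (iter in seq_len(maxIter)) {
    Fm <- -.modelGradient(model, X)
    gmax <- max(abs(Fm))
    if (gmax <= tol) break
    P <- sum(V * Fm)
    if (P > 0) {
      nUp <- nUp + 1L
      if (nUp > 5L) { dt <- min(dt * 1.1, dtMax); alpha <- alpha * 0.99 }
      vn <- sqrt(sum(V^2)); fn <- sqrt(sum(Fm^2))
      if (fn > 0) V <- (1 - alpha) * V + alpha * vn * Fm / fn
    } else {
      V[] <- 0; dt <- dt * 0.5; alpha <- alpha0; nUp <- 0L
    }
    V <- V + dt * Fm
    step <- dt * V
    step[step > cap] <- cap; step[step < -cap] <- -cap
    X <- X + step
  }
  list(X = X, energy = .modelEnergy(model, X), gradMax = gmax,
       converged = gmax <= tol)
}
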