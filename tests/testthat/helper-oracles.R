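# Independent brute-force oracles, written with plain loops and their own
# geometric formulas; they share only physical constants with the package.

.orad <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

oracleBondList <- function(s) {
  a <- atomRecords(s)
  xyz <- atomCoords(s)
  n <- nrow(a)
  out <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (a$monomer[i] != a$monomer[j]) next
    if (a$elesy[i] == "H" && a$elesy[j] == "H") next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 1.2 * (.orad[a$elesy[i]] + .orad[a$elesy[j]]))
      out[[length(out) + 1L]] <- c(i, j)
  }
  do.call(rbind, out)
}

oracleNeighbors <- function(bonds, n) {
  nb <- vector("list", n)
  if (!is.null(bonds)) for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1L]; j <- bonds[k, 2L]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

## exhaustive donor-H...acceptor enumeration; returns key strings
oracleHBonds <- function(s, maxD = 3.6, minAng = 120) {
  a <- atomRecords(s)
  xyz <- atomCoords(s)
  n <- nrow(a)
  bonds <- oracleBondList(s)
  nb <- oracleNeighbors(bonds, n)
  keys <- character(0)
  for (d in seq_len(n)) {
    if (!a$elesy[d] %in% c("N", "O")) next
    hyds <- nb[[d]][a$elesy[nb[[d]]] == "H"]
    if (!length(hyds)) next
    for (h in hyds) for (acc in seq_len(n)) {
      if (acc == d) next
      isO <- a$elesy[acc] == "O"
      isBareN <- a$elesy[acc] == "N" && !any(a$elesy[nb[[acc]]] == "H")
      if (!isO && !isBareN) next
      if (a$monomer[acc] == a$monomer[d] && a$resno[acc] == a$resno[d]) next
      ## acceptor within two covalent bonds of the donor is excluded
      shell <- unique(c(d, nb[[d]], unlist(nb[nb[[d]]])))
      if (acc %in% shell) next
      dd <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
      if (dd > maxD) next
      u <- xyz[d, ] - xyz[h, ]
      v <- xyz[acc, ] - xyz[h, ]
      cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang < minAng) next
      keys <- c(keys, paste(a$monomer[d], a$resno[d], a$elety[d], "->",
                            a$monomer[acc], a$resno[acc], a$elety[acc]))
    }
  }
  sort(keys)
}

oracleClashCount <- function(s, cutoff, heavyOnly = FALSE) {
  a <- atomRecords(s)
  xyz <- atomCoords(s)
  n <- nrow(a)
  bonds <- oracleBondList(s)
  nb <- oracleNeighbors(bonds, n)
  cnt <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (heavyOnly && (a$elesy[i] == "H" || a$elesy[j] == "H")) next
    shell <- unique(c(i, nb[[i]], unlist(nb[nb[[i]]])))
    if (j %in% shell) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) cnt <- cnt + 1L
  }
  cnt
}

## independent four-atom dihedral via bio3d
oracleDihedral <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4))
}

## mean in-register Calpha separation, recomputed directly
oracleInterlayer <- function(s) {
  a <- atomRecords(s)
  xyz <- atomCoords(s)
  ms <- sort(unique(a$monomer))
  i1 <- which(a$monomer == ms[1L] & a$elety == "CA")
  i2 <- which(a$monomer == ms[2L] & a$elety == "CA")
  mean(sapply(seq_along(i1), function(k)
    sqrt(sum((xyz[i1[k], ] - xyz[i2[k], ])^2))))
}
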