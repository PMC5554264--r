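# Independent oracles used across the suite. Everything here recomputes
# quantities from first principles in plain R, independently of the
# incremental C++ engine paths it checks.

# protrusion potential of one adhesion site given a centre of mass
oracleProtTerm <- function(site, cm, G, fibres = NULL, rhoFloor = 0.5,
                           cosFloor = 0.1) {
  dr <- site[1] - cm[1]
  dc <- site[2] - cm[2]
  rho <- max(sqrt(dr^2 + dc^2), rhoFloor)
  if (!is.null(fibres) && fibres@occupied[site[1], site[2]]) {
    th <- atan2(dr, dc)
    ca <- max(abs(cos(fibres@orientation[site[1], site[2]] - th)), cosFloor)
    return(G / (rho * ca))
  }
  G / rho
}

# full-lattice Hamiltonian (state terms: adhesive + elastic + protrusion)
# computed from scratch; cm recomputed from sigma, never taken from the
# incremental records
oracleH <- function(state, params) {
  sig <- state@sigma
  cells <- state@cells
  k <- nrow(cells)
  typeCode <- match(cells$type, c("CM", "FB"))
  tg <- matrix(0L, nrow(sig), ncol(sig))
  tg[sig > 0] <- typeCode[sig[sig > 0]]
  J <- unname(params@J)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  if (identical(params@adhesionNeighbourhood, "vonneumann"))
    offs <- offs[1:2]
  Hadh <- 0
  R <- nrow(sig); C <- ncol(sig)
  for (o in offs) {
    r1 <- max(1, 1 + o[1]):min(R, R + o[1])
    c1 <- max(1, 1 + o[2]):min(C, C + o[2])
    rA <- r1 - o[1]; cA <- c1 - o[2]
    sA <- sig[rA, cA]; sB <- sig[r1, c1]
    tA <- tg[rA, cA]; tB <- tg[r1, c1]
    diffp <- sA != sB
    Hadh <- Hadh + sum(J[cbind(tA[diffp] + 1, tB[diffp] + 1)])
  }
  vols <- tabulate(sig[sig > 0], nbins = k)
  pt <- params@perType
  Hel <- sum(pt$lambda[typeCode] * (vols - cells$targetVolume)^2)
  Hpr <- 0
  for (i in seq_len(k)) {
    a <- state@adhesions[[i]]
    if (nrow(a) == 0) next
    pos <- which(sig == i, arr.ind = TRUE)
    cm <- colMeans(pos)
    for (j in seq_len(nrow(a)))
      Hpr <- Hpr + oracleProtTerm(a[j, ], cm, pt$G[typeCode[i]],
                                  state@fibres)
  }
  Hadh + Hel + Hpr
}

# event-penalty and adhesion-event reconstruction for one accepted copy:
# returns the value deltaHamiltonian should have reported, from the
# before/after states alone
oracleDeltaH <- function(before, after, params, target, source) {
  sig <- before@sigma
  a <- sig[source[1], source[2]]
  b <- sig[target[1], target[2]]
  typeCode <- match(before@cells$type, c("CM", "FB"))
  pt <- params@perType
  dH <- oracleH(after, params) - oracleH(before, params)
  cmOf <- function(st, i) colMeans(which(st@sigma == i, arr.ind = TRUE))
  siteIn <- function(m, site) nrow(m) > 0 &&
    any(m[, 1] == site[1] & m[, 2] == site[2])
  # source-cell adhesion events
  if (a > 0) {
    reloc <- siteIn(before@adhesions[[a]], source)
    created <- !reloc && siteIn(after@adhesions[[a]], target)
    if (created) {
      # creation is free at copy time: remove its term from the from-
      # scratch difference
      dH <- dH - oracleProtTerm(target, cmOf(after, a), pt$G[typeCode[a]],
                                before@fibres)
    }
    if (reloc && !is.null(before@fibres)) {
      onS <- before@fibres@occupied[source[1], source[2]]
      onT <- before@fibres@occupied[target[1], target[2]]
      if (onS != onT) {
        # mixed substrate/fibre tip moves carry no potential difference:
        # remove the branch-state difference the from-scratch H contains
        dH <- dH - (oracleProtTerm(target, cmOf(after, a),
                                   pt$G[typeCode[a]], before@fibres) -
                    oracleProtTerm(source, cmOf(before, a),
                                   pt$G[typeCode[a]], before@fibres))
      }
      if (onS && !onT) dH <- dH + pt$Punleash[typeCode[a]]
    }
  }
  # target-cell events
  if (b > 0) {
    destroyed <- siteIn(before@adhesions[[b]], target)
    if (destroyed) {
      # destruction is energy-neutral apart from P_detach: its term left
      # the state energy, so add it back, plus the penalty
      dH <- dH + oracleProtTerm(target, cmOf(before, b),
                                pt$G[typeCode[b]], before@fibres) +
        pt$Pdetach[typeCode[b]]
    }
    cmB <- cmOf(before, b)
    if (sqrt(sum((target - cmB)^2)) < params@nucleusRadius)
      dH <- dH + 2 * pt$Pdetach[typeCode[b]]
  }
  dH
}

# dense linear-algebra reference for one ADI half-step (implicit axis
# "x" = columns, "y" = rows); react is the pre-scaled right-hand-side
# addition, weights are D * dt/2 / h^2 per face
oracleAdiHalf <- function(V, Wx, Wy, react, axis = c("x", "y")) {
  axis <- match.arg(axis)
  R <- nrow(V); C <- ncol(V); N <- R * C
  idx <- function(r, c) r + R * (c - 1)
  Lx <- matrix(0, N, N)
  if (C > 1) for (c in 1:(C - 1)) for (r in 1:R) {
    i <- idx(r, c); j <- idx(r, c + 1); w <- Wx[r, c]
    Lx[i, i] <- Lx[i, i] + w; Lx[j, j] <- Lx[j, j] + w
    Lx[i, j] <- Lx[i, j] - w; Lx[j, i] <- Lx[j, i] - w
  }
  Ly <- matrix(0, N, N)
  if (R > 1) for (c in 1:C) for (r in 1:(R - 1)) {
    i <- idx(r, c); j <- idx(r + 1, c); w <- Wy[r, c]
    Ly[i, i] <- Ly[i, i] + w; Ly[j, j] <- Ly[j, j] + w
    Ly[i, j] <- Ly[i, j] - w; Ly[j, i] <- Ly[j, i] - w
  }
  v <- as.vector(V)
  out <- if (axis == "x") {
    solve(diag(N) + Lx, v - Ly %*% v + as.vector(react))
  } else {
    solve(diag(N) + Ly, v - Lx %*% v + as.vector(react))
  }
  matrix(out, R, C)
}

# small two-cell state used by several engine tests
makeTwoCellState <- function(withFibres = FALSE, dims = c(24, 24)) {
  sig <- matrix(0L, dims[1], dims[2])
  sig[6:11, 5:10] <- 1L
  sig[13:18, 13:18] <- 2L
  fib <- if (withFibres) generateFibreField(dims, 0, 4) else NULL
  cellLattice(sig, c("CM", "FB"), c(40, 38), fibres = fib)
}

# small parameter set with energies on the thermal scale so that all
# attempt outcomes occur with useful frequency
testParams <- function(..., adhesionNeighbourhood = "moore") {
  defaults <- list(
    lambda = c(2, 1.5), targetVolume = c(40, 38), G = c(60, 40),
    Pdetach = c(1.5, 1.0), Punleash = c(2, 1), Lmax = c(12, 14),
    Nprotr = c(6, 8),
    J = matrix(c(0, 3, 2.5, 3, 5, 4, 2.5, 4, 4.5), 3, 3),
    temperature = 1.0, adhesionNeighbourhood = adhesionNeighbourhood
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(modelParams, args)
}
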