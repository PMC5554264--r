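test_that("elastic term of a removal at exact target volume is +lambda", {
  sig <- matrix(0L, 12, 12)
  sig[4:8, 4:9] <- 1L  # volume 30
  st <- cellLattice(sig, "CM", 30)
  par <- testParams(targetVolume = c(30, 38), Pdetach = c(0, 0),
                    lambda = c(2, 1.5))
  # medium invades a corner subcell of the cell
  dh <- deltaHamiltonian(st, par, target = c(4, 4), source = c(3, 3))
  comp <- attr(dh, "components")
  expect_equal(unname(comp["elastic"]), 2 * 1)  # lambda * ((V-1-V)^2 - 0)
})

test_that("2x2 -> L-tromino copy: adhesive 0 under the 4-neighbourhood", {
  sig <- matrix(0L, 10, 10)
  sig[5:6, 5:6] <- 1L
  st <- cellLattice(sig, "CM", 6)
  par <- testParams(targetVolume = c(6, 38), Pdetach = c(0, 0),
                    lambda = c(2, 1.5), adhesionNeighbourhood = "vonneumann")
  dh <- deltaHamiltonian(st, par, target = c(5, 5), source = c(4, 4))
  comp <- attr(dh, "components")
  # 8 cell-medium von Neumann pairs before and after the corner removal
  expect_equal(unname(comp["adhesive"]), 0)
  expect_equal(unname(comp["elastic"]), 2 * ((3 - 6)^2 - (4 - 6)^2))
  expect_equal(unname(comp["protrusion"]), 0)
  expect_equal(unname(comp["penalty"]), 0)
})

test_that("fibre-projected protrusion term reduces to G/rho at alpha = 0", {
  dims <- c(13, 30)
  sig <- matrix(0L, dims[1], dims[2])
  sig[5:7, 5:20] <- 1L  # bar centred on row 6, a fibre row (pitch 4)
  adh <- list(matrix(c(6L, 20L), 1, 2))
  fib <- generateFibreField(dims, 0, 4)
  expect_true(fib@occupied[6, 1])
  stF <- cellLattice(sig, "CM", 48, fibres = fib, adhesions = adh)
  st0 <- cellLattice(sig, "CM", 48, adhesions = adh)
  par <- testParams(targetVolume = c(48, 38), Lmax = c(25, 25))
  # advance the adhesion tip eastwards along the fibre (alpha = 0)
  dhF <- deltaHamiltonian(stF, par, target = c(6, 21), source = c(6, 20))
  dh0 <- deltaHamiltonian(st0, par, target = c(6, 21), source = c(6, 20))
  expect_equal(as.numeric(dhF), as.numeric(dh0), tolerance = 1e-12)
})

test_that("metropolis rule: boundary cases and draw-consumption contract", {
  expect_true(metropolisAccept(-3, 1))
  expect_true(metropolisAccept(0, 5))
  set.seed(11)
  s0 <- .Random.seed
  expect_true(metropolisAccept(-1, 1))
  expect_identical(.Random.seed, s0)  # no draw consumed for dH <= 0
  dec <- metropolisAccept(2, 1)
  s1 <- .Random.seed
  set.seed(11)
  ref <- stats::runif(1) < exp(-2)
  expect_identical(dec, ref)          # exactly one draw, same stream
  expect_identical(.Random.seed, s1)
})

test_that("empirical acceptance rate matches exp(-dH/T) within 3 SE", {
  dH <- 1.2; T <- 1
  p <- exp(-dH / T)
  n <- 1e5
  set.seed(99)
  acc <- metropolisAccept(rep(dH, n), T)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(acc) - p), 3 * se)
})

test_that("copy attempts: no-op, disappearance and L_MAX forbidden rules", {
  sig <- matrix(0L, 10, 10)
  sig[3:6, 3:6] <- 1L
  sig[8, 8] <- 2L  # volume-1 cell
  st <- cellLattice(sig, c("CM", "FB"), c(16, 1))
  par <- testParams(targetVolume = c(16, 1))
  # same index on both sites: rejected, state unchanged
  out <- copyAttempt(st, par, target = c(4, 4), source = c(5, 5))
  expect_equal(out$outcome, "rejected")
  expect_identical(sigmaMatrix(out$state), sigmaMatrix(st))
  # invading the volume-1 cell would make it disappear: forbidden
  out <- copyAttempt(st, par, target = c(8, 8), source = c(7, 7))
  expect_equal(out$outcome, "forbidden")
  # adhesion tip relocation beyond L_MAX: forbidden
  sig2 <- matrix(0L, 10, 20)
  sig2[4:6, 3:12] <- 1L
  adh <- list(matrix(c(5L, 12L), 1, 2))
  st2 <- cellLattice(sig2, "CM", 30, adhesions = adh)
  parTight <- testParams(targetVolume = c(30, 38), Lmax = c(5.2, 5))
  out <- copyAttempt(st2, parTight, target = c(5, 13), source = c(5, 12))
  expect_equal(out$outcome, "forbidden")
})

test_that("connectivity rule: bar, block and ring cases", {
  bar <- matrix(0L, 5, 5)
  bar[3, 2:4] <- 1L
  stBar <- cellLattice(bar, "CM", 3)
  expect_false(connectivityPreserved(stBar, 1, c(3, 3)))
  expect_true(connectivityPreserved(stBar, 1, c(3, 2)))

  blk <- matrix(0L, 5, 5)
  blk[2:3, 2:3] <- 1L
  stBlk <- cellLattice(blk, "CM", 4)
  for (site in list(c(2, 2), c(2, 3), c(3, 2), c(3, 3)))
    expect_true(connectivityPreserved(stBlk, 1, site))

  ring <- matrix(0L, 5, 5)
  ring[2:4, 2:4] <- 1L
  ring[3, 3] <- 0L
  stRing <- cellLattice(ring, "CM", 8)
  expect_true(connectivityPreserved(stRing, 1, c(2, 3)))
  cshape <- ring; cshape[2, 3] <- 0L
  stC <- cellLattice(cshape, "CM", 7)
  expect_false(connectivityPreserved(stC, 1, c(4, 3)))
})

test_that("one MCS performs exactly rows x cols attempts; empty lattice is inert", {
  st <- makeTwoCellState()
  par <- testParams()
  out <- monteCarloStep(st, par, n = 3, seed = 5)
  expect_equal(sum(attr(out, "counts")), 3 * 24 * 24)
  expect_equal(mcsCount(out), 3L)

  empty <- cellLattice(matrix(0L, 8, 8), character(), numeric())
  out2 <- monteCarloStep(empty, par, n = 5, seed = 1)
  expect_identical(sigmaMatrix(out2), matrix(0L, 8, 8))
})

test_that("near-greedy dynamics shrinks an oversized cell toward target", {
  sig <- matrix(0L, 20, 20)
  sig[5:16, 5:16] <- 1L  # volume 144, target 60
  st <- cellLattice(sig, "CM", 60)
  par <- testParams(targetVolume = c(60, 38), G = c(0, 0),
                    Pdetach = c(0, 0), Punleash = c(0, 0), J = matrix(0, 3, 3),
                    temperature = 0.01, Lmax = c(30, 30))
  out <- monteCarloStep(st, par, n = 40, seed = 3, recordEvery = 1)
  lg <- formationLog(out)
  expect_true(all(diff(lg$meanVolume) <= 0))
  expect_lt(abs(cellTable(out)$volume - 60), 3)
})

test_that("incremental delta H matches the from-scratch oracle", {
  for (withFib in c(FALSE, TRUE)) {
    st <- makeTwoCellState(withFibres = withFib)
    par <- testParams()
    st <- monteCarloStep(st, par, n = 5, seed = 17)  # develop adhesions
    set.seed(202 + withFib)
    off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
    accepted <- 0; tried <- 0
    while (accepted < 400 && tried < 25000) {
      tried <- tried + 1
      # sample a random boundary pair (different indices)
      sig <- st@sigma
      bnd <- which(
        (rbind(sig[-1, ], 0L) != sig) | (rbind(0L, sig[-24, ]) != sig) |
        (cbind(sig[, -1], 0L) != sig) | (cbind(0L, sig[, -24]) != sig),
        arr.ind = TRUE)
      t <- bnd[sample(nrow(bnd), 1), ]
      s <- t + off[sample(8, 1), ]
      if (any(s < 1 | s > 24)) next
      if (sig[t[1], t[2]] == sig[s[1], s[2]]) next
      out <- copyAttempt(st, par, seed = tried, target = t, source = s)
      if (out$outcome != "accepted") next
      accepted <- accepted + 1
      expected <- oracleDeltaH(st, out$state, par, t, s)
      expect_equal(out$deltaH, expected, tolerance = 1e-9)
      st <- out$state
    }
    expect_gte(accepted, 200)
  }
})

test_that("bookkeeping survives long runs: audit and invariants", {
  st <- makeTwoCellState(withFibres = TRUE)
  par <- testParams()
  out <- monteCarloStep(st, par, n = 60, seed = 23)
  expect_true(auditLattice(out))
  cells <- cellTable(out)
  pt <- par@perType
  for (i in cells$index) {
    a <- adhesionSites(out)[[i]]
    ty <- match(cells$type[i], pt$type)
    expect_lte(nrow(a), pt$Nprotr[ty])
    if (nrow(a)) {
      d <- sqrt((a[, 1] - cells$cmRow[i])^2 + (a[, 2] - cells$cmCol[i])^2)
      expect_true(all(d <= pt$Lmax[ty] + 1e-9))
    }
  }
})

test_that("identical seeds give bit-identical trajectories", {
  st <- makeTwoCellState()
  par <- testParams()
  a <- monteCarloStep(st, par, n = 20, seed = 77)
  b <- monteCarloStep(st, par, n = 20, seed = 77)
  expect_identical(sigmaMatrix(a), sigmaMatrix(b))
  expect_identical(adhesionSites(a), adhesionSites(b))
  c <- monteCarloStep(st, par, n = 20, seed = 78)
  expect_false(identical(sigmaMatrix(a), sigmaMatrix(c)))
})
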