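uniformMap <- function(dims, D = 1) {
  sig <- matrix(1L, dims[1], dims[2])
  st <- cellLattice(sig, "CM", prod(dims))
  buildConductanceMap(st, NULL, Din = D, Dend = D, Dside = D)
}

test_that("zero diffusion and zero reaction leave V unchanged", {
  dmap <- uniformMap(c(10, 10), D = 0)
  model <- alievPanfilovModel()
  model@iion <- function(V, gates) V * 0
  ms <- membraneState(c(10, 10), model)
  ms@V <- matrix(stats::rnorm(100), 10, 10)
  V0 <- ms@V
  for (i in 1:5) ms <- adiStep(ms, dmap, model)
  expect_equal(ms@V, V0, tolerance = 1e-14)
})

test_that("ADI half-steps agree with a dense linear-algebra solve", {
  set.seed(5)
  R <- 32; C <- 32
  Dx <- matrix(stats::runif(R * (C - 1), 0, 1), R, C - 1)
  Dy <- matrix(stats::runif((R - 1) * C, 0, 1), R - 1, C)
  # quantise to levels so the map is valid, keep heterogeneity
  Dx[] <- round(Dx, 2); Dy[] <- round(Dy, 2)
  V <- matrix(sin(outer(1:R, 1:C, function(r, c) r / 5 + c / 7)), R, C)
  react <- matrix(stats::rnorm(R * C, sd = 0.01), R, C)
  f <- 1e5 * 0.05 / 2.5^2
  Wx <- Dx * f; Wy <- Dy * f
  outX <- CardioLattice:::.cl_adi_half_x(V, Wx, Wy, react)
  refX <- oracleAdiHalf(V, Wx, Wy, react, "x")
  expect_lt(max(abs(outX - refX)), 1e-10)
  outY <- CardioLattice:::.cl_adi_half_y(outX, Wx, Wy, react)
  refY <- oracleAdiHalf(refX, Wx, Wy, react, "y")
  expect_lt(max(abs(outY - refY)), 1e-10)
})

test_that("closed boundaries conserve total V under pure diffusion", {
  dmap <- uniformMap(c(40, 40), D = 1)
  model <- alievPanfilovModel()
  model@iion <- function(V, gates) V * 0
  ms <- membraneState(c(40, 40), model)
  ms@V <- matrix(0, 40, 40); ms@V[20, 20] <- 100
  for (i in 1:100) ms <- adiStep(ms, dmap, model)
  expect_equal(sum(ms@V), 100, tolerance = 1e-8)
})

test_that("resting state is a fixed point of the surrogate", {
  model <- alievPanfilovModel()
  dmap <- uniformMap(c(8, 8), D = 1)
  ms <- membraneState(c(8, 8), model)
  for (i in 1:50) ms <- adiStep(ms, dmap, model)
  expect_lt(max(abs(ms@V - model@restingV)), 1e-12)
})

test_that("halving dt changes a smooth solution by O(dt) or better", {
  model <- alievPanfilovModel(tScale = 12.9)
  run <- function(dt) {
    dmap <- uniformMap(c(24, 24), D = 0.001)
    ms <- membraneState(c(24, 24), model, dt = dt)
    ms@V <- matrix(0.4 * exp(-((row(matrix(0, 24, 24)) - 12)^2 +
                               (col(matrix(0, 24, 24)) - 12)^2) / 40),
                   24, 24)
    nSteps <- round(4 / dt)
    for (i in seq_len(nSteps)) ms <- adiStep(ms, dmap, model)
    ms@V
  }
  V1 <- run(0.2); V2 <- run(0.1); V3 <- run(0.05)
  e12 <- max(abs(V1 - V2)); e23 <- max(abs(V2 - V3))
  expect_lt(e23, e12)  # differences shrink with dt
})

test_that("300 steps at dt = 1 ms with max D = 1 cm^2/s stay finite", {
  # the printed operating point of the full ionic model: huge diffusion
  # number D*dt/h^2 = 16000, tractable only implicitly
  dims <- c(64, 64)
  dmap <- uniformMap(dims, D = 1)
  model <- alievPanfilovModel(tScale = 12.9)
  prot <- stimulusProtocol(diskRegion(dims, c(32, 32), 6),
                           amplitude = 0.3, duration = 5)
  ms <- membraneState(dims, model, dt = 1)
  for (i in 1:300) ms <- adiStep(ms, dmap, model, prot)
  expect_true(all(is.finite(ms@V)))
  expect_gt(max(abs(ms@V)) + ms@t, 0)  # ran to t = 300 ms
  expect_equal(ms@t, 300)
})

test_that("no stimulus means no activation; isolated region stays isolated", {
  dmap <- uniformMap(c(20, 20), D = 1)
  sim <- simulateWave(dmap, protocol = NULL, duration = 10)
  expect_true(all(is.na(activationTimes(sim$activation))))

  # an FB-only region has zero coupling: excitation cannot escape
  sig <- matrix(0L, 20, 20)
  sig[, 1:8] <- 1L   # FB block (uncoupled)
  sig[, 12:20] <- 2L # CM block
  st <- cellLattice(sig, c("FB", "CM"), c(160, 180))
  dmap2 <- buildConductanceMap(st, NULL, Din = 1, Dend = 1, Dside = 1)
  stim <- matrix(FALSE, 20, 20); stim[8:12, 2:5] <- TRUE
  sim2 <- simulateWave(dmap2, protocol = stimulusProtocol(stim,
                       amplitude = 1, duration = 3), duration = 30)
  tm <- activationTimes(sim2$activation)
  expect_true(all(is.na(tm[, 12:20])))
})

test_that("point stimulus in homogeneous medium yields expanding isochrones", {
  dims <- c(60, 60)
  dmap <- uniformMap(dims, D = 0.001)
  prot <- stimulusProtocol(diskRegion(dims, c(30, 30), 4),
                           amplitude = 1, duration = 2)
  sim <- simulateWave(dmap, protocol = prot, duration = 120)
  tm <- activationTimes(sim$activation)
  expect_true(all(!is.na(tm)))
  # radial monotonicity: mean activation time increases with radius
  r <- sqrt((row(tm) - 30)^2 + (col(tm) - 30)^2)
  bins <- cut(r, breaks = seq(0, 28, by = 4))
  mt <- tapply(tm, bins, mean)
  expect_true(all(diff(stats::na.omit(as.numeric(mt))) > 0))
})

test_that("optical smoothing: kernel conversion, delta and constant frames", {
  d <- matrix(0, 101, 101); d[51, 51] <- 1
  sm <- opticalSmoothing(d, kernelUm = 25, h = 2.5)  # sigma = 10 px
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  prof <- sm[51, ]
  # half-max of a Gaussian of sigma 10 at ~ 11.8 px
  expect_equal(sm[51, 61] / sm[51, 51], exp(-100 / 200), tolerance = 0.02)
  cst <- opticalSmoothing(matrix(3.7, 40, 40), kernelUm = 250, h = 2.5)
  expect_equal(cst, matrix(3.7, 40, 40), tolerance = 1e-6)
})

test_that("conduction velocity recovers encoded plane-wave slopes", {
  am <- fixtureActivationMap(c(50, 50), speedX = 20, speedY = Inf)
  # time = col / 20 ms; distance = col px * 2.5 um -> speed 50 um/ms
  v <- conductionVelocity(am, c(25, 1), c(25, 50))
  expect_equal(as.numeric(v), 20 * 2.5, tolerance = 1e-9)
  # noisy map: slope recovered within the fit standard error
  set.seed(31)
  am2 <- am
  am2@times <- am@times + matrix(stats::rnorm(2500, sd = 0.05), 50, 50)
  v2 <- conductionVelocity(am2, c(25, 1), c(25, 50), band = 3)
  expect_lt(abs(as.numeric(v2) - 50), 4 * attr(v2, "se"))
  # stationary front: infinite-speed guard
  flat <- new("ActivationMap", times = matrix(5, 20, 20), h = 2.5)
  expect_error(conductionVelocity(flat, c(10, 1), c(10, 20)), "stationary")
  # unactivated line: no-propagation error
  empty <- new("ActivationMap", times = matrix(NA_real_, 20, 20), h = 2.5)
  expect_error(conductionVelocity(empty, c(10, 1), c(10, 20)),
               "no propagation")
})

test_that("anisotropy ratio on synthetic 2:1 maps is 2", {
  # plane waves radiating from the arm junction: 20 px/ms along the
  # horizontal arm, 10 px/ms along the vertical arm
  R <- 80; aw <- 40
  jr <- round(R - aw / 2); jc <- round(aw / 2)
  r <- matrix(seq_len(R), R, R)
  c <- matrix(seq_len(R), R, R, byrow = TRUE)
  times <- abs(c - jc) / 20 + abs(r - jr) / 10
  am <- new("ActivationMap", times = times, h = 2.5)
  rat <- anisotropyRatio(am, armWidth = aw, fibreAxis = "x")
  expect_equal(as.numeric(rat), 2.0, tolerance = 0.05)
  rY <- anisotropyRatio(am, armWidth = aw, fibreAxis = "y")
  expect_equal(as.numeric(rY), 0.5, tolerance = 0.02)
})
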