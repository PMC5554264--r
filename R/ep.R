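#' Two-variable excitable surrogate (Aliev-Panfilov kinetics)
#'
#' The default ionic model behind the monodomain solver: a dimensionless
#' activator V in [0, ~1] with cubic fast kinetics and one recovery gate
#' r. \code{tScale} maps the dimensionless kinetics to milliseconds. The
#' resting state (V = 0, r = 0) is a fixed point; the activation
#' threshold is half the action-potential amplitude. Any model honouring
#' the [IonicModel-class] contract can be substituted.
#'
#' @param k,a,eps0,mu1,mu2 standard Aliev-Panfilov constants
#' @param tScale time scale, ms per dimensionless time unit. The
#'   classical mapping is 12.9 ms; the default of 1 ms sharpens the
#'   upstroke to the sodium-current scale that junction-limited discrete
#'   conduction requires (a slow upstroke cannot outrun charge loss to
#'   the strongly coupled neighbours and the wave dies at its source)
#' @return an [IonicModel-class]
#' @export
alievPanfilovModel <- function(k = 8, a = 0.15, eps0 = 0.002, mu1 = 0.2,
                               mu2 = 0.3, tScale = 1.0) {
  new("IonicModel",
      name = "aliev-panfilov",
      iion = function(V, gates) {
        (k * V * (V - a) * (V - 1) + V * gates$r) / tScale
      },
      gateStep = function(V, gates, dt) {
        r <- gates$r
        eps <- eps0 + mu1 * r / (mu2 + V)
        list(r = r + dt * eps * (-r - k * V * (V - a - 1)) / tScale)
      },
      initGates = function(dims) list(r = matrix(0, dims[1], dims[2])),
      restingV = 0, amplitude = 1, threshold = 0.5)
}

#' Initial membrane state at rest
#'
#' @param dims grid (rows, cols)
#' @param model an [IonicModel-class]
#' @param dt time step, ms
#' @param h space step, micrometres
#' @param Cm membrane capacitance (model units)
#' @return a [MembraneState-class]
#' @export
membraneState <- function(dims, model = alievPanfilovModel(), dt = 0.1,
                          h = 2.5, Cm = 1) {
  new("MembraneState", V = matrix(model@restingV, dims[1], dims[2]),
      gates = model@initGates(dims), t = 0, dt = dt, h = h, Cm = Cm)
}

#' Stimulation protocol
#'
#' @param region logical matrix (TRUE = stimulated pixels)
#' @param amplitude depolarising strength, potential units per ms
#' @param onset stimulus start, ms
#' @param duration stimulus length, ms (> 0)
#' @param period repetition period, ms (Inf = single stimulus)
#' @return protocol list
#' @export
stimulusProtocol <- function(region, amplitude = 1, onset = 0,
                             duration = 3, period = Inf) {
  stopifnot(duration > 0)
  list(region = region, amplitude = amplitude, onset = onset,
       duration = duration, period = period)
}

#' Circular stimulus region
#' @param dims grid (rows, cols)
#' @param centre (row, col)
#' @param radius pixels
#' @return logical matrix
#' @export
diskRegion <- function(dims, centre, radius = 4) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  c <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (r - centre[1])^2 + (c - centre[2])^2 <= radius^2
}

# pre-scaled face weights: D (cm^2/s) -> D * dt/2 / h^2 with h in um
# (1 cm^2/s = 1e5 um^2/ms)
.faceWeights <- function(dmap, dtHalf) {
  f <- 1e5 * dtHalf / dmap@h^2
  list(Wx = dmap@Dx * f, Wy = dmap@Dy * f)
}

#' One alternating-direction implicit step of the monodomain equation
#'
#' Performs the two half-steps: ionic and stimulus currents evaluated at
#' step n enter the right-hand side of both halves; diffusion is
#' implicit along one axis (independent tridiagonal systems solved
#' exactly) and explicit along the other over dt/2, then the axes swap.
#' Gates are advanced once per full step from the step-n potential.
#'
#' @param ms a [MembraneState-class]
#' @param dmap a [ConductanceMap-class]
#' @param model an [IonicModel-class]
#' @param protocol optional [stimulusProtocol()]
#' @return the advanced [MembraneState-class]
#' @export
adiStep <- function(ms, dmap, model, protocol = NULL) {
  dt <- ms@dt
  w <- .faceWeights(dmap, dt / 2)
  istim <- 0
  if (!is.null(protocol)) {
    tl <- if (is.finite(protocol$period)) (ms@t - protocol$onset) %% protocol$period
          else ms@t - protocol$onset
    if (tl >= 0 && tl < protocol$duration)
      istim <- protocol$region * protocol$amplitude
  }
  react <- (dt / 2) * (-model@iion(ms@V, ms@gates) + istim / ms@Cm)
  Vh <- .cl_adi_half_x(ms@V, w$Wx, w$Wy, react)
  V1 <- .cl_adi_half_y(Vh, w$Wx, w$Wy, react)
  if (any(!is.finite(V1)))
    stop(sprintf(
      "ADI step diverged (dt = %g ms, max D = %g cm^2/s): non-finite V",
      dt, max(dmap@levels)))
  gates <- model@gateStep(ms@V, ms@gates, dt)
  ms@V <- V1
  ms@gates <- gates
  ms@t <- ms@t + dt
  ms
}

#' Integrate the monodomain model and record activation
#'
#' Steps the ADI solver for \code{duration} ms, recording voltage frames
#' at a configurable stride and the first upward crossing of the model's
#' activation threshold per pixel. Optionally stops early once a
#' user-supplied predicate on the activation-time matrix is satisfied.
#'
#' @param dmap a [ConductanceMap-class]
#' @param model an [IonicModel-class]
#' @param protocol a [stimulusProtocol()]
#' @param duration total simulated time, ms
#' @param dt time step, ms
#' @param frameEvery record a voltage frame every this many ms (0 = none)
#' @param stopWhen optional function(times, t) returning TRUE to stop
#' @return list: \code{activation} ([ActivationMap-class]),
#'   \code{frames} (named list of matrices), \code{state} (final
#'   [MembraneState-class])
#' @export
simulateWave <- function(dmap, model = alievPanfilovModel(), protocol,
                         duration = 100, dt = 0.1, frameEvery = 0,
                         stopWhen = NULL) {
  dims <- c(nrow(dmap@Dy) + 1L, ncol(dmap@Dx) + 1L)
  ms <- membraneState(dims, model, dt = dt, h = dmap@h)
  times <- matrix(NA_real_, dims[1], dims[2])
  frames <- list()
  nSteps <- ceiling(duration / dt)
  nextFrame <- if (frameEvery > 0) 0 else Inf
  for (i in seq_len(nSteps)) {
    ms <- adiStep(ms, dmap, model, protocol)
    hit <- is.na(times) & ms@V >= model@threshold
    if (any(hit)) times[hit] <- ms@t
    if (ms@t >= nextFrame) {
      frames[[sprintf("t%.3f", ms@t)]] <- ms@V
      nextFrame <- nextFrame + frameEvery
    }
    if (!is.null(stopWhen) && i %% 50L == 0L && stopWhen(times, ms@t))
      break
  }
  list(activation = new("ActivationMap", times = times, h = dmap@h),
       frames = frames, state = ms)
}

#' Optical-mapping-style Gaussian smoothing
#'
#' Applies the same Gaussian blur to simulated frames as is applied to
#' experimental optical-mapping recordings; the physical kernel scale is
#' converted to pixels via the space step (250 um at h = 2.5 um is a
#' 100-pixel kernel).
#'
#' @param frames matrix or list of matrices
#' @param kernelUm kernel scale, micrometres (250 or 300 typical)
#' @param h space step, micrometres
#' @return blurred frames, same shape as the input
#' @export
opticalSmoothing <- function(frames, kernelUm = 250, h = 2.5) {
  stopifnot(kernelUm >= h)
  sig <- kernelUm / h
  blur1 <- function(m) {
    # brush must fit inside the frame (and have odd size)
    rad <- min(2 * ceiling(3 * sig) + 1, min(dim(m)))
    if (rad %% 2 == 0) rad <- rad - 1
    EBImage::gblur(m, sigma = sig, radius = rad, boundary = "replicate")
  }
  if (is.matrix(frames)) return(blur1(frames))
  lapply(frames, blur1)
}

#' Conduction velocity along a sampling segment
#'
#' Least-squares fit of activation time versus physical distance along
#' the segment, restricted to its quasi-planar middle stretch; the speed
#' is the inverse slope, in um/ms (equal to mm/s).
#'
#' @param amap an [ActivationMap-class]
#' @param from,to segment endpoints, (row, col)
#' @param fraction range of the normalised distance used for the fit
#' @param band pool samples from parallel lines offset up to this many
#'   pixels perpendicular to the segment (averages out the cellular
#'   texture of discrete tissue)
#' @return speed in um/ms, with attributes "se" (standard error) and
#'   "n" (points used)
#' @export
conductionVelocity <- function(amap, from, to, fraction = c(0.2, 0.9),
                               band = 0) {
  n <- max(abs(to - from)) + 1
  rr0 <- round(seq(from[1], to[1], length.out = n))
  cc0 <- round(seq(from[2], to[2], length.out = n))
  L <- sqrt(sum((to - from)^2))
  perp <- c(-(to[2] - from[2]), to[1] - from[1]) / max(L, 1)
  rr <- cc <- integer(0)
  d <- numeric(0)
  d0 <- sqrt((rr0 - from[1])^2 + (cc0 - from[2])^2) * amap@h
  for (k in seq(-band, band)) {
    r <- round(rr0 + k * perp[1])
    c <- round(cc0 + k * perp[2])
    ok <- r >= 1 & r <= nrow(amap@times) & c >= 1 & c <= ncol(amap@times)
    rr <- c(rr, r[ok]); cc <- c(cc, c[ok]); d <- c(d, d0[ok])
  }
  t <- amap@times[cbind(rr, cc)]
  keep <- !is.na(t) & d >= fraction[1] * max(d0) & d <= fraction[2] * max(d0)
  if (sum(keep) < 2)
    stop("no propagation along the sampling segment")
  t <- t[keep]; d <- d[keep]
  if (stats::sd(t) < 1e-12)
    stop("stationary front: all activation times equal (infinite speed)")
  fit <- stats::lm(t ~ d)
  slope <- stats::coef(fit)[["d"]]
  if (slope <= 0)
    stop("activation times do not increase along the segment")
  out <- 1 / slope
  se <- suppressWarnings(summary(fit)$coefficients["d", "Std. Error"])
  attr(out, "se") <- se / slope^2
  attr(out, "n") <- length(t)
  out
}

#' Orthogonal velocity ratio after point stimulation
#'
#' Fits the expanding wavefront over all activated pixels of the fit
#' annulus with an elliptical front model
#' \eqn{t^2 = x^2/v_x^2 + y^2/v_y^2} (linear regression of squared
#' activation time on squared displacements) and returns the
#' horizontal-to-vertical speed ratio \eqn{v_x/v_y}; isotropic tissue
#' gives a ratio near 1. The global fit averages the cellular texture
#' and is robust to local conduction detours that distort single-ray
#' estimates. Per-direction sector speeds are attached for inspection.
#'
#' @param amap an [ActivationMap-class]
#' @param centre stimulation point (row, col); default: earliest pixel
#' @param margin pixels to leave at the domain border
#' @param fraction radial fit range as fractions of the largest centred
#'   radius
#' @param halfAngle half-width of the diagnostic sectors, radians
#' @return ratio with attributes "speeds" (um/ms: right, left, down, up
#'   sector estimates) and "vx", "vy" (elliptical-fit speeds, um/ms)
#' @export
orthogonalVelocityRatio <- function(amap, centre = NULL, margin = 5,
                                    fraction = c(0.2, 0.85),
                                    halfAngle = pi / 8) {
  tm <- amap@times
  if (is.null(centre)) {
    i <- which(tm == min(tm, na.rm = TRUE), arr.ind = TRUE)
    centre <- round(colMeans(i))
  }
  R <- nrow(tm); C <- ncol(tm)
  dr <- row(tm) - centre[1]
  dc <- col(tm) - centre[2]
  rad <- sqrt(dr^2 + dc^2)
  maxR <- min(centre[1], R - centre[1], centre[2], C - centre[2]) - margin
  keep <- !is.na(tm) & rad >= fraction[1] * maxR & rad <= fraction[2] * maxR
  if (sum(keep) < 100) stop("no propagation around the stimulation point")
  t <- tm[keep]
  if (stats::sd(t) < 1e-12)
    stop("stationary front: all activation times equal (infinite speed)")
  fit <- stats::coef(stats::lm(I(t^2) ~ 0 + I(dc[keep]^2) + I(dr[keep]^2)))
  if (any(fit <= 0)) stop("wavefront fit degenerate")
  vx <- amap@h / sqrt(fit[[1]])
  vy <- amap@h / sqrt(fit[[2]])
  out <- vx / vy
  # diagnostic per-direction sector fits
  ang <- atan2(dr, dc)
  sector <- function(phi) {
    da <- abs(((ang - phi + pi) %% (2 * pi)) - pi)
    k2 <- keep & da <= halfAngle
    if (sum(k2) < 10) return(NA_real_)
    slope <- stats::coef(stats::lm(tm[k2] ~ I(rad[k2] * amap@h)))[[2]]
    if (!is.finite(slope) || slope <= 0) return(NA_real_)
    1 / slope
  }
  attr(out, "speeds") <- c(right = sector(0), left = sector(pi),
                           down = sector(pi / 2), up = sector(-pi / 2))
  attr(out, "vx") <- vx
  attr(out, "vy") <- vy
  out
}

#' Longitudinal-to-transversal velocity ratio on an L-shaped sample
#'
#' The L-shaped protocol: plane wavefronts launched from the arm
#' junction propagate along each arm; the longitudinal velocity is
#' measured in the arm parallel to the fibres and the transversal
#' velocity in the other arm, and their ratio is the anisotropy ratio.
#' Assumes the mask layout of [buildLShapeMask()] (vertical arm in the
#' first \code{armWidth} columns, horizontal arm in the last
#' \code{armWidth} rows).
#'
#' @param amap an [ActivationMap-class]
#' @param armWidth arm width, pixels
#' @param fibreAxis "x" when fibres run along columns (the horizontal
#'   arm is longitudinal), "y" for the vertical arm
#' @param margin pixels left at arm ends
#' @param fraction fit range along each arm (fractions of arm length
#'   from the junction; the inner cut excludes junction curvature)
#' @param widthFraction central fraction of the arm width averaged into
#'   each isochrone sample (plane-front averaging)
#' @return ratio >= 0 with attribute "speeds" (longitudinal,
#'   transversal), um/ms
#' @export
anisotropyRatio <- function(amap, armWidth, fibreAxis = c("x", "y"),
                            margin = 5, fraction = c(0.35, 0.95),
                            widthFraction = 0.6) {
  fibreAxis <- match.arg(fibreAxis)
  tm <- amap@times
  R <- nrow(tm); C <- ncol(tm)
  wHalf <- round(armWidth * widthFraction / 2)
  jr <- round(R - armWidth / 2)
  jc <- round(armWidth / 2)
  # plane-front speed: mean activation time over the central portion of
  # the arm width, regressed on the along-arm coordinate
  planeSpeed <- function(along, times) {
    win <- along >= fraction[1] * max(along) & along <= fraction[2] * max(along)
    keep <- is.finite(times) & win
    # a conduction block leaves part of the arm unactivated; the plane-
    # wave speed is undefined for such a sample
    if (sum(keep) < 5 || mean(is.finite(times[win])) < 0.6)
      stop("no propagation along the sampling segment")
    t <- times[keep]; d <- along[keep] * amap@h
    if (stats::sd(t) < 1e-12)
      stop("stationary front: all activation times equal (infinite speed)")
    slope <- stats::coef(stats::lm(t ~ d))[["d"]]
    if (slope <= 0) stop("activation times do not increase along the arm")
    1 / slope
  }
  # horizontal arm: along columns beyond the junction block
  colsH <- seq(armWidth + 1, C - margin)
  tH <- vapply(colsH, function(cc)
    mean(tm[(jr - wHalf):(jr + wHalf), cc], na.rm = TRUE), 0)
  vH <- planeSpeed(colsH - jc, tH)
  # vertical arm: along rows above the junction block
  rowsV <- seq(R - armWidth, margin)
  tV <- vapply(rowsV, function(rr)
    mean(tm[rr, (jc - wHalf):(jc + wHalf)], na.rm = TRUE), 0)
  vV <- planeSpeed(jr - rowsV, tV)
  if (fibreAxis == "x") {
    out <- vH / vV
    attr(out, "speeds") <- c(longitudinal = vH, transversal = vV)
  } else {
    out <- vV / vH
    attr(out, "speeds") <- c(longitudinal = vV, transversal = vH)
  }
  out
}

#' @describeIn simulateWave activation-time matrix accessor
#' @param x an ActivationMap
#' @export
activationTimes <- function(x) x@times
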