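#' Generate a parallel nanofibre field
#'
#' Parallel one-subcell-wide fibre rows at a fixed pitch with a constant
#' orientation angle. With \code{orientation = 0} fibres run along the
#' column (x) axis, occupying every \code{pitch}-th row.
#'
#' @param dims lattice (rows, cols)
#' @param orientation fibre angle in radians, in [0, pi)
#' @param pitch fibre row spacing in subcells (>= 1)
#' @return a [FibreField-class]
#' @export
generateFibreField <- function(dims, orientation = 0, pitch = 4) {
  stopifnot(pitch >= 1)
  occ <- matrix(FALSE, dims[1], dims[2])
  rows <- seq(ceiling(pitch / 2), dims[1], by = pitch)
  occ[rows, ] <- TRUE
  ori <- matrix(orientation %% pi, dims[1], dims[2])
  new("FibreField", occupied = occ, orientation = ori)
}

#' Build an L-shaped admissible-domain mask
#'
#' The L is the union of a vertical arm (all rows, first \code{armWidth}
#' columns) and a horizontal arm (last \code{armWidth} rows, all
#' columns); the arm junction is their overlap, with its centre at the
#' intersection of the two arm middle lines.
#'
#' @param dims lattice (rows, cols)
#' @param armWidth arm width, subcells (< both dims)
#' @return logical matrix, TRUE inside the admissible L-shaped domain;
#'   attribute \code{"junction"} holds the (row, col) stimulation point
#' @export
buildLShapeMask <- function(dims, armWidth) {
  stopifnot(armWidth <= dims[1], armWidth <= dims[2])
  m <- matrix(FALSE, dims[1], dims[2])
  m[, seq_len(armWidth)] <- TRUE
  m[seq(dims[1] - armWidth + 1, dims[1]), ] <- TRUE
  attr(m, "junction") <- c(round(dims[1] - armWidth / 2),
                           round(armWidth / 2))
  m
}

#' Seeding plan for the initial conditions
#'
#' Divides the sample into a grid of seeding areas; one square seed of
#' side \eqn{\sqrt{V^t/10}} (rounded to the nearest subcell) is placed
#' at a uniform random admissible position within each area. Cell types
#' are assigned by a random permutation matching the requested
#' fibroblast fraction exactly (largest-remainder rounding).
#'
#' @param dims lattice (rows, cols)
#' @param seedGrid seeding areas (nx = along columns, ny = along rows)
#' @param fbFraction fraction of fibroblasts in [0, 1]
#' @return list describing the plan (area rectangles, counts)
#' @export
seedingPlan <- function(dims, seedGrid, fbFraction = 0.5) {
  nx <- seedGrid[1]; ny <- seedGrid[2]
  cx <- round(seq(0, dims[2], length.out = nx + 1))
  ry <- round(seq(0, dims[1], length.out = ny + 1))
  areas <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))
  areas$r0 <- ry[areas$iy] + 1L
  areas$r1 <- ry[areas$iy + 1L]
  areas$c0 <- cx[areas$ix] + 1L
  areas$c1 <- cx[areas$ix + 1L]
  nFB <- round(nrow(areas) * fbFraction)
  list(dims = dims, areas = areas, nCells = nrow(areas),
       nFB = nFB, nCM = nrow(areas) - nFB, fbFraction = fbFraction)
}

#' Seed square cells on the lattice
#'
#' Places one square seed per seeding area of the plan (areas whose
#' admissible part cannot host the seed are skipped when a domain mask
#' is supplied and dropped with an error otherwise). There are no focal
#' adhesions at seeding; they are established during the first
#' successful expansions of the cell border.
#'
#' @param plan a [seedingPlan()]
#' @param params a [ModelParams-class] (provides per-type target areas)
#' @param mask optional logical admissible-domain matrix
#' @param fibres optional [FibreField-class] stored on the state
#' @return a [CellLattice-class] (uses the current R random stream; seed
#'   it with set.seed or use [growTissue()])
#' @export
seedCells <- function(plan, params, mask = NULL, fibres = NULL) {
  pt <- params@perType
  dims <- plan$dims
  side <- pmax(1L, round(sqrt(pt$targetVolume / 10)))
  names(side) <- pt$type
  areas <- plan$areas
  keep <- logical(nrow(areas))
  maxSide <- max(side)
  for (i in seq_len(nrow(areas))) {
    a <- areas[i, ]
    fits <- (a$r1 - a$r0 + 1 >= maxSide) && (a$c1 - a$c0 + 1 >= maxSide)
    if (!fits) {
      if (is.null(mask)) stop("seed of side ", maxSide,
                              " cannot fit in seeding area ", i)
      keep[i] <- FALSE
      next
    }
    keep[i] <- if (is.null(mask)) TRUE else {
      # require at least one placement fully inside the mask
      any(.admissibleOffsets(mask, a, maxSide))
    }
  }
  areas <- areas[keep, , drop = FALSE]
  n <- nrow(areas)
  nFB <- round(n * plan$fbFraction)
  types <- sample(c(rep("FB", nFB), rep("CM", n - nFB)))
  sigma <- matrix(0L, dims[1], dims[2])
  for (i in seq_len(n)) {
    a <- areas[i, ]
    s <- side[[types[i]]]
    ok <- FALSE
    for (tries in 1:200) {
      r0 <- a$r0 + sample.int(a$r1 - a$r0 + 1 - s + 1, 1) - 1L
      c0 <- a$c0 + sample.int(a$c1 - a$c0 + 1 - s + 1, 1) - 1L
      rows <- r0:(r0 + s - 1L)
      colsI <- c0:(c0 + s - 1L)
      if (!is.null(mask) && !all(mask[rows, colsI])) next
      if (any(sigma[rows, colsI] != 0)) next
      sigma[rows, colsI] <- i
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place seed in area ", i)
  }
  tv <- pt$targetVolume[match(types, pt$type)]
  cellLattice(sigma, types, tv, spacing = params@spacing,
              fibres = fibres, mask = mask)
}

.admissibleOffsets <- function(mask, a, s) {
  out <- logical(0)
  for (r0 in a$r0:(a$r1 - s + 1))
    for (c0 in a$c0:(a$c1 - s + 1))
      out <- c(out, all(mask[r0:(r0 + s - 1), c0:(c0 + s - 1)]))
  out
}

#' Run tissue formation
#'
#' Applies \code{nMCS} Monte-Carlo steps of the GGH dynamics and records
#' a metrics time series (mean cell volume, total adhesion count, medium
#' fraction) every \code{recordEvery} MCS.
#'
#' @param state a seeded [CellLattice-class]
#' @param params a [ModelParams-class]
#' @param nMCS number of Monte-Carlo steps
#' @param seed engine RNG seed
#' @param recordEvery logging stride in MCS (0 disables the log)
#' @return the final [CellLattice-class]
#' @export
runFormation <- function(state, params, nMCS, seed = 1L,
                         recordEvery = 100L) {
  monteCarloStep(state, params, n = nMCS, seed = seed,
                 recordEvery = recordEvery)
}

#' Grow a virtual tissue from a named preset
#'
#' Seeds and runs the full formation for one of the four culture
#' conditions. All randomness derives from \code{seed}; identical calls
#' are bit-identical.
#'
#' @param preset a [TissuePreset-class] or preset name
#' @param seed integer seed
#' @param fbFraction fibroblast fraction (default 0.5)
#' @param nMCS Monte-Carlo budget (default: the preset's)
#' @param dims lattice dimension override
#' @param mask optional admissible-domain mask (e.g.
#'   [buildLShapeMask()]); the seeding grid is scaled to the full dims
#' @param recordEvery formation log stride
#' @return a [CellLattice-class]
#' @export
growTissue <- function(preset, seed = 1L, fbFraction = 0.5, nMCS = NULL,
                       dims = NULL, mask = NULL, recordEvery = 0L) {
  if (is.character(preset)) preset <- loadPreset(preset)
  if (is.null(nMCS)) nMCS <- preset@mcs
  fullDims <- preset@dims
  if (is.null(dims)) dims <- fullDims
  # keep the seeding density of the preset under dimension overrides
  seedGrid <- as.integer(pmax(1, round(preset@seedGrid *
                                         dims[2:1] / fullDims[2:1])))
  fibres <- NULL
  if (preset@fibres)
    fibres <- generateFibreField(dims, preset@fibreOrientation,
                                 preset@fibrePitch)
  plan <- seedingPlan(dims, seedGrid, fbFraction)
  state <- .withSeed(.subSeed(seed, 1L),
                     seedCells(plan, preset@params, mask = mask,
                               fibres = fibres))
  runFormation(state, preset@params, nMCS, seed = .subSeed(seed, 2L),
               recordEvery = recordEvery)
}
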