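#' @useDynLib CardioLattice, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Per-type parameters of the extended Glazier-Graner-Hogeweg model
#'
#' Holds, for each cell type (CM = cardiomyocyte, FB = fibroblast), the
#' volume elasticity \eqn{\lambda}, the target area \eqn{V^t} (subcells),
#' the protrusion constant \eqn{G} (lattice energy units, i.e. already
#' divided by the physical subcell size so that \eqn{G/\rho} with
#' \eqn{\rho} in subcells is an energy), the detachment and unleash
#' penalties, the maximal protrusion reach \eqn{L_{MAX}} (subcells) and
#' the focal-adhesion quota \eqn{N_{protr}}; plus the symmetric adhesion
#' matrix \eqn{J} over (medium, CM, FB), the Metropolis temperature
#' \eqn{T} and the protected nucleus radius.
#'
#' @slot perType data.frame with one row per cell type
#' @slot J symmetric 3x3 adhesion-energy matrix, rows/cols (MD, CM, FB)
#' @slot temperature Metropolis temperature \eqn{T > 0}
#' @slot nucleusRadius radius of the stiff perinuclear region, subcells
#' @slot spacing physical subcell size, micrometres
#' @exportClass ModelParams
setClass("ModelParams", representation(
  perType = "data.frame",
  J = "matrix",
  temperature = "numeric",
  nucleusRadius = "numeric",
  spacing = "numeric",
  adhesionNeighbourhood = "character"
))

setValidity("ModelParams", function(object) {
  pt <- object@perType
  need <- c("type", "lambda", "targetVolume", "G", "Pdetach", "Punleash",
            "Lmax", "Nprotr")
  if (!all(need %in% names(pt))) {
    return(paste("perType must contain columns:", paste(need, collapse = ", ")))
  }
  if (!identical(dim(object@J), c(3L, 3L))) return("J must be 3x3")
  if (max(abs(object@J - t(object@J))) > 1e-12) return("J must be symmetric")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (any(pt$lambda <= 0) || any(pt$targetVolume <= 0) ||
      any(pt$Lmax <= 0) || any(pt$Nprotr <= 0)) {
    return("lambda, targetVolume, Lmax, Nprotr must be strictly positive")
  }
  TRUE
})

#' Nanofibre scaffold field
#'
#' Boolean occupancy of nanofibre subcells and their orientation (radians,
#' angle from the column axis, values in [0, pi)); orientation is only
#' meaningful where \code{occupied} is TRUE.
#'
#' @slot occupied logical matrix, TRUE where a subcell lies on a fibre
#' @slot orientation numeric matrix of fibre angles (radians)
#' @exportClass FibreField
setClass("FibreField", representation(
  occupied = "matrix",
  orientation = "matrix"
))

setValidity("FibreField", function(object) {
  if (!identical(dim(object@occupied), dim(object@orientation)))
    return("occupied and orientation must have identical dimensions")
  ori <- object@orientation[object@occupied]
  if (length(ori) && (any(ori < 0) || any(ori >= pi)))
    return("orientation angles must lie in [0, pi)")
  TRUE
})

#' Cellular Potts lattice state
#'
#' The integer cell-index grid (0 = medium, >= 1 = cell index sigma)
#' together with per-cell bookkeeping: type, volume, target volume,
#' centre of mass and focal-adhesion sites. All dynamics operate on this
#' object; bookkeeping is maintained incrementally by the engine and can
#' be audited against the grid with [auditLattice()].
#'
#' @slot sigma integer matrix of cell indices
#' @slot spacing physical subcell size in micrometres (2.5)
#' @slot cells data.frame: index, type ("CM"/"FB"), volume, targetVolume,
#'   cmRow, cmCol (continuous, 1-based lattice coordinates)
#' @slot adhesions list (one 2-column matrix of row/col sites per cell)
#' @slot fibres a [FibreField-class] or NULL
#' @slot mask logical admissible-domain matrix or NULL (TRUE = inside)
#' @slot mcs completed Monte-Carlo steps
#' @slot log data.frame time series recorded during formation
#' @exportClass CellLattice
setClass("CellLattice", representation(
  sigma = "matrix",
  spacing = "numeric",
  cells = "data.frame",
  adhesions = "list",
  fibres = "ANY",
  mask = "ANY",
  mcs = "integer",
  log = "data.frame"
))

setValidity("CellLattice", function(object) {
  sig <- object@sigma
  k <- nrow(object@cells)
  if (length(sig) && max(sig) > k) return("sigma refers to a missing cell")
  if (any(sig < 0)) return("sigma must be non-negative")
  vols <- tabulate(sig[sig > 0], nbins = k)
  if (k > 0 && !identical(as.integer(vols), as.integer(object@cells$volume)))
    return("stored volumes disagree with sigma")
  if (k > 0 && any(vols < 1)) return("cells may not have volume 0")
  if (length(object@adhesions) != k)
    return("adhesions list must have one entry per cell")
  for (i in seq_len(k)) {
    a <- object@adhesions[[i]]
    if (nrow(a) && any(sig[cbind(a[, 1], a[, 2])] != i))
      return(sprintf("adhesion site of cell %d not owned by it", i))
  }
  if (!is.null(object@fibres) && !is(object@fibres, "FibreField"))
    return("fibres must be a FibreField or NULL")
  TRUE
})

#' Gap-junction label field
#'
#' Binary labels (1 = more-GJ, 0 = less-GJ) on the subcells of a frozen
#' cell-index grid; produced by [distributeGapJunctions()].
#'
#' @slot labels integer matrix of labels (only on non-medium subcells)
#' @slot sigma frozen copy of the cell-index grid
#' @exportClass GJLabelField
setClass("GJLabelField", representation(
  labels = "matrix",
  sigma = "matrix"
))

setValidity("GJLabelField", function(object) {
  if (!identical(dim(object@labels), dim(object@sigma)))
    return("labels and sigma must have identical dimensions")
  if (any(object@labels[object@sigma == 0] != 0))
    return("labels must be zero on medium subcells")
  TRUE
})

#' Per-face conductance map for the monodomain solver
#'
#' Diffusion coefficients on lattice faces: \code{Dx} between horizontally
#' adjacent pixels (dimensions R x (C-1)), \code{Dy} between vertically
#' adjacent pixels ((R-1) x C), in cm^2/s. Levels are D_in (within a CM),
#' D_end-end (CM-CM faces flanked by more-GJ labels on both sides),
#' D_side-side (other CM-CM faces) and 0 (CM-FB, FB, medium).
#'
#' @slot Dx,Dy numeric face matrices (cm^2/s)
#' @slot h space step, micrometres
#' @slot levels named numeric: Din, Dend, Dside
#' @exportClass ConductanceMap
setClass("ConductanceMap", representation(
  Dx = "matrix",
  Dy = "matrix",
  h = "numeric",
  levels = "numeric"
))

setValidity("ConductanceMap", function(object) {
  lv <- object@levels
  if (!all(c("Din", "Dend", "Dside") %in% names(lv)))
    return("levels must name Din, Dend, Dside")
  if (!(lv["Din"] >= lv["Dend"] && lv["Dend"] >= lv["Dside"] &&
        lv["Dside"] >= 0))
    return("conductance levels must satisfy Din >= Dend >= Dside >= 0")
  ok <- sort(unique(c(0, lv)))
  vals <- unique(c(object@Dx, object@Dy))
  if (any(!vals %in% ok)) return("face values outside the declared levels")
  TRUE
})

#' Ionic model contract for the monodomain solver
#'
#' A pluggable description of membrane kinetics: \code{iion(V, gates)}
#' returns the total ionic current divided by membrane capacitance
#' (units 1/ms times the potential unit), \code{gateStep(V, gates, dt)}
#' advances the gating state, \code{initGates(dims)} builds the resting
#' gate matrices. The resting state must be a fixed point.
#'
#' @slot name model name
#' @slot iion,gateStep,initGates functions, see description
#' @slot restingV resting potential (model units)
#' @slot amplitude nominal action-potential amplitude (model units)
#' @slot threshold activation threshold used for activation maps
#' @exportClass IonicModel
setClass("IonicModel", representation(
  name = "character",
  iion = "function",
  gateStep = "function",
  initGates = "function",
  restingV = "numeric",
  amplitude = "numeric",
  threshold = "numeric"
))

#' Membrane state of the monodomain simulation
#'
#' @slot V transmembrane potential matrix (model units)
#' @slot gates list of gate matrices of the active ionic model
#' @slot t current time, ms
#' @slot dt time step, ms
#' @slot h space step, micrometres
#' @slot Cm membrane capacitance (model units; 1 for the surrogate)
#' @exportClass MembraneState
setClass("MembraneState", representation(
  V = "matrix",
  gates = "list",
  t = "numeric",
  dt = "numeric",
  h = "numeric",
  Cm = "numeric"
))

setValidity("MembraneState", function(object) {
  if (any(!is.finite(object@V))) return("V must be finite everywhere")
  if (object@dt <= 0 || object@h <= 0) return("dt and h must be > 0")
  TRUE
})

#' First-activation-time map
#'
#' Per-pixel time (ms) of the first upward threshold crossing; NA marks
#' pixels that never activated.
#'
#' @slot times numeric matrix of activation times (ms), NA = unactivated
#' @slot h space step, micrometres
#' @exportClass ActivationMap
setClass("ActivationMap", representation(
  times = "matrix",
  h = "numeric"
))

#' Morphometric report
#'
#' Per-cell shape metrics (area in um^2, convex coverage, caliper
#' elongation, skeleton-endpoint protrusion counts at 1.0 um and convex
#' counts at 2.5 um) and their per-type mean and SD.
#'
#' @slot perCell data.frame, one row per cell
#' @slot perType data.frame, mean and sd per (type, metric)
#' @slot spacing subcell size, micrometres
#' @exportClass ShapeReport
setClass("ShapeReport", representation(
  perCell = "data.frame",
  perType = "data.frame",
  spacing = "numeric"
))

#' Named simulation preset
#'
#' A complete experiment description: model parameters, lattice
#' dimensions, seeding grid, Monte-Carlo budget and scaffold layout for
#' one of the four culture conditions.
#'
#' @slot name preset name
#' @slot params a [ModelParams-class]
#' @slot dims lattice (rows, cols)
#' @slot seedGrid seeding areas (nx = along columns, ny = along rows)
#' @slot mcs default formation length, Monte-Carlo steps
#' @slot sampleDim physical sample size (mm, x and y)
#' @slot fibres logical: nanofibre scaffold present
#' @slot fibrePitch fibre row spacing, subcells
#' @slot fibreOrientation fibre angle, radians (0 = along columns/x)
#' @exportClass TissuePreset
setClass("TissuePreset", representation(
  name = "character",
  params = "ModelParams",
  dims = "integer",
  seedGrid = "integer",
  mcs = "integer",
  sampleDim = "numeric",
  fibres = "logical",
  fibrePitch = "numeric",
  fibreOrientation = "numeric"
))

setMethod("show", "CellLattice", function(object) {
  tab <- table(object@cells$type)
  cat(sprintf("CellLattice: %d x %d subcells (%.1f um), %d cells (%s), %d MCS\n",
              nrow(object@sigma), ncol(object@sigma), object@spacing,
              nrow(object@cells),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              object@mcs))
  cat(sprintf("  medium fraction %.3f; fibres: %s; mask: %s\n",
              mean(object@sigma == 0),
              if (is.null(object@fibres)) "none" else "yes",
              if (is.null(object@mask)) "none" else "yes"))
})

setMethod("show", "ConductanceMap", function(object) {
  cat(sprintf("ConductanceMap: %d x %d pixels, h = %.2f um\n",
              nrow(object@Dy) + 1L, ncol(object@Dx) + 1L, object@h))
  cat(sprintf("  levels (cm^2/s): Din = %g, Dend = %g, Dside = %g\n",
              object@levels["Din"], object@levels["Dend"],
              object@levels["Dside"]))
})

setMethod("show", "ActivationMap", function(object) {
  act <- !is.na(object@times)
  cat(sprintf("ActivationMap: %d x %d pixels, %.1f%% activated",
              nrow(object@times), ncol(object@times), 100 * mean(act)))
  if (any(act))
    cat(sprintf(", t in [%.2f, %.2f] ms", min(object@times, na.rm = TRUE),
                max(object@times, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "TissuePreset", function(object) {
  cat(sprintf("TissuePreset '%s': %d x %d lattice (%g x %g mm), %d MCS, seeding grid %d x %d%s\n",
              object@name, object@dims[1], object@dims[2],
              object@sampleDim[1], object@sampleDim[2], object@mcs,
              object@seedGrid[1], object@seedGrid[2],
              if (object@fibres) ", nanofibres" else ""))
})

setMethod("show", "ShapeReport", function(object) {
  cat(sprintf("ShapeReport: %d cells\n", nrow(object@perCell)))
  print(object@perType, digits = 3)
})
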