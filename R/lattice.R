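#' Create a cell lattice from a label grid
#'
#' Builds the bookkeeping (volumes, centres of mass, empty adhesion sets)
#' from an integer cell-index matrix. Used for seeding and for importing
#' user-supplied labelled meshes.
#'
#' @param sigma integer matrix, 0 = medium, 1..K = cell indices
#' @param types character vector of cell types ("CM"/"FB"), one per cell
#' @param targetVolume numeric target areas in subcells, one per cell
#' @param spacing subcell size, micrometres
#' @param fibres optional [FibreField-class]
#' @param mask optional logical admissible-domain matrix
#' @param adhesions optional list of 2-column (row, col) matrices
#' @return a [CellLattice-class]
#' @export
cellLattice <- function(sigma, types, targetVolume, spacing = 2.5,
                        fibres = NULL, mask = NULL, adhesions = NULL) {
  sigma <- matrix(as.integer(sigma), nrow(sigma), ncol(sigma))
  k <- length(types)
  stopifnot(length(targetVolume) == k)
  vol <- tabulate(sigma[sigma > 0], nbins = k)
  cmR <- cmC <- rep(NA_real_, k)
  if (k > 0) {
    rows <- row(sigma)[sigma > 0]
    cols <- col(sigma)[sigma > 0]
    idx <- sigma[sigma > 0]
    cmR <- as.numeric(tapply(rows, factor(idx, levels = seq_len(k)), mean))
    cmC <- as.numeric(tapply(cols, factor(idx, levels = seq_len(k)), mean))
  }
  if (is.null(adhesions)) {
    adhesions <- replicate(k, matrix(integer(), 0, 2), simplify = FALSE)
  }
  cells <- data.frame(index = seq_len(k), type = as.character(types),
                      volume = vol, targetVolume = targetVolume,
                      cmRow = cmR, cmCol = cmC, stringsAsFactors = FALSE)
  new("CellLattice", sigma = sigma, spacing = spacing, cells = cells,
      adhesions = adhesions, fibres = fibres, mask = mask, mcs = 0L,
      log = data.frame())
}

#' @describeIn cellLattice the integer cell-index matrix
#' @param x a CellLattice
#' @export
sigmaMatrix <- function(x) x@sigma

#' @describeIn cellLattice the per-cell bookkeeping table
#' @export
cellTable <- function(x) x@cells

#' @describeIn cellLattice the focal-adhesion site list
#' @export
adhesionSites <- function(x) x@adhesions

#' @describeIn cellLattice the nanofibre field (or NULL)
#' @export
fibreField <- function(x) x@fibres

#' @describeIn cellLattice subcell size in micrometres
#' @export
latticeSpacing <- function(x) x@spacing

#' @describeIn cellLattice completed Monte-Carlo steps
#' @export
mcsCount <- function(x) x@mcs

#' @describeIn cellLattice formation time-series log
#' @export
formationLog <- function(x) x@log

# convert S4 state to the argument list of the C++ engine
.engineState <- function(state) {
  typeCode <- match(state@cells$type, c("CM", "FB"))
  if (anyNA(typeCode) && nrow(state@cells) > 0)
    stop("cell types must be 'CM' or 'FB'")
  fo <- state@fibres
  list(sigma = state@sigma,
       cellType = as.integer(typeCode),
       targetV = as.numeric(state@cells$targetVolume),
       adhList = state@adhesions,
       fibOcc = if (is.null(fo)) NULL else fo@occupied,
       fibOri = if (is.null(fo)) NULL else fo@orientation,
       mask = state@mask)
}

# fold engine output back into the S4 state
.applyEngine <- function(state, res, mcsAdd = 0L) {
  state@sigma <- res$sigma
  state@cells$volume <- as.integer(res$volume)
  state@cells$cmRow <- res$cmRow
  state@cells$cmCol <- res$cmCol
  state@adhesions <- res$adhesions
  state@mcs <- state@mcs + as.integer(mcsAdd)
  if (!is.null(res$log) && nrow(res$log) > 0) {
    state@log <- rbind(state@log, res$log)
  }
  state
}

#' Audit the incremental bookkeeping of a lattice
#'
#' Recomputes volumes, centres of mass, adhesion ownership and
#' 4-connectivity directly from the index grid and compares them with
#' the incrementally maintained records.
#'
#' @param state a [CellLattice-class]
#' @param tol tolerance for centre-of-mass comparison (lattice units)
#' @return TRUE invisibly if consistent; otherwise stops with a message
#'   naming the first offending cell
#' @export
auditLattice <- function(state, tol = 1e-9) {
  sig <- state@sigma
  cells <- state@cells
  k <- nrow(cells)
  vols <- tabulate(sig[sig > 0], nbins = k)
  bad <- which(vols != cells$volume)
  if (length(bad))
    stop("volume mismatch for cell ", bad[1])
  if (any(vols < 1))
    stop("cell ", which(vols < 1)[1], " has disappeared")
  rows <- row(sig)[sig > 0]
  cols <- col(sig)[sig > 0]
  idx <- factor(sig[sig > 0], levels = seq_len(k))
  cmR <- as.numeric(tapply(rows, idx, mean))
  cmC <- as.numeric(tapply(cols, idx, mean))
  bad <- which(abs(cmR - cells$cmRow) > tol | abs(cmC - cells$cmCol) > tol)
  if (length(bad))
    stop("centre-of-mass drift for cell ", bad[1])
  for (i in seq_len(k)) {
    a <- state@adhesions[[i]]
    if (nrow(a) == 0) next
    if (any(sig[cbind(a[, 1], a[, 2])] != i))
      stop("adhesion site not owned by cell ", i)
  }
  for (i in seq_len(k)) {
    sites <- which(sig == i, arr.ind = TRUE)
    if (nrow(sites) > 1) {
      if (!.connectedMask(sig == i))
        stop("cell ", i, " is not 4-connected")
    }
  }
  invisible(TRUE)
}

# 4-connectivity of a logical mask (pure R flood fill; used by audits)
.connectedMask <- function(mask) {
  n <- sum(mask)
  if (n <= 1) return(TRUE)
  lab <- matrix(FALSE, nrow(mask), ncol(mask))
  start <- which(mask)[1]
  queue <- start
  lab[start] <- TRUE
  nr <- nrow(mask)
  reached <- 1L
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    r <- (cur - 1L) %% nr + 1L
    c <- (cur - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > ncol(mask)) next
      i <- rr + (cc - 1L) * nr
      if (mask[i] && !lab[i]) {
        lab[i] <- TRUE
        reached <- reached + 1L
        queue <- c(queue, i)
      }
    }
  }
  reached == n
}

# evaluate code with a temporary RNG seed, restoring the caller's state
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# derive a bounded sub-seed from a user seed
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}
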