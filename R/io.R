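#' Write a lattice mesh to a directory
#'
#' Writes \code{sigma.tiff} (16-bit label image), \code{cells.csv}
#' (index, type, volume, target_volume, cm_row, cm_col, adhesions as
#' "r:c;..."), optional \code{fibres.tiff} and \code{mask.tiff}, and a
#' \code{manifest.json} with dimensions, spacing, MCS count, the fibre
#' orientation and md5 checksums of every file.
#'
#' @param state a [CellLattice-class]
#' @param dir output directory (created if needed)
#' @param extra named list merged into the manifest (e.g. preset, seed)
#' @return the manifest, invisibly
#' @export
writeMesh <- function(state, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (max(state@sigma) > 65535) stop("more than 65535 cells")
  tiff::writeTIFF(state@sigma / 65535, file.path(dir, "sigma.tiff"),
                  bits.per.sample = 16L, compression = "none")
  cells <- state@cells
  cells$adhesions <- vapply(state@adhesions, function(a) {
    if (nrow(a) == 0) "" else paste(sprintf("%d:%d", a[, 1], a[, 2]),
                                    collapse = ";")
  }, "")
  names(cells) <- c("index", "type", "volume", "target_volume", "cm_row",
                    "cm_col", "adhesions")
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  files <- c("sigma.tiff", "cells.csv")
  fo <- state@fibres
  if (!is.null(fo)) {
    tiff::writeTIFF(fo@occupied * 1, file.path(dir, "fibres.tiff"),
                    bits.per.sample = 8L, compression = "none")
    files <- c(files, "fibres.tiff")
  }
  if (!is.null(state@mask)) {
    tiff::writeTIFF(state@mask * 1, file.path(dir, "mask.tiff"),
                    bits.per.sample = 8L, compression = "none")
    files <- c(files, "mask.tiff")
  }
  manifest <- c(list(
    format = "CardioLattice mesh v1",
    dims = dim(state@sigma), spacing = state@spacing, mcs = state@mcs,
    nCells = nrow(state@cells),
    fibreOrientation = if (is.null(fo)) NULL else
      unique(fo@orientation[fo@occupied])[1],
    coordinates = "row/col, 1-based, origin top-left",
    checksums = as.list(tools::md5sum(file.path(dir, files)))
  ), extra)
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a lattice mesh from a directory
#'
#' Inverse of [writeMesh()]; verifies that the label image and the cell
#' table agree and reports the first offending cell index otherwise.
#'
#' @param dir directory written by [writeMesh()]
#' @return a [CellLattice-class]
#' @export
readMesh <- function(dir) {
  sig <- round(tiff::readTIFF(file.path(dir, "sigma.tiff")) * 65535)
  storage.mode(sig) <- "integer"
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  k <- nrow(cells)
  if (any(sort(unique(sig[sig > 0])) > k))
    stop("label image refers to cell index missing from the table: ",
         setdiff(unique(sig[sig > 0]), cells$index)[1])
  vols <- tabulate(sig[sig > 0], nbins = k)
  bad <- which(vols != cells$volume)
  if (length(bad))
    stop("volume mismatch between image and table for cell ", bad[1])
  adh <- lapply(cells$adhesions, function(s) {
    if (is.na(s) || s == "") return(matrix(integer(), 0, 2))
    parts <- strsplit(strsplit(s, ";")[[1]], ":")
    m <- do.call(rbind, lapply(parts, as.integer))
    m
  })
  fibres <- NULL
  fpath <- file.path(dir, "fibres.tiff")
  if (file.exists(fpath)) {
    occ <- tiff::readTIFF(fpath) > 0.5
    ori <- matrix(man$fibreOrientation %||% 0, nrow(occ), ncol(occ))
    fibres <- new("FibreField", occupied = occ, orientation = ori)
  }
  mask <- NULL
  mpath <- file.path(dir, "mask.tiff")
  if (file.exists(mpath)) mask <- tiff::readTIFF(mpath) > 0.5
  st <- cellLattice(sig, cells$type, cells$target_volume,
                    spacing = man$spacing, fibres = fibres, mask = mask,
                    adhesions = adh)
  st@mcs <- as.integer(man$mcs)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic toy fixtures
#'
#' Seed-free analytic inputs used in examples and tests: named masks
#' ("rect" 20x10, "square" 10x10, "bar" 1x10, "plus" the 3x3
#' plus-pentomino, "cross" a four-armed cross, "star" a five-armed
#' star), tiny lattices ("single", "pair", "cmfb") and synthetic linear
#' activation maps.
#'
#' @param name fixture name
#' @return the fixture object
#' @export
fixtureMask <- function(name = c("rect", "square", "bar", "plus", "cross",
                                 "star")) {
  name <- match.arg(name)
  switch(name,
    rect = matrix(TRUE, 10, 20),
    square = matrix(TRUE, 10, 10),
    bar = matrix(TRUE, 1, 10),
    plus = {
      m <- matrix(FALSE, 3, 3)
      m[2, ] <- TRUE; m[, 2] <- TRUE
      m
    },
    cross = {
      # arms 3 subcells wide, 12 long (30 um > the 7 um central disk)
      m <- matrix(FALSE, 27, 27)
      m[13:15, ] <- TRUE; m[, 13:15] <- TRUE
      m
    },
    star = {
      n <- 41; ctr <- 21
      m <- matrix(FALSE, n, n)
      ang <- pi / 2 + 2 * pi * (0:4) / 5
      for (k in 1:5) {
        for (s in seq(0, 18, by = 0.25)) {
          r <- ctr - round(s * sin(ang[k]))
          c <- ctr + round(s * cos(ang[k]))
          w <- if (s < 6) 1 else 0
          m[max(1, r - w):min(n, r + w), max(1, c - w):min(n, c + w)] <- TRUE
        }
      }
      m
    })
}

#' @describeIn fixtureMask tiny deterministic lattices: "single" one
#'   10x10 CM; "pair" two touching CMs; "cmfb" a touching CM/FB pair
#' @export
fixtureLattice <- function(name = c("single", "pair", "cmfb")) {
  name <- match.arg(name)
  switch(name,
    single = {
      sig <- matrix(0L, 14, 14)
      sig[3:12, 3:12] <- 1L
      cellLattice(sig, "CM", 100)
    },
    pair = {
      sig <- matrix(0L, 12, 20)
      sig[4:9, 3:9] <- 1L
      sig[4:9, 10:16] <- 2L
      cellLattice(sig, c("CM", "CM"), c(42, 42))
    },
    cmfb = {
      sig <- matrix(0L, 12, 20)
      sig[4:9, 3:9] <- 1L
      sig[4:9, 10:16] <- 2L
      cellLattice(sig, c("CM", "FB"), c(42, 42))
    })
}

#' @describeIn fixtureMask synthetic activation map with plane-wave
#'   slopes: time = row/speedY + col/speedX (ms, pixel units)
#' @param dims map dimensions
#' @param speedX,speedY plane speeds in pixels/ms (Inf = no gradient)
#' @param h space step um
#' @export
fixtureActivationMap <- function(dims = c(50, 50), speedX = 20,
                                 speedY = Inf, h = 2.5) {
  r <- matrix(seq_len(dims[1]), dims[1], dims[2])
  c <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  times <- c / speedX + r / speedY
  new("ActivationMap", times = times, h = h)
}

#' Write all fixture files to a directory
#'
#' Masks as 8-bit TIFFs, lattices as mesh directories, activation maps
#' as CSV; generation is deterministic and idempotent.
#'
#' @param outdir output directory
#' @return invisible vector of written paths
#' @export
generateFixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in c("rect", "square", "bar", "plus", "cross", "star")) {
    p <- file.path(outdir, paste0("mask_", nm, ".tiff"))
    tiff::writeTIFF(fixtureMask(nm) * 1, p, bits.per.sample = 8L,
                    compression = "none")
    paths <- c(paths, p)
  }
  for (nm in c("single", "pair", "cmfb")) {
    d <- file.path(outdir, paste0("lattice_", nm))
    writeMesh(fixtureLattice(nm), d)
    paths <- c(paths, d)
  }
  am <- fixtureActivationMap()
  p <- file.path(outdir, "activation_linear.csv")
  utils::write.table(am@times, p, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
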