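#' Parameters of the gap-junction distribution model
#'
#' Published values: spreading constant G = 25, side-to-side contact
#' energy J_H = 2, within-cell contact energy J_B = 10 (end-to-end
#' more-GJ contacts across cells cost 0). The more-GJ quota per cell is
#' the one-subcell dilation of its focal-adhesion sites (a reasonable
#' surrounding of the attachment sites); \code{mcs} is the label-swap
#' Metropolis budget.
#'
#' @param G,JH,JB,temperature model energies
#' @param mcs label Monte-Carlo steps
#' @param quotaDilate dilation radius (subcells) of the initial label
#'   patches around each adhesion site
#' @return named list of parameters
#' @export
gjParams <- function(G = 25.0, JH = 2.0, JB = 10.0, temperature = 1.0,
                     mcs = 100L, quotaDilate = 1L) {
  stopifnot(G >= 0, JH >= 0, JB >= 0, temperature > 0)
  list(G = G, JH = JH, JB = JB, temperature = temperature,
       mcs = as.integer(mcs), quotaDilate = as.integer(quotaDilate))
}

#' Distribute more-GJ membrane labels
#'
#' Initialises more-GJ labels on the dilated focal-adhesion patches of
#' every cell, then runs label-swap Metropolis dynamics under the
#' secondary GGH-like Hamiltonian (adhesive label terms J_B within a
#' cell, J_H for side contacts, 0 for cross-cell more-GJ contacts, and
#' an outward-driving protrusion term G/rho from the owning cell's
#' centre of mass) with the cell-index grid frozen. Per-cell label
#' counts are conserved; a cell without adhesions gets no labels.
#'
#' @param state a formed [CellLattice-class]
#' @param params a [gjParams()] list
#' @param seed engine RNG seed
#' @return a [GJLabelField-class]
#' @export
distributeGapJunctions <- function(state, params = gjParams(), seed = 1L) {
  sig <- state@sigma
  lab <- matrix(0L, nrow(sig), ncol(sig))
  d <- params$quotaDilate
  for (i in seq_len(nrow(state@cells))) {
    a <- state@adhesions[[i]]
    if (nrow(a) == 0) next
    for (j in seq_len(nrow(a))) {
      rr <- max(1, a[j, 1] - d):min(nrow(sig), a[j, 1] + d)
      cc <- max(1, a[j, 2] - d):min(ncol(sig), a[j, 2] + d)
      blk <- sig[rr, cc, drop = FALSE] == i
      lab[rr, cc][blk] <- 1L
    }
  }
  out <- .cl_gj_run(sig, lab, state@cells$cmRow, state@cells$cmCol,
                    params$G, params$JH, params$JB, params$temperature,
                    params$mcs, as.integer(seed))
  new("GJLabelField", labels = out, sigma = sig)
}

#' @describeIn distributeGapJunctions the label matrix
#' @param x a GJLabelField
#' @export
gjLabels <- function(x) x@labels

#' Translate tissue and labels into a per-face conductance map
#'
#' Faces within one cardiomyocyte get \code{Din}; CM-CM faces flanked by
#' more-GJ labels on both sides get \code{Dend}; other CM-CM faces get
#' \code{Dside}; CM-FB faces, fibroblast faces (unexcited obstacles) and
#' faces touching medium get 0. Requires Din >= Dend >= Dside >= 0.
#'
#' @param state a [CellLattice-class]
#' @param gj a [GJLabelField-class] (may be NULL when Dend == Dside)
#' @param Din,Dend,Dside conductance levels in cm^2/s
#' @return a [ConductanceMap-class]
#' @export
buildConductanceMap <- function(state, gj, Din, Dend, Dside) {
  if (!(Din >= Dend && Dend >= Dside && Dside >= 0))
    stop("conductance levels must satisfy Din >= Dend >= Dside >= 0")
  sig <- state@sigma
  if (is.null(gj)) {
    if (Dend != Dside)
      stop("a GJ label field is required when Dend differs from Dside")
    lab <- matrix(0L, nrow(sig), ncol(sig))
  } else {
    stopifnot(identical(dim(gj@sigma), dim(sig)))
    lab <- gj@labels
  }
  isCM <- matrix(FALSE, nrow(sig), ncol(sig))
  cmIdx <- state@cells$index[state@cells$type == "CM"]
  isCM[sig %in% cmIdx] <- TRUE

  faceD <- function(sa, sb, ca, cb, la, lb) {
    d <- numeric(length(sa))
    both <- ca & cb
    same <- both & sa == sb
    diffc <- both & sa != sb
    d[same] <- Din
    d[diffc] <- ifelse(la[diffc] == 1 & lb[diffc] == 1, Dend, Dside)
    d
  }
  R <- nrow(sig); C <- ncol(sig)
  Dx <- matrix(0, R, max(C - 1, 0))
  if (C > 1) {
    sa <- sig[, -C]; sb <- sig[, -1]
    Dx[] <- faceD(sa, sb, isCM[, -C], isCM[, -1], lab[, -C], lab[, -1])
  }
  Dy <- matrix(0, max(R - 1, 0), C)
  if (R > 1) {
    sa <- sig[-R, ]; sb <- sig[-1, ]
    Dy[] <- faceD(sa, sb, isCM[-R, ], isCM[-1, ], lab[-R, ], lab[-1, ])
  }
  new("ConductanceMap", Dx = Dx, Dy = Dy, h = state@spacing,
      levels = c(Din = Din, Dend = Dend, Dside = Dside))
}

#' @describeIn buildConductanceMap face matrices as a list (Dx, Dy)
#' @param x a ConductanceMap
#' @export
faceConductances <- function(x) list(Dx = x@Dx, Dy = x@Dy)
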