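#' Energy change of a proposed index copy
#'
#' Evaluates the exact change in the extended GGH Hamiltonian caused by
#' copying the index at \code{source} onto the neighbouring \code{target}
#' site: adhesive pair recount over the Moore neighbourhood, volume
#' elasticity for both affected cells, the focal-adhesion protrusion
#' potential \eqn{G/\rho} (fibre-projected \eqn{G/(\rho\cos\alpha)} on
#' nanofibre subcells) including the exact centre-of-mass shift, and the
#' event penalties: \eqn{P_{detach}} when the copy destroys an existing
#' focal adhesion, \eqn{P_{unleash}} when an adhesion tip moves from a
#' fibre subcell to a non-fibre subcell, and \eqn{P_N = 2 P_{detach}}
#' when medium or a foreign cell invades within the nucleus radius of a
#' cell's centre of mass.
#'
#' @param state a [CellLattice-class]
#' @param params a [ModelParams-class]
#' @param target,source length-2 integer (row, col), Moore neighbours
#'   with different indices
#' @return the total energy change, with attribute \code{"components"}
#'   (adhesive, elastic, protrusion, penalty)
#' @export
deltaHamiltonian <- function(state, params, target, source) {
  .checkNeighbours(target, source)
  if (state@sigma[target[1], target[2]] == state@sigma[source[1], source[2]])
    stop("target and source must hold different indices")
  es <- .engineState(state)
  res <- .cl_attempt(es$sigma, es$cellType, es$targetV, es$adhList,
                     es$fibOcc, es$fibOri, es$mask, .engineParams(params),
                     as.integer(target), as.integer(source), 0L, TRUE)
  if (res$outcome == "forbidden")
    stop("energy undefined: the copy would make a cell disappear")
  out <- unname(res$deltaH["total"])
  attr(out, "components") <- res$deltaH[c("adhesive", "elastic",
                                          "protrusion", "penalty")]
  out
}

.checkNeighbours <- function(target, source) {
  d <- abs(as.integer(target) - as.integer(source))
  if (length(target) != 2 || length(source) != 2 ||
      max(d) > 1 || all(d == 0))
    stop("target and source must be distinct Moore-neighbouring sites")
}

#' Metropolis acceptance rule
#'
#' Accepts with probability 1 when \code{deltaH <= 0} and with
#' probability \eqn{e^{-\Delta H/T}} otherwise. Consumes exactly one
#' uniform draw from the R random stream per positive \code{deltaH} and
#' none otherwise (reproducibility contract).
#'
#' @param deltaH energy change(s)
#' @param temperature Metropolis temperature, > 0
#' @return logical vector of acceptance decisions
#' @export
metropolisAccept <- function(deltaH, temperature) {
  stopifnot(temperature > 0)
  acc <- rep(TRUE, length(deltaH))
  pos <- which(deltaH > 0)
  if (length(pos))
    acc[pos] <- stats::runif(length(pos)) < exp(-deltaH[pos] / temperature)
  acc
}

#' Attempt a single index copy
#'
#' Picks a uniform random target site and a uniform random Moore
#' neighbour source (or uses the supplied sites), applies the forbidden
#' rules (cell disappearance, 4-connectivity breakage, protrusion spread
#' beyond L_MAX), evaluates the energy change and the Metropolis rule,
#' and on acceptance updates the grid and all bookkeeping: volumes,
#' centres of mass, bounding boxes and focal adhesions (a destroyed
#' adhesion is removed from its owner; an adhesion tip used as the copy
#' source relocates to the new subcell; a cell below its N_protr quota
#' establishes a new adhesion at a newly added border subcell).
#'
#' @param state a [CellLattice-class]
#' @param params a [ModelParams-class]
#' @param seed integer seed for the engine RNG
#' @param target,source optional explicit (row, col) sites; both random
#'   when omitted
#' @return list with \code{outcome} ("accepted", "rejected",
#'   "forbidden"), \code{deltaH} (with components; NA when the attempt
#'   was forbidden or a same-index no-op) and the updated \code{state}
#' @export
copyAttempt <- function(state, params, seed = 1L, target = NULL,
                        source = NULL) {
  es <- .engineState(state)
  if (is.null(target) != is.null(source))
    stop("supply both target and source, or neither")
  if (is.null(target)) {
    att <- .randomSites(dim(state@sigma), seed)
    target <- att$target
    source <- att$source
    if (is.null(source)) {
      return(list(outcome = "rejected", deltaH = NA_real_, state = state))
    }
  }
  .checkNeighbours(target, source)
  res <- .cl_attempt(es$sigma, es$cellType, es$targetV, es$adhList,
                     es$fibOcc, es$fibOri, es$mask, .engineParams(params),
                     as.integer(target), as.integer(source),
                     as.integer(seed), FALSE)
  state2 <- .applyEngine(state, res)
  dh <- if (res$outcome == "forbidden") NA_real_ else
    unname(res$deltaH["total"])
  list(outcome = res$outcome, deltaH = dh, state = state2,
       target = target, source = source)
}

# uniform random target site and Moore-neighbour source
# (draw order mirrors the engine: site, then neighbour; an out-of-lattice
# neighbour makes the attempt a no-op under the closed boundary)
.randomSites <- function(dims, seed) {
  u <- .withSeed(seed, stats::runif(2))
  nr <- dims[1]; nc <- dims[2]
  t0 <- min(floor(u[1] * nr * nc), nr * nc - 1)
  tr <- t0 %% nr + 1
  tc <- t0 %/% nr + 1
  off <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  k <- min(floor(u[2] * 8), 7) + 1
  sr <- tr + off[k, 1]; sc <- tc + off[k, 2]
  if (sr < 1 || sr > nr || sc < 1 || sc > nc)
    return(list(target = c(tr, tc), source = NULL))
  list(target = c(tr, tc), source = c(sr, sc))
}

#' Would removing a site keep a cell 4-connected?
#'
#' Flood fill restricted to the cell's bounding box (cost O(box), not
#' O(lattice)), the boxed connectivity-check optimisation.
#'
#' @param state a [CellLattice-class]
#' @param cell cell index
#' @param site length-2 (row, col), must belong to the cell
#' @return TRUE iff the cell's subcells minus the site stay 4-connected
#' @export
connectivityPreserved <- function(state, cell, site) {
  if (state@sigma[site[1], site[2]] != cell)
    stop("site is not owned by cell ", cell)
  .cl_connectivity(state@sigma, as.integer(cell), as.integer(site))
}

#' Run Monte-Carlo steps of the GGH dynamics
#'
#' One Monte-Carlo step performs N copy attempts, where N is the total
#' number of lattice subcells. The whole run uses a single seeded
#' generator; identical seed, state and parameters give a bit-identical
#' trajectory.
#'
#' @param state a [CellLattice-class]
#' @param params a [ModelParams-class]
#' @param n number of Monte-Carlo steps
#' @param seed integer seed for the engine RNG
#' @param recordEvery record the formation log every this many MCS
#'   (0 = no log)
#' @return the updated [CellLattice-class]; attempt outcome counts in
#'   \code{attr(, "counts")}
#' @export
monteCarloStep <- function(state, params, n = 1L, seed = 1L,
                           recordEvery = 0L) {
  es <- .engineState(state)
  res <- .cl_run_mcs(es$sigma, es$cellType, es$targetV, es$adhList,
                     es$fibOcc, es$fibOri, es$mask, .engineParams(params),
                     as.integer(n), as.integer(seed),
                     as.integer(recordEvery), state@mcs)
  out <- .applyEngine(state, res, mcsAdd = n)
  attr(out, "counts") <- res$counts
  out
}
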