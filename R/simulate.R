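#' Run one simulation
#'
#' Initializes N free agents uniformly at random on distinct pixels at z = 0,
#' seeds the RNG from \code{params@seed}, and advances \code{params@steps}
#' time steps.  Each step evaluates movement for every free agent (velocity,
#' lattice quantization, sequential collision/climb resolution in fresh
#' random order) and then all locking/unlocking decisions on the post-move
#' configuration.  The largest tower's statistics are recorded at t = 0,
#' every \code{sampleInterval} steps, and at the final step.  Bit-identical
#' under a repeated seed.
#'
#' @param params a [SimParams-class].
#' @param recordMaps if TRUE, keep the full height map at every sample (for
#'   tower tracking and diffusion estimation).
#' @return a [SimRun-class].
#' @examples
#' run <- runSimulation(simParams(L = 20, N = 40, Pu = 0.2, knl = 1/26,
#'                                c = 2, steps = 2000, seed = 7))
#' tail(simSeries(run), 3)
#' @export
runSimulation <- function(params, recordMaps = FALSE) {
  validObject(params)
  set.seed(params@seed)
  res <- .cpp_run(params@L, params@N, params@Pu, params@knl, params@Psl,
                  params@c, as.integer(params@steps),
                  params@sampleInterval, recordMaps)
  maps <- list()
  if (recordMaps) {
    arr <- res$maps
    maps <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  }
  new("SimRun", params = params, world = .listToWorld(res$world),
      series = as.data.frame(res$series), maps = maps,
      sampleTimes = res$sample_t)
}

#' Advance a world state
#'
#' Applies \code{n} full time steps (movement then state updates) to an
#' arbitrary world, drawing from the current R RNG stream (call
#' \code{set.seed()} beforehand for reproducibility).
#'
#' @param world a [WorldState-class].
#' @param params a [SimParams-class] supplying the behavioral rates (its
#'   \code{N}, \code{steps} and \code{seed} slots are ignored here).
#' @param n number of steps.
#' @param audit if TRUE, re-verify every structural invariant from scratch
#'   after each step and abort on the first violation.
#' @return the advanced [WorldState-class].
#' @export
stepWorld <- function(world, params, n = 1, audit = FALSE) {
  stopifnot(is(world, "WorldState"), is(params, "SimParams"))
  if (nrow(world@height) != params@L)
    stop("world arena size does not match params L")
  out <- .cpp_advance(.worldToList(world), params@Pu, params@knl,
                      params@Psl, params@c, as.integer(n), audit)
  .listToWorld(out)
}

#' Re-check all world-state invariants from scratch
#'
#' Conservation, one-agent-per-voxel occupancy, stack contiguity, surface
#' placement of free agents, and coverage tags are all recomputed from the
#' raw agent table (independently of any incremental bookkeeping).
#'
#' @param world a [WorldState-class].
#' @return character vector of violations; empty when the world is valid.
#' @export
auditWorld <- function(world) {
  stopifnot(is(world, "WorldState"))
  as.character(.cpp_audit(.worldToList(world)))
}

#' @rdname anttower-generics
#' @export
setMethod("simSeries", "SimRun", function(object) object@series)

#' @rdname anttower-generics
#' @export
setMethod("finalWorld", "SimRun", function(object) object@world)

#' @rdname anttower-generics
#' @export
setMethod("heightMaps", "SimRun", function(object) object@maps)

#' @rdname anttower-generics
#' @export
setMethod("runParams", "SimRun", function(object) object@params)

#' @rdname heightMap
#' @export
setMethod("heightMap", "SimRun", function(object) object@world@height)

setMethod("show", "SimRun", function(object) {
  p <- object@params
  fin <- object@series[nrow(object@series), ]
  cat(sprintf("SimRun: %g steps of N=%d on %dx%d (seed %d)\n",
              p@steps, p@N, p@L, p@L, p@seed))
  cat(sprintf("  final largest tower: %g agents, height %g, aspect %.3f (%g towers)\n",
              fin$n_agents, fin$height, fin$aspect_ratio, fin$n_towers))
  if (length(object@maps))
    cat(sprintf("  %d height-map snapshots recorded\n", length(object@maps)))
})
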