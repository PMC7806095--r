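#' Simulation parameter set
#'
#' All model constants of one simulation.  The voxel edge is the unit of
#' length (one agent body) and one update of every agent is the unit of time.
#'
#' @slot L integer, arena side length in voxels (>= 3); the arena is
#'   L x L x infinity with periodic horizontal boundaries.
#' @slot N integer, number of agents (1 <= N <= L^2; each agent needs a
#'   distinct starting pixel).
#' @slot Pu numeric in [0, 1], per-step probability that an uncovered locked
#'   agent unlocks.
#' @slot knl numeric >= 0, increase in locking probability per locked
#'   neighbor (1/knl is the neighbor count that guarantees locking).
#' @slot Psl numeric in [0, 1], per-step probability of spontaneous locking;
#'   default 1/20000, the rate used to seed towers.
#' @slot c numeric >= 0, ratio of the magnitude of attraction to the
#'   magnitude of the unit random step.
#' @slot steps integer >= 0, number of time steps to simulate.
#' @slot seed integer RNG seed.
#' @slot sampleInterval integer >= 1, recording stride in steps.
#'
#' @seealso [simParams()], [runSimulation()]
#' @export
setClass("SimParams",
  representation(L = "integer", N = "integer", Pu = "numeric",
                 knl = "numeric", Psl = "numeric", c = "numeric",
                 steps = "numeric", seed = "integer",
                 sampleInterval = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (length(object@L) != 1L || is.na(object@L) || object@L < 3L)
    msg <- c(msg, "L must be a single integer >= 3")
  if (length(object@N) != 1L || is.na(object@N) || object@N < 0L)
    msg <- c(msg, "N must be a single non-negative integer")
  if (!anyNA(c(object@N, object@L)) && object@N > object@L^2)
    msg <- c(msg, "N must not exceed L^2 (one starting pixel per agent)")
  if (object@Pu < 0 || object@Pu > 1) msg <- c(msg, "Pu must lie in [0, 1]")
  if (object@Psl < 0 || object@Psl > 1) msg <- c(msg, "Psl must lie in [0, 1]")
  if (object@knl < 0) msg <- c(msg, "knl must be >= 0")
  if (object@c < 0) msg <- c(msg, "c must be >= 0")
  if (is.na(object@steps) || object@steps < 0) msg <- c(msg, "steps must be >= 0")
  if (length(object@sampleInterval) != 1L || object@sampleInterval < 1L)
    msg <- c(msg, "sampleInterval must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Lattice occupancy state of one simulation instant
#'
#' The locked/covered agents at a pixel form a contiguous column occupying
#' voxels z = 0..height-1; a free agent occupies the surface voxel
#' z = height of its pixel, at most one per pixel.  Coordinates are 0-based
#' and horizontal coordinates live in [0, L).
#'
#' @slot height integer L x L matrix; \code{height[x+1, y+1]} is the number
#'   of locked/covered agents stacked at pixel (x, y).
#' @slot agents data.frame with one row per agent: \code{state} (one of
#'   "free", "locked", "covered"), \code{x}, \code{y}, \code{z} (0-based
#'   integer voxel coordinates).
#' @slot t numeric, current time step.
#'
#' @seealso [worldState()], [emptyWorld()], [stepWorld()], [heightMap()]
#' @export
setClass("WorldState",
  representation(height = "matrix", agents = "data.frame", t = "numeric"))

setValidity("WorldState", function(object) {
  msg <- .validateWorldR(object)
  if (length(msg)) msg else TRUE
})

#' Record of one simulation run
#'
#' @slot params the [SimParams-class] that produced the run.
#' @slot world final [WorldState-class].
#' @slot series data.frame sampled every \code{sampleInterval} steps with the
#'   largest tower's statistics: \code{t}, \code{n_agents}, \code{height},
#'   \code{base_area}, \code{eq_diameter}, \code{aspect_ratio},
#'   \code{n_towers}, \code{n_locked} (zeros where no tower exists yet).
#' @slot maps list of height-map matrices at the sample times (empty unless
#'   the run recorded them).
#' @slot sampleTimes numeric vector of sample times.
#'
#' @seealso [runSimulation()], [simSeries()], [finalWorld()]
#' @export
setClass("SimRun",
  representation(params = "SimParams", world = "WorldState",
                 series = "data.frame", maps = "list",
                 sampleTimes = "numeric"))
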