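#' Construct a simulation parameter set
#'
#' Defaults are the reference study conditions: 1000 agents in a 100 x 100
#' arena (density 0.1), spontaneous locking probability 1/20000, 500000 time
#' steps, samples every 250 steps.
#'
#' @param L arena side length in voxels (>= 3).
#' @param N number of agents (N <= L^2).
#' @param Pu per-step unlock probability of an uncovered locked agent.
#' @param knl locking-probability increase per locked Moore neighbor.
#' @param Psl per-step spontaneous locking probability.
#' @param c attraction-to-randomness ratio.
#' @param steps number of time steps.
#' @param seed RNG seed (integer).
#' @param sampleInterval recording stride in steps.
#' @return a [SimParams-class] object.
#' @examples
#' p <- simParams(L = 20, N = 40, Pu = 0.2, knl = 1/26, c = 2, steps = 1000)
#' agentDensity(p)
#' @export
simParams <- function(L = 100, N = 1000, Pu = 0, knl = 1, Psl = 1/20000,
                      c = 0, steps = 500000, seed = 1L,
                      sampleInterval = 250) {
  new("SimParams", L = as.integer(L), N = as.integer(N), Pu = as.numeric(Pu),
      knl = as.numeric(knl), Psl = as.numeric(Psl), c = as.numeric(c),
      steps = as.numeric(steps), seed = as.integer(seed),
      sampleInterval = as.integer(sampleInterval))
}

#' @describeIn simParams density rho = N / L^2 (derived, never stored).
#' @param object a \code{SimParams} object.
#' @export
setMethod("agentDensity", "SimParams", function(object) {
  object@N / object@L^2
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: L=%d N=%d (rho=%.4g) Pu=%g knl=%g Psl=%g c=%g\n",
              object@L, object@N, agentDensity(object), object@Pu,
              object@knl, object@Psl, object@c))
  cat(sprintf("  steps=%g seed=%d sampleInterval=%d\n",
              object@steps, object@seed, object@sampleInterval))
})

#' @describeIn simParams coerce to a flat named list (config schema order).
#' @param x a \code{SimParams} object.
#' @param ... ignored.
#' @export
setMethod("as.list", "SimParams", function(x, ...) {
  list(L = x@L, N = x@N, Pu = x@Pu, knl = x@knl, Psl = x@Psl, c = x@c,
       steps = x@steps, seed = x@seed, sampleInterval = x@sampleInterval)
})
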