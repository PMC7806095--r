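#' @name anttower-generics
#' @title Accessor generics
#' @param object an anttower object
#' @keywords internal
NULL

#' Extract the 2-D height map (locked-stack heights per pixel)
#'
#' Free agents contribute nothing to the height map.
#'
#' @param object a [WorldState-class] or [SimRun-class]
#' @return integer L x L matrix
#' @export
setGeneric("heightMap", function(object) standardGeneric("heightMap"))

#' @rdname anttower-generics
#' @export
setGeneric("agents", function(object) standardGeneric("agents"))

#' @rdname anttower-generics
#' @export
setGeneric("simSeries", function(object) standardGeneric("simSeries"))

#' @rdname anttower-generics
#' @export
setGeneric("finalWorld", function(object) standardGeneric("finalWorld"))

#' @rdname anttower-generics
#' @export
setGeneric("heightMaps", function(object) standardGeneric("heightMaps"))

#' @rdname anttower-generics
#' @export
setGeneric("runParams", function(object) standardGeneric("runParams"))

#' Agent density rho = N / L^2
#'
#' @param object a [SimParams-class]
#' @return numeric scalar
#' @export
setGeneric("agentDensity", function(object) standardGeneric("agentDensity"))
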