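#' Accessors for soctouch containers
#'
#' Small generic accessors so downstream code never reaches into slots.
#'
#' @param x a soctouch object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("episodes", function(x, ...) standardGeneric("episodes"))

#' @rdname accessors
#' @export
setMethod("episodes", "Session", function(x, ...) x@episodes)

#' @rdname accessors
#' @export
setGeneric("blocks", function(x, ...) standardGeneric("blocks"))

#' @rdname accessors
#' @export
setMethod("blocks", "Session", function(x, ...) x@blocks)

#' @rdname accessors
#' @export
setGeneric("sessionEnd", function(x, ...) standardGeneric("sessionEnd"))

#' @rdname accessors
#' @export
setMethod("sessionEnd", "Session", function(x, ...) {
  if (nrow(x@blocks)) max(x@blocks$end) else 0
})

#' @rdname accessors
#' @export
setGeneric("unitIds", function(x, ...) standardGeneric("unitIds"))

#' @rdname accessors
#' @export
setMethod("unitIds", "Session", function(x, ...) names(x@units))

#' Spike times of one unit
#'
#' @param x a [Session-class].
#' @param unit unit id (name in the unit list).
#' @return numeric vector of sorted spike times (s).
#' @export
spikeTimes <- function(x, unit) {
  stopifnot(is(x, "Session"))
  if (!unit %in% names(x@units)) stop(sprintf("unknown unit '%s'", unit))
  x@units[[unit]]
}

#' @rdname accessors
#' @export
setGeneric("binCounts", function(x, ...) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setMethod("binCounts", "BinnedSpikeTrain", function(x, ...) x@counts)

#' @rdname accessors
#' @export
setGeneric("keptMask", function(x, ...) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setMethod("keptMask", "BinnedSpikeTrain", function(x, ...) x@keptMask)

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x, ...) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setMethod("binWidth", "BinnedSpikeTrain", function(x, ...) x@binWidth)

#' @rdname accessors
#' @export
setMethod("binWidth", "PredictorMatrix", function(x, ...) x@binWidth)

#' @importFrom stats coef
#' @export
#' @rdname accessors
setMethod("coef", "GLMFit", function(object, ...) object@beta)

#' @importFrom stats logLik
#' @export
#' @rdname accessors
setMethod("logLik", "GLMFit", function(object, ...) object@logLik)

#' @rdname accessors
#' @export
setGeneric("converged", function(x, ...) standardGeneric("converged"))

#' @rdname accessors
#' @export
setMethod("converged", "GLMFit", function(x, ...) x@converged)

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x, ...) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setMethod("designMatrix", "PredictorMatrix", function(x, ...) x@X)

#' @rdname accessors
#' @export
setGeneric("response", function(x, ...) standardGeneric("response"))

#' @rdname accessors
#' @export
setMethod("response", "PredictorMatrix", function(x, ...) x@y)

#' Scaled population sizes of a network configuration
#'
#' Applies the configuration's scale factor to the full-scale population
#' sizes, rounding to integers.
#'
#' @param x a [NetworkConfig-class].
#' @return named integer vector of 9 population sizes.
#' @export
scaledCounts <- function(x) {
  stopifnot(is(x, "NetworkConfig"))
  n <- pmax(1L, as.integer(round(x@N * x@scale)))
  names(n) <- names(x@N)
  n
}
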