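#' @include AllClasses.R
NULL

#' Accessors for sinusflow objects
#'
#' Small generic accessors used across the package: grid geometry, mask
#' arrays, fluid volume, velocity arrays and measure values.
#'
#' @param x an object.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridOf", function(x, ...) standardGeneric("gridOf"))

#' @rdname accessors
#' @export
setGeneric("maskOf", function(x, ...) standardGeneric("maskOf"))

#' @rdname accessors
#' @export
setGeneric("gridDims", function(x, ...) standardGeneric("gridDims"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x, ...) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("volumeM3", function(x, ...) standardGeneric("volumeM3"))

#' @rdname accessors
#' @export
setGeneric("volumeMl", function(x, ...) standardGeneric("volumeMl"))

#' @rdname accessors
#' @export
setGeneric("insideArray", function(x, ...) standardGeneric("insideArray"))

#' @rdname accessors
#' @export
setGeneric("velocityArray", function(x, ...) standardGeneric("velocityArray"))

#' @rdname accessors
#' @export
setGeneric("pressureArray", function(x, ...) standardGeneric("pressureArray"))

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x, ...) standardGeneric("densityValues"))

#' @rdname accessors
#' @export
setGeneric("snapshotTimes", function(x, ...) standardGeneric("snapshotTimes"))

#' @rdname accessors
#' @export
setGeneric("scalarSeries", function(x, ...) standardGeneric("scalarSeries"))

#' @rdname accessors
#' @export
setGeneric("measureTable", function(x, ...) standardGeneric("measureTable"))

#' Flow rate of a breathing waveform at arbitrary times
#'
#' Evaluates \eqn{\dot V(t) = A \sin(2\pi t / T)} (ml/s) analytically.
#'
#' @param x a [BreathingWaveform-class].
#' @param t numeric vector of times in seconds.
#' @return numeric vector of flow rates in ml/s.
#' @export
setGeneric("flowRateAt", function(x, t) standardGeneric("flowRateAt"))

setMethod("gridOf", "GridSpec", function(x, ...) x)
setMethod("gridOf", "DomainMask", function(x, ...) x@grid)
setMethod("gridOf", "VelocitySnapshot", function(x, ...) x@grid)
setMethod("gridOf", "GradientTensorField", function(x, ...) x@grid)
setMethod("gridOf", "ScalarDensityField", function(x, ...) x@grid)
setMethod("gridOf", "FlowSeries", function(x, ...) x@mask@grid)

setMethod("maskOf", "DomainMask", function(x, ...) x)
setMethod("maskOf", "VelocitySnapshot", function(x, ...) x@mask)
setMethod("maskOf", "GradientTensorField", function(x, ...) x@mask)
setMethod("maskOf", "ScalarDensityField", function(x, ...) x@mask)
setMethod("maskOf", "FlowSeries", function(x, ...) x@mask)

setMethod("gridDims", "GridSpec", function(x, ...) x@dims)
setMethod("gridSpacing", "GridSpec", function(x, ...) x@spacing)
for (cl in c("DomainMask", "VelocitySnapshot", "GradientTensorField",
             "ScalarDensityField", "FlowSeries")) {
  setMethod("gridDims", cl, function(x, ...) gridDims(gridOf(x)))
  setMethod("gridSpacing", cl, function(x, ...) gridSpacing(gridOf(x)))
}

setMethod("volumeM3", "DomainMask", function(x, ...) x@volume)
setMethod("volumeMl", "DomainMask", function(x, ...) x@volume * 1e6)
setMethod("volumeM3", "FlowSeries", function(x, ...) x@mask@volume)
setMethod("volumeMl", "FlowSeries", function(x, ...) x@mask@volume * 1e6)
setMethod("insideArray", "DomainMask", function(x, ...) x@inside)
setMethod("insideArray", "VelocitySnapshot", function(x, ...) x@mask@inside)

setMethod("velocityArray", "VelocitySnapshot", function(x, ...) x@u)
setMethod("pressureArray", "VelocitySnapshot", function(x, ...) {
  if (length(x@p)) array(x@p, dim = x@grid@dims) else NULL
})
setMethod("densityValues", "ScalarDensityField", function(x, ...) x@values)
setMethod("snapshotTimes", "FlowSeries", function(x, ...) x@times)
setMethod("scalarSeries", "FlowSeries", function(x, ...) x@scalars)
setMethod("measureTable", "MeasureTable", function(x, ...) x@table)
setMethod("volumeMl", "MeasureTable", function(x, ...) x@volumeMl)

setMethod("flowRateAt", "BreathingWaveform", function(x, t) {
  x@amplitude * sin(2 * pi * t / x@period)
})

#' Snapshot access
#'
#' @param x a [FlowSeries-class].
#' @param k snapshot index (1-based).
#' @return a [VelocitySnapshot-class].
#' @export
snapshotAt <- function(x, k) {
  stopifnot(is(x, "FlowSeries"), k >= 1L, k <= length(x@snapshots))
  x@snapshots[[k]]
}

#' Number of snapshots in a series
#' @param x a [FlowSeries-class].
#' @export
nSnapshots <- function(x) length(x@snapshots)

setMethod("show", "GridSpec", function(object) {
  d <- object@dims
  cat(sprintf("GridSpec: %d x %d x %d voxels, spacing %.4g m%s\n",
              d[1], d[2], d[3], object@spacing,
              if (d[3] == 1L) " (planar, unit depth)" else ""))
})

setMethod("show", "DomainMask", function(object) {
  cat(sprintf("DomainMask: %d inside voxels, |V| = %.4g ml\n",
              sum(object@inside), object@volume * 1e6))
  show(object@grid)
})

setMethod("show", "BreathingWaveform", function(object) {
  cat(sprintf(
    "BreathingWaveform: A = %.4g ml/s, T = %.4g s, %d samples (dt = %.4g s)\n",
    object@amplitude, object@period, length(object@samples), object@dt))
  cat(sprintf("  tidal volume %.4g ml, minute ventilation %.4g L/min\n",
              tidalVolumeMl(object), minuteVentilation(object)))
})

setMethod("show", "VelocitySnapshot", function(object) {
  sp <- sqrt(rowSums(matrix(object@u, ncol = 3L)[c(object@mask@inside), ,
                                                 drop = FALSE]^2))
  cat(sprintf(
    "VelocitySnapshot at t = %.4g s: max speed %.4g m/s%s\n",
    object@time, if (length(sp)) max(sp) else 0,
    if (length(object@p)) ", with pressure" else ""))
  show(object@mask)
})

setMethod("show", "FlowSeries", function(object) {
  cat(sprintf(
    "FlowSeries: %d snapshots over t = [%.4g, %.4g] s (stride %d)\n",
    length(object@snapshots), min(object@times), max(object@times),
    object@snapshotEvery))
  show(object@mask)
})

setMethod("show", "FluxSeries", function(object) {
  cat(sprintf("FluxSeries: %d samples, peak |flux| %.4g ml/s\n",
              length(object@flux), max(abs(object@flux))))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    paste0("PhantomSpec: channel %.3g x %.3g m, cavity %.3g x %.3g m,\n",
           "  ostium %.3g m, constriction %.2g (depth fraction %.2g),",
           " depth %d voxel(s)\n"),
    object@channelLength, object@channelWidth, object@cavityWidth,
    object@cavityHeight, object@ostiumWidth, object@constrictionFraction,
    object@constrictionDepthFraction, object@depthVoxels))
})

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf(
    "SolverConfig: nu = %.3g m2/s, rho = %.3g kg/m3, dt = %.3g s, %d steps\n",
    object@nu, object@rho, object@dt, object@nSteps))
})

setMethod("show", "MeasureTable", function(object) {
  cat(sprintf("MeasureTable (|V| = %.4g ml)\n", object@volumeMl))
  print(format(object@table, digits = 6))
})
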