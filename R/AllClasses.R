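#' @import methods
#' @importFrom stats setNames
NULL

# Central containers for masked voxel-grid flow analysis. All grids are
# uniform Cartesian with isotropic spacing; nz = 1 encodes a planar (2-D)
# field with unit depth, so volumes and fluxes keep 3-D units throughout.

#' Uniform Cartesian voxel grid
#'
#' Describes the geometry every field in the package lives on: integer
#' dimensions, one isotropic voxel edge length (m) and a coordinate origin.
#' `nz = 1` encodes a two-dimensional grid; z-derivatives are then defined
#' as zero and a unit depth (1 m) is assumed for volumes and fluxes.
#'
#' @slot dims integer length-3, voxels per axis (nx, ny, nz), all >= 1.
#' @slot spacing voxel edge length in metres, > 0.
#' @slot origin coordinate of the centre of voxel (1,1,1), metres.
#' @export
setClass("GridSpec", representation(
  dims = "integer", spacing = "numeric", origin = "numeric"
))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three integers >= 1")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite numbers")
  if (length(msg)) msg else TRUE
})

#' Fluid-domain mask on a voxel grid
#'
#' Boolean per-voxel indicator of the fluid lumen. Carries the fluid volume
#' |V| used by every volume-averaged measure (unit depth in 2-D).
#'
#' @slot grid a [GridSpec-class].
#' @slot inside logical array with `dim = dims(grid)`.
#' @slot volume fluid volume in cubic metres.
#' @export
setClass("DomainMask", representation(
  grid = "GridSpec", inside = "array", volume = "numeric"
))

setValidity("DomainMask", function(object) {
  msg <- character()
  g <- object@grid
  if (!is.logical(object@inside) ||
      !identical(dim(object@inside), as.integer(g@dims)))
    msg <- c(msg, "inside must be a logical array matching grid dims")
  n <- sum(object@inside)
  if (n < 1L) msg <- c(msg, "mask must contain at least one inside voxel")
  d <- if (g@dims[3L] == 1L) 2L else 3L
  vol <- n * g@spacing^d
  if (!isTRUE(all.equal(vol, object@volume, tolerance = 1e-10)))
    msg <- c(msg, "volume must equal (inside voxel count) * spacing^d")
  if (length(msg)) msg else TRUE
})

#' Sinusoidal breathing waveform
#'
#' Volumetric flow rate at the larynx inlet, \eqn{\dot V(t) = A \sin(2\pi t/T)}
#' (ml/s), sampled on a uniform time grid over one full cycle. With the flow
#' rate positive into the domain at the larynx, the first half-cycle is
#' expiration and the second inspiration.
#'
#' @slot amplitude peak flow rate A in ml/s.
#' @slot period full-cycle duration T in seconds.
#' @slot dt sample interval in seconds.
#' @slot times sample times t_k = k dt, k = 0..n-1.
#' @slot samples flow rate at each sample time, ml/s.
#' @slot phase factor with levels "expiration"/"inspiration" per sample.
#' @export
setClass("BreathingWaveform", representation(
  amplitude = "numeric", period = "numeric", dt = "numeric",
  times = "numeric", samples = "numeric", phase = "factor"
))

setValidity("BreathingWaveform", function(object) {
  msg <- character()
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be positive")
  if (object@period <= 0) msg <- c(msg, "period must be positive")
  n <- length(object@samples)
  if (length(object@times) != n || length(object@phase) != n)
    msg <- c(msg, "times, samples and phase must have equal length")
  if (abs(n * object@dt - object@period) > 1e-9 * object@period)
    msg <- c(msg, "number of samples times dt must equal the period")
  # half-cycle antisymmetry and zero crossings at 0 and T/2
  if (n >= 4L && n %% 2L == 0L) {
    half <- n %/% 2L
    anti <- max(abs(object@samples[seq_len(half)] +
                    object@samples[half + seq_len(half)]))
    if (anti > 1e-9 * object@amplitude)
      msg <- c(msg, "samples must satisfy Vdot(t + T/2) = -Vdot(t)")
    if (abs(object@samples[1L]) > 1e-9 * object@amplitude ||
        abs(object@samples[half + 1L]) > 1e-9 * object@amplitude)
      msg <- c(msg, "Vdot must vanish at t = 0 and t = T/2")
  }
  if (length(msg)) msg else TRUE
})

#' One velocity (and optionally pressure) snapshot on a masked grid
#'
#' @slot grid a [GridSpec-class].
#' @slot mask a [DomainMask-class] on the same grid.
#' @slot u numeric array `c(dims, 3)`, voxel-centre velocity in m/s; values
#'   outside the mask are zero and carry no meaning.
#' @slot p numeric vector of per-voxel pressure (Pa, column-major over the
#'   grid) or a zero-length numeric when no pressure is attached.
#' @slot time time stamp in seconds.
#' @export
setClass("VelocitySnapshot", representation(
  grid = "GridSpec", mask = "DomainMask", u = "array", p = "numeric",
  time = "numeric"
))

setValidity("VelocitySnapshot", function(object) {
  msg <- character()
  d <- as.integer(object@grid@dims)
  if (!identical(dim(object@u), c(d, 3L)))
    msg <- c(msg, "u must have dim c(dims, 3)")
  ins <- rep(object@mask@inside, times = 3L)
  if (any(!is.finite(object@u[ins])))
    msg <- c(msg, "velocity must be finite on inside voxels")
  if (length(object@p) && length(object@p) != prod(d))
    msg <- c(msg, "p, when present, must have one value per voxel")
  if (length(msg)) msg else TRUE
})

#' Velocity-gradient tensor field
#'
#' Per-voxel 3x3 tensor \eqn{G_{ij} = \partial u_i / \partial x_j} (1/s) with
#' a per-voxel stencil quality flag: 2 = central everywhere, 1 = at least one
#' one-sided difference, 0 = degenerate (no neighbour along some active axis;
#' tensor zeroed).
#'
#' @slot grid a [GridSpec-class].
#' @slot mask a [DomainMask-class].
#' @slot g numeric array `c(dims, 3, 3)`.
#' @slot quality integer array `dims` with values 0/1/2.
#' @export
setClass("GradientTensorField", representation(
  grid = "GridSpec", mask = "DomainMask", g = "array", quality = "array"
))

#' Scalar density field for one vorticity measure
#'
#' @slot grid a [GridSpec-class].
#' @slot mask a [DomainMask-class].
#' @slot values numeric array `dims`; meaningful on inside voxels only.
#' @slot measure one of "helicity", "abs_helicity", "enstrophy",
#'   "q_criterion", "lambda2", "vort_mag", "divergence".
#' @export
setClass("ScalarDensityField", representation(
  grid = "GridSpec", mask = "DomainMask", values = "array",
  measure = "character"
))

.densityNonNegative <- c("abs_helicity", "enstrophy", "vort_mag")

setValidity("ScalarDensityField", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@dims)))
    msg <- c(msg, "values must match grid dims")
  v <- object@values[object@mask@inside]
  if (any(!is.finite(v))) msg <- c(msg, "density must be finite inside mask")
  if (object@measure %in% .densityNonNegative && any(v < -1e-12))
    msg <- c(msg, sprintf("%s density must be non-negative", object@measure))
  if (length(msg)) msg else TRUE
})

#' Ordered flow snapshots over a breathing cycle
#'
#' Holds voxel-centre snapshots at a recorded stride together with scalar
#' per-step time series: inlet flow rate (ml/s), inlet-minus-outlet pressure
#' drop (Pa), advective CFL number and max interior |divergence| (1/s).
#'
#' @slot snapshots list of [VelocitySnapshot-class].
#' @slot times snapshot time stamps, seconds.
#' @slot mask the common [DomainMask-class].
#' @slot scalars data.frame with columns t, flow_ml_s, dp_pa, cfl, max_div
#'   (NA columns allowed when a series was not produced by the solver).
#' @slot snapshotEvery integer stride between stored snapshots (1 when every
#'   sample is stored, as for analytic modulated series).
#' @export
setClass("FlowSeries", representation(
  snapshots = "list", times = "numeric", mask = "DomainMask",
  scalars = "data.frame", snapshotEvery = "integer"
))

setValidity("FlowSeries", function(object) {
  msg <- character()
  if (length(object@snapshots) != length(object@times))
    msg <- c(msg, "snapshots and times must align")
  if (length(object@snapshots) < 1L)
    msg <- c(msg, "series must contain at least one snapshot")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "snapshot times must be strictly increasing")
  need <- c("t", "flow_ml_s", "dp_pa", "cfl", "max_div")
  if (!all(need %in% names(object@scalars)))
    msg <- c(msg, "scalars must have columns t, flow_ml_s, dp_pa, cfl, max_div")
  if (length(msg)) msg else TRUE
})

#' Signed flux through a probe plane over time
#'
#' @slot times seconds.
#' @slot flux signed volumetric flow rate through the probe, ml/s.
#' @slot probe the probe specification used (list).
#' @export
setClass("FluxSeries", representation(
  times = "numeric", flux = "numeric", probe = "list"
))

setValidity("FluxSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@flux))
    msg <- c(msg, "times and flux must align")
  if (any(!is.finite(object@flux))) msg <- c(msg, "flux must be finite")
  if (length(msg)) msg else TRUE
})

#' Geometry of the two-dimensional airway phantom
#'
#' A straight nasal-passage-like channel, a separating wall pierced by a
#' narrow ostium gap, and a sinus-like cavity that communicates with the
#' channel only through that gap. An optional mid-channel bump occludes a
#' fraction of the channel width (a septal-deviation analog).
#'
#' @slot channelLength,channelWidth metres.
#' @slot cavityWidth,cavityHeight metres.
#' @slot ostiumWidth metres; must span at least 2 voxels at rasterisation.
#' @slot constrictionFraction fraction of channel width occluded, in [0, 1).
#' @slot depthVoxels integer; 1 = planar phantom (unit depth), > 1 = thin
#'   extrusion in z with no-slip top/bottom walls.
#' @slot constrictionDepthFraction fraction of the depth the bump spans
#'   (1 = full depth; < 1 breaks the planar symmetry, only meaningful for
#'   extruded phantoms).
#' @export
setClass("PhantomSpec", representation(
  channelLength = "numeric", channelWidth = "numeric",
  cavityWidth = "numeric", cavityHeight = "numeric",
  ostiumWidth = "numeric", constrictionFraction = "numeric",
  depthVoxels = "integer", constrictionDepthFraction = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  pos <- c(object@channelLength, object@channelWidth, object@cavityWidth,
           object@cavityHeight, object@ostiumWidth)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "all phantom lengths must be positive")
  if (object@constrictionFraction < 0 || object@constrictionFraction >= 1)
    msg <- c(msg, "constrictionFraction must be in [0, 1)")
  if (object@depthVoxels < 1L)
    msg <- c(msg, "depthVoxels must be >= 1")
  if (object@constrictionDepthFraction <= 0 ||
      object@constrictionDepthFraction > 1)
    msg <- c(msg, "constrictionDepthFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Configuration of the laminar projection solver
#'
#' @slot nu kinematic viscosity, m^2/s.
#' @slot rho fluid density, kg/m^3.
#' @slot dt time step, s.
#' @slot nSteps number of time steps.
#' @slot snapshotEvery store a voxel-centre snapshot every this many steps.
#' @slot pressureTolerance relative residual bound for the pressure solve.
#' @slot inletProfile "uniform" (plug, the physiological boundary contract)
#'   or "parabolic" (for developed-flow verification runs).
#' @export
setClass("SolverConfig", representation(
  nu = "numeric", rho = "numeric", dt = "numeric", nSteps = "integer",
  snapshotEvery = "integer", pressureTolerance = "numeric",
  inletProfile = "character"
))

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (object@nu <= 0) msg <- c(msg, "nu must be positive")
  if (object@rho <= 0) msg <- c(msg, "rho must be positive")
  if (object@dt <= 0) msg <- c(msg, "dt must be positive")
  if (object@nSteps < 1L) msg <- c(msg, "nSteps must be >= 1")
  if (object@snapshotEvery < 1L) msg <- c(msg, "snapshotEvery must be >= 1")
  if (!object@inletProfile %in% c("uniform", "parabolic"))
    msg <- c(msg, "inletProfile must be 'uniform' or 'parabolic'")
  if (length(msg)) msg else TRUE
})

.measureNames <- c("NR", "abs_helicity", "enstrophy", "helicity",
                   "lambda2", "q", "vort_mag")

#' Phase-aggregated table of vorticity measures
#'
#' One row per measure (NR, |H|, E, H, lambda2, Q, ||Omega||), one column per
#' phase window: `e` (expiration), `i` (inspiration) and `ei` (full cycle).
#' All vorticity measures are in SI units (m/s^2 for helicity, 1/s^2 for
#' enstrophy/Q/lambda2, 1/s for vorticity magnitude); NR is Pa s/ml.
#'
#' @slot volumeMl fluid volume |V| in millilitres.
#' @slot table data.frame with rownames the measure names and columns e, i, ei.
#' @export
setClass("MeasureTable", representation(
  volumeMl = "numeric", table = "data.frame"
))

setValidity("MeasureTable", function(object) {
  msg <- character()
  tb <- object@table
  if (!all(.measureNames %in% rownames(tb)) ||
      !all(c("e", "i", "ei") %in% names(tb)))
    msg <- c(msg, "table must have the seven measure rows and columns e, i, ei")
  if (object@volumeMl <= 0) msg <- c(msg, "volumeMl must be positive")
  tol <- 1e-8
  ok <- function(x) all(is.na(x) | x >= -tol * (1 + abs(x)))
  if (length(msg) == 0L) {
    for (ph in c("e", "i", "ei")) {
      if (!ok(tb[c("abs_helicity", "enstrophy", "vort_mag"), ph]))
        msg <- c(msg, "non-negative measures must be non-negative")
      ah <- tb["abs_helicity", ph]; hh <- tb["helicity", ph]
      if (!is.na(ah) && !is.na(hh) && ah < abs(hh) - tol * (1 + abs(hh)))
        msg <- c(msg, "absolute helicity must dominate |helicity|")
    }
  }
  if (length(msg)) msg else TRUE
})
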