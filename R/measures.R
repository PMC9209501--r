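#' @include AllClasses.R field-calculus.R
NULL

#' Volume average of a density over the fluid mask
#'
#' The single-bar measure: \eqn{\frac{1}{|V|}\int_V f\, dV}, evaluated as
#' (sum over inside voxels of density times voxel volume) / |V|. Boundary
#' voxels are retained, keeping |V| consistent with whole-lumen volumes.
#'
#' @param density a [ScalarDensityField-class], or a plain numeric array
#'   matching the mask dims.
#' @param mask a [DomainMask-class]; defaults to the density's own mask.
#' @return a scalar.
#' @export
volumeAverage <- function(density, mask = NULL) {
  if (is(density, "ScalarDensityField")) {
    if (is.null(mask)) mask <- density@mask
    vals <- density@values
  } else {
    if (is.null(mask)) stop("a mask is required for plain array input")
    vals <- density
  }
  ins <- mask@inside
  if (!identical(dim(vals), dim(ins)))
    stop("density and mask dimensions disagree")
  n <- sum(ins)
  if (n < 1L) stop("mask has no inside voxels")
  d <- if (mask@grid@dims[3L] == 1L) 2L else 3L
  voxVol <- mask@grid@spacing^d
  sum(vals[ins]) * voxVol / mask@volume
}

#' Time average of a scalar series over a phase window
#'
#' The double-bar measure: the arithmetic mean of the samples whose time
#' falls in `[start, end)` — the rectangle rule at the fixed sampling step.
#'
#' @param values numeric series.
#' @param times sample times, seconds (uniformly spaced).
#' @param window `c(start, end)` in seconds, e.g. from [phaseWindows()].
#' @return a scalar.
#' @export
timeAverage <- function(values, times, window) {
  stopifnot(length(values) == length(times), length(window) == 2L,
            window[1] < window[2])
  keep <- times >= window[1] & times < window[2] - 1e-12
  if (!any(keep)) stop("no samples fall inside the requested window")
  mean(values[keep])
}

#' Nasal resistance over a phase window
#'
#' \eqn{NR = \int_w |\Delta p|\,dt \;/\; \int_w |\dot V|\,dt} (Pa s/ml):
#' the phase-integrated pressure drop per unit of phase-integrated flow.
#' Phase-symmetric, robust to the zero-flow endpoints of the sinusoidal
#' waveform, and exactly R for proportional signals
#' \eqn{\Delta p = R \dot V}.
#'
#' @param dp pressure-drop series, Pa.
#' @param flow flow-rate series, ml/s (aligned with `dp`).
#' @param times sample times, seconds.
#' @param window `c(start, end)` in seconds.
#' @return resistance in Pa s/ml (positive for either phase).
#' @export
nasalResistance <- function(dp, flow, times, window) {
  stopifnot(length(dp) == length(flow), length(flow) == length(times))
  keep <- times >= window[1] & times < window[2] - 1e-12
  if (!any(keep)) stop("no samples fall inside the requested window")
  qint <- sum(abs(flow[keep]))
  if (qint <= 0)
    stop("integrated flow over the window is zero; resistance is undefined")
  sum(abs(dp[keep])) / qint
}

#' Signed flux through a probe plane
#'
#' Sums the probe-normal velocity times face area over the voxels of a
#' grid-aligned probe plane, for every snapshot of a series. Face area is
#' spacing^2 (or spacing x 1 m on planar grids).
#'
#' @param series a [FlowSeries-class].
#' @param probe a list with `axis` (1, 2 or 3: the plane normal), `index`
#'   (the voxel layer the plane passes through) and optional `span`, a named
#'   list of index ranges restricting the in-plane extent (names among
#'   "i", "j", "k").
#' @return a [FluxSeries-class] in ml/s.
#' @export
ostiumFlux <- function(series, probe) {
  stopifnot(is(series, "FlowSeries"), is.list(probe))
  ax <- as.integer(probe$axis)
  stopifnot(ax %in% 1:3)
  grid <- series@mask@grid
  d <- as.integer(grid@dims)
  idx <- as.integer(probe$index)
  if (idx < 1L || idx > d[ax]) stop("probe index is outside the grid")
  sel <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  sel[[ax]] <- idx
  span <- probe$span
  if (!is.null(span)) {
    axName <- c("i", "j", "k")
    for (a in 1:3) {
      if (a != ax && !is.null(span[[axName[a]]]))
        sel[[a]] <- intersect(sel[[a]], as.integer(span[[axName[a]]]))
    }
  }
  ins <- series@mask@inside[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  if (!any(ins)) stop("probe plane does not intersect the fluid mask")
  faceArea <- if (d[3L] == 1L) grid@spacing else grid@spacing^2
  flux <- vapply(series@snapshots, function(s) {
    un <- array(s@u[, , , ax], dim = d)[sel[[1]], sel[[2]], sel[[3]],
                                        drop = FALSE]
    sum(un[ins]) * faceArea
  }, numeric(1)) * 1e6  # m^3/s -> ml/s
  new("FluxSeries", times = series@times, flux = flux, probe = probe)
}

#' Count flow reversals in a flux series
#'
#' Number of sign changes between consecutive samples inside the window,
#' after discarding samples with |flux| at or below the deadband.
#'
#' @param flux a [FluxSeries-class] or numeric vector.
#' @param window optional `c(start, end)` window in seconds (requires a
#'   [FluxSeries-class]); default: all samples.
#' @param deadband ignore samples with |flux| <= deadband (ml/s). The
#'   default is 1 percent of the peak |flux|.
#' @return integer count of reversals.
#' @export
countFlowReversals <- function(flux, window = NULL, deadband = NULL) {
  if (is(flux, "FluxSeries")) {
    vals <- flux@flux
    times <- flux@times
  } else {
    vals <- as.numeric(flux)
    times <- seq_along(vals) - 1
  }
  if (!is.null(window)) {
    keep <- times >= window[1] & times < window[2] - 1e-12
    vals <- vals[keep]
  }
  if (is.null(deadband)) deadband <- 0.01 * max(abs(vals), 0)
  if (deadband < 0) stop("deadband must be non-negative")
  s <- sign(vals[abs(vals) > deadband])
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Phase-aggregated vorticity measures of a flow series
#'
#' For every stored snapshot, all six densities are volume-averaged over the
#' fluid mask; each resulting time series is then time-averaged over the
#' expiration window, the inspiration window and the full cycle, giving the
#' double-bar measures. Nasal resistance per phase is computed from the
#' series' pressure-drop and flow-rate scalars when present (NA otherwise),
#' and the fluid volume is reported in ml.
#'
#' @param series a [FlowSeries-class] covering one full breathing cycle.
#' @param mask a [DomainMask-class]; defaults to the series' mask and must
#'   match it.
#' @param waveform the [BreathingWaveform-class] that drove the series
#'   (defines the phase windows).
#' @return a [MeasureTable-class].
#' @export
computeMeasureTable <- function(series, mask = NULL, waveform) {
  stopifnot(is(series, "FlowSeries"), is(waveform, "BreathingWaveform"))
  if (is.null(mask)) mask <- series@mask
  if (!identical(dim(mask@inside), dim(series@mask@inside)) ||
      !identical(mask@inside, series@mask@inside))
    stop("mask does not match the series' fluid mask")
  wins <- phaseWindows(waveform)
  measNames <- c("abs_helicity", "enstrophy", "helicity", "lambda2", "q",
                 "vort_mag")
  perSnap <- vapply(series@snapshots, function(s) {
    dens <- allDensities(s)
    vapply(measNames, function(m) volumeAverage(dens[[m]], mask), numeric(1))
  }, numeric(length(measNames)))
  if (is.null(dim(perSnap)))
    perSnap <- matrix(perSnap, nrow = length(measNames))
  tb <- data.frame(e = numeric(7), i = numeric(7), ei = numeric(7),
                   row.names = c("NR", measNames))
  for (ph in c("e", "i", "ei")) {
    for (m in measNames)
      tb[m, ph] <- timeAverage(perSnap[match(m, measNames), ],
                               series@times, wins[[ph]])
    sc <- series@scalars
    tb["NR", ph] <- if (all(is.na(sc$dp_pa))) NA_real_ else
      nasalResistance(sc$dp_pa, sc$flow_ml_s, sc$t, wins[[ph]])
  }
  new("MeasureTable", volumeMl = mask@volume * 1e6, table = tb)
}
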