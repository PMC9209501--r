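#' @include AllClasses.R utils.R
NULL

#' Sinusoidal breathing waveform
#'
#' Builds the volumetric flow-rate waveform at the larynx inlet,
#' \eqn{\dot V(t) = A \sin(2\pi t/T)} in ml/s, sampled at
#' \eqn{t_k = k\,T/n}, \eqn{k = 0, \dots, n-1}. With flow positive into the
#' domain at the larynx, the first half-cycle (air pushed up from the lungs
#' and out through the nostrils) is expiration, the second inspiration.
#'
#' The defaults are the adult resting-breathing conditions used throughout
#' the package: A = 267 ml/s and T = 4 s, which give a tidal volume of
#' \eqn{A T/\pi \approx 340} ml and minute ventilation of about 5.1 L/min at
#' 15 breaths per minute.
#'
#' @param amplitude peak flow rate A, ml/s (> 0).
#' @param period full breathing-cycle duration T, seconds (> 0).
#' @param nSteps number of samples over the cycle (>= 4; even values keep
#'   the expiration/inspiration windows exactly equal).
#' @return a [BreathingWaveform-class].
#' @examples
#' wf <- breathingWaveform()
#' flowRateAt(wf, 1)      # peak: 267 ml/s
#' tidalVolumeMl(wf)      # ~ 340 ml
#' minuteVentilation(wf)  # ~ 5.1 L/min
#' @export
breathingWaveform <- function(amplitude = 267, period = 4, nSteps = 4000L) {
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("amplitude must be a positive flow rate in ml/s")
  if (!is.finite(period) || period <= 0)
    stop("period must be a positive duration in seconds")
  nSteps <- as.integer(nSteps)
  if (nSteps < 4L) stop("nSteps must be at least 4")
  dt <- period / nSteps
  t <- (seq_len(nSteps) - 1L) * dt
  s <- amplitude * sin(2 * pi * t / period)
  half <- t < period / 2
  ph <- factor(ifelse(half, "expiration", "inspiration"),
               levels = c("expiration", "inspiration"))
  new("BreathingWaveform", amplitude = amplitude, period = period, dt = dt,
      times = t, samples = s, phase = ph)
}

#' Tidal volume of a breathing waveform
#'
#' Volume moved in one half-cycle, by rectangle-rule quadrature of the
#' sampled expiration flow rate (analytically \eqn{A T / \pi} ml).
#'
#' @param waveform a [BreathingWaveform-class].
#' @return tidal volume in ml.
#' @export
tidalVolumeMl <- function(waveform) {
  stopifnot(is(waveform, "BreathingWaveform"))
  e <- waveform@phase == "expiration"
  sum(waveform@samples[e]) * waveform@dt
}

#' Minute ventilation of a breathing waveform
#'
#' Tidal volume times breaths per minute (60/T), in litres per minute.
#'
#' @param waveform a [BreathingWaveform-class].
#' @return minute ventilation in L/min.
#' @export
minuteVentilation <- function(waveform) {
  tidalVolumeMl(waveform) * (60 / waveform@period) / 1000
}

#' Phase windows of a breathing cycle
#'
#' @param waveform a [BreathingWaveform-class].
#' @return named list of `c(start, end)` windows in seconds: `e` = [0, T/2),
#'   `i` = [T/2, T), `ei` = [0, T).
#' @export
phaseWindows <- function(waveform) {
  stopifnot(is(waveform, "BreathingWaveform"))
  T <- waveform@period
  list(e = c(0, T / 2), i = c(T / 2, T), ei = c(0, T))
}

#' Rigid-rotation velocity field
#'
#' \eqn{u = (-\omega y', \omega x', 0)} about the grid centre. Closed forms:
#' vorticity (0, 0, 2w), enstrophy 2w^2, helicity 0 (u is in-plane, vorticity
#' out-of-plane), Q = w^2, lambda2 = -w^2.
#'
#' @param grid a [GridSpec-class].
#' @param omega angular velocity about z, 1/s.
#' @param mask optional [DomainMask-class]; default: whole grid.
#' @return a [VelocitySnapshot-class].
#' @export
rigidRotationField <- function(grid, omega, mask = NULL) {
  if (is.null(mask)) mask <- domainMask(grid)
  cc <- coordArrays(grid)
  ctr <- grid@origin + (grid@dims - 1) * grid@spacing / 2
  makeSnapshot(grid, mask,
               ux = -omega * (cc$y - ctr[2]),
               uy = omega * (cc$x - ctr[1]),
               uz = array(0, dim = grid@dims))
}

#' Arnold-Beltrami-Childress (ABC) velocity field
#'
#' \eqn{u = (a \sin z + c \cos y,\; b \sin x + a \cos z,\; c \sin y + b \cos x)}.
#' A Beltrami flow: its curl equals u itself, so the helicity density is
#' \eqn{\|u\|^2} (maximal alignment) with volume mean \eqn{a^2 + b^2 + c^2}
#' over the periodic box.
#'
#' @param grid a [GridSpec-class] spanning `[0, 2 pi)` per axis with
#'   endpoint-exclusive sampling (see [periodicGrid()]).
#' @param a,b,c amplitudes, m/s.
#' @param mask optional [DomainMask-class].
#' @return a [VelocitySnapshot-class].
#' @export
abcField <- function(grid, a = 1, b = 1, c = 1, mask = NULL) {
  if (is.null(mask)) mask <- domainMask(grid)
  cc <- coordArrays(grid)
  makeSnapshot(grid, mask,
               ux = a * sin(cc$z) + c * cos(cc$y),
               uy = b * sin(cc$x) + a * cos(cc$z),
               uz = c * sin(cc$y) + b * cos(cc$x))
}

#' Planar Taylor-Green velocity field
#'
#' \eqn{u = (\sin x \cos y, -\cos x \sin y, 0)}: divergence-free by
#' construction, vorticity \eqn{\Omega_z = 2 \sin x \sin y}, zero helicity
#' (in-plane velocity, out-of-plane vorticity).
#'
#' @param grid a planar [GridSpec-class] (nz = 1) spanning `[0, 2 pi)`.
#' @param mask optional [DomainMask-class].
#' @return a [VelocitySnapshot-class].
#' @export
taylorGreenField <- function(grid, mask = NULL) {
  if (grid@dims[3L] != 1L)
    stop("taylorGreenField expects a planar grid (nz = 1)")
  if (is.null(mask)) mask <- domainMask(grid)
  cc <- coordArrays(grid)
  makeSnapshot(grid, mask,
               ux = sin(cc$x) * cos(cc$y),
               uy = -cos(cc$x) * sin(cc$y),
               uz = array(0, dim = grid@dims))
}

#' Endpoint-exclusive periodic grid over [0, 2 pi)
#'
#' Convenience constructor for sampling trigonometric verification fields so
#' that discrete voxel-centre means match the continuous means.
#'
#' @param n voxels per axis.
#' @param planar if TRUE build an (n, n, 1) grid, else (n, n, n).
#' @return a [GridSpec-class] with spacing `2 pi / n` and origin 0.
#' @export
periodicGrid <- function(n, planar = FALSE) {
  n <- as.integer(n)
  gridSpec(c(n, n, if (planar) 1L else n), 2 * pi / n)
}

#' Plane-Poiseuille channel velocity field
#'
#' \eqn{u = (u_{max} (1 - (y/h)^2), 0, 0)} across a planar channel of
#' half-width h centred on the channel rows of the mask. Pure shear: its
#' Q-criterion density is identically zero.
#'
#' @param grid a planar [GridSpec-class].
#' @param uMax centreline speed, m/s.
#' @param halfWidth channel half-width h, metres; must match the masked
#'   channel height within one voxel.
#' @param mask optional [DomainMask-class] (default: whole grid treated as
#'   the channel).
#' @return a [VelocitySnapshot-class].
#' @export
poiseuilleField <- function(grid, uMax, halfWidth, mask = NULL) {
  if (grid@dims[3L] != 1L)
    stop("poiseuilleField expects a planar grid (nz = 1)")
  if (is.null(mask)) mask <- domainMask(grid)
  ins <- mask@inside
  yIdx <- which(apply(ins, 2L, any))
  width <- length(yIdx) * grid@spacing
  if (abs(width - 2 * halfWidth) > grid@spacing + 1e-12)
    stop("halfWidth is inconsistent with the masked channel height")
  yc <- grid@origin[2] + (mean(range(yIdx)) - 1) * grid@spacing
  cc <- coordArrays(grid)
  ux <- uMax * (1 - ((cc$y - yc) / halfWidth)^2)
  ux[ux < 0] <- 0
  makeSnapshot(grid, mask, ux = ux,
               uy = array(0, dim = grid@dims),
               uz = array(0, dim = grid@dims))
}

#' Construct an airway phantom specification
#'
#' Default proportions follow a 10:1 channel, a cavity of about
#' \eqn{\sqrt{Lw}} on a side and an ostium of 10 percent of the channel
#' width, echoing the anatomy in which ostium flow is far slower than nasal
#' flow. All lengths in metres.
#'
#' @param channelLength,channelWidth channel dimensions (default 0.06 x 0.006).
#' @param cavityWidth,cavityHeight cavity dimensions (default ~ sqrt(L w)).
#' @param ostiumWidth ostium gap width (default 10 percent of channel width).
#' @param constrictionFraction fraction of the channel width occluded by a
#'   mid-channel bump; 0 is the healthy analog.
#' @param depthVoxels 1 for a planar phantom; small values > 1 extrude the
#'   phantom in z between no-slip walls.
#' @param constrictionDepthFraction fraction of the depth the bump spans.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(channelLength = 0.06, channelWidth = 0.006,
                        cavityWidth = sqrt(channelLength * channelWidth),
                        cavityHeight = cavityWidth,
                        ostiumWidth = 0.1 * channelWidth,
                        constrictionFraction = 0,
                        depthVoxels = 1L,
                        constrictionDepthFraction = 1) {
  new("PhantomSpec", channelLength = channelLength,
      channelWidth = channelWidth, cavityWidth = cavityWidth,
      cavityHeight = cavityHeight, ostiumWidth = ostiumWidth,
      constrictionFraction = constrictionFraction,
      depthVoxels = as.integer(depthVoxels),
      constrictionDepthFraction = constrictionDepthFraction)
}

#' Rasterise an airway phantom mask
#'
#' Builds the fluid mask of a straight channel (the nasal-passage analog)
#' along x, a two-voxel separating wall above it, a rectangular cavity (the
#' sinus analog) that communicates with the channel only through a narrow
#' ostium gap in the wall, and optionally a rectangular bump on the channel
#' floor at mid-channel occluding `constrictionFraction` of the width (the
#' septal-deviation analog). The ostium is centred at 70 percent of the
#' channel length, downstream of the bump; the cavity is centred over the
#' ostium. The x = 0 end of the channel is the larynx-side inlet, the
#' x = L end the nostril-side outlet.
#'
#' Planar phantoms (`depthVoxels = 1`) have unit depth; extruded phantoms
#' add `depthVoxels` layers in z between no-slip walls, and the bump then
#' spans only `constrictionDepthFraction` of the depth, which makes the
#' constricted flow genuinely three-dimensional.
#'
#' @param spec a [PhantomSpec-class].
#' @param spacing voxel edge length, metres; the ostium must span at least
#'   two voxels at this spacing.
#' @return a [DomainMask-class]; use [phantomRegions()] for the index ranges
#'   of channel, wall, ostium and cavity (e.g. to place probe planes).
#' @export
airwayPhantom <- function(spec, spacing) {
  stopifnot(is(spec, "PhantomSpec"))
  r <- phantomRegions(spec, spacing)
  dims <- r$dims
  inside <- array(FALSE, dim = dims)
  inside[seq_len(r$nxChannel), r$channelRows, ] <- TRUE
  inside[r$ostiumCols, r$wallRows, ] <- TRUE
  inside[r$cavityCols, r$cavityRows, ] <- TRUE
  if (spec@constrictionFraction > 0 && r$bumpHeight >= 1L) {
    kmax <- max(1L, as.integer(round(spec@constrictionDepthFraction *
                                     dims[3L])))
    inside[r$bumpCols, seq_len(r$bumpHeight), seq_len(kmax)] <- FALSE
  }
  domainMask(gridSpec(dims, spacing), inside)
}

#' Index ranges of the phantom regions
#'
#' Recomputes, from a [PhantomSpec-class] and a spacing, the voxel index
#' ranges used by [airwayPhantom()]: channel rows, wall band, ostium gap
#' columns, cavity block and constriction bump. Useful for placing probe
#' planes and for the solver's inlet/outlet faces.
#'
#' @param spec a [PhantomSpec-class].
#' @param spacing voxel edge length, metres.
#' @return a list with elements `dims`, `nxChannel`, `channelRows`,
#'   `wallRows`, `cavityRows`, `ostiumCols`, `cavityCols`, `bumpCols`,
#'   `bumpHeight`, `ostiumCenter`.
#' @export
phantomRegions <- function(spec, spacing) {
  stopifnot(is(spec, "PhantomSpec"))
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  vox <- function(len) as.integer(round(len / spacing))
  nxc <- vox(spec@channelLength)
  nyc <- vox(spec@channelWidth)
  ncw <- vox(spec@cavityWidth)
  nch <- vox(spec@cavityHeight)
  no <- vox(spec@ostiumWidth)
  if (no < 2L)
    stop("ostium must span at least 2 voxels at the requested spacing")
  if (nxc < 4L || nyc < 3L || ncw < 2L || nch < 2L)
    stop("phantom is under-resolved at the requested spacing")
  nWall <- 2L
  xo <- as.integer(round(0.7 * nxc))
  ostiumCols <- xo - (no %/% 2L) + seq_len(no) - 1L
  cavityCols <- xo - (ncw %/% 2L) + seq_len(ncw) - 1L
  if (min(cavityCols) < 1L || max(cavityCols) > nxc)
    stop("cavity does not fit over the channel; shorten the cavity or ",
         "lengthen the channel")
  if (min(ostiumCols) < min(cavityCols) || max(ostiumCols) > max(cavityCols))
    stop("ostium gap must open into the cavity")
  channelRows <- seq_len(nyc)
  wallRows <- nyc + seq_len(nWall)
  cavityRows <- nyc + nWall + seq_len(nch)
  bumpHeight <- as.integer(round(spec@constrictionFraction * nyc))
  xb <- as.integer(round(0.5 * nxc))
  bumpCols <- xb - (nyc %/% 2L) + seq_len(nyc) - 1L
  bumpCols <- bumpCols[bumpCols >= 2L & bumpCols <= nxc - 1L]
  dims <- c(nxc, nyc + nWall + nch, spec@depthVoxels)
  list(dims = as.integer(dims), nxChannel = nxc, channelRows = channelRows,
       wallRows = wallRows, cavityRows = cavityRows,
       ostiumCols = ostiumCols, cavityCols = cavityCols,
       bumpCols = bumpCols, bumpHeight = bumpHeight, ostiumCenter = xo)
}

#' Scale a base field through a breathing cycle
#'
#' Fixture for time averaging: snapshot k is the base field scaled by
#' \eqn{\dot V(t_k)/A}, so quadratic densities (enstrophy, Q) scale with
#' \eqn{(\dot V/A)^2} and linear ones with \eqn{\dot V/A}.
#'
#' @param base a [VelocitySnapshot-class].
#' @param waveform a [BreathingWaveform-class].
#' @return a [FlowSeries-class] with one snapshot per waveform sample (plus
#'   no pressure series).
#' @export
modulatedSeries <- function(base, waveform) {
  stopifnot(is(base, "VelocitySnapshot"), is(waveform, "BreathingWaveform"))
  scale <- waveform@samples / waveform@amplitude
  snaps <- lapply(seq_along(scale), function(k) {
    s <- base
    s@u <- base@u * scale[k]
    s@time <- waveform@times[k]
    s
  })
  scalars <- data.frame(t = waveform@times, flow_ml_s = waveform@samples,
                        dp_pa = NA_real_, cfl = NA_real_,
                        max_div = NA_real_)
  new("FlowSeries", snapshots = snaps, times = waveform@times,
      mask = base@mask, scalars = scalars, snapshotEvery = 1L)
}
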