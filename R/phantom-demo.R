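#' @include AllClasses.R synthetic-fields.R solver.R measures.R io.R
NULL

#' Probe plane across (or partly across) the phantom ostium
#'
#' Builds the [ostiumFlux()] probe for an airway phantom: a y-normal plane
#' through the middle of the separating wall, spanning the ostium gap
#' columns. `half = TRUE` restricts the probe to the upstream half of the
#' gap: the net flux through the whole opening of a rigid sealed cavity is
#' identically zero for incompressible flow (air leaves one part of the gap
#' exactly as fast as it enters another), so directional exchange and its
#' reversals are measured on the half-gap flux.
#'
#' @param spec a [PhantomSpec-class].
#' @param spacing the rasterisation spacing, metres.
#' @param half restrict to the upstream half of the gap columns.
#' @return a probe list for [ostiumFlux()].
#' @export
ostiumProbe <- function(spec, spacing, half = FALSE) {
  r <- phantomRegions(spec, spacing)
  cols <- r$ostiumCols
  if (half) cols <- cols[seq_len(max(1L, length(cols) %/% 2L))]
  list(axis = 2L, index = r$wallRows[1L], span = list(i = cols))
}

#' Inlet-plane probe of a phantom (or channel) mask
#'
#' @param mask a [DomainMask-class] whose fluid region touches x = 1.
#' @return a probe list for [ostiumFlux()] measuring the x-flux through the
#'   first voxel layer.
#' @export
inletProbe <- function(mask) {
  list(axis = 1L, index = 1L)
}

#' Plane-Poiseuille verification of the flow solver
#'
#' Drives a straight planar channel with a constant flow rate until steady
#' and compares against the closed-form plane-Poiseuille solution: a
#' parabolic profile whose centreline-to-mean speed ratio is 3/2, and a
#' resistance \eqn{\Delta p / Q = 12 \mu L / w^3} per metre of depth. Run at
#' a channel Reynolds number of order one and, by default, with a developed
#' (parabolic) inflow so the measured pressure drop isolates the Poiseuille
#' solution from entrance development losses.
#'
#' @param ny voxels across the channel width.
#' @param aspect channel length in units of its width.
#' @param width channel width, m.
#' @param nu kinematic viscosity, m^2/s (default chosen for a viscous,
#'   rapidly-settling verification run).
#' @param rho density, kg/m^3.
#' @param flow constant inlet flow rate, ml/s.
#' @param tEnd integration time, s (several viscous decay times).
#' @param inletProfile "parabolic" (default) or "uniform".
#' @return list with `ratio` (centreline/mean speed at mid-channel),
#'   `resistance` and `analytic` (Pa s/ml), `relErr` (signed relative
#'   resistance error) and `imbalance` (max relative inlet/outlet flux
#'   mismatch).
#' @export
poiseuilleBenchmark <- function(ny = 16L, aspect = 5, width = 0.006,
                                nu = 1.5e-4, rho = 1.204, flow = 20,
                                tEnd = 0.5, inletProfile = "parabolic") {
  ny <- as.integer(ny)
  h <- width / ny
  nx <- as.integer(round(aspect * ny))
  mask <- domainMask(gridSpec(c(nx, ny, 1L), h))
  dt <- 0.6 * h^2 / (4 * nu)
  nSteps <- as.integer(ceiling(tEnd / dt))
  cfg <- solverConfig(nu = nu, rho = rho, dt = dt, nSteps = nSteps,
                      snapshotEvery = nSteps, inletProfile = inletProfile)
  fs <- solveFlow(mask, flow, cfg)
  s <- snapshotAt(fs, nSnapshots(fs))
  prof <- s@u[nx %/% 2L, , 1L, 1L]
  ratio <- max(prof) / mean(prof)
  dp <- fs@scalars$dp_pa[nrow(fs@scalars)]
  resistance <- dp / flow                      # Pa s/ml
  mu <- nu * rho
  analytic <- 12 * mu * ((nx - 1L) * h) / width^3 * 1e-6  # per ml/s
  list(ratio = ratio, resistance = resistance, analytic = analytic,
       relErr = (resistance - analytic) / analytic,
       imbalance = checkMassConservation(fs)$maxRelImbalance)
}

#' End-to-end healthy-versus-constricted phantom comparison
#'
#' Runs the laminar projection solver on two airway phantoms that differ
#' only in the constriction bump (the septal-deviation analog), drives both
#' with the same sinusoidal breathing waveform, computes the phase-split
#' vorticity-measure tables, the ostium flux attenuation and the
#' within-phase flow-reversal counts, and optionally writes reports.
#'
#' The default configuration is a desk-scale study: a 0.06 x 0.006 m channel
#' and a 0.019 m cavity rasterised at 0.4 mm (150 x 64 x 4 voxels), a
#' 0.8 mm ostium (the two-voxel minimum at this spacing), a thin four-voxel
#' extrusion in z with the bump spanning half the depth (so the constricted
#' flow is genuinely three-dimensional and generates helicity, while the
#' healthy duct flow stays planar), peak inlet flow 0.3 ml/s (channel
#' Reynolds number about 12, safely laminar and CFL-stable at dt = 1 ms)
#' and the standard 4 s breathing cycle in 4000 steps.
#'
#' @param constrictionFraction bump height as a fraction of channel width
#'   for the pathological phantom.
#' @param amplitude peak inlet flow rate, ml/s.
#' @param period breathing cycle, s.
#' @param spacing voxel edge, m.
#' @param depthVoxels extrusion depth in voxels.
#' @param dt solver time step, s.
#' @param snapshotEvery snapshot stride for the measure pipeline.
#' @param nu,rho fluid properties (air by default).
#' @param outDir optional output directory for reports, VTK series and the
#'   resolved configuration.
#' @return a list: `healthy` and `constricted` (each with `series`, `table`,
#'   `ostium` and `ostiumHalf` flux series), `comparison` (data.frame of
#'   full-cycle ratios), `attenuation` (peak full-gap ostium flux over peak
#'   inlet flux, per phantom), `reversals` (expiration-phase reversal counts
#'   on the half-gap flux, per phantom) and `waveform`.
#' @export
runPhantomDemo <- function(constrictionFraction = 0.5, amplitude = 0.3,
                           period = 4, spacing = 4e-4, depthVoxels = 4L,
                           dt = 1e-3, snapshotEvery = 50L, nu = 1.5e-5,
                           rho = 1.204, outDir = NULL) {
  nSteps <- as.integer(round(period / dt))
  waveform <- breathingWaveform(amplitude, period, nSteps)
  cfg <- solverConfig(nu = nu, rho = rho, dt = dt, nSteps = nSteps,
                      snapshotEvery = as.integer(snapshotEvery))
  baseArgs <- list(channelLength = 0.06, channelWidth = 0.006,
                   ostiumWidth = 2 * spacing,
                   depthVoxels = as.integer(depthVoxels),
                   constrictionDepthFraction = 0.5)
  specH <- do.call(phantomSpec, c(baseArgs, constrictionFraction = 0))
  specC <- do.call(phantomSpec,
                   c(baseArgs, constrictionFraction = constrictionFraction))

  runOne <- function(spec) {
    mask <- airwayPhantom(spec, spacing)
    series <- solveFlow(mask, waveform, cfg)
    table <- computeMeasureTable(series, mask, waveform)
    list(mask = mask, series = series, table = table,
         ostium = ostiumFlux(series, ostiumProbe(spec, spacing)),
         ostiumHalf = ostiumFlux(series, ostiumProbe(spec, spacing,
                                                     half = TRUE)))
  }
  healthy <- runOne(specH)
  constricted <- runOne(specC)

  peakInlet <- function(r) max(abs(r$series@scalars$inlet_flux_ml_s))
  attenuation <- c(
    healthy = max(abs(healthy$ostium@flux)) / peakInlet(healthy),
    constricted = max(abs(constricted$ostium@flux)) / peakInlet(constricted))
  wins <- phaseWindows(waveform)
  reversals <- c(
    healthy = countFlowReversals(healthy$ostiumHalf, wins$e),
    constricted = countFlowReversals(constricted$ostiumHalf, wins$e))
  comparison <- compareMeasureTables(healthy$table, constricted$table)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeMeasureReport(healthy$table, file.path(outDir, "healthy"))
    writeMeasureReport(constricted$table, file.path(outDir, "constricted"))
    write.csv(comparison, file.path(outDir, "comparison.csv"),
              row.names = FALSE)
    writeRunConfig(list(phantom = specC, spacing = spacing,
                        waveform = waveform, solver = cfg),
                   file.path(outDir, "run-config.yaml"))
  }
  list(healthy = healthy, constricted = constricted,
       comparison = comparison, attenuation = attenuation,
       reversals = reversals, waveform = waveform)
}
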