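#' @include AllClasses.R utils.R measures.R
#' @importFrom utils read.csv write.csv
#' @importFrom yaml read_yaml write_yaml
NULL

# Minimal legacy-ASCII VTK STRUCTURED_POINTS interchange. Point data arrays:
# "inside" (integer mask), "velocity" (3-vector), optional "pressure".

#' Write a snapshot as a legacy VTK structured-points file
#'
#' ASCII, `STRUCTURED_POINTS`, with point-data arrays `inside` (0/1 mask),
#' `velocity` (vectors, m/s) and, when present, `pressure` (Pa). Suitable
#' for ParaView and for round-tripping with [readSnapshotVTK()].
#'
#' @param snapshot a [VelocitySnapshot-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSnapshotVTK <- function(snapshot, path) {
  stopifnot(is(snapshot, "VelocitySnapshot"))
  g <- snapshot@grid
  d <- as.integer(g@dims)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    sprintf("sinusflow snapshot t=%.9g", snapshot@time),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %.9g %.9g %.9g", g@origin[1], g@origin[2], g@origin[3]),
    sprintf("SPACING %.9g %.9g %.9g", g@spacing, g@spacing, g@spacing),
    sprintf("POINT_DATA %d", prod(d)),
    "SCALARS inside int 1",
    "LOOKUP_TABLE default"
  ), con)
  writeLines(as.character(as.integer(snapshot@mask@inside)), con)
  writeLines("VECTORS velocity double", con)
  um <- matrix(snapshot@u, ncol = 3L)
  writeLines(sprintf("%.17g %.17g %.17g", um[, 1], um[, 2], um[, 3]), con)
  if (length(snapshot@p)) {
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.17g", snapshot@p), con)
  }
  invisible(path)
}

#' Read a snapshot written by [writeSnapshotVTK()]
#'
#' @param path a legacy VTK structured-points file.
#' @param time time stamp to attach, seconds.
#' @return a [VelocitySnapshot-class] (the mask is recovered from the
#'   `inside` array).
#' @export
readSnapshotVTK <- function(path, time = 0) {
  lines <- readLines(path)
  getTok <- function(prefix) {
    ln <- grep(prefix, lines, value = TRUE)[1L]
    if (is.na(ln)) stop("missing '", prefix, "' in ", path)
    as.numeric(strsplit(trimws(sub(prefix, "", ln)), "\\s+")[[1L]])
  }
  if (!any(grepl("^DATASET STRUCTURED_POINTS", lines)))
    stop("not a VTK structured-points file: ", path)
  d <- as.integer(getTok("^DIMENSIONS"))
  org <- getTok("^ORIGIN")
  sp <- getTok("^SPACING")
  if (max(abs(diff(sp[sp > 0]))) > 1e-12 * sp[1])
    stop("anisotropic spacing is not supported: ", path)
  n <- prod(d)
  grid <- gridSpec(d, sp[1], org)
  at <- function(header) grep(header, lines)[1L]
  iIns <- at("^SCALARS inside")
  ins <- as.integer(lines[(iIns + 2L):(iIns + 1L + n)]) > 0L
  mask <- domainMask(grid, array(ins, dim = d))
  iVel <- at("^VECTORS velocity")
  um <- do.call(rbind, strsplit(trimws(lines[(iVel + 1L):(iVel + n)]), "\\s+"))
  um <- matrix(as.numeric(um), ncol = 3L)
  p <- numeric(0)
  iP <- at("^SCALARS pressure")
  if (!is.na(iP)) p <- as.numeric(lines[(iP + 2L):(iP + 1L + n)])
  makeSnapshot(grid, mask,
               ux = array(um[, 1], dim = d), uy = array(um[, 2], dim = d),
               uz = array(um[, 3], dim = d), p = p, time = time)
}

#' Write a flow series as VTK files plus a manifest
#'
#' One VTK file per snapshot (`snapshot_0001.vtk`, ...), a
#' `manifest.csv` of file names and time stamps, and `scalars.csv` with the
#' per-step series (t, flow rate, pressure drop, CFL, max divergence).
#'
#' @param series a [FlowSeries-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeFlowSeries <- function(series, dir) {
  stopifnot(is(series, "FlowSeries"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("snapshot_%04d.vtk", seq_along(series@snapshots))
  for (k in seq_along(series@snapshots))
    writeSnapshotVTK(series@snapshots[[k]], file.path(dir, files[k]))
  write.csv(data.frame(file = files, t = series@times),
            file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(series@scalars, file.path(dir, "scalars.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a flow series written by [writeFlowSeries()]
#'
#' Snapshots are ordered by the manifest time stamps (re-sorted with a
#' warning if the manifest is permuted); all files must share one grid.
#'
#' @param dir directory containing `manifest.csv` and the VTK files.
#' @return a [FlowSeries-class].
#' @export
readFlowSeries <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop("missing manifest.csv in ", dir)
  man <- read.csv(mf)
  if (nrow(man) == 0L) stop("empty manifest in ", dir)
  if (is.unsorted(man$t, strictly = TRUE)) {
    warning("manifest time stamps were not sorted; re-ordering by time")
    man <- man[order(man$t), , drop = FALSE]
  }
  snaps <- vector("list", nrow(man))
  for (k in seq_len(nrow(man))) {
    snaps[[k]] <- readSnapshotVTK(file.path(dir, man$file[k]), man$t[k])
    if (k > 1L) {
      g1 <- snaps[[1L]]@grid; gk <- snaps[[k]]@grid
      if (!identical(g1@dims, gk@dims) ||
          abs(g1@spacing - gk@spacing) > 1e-12 * g1@spacing)
        stop("inconsistent grid in ", man$file[k])
    }
  }
  sf <- file.path(dir, "scalars.csv")
  scalars <- if (file.exists(sf)) read.csv(sf) else
    data.frame(t = man$t, flow_ml_s = NA_real_, dp_pa = NA_real_,
               cfl = NA_real_, max_div = NA_real_)
  new("FlowSeries", snapshots = snaps, times = man$t,
      mask = snaps[[1L]]@mask, scalars = scalars, snapshotEvery = 1L)
}

#' Write a measure table as CSV and a text report
#'
#' Produces a wide CSV mirroring the phase layout (rows = measures, columns
#' e, i, e+i), a long CSV (measure, phase, value) and a readable text
#' summary including |V| and NR. NA cells (e.g. NR without a pressure
#' series) are rendered as NA with a warning.
#'
#' @param table a [MeasureTable-class].
#' @param path base path; writes `<path>_wide.csv`, `<path>_long.csv` and
#'   `<path>.txt`.
#' @return named character vector of the files written, invisibly.
#' @export
writeMeasureReport <- function(table, path) {
  stopifnot(is(table, "MeasureTable"))
  tb <- table@table
  if (any(is.na(tb)))
    warning("measure table contains NA cells (rendered as NA)")
  wide <- data.frame(measure = rownames(tb), e = tb$e, i = tb$i,
                     `e+i` = tb$ei, check.names = FALSE)
  fw <- paste0(path, "_wide.csv")
  write.csv(wide, fw, row.names = FALSE, na = "NA")
  long <- data.frame(
    measure = rep(rownames(tb), times = 3L),
    phase = rep(c("e", "i", "e+i"), each = nrow(tb)),
    value = c(tb$e, tb$i, tb$ei))
  fl <- paste0(path, "_long.csv")
  write.csv(long, fl, row.names = FALSE, na = "NA")
  ft <- paste0(path, ".txt")
  txt <- c(
    "Vorticity measures (volume- and time-averaged)",
    sprintf("  fluid volume |V| = %.4g ml", table@volumeMl),
    sprintf("  %-14s %12s %12s %12s", "measure", "e", "i", "e+i"),
    vapply(rownames(tb), function(m) {
      sprintf("  %-14s %12.5g %12.5g %12.5g", m, tb[m, "e"], tb[m, "i"],
              tb[m, "ei"])
    }, character(1)))
  writeLines(txt, ft)
  invisible(c(wide = fw, long = fl, text = ft))
}

#' Read back the wide CSV of a measure report
#'
#' @param path the base path given to [writeMeasureReport()].
#' @param volumeMl the fluid volume to attach, ml.
#' @return a [MeasureTable-class].
#' @export
readMeasureReport <- function(path, volumeMl) {
  wide <- read.csv(paste0(path, "_wide.csv"), check.names = FALSE)
  tb <- data.frame(e = wide$e, i = wide$i, ei = wide$`e+i`,
                   row.names = wide$measure)
  new("MeasureTable", volumeMl = volumeMl, table = tb)
}

#' Per-measure comparison of two phantoms
#'
#' @param healthy,pathological two [MeasureTable-class] objects.
#' @return data.frame of full-cycle values and pathological/healthy ratios.
#' @export
compareMeasureTables <- function(healthy, pathological) {
  th <- healthy@table; tp <- pathological@table
  data.frame(measure = rownames(th), healthy = th$ei,
             pathological = tp$ei, ratio = tp$ei / th$ei)
}

#' Read a run configuration from YAML (or JSON-compatible YAML)
#'
#' The file may define blocks `phantom` (arguments of [phantomSpec()] plus
#' `spacing`), `waveform` (`amplitude`, `period`, `nSteps`) and `solver`
#' (arguments of [solverConfig()]). Missing entries fall back to package
#' defaults; all component invariants are validated before anything runs.
#'
#' @param path YAML file path.
#' @return a list with validated elements `phantom` ([PhantomSpec-class]),
#'   `spacing`, `waveform` ([BreathingWaveform-class]) and `solver`
#'   ([SolverConfig-class]).
#' @export
readRunConfig <- function(path) {
  cfg <- read_yaml(path)
  ph <- cfg$phantom %||% list()
  spacing <- ph$spacing %||% 3e-4
  ph$spacing <- NULL
  spec <- do.call(phantomSpec, ph)
  wf <- cfg$waveform %||% list()
  waveform <- breathingWaveform(
    amplitude = wf$amplitude %||% 267,
    period = wf$period %||% 4,
    nSteps = wf$nSteps %||% 4000L)
  sv <- cfg$solver %||% list()
  solver <- solverConfig(
    nu = sv$nu %||% 1.5e-5, rho = sv$rho %||% 1.204,
    dt = sv$dt %||% 1e-3,
    nSteps = sv$nSteps %||% as.integer(round(waveform@period /
                                               (sv$dt %||% 1e-3))),
    snapshotEvery = sv$snapshotEvery %||% 25L,
    pressureTolerance = sv$pressureTolerance %||% 1e-8,
    inletProfile = sv$inletProfile %||% "uniform")
  list(phantom = spec, spacing = spacing, waveform = waveform,
       solver = solver)
}

#' Write a resolved run configuration next to its outputs
#'
#' @param config a list as returned by [readRunConfig()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  spec <- config$phantom
  out <- list(
    phantom = list(
      channelLength = spec@channelLength, channelWidth = spec@channelWidth,
      cavityWidth = spec@cavityWidth, cavityHeight = spec@cavityHeight,
      ostiumWidth = spec@ostiumWidth,
      constrictionFraction = spec@constrictionFraction,
      depthVoxels = spec@depthVoxels,
      constrictionDepthFraction = spec@constrictionDepthFraction,
      spacing = config$spacing),
    waveform = list(amplitude = config$waveform@amplitude,
                    period = config$waveform@period,
                    nSteps = length(config$waveform@samples)),
    solver = list(nu = config$solver@nu, rho = config$solver@rho,
                  dt = config$solver@dt, nSteps = config$solver@nSteps,
                  snapshotEvery = config$solver@snapshotEvery,
                  pressureTolerance = config$solver@pressureTolerance,
                  inletProfile = config$solver@inletProfile))
  write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
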