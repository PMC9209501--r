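#' @include AllClasses.R utils.R synthetic-fields.R
#' @importFrom Matrix sparseMatrix forceSymmetric Cholesky solve
NULL

#' Construct a solver configuration
#'
#' @param nu kinematic viscosity, m^2/s (default: air, 1.5e-5).
#' @param rho density, kg/m^3 (default: air, 1.204).
#' @param dt time step, s. Must respect the explicit stability limits: the
#'   advective CFL `max|u| dt / h < 1` is enforced at run time, and a
#'   diffusive limit `dt <= h^2 / (2 d nu)` is checked at setup.
#' @param nSteps number of steps.
#' @param snapshotEvery store a voxel-centre snapshot every this many steps.
#' @param pressureTolerance relative residual bound for the pressure solve
#'   (the direct sparse Cholesky solve is checked against it).
#' @param inletProfile "uniform" (plug inflow, the physiological contract)
#'   or "parabolic" (developed inflow for channel verification).
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(nu = 1.5e-5, rho = 1.204, dt, nSteps,
                         snapshotEvery = 1L, pressureTolerance = 1e-8,
                         inletProfile = "uniform") {
  new("SolverConfig", nu = nu, rho = rho, dt = dt,
      nSteps = as.integer(nSteps), snapshotEvery = as.integer(snapshotEvery),
      pressureTolerance = pressureTolerance, inletProfile = inletProfile)
}

# Face classification and the pressure-Poisson factorisation for a mask.
# Inlet faces: x- boundary faces of inside cells in the first voxel layer;
# outlet faces: x+ boundary faces of inside cells in the last layer.
.solverSetup <- function(mask, config) {
  grid <- mask@grid
  d <- as.integer(grid@dims)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  h <- grid@spacing
  M <- mask@inside

  padFaceMask <- function(ax) {
    dd <- d; dd[ax] <- dd[ax] + 1L
    lo <- array(FALSE, dim = dd); hi <- array(FALSE, dim = dd)
    idxLo <- idxHi <- lapply(dd, seq_len)
    idxLo[[ax]] <- 2L:dd[ax]; idxHi[[ax]] <- seq_len(d[ax])
    lo <- do.call(`[<-`, c(list(lo), idxLo, list(M)))
    hi <- do.call(`[<-`, c(list(hi), idxHi, list(M)))
    list(cellLo = lo, cellHi = hi)  # cell on the -/+ side of each face
  }

  fx <- padFaceMask(1L)
  Ufluid <- fx$cellLo & fx$cellHi
  Uinlet <- array(FALSE, dim = dim(Ufluid))
  Uinlet[1L, , ] <- M[1L, , ]
  Uoutlet <- array(FALSE, dim = dim(Ufluid))
  Uoutlet[nx + 1L, , ] <- M[nx, , ]
  Uwall <- (fx$cellLo | fx$cellHi) & !Ufluid & !Uinlet & !Uoutlet
  Uknown <- Ufluid | Uinlet | Uoutlet | Uwall
  if (!any(Uinlet)) stop("mask has no inside cells on the inlet (x-) boundary")
  if (!any(Uoutlet)) stop("mask has no inside cells on the outlet (x+) boundary")

  fy <- padFaceMask(2L)
  Vfluid <- fy$cellLo & fy$cellHi
  Vwall <- (fy$cellLo | fy$cellHi) & !Vfluid
  Vknown <- Vfluid | Vwall

  if (nz > 1L) {
    fz <- padFaceMask(3L)
    Wfluid <- fz$cellLo & fz$cellHi
    Wwall <- (fz$cellLo | fz$cellHi) & !Wfluid
    Wknown <- Wfluid | Wwall
  } else {
    Wfluid <- Wwall <- Wknown <- NULL
  }

  # pressure-Poisson matrix over inside cells
  nCells <- sum(M)
  idx <- array(0L, dim = d)
  idx[M] <- seq_len(nCells)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diagv <- numeric(nCells)
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    Mn <- shiftArray(M, ax, +1L, FALSE)
    both <- M & Mn
    if (!any(both)) next
    p <- idx[both]
    q <- shiftArray(idx, ax, +1L, 0L)[both]
    ii <- c(ii, p, q); jj <- c(jj, q, p); xx <- c(xx, rep(-1, 2L * length(p)))
    diagv[p] <- diagv[p] + 1
    diagv[q] <- diagv[q] + 1
  }
  outCells <- idx[nx, , ][M[nx, , ]]
  diagv[outCells] <- diagv[outCells] + 2
  A <- sparseMatrix(i = c(ii, seq_len(nCells)), j = c(jj, seq_len(nCells)),
                    x = c(xx, diagv), dims = c(nCells, nCells)) / h^2
  ch <- Cholesky(forceSymmetric(A), LDL = FALSE, perm = TRUE)

  faceArea <- if (nz == 1L) h else h^2
  nInlet <- sum(Uinlet)

  # inlet profile shape, normalised to unit mean over the inlet faces
  shape <- array(1, dim = dim(Uinlet))
  if (config@inletProfile == "parabolic") {
    rows <- which(M[1L, , 1L])
    yc <- mean(range(rows))
    hw <- length(rows) / 2
    prof <- 1 - ((seq_len(ny) - yc) / hw)^2
    prof[prof < 0] <- 0
    for (j in seq_len(ny)) shape[1L, j, ] <- prof[j]
    mInlet <- mean(shape[Uinlet])
    if (mInlet <= 0) stop("degenerate parabolic inlet profile")
    shape <- shape / mInlet
  }

  # per-component, per-axis numeric (0/1) masks of known neighbour faces,
  # precomputed once: they are constant across time steps
  nbrMasks <- function(known) {
    lapply(1:3, function(ax) {
      if (dim(known)[ax] == 1L) return(NULL)
      list(kp = shiftArray(known * 1, ax, +1L, 0),
           km = shiftArray(known * 1, ax, -1L, 0))
    })
  }

  list(grid = grid, d = d, h = h, M = M, idx = idx, A = A, chol = ch,
       Ufluid = Ufluid, Uinlet = Uinlet, Uoutlet = Uoutlet, Uwall = Uwall,
       Uknown = Uknown, Vfluid = Vfluid, Vwall = Vwall, Vknown = Vknown,
       Wfluid = Wfluid, Wwall = Wwall, Wknown = Wknown,
       nbrU = nbrMasks(Uknown), nbrV = nbrMasks(Vknown),
       nbrW = if (nz > 1L) nbrMasks(Wknown) else NULL,
       fluidIdxU = which(Ufluid), fluidIdxV = which(Vfluid),
       fluidIdxW = if (nz > 1L) which(Wfluid) else NULL,
       faceArea = faceArea, nInlet = nInlet, inletShape = shape)
}

# Explicit predictor for one staggered face array: central diffusion with
# linear-reflection no-slip ghosts (-F across a wall half-cell away) and
# first-order upwind advection. Neighbour faces that are not "known" (not
# fluid/wall/inlet/outlet, or beyond the domain) are ghosts. `nbr` carries
# the precomputed 0/1 known-neighbour masks per axis, `fluidIdx` the linear
# indices of the faces being updated.
.predictFace <- function(F, nbr, advVels, fluidIdx, h, nu, dt) {
  acc <- array(0, dim = dim(F))  # nu * lap - adv, accumulated per axis
  for (ax in 1:3) {
    nb <- nbr[[ax]]
    if (is.null(nb)) next
    kp <- nb$kp; km <- nb$km
    valP <- shiftArray(F, ax, +1L) * kp - F * (1 - kp)
    valM <- shiftArray(F, ax, -1L) * km - F * (1 - km)
    a <- advVels[[ax]]
    ap <- (a > 0) * a
    acc <- acc + (nu / h^2) * (valP + valM - 2 * F) -
      (ap * (F - valM) + (a - ap) * (valP - F)) / h
  }
  out <- F
  out[fluidIdx] <- F[fluidIdx] + dt * acc[fluidIdx]
  out
}

#' Unsteady incompressible laminar flow on a masked voxel grid
#'
#' A projection (fractional-step) solver on a staggered grid: an explicit
#' predictor (first-order upwind advection, central diffusion with
#' linear-reflection no-slip ghosts at walls) followed by a pressure-Poisson
#' projection that enforces a divergence-free field on the mask. Boundary
#' contract: no-slip walls everywhere except the inlet (x- boundary), where
#' a uniform (or parabolic) velocity matching the prescribed flow rate is
#' imposed, and the outlet (x+ boundary), held at zero reference pressure
#' with zero-gradient velocity. Deterministic: a fixed configuration
#' reproduces its output bit for bit.
#'
#' @param mask a [DomainMask-class]; the fluid region must touch both x
#'   boundaries (inlet at x-, outlet at x+).
#' @param inflow a [BreathingWaveform-class], a single number (constant flow
#'   rate) or a function of time; ml/s, positive into the domain at the
#'   inlet.
#' @param config a [SolverConfig-class].
#' @param project internal negative-control hook; `FALSE` skips the pressure
#'   projection so that mass-conservation checks can demonstrate the
#'   imbalance it removes.
#' @return a [FlowSeries-class]; scalars hold per-step flow rate, pressure
#'   drop (Pa), advective CFL, max interior |divergence| (1/s) and
#'   inlet/outlet fluxes (ml/s).
#' @export
solveFlow <- function(mask, inflow, config, project = TRUE) {
  stopifnot(is(mask, "DomainMask"), is(config, "SolverConfig"))
  st <- .solverSetup(mask, config)
  d <- st$d; nx <- d[1]; ny <- d[2]; nz <- d[3]; h <- st$h
  nu <- config@nu; rho <- config@rho; dt <- config@dt
  nDim <- if (nz == 1L) 2L else 3L
  if (dt > h^2 / (2 * nDim * nu))
    warning("dt exceeds the explicit diffusive stability limit h^2/(2 d nu)")

  flowFun <- if (is(inflow, "BreathingWaveform")) {
    function(t) flowRateAt(inflow, t)
  } else if (is.function(inflow)) {
    inflow
  } else {
    force(inflow); function(t) rep(as.numeric(inflow), length(t))
  }

  U <- array(0, dim = c(nx + 1L, ny, nz))
  V <- array(0, dim = c(nx, ny + 1L, nz))
  W <- if (nz > 1L) array(0, dim = c(nx, ny, nz + 1L)) else NULL
  psi <- array(0, dim = d)
  M <- st$M
  inletArea <- st$nInlet * st$faceArea

  divergence <- function() {
    array(.divergenceCpp(U, V, if (nz > 1L) W else numeric(0), d, M, h),
          dim = d)
  }

  nbrVec <- function(nbr, ax, which) {
    nb <- nbr[[ax]]
    if (is.null(nb)) numeric(0) else as.numeric(nb[[which]])
  }
  predictC <- function(F, compAxis, O1, o1ax, O2, o2ax, nbr, fluidIdx) {
    e <- integer(0)
    array(.predictFaceCpp(
      F, dim(F), compAxis,
      if (is.null(O1)) numeric(0) else O1,
      if (is.null(O1)) e else dim(O1), o1ax,
      if (is.null(O2)) numeric(0) else O2,
      if (is.null(O2)) e else dim(O2), o2ax,
      nbrVec(nbr, 1L, "kp"), nbrVec(nbr, 1L, "km"),
      nbrVec(nbr, 2L, "kp"), nbrVec(nbr, 2L, "km"),
      nbrVec(nbr, 3L, "kp"), nbrVec(nbr, 3L, "km"),
      fluidIdx, h, nu, dt), dim = dim(F))
  }

  inletCells <- M[1L, , , drop = FALSE]
  outletCells <- M[nx, , , drop = FALSE]
  snapTimes <- numeric(0)
  snaps <- list()
  takeSnapshot <- function(tNow) {
    uc <- (U[1:nx, , , drop = FALSE] + U[2:(nx + 1L), , , drop = FALSE]) / 2
    vc <- (V[, 1:ny, , drop = FALSE] + V[, 2:(ny + 1L), , drop = FALSE]) / 2
    wc <- if (nz > 1L)
      (W[, , 1:nz, drop = FALSE] + W[, , 2:(nz + 1L), drop = FALSE]) / 2
    else array(0, dim = d)
    makeSnapshot(st$grid, mask, array(uc, d), array(vc, d), array(wc, d),
                 p = rho * psi, time = tNow)
  }

  n <- config@nSteps
  scal <- data.frame(t = numeric(n + 1L), flow_ml_s = 0, dp_pa = 0,
                     cfl = 0, max_div = 0, inlet_flux_ml_s = 0,
                     outlet_flux_ml_s = 0)
  snaps[[1L]] <- takeSnapshot(0)
  snapTimes <- 0

  for (step in seq_len(n)) {
    tNew <- step * dt
    Q <- flowFun(tNew) * 1e-6  # ml/s -> m^3/s
    uIn <- Q / inletArea

    # boundary values at the new time level
    U[st$Uinlet] <- uIn * st$inletShape[st$Uinlet]
    U[st$Uwall] <- 0; V[st$Vwall] <- 0
    if (nz > 1L) W[st$Wwall] <- 0
    U[nx + 1L, , ][outletCells[1L, , ]] <- U[nx, , ][outletCells[1L, , ]]

    maxu <- max(abs(U), abs(V), if (nz > 1L) abs(W) else 0)
    cfl <- maxu * dt / h
    if (cfl >= 1)
      stop("advective CFL reached ", signif(cfl, 3), " at step ", step,
           "; reduce dt")

    W3 <- if (nz > 1L) W else NULL
    Un <- predictC(U, 1L, V, 2L, W3, 3L, st$nbrU, st$fluidIdxU)
    Vn <- predictC(V, 2L, U, 1L, W3, 3L, st$nbrV, st$fluidIdxV)
    if (nz > 1L)
      W <- predictC(W, 3L, U, 1L, V, 2L, st$nbrW, st$fluidIdxW)
    U <- Un; V <- Vn
    U[nx + 1L, , ][outletCells[1L, , ]] <- U[nx, , ][outletCells[1L, , ]]

    if (project) {
      dv <- divergence()
      b <- -dv[M] / dt
      sol <- as.numeric(Matrix::solve(st$chol, b))
      res <- sqrt(sum((as.numeric(st$A %*% sol) - b)^2))
      bn <- sqrt(sum(b^2))
      if (bn > 0 && res / bn > config@pressureTolerance)
        stop("pressure solve residual ", signif(res / bn, 3),
             " exceeds the tolerance")
      psi <- array(0, dim = d)
      psi[M] <- sol
      # interior x-faces are 2..nx
      gpx <- (psi[2:nx, , , drop = FALSE] -
                psi[1:(nx - 1L), , , drop = FALSE]) / h
      Uint <- U[2:nx, , , drop = FALSE]
      fl <- st$Ufluid[2:nx, , , drop = FALSE]
      Uint[fl] <- Uint[fl] - dt * gpx[fl]
      U[2:nx, , ] <- Uint
      gpy <- (psi[, 2:ny, , drop = FALSE] - psi[, 1:(ny - 1L), ,
                                               drop = FALSE]) / h
      Vint <- V[, 2:ny, , drop = FALSE]
      flv <- st$Vfluid[, 2:ny, , drop = FALSE]
      Vint[flv] <- Vint[flv] - dt * gpy[flv]
      V[, 2:ny, ] <- Vint
      if (nz > 1L) {
        gpz <- (psi[, , 2:nz, drop = FALSE] - psi[, , 1:(nz - 1L),
                                                 drop = FALSE]) / h
        Wint <- W[, , 2:nz, drop = FALSE]
        flw <- st$Wfluid[, , 2:nz, drop = FALSE]
        Wint[flw] <- Wint[flw] - dt * gpz[flw]
        W[, , 2:nz] <- Wint
      }
      # outlet faces: Dirichlet zero pressure at the face (ghost -psi_P)
      oSel <- outletCells[1L, , ]
      U[nx + 1L, , ][oSel] <- U[nx + 1L, , ][oSel] +
        dt * 2 * psi[nx, , ][oSel] / h
    }

    dvAfter <- divergence()
    influx <- sum(U[1L, , ][inletCells[1L, , ]]) * st$faceArea * 1e6
    outflux <- sum(U[nx + 1L, , ][outletCells[1L, , ]]) * st$faceArea * 1e6
    dpNow <- rho * (mean(psi[1L, , ][inletCells[1L, , ]]) -
                      mean(psi[nx, , ][outletCells[1L, , ]]))
    scal[step + 1L, ] <- c(tNew, Q * 1e6, dpNow, cfl, max(abs(dvAfter)),
                           influx, outflux)

    if (step %% config@snapshotEvery == 0L) {
      snaps[[length(snaps) + 1L]] <- takeSnapshot(tNew)
      snapTimes <- c(snapTimes, tNew)
    }
  }
  scal$t[1L] <- 0
  new("FlowSeries", snapshots = snaps, times = snapTimes, mask = mask,
      scalars = scal, snapshotEvery = config@snapshotEvery)
}

# Average the face array of component `from` onto the face positions of
# component `to` (four-point average across the two staggered axes).
.faceAvg <- function(F, from, to, d) {
  # pad along `to` (the target's own axis) so the result has the target's
  # staggered dimension; average across `from`'s staggered pairs.
  dd <- dim(F)
  ddp <- dd; ddp[to] <- dd[to] + 2L
  P <- array(0, dim = ddp)
  sel <- lapply(ddp, seq_len)
  sel[[to]] <- 2L:(dd[to] + 1L)
  P <- do.call(`[<-`, c(list(P), sel, list(F)))
  td <- d; td[to] <- d[to] + 1L  # target face-array dims
  pick <- function(ofsTo, ofsFrom) {
    s <- lapply(seq_len(3L), function(ax) seq_len(td[ax]))
    s[[to]] <- seq_len(td[to]) + ofsTo
    s[[from]] <- seq_len(d[from]) + ofsFrom
    do.call(`[`, c(list(P), s, list(drop = FALSE)))
  }
  (pick(0L, 0L) + pick(0L, 1L) + pick(1L, 0L) + pick(1L, 1L)) / 4
}

#' Mass-conservation report for a solver run
#'
#' Per step: the maximum interior |divergence| and the inlet/outlet flux
#' imbalance relative to the peak flux. A converged projection keeps the
#' relative imbalance far below 1e-6.
#'
#' @param series a [FlowSeries-class] produced by [solveFlow()].
#' @param mask the [DomainMask-class] of the run (defaults to the series').
#' @return a list with `perStep` (data.frame: t, max_div, imbalance_ml_s,
#'   rel_imbalance), `maxRelImbalance` and `maxDivergence`.
#' @export
checkMassConservation <- function(series, mask = NULL) {
  stopifnot(is(series, "FlowSeries"))
  sc <- series@scalars
  if (!all(c("inlet_flux_ml_s", "outlet_flux_ml_s") %in% names(sc)))
    stop("series does not carry solver flux records")
  peak <- max(abs(sc$inlet_flux_ml_s), abs(sc$outlet_flux_ml_s), 1e-300)
  imb <- abs(sc$inlet_flux_ml_s - sc$outlet_flux_ml_s)
  per <- data.frame(t = sc$t, max_div = sc$max_div, imbalance_ml_s = imb,
                    rel_imbalance = imb / peak)
  list(perStep = per, maxRelImbalance = max(per$rel_imbalance),
       maxDivergence = max(per$max_div))
}
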