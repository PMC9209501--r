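#' @include AllClasses.R utils.R
NULL

#' Vector field on a masked grid
#'
#' Used for the vorticity field; values are meaningful on inside voxels only.
#'
#' @slot grid a [GridSpec-class].
#' @slot mask a [DomainMask-class].
#' @slot v numeric array `c(dims, 3)`.
#' @slot name what the vectors are (e.g. "vorticity", 1/s).
#' @export
setClass("VectorField", representation(
  grid = "GridSpec", mask = "DomainMask", v = "array", name = "character"
))

#' Strain-rate and spin tensor fields
#'
#' Symmetric (D) and antisymmetric (A) parts of the velocity gradient,
#' \eqn{D = (G + G^T)/2}, \eqn{A = (G - G^T)/2}, per voxel.
#'
#' @slot grid a [GridSpec-class].
#' @slot mask a [DomainMask-class].
#' @slot D,A numeric arrays `c(dims, 3, 3)` (1/s).
#' @export
setClass("StrainSpinFields", representation(
  grid = "GridSpec", mask = "DomainMask", D = "array", A = "array"
))

#' @rdname accessors
#' @export
setMethod("gridOf", "VectorField", function(x, ...) x@grid)
#' @rdname accessors
#' @export
setMethod("maskOf", "VectorField", function(x, ...) x@mask)
#' @rdname accessors
#' @export
setMethod("gridOf", "StrainSpinFields", function(x, ...) x@grid)
#' @rdname accessors
#' @export
setMethod("maskOf", "StrainSpinFields", function(x, ...) x@mask)

setMethod("show", "VectorField", function(object) {
  cat(sprintf("VectorField (%s) on %d inside voxels\n", object@name,
              sum(object@mask@inside)))
})

setMethod("show", "StrainSpinFields", function(object) {
  cat(sprintf("StrainSpinFields (D, A) on %d inside voxels\n",
              sum(object@mask@inside)))
})

#' Discrete velocity gradient on a masked grid
#'
#' Second-order central differences where both axis neighbours are inside
#' the mask, first-order one-sided differences where only one is, and zero
#' with a degenerate flag where neither is. Planar grids (nz = 1) have zero
#' z-derivatives by definition (not flagged). Central differences are exact
#' on linear fields, so rigid rotation, uniform translation and simple shear
#' reproduce their hand-computed tensors to rounding.
#'
#' @param snapshot a [VelocitySnapshot-class].
#' @return a [GradientTensorField-class]; `quality` is 2 where every active
#'   axis used a central stencil, 1 where some axis fell back to one-sided,
#'   0 where the voxel is degenerate (tensor zeroed).
#' @export
velocityGradient <- function(snapshot) {
  stopifnot(is(snapshot, "VelocitySnapshot"))
  grid <- snapshot@grid
  d <- as.integer(grid@dims)
  h <- grid@spacing
  M <- snapshot@mask@inside
  g <- array(0, dim = c(d, 3L, 3L))
  quality <- array(2L, dim = d)
  for (ax in 1:3) {
    if (d[ax] == 1L) next  # planar: z-derivatives are zero by definition
    Mp <- shiftArray(M, ax, +1L, FALSE)
    Mm <- shiftArray(M, ax, -1L, FALSE)
    central <- M & Mp & Mm
    onlyP <- M & Mp & !Mm
    onlyM <- M & !Mp & Mm
    none <- M & !Mp & !Mm
    quality[onlyP | onlyM] <- pmin(quality[onlyP | onlyM], 1L)
    quality[none] <- 0L
    for (comp in 1:3) {
      u <- array(snapshot@u[, , , comp], dim = d)
      up <- shiftArray(u, ax, +1L)
      um <- shiftArray(u, ax, -1L)
      g[, , , comp, ax] <- central * (up - um) / (2 * h) +
        onlyP * (up - u) / h + onlyM * (u - um) / h
    }
  }
  quality[!M] <- 0L
  deg <- M & (quality == 0L)
  if (any(deg)) {
    for (i in 1:3) for (j in 1:3) {
      gij <- g[, , , i, j]; gij[deg] <- 0; g[, , , i, j] <- gij
    }
    warning(sum(deg), " voxel(s) have no neighbour along some axis; ",
            "their gradient tensors were zeroed and flagged degenerate")
  }
  new("GradientTensorField", grid = grid, mask = snapshot@mask, g = g,
      quality = quality)
}

#' Vorticity (curl of velocity)
#'
#' \eqn{\Omega = \nabla \times u} assembled from the gradient tensor:
#' \eqn{\Omega_1 = G_{32} - G_{23}}, \eqn{\Omega_2 = G_{13} - G_{31}},
#' \eqn{\Omega_3 = G_{21} - G_{12}}.
#'
#' @param grad a [GradientTensorField-class].
#' @return a [VectorField-class] named "vorticity" (1/s).
#' @export
vorticityField <- function(grad) {
  stopifnot(is(grad, "GradientTensorField"))
  d <- as.integer(grad@grid@dims)
  v <- array(0, dim = c(d, 3L))
  v[, , , 1L] <- grad@g[, , , 3L, 2L] - grad@g[, , , 2L, 3L]
  v[, , , 2L] <- grad@g[, , , 1L, 3L] - grad@g[, , , 3L, 1L]
  v[, , , 3L] <- grad@g[, , , 2L, 1L] - grad@g[, , , 1L, 2L]
  new("VectorField", grid = grad@grid, mask = grad@mask, v = v,
      name = "vorticity")
}

#' Split the velocity gradient into strain-rate and spin tensors
#'
#' @param grad a [GradientTensorField-class].
#' @return a [StrainSpinFields-class]; `D + A` reassembles the gradient
#'   exactly, and pointwise \eqn{\|A\|_F^2 = \|\Omega\|^2 / 2}.
#' @export
strainSpinSplit <- function(grad) {
  stopifnot(is(grad, "GradientTensorField"))
  d <- as.integer(grad@grid@dims)
  D <- array(0, dim = c(d, 3L, 3L))
  A <- array(0, dim = c(d, 3L, 3L))
  for (i in 1:3) for (j in 1:3) {
    D[, , , i, j] <- (grad@g[, , , i, j] + grad@g[, , , j, i]) / 2
    A[, , , i, j] <- (grad@g[, , , i, j] - grad@g[, , , j, i]) / 2
  }
  new("StrainSpinFields", grid = grad@grid, mask = grad@mask, D = D, A = A)
}

.densityField <- function(grid, mask, values, measure) {
  values <- array(values, dim = as.integer(grid@dims))
  values[!mask@inside] <- 0
  new("ScalarDensityField", grid = grid, mask = mask, values = values,
      measure = measure)
}

#' Helicity density
#'
#' \eqn{h = u \cdot \Omega} (m/s^2): the local alignment of velocity and
#' vorticity. Zero for any planar flow (velocity in-plane, vorticity
#' out-of-plane); equal to \eqn{\|u\|^2} for Beltrami flows such as the ABC
#' field.
#'
#' @param snapshot a [VelocitySnapshot-class].
#' @param omega optional [VectorField-class] of vorticity; computed from the
#'   snapshot when omitted.
#' @return a [ScalarDensityField-class].
#' @export
helicityDensity <- function(snapshot, omega = NULL) {
  if (is.null(omega)) omega <- vorticityField(velocityGradient(snapshot))
  stopifnot(is(omega, "VectorField"))
  vals <- snapshot@u[, , , 1L] * omega@v[, , , 1L] +
    snapshot@u[, , , 2L] * omega@v[, , , 2L] +
    snapshot@u[, , , 3L] * omega@v[, , , 3L]
  .densityField(snapshot@grid, snapshot@mask, vals, "helicity")
}

#' Absolute helicity density
#'
#' \eqn{|h| = |u \cdot \Omega|} (m/s^2).
#'
#' @inheritParams helicityDensity
#' @return a [ScalarDensityField-class].
#' @export
absoluteHelicityDensity <- function(snapshot, omega = NULL) {
  hd <- helicityDensity(snapshot, omega)
  .densityField(hd@grid, hd@mask, abs(hd@values), "abs_helicity")
}

#' Enstrophy density
#'
#' \eqn{e = \|\Omega\|^2 / 2} (1/s^2), linked to the viscous dissipation of
#' kinetic energy.
#'
#' @param omega a [VectorField-class] of vorticity.
#' @return a [ScalarDensityField-class].
#' @export
enstrophyDensity <- function(omega) {
  stopifnot(is(omega, "VectorField"))
  vals <- (omega@v[, , , 1L]^2 + omega@v[, , , 2L]^2 +
             omega@v[, , , 3L]^2) / 2
  .densityField(omega@grid, omega@mask, vals, "enstrophy")
}

#' Vorticity-magnitude density
#'
#' \eqn{\|\Omega\|} (1/s), the simplest local measure of spinning motion.
#'
#' @param omega a [VectorField-class] of vorticity.
#' @return a [ScalarDensityField-class].
#' @export
vorticityMagnitudeDensity <- function(omega) {
  stopifnot(is(omega, "VectorField"))
  vals <- sqrt(omega@v[, , , 1L]^2 + omega@v[, , , 2L]^2 +
                 omega@v[, , , 3L]^2)
  .densityField(omega@grid, omega@mask, vals, "vort_mag")
}

#' Q-criterion density
#'
#' \eqn{q = (\|A\|_F^2 - \|D\|_F^2)/2} (1/s^2): the local excess of rotation
#' over strain. Positive values mark vortical regions; identically zero for
#' simple shear.
#'
#' @param split a [StrainSpinFields-class].
#' @return a [ScalarDensityField-class].
#' @export
qCriterionDensity <- function(split) {
  stopifnot(is(split, "StrainSpinFields"))
  d <- as.integer(split@grid@dims)
  nA2 <- array(0, dim = d); nD2 <- array(0, dim = d)
  for (i in 1:3) for (j in 1:3) {
    nA2 <- nA2 + as.vector(split@A[, , , i, j])^2
    nD2 <- nD2 + as.vector(split@D[, , , i, j])^2
  }
  .densityField(split@grid, split@mask, (nA2 - nD2) / 2, "q_criterion")
}

# Middle eigenvalue (descending sort) of a field of symmetric 3x3 matrices
# given as six component arrays, via the trigonometric closed form.
.middleEigSym3 <- function(S11, S22, S33, S12, S13, S23) {
  q <- (S11 + S22 + S33) / 3
  p1 <- S12^2 + S13^2 + S23^2
  p2 <- (S11 - q)^2 + (S22 - q)^2 + (S33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  ps <- ifelse(p > 0, p, 1)  # safe divisor; overwritten below where p == 0
  B11 <- (S11 - q) / ps; B22 <- (S22 - q) / ps; B33 <- (S33 - q) / ps
  B12 <- S12 / ps; B13 <- S13 / ps; B23 <- S23 / ps
  detB <- B11 * (B22 * B33 - B23^2) - B12 * (B12 * B33 - B23 * B13) +
    B13 * (B12 * B23 - B22 * B13)
  r <- pmin(pmax(detB / 2, -1), 1)
  # exactly repeated eigenvalues put r at +/-1 up to rounding; snapping
  # recovers exact results there (the deviation is below the acos noise
  # floor for genuinely near-degenerate tensors)
  snap <- abs(r) > 1 - 1e-12
  r[snap] <- sign(r[snap])
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e2[p == 0] <- q[p == 0]  # isotropic: all eigenvalues equal the mean
  e2
}

#' lambda2 vortex-criterion density
#'
#' The middle eigenvalue (eigenvalues sorted descending) of the symmetric
#' tensor \eqn{D^2 + A^2}, per voxel (1/s^2). Negative values mark vortex
#' cores (the Jeong-Hussain convention). Computed with the trigonometric
#' closed form for symmetric 3x3 eigenvalues, vectorised over voxels; a
#' voxel whose eigenvalues come out non-finite is zeroed with a warning.
#'
#' @param split a [StrainSpinFields-class].
#' @return a [ScalarDensityField-class].
#' @export
lambda2Density <- function(split) {
  stopifnot(is(split, "StrainSpinFields"))
  d <- as.integer(split@grid@dims)
  S <- vector("list", 9L)
  for (i in 1:3) for (j in i:3) {
    s <- array(0, dim = d)
    for (k in 1:3) {
      s <- s + as.vector(split@D[, , , i, k]) * as.vector(split@D[, , , k, j]) +
        as.vector(split@A[, , , i, k]) * as.vector(split@A[, , , k, j])
    }
    S[[(i - 1L) * 3L + j]] <- s
  }
  vals <- .middleEigSym3(S[[1L]], S[[5L]], S[[9L]], S[[2L]], S[[3L]], S[[6L]])
  bad <- !is.finite(vals) & split@mask@inside
  if (any(bad)) {
    vals[bad] <- 0
    warning(sum(bad), " voxel(s) failed the eigenvalue evaluation; ",
            "their lambda2 density was set to zero")
  }
  .densityField(split@grid, split@mask, vals, "lambda2")
}

#' Divergence of velocity
#'
#' \eqn{\nabla \cdot u = \mathrm{tr}(G)} (1/s): the incompressibility
#' diagnostic (mass conservation requires it to vanish).
#'
#' @param grad a [GradientTensorField-class].
#' @return a [ScalarDensityField-class].
#' @export
divergenceField <- function(grad) {
  stopifnot(is(grad, "GradientTensorField"))
  vals <- grad@g[, , , 1L, 1L] + grad@g[, , , 2L, 2L] + grad@g[, , , 3L, 3L]
  .densityField(grad@grid, grad@mask, vals, "divergence")
}

#' All six vorticity-measure densities of one snapshot
#'
#' Convenience wrapper computing gradient, vorticity and the strain/spin
#' split once and returning every density.
#'
#' @param snapshot a [VelocitySnapshot-class].
#' @return named list of [ScalarDensityField-class]: helicity, abs_helicity,
#'   enstrophy, q, lambda2, vort_mag.
#' @export
allDensities <- function(snapshot) {
  grad <- velocityGradient(snapshot)
  omega <- vorticityField(grad)
  split <- strainSpinSplit(grad)
  h <- helicityDensity(snapshot, omega)
  list(
    helicity = h,
    abs_helicity = .densityField(h@grid, h@mask, abs(h@values),
                                 "abs_helicity"),
    enstrophy = enstrophyDensity(omega),
    q = qCriterionDensity(split),
    lambda2 = lambda2Density(split),
    vort_mag = vorticityMagnitudeDensity(omega)
  )
}
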