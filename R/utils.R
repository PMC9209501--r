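#' @include AllClasses.R
NULL

# Shift a 3-D array along one axis by +1/-1 voxel, filling with `fill`.
# shiftArray(a, axis, +1)[i] == a[i + 1] (the value of the +1 neighbour).
# Explicit slicing per axis: this sits in the solver's inner loop.
shiftArray <- function(a, axis, dir, fill = 0) {
  d <- dim(a)
  n <- d[axis]
  out <- array(fill, dim = d)
  if (n == 1L) return(out)
  if (axis == 1L) {
    if (dir > 0) out[1:(n - 1L), , ] <- a[2:n, , ]
    else out[2:n, , ] <- a[1:(n - 1L), , ]
  } else if (axis == 2L) {
    if (dir > 0) out[, 1:(n - 1L), ] <- a[, 2:n, ]
    else out[, 2:n, ] <- a[, 1:(n - 1L), ]
  } else {
    if (dir > 0) out[, , 1:(n - 1L)] <- a[, , 2:n]
    else out[, , 2:n] <- a[, , 1:(n - 1L)]
  }
  out
}

#' Construct a uniform Cartesian grid
#'
#' @param dims integer triple (nx, ny, nz); nz = 1 encodes a planar grid.
#' @param spacing voxel edge length, metres.
#' @param origin coordinate of the centre of voxel (1,1,1), metres.
#' @return a [GridSpec-class].
#' @examples
#' gridSpec(c(16, 16, 1), 0.001)
#' @export
gridSpec <- function(dims, spacing, origin = c(0, 0, 0)) {
  new("GridSpec", dims = as.integer(dims), spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a fluid-domain mask
#'
#' @param grid a [GridSpec-class].
#' @param inside logical array matching the grid dims (default: all inside).
#' @return a [DomainMask-class]; its volume is
#'   `sum(inside) * spacing^d` with d = 2 for planar grids (unit depth).
#' @export
domainMask <- function(grid, inside = NULL) {
  if (is.null(inside))
    inside <- array(TRUE, dim = grid@dims)
  if (!is.array(inside)) inside <- array(inside, dim = grid@dims)
  d <- if (grid@dims[3L] == 1L) 2L else 3L
  new("DomainMask", grid = grid, inside = inside,
      volume = sum(inside) * grid@spacing^d)
}

# Voxel-centre coordinates along one axis.
axisCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@dims[axis]) - 1L) * grid@spacing
}

# Full coordinate arrays (nx, ny, nz) for x, y, z at voxel centres.
coordArrays <- function(grid) {
  d <- grid@dims
  x <- array(rep(axisCoords(grid, 1L), times = d[2] * d[3]), dim = d)
  y <- array(rep(rep(axisCoords(grid, 2L), each = d[1]), times = d[3]),
             dim = d)
  z <- array(rep(axisCoords(grid, 3L), each = d[1] * d[2]), dim = d)
  list(x = x, y = y, z = z)
}

# Assemble a VelocitySnapshot from component arrays.
makeSnapshot <- function(grid, mask, ux, uy, uz, p = numeric(0), time = 0) {
  u <- array(0, dim = c(grid@dims, 3L))
  u[, , , 1L] <- ux; u[, , , 2L] <- uy; u[, , , 3L] <- uz
  out <- rep(!mask@inside, times = 3L)
  u[out] <- 0
  new("VelocitySnapshot", grid = grid, mask = mask, u = u,
      p = as.numeric(p), time = as.numeric(time))
}
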