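# Shared fixture builders (all generated in code, no stored data).

# random velocity field with a random (but neighbour-rich) mask
randomMaskedSnapshot <- function(n = 5L, h = 0.1, seed = 42L,
                                 pInside = 0.75) {
  set.seed(seed)
  g <- gridSpec(c(n, n, n), h)
  ins <- array(stats::runif(n^3) < pInside, dim = c(n, n, n))
  ins[1:2, 1:2, 1:2] <- TRUE  # guarantee a non-degenerate core
  mask <- domainMask(g, ins)
  u <- array(stats::rnorm(3 * n^3), dim = c(n, n, n, 3L))
  snap <- makeLinearSnapshot(g, mask, u)
  snap
}

makeLinearSnapshot <- function(grid, mask, u) {
  methods::new("VelocitySnapshot", grid = grid, mask = mask,
               u = u, p = numeric(0), time = 0)
}

# u = L %*% x + c : arbitrary linear field (central differences exact)
linearFieldSnapshot <- function(L, const = c(0, 0, 0), n = 7L, h = 0.1) {
  g <- gridSpec(c(n, n, n), h)
  mask <- domainMask(g)
  cc <- sinusflow:::coordArrays(g)
  u <- array(0, dim = c(n, n, n, 3L))
  for (i in 1:3)
    u[, , , i] <- L[i, 1] * cc$x + L[i, 2] * cc$y + L[i, 3] * cc$z + const[i]
  makeLinearSnapshot(g, mask, u)
}

# straight 2-D channel mask spanning the full x extent
channelMask <- function(nx, ny, h) {
  domainMask(gridSpec(c(nx, ny, 1L), h))
}
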