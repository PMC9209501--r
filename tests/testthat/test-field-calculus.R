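# Closed-form values below are hand-derived for linear fields, on which
# central differences are exact.

test_that("gradient, curl and split are exact on linear fields", {
  # rigid rotation u = (-y, x, 0)
  rot <- linearFieldSnapshot(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3,
                                    byrow = TRUE))
  gr <- velocityGradient(rot)
  inner <- gr@quality == 2L
  expect_true(any(inner))
  expect_equal(gr@g[4, 4, 4, , ],
               matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE))
  om <- vorticityField(gr)
  expect_equal(om@v[4, 4, 4, ], c(0, 0, 2))
  sp <- strainSpinSplit(gr)
  expect_equal(max(abs(sp@D)), 0)
  expect_equal(sp@A[4, 4, 4, , ], gr@g[4, 4, 4, , ])

  # uniform translation: zero tensor everywhere
  tr <- linearFieldSnapshot(matrix(0, 3, 3), const = c(3, -1, 2))
  expect_equal(max(abs(velocityGradient(tr)@g)), 0)

  # simple shear u = (2y, 0, 0): curl (0, 0, -2), enstrophy 2, Q = 0
  sh <- linearFieldSnapshot(matrix(c(0, 2, 0, 0, 0, 0, 0, 0, 0), 3,
                                   byrow = TRUE))
  gsh <- velocityGradient(sh)
  osh <- vorticityField(gsh)
  expect_equal(osh@v[4, 4, 4, ], c(0, 0, -2))
  expect_equal(enstrophyDensity(osh)@values[4, 4, 4], 2)
  ssh <- strainSpinSplit(gsh)
  expect_equal(qCriterionDensity(ssh)@values[4, 4, 4], 0)
  expect_equal(lambda2Density(ssh)@values[4, 4, 4], 0, tolerance = 1e-12)

  # pure strain u = (x, -y, 0): A = 0, D = diag(1, -1, 0)
  pst <- linearFieldSnapshot(diag(c(1, -1, 0)))
  spst <- strainSpinSplit(velocityGradient(pst))
  expect_equal(max(abs(spst@A)), 0)
  expect_equal(spst@D[4, 4, 4, , ], diag(c(1, -1, 0)))
})

test_that("rigid rotation yields the textbook density suite", {
  rot <- linearFieldSnapshot(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3,
                                    byrow = TRUE))
  dens <- allDensities(rot)
  at <- function(f) f@values[4, 4, 4]
  expect_equal(at(dens$vort_mag), 2)
  expect_equal(at(dens$enstrophy), 2)
  expect_equal(at(dens$helicity), 0)
  expect_equal(at(dens$q), 1)
  expect_equal(at(dens$lambda2), -1, tolerance = 1e-12)
  # helicity vanishes everywhere: in-plane u, out-of-plane vorticity
  expect_lt(max(abs(dens$helicity@values)), 1e-12)
})

test_that("gradient converges at second order on trigonometric fields", {
  errAt <- function(n) {
    g <- periodicGrid(n, planar = TRUE)
    tg <- taylorGreenField(g)
    gr <- velocityGradient(tg)
    cc <- sinusflow:::coordArrays(g)
    exact <- cos(cc$x) * cos(cc$y)  # d(u_x)/dx
    inner <- gr@quality == 2L
    max(abs(array(gr@g[, , , 1, 1], dim = dim(exact)) - exact)[inner])
  }
  e16 <- errAt(16L)
  e32 <- errAt(32L)
  expect_gt(e16 / e32, 3)  # ~4x per halving of spacing
  expect_lt(e32, 0.05)
})

test_that("divergence diagnostic is exact on linear and small on TG fields", {
  lin <- linearFieldSnapshot(diag(c(1, 1, 1)))
  dv <- divergenceField(velocityGradient(lin))
  expect_equal(dv@values[4, 4, 4], 3)
  tg <- taylorGreenField(periodicGrid(32L, planar = TRUE))
  gtg <- velocityGradient(tg)
  dvt <- divergenceField(gtg)
  expect_lt(max(abs(dvt@values[gtg@quality == 2L])), 1e-12)
})

test_that("pointwise identities hold on every tested field", {
  fields <- list(
    rigid = linearFieldSnapshot(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3,
                                       byrow = TRUE)),
    shear = linearFieldSnapshot(matrix(c(0, 2, 0, 0, 0, 0, 0, 0, 0), 3,
                                       byrow = TRUE)),
    abc = abcField(periodicGrid(12L)),
    tg = taylorGreenField(periodicGrid(12L, planar = TRUE)),
    random = randomMaskedSnapshot(6L, seed = 7L)
  )
  for (nm in names(fields)) {
    s <- fields[[nm]]
    gr <- suppressWarnings(velocityGradient(s))
    om <- vorticityField(gr)
    sp <- strainSpinSplit(gr)
    ins <- s@mask@inside
    # D + A reassembles the gradient exactly
    expect_equal(sp@D + sp@A, gr@g, tolerance = 1e-14)
    # ||A||^2 = ||Omega||^2 / 2 pointwise
    nA2 <- apply(sp@A^2, 1:3, sum)
    om2 <- apply(om@v^2, 1:3, sum)
    expect_equal(nA2[ins], om2[ins] / 2, tolerance = 1e-12)
    # vort_mag^2 = 2 * enstrophy
    vm <- vorticityMagnitudeDensity(om)@values
    en <- enstrophyDensity(om)@values
    expect_equal(vm[ins]^2, 2 * en[ins], tolerance = 1e-12)
    # absolute variant dominates the signed variant
    h <- helicityDensity(s, om)@values
    ah <- absoluteHelicityDensity(s, om)@values
    expect_equal(ah[ins], abs(h[ins]))
  }
})

test_that("eigenvalue trace identity ties lambda sums to the Q-criterion", {
  # lambda1 + lambda2 + lambda3 = tr(D^2 + A^2) = -2 Q for any gradient
  s <- randomMaskedSnapshot(5L, seed = 11L)
  gr <- suppressWarnings(velocityGradient(s))
  sp <- strainSpinSplit(gr)
  q <- qCriterionDensity(sp)@values
  d <- dim(s@mask@inside)
  for (vox in which(s@mask@inside)[1:25]) {
    ijk <- arrayInd(vox, d)
    D <- matrix(sp@D[ijk[1], ijk[2], ijk[3], , ], 3, 3)
    A <- matrix(sp@A[ijk[1], ijk[2], ijk[3], , ], 3, 3)
    ev <- eigen(D %*% D + A %*% A, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev), -2 * q[vox], tolerance = 1e-10)
  }
})

test_that("all six densities match the brute-force oracle on a random field", {
  s <- randomMaskedSnapshot(5L, seed = 123L)
  impl <- suppressWarnings(allDensities(s))
  orac <- oracleDensities(s@u, s@mask@inside, s@grid@spacing)
  ins <- s@mask@inside
  for (nm in names(orac)) {
    a <- impl[[nm]]@values[ins]
    b <- orac[[nm]][ins]
    rel <- max(abs(a - b)) / max(1e-300, max(abs(b)))
    expect_lt(rel, 1e-10)
  }
})

test_that("boundary stencils degrade gracefully and flag degenerate voxels", {
  # a single-voxel-thick line in y: no neighbours along x at the ends is
  # fine, but a lone voxel has no neighbours along any axis
  g <- gridSpec(c(5, 5, 1), 0.1)
  ins <- array(FALSE, dim = c(5, 5, 1))
  ins[2:4, 2:4, 1] <- TRUE
  ins[1, 1, 1] <- TRUE  # isolated voxel
  mask <- domainMask(g, ins)
  u <- array(1, dim = c(5, 5, 1, 3))
  s <- makeLinearSnapshot(g, mask, u)
  expect_warning(gr <- velocityGradient(s), "degenerate")
  expect_equal(gr@quality[1, 1, 1], 0L)
  expect_equal(max(abs(gr@g[1, 1, 1, , ])), 0)
  expect_equal(gr@quality[3, 3, 1], 2L)  # central along both active axes
  expect_equal(gr@quality[2, 2, 1], 1L)  # one-sided at the block corner
})
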