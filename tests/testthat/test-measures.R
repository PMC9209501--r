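test_that("volume averaging reproduces constants and closed forms", {
  g <- gridSpec(c(6, 6, 6), 0.2)
  mask <- domainMask(g)
  expect_equal(volumeAverage(array(5, dim = c(6, 6, 6)), mask), 5)
  # rigid rotation: vorticity-magnitude density is 2 everywhere (linear
  # field, one-sided boundary stencils are exact too)
  rot <- linearFieldSnapshot(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3,
                                    byrow = TRUE))
  om <- vorticityField(velocityGradient(rot))
  expect_equal(volumeAverage(vorticityMagnitudeDensity(om)), 2,
               tolerance = 1e-12)
  expect_error(volumeAverage(array(1, dim = c(2, 2, 2)), mask), "disagree")
})

test_that("ABC volume-averaged helicity approaches a^2 + b^2 + c^2", {
  # Beltrami flow: helicity density ||u||^2, continuous mean 3 for unit
  # amplitudes; discrete error must shrink at second order
  err <- vapply(c(16L, 32L), function(n) {
    abs(volumeAverage(helicityDensity(abcField(periodicGrid(n)))) - 3)
  }, numeric(1))
  h2 <- (2 * pi / c(16, 32))^2
  expect_lt(err[1], h2[1])
  expect_lt(err[2], h2[2])
  expect_gt(err[1] / err[2], 3)
})

test_that("time averaging is the rectangle rule on [start, end)", {
  t <- seq(0, 4, by = 0.001)[-4001]
  expect_equal(timeAverage(rep(7, 4000), t, c(0, 4)), 7)
  s <- sin(2 * pi * t / 4)
  expect_lt(abs(timeAverage(s, t, c(0, 4))), 1e-12)
  expect_equal(timeAverage(s, t, c(0, 2)), 2 / pi, tolerance = 1e-3)
  expect_error(timeAverage(s, t, c(5, 6)), "window")
})

test_that("whole-cycle values equal the mean of equal phase windows", {
  # the aggregation arithmetic behind the published per-patient tables
  t <- seq(0, 4, by = 0.01)[-401]
  twoPhase <- function(e, i) ifelse(t < 2, e, i)
  agg <- function(e, i) timeAverage(twoPhase(e, i), t, c(0, 4))
  expect_equal(agg(26.52, 29.63), (26.52 + 29.63) / 2)
  expect_equal(agg(165.99, 87.82), 126.905)
})

test_that("nasal resistance integrates pressure drop against flow", {
  t <- seq(0, 4, by = 0.01)[-401]
  expect_equal(nasalResistance(rep(10, 400), rep(100, 400), t, c(0, 4)), 0.1)
  flow <- 267 * sin(2 * pi * t / 4)
  expect_equal(nasalResistance(0.05 * flow, flow, t, c(0, 2)), 0.05)
  expect_equal(nasalResistance(0.05 * flow, flow, t, c(2, 4)), 0.05)
  expect_error(nasalResistance(rep(1, 400), rep(0, 400), t, c(0, 4)),
               "undefined")
})

test_that("probe flux sums normal velocity times face area", {
  g <- gridSpec(c(10, 12, 1), 0.001)
  ins <- array(FALSE, dim = c(10, 12, 1))
  ins[, 2:11, ] <- TRUE
  mask <- domainMask(g, ins)
  u <- array(0, dim = c(10, 12, 1, 3))
  u[, , , 1] <- 1  # uniform unit x-velocity
  s <- methods::new("VelocitySnapshot", grid = g, mask = mask, u = u,
                    p = numeric(0), time = 0)
  fs <- methods::new("FlowSeries", snapshots = list(s), times = 0,
                     mask = mask,
                     scalars = data.frame(t = 0, flow_ml_s = NA_real_,
                                          dp_pa = NA_real_, cfl = NA_real_,
                                          max_div = NA_real_),
                     snapshotEvery = 1L)
  fx <- ostiumFlux(fs, list(axis = 1L, index = 5L))
  # 10 voxels across at unit depth: 10 * (h * 1 m) * 1 m/s = 0.01 m^3/s
  expect_equal(fx@flux, 10 * 0.001 * 1e6)
  # span restriction takes half the voxels
  fx2 <- ostiumFlux(fs, list(axis = 1L, index = 5L,
                             span = list(j = 2:6)))
  expect_equal(fx2@flux, 5 * 0.001 * 1e6)
  expect_error(ostiumFlux(fs, list(axis = 2L, index = 1L)), "intersect")
})

test_that("reversal counting respects the deadband", {
  expect_equal(countFlowReversals(c(1, 1, 1)), 0L)
  expect_equal(countFlowReversals(c(1, -1, 1)), 2L)
  expect_equal(countFlowReversals(c(0.5, -0.001, 0.7), deadband = 0.01), 0L)
  expect_equal(countFlowReversals(c(0.5, -0.2, 0.7, -0.3), deadband = 0.01),
               3L)
  expect_error(countFlowReversals(c(1, -1), deadband = -1), "non-negative")
})

test_that("measure tables aggregate phases and satisfy their invariants", {
  wf <- breathingWaveform(amplitude = 50, period = 2, nSteps = 16L)
  base <- abcField(periodicGrid(10L))
  fs <- modulatedSeries(base, wf)
  tb <- computeMeasureTable(fs, waveform = wf)
  m <- measureTable(tb)
  # equal windows: e+i is the mean of e and i for every measure
  for (r in rownames(m)) {
    if (is.na(m[r, "e"])) next
    expect_equal(m[r, "ei"], (m[r, "e"] + m[r, "i"]) / 2, tolerance = 1e-12)
  }
  # Jensen: mean of ||Omega||^2/2 dominates (mean ||Omega||)^2 / 2
  for (ph in c("e", "i", "ei"))
    expect_gte(m["enstrophy", ph], m["vort_mag", ph]^2 / 2 - 1e-9)
  # |H| >= |H signed| is enforced by the class validity as well
  expect_gte(m["abs_helicity", "ei"], abs(m["helicity", "ei"]))
  expect_true(is.na(m["NR", "e"]))  # no pressure series attached
  expect_equal(volumeMl(tb), volumeMl(base@mask))

  # identical snapshots: every phase triple is constant
  wfc <- breathingWaveform(amplitude = 1, period = 2, nSteps = 8L)
  sameSnaps <- lapply(wfc@times, function(tt) {
    s <- base; s@time <- tt; s
  })
  fs2 <- methods::new("FlowSeries", snapshots = sameSnaps, times = wfc@times,
                      mask = base@mask,
                      scalars = data.frame(t = wfc@times,
                                           flow_ml_s = NA_real_,
                                           dp_pa = NA_real_, cfl = NA_real_,
                                           max_div = NA_real_),
                      snapshotEvery = 1L)
  tb2 <- measureTable(computeMeasureTable(fs2, waveform = wfc))
  for (r in c("enstrophy", "helicity", "q", "vort_mag"))
    expect_equal(tb2[r, "e"], tb2[r, "i"], tolerance = 1e-12)
})

test_that("global balance links Q, strain power and enstrophy", {
  # pointwise q + ||D||^2/2 = ||A||^2/2 = enstrophy/2 carries over to the
  # double-bar measures
  wf <- breathingWaveform(amplitude = 30, period = 2, nSteps = 12L)
  fs <- modulatedSeries(abcField(periodicGrid(10L)), wf)
  wins <- phaseWindows(wf)
  perSnap <- vapply(fs@snapshots, function(s) {
    gr <- velocityGradient(s)
    sp <- strainSpinSplit(gr)
    om <- vorticityField(gr)
    nD2 <- apply(sp@D^2, 1:3, sum)
    c(q = volumeAverage(qCriterionDensity(sp)),
      halfD2 = volumeAverage(nD2, s@mask) / 2,
      halfE = volumeAverage(enstrophyDensity(om)) / 2)
  }, numeric(3))
  qbar <- timeAverage(perSnap["q", ], fs@times, wins$ei)
  d2bar <- timeAverage(perSnap["halfD2", ], fs@times, wins$ei)
  ebar <- timeAverage(perSnap["halfE", ], fs@times, wins$ei)
  expect_equal(qbar + d2bar, ebar, tolerance = 1e-10)
})
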