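test_that("zero inflow stays identically at rest", {
  mask <- channelMask(16L, 6L, 1e-3)
  cfg <- solverConfig(nu = 1e-4, dt = 5e-4, nSteps = 20L, snapshotEvery = 10L)
  fs <- solveFlow(mask, 0, cfg)
  for (k in seq_len(nSnapshots(fs)))
    expect_equal(max(abs(snapshotAt(fs, k)@u)), 0)
  expect_equal(max(abs(fs@scalars$dp_pa)), 0)
})

test_that("projection enforces mass conservation; skipping it does not", {
  mask <- channelMask(24L, 8L, 1e-3)
  cfg <- solverConfig(nu = 1e-4, dt = 2e-4, nSteps = 50L, snapshotEvery = 50L)
  fs <- solveFlow(mask, 10, cfg)
  mc <- checkMassConservation(fs)
  expect_lt(mc$maxRelImbalance, 1e-6)
  # negative control: without the pressure projection the outlet flux never
  # learns about the inlet and the imbalance is order one
  fs0 <- solveFlow(mask, 10, cfg, project = FALSE)
  mc0 <- checkMassConservation(fs0)
  expect_gt(mc0$maxRelImbalance, 1e3 * mc$maxRelImbalance)
})

test_that("compiled predictor matches the R reference stencil", {
  set.seed(5)
  mask <- channelMask(14L, 7L, 1e-3)
  cfg <- solverConfig(nu = 1e-4, dt = 1e-4, nSteps = 1L)
  st <- sinusflow:::.solverSetup(mask, cfg)
  d <- st$d; h <- st$h
  U <- array(0, dim = c(d[1] + 1L, d[2], d[3]))
  V <- array(0, dim = c(d[1], d[2] + 1L, d[3]))
  U[st$Ufluid] <- rnorm(sum(st$Ufluid), sd = 0.01)
  V[st$Vfluid] <- rnorm(sum(st$Vfluid), sd = 0.01)
  advU <- list(U, sinusflow:::.faceAvg(V, from = 2L, to = 1L, d = d), NULL)
  refU <- sinusflow:::.predictFace(U, st$nbrU, advU, st$fluidIdxU, h,
                                   cfg@nu, cfg@dt)
  cppU <- sinusflow:::.predictFaceCpp(
    U, dim(U), 1L, V, dim(V), 2L, numeric(0), integer(0), 3L,
    as.numeric(st$nbrU[[1]]$kp), as.numeric(st$nbrU[[1]]$km),
    as.numeric(st$nbrU[[2]]$kp), as.numeric(st$nbrU[[2]]$km),
    numeric(0), numeric(0), st$fluidIdxU, h, cfg@nu, cfg@dt)
  expect_equal(array(cppU, dim = dim(U)), refU, tolerance = 1e-14)
})

test_that("runs are deterministic and reject unstable time steps", {
  mask <- channelMask(16L, 6L, 1e-3)
  cfg <- solverConfig(nu = 1e-4, dt = 2e-4, nSteps = 15L, snapshotEvery = 5L)
  a <- solveFlow(mask, 8, cfg)
  b <- solveFlow(mask, 8, cfg)
  expect_identical(a@scalars, b@scalars)
  expect_identical(snapshotAt(a, 3L)@u, snapshotAt(b, 3L)@u)
  # a flow fast enough to break the advective CFL limit aborts with the step
  expect_error(
    suppressWarnings(solveFlow(mask, 1e5,
                               solverConfig(nu = 1e-4, dt = 5e-3,
                                            nSteps = 10L))),
    "CFL")
  expect_warning(solverConfig(nu = 1, dt = 1, nSteps = 1L) -> cfgBad,
                 NA)  # config itself carries no warning; solveFlow checks
  expect_warning(solveFlow(mask, 0, solverConfig(nu = 1, dt = 1,
                                                 nSteps = 1L)),
                 "stability")
})

test_that("masks that do not reach the inlet or outlet are rejected", {
  g <- gridSpec(c(10, 6, 1), 1e-3)
  ins <- array(TRUE, dim = c(10, 6, 1))
  ins[1, , ] <- FALSE
  expect_error(
    solveFlow(domainMask(g, ins), 1,
              solverConfig(nu = 1e-4, dt = 1e-4, nSteps = 1L)),
    "inlet")
})
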