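test_that("analytic fields take their closed-form pointwise values", {
  g <- gridSpec(c(9, 9, 1), 0.1)
  # rigid rotation: zero at the centre, tangential speed omega * r
  s <- rigidRotationField(g, omega = 2)
  expect_equal(s@u[5, 5, 1, ], c(0, 0, 0))
  expect_equal(s@u[5, 7, 1, 1], -2 * 0.2)  # u_x = -omega * y'
  s0 <- rigidRotationField(g, omega = 0)
  expect_true(all(s0@u == 0))

  # ABC at the origin: u = (c, a, b); zero field for zero amplitudes
  ga <- periodicGrid(8L)
  expect_equal(abcField(ga, 1, 2, 3)@u[1, 1, 1, ], c(3, 1, 2))
  expect_true(all(abcField(ga, 0, 0, 0)@u == 0))

  # Taylor-Green: u = (sin x cos y, -cos x sin y, 0), analytically
  # divergence-free
  gt <- periodicGrid(16L, planar = TRUE)
  tg <- taylorGreenField(gt)
  cc <- sinusflow:::coordArrays(gt)
  expect_equal(tg@u[, , , 1], array(sin(cc$x) * cos(cc$y), dim = c(16, 16)),
               ignore_attr = TRUE)
  expect_equal(tg@u[3, 5, 1, 2], -cos(cc$x[3, 1, 1]) * sin(cc$y[1, 5, 1]))

  # plane Poiseuille: centreline u_max, beyond-wall clamp at zero
  gp <- gridSpec(c(20, 11, 1), 0.001)
  ps <- poiseuilleField(gp, uMax = 1.5, halfWidth = 0.0055)
  expect_equal(max(ps@u[, , , 1]), 1.5, tolerance = 1e-12)
  expect_equal(ps@u[10, 6, 1, 1], 1.5)
  expect_error(poiseuilleField(gp, 1, halfWidth = 0.02), "inconsistent")
})

test_that("airway phantom rasterises to the expected fluid volume", {
  spec <- phantomSpec()
  h <- 3e-4
  m <- airwayPhantom(spec, h)
  r <- phantomRegions(spec, h)
  counted <- length(r$channelRows) * r$nxChannel +
    length(r$ostiumCols) * length(r$wallRows) +
    length(r$cavityCols) * length(r$cavityRows)
  expect_equal(sum(insideArray(m)), counted)
  # within one voxel layer of perimeter of the continuous areas
  analytic <- spec@channelLength * spec@channelWidth +
    spec@cavityWidth * spec@cavityHeight
  perim <- 2 * (spec@channelLength + spec@channelWidth +
                  spec@cavityWidth + spec@cavityHeight) * h
  expect_lt(abs(volumeM3(m) - analytic), perim + 4 * h^2)
})

test_that("constriction strictly shrinks the phantom volume", {
  h <- 3e-4
  v <- vapply(c(0, 0.25, 0.5, 0.75), function(f)
    volumeM3(airwayPhantom(phantomSpec(constrictionFraction = f), h)),
    numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("phantom connectivity runs only through the ostium", {
  spec <- phantomSpec()
  h <- 3e-4
  m <- airwayPhantom(spec, h)
  r <- phantomRegions(spec, h)
  flood <- function(ins) {
    d <- dim(ins)
    lab <- array(FALSE, d)
    start <- which(ins)[1]
    queue <- start
    lab[start] <- TRUE
    strides <- c(1L, d[1], d[1] * d[2])
    coord <- function(f, ax) switch(ax, (f - 1L) %% d[1] + 1L,
                                    ((f - 1L) %/% d[1]) %% d[2] + 1L,
                                    (f - 1L) %/% (d[1] * d[2]) + 1L)
    while (length(queue)) {
      f <- queue[length(queue)]
      queue <- queue[-length(queue)]
      for (ax in 1:3) {
        if (d[ax] == 1L) next
        for (s in c(-strides[ax], strides[ax])) {
          cpos <- coord(f, ax) + sign(s)
          if (cpos < 1L || cpos > d[ax]) next
          nb <- f + s
          if (ins[nb] && !lab[nb]) {
            lab[nb] <- TRUE
            queue <- c(queue, nb)
          }
        }
      }
    }
    lab
  }
  ins <- insideArray(m)
  expect_equal(sum(flood(ins)), sum(ins))  # one 4-connected component
  # sealing the ostium disconnects the cavity from the channel
  sealed <- ins
  sealed[, r$wallRows, ] <- FALSE
  reach <- flood(sealed)
  cavityVox <- sum(sealed[, r$cavityRows, ])
  expect_equal(sum(reach), sum(sealed) - cavityVox)
})

test_that("degenerate phantom parameters are rejected", {
  expect_error(phantomSpec(ostiumWidth = 0), "positive")
  expect_error(airwayPhantom(phantomSpec(ostiumWidth = 1e-4), 3e-4),
               "at least 2 voxels")
  expect_error(phantomSpec(constrictionFraction = 1), "\\[0, 1\\)")
})

test_that("modulated series scales densities linearly and quadratically", {
  wf <- breathingWaveform(amplitude = 100, period = 2, nSteps = 8L)
  base <- abcField(periodicGrid(8L))
  fs <- modulatedSeries(base, wf)
  expect_equal(nSnapshots(fs), 8L)
  # snapshot at t = T/2 is the zero field
  expect_true(all(abs(snapshotAt(fs, 5L)@u) < 1e-12))
  bd <- allDensities(base)
  baseE <- volumeAverage(bd$enstrophy)
  baseH <- volumeAverage(bd$helicity)
  baseVM <- volumeAverage(bd$vort_mag)
  k <- 2L
  sc <- wf@samples[k] / wf@amplitude
  dk <- allDensities(snapshotAt(fs, k))
  expect_equal(volumeAverage(dk$enstrophy), sc^2 * baseE, tolerance = 1e-12)
  expect_equal(volumeAverage(dk$helicity), sc^2 * baseH, tolerance = 1e-12)
  expect_equal(volumeAverage(dk$vort_mag), abs(sc) * baseVM,
               tolerance = 1e-12)
})
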