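test_that("sinusoidal waveform reproduces the breathing-cycle arithmetic", {
  wf <- breathingWaveform(amplitude = 267, period = 4, nSteps = 4000L)
  # peak of the sine at quarter period; zero at t = 0
  expect_equal(flowRateAt(wf, 1), 267)
  expect_equal(flowRateAt(wf, 0), 0)
  expect_equal(flowRateAt(wf, 2), 0, tolerance = 1e-12)
  # tidal volume: analytic A T / pi, cross-checked by quadrature
  expect_equal(tidalVolumeMl(wf), 267 * 4 / pi, tolerance = 1e-6)
  expect_equal(wf@dt, 0.001)
})

test_that("waveform satisfies antisymmetry and zero net volume", {
  wf <- breathingWaveform(amplitude = 120, period = 3, nSteps = 600L)
  half <- length(wf@samples) / 2
  anti <- wf@samples[seq_len(half)] + wf@samples[half + seq_len(half)]
  expect_lt(max(abs(anti)), 1e-9 * wf@amplitude)
  # what goes in comes out over a full cycle
  expect_lt(abs(sum(wf@samples) * wf@dt), 1e-9 * wf@amplitude * wf@period)
  # first half expiration, second inspiration
  expect_true(all(wf@phase[seq_len(half)] == "expiration"))
  expect_true(all(wf@phase[half + seq_len(half)] == "inspiration"))
})

test_that("invalid waveform parameters are rejected", {
  expect_error(breathingWaveform(amplitude = -1), "positive")
  expect_error(breathingWaveform(period = 0), "positive")
  expect_error(breathingWaveform(nSteps = 2L), "at least 4")
})

test_that("phase windows partition the cycle", {
  wf <- breathingWaveform(nSteps = 100L)
  w <- phaseWindows(wf)
  expect_equal(w$e, c(0, 2))
  expect_equal(w$i, c(2, 4))
  expect_equal(w$ei, c(0, 4))
})
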