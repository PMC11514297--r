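test_that("Poisson-gap schedules hit the exact count with early weighting", {
  for (seed in c(1, 7, 33)) {
    s <- poissonGap(128L, 0.5, seed)
    idx <- scheduleIndices(s)
    expect_length(idx, 64L)
    expect_true(0L %in% idx)
    expect_false(any(duplicated(idx)))
    expect_true(all(idx >= 0 & idx < 128))
    expect_false(is.unsorted(idx, strictly = TRUE))
  }
  ## complete sampling
  expect_identical(scheduleIndices(poissonGap(16L, 1, 3)), 0:15)
  ## sinusoidal gap weighting front-loads the schedule
  means <- vapply(1:100, function(s)
    mean(scheduleIndices(poissonGap(128L, 0.5, s))), numeric(1))
  expect_lt(mean(means), 64)
  ## determinism
  expect_identical(scheduleIndices(poissonGap(128L, 0.5, 5)),
                   scheduleIndices(poissonGap(128L, 0.5, 5)))
  expect_error(poissonGap(128L, 0, 1), "fraction")
  expect_error(poissonGap(128L, 1.2, 1), "fraction")
})

test_that("IST completes Echo-only data of a noiseless single peak", {
  cfg <- simConfig(nIndirect = 32L, nDirect = 32L, nExponentials = 1L,
                   snr = Inf, tauIndirectRange = c(64, 320),
                   tauDirectRange = c(1.6, 16))
  S <- processSpectrum(synthesizeFid(
    onePeak(freq1 = 0.25, freq2 = -0.125, tau1 = 160, tau2 = 8), cfg))
  e <- echoSpectrum(S, "echo")
  cs <- istConfig(nIterations = 200L, noiseFloorFactor = 0)
  rec <- csEcho(e, cs)
  expect_lt(rmsOverMax(specValues(rec), specValues(S)), 1e-3)
  ## data consistency: the reconstruction's VE equals the measured data on
  ## the interior known support
  veKnown <- stats::fft(specValues(e), inverse = TRUE) / prod(dim(e))
  veRec <- stats::fft(specValues(rec), inverse = TRUE) / prod(dim(rec))
  M <- quadrantWeights(dim(e), "echo")
  expect_lt(max(abs((veRec - veKnown)[M == 1])) / max(abs(veKnown)), 1e-10)
  ## zero input returns zero without iterating forever
  zp <- completionProblem(matrix(0 + 0i, 8, 8), quadrantWeights(c(8, 8),
                                                                "echo"))
  expect_equal(specValues(istComplete(zp)), matrix(0, 8, 8))
})

test_that("IST is scale-equivariant and its residual history shrinks", {
  cfg <- tinyCfg(snr = Inf)
  S <- processSpectrum(synthesizeFid(sampleParams(cfg, 4), cfg))
  e <- echoSpectrum(S, "echo")
  cs <- istConfig(nIterations = 80L)
  r1 <- csEcho(e, cs)
  r2 <- csEcho(newEchoSpectrum(specValues(e) * 3.7, "echo"), cs)
  expect_lt(relMaxErr(specValues(r2), 3.7 * specValues(r1)), 1e-12)
  res <- residualHistory(r1)
  expect_length(res, 80L)
  expect_lt(res[length(res)], res[1])
  ## non-increasing residual up to numerical jitter
  expect_lt(max(diff(res)), 1e-8 * res[1])
})

test_that("Echo and Anti-Echo completions mirror each other exactly", {
  cfg <- tinyCfg(snr = Inf)
  S <- processSpectrum(synthesizeFid(sampleParams(cfg, 12), cfg))
  cs <- istConfig(nIterations = 120L, noiseFloorFactor = 0)
  recE <- csEcho(echoSpectrum(S, "echo"), cs)
  recA <- csEcho(echoSpectrum(S, "anti_echo"), cs)
  ## reflection equivariance: reconstructing the reflected spectrum's Echo
  ## data equals the reflected Anti-Echo reconstruction, to machine precision
  SR <- absorptiveSpectrum(reflectIndirect(specValues(S)))
  recER <- csEcho(echoSpectrum(SR, "echo"), cs)
  expect_lt(relMaxErr(reflectIndirect(specValues(recER)),
                      specValues(recA)), 1e-10)
  ## both flavors recover the reference on balanced data
  expect_lt(rmsOverMax(specValues(recE), specValues(S)), 2e-2)
  expect_lt(rmsOverMax(specValues(recA), specValues(S)), 2e-2)
  expect_lt(rmsOverMax(specValues(recE), specValues(recA)),
            4e-2)
  ## zero echo spectrum reconstructs to zero
  z <- newEchoSpectrum(matrix(0, 8, 8), "echo")
  expect_equal(specValues(csEcho(z, istConfig(nIterations = 5L))),
               matrix(0, 8, 8))
})

test_that("NUS reconstruction honors the schedule and recovers peaks", {
  cfg <- scaledSimConfig(16L, 16L, snr = Inf)
  fid <- synthesizeFid(sampleParams(cfg, 3), cfg)
  S <- processSpectrum(fid)
  ## full schedule: the reconstruction returns the input within tolerance
  full <- poissonGap(16L, 1, 9)
  recF <- csNus(S, full, istConfig(nIterations = 100L))
  expect_lt(relMaxErr(specValues(recF), specValues(S)), 1e-3)
  ## 50% Poisson-gap schedule on well-separated noiseless peaks
  cfg5 <- simConfig(nIndirect = 16L, nDirect = 32L, nExponentials = 5L,
                    snr = Inf, tauIndirectRange = c(32, 160),
                    tauDirectRange = c(1.6, 16))
  p5 <- data.frame(amplitude = c(1, 0.8, 0.6, 0.5, 0.4),
                   freq1 = c(-0.4, -0.2, 0, 0.2, 0.4),
                   freq2 = c(0.3, -0.3, 0.1, -0.1, 0.45),
                   phase1 = 0, phase2 = 0, tau1 = 80, tau2 = 10)
  S5 <- processSpectrum(synthesizeFid(p5, cfg5))
  sched <- poissonGap(16L, 0.5, 21)
  nus <- nusCorrupt(synthesizeFid(p5, cfg5), sched)
  rec <- csNus(nus, sched, istConfig(nIterations = 200L,
                                     noiseFloorFactor = 0))
  expect_lt(rmsOverMax(specValues(rec), specValues(S5)), 1e-2)
  ## sampled-row consistency in the VE presentation
  veIn <- stats::fft(specValues(nus), inverse = TRUE) / prod(dim(nus))
  veRec <- stats::fft(specValues(rec), inverse = TRUE) / prod(dim(rec))
  rows <- scheduleIndices(sched) + 1L
  expect_lt(max(abs((veRec - veIn)[rows, ])) / max(abs(veIn)), 1e-10)
})
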