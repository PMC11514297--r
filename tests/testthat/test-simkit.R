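test_that("parameter sampling respects ranges, count and seed", {
  cfg <- simConfig()
  p <- sampleParams(cfg, 42)
  expect_equal(nrow(p), 512L)
  expect_true(all(p$amplitude >= -0.2 & p$amplitude <= 1))
  expect_true(all(p$freq1 >= -0.5 & p$freq1 <= 0.5))
  expect_true(all(p$freq2 >= -0.5 & p$freq2 <= 0.5))
  expect_true(all(abs(p$phase1) <= 3 & abs(p$phase2) <= 3))
  expect_true(all(p$tau1 >= 256 & p$tau1 <= 1280))
  expect_true(all(p$tau2 >= 12.8 & p$tau2 <= 128))
  expect_identical(p, sampleParams(cfg, 42))
  expect_false(identical(p, sampleParams(cfg, 43)))
  empty <- sampleParams(simConfig(nExponentials = 0L), 1)
  expect_equal(nrow(empty), 0L)
  expect_error(simConfig(ampRange = c(1, -0.2)), "lo <= hi")
})

test_that("FID synthesis matches the damped-exponential model", {
  cfg <- simConfig(nIndirect = 8L, nDirect = 16L, nExponentials = 1L,
                   snr = Inf)
  ## zero-frequency, zero-phase, undamped: every sample is 1
  fid <- synthesizeFid(onePeak(), cfg)
  expect_equal(fidP(fid), matrix(1 + 0i, 8, 16))
  expect_equal(fidN(fid), matrix(1 + 0i, 8, 16))
  ## direct formula check: w1 = 1/4 cycle/dwell puts e^{i pi/2} = i at t1 = 1
  fid <- synthesizeFid(onePeak(freq1 = 0.25), cfg)
  expect_equal(fidP(fid)[2, 1], 0 + 1i)
  expect_equal(fidN(fid)[2, 1], 0 - 1i)
  ## linearity in the parameter list and in amplitudes
  pA <- onePeak(amplitude = 0.7, freq1 = 0.1, freq2 = -0.3, tau1 = 40,
                tau2 = 6)
  pB <- onePeak(amplitude = -0.2, freq1 = -0.4, freq2 = 0.2, phase1 = 2,
                tau1 = 25, tau2 = 9)
  fAB <- synthesizeFid(rbind(pA, pB), cfg)
  fA <- synthesizeFid(pA, cfg)
  fB <- synthesizeFid(pB, cfg)
  expect_equal(fidP(fAB), fidP(fA) + fidP(fB))
  expect_equal(fidN(fAB), fidN(fA) + fidN(fB))
  p2 <- pA; p2$amplitude <- 2 * p2$amplitude
  expect_equal(fidP(synthesizeFid(p2, cfg)), 2 * fidP(fA))
  ## with a real direct factor (w2 = 0, phases 0) the N-type signal is the
  ## complex conjugate of the P-type signal: only the indirect phase flips
  pC <- onePeak(freq1 = 0.15, tau1 = 30, tau2 = 7)
  fC <- synthesizeFid(pC, cfg)
  expect_equal(fidN(fC), Conj(fidP(fC)))
  ## the indirect envelope decays by default and grows under the flag
  pDecay <- onePeak(tau1 = 4, tau2 = Inf)
  fd <- synthesizeFid(pDecay, cfg)
  expect_lt(Mod(fidP(fd)[8, 1]), Mod(fidP(fd)[1, 1]))
  cfgG <- simConfig(nIndirect = 8L, nDirect = 16L, nExponentials = 1L,
                    snr = Inf, literalIndirectGrowth = TRUE)
  fg <- synthesizeFid(pDecay, cfgG)
  expect_gt(Mod(fidP(fg)[8, 1]), Mod(fidP(fg)[1, 1]))
  ## empty parameter list gives the zero signal
  z <- synthesizeFid(sampleParams(simConfig(nExponentials = 0L), 1),
                     simConfig(nIndirect = 4L, nDirect = 4L,
                               nExponentials = 0L, snr = Inf))
  expect_equal(fidP(z), matrix(0 + 0i, 4, 4))
})

test_that("noise injection has the configured statistics", {
  k <- 128L; l <- 256L
  clean <- hypercomplexFid(matrix(0 + 0i, k, l), matrix(0 + 0i, k, l))
  expect_identical(addNoise(clean, Inf, 1), clean)
  noisy <- addNoise(clean, 500, 7)
  draws <- c(Re(fidP(noisy)), Im(fidP(noisy)), Re(fidN(noisy)),
             Im(fidN(noisy)))
  expect_gte(length(draws), 1e5)
  expect_lt(abs(sd(draws) - 1 / 500) / (1 / 500), 0.05)
  expect_lt(abs(mean(draws)), 5 * (1 / 500) / sqrt(length(draws)))
  ## distinct seeds give distinct realizations; P and N noise are independent
  noisy2 <- addNoise(clean, 500, 8)
  expect_false(identical(fidP(noisy), fidP(noisy2)))
  expect_lt(abs(cor(Re(as.vector(fidP(noisy))),
                    Re(as.vector(fidN(noisy))))), 0.02)
  expect_error(addNoise(clean, 0, 1), "positive")
  expect_error(addNoise(clean, -2, 1), "positive")
})

test_that("P-type imbalance scales only the P component", {
  cfg <- simConfig(nIndirect = 8L, nDirect = 16L, nExponentials = 1L,
                   snr = Inf)
  fid <- synthesizeFid(onePeak(freq1 = 0.2, freq2 = -0.1, tau1 = 20,
                               tau2 = 8), cfg)
  imb <- applyImbalance(fid, 0.10)
  expect_equal(max(Mod(fidP(imb))) / max(Mod(fidN(imb))), 0.9)
  expect_identical(fidN(imb), fidN(fid))
  expect_identical(applyImbalance(fid, 0), fid)
  expect_error(applyImbalance(fid, 1), "\\[0, 1\\)")
  expect_error(applyImbalance(fid, -0.1), "\\[0, 1\\)")
  ## the imbalanced reference spectrum keeps a residual twist
  sBal <- processSpectrum(fid)
  sImb <- processSpectrum(imb)
  expect_gt(rmsd(sImb, sBal), 0)
})

test_that("pair generation is reproducible, distinct and self-consistent", {
  cfg <- tinyCfg(snr = 500)
  pairs <- generatePairs(cfg, 4, mode = "echo", seed = 9)
  expect_equal(length(pairs), 4L)
  ## a pair's input is exactly the Echo spectrum of its reference
  e1 <- echoSpectrum(pairReferences(pairs)[[1]], "echo")
  expect_equal(specValues(pairInputs(pairs)[[1]]), specValues(e1))
  ## pairwise distinct under distinct derived seeds
  for (i in 1:3)
    expect_gt(max(abs(specValues(pairReferences(pairs)[[i]]) -
                        specValues(pairReferences(pairs)[[i + 1]]))), 0)
  ## bit-identical regeneration from the same master seed
  again <- generatePairs(cfg, 4, mode = "echo", seed = 9)
  expect_identical(specValues(pairInputs(pairs)[[2]]),
                   specValues(pairInputs(again)[[2]]))
  expect_error(generatePairs(cfg, 1, mode = "bogus", seed = 1))
  ## nus mode produces absorptive inputs on the same grid
  nusPairs <- generatePairs(cfg, 2, mode = "nus", seed = 9)
  expect_s4_class(pairInputs(nusPairs)[[1]], "AbsorptiveSpectrum")
  expect_equal(dim(pairInputs(nusPairs)[[1]]),
               dim(pairReferences(nusPairs)[[1]]))
})
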