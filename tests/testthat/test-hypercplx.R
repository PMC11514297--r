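test_that("processing maps on-grid exponentials to the predicted bins", {
  cfg <- simConfig(nIndirect = 8L, nDirect = 16L, nExponentials = 1L,
                   snr = Inf)
  ## zero FID in, zero spectrum out (linear operator null)
  z <- hypercomplexFid(matrix(0 + 0i, 8, 16), matrix(0 + 0i, 8, 16))
  expect_equal(specValues(processSpectrum(z)), matrix(0, 16, 32))
  ## discrete-FT oracle: w1 = 0.25 -> row 0.25*16 (0-based); w2 = -0.125 ->
  ## column (32 - 0.125*32) on the unshifted doubled grid
  fid <- synthesizeFid(onePeak(freq1 = 0.25, freq2 = -0.125), cfg)
  S <- processSpectrum(fid, apodization = "none", firstPointScale = 1)
  pk <- which(specValues(S) == max(specValues(S)), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(0.25 * 16 + 1, 32 - 0.125 * 32 + 1))
  ## DC peak sits at the origin
  S0 <- processSpectrum(synthesizeFid(onePeak(), cfg),
                        apodization = "none", firstPointScale = 1)
  pk0 <- which(specValues(S0) == max(specValues(S0)), arr.ind = TRUE)
  expect_equal(unname(pk0[1, ]), c(1, 1))
  expect_error(hypercomplexFid(matrix(0 + 0i, 8, 16),
                               matrix(0 + 0i, 8, 15)), "identical shape")
})

test_that("the Virtual Echo transform round-trips and is conjugate-symmetric", {
  cfg <- tinyCfg(snr = Inf)
  S <- processSpectrum(synthesizeFid(sampleParams(cfg, 7), cfg))
  ve <- toVirtualEcho(S)
  back <- fromVirtualEcho(ve)
  expect_lt(relMaxErr(specValues(back), specValues(S)), 1e-10)
  ## VE(-t) = Conj(VE(t)) on the doubled grid
  v <- specValues(ve)
  neg <- v[c(1, nrow(v):2), c(1, ncol(v):2)]
  expect_lt(max(abs(neg - Conj(v))) / max(abs(v)), 1e-10)
  ## a generic absorptive peak populates all four time quadrants
  w <- quadrantWeights(dim(v), "echo")
  quadP <- abs(v)[w == 1]
  quadN <- abs(v)[w == 0]
  expect_gt(max(quadP), 0)
  expect_gt(max(quadN), 0)
  ## zero VE -> zero spectrum
  zv <- new("VirtualEcho", values = matrix(0 + 0i, 4, 4), metadata = list())
  expect_equal(specValues(fromVirtualEcho(zv)), matrix(0, 4, 4))
})

test_that("quadrant projectors partition the identity", {
  dims <- c(8L, 8L)
  we <- quadrantWeights(dims, "echo")
  wa <- quadrantWeights(dims, "anti")
  expect_equal(we + wa, matrix(1, 8, 8))
  ## enumerate the index -> time map: interior N-quadrant indices have
  ## negative t1 and positive t2 (or vice versa), boundaries carry 1/2
  t <- function(i, M) ifelse(i - 1 < M / 2, i - 1, i - 1 - M)  # 1-based idx
  for (i in 1:8) for (j in 1:8) {
    t1 <- t(i, 8); t2 <- t(j, 8)
    onB <- (i - 1) %in% c(0, 4) || (j - 1) %in% c(0, 4)
    if (!onB) {
      expected <- as.numeric(sign(t1) == sign(t2))
      expect_identical(we[i, j], expected)
    }
  }
  expect_equal(we[1, 1], 0.5)   # t1 = t2 = 0 corner
  expect_equal(we[5, 3], 0.5)   # Nyquist row, positive t2
  ## projectors: applying both and summing reproduces the input
  set.seed(1)
  v <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  ve <- new("VirtualEcho", values = v, metadata = list())
  zN <- zeroQuadrants(ve, "N_side")
  zP <- zeroQuadrants(ve, "P_side")
  expect_equal(specValues(zN) + specValues(zP), v)
  ## idempotent on the interior quadrants
  zz <- zeroQuadrants(zN, "N_side")
  interior <- we == 1 | we == 0
  expect_equal(specValues(zz)[interior], specValues(zN)[interior])
  expect_error(zeroQuadrants(ve, "sideways"), "N_side")
})

test_that("Echo and Anti-Echo spectra carry the twist and sum to the input", {
  cfg <- tinyCfg(snr = Inf)
  S <- processSpectrum(synthesizeFid(sampleParams(cfg, 11), cfg))
  e <- echoSpectrum(S, "echo")
  a <- echoSpectrum(S, "anti_echo")
  ## partition of identity: S_Echo + S_Anti-Echo = S exactly
  expect_lt(relMaxErr(specValues(e) + specValues(a), specValues(S)), 1e-10)
  ## phase-twist signature: negative lobes appear even if S >= 0 around peaks
  expect_lt(min(specValues(e)), 0)
  expect_lt(min(specValues(a)), 0)
  ## both flavors stay real: their VE quadrant pairs are conjugate-symmetric
  expect_s4_class(e, "EchoSpectrum")
  expect_identical(echoFlavor(e), "echo")
  ## zero spectrum maps to zero
  z <- absorptiveSpectrum(matrix(0, 8, 8))
  expect_equal(specValues(echoSpectrum(z, "echo")), matrix(0, 8, 8))
  expect_error(echoSpectrum(S, "sideways"), "flavor")
  ## reflecting the indirect axis swaps the twist chirality exactly
  er <- echoSpectrum(absorptiveSpectrum(reflectIndirect(specValues(S))),
                     "echo")
  expect_equal(specValues(er), reflectIndirect(specValues(a)))
})

test_that("imbalanced P/N processing leaves a dispersive residual", {
  cfg <- simConfig(nIndirect = 8L, nDirect = 16L, nExponentials = 1L,
                   snr = Inf)
  fid <- synthesizeFid(onePeak(freq1 = 0.2, freq2 = -0.1, tau1 = 20,
                               tau2 = 8), cfg)
  sBal <- processSpectrum(fid)
  sImb <- processSpectrum(applyImbalance(fid, 0.10))
  resid <- specValues(sImb) - 0.95 * specValues(sBal)
  ## the residual is a twist component: substantial negative excursions
  expect_gt(max(resid), 0)
  expect_lt(min(resid), -0.1 * max(abs(resid)))
  expect_gt(rmsd(sImb, sBal), 1e-3)
})

test_that("NUS corruption zeroes increments consistently in both routes", {
  cfg <- scaledSimConfig(16L, 16L, snr = Inf)
  fid <- synthesizeFid(sampleParams(cfg, 3), cfg)
  S <- processSpectrum(fid)
  sched <- poissonGap(16L, 0.5, 9)
  nFid <- nusCorrupt(fid, sched)
  nSpec <- nusCorrupt(S, sched)
  expect_lt(relMaxErr(specValues(nFid), specValues(nSpec)), 1e-10)
  ## projection: corrupted spectrum has no more energy than the full one
  expect_lte(sum(specValues(nFid)^2), sum(specValues(S)^2))
  ## full schedule leaves the spectrum untouched
  full <- poissonGap(16L, 1, 9)
  expect_equal(specValues(nusCorrupt(fid, full)), specValues(S))
  ## schedule/grid mismatch is refused
  expect_error(nusCorrupt(fid, poissonGap(8L, 0.5, 1)), "increments")
})
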