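## Shared fixtures: all synthetic, generated in code at test time.

## Three-layer network sized for 16 x 32 test spectra (receptive field 7 x 15).
smallSpec <- function(filters = 16L) {
  wnnSpec(nLayers = 3L, filters = filters,
          kernels = rbind(c(2L, 4L), c(2L, 2L), c(2L, 2L)),
          dilations = rbind(c(1L, 1L), c(2L, 4L), c(4L, 8L)))
}

## Desk-scale configuration: 8 x 16 complex FID -> 16 x 32 spectra.
tinyCfg <- function(...) scaledSimConfig(8L, 16L, ...)

## One-exponential parameter row; tau = Inf gives an undamped signal.
onePeak <- function(amplitude = 1, freq1 = 0, freq2 = 0, phase1 = 0,
                    phase2 = 0, tau1 = Inf, tau2 = Inf) {
  data.frame(amplitude = amplitude, freq1 = freq1, freq2 = freq2,
             phase1 = phase1, phase2 = phase2, tau1 = tau1, tau2 = tau2)
}

relMaxErr <- function(a, b) {
  max(abs(a - b)) / max(abs(b))
}

rmsOverMax <- function(a, b) {
  sqrt(mean((a - b)^2)) / max(abs(b))
}
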