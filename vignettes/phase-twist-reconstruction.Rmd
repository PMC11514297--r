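---
title: "Reconstructing pure-absorption 2D NMR spectra from single Echo/Anti-Echo data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pure-absorption 2D NMR spectra from single Echo/Anti-Echo data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrtwist)
```

## The signal model

A gradient coherence-selection 2D experiment delivers two complex
time-domain matrices: the P-type (Echo) signal, modulated as
$e^{+i(2\pi\omega_1 t_1+\phi_1)}$ in the indirect evolution time, and the
N-type (Anti-Echo) signal with the opposite modulation sign.  The direct
dimension factor $e^{i(2\pi\omega_2 t_2+\phi_2)}e^{-t_2/\tau_2}$ is common
to both.  The simulator (`synthesizeFid()`) evaluates a sum of $N$ such
damped exponentials on the $k \times l$ complex grid, times indexed
$0,\dots,T-1$ per dimension.

One convention needs stating: the indirect envelope is implemented as a
decay $e^{-t_1/\tau_1}$, matching the direct dimension and the physical
interpretation of $\tau$ as a relaxation time.  A growing-envelope variant
(`literalIndirectGrowth = TRUE`) is available for users who want the
opposite sign, but a growing envelope contradicts FID physics and is not
the default.

### What the generator emulates — and what it does not

Default parameter ranges describe a ¹H-¹⁵N-correlation-like dataset:
128 × 256 complex points, 512 exponentials, frequencies uniform in
$[-0.5, 0.5]$ cycles/dwell, phases in $[-3°, 3°]$, amplitudes in
$[-0.2, 1]$, decay times 256–1280 (indirect) and 12.8–128 (direct) dwell
points, additive Gaussian noise at SNR 500.  SNR is defined as the maximum
attainable single-exponential amplitude (1) divided by the per-component
noise standard deviation; an SNR figure alone does not fix a noise scale,
and this convention pegs the noise to the amplitude scale.  Noise is drawn independently
for the P and N components because they are separate acquisitions.  The
optional imbalance operator scales only the P-type component by
$1-\text{deficit}$ and is applied *before* noise, since the amplitude
imbalance originates in the pulse sequence, not in the receiver.

The generator does not emulate pulse-sequence-specific transfer functions
(TROSY vs HSQC), solvent signals, or $t_1$-noise.  Tests passing on this
synthetic family therefore demonstrate correctness of the algorithms under
idealized peak statistics, not performance on pathological experimental
artifacts.

`scaledSimConfig()` shrinks the grid while preserving peak density
(exponentials per spectral point) and relative decay; desk-scale test
spectra (16 × 32 points, 2 exponentials) have the same character as the
full-size ones.  All randomness is seeded; per-pair seeds are derived from
the master seed by a counter scheme, so datasets are order-independent.

## Hypercomplex processing and the Virtual Echo

`processSpectrum()` converts the P/N pair into cosine/sine amplitude
modulation ($\cos = (X_P+X_N)/2$, $\sin = (X_P-X_N)/2i$), then performs
States-equivalent processing: cosine-squared apodization, zero-filling ×2,
complex FT of the direct dimension, real-part extraction, recombination
into the indirect interferogram and a second FT.  The first time-domain
point in each dimension is halved (the standard baseline-offset
correction).  Window, zero-fill, first-point scaling and zero-order phases are all
exposed as options; the defaults are ordinary choices for this kind of
data, not a prescription.  Synthetic phases ($\pm 3°$) are deliberately
*not* phase-corrected away — they remain as realistic imperfections.

The Virtual Echo of a real spectrum is its inverse 2D FT: a complex,
conjugate-symmetric array on the doubled grid whose four time quadrants
hold P, N and their time-reversed conjugates.  The index convention is the
standard unshifted FFT layout (index 0 is $t=0$, index $T$ the Nyquist
point, upper indices negative times).

**Boundary weighting.** The lines $t=0$ and Nyquist belong to both the
positive- and negative-time half in each dimension.  The quadrant
projectors give them weight $\tfrac12$ on each side, which makes
$Z_E + Z_N = \mathrm{Id}$ *exact* and yields the testable identity
$S_{\text{Echo}} + S_{\text{Anti-Echo}} = S$.  A hard assignment of the
shared lines would break both identities at order $1/T$; whether the
original implementation halves them is not documented, so the choice here
is driven by exactness.

## Compressed-sensing completion

Losing the N-type data zeroes the N quadrants of the VE; `csEcho()` poses
the reconstruction as completion of the missing quadrants and solves it by
iterative soft thresholding:
$x \leftarrow \mathrm{ST}_\lambda(\mathrm{FT}[\text{known} +
(1-M)\,\mathrm{iFT}[x]])$, with a final consistency projection restoring
the measured quadrants exactly (they are exact data).  The threshold
schedule is geometric from $0.9\cdot\max|\mathrm{FT}[\text{known}]|$ down
to a floor of $5\times$ the median absolute spectrum value (a crude noise
estimate), never below $10^{-8}$ of the maximum; 200 iterations by
default.  The exact parameterization used by existing CS software is not
published, so these are package defaults, all exposed in `istConfig()`.
For noiseless benchmarks the median-based floor overestimates the noise
(it sees signal tails); such tests pass `noiseFloorFactor = 0`.
Thresholds are proportional to the data maximum, so reconstruction
commutes with global rescaling.

The same solver handles NUS data (known support = sampled increments and
their mirrored negative-time rows).  `poissonGap()` generates the
schedules: Poisson-distributed gaps with a sinusoidally increasing mean
(dense sampling early), the rate tuned by bisection to hit the requested
count exactly, index 0 always kept.

## The dilated-convolution cascade

The reconstruction network is a five-layer dilated stack: layer 1 uses a
2×4 kernel without dilation, layer $m$ (2…5) a 2×2 kernel with dilation
$(2^{m-1}, 2^m)$, 50 filters per layer, ReLU activations, no padding, so
the receptive field shrinks a 63×127 input to a 32×64 output.  The
reduction from 50 channels to the single output channel is implemented as
a 1×1 linear convolution *without* a final ReLU, so negative spectral
values remain representable.

Full spectra are mapped onto network patches by a tiling scheme of the
package's own design:
output tiles partition the zero-padded spectrum without overlap (stride =
output extent), each input patch adds the receptive margin split 15/16
rows and 31/32 columns.  Normalization is per full spectrum by the
Euclidean norm of the *input*, applied to inputs and targets alike.

Five stages are trained sequentially, each on the corrected outputs of the
frozen upstream stages; the correction
$S^i_{\text{cor}} = S_{\text{Echo}} + C(i)\cdot
\mathrm{FT}[Z_E[\mathrm{iFT}[\tilde S^i]]]$ with
$C(i) = 1 - 0.05\cdot 2^{1-i}$ restores the measured quadrants while
attenuating the predicted ones, and is not applied after the final stage.
Anti-Echo data are handled by reflecting the indirect frequency axis —
which converts Anti-Echo twist into Echo twist exactly — and reusing
Echo-trained weights; a separate training run remains possible.

Training uses Adam (default learning rate $10^{-4}$, batch 64, MSE loss,
up to 1000 epochs) with a 90/10 train/validation split and early stopping
(patience 20), all in `trainConfig()`.  The split fraction and patience
are package choices.

**Problem sizes.** The package validates training at desk scale: 16×32
spectra (8×16 FIDs, 2 exponentials), 200 training pairs, one stage, ≤100
epochs, a three-layer 16-filter variant of the stack, learning rate
$10^{-3}$ and batch 16 (small datasets train poorly at the full-scale
defaults — fewer than a handful of updates per epoch otherwise).  Under
these conditions the trained stage reduces the held-out MSE against the
reference to well under half of the raw twisted-input baseline.
Full-scale training (1024 pairs of 256×512 spectra, five stages, 50
filters) is supported by the same code path but is a multi-hour GPU-class
computation and is not exercised by the test suite.

## Uncertainty estimation and pSQ

A second network with the same architecture learns per-point error
standard deviations: the reconstruction of a *fixed* method provides the
Gaussian mean $\mu$, the synthetic truth provides $y$, and the network —
seeing only the corrupted input — outputs $\sigma$, trained with the
negative log-likelihood $(y-\mu)^2/2\sigma^2 + \log\sigma$.  Positivity
follows from a rectifier on the output plus a floor
$\varepsilon = 10^{-6}$ (in input-normalized units; the floor value is a
package choice).

Two numerical choices matter here.  First, the projection bias is
initialized at the RMS of the observed residuals, so the network starts
calibrated in scale and only has to learn spatial variation.  Second, the
rectified $\sigma$ head keeps its exact forward semantics but leaks a 1%
slope through the flat region in the backward pass: with a hard gate, any
point pushed negative is pinned at the floor with enormous loss and zero
gradient, and training cannot recover it.

The **pSQ** score normalizes predicted $\sigma$ by the maximum absolute
intensity of the reconstruction and summarizes the distribution over
points above 1% of that maximum.  The median is the headline statistic
(robust); the mean is reported alongside.  pSQ is invariant under joint
rescaling of spectrum and $\sigma$, monotone in pointwise $\sigma$, and —
because it never touches a reference — insensitive to reference bias: on
synthetic data with a 10% P-type amplitude deficit, the reference-based
RMSD systematically favors the Anti-Echo reconstruction (the traditional
reference itself carries residual N-flavored twist), while pSQ scores the
two flavors alike.  The test suite reproduces this contrast at desk scale
with CS reconstructions and a small uncertainty network.

## Reference-based metrics

`rmsd()` and `r2s()` follow the 1%-of-max support rule: both spectra are
normalized by their own maximum absolute intensity and compared only where
either exceeds the threshold, using absolute values so dispersive
(negative) artifacts enter the support.  $R^2_s$ is interpreted as the
squared Pearson correlation over the support.  Note that max-normalization means
a constant offset does not map to an RMSD equal to that offset (the
maximum shifts too); the un-normalized variant (`normalize = FALSE`)
recovers the naive identity.

## Known limitations

* 2D only; no ≥3D virtual-echo variants.
* No first-order phase correction, linear prediction or solvent
  suppression; no Bruker/Varian raw readers (NMRPipe-style binary and RDS
  containers only).
* The CS and network routes are validated on synthetic data; experimental
  spectra with features outside the simulated ranges (large phase errors,
  extreme dynamic range) would require re-training and possibly
  architecture changes.
* Desk-scale training demonstrates the mechanics and the qualitative
  claims, not full-scale reconstruction quality.
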