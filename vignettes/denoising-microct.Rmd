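---
title: "Locally adaptive non-local means for 3D volumes: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locally adaptive non-local means for 3D volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlm3d)
```

## The model

Non-local means assumes that small neighbourhoods recur across an image:
for every voxel $i$, other voxels $j$ whose surrounding patch resembles
the patch around $i$ carry independent observations of the same
underlying intensity. The denoised value is the weighted average

$$\hat u(i) = \frac{\sum_{j \in W(i)} w(i,j)\, u(j)}
                   {\sum_{j \in W(i)} w(i,j)},
\qquad
w(i,j) = \exp\!\left(-\left(\frac{\mathrm{ssd}(i,j)}{h^2}\right)^{p}\right),$$

where $\mathrm{ssd}(i,j)$ is the sum of squared intensity differences
between the two $m^3$ patches, $W(i)$ is the search window, $h$ the
smoothing bandwidth and $p$ a kernel-shape exponent. With $p = 1$ this is
the classical kernel, which is matched to additive white Gaussian noise
(AGWN); $p > 1$ cuts dissimilar patches off more sharply, which in
practice compensates for heavier-tailed or signal-dependent noise, and
$p < 1$ softens the cutoff. The center's own weight is set to the maximum
of the other offsets' weights before normalization — at weight 1 the
center would dominate and re-inject its own noise.

The filter is run fully in 3D. A volume with a single slice degenerates
gracefully: the patch and search radii along the trivial axis clamp to
zero and the filter becomes the 2D algorithm on that slice. Axes that
have more than one slice but fewer than one patch edge are rejected
(`"volume too small for patch size"`) rather than silently shrinking the
patch.

## Automatic bandwidth from local noise

Classical NLM asks the user for a noise estimate and a bandwidth; both
are replaced here by estimation from the data.

**Pseudo-residuals.** For each voxel,
$\epsilon_i = \sqrt{6/7}\,\bigl(u_i - \tfrac16\sum_{j \sim i} u_j\bigr)$,
the sum running over the six face neighbours (mirror-reflected at the
boundary). On locally constant signal with i.i.d. noise of variance
$\sigma^2$, $\mathrm{Var}(\epsilon) = \sigma^2$ — the $\sqrt{6/7}$
prefactor removes the inflation caused by the neighbour mean itself being
noisy. Structure (edges) leaks into $\epsilon$, which biases the
estimate upward; patch-based filtering is tolerant of a modestly
over-estimated $\sigma$, and the block median used in the tests is robust
to edge blocks. For single-slice volumes the internal estimator falls
back to the four in-plane neighbours with prefactor $\sqrt{4/5}$.

**Per-block estimates.** $\hat\sigma$ is the root mean square of
$\epsilon$ over sub-blocks of `blockSize` voxels per edge (default 16),
anchored at the volume origin, edge blocks truncated. Per-voxel lookup is
piecewise constant (the block containing the voxel), with no
interpolation — the simplest contract that realizes spatially adaptive
smoothing. The default of 16 makes a 64³ volume a 4³ grid of blocks:
small enough to track scanner shading, large enough (4096 voxels) that
the RMS is stable. Block size 8 is the sensible floor; below that the
estimate is too noisy to drive a bandwidth (`blockSize >= 4` is
enforced, `8`–`32` is the useful range).

**Bandwidth.** With $|N| = m^3$ the patch voxel count,

$$h = \max\!\left(h_{\min}\frac{g}{g_{\mathrm{ref}}},\;
      \sqrt{2\,\beta\,\hat\sigma^2\,|N|}\right),$$

where $g$ is the volume's gray-scale value (gsv) level count and
$g_{\mathrm{ref}} = 256$. The $\sqrt{2\sigma^2|N|}$ scale comes from the
expected SSD between two patches of pure noise, $2\sigma^2|N|$: at
$\beta = 1$, patches that differ only by noise land near $\mathrm{ssd}
\approx h^2$ and keep substantial weight, while patches across an edge
are suppressed. $\beta$ is a dimensionless multiplier for users who want
more ($\beta > 1$) or less smoothing.

**Why only the floor scales with the gsv range.** $\hat\sigma$ is
measured in the volume's own intensity units, so the main term is already
covariant with intensity rescaling: recode an 8-bit scene to 16 bits with
a 256× stretch and $\hat\sigma$, $h$ and the SSD all scale together,
leaving every weight unchanged. Scaling $\beta$ with bit depth as well
would break exactly that invariance. The only quantity that must be told
about the coding scale is the floor $h_{\min}$, whose default
($10^{-6} g$) exists for noise-free blocks: $\hat\sigma = 0$ would make
weights undefined, whereas with the floor the filter averages only
exactly-identical patches there. The package therefore keeps $\beta$
dimensionless and rescales $h_{\min}$ linearly with $g/g_{\mathrm{ref}}$;
the recoding invariance is part of the test suite.

## The moving-average-filter SSD

Patch SSDs dominate NLM runtime. For a fixed search offset, the patches
of two adjacent centers along the traversal axis overlap in all but two
end slices, so the SSD can be updated incrementally — subtract the
departing slice's squared differences, add the arriving slice's — instead
of being resummed. Along a row of $N$ centers with patch edge $M$ this
costs

$$M^3 + (N-1)\cdot 2M^2
\quad\text{instead of}\quad
N \cdot M^3$$

difference operations. `countDifferenceOps()` evaluates both formulas;
`mafRowSSD()` runs the literal sliding traversal with an operation
counter so the model is verified against the implementation rather than
assumed. (At $M = 100$ and very large $N$ the ratio approaches
$M/2 = 50$; the saving is bounded by half the patch edge, however large
$N$ grows.)

Two implementation layers share this principle:

* `ssdMapMAF()` / `mafRowSSD()` are the instrumented, paper-literal
  traversal: per offset, per row, initialize one full $M^3$ sum, then
  slide with $2M^2$ work per step. They exist for validation and
  counting.
* `denoise()` applies the same idea in bulk: per search offset it forms
  the squared-difference field once and builds patch sums with running
  box sums along $z$, then $y$, then $x$. The values are identical —
  exactly so on integer volumes, where floating-point addition and
  subtraction of the (integer-valued) terms is exact.

**Numerical choices.** Incremental subtraction accumulates rounding
error on floating-point data, so every running sum restarts at the
beginning of its row; the test suite holds the accelerated path to
within $10^{-6}$ relative of the brute-force oracle on float volumes and
to exact equality on integer volumes. Accumulated SSDs are clamped at
zero before use (a tiny negative value is representational noise, not a
similarity signal). `ssdNaive()` is the independent brute-force
reference and is kept deliberately simple.

**Boundaries.** Mirror (edge-inclusive symmetric) padding is the
default everywhere — patches that straddle the boundary then see locally
plausible statistics; zero padding is available as an alternative
(`boundary = "zero"`). Mirror padding also makes the filter commute with
axis flips.

## Defaults and their rationale

| parameter | default | why |
|---|---|---|
| `patchRadius` | 1 (3³ patch) | the established 3D patch size; larger patches blur fine structure at micro-CT feature scales |
| `searchRadius` | 5 (11³ window) | beyond this, patch-similarity statistics degrade and quality stops improving while cost grows cubically |
| `blockSize` | 16 | see above |
| `beta` | 1 | the $2\sigma^2\lvert N\rvert$ calibration needs no extra gain |
| `shapeP` | 1 | AGWN baseline; raise for non-Gaussian scanners |
| `hMin` | $10^{-6}\cdot g$ | degenerate-input safety only; negligible against any real noise |
| `boundary` | mirror | preserves local statistics; flip-equivariant |

Window sizes are deliberately fixed rather than exposed as tuning
advice: the point of the automatic bandwidth is that runs do not need
per-scan adjustment.

## What the phantom generator does and does not emulate

`generatePhantom()` draws piecewise-constant primitives — spheres, boxes,
and striped slabs (`lamellaeShape()`, a stand-in for layered structures
such as cerebellar folia) — on a constant background, in list order,
clipped at the volume boundary, entirely deterministically.
`addNoise()` then applies one of three seeded models: additive white
Gaussian noise, Poisson-Gaussian (photon counting plus readout), or
Rician (magnitude) noise. Intensities are *not* clamped to the gsv range
internally, so the injected noise statistics are exactly what the
estimator tests assume; clamping would censor the tails.

This emulates the geometry/noise structure that the denoiser and its
evaluation need, and nothing else. In particular there is **no CT
physics**: no beam hardening, ring artifacts, partial-volume blur, or
reconstruction correlations. Real scanner noise is also spatially
correlated in ways the i.i.d. models are not. Passing tests on phantoms
therefore demonstrate the algorithmic properties (oracle equivalence,
noise-level recovery, adaptive benefit, profile tightening) — they do not
certify denoising quality on any particular scanner, which should be
spot-checked with line profiles on real data.

## Evaluating denoising with line profiles

`lineProfile()` samples the volume by trilinear interpolation at equally
spaced arc-length positions between two voxel coordinates (the 3D
analogue of a viewer's line-profile tool).
`profileVariability()` is the standard deviation of the profile about
its running median: the median tracks plateaus and steps (structure)
without smearing them, so the residual spread measures noise, not
anatomy. The default window of 9 samples spans a few voxels at typical
sampling density — wide enough to be robust, narrow enough to follow
real edges; it is a parameter, not a constant. Note that sampling
denser than the voxel grid correlates adjacent samples and lowers the
absolute variability; comparisons (noisy vs denoised along the same
line) are unaffected, absolute values should be read with the sampling
density in mind.

`psnr()` backs the profile comparison with a conventional fidelity
number against the known clean phantom, using the gsv peak (e.g. 255)
as reference amplitude.

## Design decisions that were genuinely open

* **Self-weight.** Set to the maximum of the other offsets' weights
  (standard practice; the alternative, weight 1, lets the center
  dominate).
* **Block anchoring.** The noise-block grid is anchored at the volume
  origin. Consequence: denoising commutes with axis flips exactly when
  each axis is a multiple of `blockSize` (otherwise the truncated edge
  blocks land on different voxels after the flip). The equivariance
  tests use such volumes; for arbitrary sizes the discrepancy is
  confined to block-boundary voxels.
* **Degenerate inputs.** Constant volumes are an exact fixed point (all
  SSDs are zero, all weights equal). $\hat\sigma = 0$ blocks fall back
  to the $h_{\min}$ floor. Single-slice volumes run the 2D degenerate
  mode.
* **netCDF layout.** Written volumes use one `double` variable named
  `volume`, dimensions ordered (z, y, x) with coordinate variables
  carrying spacing in micrometres; the reader, by contrast, accepts any
  single 3D variable rather than assuming a schema, because
  reconstruction pipelines differ.
* **DICOM scope.** The built-in reader/writer covers single-frame
  Explicit-VR-little-endian series with rescale and spacing attributes —
  what axial CT exports look like — and nothing more; it is validated
  against an independent reader (pydicom) in the test suite.

## Problem sizes and runtime

The package's own test and validation runs use 7³ fixtures for
exhaustive oracle comparisons, 32³ phantoms for end-to-end denoising
properties, and 64³ volumes for noise-estimator statistics; a 32³
denoise at default parameters takes well under a second and the full
suite a few tens of seconds on one CPU core. These sizes were chosen to
make exhaustive and repeated-run checks cheap while remaining
statistically meaningful (a 32³ phantom offers 32k voxels per
condition); the algorithm itself streams over offsets and scales to
production volumes in time proportional to $w^3 \cdot n_{voxels}$.

## Known limitations

* The noise estimator assumes noise that is locally additive with
  slowly varying level; strongly signal-dependent noise is only
  approximated (use `poisson_gaussian` phantoms to gauge the effect, and
  `shapeP` to compensate).
* Per-voxel bandwidth lookup is piecewise constant across blocks; a
  voxel just inside a block boundary uses its own block's $\hat\sigma$,
  not a blend.
* No patch pre-selection: every offset in the search window is
  evaluated. This is the predictable-cost choice, not the fastest one.
* 2D operation exists only as the degenerate single-slice mode; there is
  no slice-by-slice batch mode for anisotropic stacks.
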