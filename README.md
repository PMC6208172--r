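# nlm3d — locally adaptive non-local means denoising for 3D micro-CT

Micro-CT scans of stained soft tissue — especially scans from in vivo
scanners, whose short exposure times keep radiation dose down at the price
of a low signal-to-noise ratio — often need post-acquisition denoising
before structures can be segmented or measured. Non-local means (NLM) is
well suited to this because it preserves spatial detail: each voxel is
replaced by a weighted average of voxels whose surrounding patches look
like its own, so edges are averaged with edges and flat regions with flat
regions.

`nlm3d` implements a parameter-free 3D NLM for volumetric grayscale data.
It is aimed at researchers processing micro-CT (or similar 3D) volumes who
do not want to hand-tune a noise estimate and smoothing bandwidth per
scan:

* **Local noise estimation.** The noise standard deviation σ̂ is estimated
  per sub-block of the volume (default 16³ voxels) from pseudo-residuals
  ε = √(6/7) · (u − mean of the 6 face neighbours), rather than as a
  single whole-volume value, so the filter adapts to spatially varying
  noise.
* **Automatic smoothing parameter.** For a voxel in a block with estimate
  σ̂, the NLM bandwidth is h = max(h_min, √(2 β σ̂² |N|)), with |N| the
  patch voxel count, β = 1 by default, and a floor h_min that scales with
  the volume's gray-scale value (gsv) range (number of representable
  intensity levels, 256 or 65536).
* **Kernel shape for non-Gaussian noise.** Weights are
  w = exp(−(ssd/h²)^p); p = 1 is the classical Gaussian kernel for
  additive white Gaussian noise, p ≠ 1 reshapes the cutoff for scanners
  whose noise is not Gaussian.
* **Moving-average-filter (MAF) accelerated SSD.** The patch
  sum-of-squared-differences for adjacent centers differs only in two end
  slices, so a row of N centers with patch edge M costs
  M³ + (N−1)·2·M² difference operations instead of N·M³. The
  implementation counts its own operations so the cost model can be
  checked, not just quoted.
* **Volume I/O** for DICOM series, netCDF and multi-page TIFF stacks,
  a seedable phantom generator with Gaussian / Poisson-Gaussian / Rician
  noise models, grayscale line-profile evaluation with a detrended
  variability statistic, PSNR, and a command-line interface.

## Worked example

```r
library(nlm3d)

## a 32^3 two-intensity phantom (values 50/150) with AGWN sigma = 10
spec  <- phantomSpec(c(32, 32, 32), background = 50,
                     shapes = list(boxShape(c(1, 1, 17), c(32, 32, 16), 150)),
                     gsvLevels = 256)
clean <- generatePhantom(spec)
noisy <- addNoise(clean, noiseModel("gaussian", sigma = 10, seed = 42))

estimateNoiseLocal(noisy, 16)
#> NoiseMap 2 x 2 x 2 blocks of 16^3 voxels (pseudo-residual estimator)
#>   sigma-hat: min 10.25, median 10.58, max 10.64

den <- denoise(noisy)          # defaults: 3^3 patch, 11^3 search window
psnr(clean, noisy, 255)        # 28.13 dB
psnr(clean, den,   255)        # 52.99 dB

prN <- lineProfile(noisy, c(16, 16, 1), c(16, 16, 32), 128)
prD <- lineProfile(den,   c(16, 16, 1), c(16, 16, 32), 128)
profileVariability(prN, 9)     # 1.97
profileVariability(prD, 9)     # 0.05

countDifferenceOps(3, 1000, "naive")  # 27000
countDifferenceOps(3, 1000, "maf")    # 18009
```

The noise map recovers the injected sigma (10.6 vs 10), denoising raises
PSNR against the clean phantom from 28.1 to 53.0 dB, and the line profile
across the intensity step loses almost all of its spread about the local
structure while keeping the step itself.

The same pipeline is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nlm3d", package = "nlm3d"))')
Rscript $CLI pipeline --out-dir out --shape 32,32,32 --background 50 \
    --box 1,1,17,32,32,16,150 --noise gaussian --sigma 10 --seed 42
```

which writes the noisy and denoised volumes as netCDF plus a `report.tsv`
with the PSNR and profile-variability numbers.

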