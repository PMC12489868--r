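# mocsClahe

Per-image tuning of contrast-limited adaptive histogram equalization
(CLAHE) for bright-background microvascular imagery — bulbar conjunctiva
frames acquired with a functional slit lamp biomicroscope — using a
multi-objective cuckoo search (MOCS) that trades texture contrast against
noise amplification.

Conjunctival vessels are thin dark structures on a bright, vignetted,
negatively skewed scleral background, and acquisitions swing between under-
and overexposure. CLAHE with fixed hyperparameters either under-enhances or
amplifies sensor noise. This package searches the four CLAHE parameters —
horizontal and vertical tile counts, clip limit, and the Rayleigh shape α of
the output-histogram transfer function — per image, and applies the balanced
middle solution of the Pareto front.

## Method at a glance

* **Objectives.** For a candidate parameter vector, the enhanced image is
  scored by
  * GLCM contrast (maximize): `Contrast = Σ_{i,j} (i−j)² p_{i,j}` over the
    normalized gray-level co-occurrence matrix (8 levels, offset (0,1),
    symmetric), and
  * FNVE (minimize): the fast noise-variance estimate
    `σ̂ = √(π/2) · Σ|I∗N| / (6(W−2)(H−2))` with
    `N = [1 −2 1; −2 4 −2; 1 −2 1]`, the difference of two Laplacian
    approximations, which annihilates affine intensity and passes noise.
* **Search.** Cuckoo search with Mantegna Lévy flights (β = 1.5) toward
  crowding-weighted front guides, dominance-based replacement, an
  abandonment random walk (discovery probability 0.75 by default), and an
  elitist non-dominated archive with crowding-distance truncation.
  Defaults: 50 nests, 20 iterations, bounds tiles ∈ [4, 12]²,
  clip ∈ [0.001, 0.01], α ∈ [0.5, 0.9].
* **Pipeline.** HSV value-channel extraction → Laplacian-of-Gaussian
  sharpest-frame selection (for sequences) → exposure classification
  (V̄ ≤ 0.6 / ≤ 0.8 / > 0.8) → MOCS optimization → enhancement with both
  the optimized parameters and a fixed baseline (8×8 tiles, clip 0.01,
  α 0.6) → PSNR and global SSIM of both arms against the original.

See `vignettes/mocs-clahe-methods.Rmd` for the full model description and
the design decisions.

## Worked example

Everything runs on synthetic conjunctiva phantoms with known ground truth,
so no data download is needed:

```r
library(mocsClahe)

ph <- generatePhantom(phantomSpec(seed = 1, noiseSigma = 0.02))
ph
#> PhantomBundle: 128 x 128, 11.7% vessel pixels, true sigma 0.02, target 'correct'

cfg <- pipelineConfig(mocs = mocsConfig(population = 15, iterations = 8,
                                        seed = 101))
rep <- runPipeline(ph@image, cfg, inputId = "phantom1")
rep
#> RunReport for 'phantom1' (correct, frame 1, seed 101)
#>   optimized: ClaheParams: 7 x 9 tiles, clip 0.00481, Rayleigh alpha 0.593
#>   contrast  original 0.2162 | fixed 0.4541 | MOCS 0.3342
#>   FNVE      original 0.01986 | fixed 0.03612 | MOCS 0.0187
#>   quality   fixed PSNR 26.69 / SSIM 0.9400 | MOCS PSNR 27.70 / SSIM 0.9818
```

Reading the report: both enhancement arms raise GLCM contrast over the
original (0.22 → 0.45 fixed, 0.33 optimized); the fixed baseline buys its
extra contrast with almost doubled noise (FNVE 0.020 → 0.036), while the
optimized parameters *reduce* the noise estimate (0.019) and preserve
structural similarity far better (SSIM 0.982 vs 0.940). That is the intended
behavior: the optimizer finds the balanced trade-off instead of the
aggressive extreme.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/mocsclahe.R enhance frames_dir/ --seed 3 --out out/
Rscript inst/scripts/mocsclahe.R phantom spec.json --out phantoms/
Rscript inst/scripts/mocsclahe.R batch images/ --summary summary.csv
```

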