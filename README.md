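# mapvpeaks

Peak detection and quantification for profile-mode MALDI mass spectra.

MALDI-TOF spectra carry peaks that are noisy, sit on a decaying
baseline, overlap, and are frequently *asymmetric* — a symmetric
Gaussian or Lorentzian profile mislocates their summits and
misestimates their areas, which in turn misidentifies the underlying
biomolecule and biases its abundance estimate. `mapvpeaks` implements a
complete detection pipeline built around a six-parameter **modified
asymmetric pseudo-Voigt (mAPV)** peak profile:

```
V(m) = H * [ beta1 / (1 + ((m - alpha)/sigma1)^2)
           + (1 - beta1) * exp(-ln 2 * ((m - alpha)/sigma1)^2) ]   for m <  alpha
V(m) = H * [ beta2 / (1 + ((m - alpha)/sigma2)^2)
           + (1 - beta2) * exp(-ln 2 * ((m - alpha)/sigma2)^2) ]   for m >= alpha
```

`H` is the summit height, `alpha` the summit m/z, `sigma1`/`sigma2` the
half-widths at half maximum of the two halves, and `beta1`/`beta2` the
Lorentzian fractions of each half (`0` = pure Gaussian, `1` = pure
Lorentzian). The profile contains the Gaussian, Lorentzian and
Bi-Gaussian models as exact special cases, peaks at `H`, and always
passes through `H/2` at `alpha - sigma1` and `alpha + sigma2`. The peak
asymmetry is `mu = max(sigma1, sigma2) / min(sigma1, sigma2)`.

The pipeline:

1. **Smoothing** — the spectrum is cut into 4 equal sections (noise
   shrinks along a MALDI spectrum) and each is denoised with a 1-D
   dual-tree complex wavelet transform (q-shift Hilbert pair, near
   shift-invariant); complex detail magnitudes are soft-thresholded at
   a per-level threshold that minimizes Stein's unbiased risk estimate,
   so no smoothing parameter needs hand tuning.
2. **Baseline** — a monotone local-minimum curve (running minimum) is
   subtracted.
3. **Peak picking** — the corrected spectrum is split into components
   at its valleys; each component is fitted with the mAPV profile by
   minimizing the sum of squared residuals `F(theta) = sum_m (V(m) -
   S(m))^2` with self-organizing **hierarchical particle swarm
   optimization** (no inertia term; time-varying acceleration
   coefficients 2.5 -> 0.5 and 0.5 -> 2.5; collapsed velocity
   components are randomly re-energized). Fits with area below a
   threshold are discarded; fits that are too wide or highly asymmetric
   (`mu > 2`) are re-split at interior valleys and refitted, which
   decomposes overlapping peaks such as unresolved isotopologues.

Peak area is computed analytically from the fitted parameters:
`area = H * sum_k sigma_k * (beta_k * pi/2 + (1 - beta_k) *
sqrt(pi / ln 2) / 2)`.

The package also ships the simulation and evaluation framework used to
validate the method: two-component mAPV mixtures over asymmetry /
overlap / noise grids, multi-peak MALDI-like spectra with baseline and
mass-dependent noise, peak matching at a relative m/z tolerance
(default +/-1%), sensitivity / FDR / F1, and a four-model comparison
(Gaussian, Lorentz, Bi-Gaussian, mAPV — all fitted with the same
optimizer so the comparison is unbiased).

## Worked example

A small simulated two-peak spectrum (true summits at m/z 152 and 158,
true areas 430.6 and 276.7, noise sd 1.2) ships with the package:

```r
library(mapvpeaks)

path <- system.file("extdata", "example_spectrum.txt",
                    package = "mapvpeaks")
s     <- read_spectrum(path)                 # two-column text or mzML
pre   <- preprocess_spectrum(s)              # DT-CWT smoothing + baseline
peaks <- detect_peaks(pre, detector_config(area_threshold = 50),
                      hpso = list(seed = 1))
peaks[, c("summit_mz", "height", "sigma1", "sigma2",
          "beta1", "beta2", "area", "asymmetry")]
#>   summit_mz height sigma1 sigma2  beta1  beta2  area asymmetry
#> 1     152.0 122.86  1.198  1.647 0.2778 0.9711 492.3     1.374
#> 2     158.1  74.61  1.902  1.480 1.0000 0.6799 378.5     1.285
```

Both summits are recovered within 0.1 u (well inside the +/-1%
matching rule), the areas within ~15–35% (the two peaks overlap, which
is exactly the hard case), and the fitted `beta` values reveal the
mixed Gaussian/Lorentzian character of each flank. Scoring against the
truth:

```r
mr <- match_peaks(peaks$summit_mz, c(152, 158))
sensitivity(mr)   # 100
fdr(mr)           # 0
```

The same pipeline is available from the command line:

```sh
Rscript -e 'mapvpeaks::run_cli()' detect spectrum.txt \
    --config cfg.yaml --out peaks.csv
Rscript -e 'mapvpeaks::run_cli()' simulate --mu 2 --sep 2 \
    --noise 0.02 --seed 7 --out spec.txt --truth truth.csv
Rscript -e 'mapvpeaks::run_cli()' evaluate --detected peaks.csv \
    --truth truth.csv
```

## Documentation

The methods vignette (`vignettes/mapv-peak-detection.Rmd`) describes
the model, the optimizer, every tunable threshold with its default and
rationale, what the simulators do and do not emulate, and known
limitations.
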