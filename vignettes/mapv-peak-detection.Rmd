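---
title: "Methods: asymmetric pseudo-Voigt peak detection for MALDI spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: asymmetric pseudo-Voigt peak detection for MALDI spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the algorithmic choices, the tunable
parameters, and the limits of what the package's tests establish. It is
written for a reader who wants to understand or audit the method, not
just run it.

# The peak model

A profile-mode mass-spectral peak is modelled by the modified
asymmetric pseudo-Voigt (mAPV) profile with parameter vector
`theta = (H, alpha, sigma1, sigma2, beta1, beta2)`. Each half of the
peak (left and right of the summit `alpha`) is an independent convex
combination of a Lorentzian and a Gaussian that share the same
half-width at half maximum:

* `H` (intensity units): summit height; the profile's maximum, attained
  at `alpha`.
* `alpha` (u): summit location.
* `sigma1`, `sigma2` (u): half-width at half maximum of the left/right
  half. In this parameterization *every* member of the family passes
  through `H/2` at `alpha - sigma1` and `alpha + sigma2`, regardless of
  the mixing fractions — which makes the sigmas directly interpretable
  and keeps them comparable across shapes.
* `beta1`, `beta2` in `[0, 1]`: Lorentz fraction of each half.

Gaussian (`beta = 0`, equal sigmas), Lorentzian (`beta = 1`, equal
sigmas) and Bi-Gaussian (`beta = 0`, free sigmas) are exact corners of
the family; the tests verify these degeneracies to machine precision.
The pseudo-Voigt linear combination is used instead of the true Voigt
convolution deliberately: it is orders of magnitude cheaper and the
extra fidelity of the convolution is not resolvable in noisy TOF data.

Peak area is the analytic integral over the whole real line,
`H * sum_k sigma_k (beta_k pi/2 + (1-beta_k) sqrt(pi/ln 2)/2)`.
Defining area on the infinite line (rather than truncated to the fitted
window) gives a model-consistent abundance measure; the difference is
negligible for well-contained peaks but *not* for fits whose Lorentzian
tail is unconstrained by data — see "Known limitations".

Peak asymmetry is `mu = max(sigma1, sigma2)/min(sigma1, sigma2) >= 1`;
`mu > 2` is treated as evidence that a single fitted component may hide
overlapping peaks.

# Smoothing

The raw spectrum is split into `n_segments = 4` equal-index sections
that are denoised independently, because MALDI noise decreases along
the m/z axis and a single global threshold under- or over-smooths one
end. Whether sections should be equal in index count or in m/z span is
an open choice; equal index count is implemented.

Each section is transformed with a 1-D dual-tree complex wavelet
transform (DT-CWT): two parallel critically-sampled wavelet trees whose
detail coefficients form the real and imaginary parts of approximately
analytic complex coefficients. The dual tree is what makes decimated
wavelet denoising nearly shift-invariant at only 2x redundancy — a
plain DWT's output can change materially when the spectrum is shifted
by one sample.

Implementation choices (no wavelet library is assumed; the transform is
implemented in the package):

* Level 1: the classical (5,7)-tap near-symmetric biorthogonal pair
  (exact rational coefficients `[-1,5,12,5,-1]/20` and
  `[-3,-15,73,170,73,-15,-3]/280`); tree B applies the same filters one
  sample offset, which supplies the required one-sample inter-tree
  delay.
* Levels >= 2: the published 14-tap q-shift orthonormal lowpass filter;
  tree B uses its time reverse, giving the +/- quarter-sample group
  delays of the Hilbert pair. The filter table is a literature
  constant; its double-shift orthonormality holds to the printed 1e-8
  precision, which bounds the reconstruction error of the transform
  (~5e-8 relative — in effect exact for denoising purposes).
* All filtering is circular via FFT after extending the section
  symmetrically (reflect to a transform-friendly length, then mirror
  the whole section), so no wrap-around discontinuity exists.
* Decomposition depth defaults to `floor(log2(n)) - 3`, clamped to
  `[3, 8]`: the coarse approximation (which carries the baseline) is
  never thresholded.

Thresholding: per level, the complex detail magnitudes
`sqrt(dA^2 + dB^2)` are soft-thresholded (phase preserved) at the
threshold minimizing Stein's unbiased risk estimate

```
SURE(t) = d sigma^2 + sum_i min(x_i^2, t^2) - 2 sigma^2 #{i : |x_i| <= t}
```

whose minimizer lies on the set `{0} union {|x_i|}` (searched exactly;
ties break to the smaller threshold — less smoothing). The noise scale
`sigma` is estimated per segment from the finest-level magnitudes by
`median(|x - median(x)|)/0.6745`. Two remarks a careful reader will
want: (1) the SURE formula is derived for Gaussian coordinates and is
applied here to Rayleigh-ish magnitudes, a deliberate simplification
that errs toward light smoothing; (2) the MAD constant is likewise the
Gaussian one. Both choices make the smoother conservative; the
downstream area filter, not the smoother, is responsible for rejecting
surviving ripple. When the finest-level dispersion is exactly zero the
section is returned untouched (noiseless input is a fixed point up to
<1% relative L2, which the suite asserts).

# Baseline

MALDI baselines fall steeply at low mass then level off. The estimate
is the monotone local-minimum curve — a running minimum
(`b[i] = min(b[i-1], y[i])`): it follows the spectrum downhill and
holds flat uphill. Subtraction clips residual negatives at zero.

The running minimum is deliberately crude (and faithful): it cannot
follow a baseline that rises again, and it leaves the *noise-floor
offset* in place — after subtraction the noise floor sits ~1 sigma
above zero, because the curve tracks noise minima, not noise means.
This offset is why spurious low components exist at all and why the
detector's area filter matters.

# The optimizer

Each component is fitted by minimizing the residual sum of squares with
self-organizing hierarchical particle swarm optimization (HPSO):

* No inertia term: each velocity component is rebuilt every iteration
  from the cognitive and social attractions alone,
  `v = c1 rand (p - x) + c2 Rand (pg - x)`, with fresh uniform draws
  per particle *and* per dimension.
* Time-varying acceleration: `c1` ramps 2.5 -> 0.5 and `c2` ramps
  0.5 -> 2.5 linearly over `max_iter` — exploration first, consensus
  later.
* Self-organizing rule: a velocity component that collapses to exactly
  zero (inevitable once `x = p = pg`) is re-energized to a random sign
  times a fraction of `v_max`, the fraction decaying 0.1 -> 0.01 over
  the run. Without this rule the inertia-free update stagnates; with it
  the late swarm performs a fine local search.
* `v_max` is half the box width per dimension; positions are clamped to
  the box and the offending velocity component zeroed.
* Defaults: 40 particles, 1000 iterations, early stop after 50
  iterations with improvement below `1e-8 * initial best`. A fit of a
  200-point component takes well under a second; the budget was chosen
  so that noiseless single-peak recovery of all six parameters within
  5% relative error succeeds in >= 90% of seeded trials (the suite
  runs this at 50 trials).

Search box per component (data-driven): `H` within a factor 2 of the
component maximum, `alpha` inside the component's m/z window, sigmas
between the grid spacing and the window span, betas in `[0, 1]`.

# Peak picking

1. Split the corrected spectrum at its valleys — interior local minima,
   plateaus collapsing to their midpoint. Valleys are pruned by
   *prominence*: while any valley's shallower exit barrier is below
   `valley_tolerance`, the least prominent valley is removed (noise
   dips merge into their neighbouring basins; deep valleys survive).
   Adjacent components share the valley point.
2. Fit each component with the mAPV model; drop it if the fitted area
   is below `area_threshold`.
3. If the fitted width `sigma1 + sigma2` exceeds `width_threshold`, or
   the fit is highly asymmetric (`mu > asymmetry_threshold`, default
   2), the component may hide overlapping peaks: re-split it at its
   interior valleys — this time at tolerance 0, so dips hidden by the
   initial pruning become cut points — and recurse (depth capped at
   `max_depth = 3`). If no interior valley exists the single fit is
   kept: decomposition is only attempted where the data show a dip.
4. A candidate must carry its own summit: a component whose maximum
   sits on a cut boundary is a monotone flank fragment and is dropped.
   Fits whose summit escapes the component window are dropped with a
   warning. Surviving peaks are reported sorted by summit.

Defaults and their reasoning:

* `area_threshold = 5 * sigma_mad * 10 * median(diff(mz))`, where
  `sigma_mad` is the MAD of the corrected intensities: five noise
  sigmas sustained over a minimal credible peak width of ten samples.
  The MAD of the intensities (not of first differences) is used because
  wavelet smoothing leaves *correlated* ripple that first differences
  cannot see. The default deliberately errs toward sensitivity; for a
  known noise level users should set the threshold explicitly (the
  worked example uses `area_threshold = 50` for noise sd ~1 and peak
  areas ~400).
* `width_threshold = Inf` by default. Peak width is a physical property
  of the instrument; any grid-derived default is wrong on some data (a
  sample-count rule that is safe on a coarse grid dissects genuine
  peaks on a fine one). The asymmetry rule — whose threshold 2 *is*
  stated by the method — drives overlap decomposition; supply an
  instrument-informed width to enable the width rule as well.
* `valley_tolerance = 3 * sigma` (first-difference noise estimate) by
  default: dips that noise alone could produce do not segment the
  spectrum.
* `min_points = 5`: fewer points cannot constrain six parameters.

# Simulators

`simulate_two_peak_spectrum` / `dataset1_grid` generate the
two-component mAPV mixtures used by the model-comparison study: exact
component intensities summed, i.i.d. Gaussian noise added, clipped at
zero; the truth table carries exact parameters and analytic areas. The
default grid emulates the reference study's *axes* — asymmetry
`mu in {1, 1.25, 1.5, 1.75, 2}` (components built with exactly that
sigma ratio), separation `{1, 2, 3, 4}` in units of the sum of facing
half-widths (1 = just resolved, 4 = baseline-separated), noise
`{1, 2, 5}%` of the first component height — with heights uniform in
`[50, 150]`, base half-widths in `[1, 4]` u, Lorentz fractions from
`{0, 0.25, 0.5, 0.75, 1}`, first summit at 50 u, grid spacing 0.1 u,
8-half-width margins. The reference study's actual 12-parameter table
lives in supplementary material that is not available; these values are
a stated, fixed emulation, chosen once so that percentage errors land
on the scale of the published tables (summit errors of a few percent
require summits at low m/z) and overridable for users who obtain the
original grid.

`simulate_multipeak_spectrum` builds end-to-end fixtures with MALDI
character: mAPV peaks with random shape, an exponentially decaying
baseline, and Gaussian noise whose scale falls linearly along the index
range (defaults: 30 peaks on [100, 1100] u at 0.1 u spacing, heights
50–300, half-widths 0.8–2.5 u, per-peak asymmetry up to 1.8, baseline
60·exp(-0.005 (m - 100)), noise sd 4 -> 1). What it does *not* emulate:
isotope envelopes, detector saturation, chemical (non-Gaussian) noise,
mass-dependent peak broadening, or the physical TOF instrument model
used by the reference study's external benchmark. A green end-to-end
test therefore establishes that the pipeline recovers known summits
under baseline + heteroscedastic noise — not instrument-level realism.

# Evaluation

Detected and true peaks are matched one-to-one, greedily by increasing
relative distance (ties to the lower detected m/z), within a relative
tolerance of 1% (boundary inclusive). Sensitivity is the percentage of
true peaks matched; FDR the percentage of detections unmatched (0 by
convention when nothing is detected);
`F1 = 2 (1-FDR) Sens / ((1-FDR) + Sens)` on fractions. Percentage
errors are absolute relative deviations; study-level tables aggregate
mean +/- standard error of the mean over fitted components (both
components of each mixture enter the average).

The four-model comparison fits Gaussian, Lorentz, Bi-Gaussian and mAPV
to each component of each simulated mixture with identical optimizer
settings and seeds derived from the design, so no model is favoured by
the search. Components are cut at the deepest sampled point between the
true summits — the same valley rule the detector itself uses.

# Known limitations

* **Unresolved mixtures break area estimation for every model.** When
  two peaks are separated by about one half-width sum, the inter-peak
  valley is shallow or absent; a fit truncated at that valley leaves
  the outer tail unconstrained, and the analytic infinite-line area of
  a Lorentzian-leaning fit can be off by integer factors. The more
  flexible the model, the worse the extrapolation — mAPV most of all.
  In the package's comparison study the mAPV model has the lowest area
  error in the resolved strata and the highest in the just-resolved
  stratum; the acceptance suite runs the full default grid and reports
  the aggregate, which is dominated by the hard stratum. A production
  rule of thumb: trust fitted areas only for peaks whose window
  extends several half-widths beyond the summit on both sides.
* **A converged true-model fit is hard to beat.** The comparison
  world generates data *from* mAPV profiles; with the optimizer run to
  convergence at 1–5% noise, mAPV locates symmetric summits at least
  as well as the symmetric models. Published comparisons in which
  simpler models win on symmetric peaks imply a harsher regime (more
  noise, tighter optimization budgets, or different windowing) than
  this package's stated defaults.
* The running-minimum baseline leaves the noise-floor offset in the
  corrected spectrum; the default area threshold compensates but a
  quantile- or morphology-based baseline would reduce the false
  discovery rate, at the cost of departing from the method being
  implemented.
* The SURE smoother is conservative by construction (Gaussian-formula
  shrinkage applied to magnitudes); heavy ripple at very low SNR is
  passed to the detector rather than smoothed away.
* mzML support is a minimal reader (m/z + intensity arrays, 32/64-bit
  floats, uncompressed or zlib); centroided input, vendor formats and
  imaging datasets are out of scope.
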