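---
title: "Calibrated glucose metabolism and the global-mean-normalization artifact: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated glucose metabolism and the global-mean-normalization artifact: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, parameters and
numerical choices, in the spirit of a methods section: what is computed, under
which assumptions, and where the design was genuinely open.

## The problem

Whole-brain glucose metabolism is not a nuisance variable. Sedation,
disorders of consciousness and even eye opening shift the brain's *global*
metabolic rate by 10–60%, while some conditions (congenital blindness) leave
the global level untouched and alter only specific regions. Global mean
normalization (GMN) — dividing each subject's image by its whole-brain mean
before group comparison — is algebraically guaranteed to delete any
per-subject multiplicative factor. When the underlying change *is* a global
(and tissue-wise heterogeneous) shift, GMN does two damaging things:

1. it removes the shift itself, so the dominant effect vanishes from the
   t-map; and
2. because gray and white matter do not shift by the same factor, voxels
   above the post-normalization mean appear "increased" and those below it
   "decreased" — a unidirectional change is reported as bidirectional.

The package's core is a calibration that avoids normalization altogether:
map each site's raw counts to quantified CMR~glc~ (qCMR~glc~, µmol/g/min) by
distribution matching against a reference absolute-CMR~glc~ map, then compare
groups on the calibrated scale.

## The calibration model

Counts from a given scanner are assumed affinely related to tissue
metabolism: qCMR~glc~ = a~site~·FDG + b~site~. The pair (a, b) is estimated
per site, from the control (healthy awake, eyes closed) group only, by
minimizing the Jensen–Shannon divergence between two voxel-intensity
distributions:

* the reference absolute-CMR~glc~ map over cerebral gray + white matter
  (cerebellum excluded), and
* a·⟨FDG⟩ + b over intracranial voxels, where ⟨FDG⟩ is the across-subject
  mean control count image, first smoothed so its point-spread function
  matches the reference's (Gaussian quadrature increment
  √(target² − current²) per axis; smoothing is only ever applied to the
  count image, never to the reference).

The fit uses the *mean image* across control subjects rather than pooled
per-subject voxels; a per-subject fit is possible through the same function
but is not the default, since averaging suppresses subject-level noise
without biasing the affine relation. The same (a, b) is then applied to every
subject and state from that site.

Key assumptions: the control condition is comparable across sites; the
count–metabolism relation is affine (no lesions, no saturation); masks are
registered to a common grid beforehand (registration is out of scope — all
inputs are consumed already aligned, 3 mm isotropic by default).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `n_bins` | 128 | bins | stable divergences at ~3·10⁴ mask voxels; the objective is piecewise constant below the bin width |
| histogram range | 0.1–99.9 pct of reference, +5% pad | µmol/g/min | robust to stray voxels; fixed once per fit so every (a, b) sees the same bins |
| logarithm | natural | nats | divergence bound log 2 ≈ 0.693; the minimizer's location does not depend on the base |
| optimizer | 25×25 grid ±50%/±30% → 25×25 zoom ±6% → Nelder–Mead, `reltol` 1e-6 | — | the binned objective has flat micro-plateaus; the grid stages avoid false local minima and the best point ever evaluated is returned |
| smoothing for t-maps | 8 | mm FWHM | conventional single-subject PET smoothing |
| cluster connectivity | 26 | — | face+edge+corner neighborhoods; 6 and 18 available |
| cluster thresholds | 2 (sedation), 1 (eyes-open), 0.5 (regional) | t | per-condition choices; group sizes differ too much for one common threshold |
| permutations | 1000 | — | region-order permutations for profile similarity p-values |

## The phantom: what it emulates, and what it does not

The generator builds an ellipsoidal "brain" on a 48³ grid of 3 mm voxels: an
outer gray shell at 0.31 µmol/g/min and an inner white core at 0.12 (the
2–3× gray:white contrast of healthy cortex; shell volume twice the core), an
inferior cap standing in for the cerebellum (inside the skull, excluded from
the cerebrum calibration masks), and 41 contiguous gray regions cut by
latitude band and longitude sector, each perturbed by a multiplicative
factor with 10% coefficient of variation. The three most posterior labels
are flagged as "visual cortex" for regional-effect experiments.

Cohorts add, in order: state factors (gray, white, per-region overrides and
an optional additive offset), a per-subject global lognormal multiplier
(mean 1, CV 5% by default — the scalar individual factor that GMN is designed
to remove; kept modest because it models within-site global variability, not
the much larger between-site and regional spread seen in group standard
deviations), inversion through the site transform
counts = (qCMR~glc~ − b)/a, additive Gaussian count noise (≈2–3% of the gray
signal), and a site point-spread blur (3.3–4.5 mm, high-resolution-tomograph
to PET/MR territory) applied with a mask-renormalized kernel so no signal
bleeds out of the head. Cohorts with the same seed and size reuse subject
multipliers and noise draws — that is how "same subjects scanned in two
states" (the sedation site's paired design) is simulated; independent groups
use different seeds.

The reference map as *observed* is the sharp phantom truth blurred at
6.5 mm, emulating a published database acquired on its own scanner.

What the phantom deliberately does not emulate: real anatomy, lesions,
motion, scatter/attenuation physics, kinetic modeling, or within-region
texture. Consequences for interpretation: passing tests show the analysis
machinery is correct and that the GMN artifact follows from the arithmetic
of normalization — they do not certify accuracy on real anatomies, where
partial-volume effects and registration error add biases the phantom does
not contain. In particular, in the phantom the GMN bidirectionality
expresses itself across tissue classes (gray down / white "up"), whereas in
real data it also fragments within gray matter.

## Numerical choices and degenerate inputs

* **Smoothing** is evaluated in the Fourier domain with the exact Gaussian
  transfer function: constants are preserved exactly, and successive kernels
  compose by quadrature to machine precision (a point-sampled spatial kernel
  fails this at sub-voxel σ). Boundaries are periodic; brain volumes are
  smoothed through `masked_smooth()`, which renormalizes inside the
  intracranial mask and zeroes the background, making wrap-around
  irrelevant.
* **Smoothness estimation** is the classical first-difference estimator
  (lag-one autocorrelation inverted under a Gaussian model), reporting 0 for
  sub-voxel estimates. It is accurate for noise-driven fields, but on a
  piecewise-anatomical phantom the autocorrelation reflects anatomy, not
  scanner blur; the pipeline therefore matches point-spread functions from
  acquisition metadata by default (`psf_source = "metadata"`), with
  estimation available as an option for data lacking metadata.
* **Histogram-matching degeneracy.** With a *noise-free, blur-free,
  regionally flat* phantom the intensity distribution collapses to two
  spikes and the divergence landscape becomes a field of needles; the
  optimizer cannot be expected to find the true transform there, and because
  the reference and count distributions are taken over different masks
  (GM+WM versus intracranial), the identity transform is not even the exact
  optimum. Realistic point-spread blur regularizes the problem completely —
  with 3.3 mm blur and matched smoothness the fit recovers simulated
  transforms to well under 1% systematic error.
* **Zero-variance voxels in t-maps**: equal means give t = 0 (with a
  relative tolerance of 1e-8 so floating-point noise does not manufacture
  infinities); a real mean difference with zero pooled variance gives signed
  infinity, preserving the direction of a noise-free global effect. Both
  kinds are counted and reported.
* **Permutation p-values** use the plain percentile convention (a p-value of
  exactly 0 means no permutation matched or beat the observed statistic); a
  (k+1)/(n+1) variant is available. Permuting one profile's region order is
  the standard exchangeability construction; permuting both is equivalent in
  distribution.
* **Through-origin R²** is computed against the uncentred sum of squares
  Σy², the convention for origin-constrained regression (centred R² can be
  negative or misleading there).
* **Negative values**: noise-free counts that would go negative inside the
  head are clamped to zero with a warning; calibrated qCMR~glc~ values that
  come out negative are preserved but counted.
* **Seeds**: a single master seed; each pipeline stage derives its own seed
  by a stable 32-bit hash of the stage name, so runs are byte-reproducible
  and stages are statistically decoupled.

## Problem sizes

All experiments run on the 48³ standard phantom: 20 simulated sites for
calibration recovery (8 control subjects each), 5 sites for the
grid-oracle comparison (50×50 grid around each optimum), 8 vs 8 subjects for
the sedation contrast, 16 vs 16 for the regional-effect contrast, 500
replicates of the 1000-permutation null for calibration of the permutation
test, and the three-site end-to-end pipeline run twice for determinism.
These sizes keep the whole validation suite within a few minutes on one CPU
while leaving the phantom at the full analysis grid resolution.

## Known limitations

* The calibration assumes an affine count–metabolism relation per site; any
  scanner nonlinearity folds into the recovered (a, b).
* The divergence objective compares distributions over different masks by
  design (reference: cerebral GM+WM; counts: intracranial), so a small
  mask-composition mismatch is part of the objective floor; it is negligible
  at realistic smoothness but visible in degenerate flat phantoms.
* Regional profiles cover gray matter only; white matter enters through the
  whole-brain mask and the white-core state factors.
* No multiple-comparison correction or cluster-level inference is provided —
  cluster counting at explicit thresholds is the object of study here, not a
  significance procedure.
* The per-subject global multiplier is a single scalar; real inter-subject
  variability also has regional structure that GMN does not remove.
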