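---
title: "Two-stage decoding of FDG-PET volumes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage decoding of FDG-PET volumes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petdecode)
```

# The procedure

petdecode implements the two-stage procedure that turned group-level PET
findings into an individual classifier: a mass-univariate statistical mask
followed by a multivariate linear decoder. The two stages answer different
questions and are deliberately kept separate — the mask is built **only**
from training subjects, and the testing branch applies the frozen mask and
model without refitting anything. This train/test separation is the
pipeline's central validity property and is enforced programmatically
(disjoint subject-id namespaces; `run_testing()` refuses overlapping ids).

## Stage 1: voxel-wise ANCOVA and cluster-extent filtering

At every in-mask voxel the same ordinary-least-squares model is fitted:

$$ y_i = \beta_0 + \beta_1 \cdot \mathbb{1}[\text{healthy}_i] +
         \beta_2 (\text{age}_i - \overline{\text{age}}) + \varepsilon_i $$

The contrast picks $\beta_1$ (healthy minus disease), so a positive $t$
means relative hypometabolism in the disease group. The statistic is the
textbook $t = \mathbf{c}^\top\hat\beta / \sqrt{\hat\sigma^2\,
\mathbf{c}^\top(X^\top X)^{-1}\mathbf{c}}$ with $\hat\sigma^2 =
\text{RSS}/(n - \text{rank}(X))$; with no covariate this reduces exactly to
the pooled two-sample $t$, which the test suite verifies to $10^{-8}$
against the closed form on randomized cohorts.

Assumptions worth stating: Gaussian, homoscedastic residuals per voxel;
the same design for all voxels; age entering linearly. The p-value is
**one-sided**. The direction choice is a genuine design decision — the
cluster tables this lineage of analyses reports contain only *decreased*
uptake, so only the hypometabolic direction enters the mask and a
hypermetabolic signal is deliberately invisible. The equivalent normal
quantile $z = \Phi^{-1}(1-p)$ is carried per voxel for the weight-vs-z
analysis; $p$ is clipped to $[10^{-300}, 1-10^{-16}]$ before the quantile
transform so $z$ stays finite even at the degenerate-voxel conventions.

Degenerate voxels follow explicit conventions rather than NaN propagation:
an all-zero intensity series reports $t = 0, p = 1$ (never enters the
mask); a numerically perfectly-fit voxel with a vanishing contrast reports
$t = 0, p = 0.5$. "Vanishing" is judged relative to the voxel's own scale
(residual SD below $10^{-10}$ of the root-mean-square signal), not against
exact floating-point zero.

Thresholding conventions: the voxel threshold is **strict** ($p < 0.005$;
a voxel at exactly 0.005 is excluded), the extent threshold is
**inclusive** ($k \ge 200$; a 200-voxel cluster survives) — matching how
the conventional "P < 0.005, k ≥ 200" is printed. Clusters are connected
components under 18-connectivity (faces + edges, the convention of the
mainstream SPM software lineage), configurable to 6 or 26; labelling is
deterministic (components numbered by raster order of their first voxel)
and is property-tested against two independent algorithms (scalar flood
fill, vectorized min-label propagation). No correction beyond cluster
extent is applied — no FWE or FDR — because the procedure being
re-implemented used extent filtering only.

## Stage 2: linear maximum-margin decoder

On the masked voxels the decoder solves the soft-margin linear SVM

$$ \min_{\mathbf{w},b}\ \tfrac12\|\mathbf{w}\|^2 +
   C\sum_i \max(0, 1 - y_i(\mathbf{w}\cdot\mathbf{x}_i + b)) $$

with disease coded $y=+1$. The convex dual is solved by libsvm (through
e1071) at tolerance $10^{-6}$; there is no stochastic subsampling, so a
configuration + seed determines the model bit-for-bit (the pipeline
records an MD5 checksum of $(\mathbf{w}, b, C)$ to make this auditable).
Toy problems are cross-checked against an independent quadratic-programming
oracle on the dual (kernlab::ipop) to $10^{-4}$ in $(\mathbf{w}, b)$.

Three deliberate choices:

* **C = 1.** The original analysis names no hyperparameter; 1.0 is the
  default of the software lineage it used. It is configurable and logged.
* **No per-feature standardization.** The interpretation of the weight map
  — strongly hypometabolic voxels draw *negative* weights that, dotted
  with *reduced* patient intensities, raise the patient's score — lives on
  the raw normalized-intensity scale. Standardizing would decouple weights
  from intensities and destroy that reading. The negative Spearman
  correlation between univariate $z$ and weight is asserted as an
  acceptance property.
* **Score ties go to disease.** $s = 0$ classifies as disease, favouring
  sensitivity in a screening context; the convention is logged in the
  score-set contract.

## Evaluation

Confusion counts use disease-as-positive. The five ratios (Se, Sp, PPV,
NPV, Acc) are exactly the textbook formulas; any zero denominator yields a
missing value with a warning, never a silent zero. Machine output keeps
full precision; `format_metrics_percent()` adds the two printed styles
(nearest-integer and one-decimal percent) so rounded report figures are
reproducible without hard-coding. Note one arithmetic subtlety the package
documents rather than hides: 17/19 is 89.47…%, which prints as 89% at
integer precision but 89.5% at one decimal.

The Mann-Whitney U comparison of decision scores uses exhaustive
enumeration of all $\binom{n_1+n_2}{n_1}$ rank assignments when the
combined sample is ≤ 12 (exact, ties handled by the ½-count convention)
and the tie- and continuity-corrected normal approximation otherwise; the
method used is recorded in the result. The switch point is configurable;
the 19 + 20 testing layout always takes the approximation path, which the
suite cross-checks against the exact Wilcoxon distribution at $n_1 = n_2
= 15$ (agreement within 0.01).

# Preprocessing

* **Smoothing** — separable Gaussian convolution, default FWHM 8 mm
  ($\sigma = \text{FWHM}/(2\sqrt{2\ln 2}) \approx 3.40$ mm, 1.70 voxels at
  2 mm). Boundary handling is half-sample reflection, which makes the
  discrete convolution operator symmetric and doubly stochastic: constants
  are preserved exactly, the total in-grid sum is conserved, and no edge
  attenuation leaks into the brain mask. The kernel is truncated at
  $4\sigma$ and renormalized to unit sum. FWHM 0 is the bit-exact identity.
* **Global normalization** — proportional scaling of each scan so its
  in-mask mean equals 50. Clinical pipelines of this lineage typically say only "normalized";
  proportional scaling is the dominant convention in this software lineage
  and makes the decoder invariant to per-subject global scaling (injected
  dose, uptake time, scanner gain). The alternative — modelling global
  signal as an ANCOVA nuisance — was considered and not taken: it changes
  only stage 1 and leaves the decoder exposed to global variation.
  Smoothing runs first, normalization second; the order and both
  parameters are recorded in each cohort's `preprocess` field and the run
  log, and the testing branch replays the training-time values.

# The synthetic cohort generator

Each subject volume is

$$ v = g\,\bigl[T\,(1 - E\cdot\mathbb{1}[\text{disease}]) +
   s\,(\text{age}-\bar a)\bigr] + \varepsilon $$

inside the brain mask and exactly zero outside, where $T$ is a constant
ellipsoidal template (baseline 100), $E$ the planted fractional-reduction
map, $s$ the age slope, $g \sim N(1, \sigma_g)$ truncated positive, and
$\varepsilon \sim N(0, \sigma_\varepsilon)$ i.i.d. per voxel. Disease acts
*multiplicatively* (a fractional reduction is what "hypometabolism"
means), age *additively* via the centred slope (the simplest mechanism
that makes the ANCOVA covariate consequential; the reference age is the
cohort's expected pooled mean), and overlapping planted spheres combine by
**max**, never sum, so planted effects cannot exceed 100%.

Defaults, chosen once as field-plausible values (published group studies
of this kind report cluster t-statistics, not percent reductions, so
effect sizes are free parameters): baseline 100; noise SD 10 (10% of baseline); global
scale SD 0.1; age slope −0.2 intensity/year; ages Normal per group
(training 46.5 ± 12 vs 45.4 ± 16 y; testing 42.5 ± 15 vs 52 ± 15 y)
truncated to [18, 90]; four planted spheres (bilateral posterior pair at
12% reduction, a midline posterior 10%, a frontal 8%) sized to clear the
200-voxel extent threshold at 2 mm. The default grid is 48×56×48 at 2 mm —
a reduced template-like lattice that keeps a full pipeline run in seconds;
full 91×109×91 resolution is supported through `grid_spec()`.

Reproducibility: every cohort requires an explicit seed, and all
randomness flows from it in a fixed, documented draw order (all ages
first, then each subject's global scale and noise in manifest order), so
identical specs produce bit-identical cohorts and identical model
checksums.

**What the generator does *not* emulate** — and therefore what passing
tests do and do not show. There is no anatomy (no gray/white contrast, no
gyri), no scanner point-spread function, no attenuation or reconstruction
physics, no inter-scanner offset, and crucially **no spatially correlated
between-subject variability**: noise is independent per voxel. After 8 mm
smoothing, independent noise averages away almost completely, so
synthetic t-values reach the tens and the default decoding task is far
easier than the clinical one — the suite's near-perfect held-out accuracy
on synthetic cohorts demonstrates pipeline correctness, not clinical
performance. Real anatomical variability is smooth and survives
smoothing, which is why patient-data t-values stay in single digits.

# Validation design and problem sizes

The acceptance layer of the test suite checks, at sizes chosen to keep
the whole suite under a minute:

* the printed-counts confusion matrix (TP 17, FN 2, FP 3, TN 17)
  reproduces the published ratio set exactly (17/19, 17/20, 34/39 and
  their integer/one-decimal renderings);
* GLM-vs-closed-form equivalence on 100 random micro-cohorts (tolerance
  $10^{-8}$); component labelling vs an independent oracle on 100 random
  16³ volumes at all three connectivities;
* null calibration: with no planted effect (20/20 subjects, unsmoothed),
  the fraction of in-mask voxels passing $p < 0.005$ lies within the 99%
  binomial band — run at FWHM 0 because the binomial bound presupposes
  independent voxels, which smoothing would deliberately violate;
* mask recovery: a planted 20% sphere (radius 10 mm, noise 10%, 50/group,
  unsmoothed) is recovered with Jaccard ≥ 0.5 against the planted
  support — also run at FWHM 0, because the criterion measures support
  *localization* and Gaussian blur dilates the suprathreshold region
  several voxels beyond the planted sphere by construction (at 8 mm FWHM
  the geometry alone caps Jaccard near 0.25 regardless of implementation
  quality);
* decoder recovery at the published cohort sizes (100/44 train, 19/20
  test, 30% effect, full default preprocessing) with held-out accuracy
  ≥ 0.9, plus 20-repetition null calibration at chance within the 99%
  binomial band using a fixed spherical feature mask (under a true null
  the data-driven mask is empty by design, so calibration uses a frozen
  geometric mask);
* the negative Spearman relation between univariate $z$ and decoder
  weight on the strong-effect run;
* max-margin toys vs the QP dual oracle (at $C = 10$, which is already
  hard-margin for those geometries but keeps the primal objective
  numerically comparable across solvers; at very large $C$ the hinge term
  amplifies solver-tolerance-level margin slack by $10^6$ and objective
  comparisons become meaningless).

# Known limitations

* The synthetic task overstates separability (see above); no claim about
  clinical accuracy follows from these tests.
* One-sided masking discards hypermetabolic information by design.
* The GLM assumes homoscedastic Gaussian voxels and a linear age effect;
  no random-field or permutation inference is provided.
* Anatomical labelling of clusters (atlas regions) is out of scope; the
  cluster report gives template mm coordinates only.
* Spatial normalization/registration is assumed done: inputs must already
  share the template grid.
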