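---
title: "Methods: spheroid morphometry, plate QC and dose-response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spheroid morphometry, plate QC and dose-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroscreen)
```

# Scope

`spheroscreen` implements the computational side of a high-throughput 3D
cytotoxicity screen built on single spheroids in ultra-low-attachment
(ULA) round-bottom 96-well plates: automated volume morphometry from
phase-contrast images, the assay-quality statistics used to validate such
screens, and dose-response analysis with IC50 meta-analysis across runs.
Because the biological inputs (cells, drugs, cameras) are not available to
a software package, every stage is exercised against synthetic fixtures
with known ground truth; the generators are first-class, tested code.

# Spheroid morphometry

## The equivalent-sphere estimate

A spheroid's 2D projection with measured area $S$ defines an equivalent
circle of radius $r = \sqrt{S/\pi}$ and an equivalent sphere of volume

$$V = \tfrac{4}{3}\pi r^3 .$$

The estimate is approximately valid for ellipsoids up to a width/length
ratio of 1.5; `segment_spheroid()` flags measurements beyond that bound
(`aspect_gt_1.5`) rather than suppressing them. Feret (caliper) diameters
are reported for shape QC but deliberately not used for volume: an
ellipsoid-volume estimate from the two Feret diameters is more sensitive
to thresholding artifacts than the area route.

## Segmentation pipeline

`segment_spheroid()` runs: (1) binarise at a Yen threshold, (2) remove
objects smaller than 0.5% of the frame (artifact cleaning), (3) fill
holes, (4) keep the largest object, breaking size ties by centroid
proximity to the frame centre (ULA wells centre the spheroid), and (5)
measure. Area is measured after hole filling, as pixel count times the
square of the µm-per-pixel calibration; the calibration is a required
input, never guessed.

Two numerical decisions deserve record:

* **Constrained Yen cut.** Yen's maximum-correlation criterion
  $TC(t) = -\ln[G_1(t)G_2(t)] + 2\ln[P(t)(1-P(t))]$ depends only on the
  histogram's class masses, not on intensity positions. On quasi-discrete
  histograms — a tiny bright halo class, or low-noise images whose classes
  occupy a few bins — its global maximum can isolate a sliver of
  probability mass at a class edge instead of splitting the two dominant
  classes (reference implementations behave identically). The pipeline
  therefore maximises the criterion subject to each side of the cut
  holding at least 5% of the pixels (`yen_threshold(min_class_frac =)`);
  the exported default remains the plain criterion, and an exhaustive-scan
  oracle test pins the implementation to it. Objects smaller than 5% of
  the frame are below the empty-well floor anyway (next item), so the
  constraint costs nothing in the supported regime.
* **Empty-well verdict.** A well is reported empty when no object of at
  least 1% of the frame survives cleaning, *or* when the two intensity
  classes show no real separation: $|\tilde\mu_{fg}-\tilde\mu_{bg}| \le
  2(\mathrm{MAD}_{fg}+\mathrm{MAD}_{bg})$ using medians and MADs. The
  second rule is needed because thresholding pure noise yields a giant
  percolating pixel cluster that passes any size test; the robust
  statistics keep the rule insensitive to the few background-tail pixels
  an edge-seeking cut can sweep into the foreground class.

The spheroid is taken to be the *dark* class (phase-contrast polarity);
`invert = TRUE` serves bright-object modalities. Feret diameters are
computed over the convex hull of the object's pixel centres by rotating
calipers, plus one pixel for the unit pixel footprint.

`batch_measure()` applies the pipeline to a folder in sorted-filename
order, writes an RGB copy of each image with the detected outline in blue,
emits one CSV row per image, and flags unreadable files without aborting
the batch.

# Synthetic fixtures

## Images

`generate_spheroid_image()` renders a dark elliptical body (intensity 60)
with a 2-px brighter halo (200) on a mid-gray background (140), optional
dark debris discs of 3-10 px radius placed disjoint from the body, and
additive Gaussian noise, quantised to 8 bits. Only contrast polarity
matters to the segmentation contract; the levels are fixed constants so
thresholding behaviour is reproducible. The truth record (centre,
semi-axes, orientation, noise, debris, seed) makes every downstream
estimate scorable without external reference, and identical seeds yield
byte-identical images. `sample_image_truth()` draws truths from the
validation envelope: diameters 150-800 px (the working 160-800 µm size
range at ~1 µm/px), aspect ratios 1-1.5, noise SD up to 10, up to 20
debris specks. No optical physics is simulated; consequences: passing the
area-recovery suite shows robustness to threshold placement, debris and
additive noise, not to out-of-focus imaging, illumination gradients or
well-edge shading, which real images contain.

## Plates

`simulate_plate()` lays out a 96-well screen the way the assay is run: 9
concentrations (0.03-300 µM in half-log steps) across columns, 6
replicate spheroids down rows, vehicle (negative) controls, 25%-DMSO-style
killed (positive) controls, and a media-only row. Raw readings are an
affine image of percent viability (so normalisation is exact at zero
noise) perturbed by *multiplicative* Gaussian noise with a stated CV —
plate variability in this field is quoted as CV, so the generator speaks
the same language. Defaults: CV 10%, monophasic truth logIC50 0.5 (3.2
µM), Hill slope -1, top 100, bottom 0.

The biphasic default truth is a two-population curve: a sharp first
transition (`nH1 = -2.5`) for the sensitive half (`frac = 0.5`) and a
moderate second transition (`nH2 = -1`), sites at 0.3 µM and 30 µM. Both
sites sit well inside the sampled concentration range: with the first
site near the lowest tested dose the least-squares optimum itself drifts
(verified by comparing residual sums of squares at the fit and at the
truth), and no estimator can recover a parameter the design barely
samples. A ground-truth fixture is only informative where the design
supports recovery, so in-range sites are the default; users emulating
edge-of-range designs can set any truth they like.

# Plate quality control

* **Z-factor** $Z = 1 - 3(\sigma_s+\sigma_c)/|\mu_s-\mu_c|$; the same
  formula on positive vs negative controls is Z'. $Z \le 1$, with
  equality exactly at zero SDs.
* **Signal window** $SW = (|\mu_h-\mu_l| - 3(\sigma_h+\sigma_l))/\sigma_h$.
  The source material renders this equation as an image; the NCATS Assay
  Guidance definition is adopted, an assumption recorded here.
* **CV%** $= 100\,\sigma/\mu$, always computed on raw readings
  (normalisation changes CV).
* Acceptance criteria: Z > 0.4, SW > 2, CV < 20%.

Z and SW are invariant under shared affine rescaling of the readings
(gain/offset of the reader), a property the tests exercise.

**Outlier removal** (`detect_outliers_robust`) is a location-model variant
of the robust-fit + FDR idea behind Prism's ROUT: residuals from the
median, robust scale from the 68.27th percentile of absolute residuals,
t-like scores, and a Benjamini-Hochberg step at rate Q (default 1%). The
published ROUT couples outlier testing to robust *nonlinear regression*;
for plate-uniformity data the location model is the appropriate
reduction, and the divergence is deliberate.

**Normality** is assessed with the D'Agostino-Pearson omnibus statistic
$K^2 = Z^2_{g_1} + Z^2_{g_2}$ (transformed skewness, D'Agostino 1970;
transformed kurtosis, Anscombe-Glynn 1983; $\chi^2_2$ reference). The
transformations need $n \ge 20$. The implementation agrees with
scipy.stats.normaltest to ~1e-4 on frozen samples and holds its 5% size
at plate-sized $n = 66$.

**Detection power** uses the noncentral-t distribution for a one-tailed
two-sample t-test in which the control group has mean 100 and SD equal to
the plate CV, the treated group mean $100 - \mathrm{drop}$ with SD
proportional to its mean, pooled SD, and $n$ per group. This reading
reproduces the reported 74%/99% pair for a 20% drop at CVs of 15%/9% with
$n = 6$; whether the original computation pooled SDs is not stated, so a
one-sample design is exposed behind a flag rather than asserted. A
Monte-Carlo t-test oracle (simulated experiments, not the noncentral-t
formula) cross-checks the computation in the tests and the acceptance
script.

`residual_fraction()` records the washout arithmetic: each exchange of
150 µl from a 200-µl well leaves 1/4 of the drug, two exchanges 1/16.

# Dose-response analysis

## Models

Monophasic four-parameter logistic, fitted on $X = \log_{10}$
concentration:

$$Y = \mathrm{bottom} + \frac{\mathrm{top}-\mathrm{bottom}}
      {1 + 10^{(\log IC_{50} - X)\,h}}$$

and the biphasic two-site mixture with shared plateaus, weight
$f \in [0,1]$ and per-site slopes. At $f = 1$ the biphasic model reduces
exactly to the 4PL; at well-separated sites it shows the intermediate
shoulder characteristic of two cell sub-populations with distinct
sensitivities.

## Fitting

`dr_fit()` is unweighted least squares (the convention of the Prism
workflow it mirrors) driven by Levenberg-Marquardt (`minpack.lm::nls.lm`)
with tight tolerances (`ftol = ptol = 1e-12`) so noise-free data
converges to the exact fixed point. Replicates are fitted as individual
points, never averaged — this preserves the residual degrees of freedom
the F-test below relies on. Initialisation: plateaus from the extreme
concentration means, logIC50 from the concentration nearest half-range,
slope magnitude 1 signed by the data; the biphasic fit starts from
$f = 0.5$ with sites at the 25th/75th percentile concentrations and runs
a small deterministic grid of extra starts (weight, site placement, first
slope sharpness) because the 7-parameter surface is multi-modal. Biphasic
site slopes are bounded to magnitude $[0.1, 10]$ (whether the original
workflow fixed them is unpublished; free-but-bounded is the assumption),
$f$ to $[0,1]$, and sites are ordered $\log IC_{50,1} < \log IC_{50,2}$
after fitting. Standard errors come from the Gauss-Newton $J^\top J$
covariance, CIs from $t_{df}$ quantiles. Convergence status is reported,
never silently absorbed. Zero-concentration vehicle wells are
normalisation anchors and never enter the log-space fit; `pin_bottom = 0`
is available because the killed control defines the bottom of the
normalised scale, but the default leaves the bottom free.

## Combining IC50s across runs

`combine_ic50()` implements the three procedures, all on the log scale
(logIC50 is the closer-to-normal quantity):

* **pooled** — one fit over the concatenated points;
* **geometric mean** — $\overline{\log IC_{50}}$ across runs with a
  t-based CI; the combined IC50 is exactly the geometric mean of the run
  IC50s;
* **shared_ftest** — a joint fit with every parameter free per run except
  one shared logIC50, compared with the separate fits by the
  extra-sum-of-squares F-test
  $F = \frac{(SS_{sh}-SS_{sep})/(df_{sh}-df_{sep})}{SS_{sep}/df_{sep}}$.
  A small p flags runs whose IC50s genuinely differ; the package reports
  the flag with the shared estimate rather than choosing for the user.

On homogeneous simulated runs the geometric-mean CI tends to be broader
than the pooled CI — the expected behaviour, asserted in the tests as a
tendency over seeds, not per seed.

# Problem sizes and calibration checks

The validation suite was sized to measure each property with useful
precision while remaining quick to run routinely: 200 seeded images for
segmentation fidelity (median relative area error, observed ~0.02%,
bound 5%); 200 seeds for 4PL recovery, CI coverage and the shared-logIC50
F-test size; 600 seeds for biphasic recovery, whose ~93% pass rate sits
close enough to the 90% bar that 200-seed estimates are dominated by
binomial noise; 1000 replicates for the K2 test's size; $10^5$ simulated
experiments for the Monte-Carlo power oracle. All simulation flows from
explicit integer seeds; two runs of the CLI chain
`simulate -> measure -> qc -> fit` with the same seed produce
byte-identical outputs.

# Known limitations

* The image generator does not model optics (defocus, vignetting, uneven
  illumination); real-image performance must be validated per microscope.
* The empty-well contrast rule assumes roughly unimodal background noise;
  heavily textured debris fields could defeat it.
* The ROUT variant is a location-model reduction, not the published
  regression-coupled procedure.
* The SW and Z equations follow the cited standard definitions; the
  original rendering of those equations was not machine-readable.
* Minimum-significance-ratio analysis and plate spatial-effect (edge,
  drift) modelling are out of scope.
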