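---
title: "Normal databases and defect scoring for cardiac MIBG SPECT: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal databases and defect scoring for cardiac MIBG SPECT: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibgndb)
```

## The problem

Cardiac scintigraphy with iodine-123 MIBG, a norepinephrine analog, images
the integrity of the heart's sympathetic innervation. Two semi-quantitative
readouts dominate practice:

* the **heart-to-mediastinum ratio (HMR)** from planar images -- a global
  index, the mean count in a cardiac region of interest divided by the mean
  count in an upper-mediastinal reference region;
* **segmental defect scores** from SPECT polar maps -- a regional readout on
  the AHA 17-segment model, each segment scored 0 (normal) to 4 (absent
  uptake) and summed to a 0-68 total (SES for the early acquisition, SLS
  for the late one).

Automated segmental scoring needs a **normal database (NDB)**: per-segment
reference means and dispersions from disease-free subjects, matched to the
camera, tracer protocol and population. This package implements the full
chain -- polar-map geometry, NDB construction and pooling across
populations, automated and visual scoring, HMR computation and collimator
standardization, and the diagnostic evaluation statistics -- together with
a synthetic-cohort generator so that every stage runs, and is tested,
without patient data.

## Polar-map geometry

The bullseye is partitioned with equal-width rings: apex disc at radius
fraction $\le 0.25$, apical ring to $0.5$, mid to $0.75$, basal to $1$.
Basal and mid rings carry six 60-degree sectors, the apical ring four
90-degree sectors, each ring's first sector centered on the anterior wall,
numbered in the AHA order. This is the common realization of the 17-segment
sampling; clinical packages differ in their exact radial sampling depth and
apex handling, which are proprietary, so the piecewise-constant geometry
here is a documented stand-in and is configurable through
`segment_geometry()`. Per-segment values are means of in-map pixel counts;
`raster_from_profile()` inverts the sampling exactly for piecewise-constant
maps, which gives the round-trip identity the tests assert.

**Normalization.** Segment values are expressed as percent of reference.
The reference is the highest-valued *segment* (its mean maps to 100%),
a deterministic, noise-tolerant choice at segment granularity; an explicit
reference count (e.g. the mean of the brightest pixels) can be supplied via
`normalize_profile(reference = "value")`. Normalization is linear, so it is
invariant to global intensity scaling.

## Normal databases

`build_ndb()` stores, per segment, the cohort mean and the *sample* SD
(n − 1 denominator -- the cohorts of interest are small, tens of
subjects), with the stratum (population, sex, phase) and n. Two decisions
worth stating:

* **Dispersion is always an SD internally.** Clinical NDB files often store
  a *mean deviation*; assuming normality, the mean absolute deviation about
  the mean is $\sigma\sqrt{2/\pi}$, so files declaring mean-deviation
  dispersion are converted by $\sigma = d\sqrt{\pi/2}$ on load
  (`md_to_sd()`) and flagged `md_converted`. Whether a given vendor's "mean
  deviation" is taken about the mean or the median is generally
  undocumented; the mean-based relation is used here.
* **Pooling is subject-level and unweighted.** The combined database equals
  `build_ndb()` on the concatenated subject list, so a 55-subject cohort
  contributes 55/88 of the pooled information. This is the plain reading of
  "combined"; it makes pooling associative, which the tests assert.

`compare_ndbs()` runs a per-segment one-way ANOVA **from summary statistics
only** (between/within sums of squares reconstructed from group means, SDs
and ns), because an external NDB carries no raw data. With two groups the
F statistic is the square of the pooled-variance t; the tests check both
identities against raw-data `lm()`/`t.test()` fits on cohorts where the raw
data are available. Sex-pooled databases are the default; sex-specific
strata are available through the `sex` filter.

## Defect scoring

Two scoring routes share the 0-4 scale and the 0-68 summed score:

* **Visual rule** (`visual_score_segment()`): the percent-count bands
  $\ge 70$, 60-69, 50-59, 40-49, $< 40$ map to scores 0-4. The band edges
  are closed on the left ($u = 70 \to 0$, $u = 40 \to 3$, $u = 39.999 \to
  4$). This is a pure step function of the segment's own uptake, with no
  reference database -- which is exactly why it over-calls physiologically
  low regions (male inferior wall, apex).
* **Automated NDB-relative rule** (`auto_score_segment()`): the defect
  depth in database units, $z_s = (m_s - u_s)/\sigma_s$, is graded by how
  many of the thresholds (2, 3, 4, 5) SD it meets, capped at 4. The
  vendor mapping inside clinical software is unpublished; an SD-graded
  ladder is the established perfusion-scoring convention and has the
  properties the analysis relies on: the database's own mean profile scores
  0 everywhere, uptake above the mean is never penalized, and the score is
  monotone in defect depth. The thresholds are exposed as a parameter.
  Segments with $\sigma_s$ below 0.5% use that floor (a warning reports
  it), so a degenerate stratum cannot produce unbounded z-scores. The apex
  (segment 17) is scored like any other segment.

## HMR and standardization

`compute_hmr()` is the mean-count ratio over a circular heart ROI and a
rectangular upper-mediastinal box (non-overlapping, inside the image);
it is invariant to global intensity scaling. Because different collimators
compress or stretch the ratio, values are standardized to a common
(medium-energy general-purpose) condition with the one-point-fixed linear
form
$$\mathrm{HMR}_{std} = c\,(\mathrm{HMR}_{raw} - 1) + 1,$$
the published phantom cross-calibration convention: an image with no
cardiac excess (ratio 1) maps to 1 under any coefficient, and composing two
conversions multiplies their coefficients. No numeric constants ship with
the package -- $c$ is a property of a camera/collimator pair and comes from
the user's calibration; the default is the identity.

## Evaluation statistics

* **Agreement** (`agreement()`): Pearson r plus Bland-Altman mean
  difference and 95% limits of agreement (mean ± 1.96 SD of the paired
  differences).
* **ROC** (`roc()`): the empirical AUC is the Mann-Whitney probability
  (ties count one half); its CI uses the DeLong placement-value variance;
  the paired AUC comparison (`compare_rocs()`) is the DeLong test. The
  operating point maximizes the Youden index, ties resolved towards the
  more specific cutoff -- the cutoff-selection rule in the motivating
  clinical analyses is typically unstated, and Youden is the standard
  default. Markers are oriented internally so that "higher = disease":
  defect scores as-is, HMR negated (`direction = "<"`).
* **Group contrasts** (`kruskal_wallis()`): tie-corrected Kruskal-Wallis H
  with chi-square reference, plus Holm-adjusted pairwise Wilcoxon flags.
* **Combined model** (`fit_combined()`): maximum-likelihood logistic
  regression of case status on HMR and summed score (IRLS via `glm`,
  deviance tolerance 1e-8, max 100 iterations). The in-sample predicted
  probability is the combined marker fed to `roc()`. Perfect separation is
  detected and flagged rather than hidden; nested single-predictor
  deviances are reported, and the combined deviance can never exceed them.
* Two-sided tests and $\alpha = 0.05$ throughout.

`run_validation_pipeline()` chains these into the full analysis per phase:
database construction (two populations plus pooled), scoring of a
validation cohort (three automated variants plus visual), agreement among
them, Kruskal-Wallis contrasts of HMR and automated score across
CAD / DCM / no-disease, and ROC for visual score, automated score, HMR and
the combined model, with the paired automated-vs-visual comparison.

## The synthetic generator: what it emulates, and what it does not

`default_generator_config()` holds the generator truth; all values are
synthetic choices, made once, shaped to the qualitative structure of
normal MIBG cohorts rather than to any published table:

* base segment means 72-87% of reference, anterior/lateral high, inferior
  and septal lower, apex intermediate; late phase a uniform 2% below early;
* a **male inferior-wall decrement** of 6% (half-strength on the
  neighboring inferoseptal/inferolateral segments), reflecting the
  well-known sex difference in inferior uptake;
* an **Italian anterior decrement** of 4% (half on the anteroseptal
  neighbors) and a larger per-segment SD (8% vs 6%), mirroring the
  anterior-wall population difference and the greater heterogeneity of a
  less strictly selected cohort;
* **CAD** as a focal territorial lesion: one coronary territory (LAD, RCA
  or LCx, standard AHA segment assignment) loses a depth drawn uniformly
  from 25-50% -- sharply demarcated denervation;
* **DCM** as diffuse disease: a global 3-10% decrement on all 17 segments
  with per-segment noise inflated 1.5-fold -- widespread, heterogeneous
  dysfunction that rarely crosses the 2 SD scoring threshold in any single
  segment;
* **HMR** drawn per subject around group means 2.46/2.47 (no disease),
  2.07/1.91 (CAD) and 1.81/1.78 (DCM) for early/late, noise SD 0.25,
  floored at 1.

This produces the dissociation the pipeline is designed to exhibit: both
diseases depress the global HMR (DCM most), but only the focal CAD pattern
elevates the automated summed score, while diffuse DCM scores sit near the
normals -- so combining HMR with the score outperforms either alone.

Segment noise is independent across segments (no covariance structure is
assumed); profiles are clipped to [0, 120]% with a message. Planar images
(`simulate_planar()`) are a background plus a 2D Gaussian cardiac blob
whose amplitude is solved exactly for the target noise-free HMR, with
optional Poisson counting noise; they are generic anterior-view stand-ins,
not planogram geometry. The generator does **not** emulate acquisition
physics (attenuation, scatter, collimator response), inter-segment
correlation, age effects, or neurological uptake patterns -- so green
tests demonstrate correctness of the estimators and scoring rules under
the stated statistical model, not clinical performance on real data.

Randomness uses R's default Mersenne-Twister stream, seeded once per
generator call; identical seeds reproduce cohorts exactly.

## Numerical and test-design choices

* Sample SD throughout (n − 1); significance flags at $\alpha$ = 0.05.
* Degenerate inputs are errors, not NaNs: all-zero profiles cannot be
  normalized, databases need n ≥ 2 and a single phase, ROC needs both
  classes, the all-tied Kruskal-Wallis case reports H = 0, p = 1.
* NDB CSV round-trips are bit-exact (17 significant digits); cohort CSVs
  serialize at 6 significant digits so identical inputs give identical
  bytes.
* Test problem sizes are chosen so each property has comfortable
  statistical margin at a fixed seed: parameter recovery at n = 500 is
  asserted on the across-segment mean relative error (≤ 1% for means,
  ≤ 5% for SDs; the per-segment SD estimator alone has ~3.2% relative SE
  at this n, so per-segment bands are set wider at 3%/15%), the
  Kruskal-Wallis null level on 2000 replicates, Bland-Altman coverage at
  n = 5000, logistic coefficient recovery at n = 2000 with a design whose
  expected relative SEs (~5-6%) sit well inside the 10% tolerance, and the
  CAD/DCM/normal dissociation on groups of 200. The end-to-end driver
  scripts use the study-scale cohorts (55 + 33 normals; 19 + 8 + 12
  validation subjects).

## Known limitations

The polar-map sampling is an idealized stand-in for proprietary clinical
geometry; the automated score ladder is a convention, not a reproduction of
any vendor's mapping; HMR conversion coefficients must come from the user's
own phantom calibration; and all empirical claims in this vignette are
claims about the synthetic model that the test suite itself computes.
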