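# mibgndb

Quantitative cardiac sympathetic-innervation imaging with ¹²³I-MIBG:
normal-database construction, segmental defect scoring and
heart-to-mediastinum ratio (HMR) analysis for AHA 17-segment SPECT polar
maps, with the statistics used to validate them for heart-failure
discrimination. Intended for nuclear-cardiology methodologists building or
evaluating camera- and population-specific reference databases.

## What it computes

**Normal database (NDB).** From a cohort of disease-free subjects'
normalized segmental profiles \(u_{is}\) (percent of reference), the NDB
stores per segment \(s\) the mean \(m_s\) and sample SD \(\sigma_s\),
stratified by population, sex and phase (early/late). Databases that store
a mean deviation \(d_s\) are converted by the normal-distribution relation
\(\sigma_s = d_s\sqrt{\pi/2}\). Cohorts pool at the subject level, and
databases are compared segment-wise by one-way ANOVA reconstructed from
summary statistics.

**Defect scores.** Each segment gets an integer 0 (normal) to 4 (absent):

* visual rule — percent-count bands ≥ 70, 60–69, 50–59, 40–49, < 40;
* automated rule — \(z_s = (m_s - u_s)/\sigma_s\) graded by the thresholds
  2, 3, 4, 5 SD below the normal mean.

Summing over the 17 segments gives the summed early/late score (SES/SLS,
range 0–68).

**HMR.** Mean heart-ROI counts over mean mediastinal-ROI counts on the
planar image, standardized across collimators by the fixed-point linear
form \(\mathrm{HMR}_{std} = c(\mathrm{HMR}_{raw}-1)+1\).

**Evaluation.** Pearson correlation and Bland–Altman limits of agreement
between scoring variants; Mann–Whitney AUC with DeLong CI and paired
DeLong tests; tie-corrected Kruskal–Wallis contrasts across CAD / DCM /
no-disease groups; and a multivariable logistic model combining HMR with
the defect score, whose predicted probability is itself ROC-analyzed.

A seeded synthetic-cohort generator (population- and sex-specific segment
means, focal coronary-territory lesions for CAD, diffuse decrements for
DCM, planar images with target HMR) exercises everything end to end; the
methods vignette (`vignettes/mibg-ndb-methods.Rmd`) documents the model
and every default.

## Worked example

```r
library(mibgndb)

study <- simulate_study(n_jp = 55, n_it = 33, n_cad = 19, n_dcm = 8,
                        n_control = 12, seed = 20260101)
report <- run_validation_pipeline(study$jp_normals, study$it_normals,
                                  study$validation)
print(report)
#> == late phase ==
#> agreement (summed scores): JpIt~Jp r=0.990, JpIt~It r=0.989, visual~auto r=0.956
#> Kruskal-Wallis p: HMR 0.0001239, automated score 1.133e-07
#> AUC: visual 1.000, automated 1.000 (DeLong p=1.000), HMR 0.907, combined 1.000
```

Reading this: the subject-pooled combined database scores agree closely
with each population database (r ≈ 0.99); both HMR and the automated score
separate the three clinical groups (Kruskal–Wallis p < 0.001); and on this
synthetic validation cohort each marker discriminates disease from
controls, with the logistic combination at least as good as either alone.
The group patterns behind those numbers (from `analysis/03_score_defects.R`
on the same seed) show the designed dissociation — only focal disease
drives the summed score, while both diseases depress HMR:

```
late-phase mean summed score (JpIt automated):  none 0.9 | CAD 19.4 | DCM 7.0
late-phase mean HMR:                            none 2.51 | CAD 1.97 | DCM 1.81
```

The numbered drivers reproduce the whole workflow and leave their tables
under `results/`:

```sh
Rscript analysis/01_simulate.R       # cohorts + generator manifest
Rscript analysis/02_build_ndbs.R     # Jp / It / pooled NDBs + segment ANOVA
Rscript analysis/03_score_defects.R  # automated + visual score tables
Rscript analysis/04_evaluate.R       # agreement / contrasts / ROC report
```

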