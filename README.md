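# netconsist

Quantifying how *consistently* subcortical-cerebellar-to-cortical intrinsic
functional connectivity (iFC) patterns differ between two groups of
resting-state fMRI subjects.

## The problem

Slow (< 0.1 Hz) spontaneous BOLD fluctuations organize the brain into
intrinsic networks. Group studies usually ask whether connectivity differs
*on average*; this package asks how *reliably per subject* a multivariate
connectivity pattern separates patients from controls. The probe is
leave-one-out cross-validated (LOOCV) classification: a held-out subject is
assigned to a group by a linear support-vector machine (SVM) trained on
everyone else, so accuracy measures the inter-subject consistency of the
group difference, not just its mean size.

Connectivity features are Fisher r-to-z transformed Pearson correlations
of time courses, in four families:

| family            | rows x columns                               |
|-------------------|-----------------------------------------------|
| `allROIs-NWs`     | all seed ROIs x all cortical networks          |
| `NWs-NWs`         | network pairs (strict upper triangle)          |
| `allROIs-allROIs` | ROI pairs (strict upper triangle)              |
| `separateROI-NWs` | one system's ROIs (striatum / cerebellum / MTL / amygdala) x all networks |

Feature families are compared by the exact paired binomial (sign) test on
per-subject outcomes: with `W` the subjects one family gets right and the
other wrong, out of `N` discordant subjects, `W ~ B(N, 1/2)` under equal
performance.

The pipeline covers every stage: a seeded synthetic BOLD cohort generator
with planted group-dependent ROI-network coupling (no patient data are
distributable); motion/tSNR quality control with conventional exclusion
thresholds (cumulative translation > 3 mm, mean point-to-point > 0.15 mm /
0.1 deg); band-pass (0.009-0.08 Hz Butterworth, zero-phase) and nuisance
regression; group spatial ICA (two-step PCA, infomax, multi-run ICASSO
stability, dual-regression back-reconstruction, spatial-regression template
matching); feature construction; a native SMO linear-SVM LOOCV classifier;
and the exact binomial family comparison.

## Worked example

A desk-scale run — 18 + 18 subjects, 300 volumes at TR 2 s, 16 spherical
seed ROIs at literature MNI coordinates, 8 latent cortical networks on a
9600-voxel grid, with large planted cerebellum/MTL coupling shifts and
small striatum/amygdala shifts:

```r
library(netconsist)
cfg <- run_config(
  sim = sim_config(seed = 0),
  ica = ica_config(n_group_components = 12, n_icasso_runs = 2,
                   max_iter = 50, tol = 1e-4),
  seed = 1)
report <- run_pipeline(cfg, verbose = FALSE)
print(report)
```

```
== Classification consistency report ==
subjects analyzed: 36 (excluded by QC: 0)
          family accuracy sensitivity specificity n_features n_subjects
     allROIs-NWs   100.0%        1.00        1.00        128         36
         NWs-NWs    77.8%        0.72        0.83         28         36
 allROIs-allROIs    33.3%        0.33        0.33        120         36
    striatum-NWs    61.1%        0.50        0.72         32         36
  cerebellum-NWs   100.0%        1.00        1.00         32         36
         MTL-NWs   100.0%        1.00        1.00         32         36
    amygdala-NWs    58.3%        0.56        0.61         32         36
```

Reading the output: the planted strong cerebellar and MTL coupling shifts
are recovered as perfect classification consistency, the weak striatal and
amygdalar shifts stay near chance, and the combined `allROIs-NWs` family
is at least as consistent as the cortico-cortical `NWs-NWs` baseline
(which carries no planted effect; its above-chance accuracy is an emergent
consequence of shared signal paths, discussed in the vignette). The report
also carries the pairwise `W`, `N` and exact p-values — in this run
`cerebellum-NWs` beats `striatum-NWs` on `W = 14` of `N = 14` discordant
subjects, one-sided `p = 6.1e-05` — and the ICASSO stability indices of
the selected components.

Ground truth for every planted quantity is returned by
`generate_cohort()`, so each stage can be checked in isolation:
`extract_roi_timecourse()`, `bandpass()`, `regress_nuisance()`,
`concat_reduce()`, `infomax_ica()`, `icasso_stability()`,
`back_reconstruct()`, `match_templates()`, `build_feature_matrix()`,
`train_linear_svm()`, `loocv()`, `paired_binomial()`,
`compare_all_families()`.

A thin CLI over the same functions lives at
`inst/scripts/run-pipeline.R` (`run-all` / `simulate` subcommands with
`--config`, `--seed`, `--out`).

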