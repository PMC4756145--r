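---
title: "Methods: classifying subcortical-cortical connectivity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying subcortical-cortical connectivity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the pipeline answers

Resting-state fMRI measures slow (< 0.1 Hz) spontaneous BOLD fluctuations.
Correlations between the time courses of brain regions or networks —
intrinsic functional connectivity (iFC) — form a per-subject connectivity
fingerprint. Given two groups (here labelled *patients* and *controls*),
the question is not merely whether connectivity differs on average but how
**consistently** a multivariate connectivity pattern separates individuals:
if a classifier trained on everyone else assigns a held-out subject to the
right group, the group difference must be expressed reliably in that
subject too. Leave-one-out classification accuracy is therefore read as a
consistency measure, not as a diagnostic claim.

The pipeline compares four families of iFC features:

* `allROIs-NWs` — every subcortical-cerebellar seed region (ROI) against
  every cortical intrinsic network (NW);
* `NWs-NWs` — network-network connectivity (strict upper triangle);
* `allROIs-allROIs` — ROI-ROI connectivity (strict upper triangle);
* `separateROI-NWs` — one system's ROIs (striatum, cerebellum, medial
  temporal lobe, or amygdala) against all networks.

Two contrasts matter: whether ROI-to-network patterns classify better than
either within-cortical or within-subcortical patterns, and whether the four
subcortical-cerebellar systems differ among themselves — *differential
consistency*.

# Stages and their models

## Synthetic cohort (`sim_config()`, `generate_cohort()`)

No empirical scans ship with the package; a seeded generator produces
cohorts in which every downstream claim can be checked against ground
truth. Per subject, the voxel-by-time data are

```
Y = baseline + networks + ROI signals + nuisance + noise
```

* **Latent networks.** `n_latent_networks` (default 8) Gaussian blobs
  (sigma 8 mm) on a dorsal band of the grid, placed by farthest-point
  ordering so each map has a disjoint-dominant peak — the condition under
  which template matching is well-posed. Their time courses are
  band-limited (< 0.1 Hz) unit-variance Gaussian processes.
* **Planted coupling.** Each system's ROIs receive a target correlation
  with the system's designated networks: `baseline_coupling` (0.2) for
  controls, plus a per-system shift for patients
  (`effect_size_per_system`, defaults −0.45 cerebellum, −0.40 MTL, −0.05
  striatum, −0.05 amygdala — large cerebellar/MTL hypoconnectivity, small
  striatal/amygdalar shifts). Subjects vary around their group target with
  SD `within_group_sd` (0.1, correlation units). The joint
  network-plus-ROI-signal correlation matrix is assembled explicitly and
  checked for positive semi-definiteness; an infeasible request is
  projected to the nearest correlation matrix, silently below an
  adjustment of 1e-6 (Frobenius), with a warning up to 0.05, and rejected
  beyond that, naming the offending system block.
* **Nuisance.** A global signal (flat spatial map, including a linear
  scanner drift), plus white-matter and CSF blobs, each with its own
  band-limited time course and amplitude (`nuisance_amplitudes`, data
  units). Tissue masks for these compartments are part of the ground truth
  so that nuisance extraction downstream needs no segmentation.
* **Motion.** Six-parameter random walks (default steps 0.01 mm,
  2e-4 rad), written in the SPM `rp` file dialect (radians on disk,
  degrees in memory). Motion is independent of the BOLD content; it exists
  to exercise QC, not to corrupt the data.
* **Geometry.** The default grid is 20 x 24 x 20 voxels at 5 mm (9600
  voxels), positioned to cover the printed MNI seed coordinates and to be
  symmetric about x = 0 so left/right seeds resolve to mirror masks.

What the generator deliberately does **not** emulate: hemodynamic response
convolution, scanner artifacts, spatial autocorrelation of noise, subject
misregistration, or spatial smoothing. Passing tests therefore demonstrate
that the *analysis machinery* recovers planted effects under realistic
temporal structure — not that real scanner data would behave identically.

## Quality control and temporal preprocessing

The first 3 of 300 volumes are discarded (magnetization equilibration in
the emulated acquisition; TR = 2 s). Exclusion thresholds follow the
emulated protocol: cumulative translation > 3 mm, mean point-to-point
translation > 0.15 mm, mean point-to-point rotation > 0.1 degrees.
"Cumulative translation" is read as the maximum Euclidean displacement
from the first retained volume (a path-length alternative is a flag). RMS
translation is computed on demeaned traces so that every QC metric is
invariant to a constant parameter offset. tSNR is the voxelwise temporal
mean over SD, averaged with zero-SD voxels excluded and counted.

ROI time courses are extracted as the first right-singular vector of the
row-centered voxel-by-time submatrix of each 6 mm spherical seed (sign
fixed against the ROI mean course, unit variance), band-pass filtered to
0.009-0.08 Hz with an order-4 Butterworth applied forward-backward (zero
phase; the effective gain is the squared single-pass response), and
cleaned by OLS regression on nine nuisance regressors: gray-matter,
white-matter and CSF mean signals plus the six motion parameters. The
processing order — filter first, then regress, with the regressors
band-passed to the same band — avoids reintroducing out-of-band variance
through the regression; both the order and the Butterworth order are
configuration switches. Whether network time courses receive the same
cleanup is genuinely open in the emulated protocol; the default is off
(`clean_network_tcs = FALSE`), cleaning only ROI courses.

## Group ICA (`concat_reduce()`, `icasso_stability()`, `back_reconstruct()`, `match_templates()`)

Subjects are reduced by two-step PCA (per-subject temporal PCA to
`n_subject_pcs`, default 1.5x the component count; concatenation; group
PCA to `n_group_components`), then unmixed by natural-gradient infomax
with the logistic nonlinearity — appropriate for the super-Gaussian
spatial sources of BOLD networks. Infomax starts from a seeded random
rotation, anneals its learning rate on oscillation, and flags
non-convergence. Stability is assessed ICASSO-style: `n_icasso_runs`
restarts (different seeds; voxel bootstrap optional) are pooled and
clustered by average linkage on `1 - |r|` of the spatial maps; each
cluster's centrotype is returned with a stability index (mean
within-cluster minus mean between-cluster `|r|`). A single run returns
`NA` stability with a warning.

Back-reconstruction uses spatio-temporal (dual) regression — subject time
courses from regressing data on group maps, subject maps from regressing
data on those time courses. Among the back-reconstruction variants in
common toolboxes this one was chosen for transparency: it is two ordinary
least-squares steps whose recovery can be verified exactly on noiseless
planted data.

Networks of interest are selected by template matching at the group level:
each template is regressed on all component maps and the standardized
coefficient scores the pair (plain correlation is a fallback flag);
assignment is greedy in descending score without replacement, with
deterministic index tie-breaks. In synthetic runs the templates are the
ground-truth network maps — the stand-in for a canonical cortical template
set. The emulated full design decomposes into 75 components, runs 40
ICASSO restarts and keeps 22 cortical networks; those remain valid
configuration values, while the desk-scale defaults (8-12 components, a
handful of restarts) keep a full run on one CPU in tens of seconds. The
pipeline default requests `n_latent_networks + 4` components so nuisance
structure can occupy components that template matching then ignores,
mirroring the overcomplete-decompose-then-select approach.

## Features, classifier, comparison

Per subject and family, Pearson correlations of the prescribed time-course
pairs are Fisher r-to-z transformed (`atanh`), with `|r|` clipped at
`1 - 1e-7` (each clip logged) so features stay finite. Feature order is
lexicographic in the entity names and identical across subjects. No
cohort-level standardization happens at this stage — any standardization
belongs inside the training fold.

Classification is a soft-margin linear SVM solved natively by SMO with
maximal-violating-pair working-set selection (second-order candidate
scoring, deterministic tie-breaks) to a KKT gap of `tol` (default 1e-3;
`C = 1`). Within each leave-one-out fold, features are z-standardized
using training-fold statistics only, applied unchanged to the held-out
subject — the usual toolbox normalization, made leakage-free. The held-out
prediction rule is `w.x + b > 0` for the patient class; patient is the
positive class for sensitivity. Off-the-shelf SVMs (libsvm, an
interior-point QP) appear only as test oracles, never in the pipeline.

Families are compared by the exact paired binomial (sign) test on the
per-subject outcome vectors: with `W` the subjects one family classifies
correctly and the other not, out of `N` discordant subjects,
`W ~ Binomial(N, 1/2)` under equal performance; the one-sided tail is
summed from binomial coefficients. `N = 0` returns `p = 1` by convention.
Sidedness is not fixed by the emulated protocol; the default is one-sided
in the direction of the numerically better family (the orientation every
report states), two-sided by flag. No multiple-testing correction is
applied by default, mirroring the emulated tables; Holm adjustment of the
resulting column is a one-liner for users who want it.

# Determinism, caching, problem sizes

One global seed fans out to per-stage child seeds; identical
configurations reproduce reports bit-identically (this is asserted in the
tests). With an output directory set, stages downstream of simulation are
cached keyed by a hash of the configuration sections they depend on;
the cohort itself is regenerated rather than cached because at desk scale
it is ~0.8 GB in memory and re-simulation is cheap and deterministic.

Test and acceptance problem sizes are the package's own choices: unit
tests run on ~10-subject cohorts with a 10^3-voxel grid; the
differential-consistency study runs 50 seeds at desk scale (36 subjects,
297 retained volumes, 9600 voxels, 8 latent networks, ICA with 12
components, 2 ICASSO restarts capped at 50 epochs) — settings at which the
planted large-versus-small system shifts are recovered while a full
50-seed study completes on a single CPU. Paper-scale settings (75
components, 40 restarts, 22 templates) are configuration values, not code
changes.

# Known limitations

* The generator's group difference lives entirely in ROI-network coupling
  blocks; network-network differences arise only indirectly (shared
  nuisance, regression cross-talk), so `NWs-NWs` accuracy in synthetic
  runs is an emergent, not planted, quantity.
* Infomax model-order selection is not addressed; the component count is
  a configuration input.
* The exact binomial comparison conditions on discordant pairs and is
  conservative for small `N`; with 36 subjects and similar accuracies,
  `N` is often in the single digits.
* The published p-values and accuracies of the study this design emulates
  derive from unpublished per-subject scanner data and outcome vectors;
  they cannot be recomputed here, and nothing in this package attempts to.

```{r}
library(netconsist)
cfg <- run_config(sim = sim_config(seed = 0), seed = 1)
report <- run_pipeline(cfg)
print(report)
```
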