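---
title: "Shape and CSF biomarkers along the dementia cascade: methods and design"
author: "shapemarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape and CSF biomarkers along the dementia cascade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapemarkers)
```

# The analysis

`shapemarkers` implements a baseline-biomarker analysis of early
neurodegeneration: given per-subject cerebrospinal-fluid markers (A&beta;42,
t-tau, p-tau) and corresponded triangulated surfaces of the hippocampus and
lateral ventricles for normal controls (NC), mild cognitive impairment (MCI,
split post hoc into two-year converters MCI-c and non-converters MCI-s) and
Alzheimer's disease (AD), it asks which markers separate which pair of
diagnostic groups, and how well the baseline markers predict MCI-to-AD
conversion. The pipeline is

1. **shape representation** — pairwise diffeomorphic metric distances between
   corresponded surfaces, reduced to ~20 coordinates by ISOMAP;
2. **feature screening** — pooled-variance Student t-tests select the shape
   components and CSF markers separating a given contrast;
3. **classification** — a linear soft-margin SVM evaluated by leave-one-out
   cross-validation inside 100 balanced random subsamples of the diagnostic
   groups;
4. **conversion prediction** — the NC-vs-AD classifier applied to all MCI
   subjects at baseline;
5. **deformation maps** — vertex-wise signed normal displacement between
   group mean surfaces.

Real corresponded surfaces come from atlas injection (deforming one smooth
atlas surface into every subject's segmentation), which is out of scope
here; the package ships a synthetic cohort generator that emulates the
statistical structure such data would have, so every stage is testable
without restricted clinical data.

# The shape metric

Corresponded surfaces with vertex sets $x_a, x_b \in \mathbb{R}^{V\times3}$
are compared with the first-order (initial-momentum) approximation of the
LDDMM landmark geodesic distance at the identity:

$$ d^2(a, b) = \sum_{c \in \{x,y,z\}} \Delta_c^\top K^{-1} \Delta_c, \qquad
   K_{ij} = \exp\!\left(-\frac{\lVert x_{a,i} - x_{a,j}\rVert^2}{2\sigma^2}\right), $$

with $\Delta = x_b - x_a$ the corresponded displacement and the momentum
$p = K^{-1}\Delta$ solved per coordinate (a ridge $\varepsilon$ on the
diagonal keeps the solve well-posed). The metric charges a displacement by
how hard it is to generate with a smooth velocity field: smooth fields
(global growth, wide deformations) are cheap, rough fields are expensive.
Because the one-sided form evaluates the kernel on the first shape, the
reported distance is the symmetrized
$\sqrt{(d_{a\to b}^2 + d_{b\to a}^2)/2}$, making the distance matrix exactly
symmetric. Every subject is first rigidly aligned (rotation + translation,
*no scaling* — overall size is a finding in this analysis, not a nuisance)
to the cohort's first subject.

Key parameters:

| parameter | default | units | rationale |
|---|---|---|---|
| `kernelSigma` | 5 × mean edge length | mm | smooth anatomical deformations are cheap at this scale, localized change is still resolved |
| `ridge` | 1e-6 | — | conditioning only; the kernel diagonal is 1 |
| ISOMAP `k` | 10 | neighbours | doubled automatically (with a warning) if the graph disconnects |
| ISOMAP `m` | 20 | components | the dimension at which real bilateral shape embeddings become quasi-isometric |
| selection `alpha` | 0.05 | — | per-component two-tailed screen, no multiplicity correction (an FDR switch exists) |
| SVM `C` | 1 | — | on z-scored features |
| `nTrials` | 100 | — | balanced subsampling repeats |

# ISOMAP embedding

The distance matrix is turned into coordinates by geodesic distances on the
symmetric k-nearest-neighbour graph (Dijkstra) followed by classical
scaling: eigendecomposition of $B = -\tfrac12 J D^{(2)} J$, with $J$ the
centering matrix, coordinates being the top-$m$ eigenvectors scaled by the
square roots of their eigenvalues. Numerical conventions: negative
eigenvalues (non-Euclidean input) are clamped to zero for coordinates but
kept in the eigenvalue slot as a diagnostic; each eigenvector's sign is
fixed so its largest-magnitude entry is positive (eigenvector sign is
otherwise arbitrary and would break byte-level reproducibility); columns
are centered by construction. The embedding's *fidelity* is the Pearson
correlation between embedded Euclidean distances and the input metric
distances over subject pairs — on real bilateral hippocampal and
ventricular shapes this figure is reported around 0.91 and 0.97 at 20
components, and the default synthetic cohort reproduces that regime (the
acceptance suite computes it).

Left and right structures enter one embedding through the entrywise
root-sum-square combination $d = \sqrt{d_L^2 + d_R^2}$, the distance induced
by concatenating the two displacement spaces. Whether the original analysis
concatenated surfaces or combined per-side distances is not documented; the
combination rule is exposed as its own operation so either reading can be
assembled.

The embedding is *transductive*: all subjects, including those later used
as test subjects, are embedded jointly before classification. This mirrors
the reference protocol (which embeds the full sample at once) and is a
known source of optimism; nested per-fold embedding is deliberately not
silently substituted, because the goal is to reproduce the protocol as
described. The same applies to feature selection, which runs once per
contrast on the full cohort rather than inside the cross-validation loop.
Conversion prediction is the exception: there the spec of the task itself
separates training (NC + AD) from application (MCI), so selection and
z-scoring statistics are computed on NC + AD subjects only.

# Classification protocol

Group sizes are unequal (72 NC / 111 MCI / 35 AD), so each evaluation
repeatedly subsamples every group, without replacement, to the smallest
diagnostic group's size (35 by default) and runs leave-one-out
cross-validation within the trial; accuracy, sensitivity and specificity
are averaged over 100 trials and the 95% confidence interval of the mean
accuracy is reported as mean ± 1.96·SD/√n (a percentile option exists).
The positive class is always the more impaired group (AD > MCI > NC), so
sensitivity means detecting disease. Within a balanced trial, accuracy
equals (sensitivity + specificity)/2 exactly — the suite asserts this
identity. Trial RNG streams derive from the report seed, so two marker sets
evaluated with the same seed have paired trials, and paired Student t-tests
compare their per-trial accuracies.

**A calibration caveat the tests make explicit.** The trial CI measures
subsample-resampling noise *within one cohort*. Under a null cohort (no
planted effects) two things happen: the smallest group is reused in full in
every trial, so the realized chance separation of that group is invisible
to the trial CI (cohort-level accuracy varies with SD ≈ 0.05–0.08 across
null cohorts, several times the CI half-width); and leave-one-out itself is
pessimistically biased (the held-out subject's class is always the 34-vs-35
training minority, so the C = 1 SVM leans toward the majority class,
shifting null accuracy to ≈ 0.45). Consequently the trial CI of a null run
usually does *not* cover 0.5 — the acceptance suite contains a calibration
check that documents exactly this behaviour. The CI should be read as "the
mean over subsampling trials of this cohort is estimated this precisely",
never as a population-level confidence statement.

# Conversion prediction

Per trial, NC is subsampled to the AD group's size (balanced training; a
flag trains on all 72 NC instead), the linear classifier is trained on
NC vs AD and applied to all 111 MCI subjects. Sensitivity is the fraction
of MCI-c labeled AD-like, specificity the fraction of MCI-s labeled
NC-like. With stable MCI drawn from an intermediate marker distribution —
the default — many non-converters fall on the AD side of the NC/AD
boundary: high sensitivity, low specificity, the qualitative pattern the
analysis is known for. The suite asserts it as a majority property over
cohort seeds rather than as a value match.

# Deformation maps

For two groups, each subject's vertex positions are projected on the atlas
mesh's outward area-weighted vertex normals; the map is the normal component
of the difference of group means (positive = outward in the first-named
group), with a per-vertex pooled-t statistic and two-tailed p alongside (the
map is descriptive; no vertex-wise multiplicity correction by default).
Swapping the groups negates the map exactly. A global shrinkage effect
produces same-signed (inward) displacement almost everywhere, while the
volume-neutral planted bump produces mixed signs — both are asserted on
synthetic cohorts.

# The synthetic cohort generator

`generateCohort()` emulates the joint structure the analysis assumes, with
defaults frozen as the package's study conditions:

* **composition**: NC 72, MCI-s 86, MCI-c 25, AD 35 (218 subjects, 111 MCI);
* **CSF**: per-group correlated Gaussians (pg/mL). NC (205, 70, 25) ±
  (55, 30, 10); MCI-s (170, 115, 38) ± (50, 45, 13); MCI-c and AD
  (115, 115, 38) ± (45, 45, 13); corr(t-tau, p-tau) = 0.95 (the two tau
  measures are nearly collinear in CSF assays), corr(A&beta;42, tau) = −0.15.
  The tau means *plateau* by MCI while A&beta;42 keeps falling — so all
  three markers separate NC from MCI and from AD, but only A&beta;42
  separates MCI from AD, the marker pattern the screening stage must
  recover. Equal tau SDs across MCI/AD keep the pooled t-test calibrated
  under the group-size imbalance. MCI-c draws its CSF from the AD
  distribution and MCI-s from the intermediate MCI distribution, giving
  baseline markers genuine conversion signal;
* **global volume effects**: hippocampal linear scale 0.95 and ventricular
  1.06 shared by MCI and AD (≈ −14% and +19% volume) — volumes separate
  the impaired groups from NC but *not* MCI from AD;
* **local shape effect**: a paired outward + inward Gaussian bump
  (amplitude 0.6 mm, angular width 0.6 rad, antipodal centers chosen on the
  hippocampal base mesh) carried by AD and MCI-c only. The pairing makes the
  deformation volume-neutral to first order (measured residual ≈ 0.5%), so
  MCI vs AD is separable by shape components but not by volume — the
  dissociation at the heart of the analysis;
* **inter-subject variability**: a per-subject lognormal global size jitter
  (SD 0.05) gives the continuous volume spread that makes component–volume
  correlations meaningful; per-vertex i.i.d. jitter defaults to 0 mm
  because atlas-injected surfaces are smooth by construction — white vertex
  noise is not a feature of such data, and the smoothness-penalizing metric
  correctly assigns it enormous cost (it lives in the kernel's near-null
  space). The jitter parameter exists for robustness experiments and for
  stages that do not pass through the metric (e.g. deformation-map
  localization tests use 0.15 mm);
* **geometry**: ellipsoidal icosphere base meshes, subdivision 2
  (162 vertices / 320 triangles), semi-axes (17.5, 8, 6) mm for the
  hippocampus (≈ 3500 mm³) and (30, 15, 10.6) mm for the ventricle;
  left/right are independent draws sharing one connectivity;
* **reproducibility**: all randomness flows from one cohort seed through
  per-subject substreams (a splitmix-style integer mix decorrelates the
  streams), so adding a subject never perturbs existing records.

What the generator does **not** emulate: segmentation error, topological
repair artifacts, scanner effects, longitudinal trajectories, age/sex
confounding, or realistic anatomical shape variation beyond size and one
planted local effect. Passing tests therefore show the *pipeline* recovers
planted structure under the stated conditions; they are not evidence about
real cohorts. One consequence worth knowing: because the planted bump is
binary (carriers vs non-carriers), the default cohort is bimodal in shape
space and the k = 10 neighbourhood graph disconnects; the embedding's
automatic k-doubling then connects it (at k = 80 for the default cohort)
with a warning. Real cohorts vary continuously and would not trigger this.

# Numerical choices and degenerate inputs

* Meshes are validated as closed, consistently oriented 2-manifolds with no
  degenerate triangles (area < 1e-12 mm²); volume is the absolute
  divergence-theorem sum, so either global orientation is accepted.
* Vertex indices are 1-based in memory; OFF/PLY writers emit the formats'
  native 0-based indices, coordinates at 10 significant digits.
* A singular kernel at ridge 0 raises an error directing the user to a
  positive ridge rather than returning garbage momenta.
* Zero pooled variance makes the Student t undefined: the screening
  operation raises an error, while the deformation map (where noise-free
  identical groups are legitimate) reports NA at the affected vertices.
* Degenerate paired comparisons (zero-variance accuracy differences) are
  flagged rather than silently tested.
* Problem sizes in the test suite are the package's own choices: base
  meshes at subdivision 1–2, cohorts of 218 (composition-sensitive checks)
  or a few dozen subjects (pipeline checks), 4–25 subsampling trials in
  unit tests and 20–25 in the acceptance suite, 50-replicate calibration
  loops. The full reference protocol (100 trials) remains the default of
  every exported function.

# Known limitations

* Transductive embedding and whole-cohort feature selection reproduce the
  reference protocol's optimism; nested alternatives are exposed but off by
  default.
* The first-order metric is a linearization at the identity: it is accurate
  for the small-to-moderate deformations the generator produces and
  increasingly crude for large ones (no geodesic shooting, currents or
  varifolds).
* The trial confidence interval is conditional on the cohort (see the
  calibration caveat above).
* Synthetic anatomy is ellipsoidal; vertex counts are an order of magnitude
  below the real atlas surfaces, and the kernel width rule (5 × mean edge)
  therefore corresponds to a coarser smoothing scale than on real data.
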