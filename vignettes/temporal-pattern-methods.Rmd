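---
title: "Temporal-pattern features of postprandial time courses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal-pattern features of postprandial time courses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttpatterns)
```

## The data and the problem

An oral glucose tolerance test perturbs the whole blood metabolome: after
a 75 g glucose load, glucose-related hormones surge within an hour, free
fatty acids and ketone bodies are suppressed, and amino acids drift down
over several hours as insulin promotes their uptake. With a dense sampling
grid (13 draws over 0–240 min, the fasting draw usually duplicated at
−10 min) and a panel of tens of molecules in tens of subjects, the
questions this package answers are: which molecules respond, what shape
the response has, how reproducible that shape is across people, whether
people keep their relative positions over time, and which molecules move
together.

The canonical container is `timecourse_dataset`: a subject × molecule ×
time array with explicit `NA`s for missing draws, plus an annotation
assigning each molecule to one of six metabolic groups (glucose-related,
lipid, amino acid, ion, hormone, other). The tidy CSV interchange format
has one measurement per row; an empty cell is the only missing marker, so
round trips preserve missingness exactly.

## Preprocessing

**Fasting duplicates.** When both pre-ingestion draws exist, the t = 0
value becomes their mean; a single draw is used as is. The published
protocol does not say whether the analysed fasting value is the mean or
the second draw; the mean is the less noisy choice and is logged.

**Missing-data exclusion** removes molecules whose missing-cell count
strictly exceeds `floor(n_subjects × n_times × 0.05)` — 14 cells for the
20 × 14 raw layout. The strict comparison retains molecules sitting
exactly at the budget. Filtering runs on the raw (pre-collapse) grid so
the budget matches the sampling protocol. No imputation is done anywhere.

**Normalization** expresses each subject's trajectory as the difference
from fasting divided by the molecule's time-averaged cross-subject
standard deviation. Two denominator conventions coexist deliberately: the
dispersion scale $\bar S_k$ uses the population denominator $N$, while the
TVRI z-scores use the sample denominator $N-1$. Both are implemented
exactly as defined, each in its own module; no "correction" is applied,
and tests pin both. A time point with fewer than two available subjects
contributes no dispersion estimate and is skipped in the time average; a
molecule constant everywhere has $\bar S_k = 0$ and is excluded with
reason `"zero dispersion"`. By construction $\bar Y_{k,0} = 0$ exactly,
and $Y$ is invariant to rescaling a molecule's unit — both are asserted in
the suite.

## Responder calling

Each post-ingestion time point is compared with fasting by a two-tailed
paired t-test (pairwise-complete subjects, at least 3 pairs). The fold
change is the mean over subjects of the per-subject log2 ratio — chosen
over the ratio of means because the design is paired; the alternative is
available via `fold_changes(method = "ratio_of_means")`. Subjects with
non-positive concentrations are dropped from the log ratio with a warning.

Q-values follow Storey's procedure: $\hat\pi_0 = \#\{p > \lambda\} /
((1-\lambda) m)$ at a fixed $\lambda = 0.5$, then the Benjamini–Hochberg
step-up quantities scaled by $\hat\pi_0$ and clipped to [0, 1]. The fixed
$\lambda$ keeps results deterministic; the spline smoother over a
$\lambda$ grid is available by flag. All molecule × time tests form one
q-value family by default (the conservative reading when nothing is said
about stratification); per-molecule families are a config option.

A molecule is a responder when some time point has |log2 FC| strictly
above 0.585 and q strictly below 0.1; its direction is the sign of the
fold change at the earliest such time, which resolves trajectories that
cross zero. Degenerate paired tests are made explicit rather than left to
floating point: all differences zero gives p = 1; identical non-zero
differences give p = 0 with a `degenerate` flag.

## Clustering and the amplitude–rate decomposition

Mean normalized trajectories are clustered with Euclidean distance and
Ward's criterion in the `ward.D2` convention (distances not pre-squared),
the variant consistent with Ward's original objective and the default in
modern implementations; the merge heights are verified against an
independent Lance–Williams agglomeration in the tests. The tree is cut to
a requested K (13 for the full panel, 4 for the fasting-correlation
matrix — the published dendrogram cut heights are never given numerically,
so K is the ground truth and a config parameter). Cluster mean
trajectories are labelled: amplitude large above 2.5 normalized units,
small between 1.5 and 2.5, not clear below 1.5; transient when the
absolute value falls to ≤ 50% of the extremum later in the window,
sustained otherwise.

PCA mean-centres the time-point columns across molecules (no variance
scaling) and decomposes by SVD. Column centring was chosen over row
centring because a molecule with no excursion then sits at the origin of
the score space, which is how unresponsive molecules should read.
Loadings are reported as correlations between scores and time columns, so
they live on [−1, 1]. Because singular vectors have arbitrary sign, a
fixed orientation is imposed: PC1's loading at the time point nearest
90 min is positive (PC1 then reads as amplitude-and-direction), and PC2's
loading at the earliest post-ingestion point is positive (PC2 then reads
as rate: early-positive, late-negative). On the study-like preset two
components carry well over 85% of the variance, as expected for a
generator built from two effective temporal degrees of freedom plus
noise.

## The similarity indices

**TPSI** concatenates, over all unordered subject pairs (i < j in input
order), the two difference-from-fasting trajectories into two long
vectors and takes one Pearson correlation. The t = 0 entries are included
although they are identically zero — the index is defined over the whole
trajectory and this deflates correlations slightly; it is kept as defined.
The value is invariant to the block order of the concatenation, to
subject-specific additive offsets (differencing removes them) and to a
common rescaling.

**TVRI** is 1 minus the mean over subjects of the time-wise standard
deviation of cross-subject z-scores. It needs the complete subject × time
block: any missing cell skips the molecule (with a recorded reason), as
does zero cross-subject variance at any time point. Two exact anchors:
data of the form $x_{j,t} = a_j + f(t)$ give TVRI = 1; two subjects
swapping positions between two time points give TVRI = 0.

**TPSM** correlates two molecules' subject-concatenated
difference-from-fasting vectors (fixed subject order; pairwise-complete
positions). Its absolute value feeds the network. Missing-data handling
throughout the indices is pairwise complete — a necessary extension beyond
the original definitions, which are silent on the point.

## Network analysis

Edges require |TPSM| strictly above 0.6, the conventional cut for a
moderately high correlation. Shortest paths are unweighted; the
similarity is kept only as edge metadata. Betweenness (Brandes) is
normalized by $2/((n-1)(n-2))$ with n the number of *connected* nodes of
the whole graph; isolated molecules are reported separately with
centrality 0, and per-component normalization is available by flag. The
group-normalized degree divides a molecule's degree by the size of its
own metabolic group in the analysed panel — the verbal definition; the
printed sum-over-groups formula is not well-posed as written and is not
implemented. Monotonicity (raising the threshold never adds edges or
degree) and agreement with brute-force geodesic enumeration on all small
graphs are asserted in the suite.

## AUC features

The per-subject signed area under the difference-from-fasting trajectory
is computed by the trapezoid rule on the irregular grid, with interior
missing points bridged linearly and no smoothing; whether the original
analysis integrated raw curves or differences is not stated, and the
difference convention is the default (`auc_trapezoid` also accepts any
trajectory). T<sub>AUC1/2</sub> is the earliest time at which the
cumulative area reaches half the total, located by linear interpolation
in the bracketing interval; sign-changing trajectories can cross the half
level more than once, so the earliest crossing is returned with a
`non_monotone` flag. The correlation screen (per-subject features of
targets against glucose/insulin) reuses the Storey machinery over one
family of screen p-values.

## The synthetic cohort generator

The generator emulates the study's data structure, not its physiology:

$$x_{j,k,t} = b_{j,k}\,\bigl(1 + a_{j,k} f_k(t) + o_{j,k,t} + \epsilon_{j,k,t}\bigr)$$

with lognormal subject baselines $b$, archetype templates $f_k$ (cosine
rise to the extremum at the peak time, cosine relaxation to a set return
fraction; late-rebound for counter-regulatory hormones), subject
amplitudes $a \sim N(1, \sigma_{shape})$, subject offsets that persist
across time points with probability `rank_stability` (the TVRI dial — a
redraw reshuffles the cohort order), and residual noise split within each
metabolic group by `within_group_corr` (the TPSM dial).

Defaults are chosen to be physiologically plausible for a healthy cohort:
baseline CV 0.2 across subjects; shape noise 0.08 (assay plus biological
variation well under 10% of baseline); offset s.d. 0.15 with persistence
0.85; within-group correlation 0.5; missing rate 0.002, which leaves
roughly a third of molecules with at least one missing cell, matching the
sparseness of a well-run panel. The study-like preset reproduces the
published shape census — 83 molecules, of which 18 carry archetypes
exceeding the 1.5-fold cut (6 increasing: a glucose-related burst peaking
20–60 min plus two slower metabolites; 12 decreasing: lipids, amino
acids, a citrulline-like amino acid with lipid kinetics, and two
hormones). The water-control preset sets every archetype flat.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: glucose–insulin feedback dynamics (templates
are independent given the group structure), non-Gaussian assay error,
informative missingness (cells are deleted uniformly at random), and
demographic covariate effects. Parameter-recovery tests (TPSI → 1 in the
noise-free limit, TVRI ordering by rank stability over 20 seeds,
within-group > between-group |TPSM|) validate the statistics, not human
physiology.

## Numerical choices and degenerate inputs

- Strict inequalities at every published threshold (fold change, q,
  |TPSM|, missing budget), so boundary cases are retained/unconnected.
- Correlations with zero-variance inputs are reported `NA`, never 0.
- The Storey estimate $\hat\pi_0$ is clipped to (0, 1]; an all-small
  p-value family falls back to $1/m$ rather than 0.
- Cluster ids are renumbered in dendrogram traversal order so they are
  stable under permutation of the input rows (asserted).
- All randomness flows from a single integer seed; two runs with the same
  seed are byte-identical through the CSV/JSON writers.

## Problem sizes

The suite runs toy fixtures (2–20 subjects, 1–12 molecules) for the exact
oracles, and 10–20 seed replicates of 10-subject cohorts for the
statistical properties; the acceptance script runs the full 20 × 83 × 14
study-like cohort, which completes in seconds.

## Known limitations

TPSI includes the identically-zero fasting entries, slightly deflating
the index for short grids. TVRI requires complete data, so any missing
cell drops the molecule rather than imputing. The q-value family pools
all molecule × time tests; stratified analyses need the per-molecule
option. The network treats edges as unweighted for path purposes, so
betweenness reflects topology only.
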