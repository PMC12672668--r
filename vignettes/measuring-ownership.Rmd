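---
title: "Measuring body-ownership illusion strength from item arrangements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring body-ownership illusion strength from item arrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodymds)
```

## The measurement model

The package treats felt body ownership as a position in a low-dimensional
"bodily space". Participants repeatedly arrange items representing bodily
experiences inside a circular arena so that distance expresses felt
dissimilarity; a session yields a set of partial, differently zoomed
distance matrices. The analysis chain is: estimate one dissimilarity
matrix per session, embed it by interval MDS, anchor and align the
resulting configurations, and read illusion strength off the experimental
item's position relative to two fixed baselines — *normal body feelings*
(full ownership) and an *empty glove* (no ownership).

Two families of indices are exposed. *Ownership scores* are min–max
normalized coordinates on the embodiment dimension,
$z_i = (x_i - \min x) / (\max x - \min x)$, so the item at the dimension
minimum (by convention the empty glove, after anchoring) scores 0.
*Distance indices* are Euclidean distances between the experimental item
and each baseline in Procrustes-aligned units: distance to the
normal-body item (embodiment; smaller = stronger illusion) and distance
to the empty glove (de-objectification; larger = stronger illusion). The
distance indices need no interpretable dimensions and therefore work for
every participant; the de-objectification direction is the more sensitive
of the two.

## Dissimilarity estimation and the adaptive schedule

Each trial contributes, for every co-presented pair, the Euclidean
distance and an evidence weight $w = (d / d_{\max})^2$ — squared relative
on-screen distance, encoding that widely separated pairs are measured
with better signal-to-noise. The original multi-arrangement software does
not publish its exact weighting formula; this squared-relative form is
this package's declared choice and is tested for its consequences
(recovery, termination behavior), not as a claim about the original
implementation.

Trials may use different zoom levels, so the combined estimate
$\hat{D}$ alternates between (i) a non-negative per-trial scale
$s_t = \sum w\, d\, \hat{D} / \sum w\, d^2$ by evidence-weighted least
squares and (ii) the evidence-weighted average of rescaled trial
distances, with $\hat{D}$ renormalized to unit root mean square each
sweep. Convergence of this alternation is linear (contraction roughly
0.87 per sweep on typical sessions), so the default cap is 1000 sweeps at
tolerance $10^{-6}$ on the unit-RMS scale — measured as maximum absolute
change, since per-pair relative change is ill-defined for near-zero
dissimilarities. Non-convergence is reported as a flag, never an error.

Subset selection is greedy: pair deficits
$u_{ij} = \max(0, 1 - W_{ij}/0.5)$ define stimulus utilities
$U_s = \sum_j u_{sj}^{E}$ with $E = 10$; the subset seeds with the
maximum-deficit pair (lexicographic tie-break for reproducibility) and
grows while per-trial efficiency $\sum_{i<j \in S} u_{ij} / |S|$ does not
decrease, within size bounds (minimum 3 — a 2-item trial pins only one
distance and degenerates scale alignment). Sessions stop when the weakest
pair's accumulated evidence exceeds 0.5 or after 12 arrangements. Which
rule fires depends mostly on the *structure* of the space, not the noise
level: tightly clustered spaces (the realistic default) keep some pairs
at small relative distances in every trial and run to the 12-trial cap,
while well-spread spaces saturate evidence early.

## Interval MDS by majorization

`fit_interval_mds()` minimizes stress by SMACOF majorization with
interval disparities $\hat{\delta} = a + b D$, $b \ge 0$, negative values
clamped to zero, re-estimated by weighted least squares each sweep and
normalized (de Leeuw's convention) to prevent collapse; the Guttman
transform uses the Moore–Penrose inverse of the weight Laplacian so that
zero-weight pairs (never co-presented, or down-weighted by familiarity)
are excluded exactly. The reported `stress1` is Kruskal's stress-1 with
the interval transform refit *without* normalization at the final
configuration — the conventional diagnostic value, and the quantity the
1-D grid-search oracle in the tests reproduces. The per-iteration trace
uses the internally normalized stress, which is the quantity majorization
guarantees to be non-increasing.

Defaults follow the reference analysis: 1000 random starts (uniform in
$[-1,1]^k$ from one seeded generator; the winning start index is logged),
convergence at relative stress change $10^{-6}$. Stress-per-point
attributes each pair's weighted squared residual half to each endpoint
and is expressed in percent; numerically perfect fits (total residual
below $10^{-12}$ of the distance scale) return the uniform convention
$100/n$.

The permutation benchmark refits solutions to matrices whose
upper-triangle entries are uniformly permuted (evidence weights travel
with their values, which only matters for weighted records). Each
permutation uses a reduced budget of 10 starts by default — the
per-permutation start budget of the reference analysis is unstated, and
10 starts keeps a 500-permutation benchmark at desk scale. In type-I
calibration the observed fit must use the same start budget as the
permuted refits; unequal budgets bias the observed stress low.

Familiarity weighting maps ratings $f \in [1,5]$ to pair weights
$f_i f_j / 25 \in (0,1]$ — a normalized product, chosen so that two fully
familiar items keep weight 1; the reference analysis states only the
direction (more familiar = higher weight), not the form.

## Alignment conventions

`procrustes_align()` centres both configurations, scales both to unit
centroid size ("Procrustes normalized units"; whether the original
analysis scaled one or both is unstated — both-to-unit-size makes the
units symmetric in source and target), and finds the optimal orthogonal
map by SVD, with optional reflection and scaling. Configurational
similarity is summarized by the congruence coefficient of corresponding
distances, the Pearson correlation of stacked coordinates (stacked, not
per-dimension), and the alienation coefficient
$a = \sqrt{1 - c^2}$, benchmarked against alignments of random
configurations drawn uniformly on the unit square.

One convention matters for inference: when distance indices are compared
across conditions, the alignment uses **rotation/reflection only**
(`allow_scaling = FALSE`). The optimal Procrustes scale equals the sum of
singular values of the cross-product of two unit-size configurations and
is therefore below 1, so a scaled source has systematically shorter
inter-item distances than its target; in simulation this inflated the
one-sided false-positive rate of the paired de-objectification test from
0.05 to about 0.20. With rotation-only alignment of unit-size
configurations the planted-null rejection rate is at the nominal 0.05.
Optimal scaling remains the default for configurational-similarity
reporting, where it is standard.

Baseline anchoring searches rotation angles on a 5° grid (every rotation
a typical analysis reports is a multiple of 5°) and minimizes the summed
normalized coordinates of the empty-glove item; the embodiment dimension
is then identified as the one where the glove is minimal, with an
explicit override for analysts who prefer expert identification.

## Inference and planning

Paired comparisons are classical paired t tests; the reported effect size
is $d_z = t/\sqrt{n}$, the difference-score standardization that the
published $(t, n, d)$ triples satisfy. Sample-size planning converts a
between-condition effect $d$ and cross-condition correlation $r$ to
$d_z = d / \sqrt{2(1-r)}$ and offers two criteria: the exact smallest $N$
whose noncentral-$t$ power reaches the target, and the classical
normal-approximation formula
$N = \lceil ((z_\alpha + z_\beta)/d_z)^2 + z_\alpha^2/2 \rceil$. For
$d = 0.95$, $r = 0.44$, power 0.90, one-sided $\alpha = 0.05$ (the
conventional $\alpha$; the reference planning statement omits it), the
approximation gives $N = 12$ and the exact criterion $N = 13$ — exact
power at 12 is 0.897. The reference value of 12 is consistent with the
approximation, so that is what the reproduction script reports; both
methods are exposed and tested.

## Clustering

k-means runs on min–max normalized dimensions (cluster means are then
directly readable as normalized scores). The cluster count is chosen by
majority vote over a fixed panel of eight validity indices — silhouette,
Calinski–Harabasz, Davies–Bouldin (minimized), Dunn, gap statistic with
50 uniform reference sets, elbow (second difference of within-SS),
C-index (minimized), point-biserial — with ties resolved toward the
smaller k. A 30-index panel exists in the literature; re-implementing all
30 would be out of proportion, so the 8-index panel is the declared
substitute and every report logs the individual votes so the decision is
auditable.

## What the simulator does and does not emulate

Synthetic participants share one latent 2-D bodily space (embodiment ×
stimulation, with three regions: de-embodiment experiences, artificial
stimulation, normal bodily feelings; the experimental item at moderate
embodiment and low stimulation). The packaged coordinates were chosen
once to mirror the qualitative structure reported for real participants.
A trial takes the true coordinates of the requested subset, applies a
random rotation and (probability ½) reflection, a log-normal zoom
($\sigma = 0.1$ by default), adds isotropic Gaussian placement noise
(default 0.05 arena units; 0.08 in the power-style experiments), and
rescales to the arena. Condition effects displace only the experimental
item. Questionnaire means are an affine map of the latent ownership score
onto the −3..3 scale plus Gaussian response noise ($\sigma = 0.8$ scale
points, chosen so simulated spreads resemble published SDs after 3-item
averaging); familiarity ratings are drawn from a fixed discrete
distribution on 1..5 with experimental/baseline items pinned at 5.

The simulator deliberately omits: individual differences in the latent
space itself, strategy diversity (clustered or circular arrangement
styles real participants produce), item-image idiosyncrasies, and any
nonlinear mapping between latent ownership and placements. Passing
recovery tests therefore shows the *pipeline* is correct and calibrated
under a faithful generative model — not that real bodily spaces are 2-D
or that real effect sizes match the planted ones.

## Problem sizes used in the test suite

Fits in simulation-heavy tests use 10–100 random starts (13 items in 2-D
is an easy SMACOF problem; 10 starts already find the global optimum in
virtually every session, and the planted-effect conclusions are
unchanged at 1000 starts). Permutation calibration uses 200 replicates of
100 permutations × 5 starts; end-to-end detection uses 100 replicates of
24 participants × 2 conditions at placement noise 0.08 and planted shift
0.5. These sizes are the package's choices for routine verification;
all defaults remain at the reference analysis's scale (1000 starts, 500
permutations).

## Known limitations

- Dimension labels (embodiment, stimulation) are conventions attached to
  anchored solutions; the package never infers semantics.
- The evidence-weight and stimulus-utility forms are declared substitutes
  honoring the documented behavior of the adaptive task, not a
  reproduction of the original MATLAB internals.
- Ownership-loss baselines: both the maximum-score and the
  normal-body-score variants are exposed; which is canonical is left to
  the analyst.
- Exclusion rules (stress above 0.2, visual peculiarities) surface as
  flags with written rationales; visual-inspection judgments cannot be
  automated and are never applied silently.
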