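---
title: "Similarity-based individual-differences analysis of regional activity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based individual-differences analysis of regional activity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Group-average fMRI analyses ask where a contrast is activated on average;
this package asks a different question: *when two people respond differently
to the same persuasive messages, which measurable differences between them
track that divergence?* The unit of analysis is therefore the subject
*pair*, not the subject. For a cohort of $n$ participants there are
$n(n-1)/2$ unordered pairs, and every quantity in the model is a per-pair
(dis)similarity:

- **Response.** For each region of interest (ROI), each subject contributes
  a voxel activity pattern from their contrast map (here, the interaction of
  message sensation value and argument strength, MSVxAS). The response for
  pair $(i,j)$ is the Euclidean distance
  $d_{ij} = \lVert \mathbf{p}_i - \mathbf{p}_j \rVert_2$ between the two
  patterns within the ROI mask.
- **Univariate regressors.** For a trait score $t$ (marijuana-use risk,
  sensation seeking, task compliance), pair similarity is $|t_i - t_j|$.
- **Profile regressors.** A per-video evaluation measure (perceived message
  sensation value, perceived argument strength, ad liking, positive and
  negative affect, thought valence) gives each subject a vector over the 32
  videos. Each pair is compared three ways: the Pearson correlation of the
  two profiles, $|\bar{x}_i - \bar{x}_j|$, and $|s_i - s_j|$ (sample sd,
  $n-1$ denominator). The correlation is reoriented as $1 - r$ so every
  column reads as a distance; $\Delta R^2$ is invariant to this affine map.
- **Neural controls.** Whole-brain distances for the contrast map, a
  structural (gray-matter probability) segmentation, and two control-task
  maps form one whole-brain control block (`wbFxnSim`); the same structural
  and control-task distances restricted to the ROI mask form an ROI-level
  block (`ROIneur`).
- **Participant intercepts.** One 0/1 column per subject, active in the
  $n-1$ pairs that subject belongs to (`subints`). Their unique variance is
  individual-difference structure that is *explainable in principle* but not
  by any measured variable.

Each ROI's distance vector is regressed on all of these columns at once by
ordinary least squares. Credit is assigned by a **round-robin** over
regressor groups: the unique variance of group $g$ is
$\Delta R^2_g = R^2_{\text{full}} - R^2_{-g}$, non-negative by nesting.
Whatever the full model explains beyond the sum of unique contributions is
**shared variance**, $R^2_{\text{full}} - \sum_g \Delta R^2_g$; it can be
negative under suppression, in which case it is reported with a warning,
never clamped, because clamping would hide the suppression.

## ROI masks

A mask is the centre voxel plus all voxels within Manhattan (L1) distance 2,
which contains exactly 25 voxels; in general radius $r$ gives
$(2r+1)(2r^2+2r+3)/3$ voxels. The mask is defined by this voxel-count rule;
its millimetre volume follows from the configured voxel size (25 voxels at
5 mm isotropic is 3125 mm³, at 3 mm it is 675 mm³ — both grids are
supported, with the affine always supplied explicitly, never guessed).
Masks that straddle the grid boundary raise an error rather than being
clipped, because silent clipping would change the pattern dimensionality
between subject sets.

## Inference: subject-level permutation p\*

Pairwise similarities are not independent: each subject contributes $n-1$
pairs to every column, so row-level permutation would be grossly
anti-conservative. The null implemented here permutes *subject labels* of
the focal group's underlying data (scores, rating profiles, or voxel
patterns) and rebuilds that group's pair-level columns from the permuted
data — a Mantel-style scheme that preserves the dyadic dependence
structure. Because every similarity value is a function of its unordered
subject pair alone, rebuilding under a permutation is exactly equivalent to
indexing the observed column at the induced pairs, which is how the test
statistic loop is computed (the equivalence is verified in the test suite).
With $B$ permutations,

$$p^* = \frac{1 + \#\{\Delta R^2_{\text{perm}} \ge \Delta R^2_{\text{obs}}\}}{B + 1},$$

one-tailed and uncorrected: these values are used for dimensionality
reduction and evidence ranking, not confirmatory hypothesis tests. A
subject-level bootstrap mode (resampling subjects with replacement,
self-pairs dropped) is provided as a sensitivity analysis. The
participant-intercept block has no permutation test: permuting subject
labels merely permutes its columns, leaving the column space — and hence
its $\Delta R^2$ — unchanged.

## Profiling: Ward clustering and MAP shrinkage

ROIs are clustered on their evidence profiles — the probit transform
$z = \Phi^{-1}(1 - p^*)$ across variables, clipped to stay finite — with
Ward's minimum-variance criterion on Euclidean distances
(`hclust(method = "ward.D2")`). The number of clusters defaults to the
silhouette-maximising $K$ in 2..10, with a fixed-`K` override, since no
selection rule is canonical for this kind of profile data.

Cluster-level summaries use a zero-centred normal–normal MAP estimate: for
one variable across a cluster's ROIs,
$$\hat\mu_{\text{MAP}} = \bar{x}\,\frac{n\tau^2}{n\tau^2 + \sigma^2},$$
so the estimate never exceeds the raw mean in magnitude and larger or more
homogeneous clusters shrink less. By default $\sigma^2$ is the pooled
within-cluster variance for that variable and $\tau^2$ the method-of-moments
between-cluster variance, $\max\!\big(0,\ \mathrm{var}(\bar{x}_k) -
\sigma^2\,\overline{1/n_k}\big)$; both can be overridden. These shrunken
profiles are for visualisation and description, like the clustering itself.

## The synthetic cohort generator

Real contrast maps for this design are not shippable test fixtures, so the
package carries a first-class generator that emulates the study conditions:
28 subjects, 23 ROIs of 25 voxels inside a shared whole-brain grid, 32
videos of Likert-bounded ratings with completely-at-random missingness
(default rate 0.05), and item-level trait responses. Each
individual-difference variable gets a standardized latent score per
subject. An ROI may designate one *driver* variable with effect size
$\gamma$:

$$\mathbf{p}_s = \mathbf{m} + \gamma\, t_s\, \mathbf{u} + \varepsilon_s,
  \qquad \varepsilon_s \sim N(0, \sigma^2 I),$$

with $\mathbf{u}$ a unit direction, so the expected squared pair distance is
$\gamma^2 (t_i - t_j)^2 + 2\sigma^2 V$ for $V$ mask voxels — a closed form
(`expected_pair_distance()`) used to validate the generator by simulation.
With $\sigma = 1$ and $V = 25$, $\gamma = 5$ makes the planted signal
comparable to the noise term, the "strong effect" setting used in the
recovery checks. Whole-brain maps embed the ROI patterns at their peak
locations inside a background noise field, so whole-brain similarity is
genuinely correlated with ROI similarity, as in real data. Item-level
responses are integer Likert draws around the latent (so measured scores
recover the latent imperfectly, as real scales do).

What the generator does **not** emulate: spatial autocorrelation and
smoothness of real maps, non-Gaussian voxel noise, structured (non-MCAR)
missingness, correlated latent traits, and multi-component trait-pattern
couplings (one signal direction per ROI). Passing tests therefore certify
the statistical machinery — calibration, credit assignment, recovery —
under the model's own assumptions, not robustness to every property of real
fMRI data.

## Numerical choices

- **Rank deficiency.** The global intercept is collinear with the
  participant-intercept block (row sums are constantly 2). $R^2$ depends
  only on the column space, so fits use pivoted QR; reported coefficients
  are the minimum-norm solution from the SVD pseudo-inverse.
- **z-scoring.** Regressor columns are z-scored (intercepts excepted).
  $\Delta R^2$ is affine-invariant, so this only standardises coefficient
  scales.
- **Tiny negatives.** $\Delta R^2$ below 0 by more than $10^{-8}$ warns;
  numerical dust is clipped to 0. The partition identity
  $\sum_g \Delta R^2_g + \text{shared} = R^2_{\text{full}}$ is enforced in
  tests at $10^{-10}$.
- **Ties in mm-to-voxel rounding** are broken half-away-from-zero,
  deterministically.
- **Degenerate inputs.** Constant regressors, zero-variance rating
  profiles, all-missing columns and out-of-bounds responses raise errors
  naming the offender; imputation must precede similarity construction.
- **Determinism.** All resampling flows from one seed; per-test sub-seeds
  are derived arithmetically (kept below $2^{31}$), so reruns are
  bit-identical.

## Design choices that were genuinely open

- **Scale summary.** Item *mean* rather than sum; the downstream
  $|\Delta|$ similarities differ only by a constant factor and
  $\Delta R^2$ is scale-invariant, so the choice is inert; it is fixed here
  for reproducibility.
- **Thought-valence sign.** Stay-away minus want-try (higher =
  message-consistent thoughts); pairwise $|\Delta|$ is invariant to the
  global flip.
- **Imputation scope.** Per question column *across subjects* (the mean of
  everyone's non-missing responses to that item for that video), matching
  the stated rule literally, not within-subject.
- **Structural similarity** uses one tissue class (gray-matter
  probability) per map by default; which classes enter is configurable
  since either convention is defensible.
- **Whole-brain grouping.** The whole-brain structural and control-task
  distances are grouped with the whole-brain contrast distance in the
  `wbFxnSim` control block, and the ROI-level ones form `ROIneur`;
  membership is declared in code and can be re-declared.
- **Resampling null.** A subject-level permutation with column rebuilding
  is the default because it is the simplest scheme honouring the
  $n-1$-pairs-per-subject dependence; the bootstrap variant is provided for
  sensitivity, not as the default.
- **Unused emotion items.** Four of the 14 emotion items belong to neither
  the positive nor the negative summary; they are carried through untouched.
- **Marijuana-risk instrument.** The item count of the source scale is not
  reproduced here; the generator defaults to 5 items on a 1–5 response
  scale, configurable via `default_scales()`.

## Problem sizes used in the checks

The replicated simulation checks run at the cohort size of the emulated
study ($n = 28$, $B = 199$) but on compact two-ROI grids (a few hundred
voxels), chosen so that hundreds of replicates are cheap: 200 null cohorts
for calibration of the rejection rate at $\alpha = 0.05$ (exact binomial
interval), and 100 planted-driver cohorts for rank and power recovery. The
single full-scale demonstration uses all 23 packaged ROI peaks on the
resulting whole-brain grid with $B = 99$. The packaged miniature fixture
(8 subjects, 4 ROIs, 10 videos) exists for interface smoke tests; with only
28 pairs against a richer column set its fits are saturated, so it is not a
setting for interpreting variance partitions.

## Known limitations

- OLS on distances ignores heteroscedasticity of dyadic data; inference
  relies entirely on the resampling null rather than model-based standard
  errors.
- The permutation null tests one focal group at a time against the observed
  remainder; joint nulls across groups are not computed.
- $p^*$ values are uncorrected by design; the strength table is a screening
  device.
- Cluster count selection by silhouette is heuristic; the clustering and
  MAP profiles describe, they do not test.
- The generator's couplings are linear in one latent per variable; real
  trait-pattern relationships may be nonlinear or multidimensional.
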