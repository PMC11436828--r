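---
title: "Probabilistic parcellation by dataset fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic parcellation by dataset fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcelfuse)
```

## The model

`parcelfuse` fits probabilistic functional parcellations that pool evidence
from several functional imaging datasets. The generative model has two
parts.

**Emission models.** Each dataset gets its own likelihood of the observed
functional profiles given parcel membership. Voxel $i$ of subject $s$
contributes, per session $n$, a direction $\mathbf{y}_i^n$ on the unit
sphere of condition space (profiles are normalized per session, see below).
Given membership in parcel $k$, the direction follows a von Mises–Fisher
distribution with parcel- and session-specific mean direction
$\mathbf{v}_k^n$ and one session-wide concentration $\kappa^n$ shared
across parcels:

$$p(\mathbf{y}_i^n \mid U_i = k) =
  C_d(\kappa^n)\, \exp(\kappa^n \mathbf{v}_k^{n\top} \mathbf{y}_i^n).$$

One concentration per session (rather than per parcel) keeps the parcel
comparison fair and makes $\kappa^n$ act as the session's reliability
weight: during fusion, sessions with cleaner data pull the group map
harder, with no hand-set dataset weights anywhere.

**Arrangement model.** The group prior over assignments treats voxels
independently: $p(U_i = k) = \mathrm{softmax}_k(\eta_{k,i})$ with a
$K \times P$ matrix of log-potentials. Its M-step is exact and simple —
the updated prior is the mean of the individual posterior maps — which is
what makes fusing many heterogeneous datasets cheap.

Both parts are estimated jointly by EM on the marginal likelihood. The
E-step multiplies each subject's emission likelihood into the prior; the
M-step averages posteriors into the arrangement and updates each
emission's mean directions (normalized weighted resultants) and
concentration (closed-form approximation
$\hat\kappa \approx \bar r (d - \bar r^2)/(1 - \bar r^2)$ refined by up to
10 Newton steps on the exact score $A_d(\kappa) = \bar r$, clipped to
$[10^{-3}, 10^5]$).

### Symmetry

The symmetric atlas variant confines parcels $1..K/2$ to the left
hemisphere and $K/2+1..K$ to the right, and ties the potentials so that
the probability of parcel $k$ at a left voxel equals the probability of
parcel $k + K/2$ at its mirrored voxel — exactly, by construction, not up
to tolerance. Functional profiles remain free per hemisphere, so
lateralization stays measurable. The asymmetric companion is obtained by
`desymmetrize()`: emissions are frozen and the arrangement alone is refit
without the mirror tie (confinement kept), a pure constraint relaxation
that can only raise the marginal likelihood. Midline voxels, when a space
has them, split their mass equally between the paired parcels; this is a
package convention, chosen because no principled assignment exists for a
self-paired voxel.

### Individual precision mapping

Three maps per subject: the *group* map (prior only), the *data-only* map
(emission likelihood only), and the *integrated* map, the voxel-wise
renormalized product of prior and likelihood. For a new localizer task
set, `train_localizer_emission()` fits a fresh emission model across
subjects with the arrangement frozen, after which `individual_map()`
personalizes the atlas from any single subject's localizer matrix.

## Numerical choices

- **Normalization.** Each voxel's session block is scaled to unit norm;
  all-zero or partially missing blocks are flagged and excluded from both
  E- and M-step sums (consistent under data missing completely at
  random). Pre-normalization lengths are kept and weight the cosine
  prediction error.
- **vMF normalizing constant.** Evaluated in the log domain with
  exponentially scaled Bessel functions; for orders $\geq 100$ the uniform
  asymptotic expansion takes over, keeping the constant finite up to
  $\kappa = 10^5$ and hundreds of dimensions.
- **vMF sampling.** Ulrich/Wood rejection sampling for the radial
  component with a uniform tangent direction, dimension-general; the
  mixing coefficient $b$ is computed in a cancellation-free form so the
  sampler stays correct at $\kappa \ge 10^8$.
- **Initialization.** Each EM start seeds the responsibilities from a
  randomized k-means partition of the voxel profiles concatenated across
  subjects and datasets (computed per hemisphere under symmetry, then
  mirrored). We chose this over fully random parameter draws after
  observing that random starts essentially never reach the dominant
  likelihood basin at realistic K within a 20-start budget — consistent
  with the thousands of random starts that production fits of this model
  family budget for. `init = "random"` retains the classical scheme.
- **Ties and floors.** Winner-take-all ties break to the lowest parcel
  index. Posterior floors of $10^{-10}$ precede logs in the arrangement
  M-step; hemisphere confinement uses a large negative potential
  ($-10^{10}$) whose softmax underflows to exactly zero, so "confined"
  means zero probability, not small probability.
- **Stopping.** EM stops when the relative log-likelihood change falls
  below `tol` ($10^{-6}$ by default) or at `max_iter` (200). Defaults are
  the package's own choices; the underlying study does not state its
  stopping rule.

## Evaluation metrics

**DCBC.** The distance-controlled boundary coefficient bins voxel pairs
by spatial distance (default: 1 template-unit bins up to 35 units,
following the metric's source publication) and, per bin, subtracts the
mean between-parcel profile correlation from the mean within-parcel one.
Bins are combined with weights $n_w n_b / (n_w + n_b)$, the
variance-minimizing weight for a difference of two means. Distance
control matters: any spatially contiguous parcellation looks good on
spatially smooth data if distance is ignored.

**Reliability-adjusted ARI.** Parcellation ladders (default granularities
10/20/34/40/68) are compared by the mean ARI over all granularity pairs,
divided by the geometric mean of the two within-ladder reliabilities
(mean ARI between different granularities of the same ladder). One
subtlety is documented in `?reliability_adjusted_ari`: with the
all-pairs numerator (the convention for comparing different datasets,
$L^2$ pairs) the self-similarity of a ladder with itself exceeds 1,
because the numerator contains $L$ trivial same-granularity comparisons
that the 10-pair denominator lacks. The `include_same_level = FALSE`
variant uses the same pair structure in numerator and denominator and
has the exact identity $\mathrm{raARI}(a, a) = 1$; tests assert the
identity on that variant.

**Prediction error.** One minus the cosine of predicted and observed
profiles, averaged with the observed vector length as weight, so
high-signal voxels dominate. Region predictions come from independent
training subjects.

**Inter-subject variability.** Pairwise between-subject profile
correlations per voxel, each pair divided by
$\sqrt{\mathrm{rel}_{s}\,\mathrm{rel}_{t}}$ of the two split-half
reliabilities, then averaged over pairs. We deliberately do not divide a
second time by the mean reliability: that second division belongs to a
visualization-only recipe and would double-correct; the returned tibble
carries the per-voxel reliability so either display can be built.

## The synthetic world

Every stage is validated on generated data. Worlds are 2-D mirror-
symmetric grids; ground-truth group maps are softened Voronoi partitions
(seeds drawn in the left hemisphere and mirrored when symmetric), because
the spatially independent arrangement model needs spatially coherent
truth for boundary metrics to have boundaries to find. The `smoothness`
parameter is an inverse temperature on the seed distances; the default
used in tests (3 per template unit) yields boundary voxels with winner
probabilities around 0.9–0.95, i.e. soft but identifiable borders. Per
subject, hard labels are drawn from the group map, then per session each
voxel's profile is a vMF draw around its parcel's mean with the session's
$\kappa$. The standard validation conditions are a 20×20 grid (P = 400),
K = 10, two datasets of five subjects, sessions of 6–8 conditions, and
$\kappa = 20$; localizer data for precision-mapping experiments use
$\kappa = 8$, reflecting that short localizer runs are noisier than the
curated training datasets.

What the generator does **not** emulate: hemodynamics, autocorrelated
noise, inter-subject anatomical misalignment, or realistic anatomy.
Passing tests therefore demonstrate the estimator's correctness and the
claimed orderings under the model's own assumptions — not performance on
real data.

Problem sizes in the test-suite and acceptance runs (400 voxels, 4–20
starts, 10–50 simulation seeds) are the package's chosen defaults for
simulation studies; production fits at atlas scale use the same code with
more starts and voxels.

## Connectivity

Cortico-cerebellar connectivity models are per-subject ridge regressions
$\mathbf{Y} = \mathbf{X}\mathbf{W}$ from cortical parcel activity to
cerebellar voxel activity, with the closed-form solution as the contract.
The penalty is tuned per dataset by cross-dataset prediction (cosine
similarity of predicted and observed patterns, concatenated over voxels;
ties on a plateau resolve to the smallest penalty, default grid
$10^{-2}..10^4$). Fusion averages weight matrices across datasets,
always excluding an evaluation subject's own model from any average that
would contaminate it. The noise-ceiling adjustment divides a score by
$\sqrt{\mathrm{rel}_\mathrm{cereb}\,\mathrm{rel}_\mathrm{pred}}$; this
formula is one explicit interpretation of reliability-based ceilings and
is flagged as such in the documentation.

## Known limitations

- The arrangement model is spatially independent; smoothness in fitted
  maps comes entirely from the data. Markov-random-field couplings are
  out of scope.
- Parcel matching for recovery scoring is greedy maximum-weight
  matching on mean-direction cosines; for adversarial similarity
  structures an optimal assignment could differ, but at the tested K the
  greedy and optimal matchings coincide in practice.
- The merging pass refits emissions with the arrangement fixed for a
  bounded number of EM iterations (20); this is a deliberate cost cap.
- `data_amount_curve` models "minutes of data" as runs × minutes-per-run
  with i.i.d. replicate runs; real scanner runs share slow drifts that
  this ignores.
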