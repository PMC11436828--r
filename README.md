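# parcelfuse

Probabilistic functional brain parcellation by multi-dataset fusion.

Functional atlases of structures like the cerebellum are usually built
from a single task battery or a single resting-state sample, and each
dataset highlights different functional boundaries. `parcelfuse`
implements a hierarchical Bayesian framework that fuses any number of
functional MRI datasets into one probabilistic group atlas and then
tailors that atlas to individual subjects from short localizer scans. It
is aimed at researchers building or evaluating functional parcellations —
of the cerebellum in particular, but nothing in the code is specific to
it — and at methodologists who want a fully synthetic, fully seeded
test-bed for this model family.

## The model

Each dataset *n* gets its own **emission model**: given that voxel *i*
belongs to parcel *k*, its session-normalized activity profile
**y**ᵢⁿ follows a von Mises–Fisher distribution on the unit sphere of
condition space,

> p(**y**ᵢⁿ | Uᵢ = k) = C(κⁿ) exp(κⁿ **v**ₖⁿᵀ **y**ᵢⁿ),

with parcel mean directions **v**ₖⁿ per session and one concentration κⁿ
per session. A spatially independent **arrangement model** supplies the
group prior, p(Uᵢ = k) = softmax(η₍k,i₎). Everything is estimated jointly
by multi-start EM; κⁿ doubles as each session's reliability weight, so
cleaner datasets automatically pull the fused map harder. A symmetric
variant ties mirrored voxels to paired parcels (identical boundaries,
free per-hemisphere profiles), and `desymmetrize()` produces the matched
asymmetric atlas. Individual maps come from Bayes' rule:
p(Uᵢ | data) ∝ p(data | Uᵢ) p(Uᵢ).

On top of the estimator the package provides the evaluation suite
(distance-controlled boundary coefficient, reliability-adjusted adjusted
Rand index, weighted cosine prediction error, inter-subject
variability), parcel hierarchies with similarity-derived colormaps and
lateralization indices, ridge-regression cortico-cerebellar
connectivity with cross-dataset tuning and weight-averaged fusion, and a
synthetic-world generator that makes every stage testable without any
imaging data.

## Worked example

Simulate a symmetric ground-truth world, sample one dataset, fuse, and
personalize:

```r
library(parcelfuse)

sp    <- make_symmetric_grid(20, 20)                  # 400-voxel template
gp    <- sample_group_arrangement(sp, 10, smoothness = 3,
                                  symmetric = TRUE, seed = 2)
truth <- ground_truth(gp, sessions = c(8, 8), kappa = c(20, 20), seed = 3)
ds    <- sample_dataset(truth, sp, n_subjects = 5, seed = 4,
                        dataset_id = "task-battery")
ds
#> <functional_dataset> 'task-battery': 5 subjects, 400 voxels, 16 conditions in 2 sessions

fit <- fit_fusion(ds, sp, K = 10, symmetric = TRUE, n_starts = 10, seed = 5)
glance(fit)
#> # A tibble: 1 × 6
#>       K n_datasets logLik n_iter converged symmetric
#>   <int>      <int>  <dbl>  <int> <lgl>     <lgl>
#> 1    10          1  3755.     16 TRUE      TRUE

lab <- hard_parcellation(group_prob(fit$arrangement))
adjusted_rand_index(lab, hard_parcellation(gp))
#> [1] 0.981

tidy(fit)
#> # A tibble: 10 × 4
#>   parcel n_voxels prob_mass hemisphere
#>    <int>    <int>     <dbl> <chr>
#> 1      1       44      45.3 left
#> 2      2       17      15.5 left
#> 3      3       26      25.2 left
#> 4      4       67      65.2 left
#> # ℹ 6 more rows

indiv <- individual_map(fit, ds$data[[1]], "task-battery")
sum(indiv$hard_labels != group_map(fit)$hard_labels)
#> [1] 24
```

The fit recovers the generating parcellation almost perfectly (ARI
0.98; the marginal log-likelihood is the EM objective and must never
decrease), and the Bayes-integrated individual map moves 24 of 400
voxels away from the group assignment for this subject — exactly the
boundary voxels where this subject's localizer data disagree with the
group prior.

Downstream: `parcel_similarity()` + `build_domains()` +
`colormap_from_similarity()` organize fitted parcels into named,
colored functional domains; `dcbc_individual()` and
`data_amount_curve()` reproduce the localizer-style evaluations;
`fit_ridge()`/`tune_lambda()`/`fuse_connectivity()` cover the
connectivity models; `run_pipeline(pipeline_config(...))` drives the
whole sequence end to end and writes a deterministic manifest.

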