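# Small synthetic worlds shared across test files. Built once per test run
# and cached in the helper environment to keep the suite fast.

.world_cache <- new.env(parent = emptyenv())

# standard small world: 12x12 grid, K = 6 symmetric parcels, two datasets
small_world <- function() {
  if (is.null(.world_cache$small)) {
    sp <- make_symmetric_grid(12, 12)
    gp <- sample_group_arrangement(sp, 6, smoothness = 3, symmetric = TRUE,
                                   seed = 41)
    gt1 <- ground_truth(gp, sessions = c(8, 8), kappa = c(20, 20), seed = 42)
    gt2 <- ground_truth(gp, sessions = c(6, 6), kappa = c(20, 20), seed = 43)
    ds1 <- sample_dataset(gt1, sp, 4, seed = 44, dataset_id = "a")
    ds2 <- sample_dataset(gt2, sp, 4, seed = 45, dataset_id = "b")
    .world_cache$small <- list(space = sp, gp = gp, gt1 = gt1, gt2 = gt2,
                               datasets = list(ds1, ds2))
  }
  .world_cache$small
}

# a fitted symmetric model for the small world
small_model <- function() {
  if (is.null(.world_cache$small_model)) {
    w <- small_world()
    .world_cache$small_model <- fit_fusion(w$datasets, w$space, 6,
                                           symmetric = TRUE, n_starts = 5,
                                           seed = 46)
  }
  .world_cache$small_model
}

# spatially smooth but parcel-free data: Gaussian-kernel-smoothed noise
smooth_noise_data <- function(space, n_cond, length_scale = 2) {
  d <- as.matrix(stats::dist(space$coords))
  S <- exp(-d^2 / (2 * length_scale^2))
  S %*% matrix(rnorm(n_voxels(space) * n_cond), n_voxels(space), n_cond)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")

softmax_cols_test <- function(x) parcelfuse:::softmax_cols(x)
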