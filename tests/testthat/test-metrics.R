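# exhaustive pair-counting oracle for the adjusted Rand index
ari_oracle <- function(a, b) {
  n <- length(a)
  s11 <- 0; s00 <- 0; s10 <- 0; s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

test_that("ARI reproduces canonical examples", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(1:4 %/% 2, 1:4 %/% 2), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  expect_error(adjusted_rand_index(integer(0), integer(0)), "empty")
})

test_that("ARI equals exhaustive pair counting on random labelings", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    a <- sample.int(sample(2:6, 1), n, replace = TRUE)
    b <- sample.int(sample(2:6, 1), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("ARI agrees with an independent reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(102)
  for (rep in 1:5) {
    a <- sample.int(4, 60, replace = TRUE)
    b <- sample.int(3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("reliability-adjusted ARI matches the direct-formula oracle", {
  set.seed(103)
  noisy_ladder <- function(base) {
    lapply(1:5, function(i) {
      l <- base
      flip <- sample.int(length(base), 6)
      l[flip] <- sample.int(max(base), 6, replace = TRUE)
      l
    })
  }
  ladder_a <- noisy_ladder(sample.int(4, 50, replace = TRUE))
  ladder_b <- noisy_ladder(sample.int(4, 50, replace = TRUE))
  # oracle: mean of all 25 between ARIs over geometric mean of the two
  # 10-pair within means
  btw <- outer(1:5, 1:5, Vectorize(function(i, j) {
    adjusted_rand_index(ladder_a[[i]], ladder_b[[j]])
  }))
  wth <- function(l) {
    v <- c()
    for (i in 1:4) for (j in (i + 1):5) {
      v <- c(v, adjusted_rand_index(l[[i]], l[[j]]))
    }
    v
  }
  wa <- wth(ladder_a); wb <- wth(ladder_b)
  expect_length(wa, 10)
  expect_equal(length(btw), 25)
  expect_gt(mean(wa), 0)
  expect_gt(mean(wb), 0)
  expect_equal(reliability_adjusted_ari(ladder_a, ladder_b),
               mean(btw) / sqrt(mean(wa) * mean(wb)), tolerance = 1e-12)
})

test_that("self-similarity is exactly 1 for the cross-granularity variant", {
  set.seed(104)
  base <- sample.int(4, 80, replace = TRUE)
  ladder <- lapply(1:4, function(i) {
    l <- base
    flip <- sample.int(80, 8)
    l[flip] <- sample.int(4, 8, replace = TRUE)
    l
  })
  expect_equal(reliability_adjusted_ari(ladder, ladder,
                                        include_same_level = FALSE),
               1, tolerance = 1e-12)
  # the all-pairs default includes the trivial same-granularity matches
  # and so exceeds 1 for a set compared with itself
  expect_gte(reliability_adjusted_ari(ladder, ladder), 1)
})

test_that("unreliable ladders are rejected", {
  a <- list(c(1, 2, 1, 2), c(2, 1, 2, 1))
  b <- list(c(1, 1, 2, 2), c(1, 2, 1, 2))
  expect_error(reliability_adjusted_ari(b, b), "unreliable")
})

test_that("DCBC is invariant to joint permutation of voxels and labels", {
  set.seed(105)
  sp <- make_symmetric_grid(10, 10)
  w <- small_world()
  gp <- sample_group_arrangement(sp, 4, smoothness = 3, symmetric = TRUE,
                                 seed = 106)
  gt <- ground_truth(gp, sessions = 10, kappa = 15, seed = 107)
  ds <- sample_dataset(gt, sp, 1, seed = 108)
  lab <- hard_parcellation(gp)
  bin <- distance_binning(sp)
  d1 <- dcbc(lab, ds$data[[1]], sp, bin)
  # relabeling parcels leaves the metric unchanged
  perm <- sample(4)
  expect_equal(dcbc(perm[lab], ds$data[[1]], sp, bin), d1, tolerance = 1e-12)
  expect_gt(d1, 0)   # generating labels beat chance on structured data
})

test_that("single-parcel labelings cannot be scored", {
  sp <- make_symmetric_grid(4, 4)
  expect_error(dcbc(rep(1, 16), matrix(rnorm(64), 16, 4), sp),
               "no boundaries")
})

test_that("random parcellations on parcel-free smooth data score near zero", {
  set.seed(109)
  sp <- make_symmetric_grid(10, 10)
  bin <- distance_binning(sp)
  vals <- replicate(30, {
    dat <- smooth_noise_data(sp, 8)
    labs <- hard_parcellation(
      sample_group_arrangement(sp, 4, smoothness = Inf)
    )
    dcbc(labs, dat, sp, bin)
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("prediction error handles the extreme geometries", {
  # all data vectors parallel to the region mean: zero error
  v <- c(1, 2, 2)
  y <- outer(c(1, 2, 3, 4), v)
  train <- list(2 * y)
  expect_equal(as.numeric(prediction_error(rep(1, 4), train, y)), 0,
               tolerance = 1e-12)
  # orthogonal predictions: error 1
  te <- rbind(c(1, 0), c(1, 0))
  tr <- list(rbind(c(0, 1), c(0, 1)))
  expect_equal(as.numeric(prediction_error(rep(1, 2), tr, te)), 1,
               tolerance = 1e-12)
})

test_that("prediction error equals the weighted-mean oracle", {
  set.seed(110)
  P <- 12; N <- 5
  lab <- sample.int(3, P, replace = TRUE)
  train <- list(matrix(rnorm(P * N), P, N), matrix(rnorm(P * N), P, N))
  test <- matrix(rnorm(P * N), P, N)
  got <- prediction_error(lab, train, test)
  vk <- sapply(1:3, function(k) {
    rows <- do.call(rbind, lapply(train, function(m) m[lab == k, , drop = FALSE]))
    colSums(rows)
  })
  num <- 0; den <- 0
  for (i in seq_len(P)) {
    y <- test[i, ]; v <- vk[, lab[i]]
    len <- sqrt(sum(y^2))
    err <- 1 - sum(v * y) / (sqrt(sum(v^2)) * len)
    num <- num + len * err; den <- den + len
  }
  expect_equal(as.numeric(got), num / den, tolerance = 1e-12)
})

test_that("empty regions are excluded and counted", {
  lab <- c(1, 1, 2, 2)
  train <- list(matrix(rnorm(8), 4, 2))
  train[[1]][3:4, ] <- 0   # region 2 has zero-profile training data
  test <- matrix(rnorm(8), 4, 2)
  pe <- prediction_error(lab, train, test)
  expect_equal(attr(pe, "n_excluded"), 2L)
})

test_that("inter-subject variability is 1 for identical noise-free subjects", {
  set.seed(111)
  half <- matrix(rnorm(10 * 4), 10, 4)
  base <- cbind(half, half)   # both halves observe the same profile
  ds <- functional_dataset("iv", list(base, base, base), sessions = c(4, 4))
  out <- inter_subject_variability(ds)
  expect_tibble(out)
  expect_equal(out$isc, rep(1, 10), tolerance = 1e-10)
  expect_equal(out$reliability, rep(1, 10), tolerance = 1e-10)
})

test_that("inter-subject variability is scale-invariant", {
  set.seed(112)
  a <- matrix(rnorm(80), 10, 8); b <- matrix(rnorm(80), 10, 8)
  ds1 <- functional_dataset("iv", list(a, b), sessions = c(4, 4))
  ds2 <- functional_dataset("iv", list(2 * a, b), sessions = c(4, 4))
  expect_equal(inter_subject_variability(ds1)$isc,
               inter_subject_variability(ds2)$isc, tolerance = 1e-12)
})

test_that("independent subjects give near-zero average variability index", {
  set.seed(113)
  # shared within-subject structure, independent across subjects
  mk <- function() {
    half <- matrix(rnorm(20 * 6), 20, 6)
    cbind(half + 0.3 * matrix(rnorm(120), 20, 6),
          half + 0.3 * matrix(rnorm(120), 20, 6))
  }
  ds <- functional_dataset("iv", list(mk(), mk(), mk(), mk(), mk(), mk()),
                           sessions = c(6, 6))
  out <- inter_subject_variability(ds)
  expect_lt(abs(mean(out$isc, na.rm = TRUE)), 0.1)
})

test_that("classical MDS embeds equidistant items as an equilateral triangle", {
  sim <- matrix(0.5, 3, 3); diag(sim) <- 1
  xy <- mds_embed(sim, 2)
  d <- as.matrix(dist(xy))
  off <- d[upper.tri(d)]
  expect_equal(off, rep(off[1], 3), tolerance = 1e-10)
})

test_that("MDS round-trips exactly Euclidean dissimilarities", {
  set.seed(114)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  sim <- 1 - D / max(D) * 0.9
  xy <- mds_embed(sim, 2)
  expect_equal(as.matrix(dist(xy)), D / max(D) * 0.9, tolerance = 1e-8)
  # the diagonal is ignored: shifting it changes nothing
  sim2 <- sim; diag(sim2) <- diag(sim2) - 0.3
  expect_equal(mds_embed(sim2, 2), xy, tolerance = 1e-10)
})

test_that("MDS refuses more dimensions than positive eigenvalues", {
  sim <- matrix(0.5, 3, 3); diag(sim) <- 1
  expect_error(mds_embed(sim, 3), "positive eigenvalues")
})

test_that("parcel matching pairs identical mean sets with cosine 1", {
  set.seed(115)
  V <- parcelfuse:::unit_rows(matrix(rnorm(4 * 6), 4, 6))
  perm <- c(3, 1, 4, 2)
  mm <- match_parcels(V[perm, ], V)
  expect_equal(mm$cosine, rep(1, 4), tolerance = 1e-12)
  expect_equal(mm$ref[order(mm$est)], perm)
})
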