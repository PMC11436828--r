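test_that("parcel similarity matches the weighted-sum oracle", {
  set.seed(121)
  K <- 4; sp <- make_symmetric_grid(4, 2)
  V1 <- parcelfuse:::unit_rows(matrix(rnorm(K * 5), K, 5))
  V2 <- parcelfuse:::unit_rows(matrix(rnorm(K * 3), K, 3))
  em <- vmf_emission("x", list(V1, V2), kappa = c(10, 4), sessions = c(5, 3))
  arr <- arrangement(matrix(0, K, 8))
  m <- parcelfuse:::new_fused_model(arr, list(x = em), sp, list())
  S <- parcel_similarity(m, hemisphere_average = FALSE)
  oracle <- (10 * V1 %*% t(V1) + 4 * V2 %*% t(V2)) / 14
  expect_equal(S, oracle, tolerance = 1e-12)
  expect_equal(diag(S), rep(1, K), tolerance = 1e-12)
})

test_that("session weights scale linearly with kappa", {
  set.seed(122)
  K <- 3; sp <- make_symmetric_grid(4, 2)
  V1 <- parcelfuse:::unit_rows(matrix(rnorm(K * 4), K, 4))
  V2 <- parcelfuse:::unit_rows(matrix(rnorm(K * 4), K, 4))
  mk <- function(k1) {
    em <- vmf_emission("x", list(V1, V2), kappa = c(k1, 5), sessions = c(4, 4))
    parcelfuse:::new_fused_model(arrangement(matrix(0, K, 8)), list(x = em),
                                 sp, list())
  }
  S1 <- parcel_similarity(mk(5), hemisphere_average = FALSE)
  S2 <- parcel_similarity(mk(10), hemisphere_average = FALSE)
  # doubling session 1's kappa doubles its weight in the mean
  C1 <- V1 %*% t(V1); C2 <- V2 %*% t(V2)
  expect_equal(S1, (5 * C1 + 5 * C2) / 10, tolerance = 1e-12)
  expect_equal(S2, (10 * C1 + 5 * C2) / 15, tolerance = 1e-12)
})

test_that("never-winning parcels are merged into functional neighbors", {
  set.seed(123)
  sp <- make_symmetric_grid(8, 8)
  P <- 64
  # 8 planted parcels that win voxels + 4 empty ones
  gp_active <- sample_group_arrangement(sp, 8, smoothness = Inf, seed = 124)
  prob <- rbind(gp_active * 0.97, matrix(0.01, 4, P))
  prob <- sweep(prob, 2, colSums(prob), "/")
  V <- list(parcelfuse:::unit_rows(matrix(rnorm(12 * 6), 12, 6)))
  em <- vmf_emission("x", V, kappa = 10, sessions = 6)
  arr <- arrangement(log(prob))
  m <- parcelfuse:::new_fused_model(arr, list(x = em), sp, list())
  truth_lab <- hard_parcellation(prob)
  res <- merge_until_winners(m)
  expect_equal(res$model$arrangement$K, 8)
  expect_equal(nrow(res$steps), 4)
  lab_after <- hard_parcellation(group_prob(res$model$arrangement))
  expect_equal(adjusted_rand_index(lab_after, truth_lab), 1)
})

test_that("merged probability columns are the sum of their children", {
  set.seed(125)
  P <- 16
  prob <- softmax_cols_test(matrix(rnorm(3 * P), 3, P))
  merged <- parcelfuse:::merge_prob_rows_(prob, from = 3, into = 1)
  expect_equal(merged[1, ], prob[1, ] + prob[3, ], tolerance = 1e-12)
  expect_equal(colSums(merged), rep(1, P), tolerance = 1e-12)
})

test_that("paired merging keeps symmetric models symmetric", {
  m <- small_model()
  w <- small_world()
  # force a pair to never win by shrinking its potentials
  m2 <- m
  lab <- hard_parcellation(group_prob(m2$arrangement))
  victim <- 2
  m2$arrangement$eta[c(victim, victim + 3), ] <- -30
  res <- merge_until_winners(m2, w$datasets)
  expect_equal(res$model$arrangement$K, 4)
  p <- group_prob(res$model$arrangement)
  expect_lt(symmetry_deviation(p, w$space), 1e-12)
})

test_that("domain clustering cuts planted blocks perfectly", {
  sim <- rbind(
    c(1.0, 0.9, 0.85, 0.1, 0.15, 0.1),
    c(0.9, 1.0, 0.9, 0.1, 0.1, 0.12),
    c(0.85, 0.9, 1.0, 0.15, 0.1, 0.1),
    c(0.1, 0.1, 0.15, 1.0, 0.9, 0.88),
    c(0.15, 0.1, 0.1, 0.9, 1.0, 0.9),
    c(0.1, 0.12, 0.1, 0.88, 0.9, 1.0)
  )
  h <- build_domains(sim, 2)
  expect_equal(h$levels$domain, c(1, 1, 1, 2, 2, 2))
  expect_true(all(grepl("^A", h$names[1:3])))
  expect_true(all(grepl("^B", h$names[4:6])))
  # one domain per parcel at the fine end
  h6 <- build_domains(sim, 6)
  expect_equal(length(unique(h6$levels$domain)), 6)
  expect_error(build_domains(sim, 7), "more domains")
})

test_that("domain labels nest the parcel level exactly", {
  set.seed(126)
  sim <- stats::cov2cor(crossprod(matrix(rnorm(64), 8, 8)))
  h2 <- build_domains(sim, 2)
  h4 <- build_domains(sim, 4)
  # hierarchical cuts of the same tree: the finer cut refines the coarser
  tab <- table(h4$levels$domain, h2$levels$domain)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("colormaps give identical colors to identical parcels", {
  sim <- rbind(
    c(1, 1, 0.2, 0.1),
    c(1, 1, 0.2, 0.1),
    c(0.2, 0.2, 1, 0.3),
    c(0.1, 0.1, 0.3, 1)
  )
  anchors <- rbind(c(0, 1, 0), c(1, 0, 0), c(1, 1, 0))
  rownames(anchors) <- c(1, 3, 4)
  cols <- suppressWarnings(colormap_from_similarity(sim, anchors))
  expect_equal(cols[1, ], cols[2, ], tolerance = 1e-8)
  expect_true(all(cols >= 0 & cols <= 1))
})

test_that("colormap distances track functional similarity", {
  set.seed(127)
  # two tight blocks: within-block color distances must be smaller
  sim <- matrix(0.1, 8, 8)
  sim[1:4, 1:4] <- 0.9; sim[5:8, 5:8] <- 0.9
  diag(sim) <- 1
  anchors <- rbind(c(0, 1, 0), c(1, 0, 0), c(1, 1, 0))
  rownames(anchors) <- c(1, 5, 8)
  cols <- suppressWarnings(colormap_from_similarity(sim, anchors))
  dc <- as.matrix(dist(cols))
  within <- c(dc[1:4, 1:4][upper.tri(dc[1:4, 1:4])],
              dc[5:8, 5:8][upper.tri(dc[5:8, 5:8])])
  between <- dc[1:4, 5:8]
  # rank agreement between similarity and color proximity
  expect_gt(stats::cor(as.vector(sim[upper.tri(sim)]),
                       -as.vector(dc[upper.tri(dc)]),
                       method = "spearman"), 0.8)
  expect_lt(mean(within), mean(between))
})

test_that("lateralization is 1 for mirrored profiles and -1 for negated", {
  m <- small_model()
  li <- lateralization_index(m)
  expect_tibble(li)
  # construct a model whose right-hemisphere profiles mirror the left
  w <- small_world()
  K <- 6; Kh <- 3
  V <- m$emissions[["a"]]$V
  V_sym <- lapply(V, function(v) rbind(v[1:Kh, ], v[1:Kh, ]))
  em_sym <- vmf_emission("a", V_sym, m$emissions[["a"]]$kappa, c(8, 8))
  ms <- m; ms$emissions <- list(a = em_sym)
  li_sym <- lateralization_index(ms)
  expect_equal(li_sym$lateralization, rep(1, nrow(li_sym)), tolerance = 1e-9)
  V_neg <- lapply(V, function(v) rbind(v[1:Kh, ], -v[1:Kh, ]))
  em_neg <- vmf_emission("a", V_neg, m$emissions[["a"]]$kappa, c(8, 8))
  mn <- m; mn$emissions <- list(a = em_neg)
  li_neg <- lateralization_index(mn)
  expect_equal(li_neg$lateralization, rep(-1, nrow(li_neg)), tolerance = 1e-9)
})

test_that("a planted lateralized parcel has the lowest region index", {
  m <- small_model()
  w <- small_world()
  Kh <- 3
  V <- m$emissions[["a"]]$V
  # mirror-symmetric profiles except parcel pair 2, which is flipped
  V_pl <- lapply(V, function(v) {
    out <- rbind(v[1:Kh, ], v[1:Kh, ])
    out[Kh + 2, ] <- -v[2, ]
    out
  })
  em_pl <- vmf_emission("a", V_pl, m$emissions[["a"]]$kappa, c(8, 8))
  mp <- m; mp$emissions <- list(a = em_pl)
  li <- lateralization_index(mp)
  lab <- hard_parcellation(group_prob(m$arrangement))
  by_region <- vapply(1:Kh, function(k) {
    mean(li$lateralization[lab[li$left_voxel] == k])
  }, 0)
  expect_equal(which.min(by_region), 2L)
})

test_that("boundary symmetry is 1 for identical models", {
  m <- small_model()
  bs <- boundary_symmetry(m, m)
  expect_equal(bs$boundary_symmetry, rep(1, nrow(bs)), tolerance = 1e-12)
})

test_that("boundary symmetry drops exactly at shifted boundaries", {
  sp <- make_symmetric_grid(6, 2)
  eta <- matrix(-20, 2, 12)
  left_cols <- which(sp$hemisphere == "left")
  eta[1, left_cols] <- 5; eta[2, -left_cols] <- 5
  a1 <- arrangement(eta)
  eta2 <- eta
  flip <- left_cols[1:2]
  eta2[1, flip] <- -20; eta2[2, flip] <- 5    # boundary moved at 2 voxels
  a2 <- arrangement(eta2)
  sp4 <- make_symmetric_grid(6, 2)
  m1 <- parcelfuse:::new_fused_model(a1, list(), sp4, list())
  m2 <- parcelfuse:::new_fused_model(a2, list(), sp4, list())
  bs <- boundary_symmetry(m1, m2)
  expect_equal(which(bs$boundary_symmetry < 0.99), sort(flip))
})

test_that("profile ridge regression matches the closed form", {
  set.seed(128)
  C <- 12; Fk <- 4; K <- 3
  X <- matrix(rnorm(C * Fk), C, Fk)
  Y <- matrix(rnorm(C * K), C, K)
  out <- profile_regression(Y, X, l2 = 0.7, normalize = FALSE)
  B <- solve(crossprod(X) + 0.7 * diag(Fk), crossprod(X, Y))
  expect_equal(matrix(out$estimate, Fk, K), B, tolerance = 1e-10)
})

test_that("unregularized fits on orthonormal designs are projections", {
  X <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  y <- matrix(rnorm(6), 6, 1)
  out <- profile_regression(y, X, l2 = 0, normalize = FALSE)
  expect_equal(out$estimate, as.vector(t(X) %*% y), tolerance = 1e-10)
  # a profile equal to a design column loads on that column only
  out2 <- profile_regression(X[, 2, drop = FALSE], X, l2 = 0,
                             normalize = FALSE)
  expect_equal(out2$estimate, c(0, 1, 0), tolerance = 1e-10)
  expect_error(profile_regression(y, cbind(X, X), l2 = 0,
                                  normalize = FALSE), "rank-deficient")
})

test_that("region sizes are equal under symmetry and sum to P", {
  m <- small_model()
  sz <- region_size_asymmetry(m)
  expect_equal(sz$left_count, sz$right_count)
  expect_equal(sum(sz$left_count) + sum(sz$right_count), 144)
})
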