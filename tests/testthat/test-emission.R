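test_that("normalization rescales session blocks and flags degenerate rows", {
  m <- rbind(c(3, 4), c(0, 0), c(1, NA))
  nr <- normalize_profiles(m, sessions = 2)
  expect_equal(nr$dirs[1, ], c(0.6, 0.8))
  expect_equal(nr$lengths[1, 1], 5)
  expect_false(nr$ok[2, 1])   # all-zero block
  expect_false(nr$ok[3, 1])   # missing value
  norms <- sqrt(rowSums(nr$dirs^2))
  expect_true(all(abs(norms) < 1e-12 | abs(norms - 1) < 1e-12))
})

test_that("emission log-probability matches a naive per-term oracle", {
  set.seed(21)
  K <- 3; P <- 7; sessions <- c(4, 3)
  V <- list(parcelfuse:::unit_rows(matrix(rnorm(K * 4), K, 4)),
            parcelfuse:::unit_rows(matrix(rnorm(K * 3), K, 3)))
  em <- vmf_emission("x", V, kappa = c(8, 3), sessions = sessions)
  Y <- matrix(rnorm(P * 7), P, 7)
  L <- emission_logprob(em, Y)
  nr <- normalize_profiles(Y, sessions)
  cols <- list(1:4, 5:7)
  for (k in 1:K) for (i in 1:P) {
    ref <- 0
    for (n in 1:2) {
      y <- nr$dirs[i, cols[[n]]]
      ref <- ref + vmf_log_norm_const(sessions[n], em$kappa[n]) +
        em$kappa[n] * sum(V[[n]][k, ] * y)
    }
    expect_equal(L[k, i], ref, tolerance = 1e-12)
  }
})

test_that("a profile equal to the mean direction attains the maximum", {
  V <- list(parcelfuse:::unit_rows(matrix(rnorm(8), 2, 4)))
  em <- vmf_emission("x", V, kappa = 6, sessions = 4)
  L <- emission_logprob(em, rbind(V[[1]][1, ]))
  expect_equal(L[1, 1], vmf_log_norm_const(4, 6) + 6, tolerance = 1e-12)
  expect_gt(L[1, 1], L[2, 1])
})

test_that("with one parcel every voxel trivially picks it", {
  V <- list(parcelfuse:::unit_rows(matrix(rnorm(5), 1, 5)))
  em <- vmf_emission("x", V, kappa = 2, sessions = 5)
  L <- emission_logprob(em, matrix(rnorm(20 * 5), 20, 5))
  expect_equal(nrow(L), 1)
  expect_true(all(is.finite(L)))
})

test_that("session-partition mismatches are rejected", {
  V <- list(parcelfuse:::unit_rows(matrix(rnorm(8), 2, 4)))
  em <- vmf_emission("x", V, kappa = 6, sessions = 4)
  expect_error(emission_logprob(em, matrix(0, 3, 5)), "session")
})

test_that("one-hot responsibilities recover the data direction exactly", {
  y <- c(0.6, 0.8, 0)
  Y <- rbind(y, y, y, y)
  nr <- normalize_profiles(Y, sessions = 3)
  em0 <- vmf_emission("x", list(parcelfuse:::unit_rows(matrix(rnorm(3), 1, 3))),
                      kappa = 1, sessions = 3)
  up <- emission_m_step(em0, list(nr), list(matrix(1, 1, 4)))
  expect_equal(up$V[[1]][1, ], y, tolerance = 1e-12)
  expect_equal(up$kappa, 1e5)  # perfectly aligned data hits the cap
})

test_that("antipodal clusters drive the concentration to its floor", {
  Y <- rbind(c(1, 0), c(-1, 0), c(1, 0), c(-1, 0))
  nr <- normalize_profiles(Y, sessions = 2)
  em0 <- vmf_emission("x", list(matrix(c(1, 0), 1, 2)), kappa = 5,
                      sessions = 2)
  up <- emission_m_step(em0, list(nr), list(matrix(1, 1, 4)))
  expect_equal(up$kappa, 1e-3)
})

test_that("parcels with zero weight keep their mean and are flagged", {
  set.seed(22)
  Y <- matrix(rnorm(12), 4, 3)
  nr <- normalize_profiles(Y, sessions = 3)
  V0 <- parcelfuse:::unit_rows(matrix(rnorm(6), 2, 3))
  em0 <- vmf_emission("x", list(V0), kappa = 5, sessions = 3)
  U <- rbind(rep(1, 4), rep(0, 4))
  up <- emission_m_step(em0, list(nr), list(U))
  expect_equal(up$V[[1]][2, ], V0[2, ])
  expect_equal(attr(up, "empty_parcels"), 2L)
})

test_that("the concentration update matches a 1-D likelihood grid search", {
  set.seed(23)
  P <- 20; K <- 2; N <- 5
  mu <- parcelfuse:::unit_rows(matrix(rnorm(K * N), K, N))
  lab <- rep(1:2, each = P / 2)
  Y <- t(sapply(seq_len(P), function(i) sample_vmf(1, mu[lab[i], ], 15)))
  nr <- normalize_profiles(Y, sessions = N)
  U <- matrix(0, K, P); U[cbind(lab, seq_len(P))] <- 1
  em0 <- vmf_emission("x", list(mu), kappa = 5, sessions = N)
  up <- emission_m_step(em0, list(nr), list(U))
  # oracle: expected complete-data log-likelihood maximized over a kappa grid
  ell <- function(kap) {
    lc <- vmf_log_norm_const(N, kap)
    sum(sapply(seq_len(P), function(i) {
      lc + kap * sum(up$V[[1]][lab[i], ] * nr$dirs[i, ])
    }))
  }
  grid <- seq(0.2, 60, by = 0.02)
  k_star <- grid[which.max(sapply(grid, ell))]
  expect_equal(up$kappa, k_star, tolerance = 0.01)
})

test_that("the M-step never decreases the expected complete-data objective", {
  set.seed(24)
  for (rep in 1:5) {
    P <- 15; K <- 3; N <- 4
    Y <- matrix(rnorm(P * N), P, N)
    nr <- normalize_profiles(Y, sessions = N)
    U <- softmax_cols_test(matrix(rnorm(K * P), K, P))
    em0 <- vmf_emission("x",
                        list(parcelfuse:::unit_rows(matrix(rnorm(K * N), K, N))),
                        kappa = stats::runif(1, 0.5, 30), sessions = N)
    obj <- function(em) sum(U * emission_logprob(em, nr))
    em1 <- emission_m_step(em0, list(nr), list(U))
    expect_gte(obj(em1), obj(em0) - 1e-8 * abs(obj(em0)))
  }
})

test_that("the mean-direction update is rotation-equivariant", {
  set.seed(25)
  P <- 10; N <- 4
  Y <- matrix(rnorm(P * N), P, N)
  qr_ <- qr.Q(qr(matrix(rnorm(N * N), N, N)))   # random rotation
  U <- softmax_cols_test(matrix(rnorm(2 * P), 2, P))
  em0 <- vmf_emission("x", list(parcelfuse:::unit_rows(matrix(rnorm(2 * N), 2, N))),
                      kappa = 3, sessions = N)
  up1 <- emission_m_step(em0, list(normalize_profiles(Y, N)), list(U))
  em0r <- vmf_emission("x", list(em0$V[[1]] %*% qr_), kappa = 3, sessions = N)
  up2 <- emission_m_step(em0r, list(normalize_profiles(Y %*% qr_, N)), list(U))
  expect_equal(up1$V[[1]] %*% qr_, up2$V[[1]], tolerance = 1e-10)
  expect_equal(up1$kappa, up2$kappa, tolerance = 1e-10)
})

test_that("the emission density integrates to one on low-dim spheres", {
  # surface integral of exp(logprob) over S^(d-1) by radial quadrature
  for (d in c(3, 4)) {
    kap <- 7
    area_sub <- 2 * pi^((d - 1) / 2) / gamma((d - 1) / 2)
    f <- function(t) exp(vmf_log_norm_const(d, kap) + kap * t) *
      (1 - t^2)^((d - 3) / 2) * area_sub
    I <- stats::integrate(f, -1, 1, rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-8)
  }
})
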