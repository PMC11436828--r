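#' von Mises-Fisher emission models
#'
#' A `vmf_emission` is the dataset-specific likelihood of functional
#' profiles given parcel membership: each parcel k has a unit mean direction
#' per session, and each session has one shared concentration kappa (which
#' acts as the dataset's reliability weight during fusion).
#'
#' @param dataset_id identifier of the dataset the model belongs to.
#' @param V list with one `K x N_n` matrix of mean directions per session;
#'   rows are normalized.
#' @param kappa numeric vector of per-session concentrations.
#' @param sessions integer vector of condition counts per session.
#' @return An object of class `vmf_emission`.
#' @export
vmf_emission <- function(dataset_id, V, kappa, sessions) {
  sessions <- as.integer(sessions)
  stopifnot(length(V) == length(sessions), length(kappa) == length(sessions),
            all(kappa > 0))
  K <- nrow(V[[1]])
  for (n in seq_along(V)) {
    stopifnot(nrow(V[[n]]) == K, ncol(V[[n]]) == sessions[n])
    V[[n]] <- unit_rows(V[[n]])
  }
  structure(
    list(dataset_id = dataset_id, V = V, kappa = kappa, K = K,
         sessions = sessions),
    class = "vmf_emission"
  )
}

# random initialization: mean directions uniform on the sphere
vmf_emission_init <- function(dataset_id, K, sessions, kappa0 = 5) {
  V <- lapply(sessions, function(N) unit_rows(matrix(rnorm(K * N), K, N)))
  vmf_emission(dataset_id, V, rep(kappa0, length(sessions)), sessions)
}

#' @export
print.vmf_emission <- function(x, ...) {
  cat(sprintf("<vmf_emission> '%s': K = %d, %d sessions, kappa = %s\n",
              x$dataset_id, x$K, length(x$sessions),
              paste(signif(x$kappa, 4), collapse = ", ")))
  invisible(x)
}

#' Normalize functional profiles to session-wise unit vectors
#'
#' The vMF likelihood acts on directions, so each voxel's sub-vector within
#' a session is rescaled to unit norm. The pre-normalization lengths are
#' retained (they weight the cosine prediction error). Voxels whose session
#' block is all-zero or contains missing values are flagged and excluded
#' from likelihood sums rather than treated as errors.
#'
#' @param data `P x N` matrix of activation estimates (may contain `NA`).
#' @param sessions integer vector of condition counts per session.
#' @return A list with `dirs` (P x N, unit rows per session block, zeros for
#'   flagged blocks), `lengths` (P x S pre-normalization norms) and `ok`
#'   (P x S logical validity flags).
#' @export
normalize_profiles <- function(data, sessions) {
  data <- as.matrix(data)
  cols <- session_cols(sessions)
  P <- nrow(data)
  S <- length(sessions)
  dirs <- matrix(0, P, ncol(data))
  lens <- matrix(0, P, S)
  ok <- matrix(FALSE, P, S)
  for (n in seq_len(S)) {
    blk <- data[, cols[[n]], drop = FALSE]
    good <- rowSums(is.na(blk)) == 0
    nrm <- numeric(P)
    nrm[good] <- sqrt(rowSums(blk[good, , drop = FALSE]^2))
    use <- good & nrm > 0
    dirs[use, cols[[n]]] <- blk[use, , drop = FALSE] / nrm[use]
    lens[, n] <- nrm
    ok[, n] <- use
  }
  list(dirs = dirs, lengths = lens, ok = ok)
}

#' Emission log-likelihood of a subject's data under each parcel
#'
#' Entry (k, i) is the log-probability of voxel i's observed directions
#' given membership in parcel k, summed over sessions:
#' `sum_n log C(kappa_n) + kappa_n * v_k^n . y_i^n`. Sessions flagged as
#' missing or degenerate for a voxel contribute nothing for that voxel.
#'
#' @param emission a [vmf_emission()].
#' @param data `P x N` matrix for one subject (raw scale; normalized
#'   internally), or a precomputed [normalize_profiles()] result.
#' @return A `K x P` matrix of log-likelihoods.
#' @export
emission_logprob <- function(emission, data) {
  norm <- if (is.list(data) && !is.null(data$dirs)) data else {
    if (ncol(as.matrix(data)) != sum(emission$sessions)) {
      stop("condition count does not match the emission's session partition")
    }
    normalize_profiles(data, emission$sessions)
  }
  if (ncol(norm$dirs) != sum(emission$sessions)) {
    stop("condition count does not match the emission's session partition")
  }
  cols <- session_cols(emission$sessions)
  P <- nrow(norm$dirs)
  L <- matrix(0, emission$K, P)
  for (n in seq_along(cols)) {
    kap <- emission$kappa[n]
    lc <- vmf_log_norm_const(emission$sessions[n], kap)
    proj <- emission$V[[n]] %*% t(norm$dirs[, cols[[n]], drop = FALSE])
    okn <- norm$ok[, n]
    contrib <- lc + kap * proj
    contrib[, !okn] <- 0
    L <- L + contrib
  }
  L
}

# Banerjee-style closed-form kappa with Newton refinement on the exact
# score A_d(kappa) = rbar; clipped to [1e-3, 1e5].
estimate_kappa <- function(rbar, dim, newton = 10) {
  lo <- 1e-3; hi <- 1e5
  rbar <- min(max(rbar, 0), 1 - 1e-8)
  if (rbar == 0) return(lo)
  k <- rbar * (dim - rbar^2) / (1 - rbar^2)
  k <- min(max(k, lo), hi)
  for (it in seq_len(newton)) {
    A <- vmf_mean_resultant(dim, k)
    dA <- 1 - A^2 - (dim - 1) / k * A
    if (!is.finite(dA) || dA <= 0) break
    step <- (A - rbar) / dA
    k_new <- min(max(k - step, lo), hi)
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  k
}

#' M-step update of a vMF emission model
#'
#' Given per-subject posterior parcel responsibilities, updates each
#' session's mean directions to the normalized responsibility-weighted
#' resultants and re-estimates the session concentration from the mean
#' resultant length (closed-form approximation plus Newton refinement of
#' the exact score). Parcels that received no weight keep their previous
#' mean direction and are reported in the `empty_parcels` attribute.
#'
#' @param emission the current [vmf_emission()].
#' @param norms list of [normalize_profiles()] results, one per subject.
#' @param posteriors list of `K x P` responsibility matrices, one per
#'   subject (columns sum to 1).
#' @return The updated [vmf_emission()].
#' @export
emission_m_step <- function(emission, norms, posteriors) {
  K <- emission$K
  cols <- session_cols(emission$sessions)
  V_new <- emission$V
  kappa_new <- emission$kappa
  empty <- integer(0)
  for (n in seq_along(cols)) {
    R <- matrix(0, K, emission$sessions[n])
    W <- 0
    for (s in seq_along(norms)) {
      okn <- norms[[s]]$ok[, n]
      if (!any(okn)) next
      U <- posteriors[[s]][, okn, drop = FALSE]
      Y <- norms[[s]]$dirs[okn, cols[[n]], drop = FALSE]
      R <- R + U %*% Y
      W <- W + sum(okn)
    }
    rk <- sqrt(rowSums(R^2))
    upd <- rk > 1e-12
    V_new[[n]][upd, ] <- R[upd, , drop = FALSE] / rk[upd]
    empty <- union(empty, which(!upd))
    if (W > 0) {
      kappa_new[n] <- estimate_kappa(sum(rk) / W, emission$sessions[n])
    }
  }
  out <- vmf_emission(emission$dataset_id, V_new, kappa_new, emission$sessions)
  attr(out, "empty_parcels") <- sort(empty)
  out
}
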