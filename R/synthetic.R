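#' Synthetic ground-truth parcellations
#'
#' Samples a K x P group probability map over a voxel space by softened
#' Voronoi partitioning: K seed voxels are drawn, and each voxel's parcel
#' probabilities decay with distance to the seeds at a rate set by
#' `smoothness` (larger = sharper; `Inf` gives hard nearest-seed labels).
#' The generating arrangement model is spatially independent, so spatial
#' contiguity has to be built into the ground truth for boundary-based
#' evaluations to have boundaries to find.
#'
#' With `symmetric = TRUE` (requires even K), seeds are drawn in the left
#' hemisphere only; parcels `1..K/2` live on the left and parcels
#' `K/2+1..K` are their mirror images, so
#' `p[k, i] == p[k + K/2, mirror(i)]` holds exactly. Midline voxels, if
#' present, split their mass equally between the paired parcels.
#'
#' @param space a [voxel_space()].
#' @param K number of parcels.
#' @param smoothness inverse temperature of the softened partition, in
#'   1/template units; `Inf` for hard labels.
#' @param symmetric mirror-symmetric map with paired parcels?
#' @param seed optional integer seed (local to this call).
#' @return A `K x P` matrix with columns summing to 1.
#' @export
sample_group_arrangement <- function(space, K, smoothness = 2,
                                     symmetric = FALSE, seed = NULL) {
  P <- n_voxels(space)
  stopifnot(K >= 1)
  if (K > P) stop("more parcels than voxels")
  if (K == 1) return(matrix(1, 1, P))
  if (symmetric && K %% 2 != 0) stop("symmetric maps need an even K")
  with_seed_(seed, {
    if (!symmetric) {
      seeds <- sample.int(P, K)
      soft_voronoi_(space$coords, space$coords[seeds, , drop = FALSE],
                    smoothness)
    } else {
      left <- which(space$hemisphere == "left")
      Kh <- K %/% 2
      if (Kh > length(left)) stop("more parcels than left-hemisphere voxels")
      seeds <- sample(left, Kh)
      p_left <- soft_voronoi_(space$coords[left, , drop = FALSE],
                              space$coords[seeds, , drop = FALSE], smoothness)
      prob <- matrix(0, K, P)
      prob[seq_len(Kh), left] <- p_left
      right_of <- space$mirror[left]
      prob[Kh + seq_len(Kh), right_of] <- p_left
      mid <- which(space$hemisphere == "midline")
      if (length(mid) > 0) {
        # equal split between the paired parcels, by convention
        d_mid <- soft_voronoi_(space$coords[mid, , drop = FALSE],
                               space$coords[seeds, , drop = FALSE], smoothness)
        prob[seq_len(Kh), mid] <- d_mid / 2
        prob[Kh + seq_len(Kh), mid] <- d_mid / 2
      }
      prob
    }
  })
}

# columns of the result are softmax(-smoothness * distance-to-seed)
soft_voronoi_ <- function(coords, seed_coords, smoothness) {
  K <- nrow(seed_coords)
  P <- nrow(coords)
  d <- matrix(0, K, P)
  for (k in seq_len(K)) {
    d[k, ] <- sqrt(colSums((t(coords) - seed_coords[k, ])^2))
  }
  if (!is.finite(smoothness)) {
    lab <- apply(d, 2, which.min)
    prob <- matrix(0, K, P)
    prob[cbind(lab, seq_len(P))] <- 1
    return(prob)
  }
  softmax_cols(-smoothness * d)
}

# column-wise softmax with logsumexp stabilisation
softmax_cols <- function(lp) {
  mx <- apply(lp, 2, max)
  e <- exp(sweep(lp, 2, mx))
  sweep(e, 2, colSums(e), "/")
}

#' Ground truth for a synthetic functional world
#'
#' Bundles a group probability map with the true emission parameters of one
#' dataset: per-session parcel mean directions (unit vectors in condition
#' space) and per-session concentrations. Mean directions are drawn
#' uniformly on the sphere unless supplied, which lets experiments plant
#' structure (e.g. sessions informative about only a subset of parcels).
#'
#' @param group_prob `K x P` probability matrix (columns sum to 1).
#' @param sessions integer vector of condition counts, one per session.
#' @param kappa per-session concentration(s), recycled to `length(sessions)`.
#' @param V optional list of `K x sessions[n]` matrices of true mean
#'   directions; rows are normalized.
#' @param seed optional integer seed (local to this call).
#' @return An object of class `ground_truth` with fields `group_prob`, `K`,
#'   `sessions`, `true_kappa`, `true_V`.
#' @export
ground_truth <- function(group_prob, sessions, kappa, V = NULL, seed = NULL) {
  K <- nrow(group_prob)
  if (max(abs(colSums(group_prob) - 1)) > 1e-8) {
    stop("group_prob columns must sum to 1")
  }
  kappa <- rep_len(kappa, length(sessions))
  stopifnot(all(kappa > 0), all(sessions >= 2))
  if (is.null(V)) {
    V <- with_seed_(seed, lapply(sessions, function(N) {
      unit_rows(matrix(rnorm(K * N), K, N))
    }))
  } else {
    stopifnot(length(V) == length(sessions))
    V <- lapply(V, unit_rows)
  }
  structure(
    list(group_prob = group_prob, K = K, sessions = as.integer(sessions),
         true_kappa = kappa, true_V = V),
    class = "ground_truth"
  )
}

#' Sample a multi-subject functional dataset from a ground truth
#'
#' For each subject, a hard parcel assignment is drawn per voxel from the
#' group probability map; each voxel's per-session functional profile is
#' then a vMF draw around the assigned parcel's true mean direction with the
#' session's concentration. The generating labels are recorded for scoring.
#'
#' @param truth a [ground_truth()].
#' @param space the [voxel_space()] the truth lives on.
#' @param n_subjects number of subjects to simulate.
#' @param sessions condition counts per session; must match the truth.
#' @param seed optional integer seed (local to this call).
#' @param dataset_id identifier stored on the dataset.
#' @return A [functional_dataset()] with a `true_labels` P x S matrix.
#' @export
sample_dataset <- function(truth, space, n_subjects,
                           sessions = truth$sessions, seed = NULL,
                           dataset_id = "synthetic") {
  stopifnot(inherits(truth, "ground_truth"))
  if (!identical(as.integer(sessions), truth$sessions)) {
    stop("session condition counts do not match the ground truth")
  }
  P <- ncol(truth$group_prob)
  stopifnot(P == n_voxels(space))
  K <- truth$K
  with_seed_(seed, {
    labels <- matrix(0L, P, n_subjects)
    for (s in seq_len(n_subjects)) {
      u <- runif(P)
      cum <- apply(truth$group_prob, 2, cumsum)
      labels[, s] <- as.integer(colSums(sweep(cum, 2, u, "<"))) + 1L
    }
    data <- vector("list", n_subjects)
    for (s in seq_len(n_subjects)) {
      mats <- vector("list", length(sessions))
      for (n in seq_along(sessions)) {
        Y <- matrix(0, P, sessions[n])
        for (k in seq_len(K)) {
          idx <- which(labels[, s] == k)
          if (length(idx) == 0) next
          Y[idx, ] <- sample_vmf(length(idx), truth$true_V[[n]][k, ],
                                 truth$true_kappa[n])
        }
        mats[[n]] <- Y
      }
      data[[s]] <- do.call(cbind, mats)
    }
    names(data) <- sprintf("sub-%02d", seq_len(n_subjects))
    functional_dataset(dataset_id, data, sessions, true_labels = labels)
  })
}
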