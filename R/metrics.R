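#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement of two hard parcellations under the
#' permutation model, computed from the contingency table. Invariant to
#' label permutations; 1 for identical partitions, about 0 for independent
#' ones.
#'
#' @param labels_a,labels_b integer/factor vectors of equal length.
#' @return Scalar ARI.
#' @examples
#' adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0))
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) == 0) stop("empty labelings")
  stopifnot(length(labels_a) == length(labels_b))
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Reliability-adjusted ARI between two parcellation ladders
#'
#' Compares two sets of parcellations fit at a ladder of granularities
#' (e.g. 10/20/34/40/68 regions). The between-set similarity is the mean
#' ARI over granularity pairs; it is divided by the geometric mean of the
#' two within-set reliabilities, each the mean ARI between different
#' granularities of the same set — so unreliable sets are not penalized
#' for disagreeing with each other.
#'
#' With `include_same_level = TRUE` (default) the between-set mean runs
#' over all `L x L` granularity pairs, the convention used when comparing
#' parcellations of different datasets. Setting it to `FALSE` restricts
#' the mean to different-granularity pairs, the same pair structure as the
#' reliability term; only under this variant is the self-similarity of a
#' set with itself exactly 1.
#'
#' @param parcellations_a,parcellations_b lists of label vectors, one per
#'   granularity, same ladder length for both.
#' @param include_same_level include same-granularity pairs in the
#'   between-set mean?
#' @return Scalar reliability-adjusted ARI.
#' @export
reliability_adjusted_ari <- function(parcellations_a, parcellations_b,
                                     include_same_level = TRUE) {
  L <- length(parcellations_a)
  stopifnot(L >= 2, length(parcellations_b) == L)
  within_mean <- function(set) {
    prs <- utils::combn(L, 2)
    mean(apply(prs, 2, function(ij) {
      adjusted_rand_index(set[[ij[1]]], set[[ij[2]]])
    }))
  }
  wa <- within_mean(parcellations_a)
  wb <- within_mean(parcellations_b)
  if (wa <= 0 || wb <= 0) stop("unreliable parcellation")
  idx <- expand.grid(i = seq_len(L), j = seq_len(L))
  if (!include_same_level) idx <- idx[idx$i != idx$j, ]
  between <- mean(mapply(function(i, j) {
    adjusted_rand_index(parcellations_a[[i]], parcellations_b[[j]])
  }, idx$i, idx$j))
  between / sqrt(wa * wb)
}

#' Precompute spatial distance bins for DCBC
#'
#' Bins all voxel pairs by Euclidean distance into half-open intervals
#' `[b, b + bin_width)`, dropping pairs beyond `max_dist`. The defaults
#' (1 template unit bins up to 35 units) follow the metric's original
#' formulation and are exposed because sensible values scale with the
#' template.
#'
#' @param space a [voxel_space()].
#' @param bin_width bin width in template units.
#' @param max_dist maximum pair distance considered.
#' @return An object of class `distance_binning` with the pair index.
#' @export
distance_binning <- function(space, bin_width = 1, max_dist = 35) {
  d <- as.matrix(stats::dist(space$coords))
  P <- nrow(d)
  ut <- upper.tri(d)
  keep <- ut & d <= max_dist & d > 0
  idx <- which(keep, arr.ind = TRUE)
  dist_kept <- d[keep]
  bin <- floor(dist_kept / bin_width) + 1L
  structure(
    list(bin_width = bin_width, max_dist = max_dist,
         pair_i = idx[, 1], pair_j = idx[, 2], bin = bin,
         n_bins = max(bin)),
    class = "distance_binning"
  )
}

#' Distance-controlled boundary coefficient
#'
#' Within each spatial distance bin, computes the mean Pearson correlation
#' of functional profiles for voxel pairs inside the same parcel minus the
#' mean for pairs straddling a boundary, then averages the bin differences
#' with weights `n_w * n_b / (n_w + n_b)` (the variance-minimizing weight
#' for a difference of two means). Controlling for distance removes the
#' trivial advantage that any spatially contiguous parcellation has on
#' spatially smooth data; a positive DCBC indicates boundaries that track
#' real functional transitions.
#'
#' @param hard_labels integer parcel labels, length P.
#' @param data `P x N` functional data matrix used for the correlations.
#' @param space a [voxel_space()] (used only through `binning`).
#' @param binning a [distance_binning()] for `space`.
#' @return Scalar DCBC (higher is better).
#' @export
dcbc <- function(hard_labels, data, space, binning = distance_binning(space)) {
  if (length(unique(hard_labels)) < 2) stop("no boundaries to evaluate")
  stopifnot(length(hard_labels) == nrow(data))
  r <- suppressWarnings(stats::cor(t(data)))
  rp <- r[cbind(binning$pair_i, binning$pair_j)]
  within <- hard_labels[binning$pair_i] == hard_labels[binning$pair_j]
  num <- 0; den <- 0
  for (b in seq_len(binning$n_bins)) {
    inb <- binning$bin == b & !is.na(rp)
    nw <- sum(inb & within)
    nb <- sum(inb & !within)
    if (nw == 0 || nb == 0) next
    w <- nw * nb / (nw + nb)
    num <- num + w * (mean(rp[inb & within]) - mean(rp[inb & !within]))
    den <- den + w
  }
  if (den == 0) stop("no distance bin contains both within- and between-parcel pairs")
  num / den
}

#' Weighted cosine prediction error
#'
#' Predicts each voxel's functional profile by the mean profile of its
#' assigned region, estimated from independent training subjects, and
#' scores `1 - cosine(prediction, observation)` per voxel. Voxel errors
#' are averaged with weights equal to the observed vector length, so
#' high-signal voxels dominate and noise-only voxels hardly count.
#'
#' @param hard_labels region assignment of the test subject's voxels
#'   (typically from a localizer-derived individual map).
#' @param train_subjects_data list of `P x N` matrices from the training
#'   subjects (held-out data half).
#' @param test_subject_data `P x N` matrix of the test subject's held-out
#'   data.
#' @param train_labels optional list of label vectors for the training
#'   subjects; defaults to `hard_labels` for all.
#' @return Scalar weighted mean error in `[0, 2]`; voxels whose region has
#'   no training data are excluded and counted in the `n_excluded`
#'   attribute.
#' @export
prediction_error <- function(hard_labels, train_subjects_data,
                             test_subject_data, train_labels = NULL) {
  P <- nrow(test_subject_data)
  N <- ncol(test_subject_data)
  K <- max(hard_labels)
  if (is.null(train_labels)) {
    train_labels <- rep(list(hard_labels), length(train_subjects_data))
  }
  vk <- matrix(0, K, N)
  cnt <- numeric(K)
  for (s in seq_along(train_subjects_data)) {
    m <- train_subjects_data[[s]]
    lab <- train_labels[[s]]
    for (k in seq_len(K)) {
      idx <- which(lab == k)
      if (length(idx) > 0) {
        vk[k, ] <- vk[k, ] + colSums(m[idx, , drop = FALSE])
        cnt[k] <- cnt[k] + length(idx)
      }
    }
  }
  have <- cnt > 0
  num <- 0; den <- 0; n_excl <- 0L
  for (i in seq_len(P)) {
    k <- hard_labels[i]
    y <- test_subject_data[i, ]
    len <- sqrt(sum(y^2))
    if (!have[k]) { n_excl <- n_excl + 1L; next }
    if (len == 0) next
    v <- vk[k, ]
    vn <- sqrt(sum(v^2))
    if (vn == 0) { n_excl <- n_excl + 1L; next }
    err <- 1 - sum(v * y) / (vn * len)
    num <- num + len * err
    den <- den + len
  }
  out <- if (den > 0) num / den else NA_real_
  attr(out, "n_excluded") <- n_excl
  out
}

#' Inter-individual variability map
#'
#' Pairwise between-subject Pearson correlations of each voxel's response
#' profile, corrected for measurement noise: each subject pair's
#' correlation is divided by the square root of the product of the two
#' subjects' split-half reliabilities at that voxel, and the corrected
#' values are averaged over pairs. Pairs with non-positive reliability at
#' a voxel are excluded there.
#'
#' @param dataset a [functional_dataset()] with at least two sessions (the
#'   split-half reliabilities come from the first vs second half of the
#'   sessions).
#' @return A tibble with one row per voxel: `voxel`, `reliability` (mean
#'   within-subject split-half correlation), `isc` (mean noise-corrected
#'   between-subject correlation) and `n_pairs` used.
#' @export
inter_subject_variability <- function(dataset) {
  halves <- split_halves(dataset)
  S <- n_subjects(dataset)
  if (S < 2) stop("need at least two subjects")
  P <- nrow(dataset$data[[1]])
  rel <- sapply(seq_len(S), function(s) {
    h1 <- halves$first$data[[s]]
    h2 <- halves$second$data[[s]]
    vapply(seq_len(P), function(i) {
      suppressWarnings(stats::cor(h1[i, ], h2[i, ]))
    }, 0)
  })
  full <- dataset$data
  isc <- numeric(P)
  npair <- integer(P)
  prs <- utils::combn(S, 2)
  for (p in seq_len(ncol(prs))) {
    s1 <- prs[1, p]; s2 <- prs[2, p]
    r12 <- vapply(seq_len(P), function(i) {
      suppressWarnings(stats::cor(full[[s1]][i, ], full[[s2]][i, ]))
    }, 0)
    okv <- !is.na(r12) & rel[, s1] > 0 & rel[, s2] > 0
    isc[okv] <- isc[okv] + r12[okv] / sqrt(rel[okv, s1] * rel[okv, s2])
    npair[okv] <- npair[okv] + 1L
  }
  tibble::tibble(
    voxel = seq_len(P),
    reliability = rowMeans(rel, na.rm = TRUE),
    isc = ifelse(npair > 0, isc / npair, NA_real_),
    n_pairs = npair
  )
}

#' Classical multidimensional scaling of a similarity matrix
#'
#' Torgerson MDS of the dissimilarity `1 - similarity` (diagonal zeroed):
#' the leading coordinates optimally reproduce the similarity structure as
#' Euclidean distances.
#'
#' @param similarity symmetric similarity matrix.
#' @param dims number of output dimensions.
#' @return A matrix of coordinates (`nrow(similarity) x dims`).
#' @export
mds_embed <- function(similarity, dims = 2) {
  if (!isSymmetric(unname(similarity), tol = 1e-8)) {
    stop("similarity matrix must be symmetric")
  }
  D <- 1 - similarity
  diag(D) <- 0
  fit <- stats::cmdscale(stats::as.dist(D), k = min(dims, nrow(D) - 1),
                         eig = TRUE)
  n_pos <- sum(fit$eig > 1e-10)
  if (dims > n_pos) {
    stop(sprintf("requested %d dimensions but only %d positive eigenvalues",
                 dims, n_pos))
  }
  fit$points[, seq_len(dims), drop = FALSE]
}

#' Match estimated parcels to reference parcels
#'
#' Mixture labels are arbitrary, so recovery scoring needs an explicit
#' correspondence. Parcels are matched by greedy maximum-weight bipartite
#' matching on the cosine similarity of their mean directions
#' (concatenated across sessions): repeatedly pair the most similar
#' unmatched parcels.
#'
#' @param V_est,V_ref lists of `K x N` mean-direction matrices (one per
#'   session) or single matrices; sessions are concatenated.
#' @return A tibble with `est`, `ref` and the matched `cosine`.
#' @export
match_parcels <- function(V_est, V_ref) {
  cat_rows <- function(V) {
    if (is.list(V)) do.call(cbind, V) else as.matrix(V)
  }
  A <- unit_rows(cat_rows(V_est))
  B <- unit_rows(cat_rows(V_ref))
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  S <- A %*% t(B)
  K <- nrow(S)
  est <- integer(K); ref <- integer(K); cs <- numeric(K)
  free_e <- rep(TRUE, K); free_r <- rep(TRUE, K)
  for (m in seq_len(K)) {
    Sm <- S
    Sm[!free_e, ] <- -Inf
    Sm[, !free_r] <- -Inf
    ij <- arrayInd(which.max(Sm), dim(Sm))
    est[m] <- ij[1]; ref[m] <- ij[2]; cs[m] <- S[ij[1], ij[2]]
    free_e[ij[1]] <- FALSE; free_r[ij[2]] <- FALSE
  }
  ord <- order(est)
  tibble::tibble(est = est[ord], ref = ref[ord], cosine = cs[ord])
}
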