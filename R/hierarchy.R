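#' Functional similarity between parcels
#'
#' Cosine similarity of parcel mean functional profiles, averaged over
#' sessions and datasets with weights `kappa_n * N_n` (session
#' concentration times subject count), so reliable, well-sampled sessions
#' count more. For symmetric models the left/right counterpart mean
#' vectors are averaged first, giving a `K/2 x K/2` matrix of hemisphere
#' pairs; otherwise the full `K x K` matrix is returned.
#'
#' @param model a [fused_model].
#' @param datasets optional list of [functional_dataset()]s supplying
#'   subject counts; defaults to weight 1 subject per dataset.
#' @param hemisphere_average average left/right counterparts first?
#'   (default: the model's symmetry/confinement flag).
#' @return A symmetric similarity matrix.
#' @export
parcel_similarity <- function(model, datasets = NULL,
                              hemisphere_average = model$arrangement$confined) {
  K <- model$arrangement$K
  n_sub <- function(d) {
    if (is.null(datasets)) 1 else n_subjects(as_dataset_list_(datasets)[[d]])
  }
  acc <- NULL
  wsum <- 0
  for (d in names(model$emissions)) {
    em <- model$emissions[[d]]
    Ns <- n_sub(d)
    for (n in seq_along(em$V)) {
      V <- em$V[[n]]
      if (hemisphere_average) {
        Kh <- K %/% 2
        V <- (V[seq_len(Kh), , drop = FALSE] +
                V[Kh + seq_len(Kh), , drop = FALSE]) / 2
      }
      Vu <- unit_rows(V)
      S <- Vu %*% t(Vu)
      w <- em$kappa[n] * Ns
      acc <- if (is.null(acc)) w * S else acc + w * S
      wsum <- wsum + w
    }
  }
  acc / wsum
}

#' Parcel hierarchies
#'
#' Bookkeeping for the nested organization of an atlas: a merge/step log,
#' label vectors per level (coarser levels are exact unions of finer
#' parcels), human-readable names, and parcel colors.
#'
#' @param levels named list of integer label vectors over the fine
#'   parcels, ordered fine to coarse.
#' @param merge_tree optional data frame of merge steps.
#' @param names_ optional character names per fine parcel.
#' @param colors optional `K x 3` RGB matrix in `[0, 1]`.
#' @return An object of class `parcel_hierarchy`.
#' @export
parcel_hierarchy <- function(levels, merge_tree = NULL, names_ = NULL,
                             colors = NULL) {
  structure(
    list(levels = levels, merge_tree = merge_tree, names = names_,
         colors = colors),
    class = "parcel_hierarchy"
  )
}

#' @export
print.parcel_hierarchy <- function(x, ...) {
  cat(sprintf("<parcel_hierarchy> levels: %s\n",
              paste(sprintf("%s (%d)", names(x$levels),
                            vapply(x$levels, function(l) length(unique(l)), 0L)),
                    collapse = " -> ")))
  invisible(x)
}

# merge rows j of a probability map into rows m (probability mass adds)
merge_prob_rows_ <- function(prob, from, into) {
  prob[into, ] <- prob[into, ] + prob[from, ]
  prob[-from, , drop = FALSE]
}

#' Merge parcels that win no voxels into their functional neighbors
#'
#' Repeatedly finds the smallest parcel by winner-take-all voxel count
#' and, while any parcel wins no voxel, merges it into its functionally
#' most similar parcel by summing their probability maps; emission mean
#' directions are re-derived for the merged parcel (resultant of the
#' children) and, when datasets are supplied, re-fit by EM with the
#' arrangement fixed. For symmetric/confined models, hemisphere pairs are
#' merged jointly so the pairing survives.
#'
#' @param model a fitted [fused_model].
#' @param datasets optional datasets for the emission refit.
#' @param similarity optional precomputed [parcel_similarity()] matrix.
#' @return A list with `model` (the merged [fused_model]) and `steps`
#'   (a tibble logging each merge: `from`, `into`, both in the labels of
#'   the then-current model).
#' @export
merge_until_winners <- function(model, datasets = NULL, similarity = NULL) {
  steps <- list()
  paired <- isTRUE(model$arrangement$confined)
  repeat {
    prob <- group_prob(model$arrangement)
    K <- nrow(prob)
    lab <- hard_parcellation(prob)
    counts <- tabulate(lab, nbins = K)
    if (paired) {
      Kh <- K %/% 2
      pair_counts <- counts[seq_len(Kh)] + counts[Kh + seq_len(Kh)]
      if (all(pair_counts > 0) || Kh <= 1) break
      sim <- if (is.null(similarity)) {
        parcel_similarity(model, datasets, hemisphere_average = TRUE)
      } else similarity
      j <- which.min(pair_counts)
      cand <- setdiff(seq_len(Kh), j)
      m <- cand[which.max(sim[j, cand])]
      prob2 <- merge_prob_rows_(prob, c(j, Kh + j), c(m, Kh + m))
      model <- rebuild_merged_(model, prob2, from = c(j, Kh + j),
                               into = c(m, Kh + m), datasets)
      steps[[length(steps) + 1]] <- tibble::tibble(from = j, into = m,
                                                   paired = TRUE)
    } else {
      if (all(counts > 0) || K <= 1) break
      sim <- if (is.null(similarity)) {
        parcel_similarity(model, datasets, hemisphere_average = FALSE)
      } else similarity
      j <- which.min(counts)
      cand <- setdiff(seq_len(K), j)
      m <- cand[which.max(sim[j, cand])]
      prob2 <- merge_prob_rows_(prob, j, m)
      model <- rebuild_merged_(model, prob2, from = j, into = m, datasets)
      steps[[length(steps) + 1]] <- tibble::tibble(from = j, into = m,
                                                   paired = FALSE)
    }
    similarity <- NULL  # stale after a merge
    if (nrow(group_prob(model$arrangement)) == 1) {
      warning("merged down to a single parcel")
      break
    }
  }
  list(model = model, steps = dplyr::bind_rows(steps))
}

# rebuild a fused model after merging parcels 'from' into 'into'
rebuild_merged_ <- function(model, prob2, from, into, datasets) {
  eta <- ifelse(prob2 > 0, log(prob2), NEG_POTENTIAL)
  arr <- model$arrangement
  arr2 <- arrangement(eta, model$space, symmetric = arr$symmetric,
                      confined = arr$confined)
  emissions <- lapply(model$emissions, function(em) {
    V <- lapply(em$V, function(v) {
      v[into, ] <- v[into, , drop = FALSE] + v[from, , drop = FALSE]
      unit_rows(v[-from, , drop = FALSE])
    })
    vmf_emission(em$dataset_id, V, em$kappa, em$sessions)
  })
  out <- new_fused_model(arr2, emissions, model$space,
                         list(parent = "merged", K = nrow(prob2)))
  if (!is.null(datasets)) {
    datasets <- as_dataset_list_(datasets)
    norms <- normalize_all_(datasets)
    run <- em_run_(datasets, norms, arr2, out$emissions, max_iter = 20,
                   tol = 1e-8, update_emissions = TRUE)
    # arrangement stays fixed: keep arr2, adopt refit emissions only
    out$emissions <- run$emissions
    out$arrangement <- arr2
  }
  out
}

#' Group parcels into functional domains
#'
#' Agglomerative clustering (average linkage on cosine distance) of the
#' parcel similarity matrix, cut at `n_domains`. Parcels are named
#' Domain-letter + region-number (+ hemisphere when expanded): region
#' numbers run medial to lateral when winner centroids are available from
#' a model, otherwise in parcel order.
#'
#' @param similarity symmetric parcel similarity matrix (typically
#'   hemisphere-averaged, `K/2 x K/2`).
#' @param n_domains number of domains to cut the dendrogram into.
#' @param model optional [fused_model] used for medial-to-lateral
#'   numbering of regions within each domain.
#' @return A [parcel_hierarchy()] with levels `parcel` and `domain`, names
#'   per parcel, and the `hclust` tree in `$merge_tree`.
#' @export
build_domains <- function(similarity, n_domains, model = NULL) {
  K <- nrow(similarity)
  if (n_domains > K) stop("more domains than parcels")
  if (!isSymmetric(unname(similarity), tol = 1e-8)) {
    stop("similarity matrix must be symmetric")
  }
  hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
  dom <- stats::cutree(hc, k = n_domains)
  # relabel domains in order of first appearance for stable letters
  dom <- match(dom, unique(dom))
  lateral <- if (!is.null(model)) {
    prob <- group_prob(model$arrangement)
    lab <- hard_parcellation(prob)
    Kfull <- nrow(prob)
    Kh <- if (model$arrangement$confined) Kfull %/% 2 else Kfull
    vapply(seq_len(K), function(k) {
      idx <- which(lab == k | (Kh < Kfull & lab == k + Kh))
      if (length(idx) == 0) return(Inf)
      mean(abs(model$space$coords[idx, 1]))
    }, 0)
  } else seq_len(K)
  nm <- character(K)
  for (d in seq_len(n_domains)) {
    members <- which(dom == d)
    ord <- members[order(lateral[members])]
    nm[ord] <- paste0(LETTERS[d], seq_along(ord))
  }
  parcel_hierarchy(
    levels = list(parcel = seq_len(K), domain = dom),
    merge_tree = hc, names_ = nm
  )
}

#' Similarity-preserving parcel colormap
#'
#' Embeds the parcel similarity matrix in 3-D by classical MDS and maps
#' the embedding into RGB space with an anchored orthogonal alignment:
#' a Procrustes rotation/reflection plus scale and translation is chosen
#' to minimize the squared distance between selected anchor parcels and
#' their prescribed colors, then all coordinates are clipped to the unit
#' cube. Functionally similar parcels end up with similar colors.
#'
#' @param similarity symmetric parcel similarity matrix.
#' @param anchors numeric matrix with one row per anchor (RGB in
#'   `[0, 1]`), rownames giving parcel indices; at least 3 anchors.
#' @return A `K x 3` matrix of RGB values in `[0, 1]`.
#' @export
colormap_from_similarity <- function(similarity, anchors) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 3) stop("need at least 3 anchors for a determined alignment")
  idx <- as.integer(rownames(anchors))
  if (anyNA(idx)) stop("anchor rownames must be parcel indices")
  K <- nrow(similarity)
  D <- 1 - similarity
  diag(D) <- 0
  fit <- stats::cmdscale(stats::as.dist(D), k = min(3, K - 1), eig = TRUE)
  X <- fit$points
  if (ncol(X) < 3) {
    warning("similarity matrix has rank < 3; padding embedding with zeros")
    X <- cbind(X, matrix(0, K, 3 - ncol(X)))
  }
  Xa <- X[idx, , drop = FALSE]
  mx <- colMeans(Xa)
  ma <- colMeans(anchors)
  Xc <- sweep(Xa, 2, mx)
  Ac <- sweep(anchors, 2, ma)
  sv <- svd(t(Xc) %*% Ac)
  R <- sv$u %*% t(sv$v)
  denom <- sum(Xc^2)
  s <- if (denom > 0) sum(sv$d) / denom else 1
  Y <- s * sweep(X, 2, mx) %*% R
  Y <- sweep(Y, 2, ma, "+")
  pmin(pmax(Y, 0), 1)
}

#' Functional lateralization of mirrored voxel pairs
#'
#' For every left/right voxel pair, the cosine similarity of the model's
#' expected functional profiles (posterior-weighted parcel means) per
#' session, averaged over sessions and datasets with weights
#' `kappa_n * N_n`. Values near 1 mean the two hemispheres respond alike
#' at that location; strongly lateralized functions pull the index down.
#'
#' @param model a fitted [fused_model] (its space supplies the pairing).
#' @param datasets optional datasets for subject-count weights.
#' @return A tibble with one row per left-hemisphere voxel: `left_voxel`,
#'   `right_voxel`, `lateralization`.
#' @export
lateralization_index <- function(model, datasets = NULL) {
  space <- model$space
  left <- which(space$hemisphere == "left")
  right <- space$mirror[left]
  p <- group_prob(model$arrangement)
  n_sub <- function(d) {
    if (is.null(datasets)) 1 else n_subjects(as_dataset_list_(datasets)[[d]])
  }
  num <- numeric(length(left))
  wsum <- 0
  for (d in names(model$emissions)) {
    em <- model$emissions[[d]]
    Ns <- n_sub(d)
    for (n in seq_along(em$V)) {
      prof <- t(em$V[[n]]) %*% p   # N x P expected profiles
      a <- prof[, left, drop = FALSE]
      b <- prof[, right, drop = FALSE]
      cs <- colSums(a * b) /
        pmax(sqrt(colSums(a^2)) * sqrt(colSums(b^2)), 1e-12)
      w <- em$kappa[n] * Ns
      num <- num + w * cs
      wsum <- wsum + w
    }
  }
  tibble::tibble(left_voxel = left, right_voxel = right,
                 lateralization = num / wsum)
}

#' Boundary symmetry between symmetric and asymmetric atlases
#'
#' Per-voxel Pearson correlation between the K-length parcel probability
#' vectors of the two atlas versions: 1 where the asymmetric refit left
#' the boundary untouched, lower where boundaries shifted. At the
#' individual level the correlation is computed on each subject's
#' integrated individual maps and averaged.
#'
#' @param sym_model,asym_model fitted [fused_model]s sharing K and space.
#' @param level `"group"` or `"individual"`.
#' @param datasets datasets (required for `level = "individual"`).
#' @return A tibble with `voxel` and `boundary_symmetry` (NA where a
#'   probability vector is constant).
#' @export
boundary_symmetry <- function(sym_model, asym_model,
                              level = c("group", "individual"),
                              datasets = NULL) {
  level <- match.arg(level)
  stopifnot(sym_model$arrangement$K == asym_model$arrangement$K)
  cor_cols <- function(a, b) {
    vapply(seq_len(ncol(a)), function(i) {
      if (stats::sd(a[, i]) == 0 || stats::sd(b[, i]) == 0) return(NA_real_)
      stats::cor(a[, i], b[, i])
    }, 0)
  }
  if (level == "group") {
    v <- cor_cols(group_prob(sym_model$arrangement),
                  group_prob(asym_model$arrangement))
  } else {
    if (is.null(datasets)) stop("individual-level boundary symmetry needs datasets")
    datasets <- as_dataset_list_(datasets)
    acc <- NULL; n <- 0
    for (d in names(datasets)) {
      for (s in seq_len(n_subjects(datasets[[d]]))) {
        y <- datasets[[d]]$data[[s]]
        ps <- individual_map(sym_model, y, dataset_id = d)$posterior
        pa <- individual_map(asym_model, y, dataset_id = d)$posterior
        v1 <- cor_cols(ps, pa)
        acc <- if (is.null(acc)) v1 else acc + v1
        n <- n + 1
      }
    }
    v <- acc / n
  }
  tibble::tibble(voxel = seq_along(v), boundary_symmetry = v)
}

#' Ridge regression of region profiles on condition features
#'
#' Separates feature-driven activation (e.g. movement covariates) from
#' condition-specific activation by regressing each region's mean
#' condition profile on a condition-by-feature design with L2
#' regularization. Columns of both design and profiles can be z-scored
#' across conditions first (the convention for motor-covariate
#' adjustment).
#'
#' @param region_profiles `C x K` matrix of mean responses (conditions by
#'   regions).
#' @param design `C x F` feature matrix.
#' @param l2 ridge penalty (>= 0; 0 requires a full-rank design).
#' @param normalize z-score columns of design and profiles first?
#' @return A tibble with columns `region`, `feature`, `estimate`.
#' @export
profile_regression <- function(region_profiles, design, l2 = 1,
                               normalize = TRUE) {
  X <- as.matrix(design)
  Y <- as.matrix(region_profiles)
  stopifnot(nrow(X) == nrow(Y), l2 >= 0)
  if (normalize) {
    X <- scale(X)
    Y <- scale(Y)
  }
  XtX <- crossprod(X) + diag(l2, ncol(X))
  if (l2 == 0 && rcond_(XtX) < 1e-12) {
    stop("rank-deficient design with l2 = 0")
  }
  B <- solve(XtX, crossprod(X, Y))   # F x K
  feats <- colnames(X)
  if (is.null(feats)) feats <- paste0("f", seq_len(ncol(X)))
  regs <- colnames(Y)
  if (is.null(regs)) regs <- paste0("r", seq_len(ncol(Y)))
  tibble::tibble(
    region = rep(regs, each = length(feats)),
    feature = rep(feats, times = length(regs)),
    estimate = as.vector(B)
  )
}

rcond_ <- function(m) {
  s <- svd(m, nu = 0, nv = 0)$d
  if (max(s) == 0) 0 else min(s) / max(s)
}

#' Left/right region sizes of an asymmetric atlas
#'
#' Winner-take-all voxel counts per hemisphere-paired region; in a
#' symmetric atlas the counts are equal by construction, so differences
#' quantify boundary asymmetry in region-size terms.
#'
#' @param model a fitted [fused_model] with hemisphere-confined parcels.
#' @return A tibble with `pair`, `left_count`, `right_count`.
#' @export
region_size_asymmetry <- function(model) {
  if (!model$arrangement$confined) {
    stop("region pairing requires a hemisphere-confined model")
  }
  prob <- group_prob(model$arrangement)
  lab <- hard_parcellation(prob)
  K <- nrow(prob)
  Kh <- K %/% 2
  counts <- tabulate(lab, nbins = K)
  tibble::tibble(
    pair = seq_len(Kh),
    left_count = counts[seq_len(Kh)],
    right_count = counts[Kh + seq_len(Kh)]
  )
}
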