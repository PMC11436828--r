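#' Cortico-cerebellar connectivity models
#'
#' A linear model `Y = X W` predicting cerebellar voxel activity (`Y`,
#' conditions x voxels) from cortical parcel activity (`X`, conditions x
#' parcels), with ridge-regularized weights `W` (parcels x voxels).
#'
#' @param W `Q x P` weight matrix.
#' @param lambda ridge coefficient used in the fit.
#' @param train_dataset id of the training dataset.
#' @param subject subject id (or `"average"` for fused/averaged models).
#' @return An object of class `connectivity_model`.
#' @export
connectivity_model <- function(W, lambda, train_dataset = NA_character_,
                               subject = NA_character_) {
  stopifnot(all(is.finite(W)))
  structure(
    list(W = W, lambda = lambda, train_dataset = train_dataset,
         subject = subject),
    class = "connectivity_model"
  )
}

#' @export
print.connectivity_model <- function(x, ...) {
  cat(sprintf("<connectivity_model> Q = %d, P = %d, lambda = %g (%s/%s)\n",
              nrow(x$W), ncol(x$W), x$lambda, x$train_dataset, x$subject))
  invisible(x)
}

#' Paired cortical/cerebellar data for connectivity fitting
#'
#' @param dataset_id identifier.
#' @param X list of `N x Q` cortical matrices, one per subject.
#' @param Y list of `N x P` cerebellar matrices, matched per subject.
#' @return An object of class `connectivity_dataset`.
#' @export
connectivity_dataset <- function(dataset_id, X, Y) {
  stopifnot(length(X) == length(Y), length(X) >= 1)
  if (is.null(names(X))) names(X) <- sprintf("sub-%02d", seq_along(X))
  names(Y) <- names(X)
  structure(
    list(dataset_id = dataset_id, subjects = names(X), X = X, Y = Y),
    class = "connectivity_dataset"
  )
}

#' Fit ridge-regression connectivity weights
#'
#' Closed-form solution `W = (X'X + lambda I)^(-1) X' Y`.
#'
#' @param X `N x Q` cortical activity matrix.
#' @param Y `N x P` cerebellar activity matrix.
#' @param lambda ridge penalty, >= 0 (0 requires full-rank `X'X`).
#' @param train_dataset,subject metadata stored on the model.
#' @return A [connectivity_model()].
#' @export
fit_ridge <- function(X, Y, lambda, train_dataset = NA_character_,
                      subject = NA_character_) {
  stopifnot(lambda >= 0, nrow(X) == nrow(Y), nrow(X) >= 1)
  XtX <- crossprod(X) + diag(lambda, ncol(X))
  if (lambda == 0 && rcond_(XtX) < 1e-12) {
    stop("rank-deficient design with lambda = 0")
  }
  W <- solve(XtX, crossprod(X, Y))
  connectivity_model(W, lambda, train_dataset, subject)
}

# cosine similarity of two matrices treated as concatenated vectors
cosine_flat_ <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' Evaluate connectivity models on a dataset
#'
#' Weights are averaged across the training models and applied to each
#' evaluation subject's cortical data; the score is the cosine similarity
#' between predicted and observed cerebellar activity (concatenated over
#' voxels). When evaluating on the training dataset itself
#' (`same_dataset = TRUE`), the evaluation subject's own model is left
#' out of the average (leave-one-subject-out).
#'
#' @param models list of [connectivity_model()]s (one per training
#'   subject), or a single model.
#' @param eval_dataset a [connectivity_dataset()].
#' @param same_dataset were the models trained on `eval_dataset`? If so,
#'   models must be in the dataset's subject order.
#' @return A tibble with `subject` and `score`; degenerate (all-zero)
#'   predictions yield score 0 and are flagged in the `flagged` column.
#' @export
evaluate_connectivity <- function(models, eval_dataset,
                                  same_dataset = FALSE) {
  if (inherits(models, "connectivity_model")) models <- list(models)
  S <- length(eval_dataset$X)
  if (same_dataset) {
    if (length(models) != S) {
      stop("same-dataset evaluation needs one model per subject")
    }
    if (S < 2) stop("single-subject same-dataset evaluation is impossible")
  }
  Ws <- lapply(models, `[[`, "W")
  rows <- lapply(seq_len(S), function(s) {
    W <- if (same_dataset) {
      Reduce(`+`, Ws[-s]) / (length(Ws) - 1)
    } else {
      Reduce(`+`, Ws) / length(Ws)
    }
    pred <- eval_dataset$X[[s]] %*% W
    sc <- cosine_flat_(pred, eval_dataset$Y[[s]])
    tibble::tibble(
      subject = eval_dataset$subjects[s],
      score = if (is.na(sc)) 0 else sc,
      flagged = is.na(sc)
    )
  })
  dplyr::bind_rows(rows)
}

#' Tune the ridge penalty per dataset by cross-dataset prediction
#'
#' For each training dataset and each grid value, fits per-subject models
#' and scores the subject-averaged weights on every other dataset; the
#' selected lambda maximizes the mean cross-dataset score. Ties (plateaus)
#' resolve to the smallest lambda.
#'
#' @param datasets list of [connectivity_dataset()]s (>= 2).
#' @param grid numeric vector of candidate penalties.
#' @return A tibble with `dataset`, `lambda` and the achieved `score`.
#' @export
tune_lambda <- function(datasets, grid) {
  if (length(grid) == 0) stop("empty lambda grid")
  if (length(datasets) < 2) stop("cross-dataset tuning needs >= 2 datasets")
  grid <- sort(grid)
  names(datasets) <- vapply(datasets, `[[`, "", "dataset_id")
  rows <- lapply(names(datasets), function(d) {
    scores <- vapply(grid, function(lam) {
      models <- lapply(seq_along(datasets[[d]]$X), function(s) {
        fit_ridge(datasets[[d]]$X[[s]], datasets[[d]]$Y[[s]], lam, d,
                  datasets[[d]]$subjects[s])
      })
      mean(vapply(setdiff(names(datasets), d), function(e) {
        mean(evaluate_connectivity(models, datasets[[e]])$score)
      }, 0))
    }, 0)
    best <- which.max(scores)   # first max = smallest lambda on a plateau
    tibble::tibble(dataset = d, lambda = grid[best], score = scores[best])
  })
  dplyr::bind_rows(rows)
}

#' Fuse connectivity models by weight averaging
#'
#' Elementwise mean of the weight matrices — the integration step that
#' pools connectivity evidence across datasets. Exclusion of an
#' evaluation subject's own model from any average is the caller's
#' responsibility (see [evaluate_connectivity()] for the within-dataset
#' case).
#'
#' @param models list of [connectivity_model()]s with identical
#'   dimensions.
#' @return A [connectivity_model()] with `subject = "average"`.
#' @export
fuse_connectivity <- function(models) {
  stopifnot(length(models) >= 1)
  dims <- vapply(models, function(m) dim(m$W), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("weight matrices differ in shape")
  }
  W <- Reduce(`+`, lapply(models, `[[`, "W")) / length(models)
  connectivity_model(W, mean(vapply(models, `[[`, 0, "lambda")),
                     train_dataset = "fused", subject = "average")
}

#' Noise-ceiling adjustment of a prediction score
#'
#' Divides a raw prediction score by the ceiling implied by the
#' measurement reliabilities of the observed and predicted data,
#' `sqrt(rel_cereb * rel_pred)`, both estimated as split-half
#' correlations. An adjusted score of 1 means the model predicts as well
#' as the data's reliability allows.
#'
#' @param score raw cosine/correlation score.
#' @param rel_cereb split-half reliability of the cerebellar data, in
#'   (0, 1].
#' @param rel_pred split-half reliability of the prediction (cortical
#'   side), in (0, 1].
#' @return The adjusted score.
#' @export
noise_ceiling_adjust <- function(score, rel_cereb, rel_pred) {
  if (rel_cereb <= 0 || rel_pred <= 0) stop("non-positive reliability")
  score / sqrt(rel_cereb * rel_pred)
}

#' Network-by-region summary of connectivity weights
#'
#' Averages the weight matrix over cortical networks (rows) and
#' cerebellar regions (columns), the standard compression for displaying
#' which networks drive which regions.
#'
#' @param model a [connectivity_model()].
#' @param network_labels network id per cortical parcel (length Q; no
#'   missing values).
#' @param region_labels region id per cerebellar voxel (length P);
#'   defaults to a single region.
#' @return A tibble with `network`, `region`, `mean_weight`.
#' @export
network_summary <- function(model, network_labels, region_labels = NULL) {
  Q <- nrow(model$W); P <- ncol(model$W)
  if (length(network_labels) != Q || anyNA(network_labels)) {
    stop("every cortical parcel needs a network label")
  }
  if (is.null(region_labels)) region_labels <- rep(1L, P)
  stopifnot(length(region_labels) == P)
  nets <- sort(unique(network_labels))
  regs <- sort(unique(region_labels))
  rows <- lapply(nets, function(nw) {
    ri <- which(network_labels == nw)
    tibble::tibble(
      network = nw,
      region = regs,
      mean_weight = vapply(regs, function(rg) {
        mean(model$W[ri, region_labels == rg, drop = FALSE])
      }, 0)
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulate a shared-weights connectivity world
#'
#' Generates several datasets whose subjects all share a common underlying
#' connectivity matrix, each dataset seeing a noisy dataset-specific copy
#' of it. Same-dataset predictions therefore beat cross-dataset ones
#' (diagonal dominance of the score matrix) and weight-averaged fusion
#' recovers the shared structure better than any single dataset.
#'
#' @param n_datasets,n_subjects numbers of datasets and subjects each.
#' @param n_cond conditions per subject.
#' @param Q,P cortical parcel and cerebellar voxel counts.
#' @param dataset_sd sd of the dataset-specific weight perturbation,
#'   relative to the shared weights' scale.
#' @param noise_sd observation noise sd.
#' @param seed optional integer seed (local to this call).
#' @return A list with `datasets` (list of [connectivity_dataset()]s),
#'   `W_true` and `W_datasets`.
#' @export
simulate_connectivity_world <- function(n_datasets = 3, n_subjects = 5,
                                        n_cond = 40, Q = 20, P = 30,
                                        dataset_sd = 0.3, noise_sd = 1,
                                        seed = NULL) {
  with_seed_(seed, {
    W_true <- matrix(rnorm(Q * P), Q, P) / sqrt(Q)
    W_ds <- lapply(seq_len(n_datasets), function(d) {
      W_true + dataset_sd * matrix(rnorm(Q * P), Q, P) / sqrt(Q)
    })
    datasets <- lapply(seq_len(n_datasets), function(d) {
      X <- lapply(seq_len(n_subjects), function(s) matrix(rnorm(n_cond * Q), n_cond, Q))
      Y <- lapply(seq_len(n_subjects), function(s) {
        X[[s]] %*% W_ds[[d]] + noise_sd * matrix(rnorm(n_cond * P), n_cond, P)
      })
      connectivity_dataset(sprintf("conn-%02d", d), X, Y)
    })
    list(datasets = datasets, W_true = W_true, W_datasets = W_ds)
  })
}
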