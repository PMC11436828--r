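#' Fused parcellation models
#'
#' A `fused_model` couples one arrangement model (the group spatial prior)
#' with one vMF emission model per dataset, fitted jointly by EM. Datasets
#' with higher concentrations (more reliable data) automatically carry more
#' weight in the fused group map, because their emission log-likelihoods
#' dominate the individual posteriors that are averaged into the prior.
#'
#' @name fused_model
NULL

new_fused_model <- function(arrangement, emissions, space, fit_info) {
  structure(
    list(arrangement = arrangement, emissions = emissions, space = space,
         fit_info = fit_info),
    class = "fused_model"
  )
}

#' @export
print.fused_model <- function(x, ...) {
  cat(sprintf("<fused_model> K = %d, P = %d, %d dataset(s): %s\n",
              x$arrangement$K, ncol(x$arrangement$eta), length(x$emissions),
              paste(names(x$emissions), collapse = ", ")))
  if (!is.null(x$fit_info$loglik)) {
    cat(sprintf("  final log-lik %.4f after %d iterations (%s)\n",
                utils::tail(x$fit_info$loglik, 1),
                length(x$fit_info$loglik),
                if (isTRUE(x$fit_info$converged)) "converged" else "max iterations"))
  }
  invisible(x)
}

# wrap a single dataset, and name the list by dataset ids
as_dataset_list_ <- function(datasets) {
  if (inherits(datasets, "functional_dataset")) datasets <- list(datasets)
  names(datasets) <- vapply(datasets, `[[`, "", "dataset_id")
  if (anyDuplicated(names(datasets))) stop("dataset ids must be unique")
  datasets
}

# precompute per-subject normalizations for every dataset
normalize_all_ <- function(datasets) {
  lapply(datasets, function(ds) {
    lapply(ds$data, normalize_profiles, sessions = ds$sessions)
  })
}

# column logsumexp
logsumexp_cols <- function(a) {
  m <- apply(a, 2, max)
  m + log(colSums(exp(sweep(a, 2, m))))
}

#' E-step: individual posteriors and marginal log-likelihood
#'
#' For every subject, the posterior probability of parcel k at voxel i is
#' proportional to `exp(emission log-lik + log group prior)`; the marginal
#' log-likelihood accumulates `log sum_k` of the same quantity over voxels
#' and subjects. Voxels with no usable data fall back to the group prior
#' and contribute zero to the log-likelihood.
#'
#' @param model a [fused_model].
#' @param datasets list of [functional_dataset()]s matching the model's
#'   emissions (by `dataset_id`).
#' @param norms optional precomputed [normalize_profiles()] results (as
#'   produced internally; exposed for reuse in loops).
#' @return List with `posteriors` (per dataset, per subject `K x P`
#'   matrices), `loglik` (scalar) and `loglik_by_dataset`.
#' @export
e_step <- function(model, datasets, norms = NULL) {
  datasets <- as_dataset_list_(datasets)
  if (is.null(norms)) norms <- normalize_all_(datasets)
  lp <- log(group_prob(model$arrangement))
  posteriors <- list()
  ll_ds <- numeric(length(datasets))
  names(ll_ds) <- names(datasets)
  for (d in names(datasets)) {
    em <- model$emissions[[d]]
    if (is.null(em)) stop(sprintf("no emission model for dataset '%s'", d))
    posteriors[[d]] <- lapply(norms[[d]], function(nr) {
      A <- emission_logprob(em, nr) + lp
      ll_s <- sum(logsumexp_cols(A))
      if (!is.finite(ll_s)) {
        stop(sprintf("non-finite likelihood in dataset '%s'", d))
      }
      ll_ds[d] <<- ll_ds[d] + ll_s
      softmax_cols(A)
    })
  }
  list(posteriors = posteriors, loglik = sum(ll_ds), loglik_by_dataset = ll_ds)
}

# average posterior over all subjects of all datasets
mean_posterior_ <- function(posteriors) {
  all_u <- unlist(posteriors, recursive = FALSE)
  Reduce(`+`, all_u) / length(all_u)
}

# one multi-start initialization: either a randomized k-means partition of
# the concatenated voxel profiles (hemisphere-aware under symmetry) or
# fully random parameters; falls back to random if k-means degenerates
start_init_ <- function(init, K, space, symmetric, datasets, norms,
                        profiles, kappa0) {
  arr <- arrangement_init(K, space, symmetric)
  if (init == "kmeans") {
    labs <- tryCatch({
      if (symmetric) {
        Kh <- K %/% 2
        left <- which(space$hemisphere == "left")
        km <- stats::kmeans(profiles[left, , drop = FALSE], Kh, nstart = 1)
        out <- integer(n_voxels(space))
        out[left] <- km$cluster
        out[space$mirror[left]] <- km$cluster + Kh
        mid <- which(space$hemisphere == "midline")
        if (length(mid) > 0) {
          d2 <- apply(km$centers, 1, function(cc) {
            rowSums(sweep(profiles[mid, , drop = FALSE], 2, cc)^2)
          })
          out[mid] <- max.col(-matrix(d2, nrow = length(mid)))
        }
        out
      } else {
        stats::kmeans(profiles, K, nstart = 1)$cluster
      }
    }, error = function(e) NULL)
    if (!is.null(labs) && all(labs >= 1)) {
      resp <- matrix(1e-3, K, length(labs))
      resp[cbind(labs, seq_along(labs))] <- 1
      resp <- sweep(resp, 2, colSums(resp), "/")
      arr <- arrangement_m_step(resp, arr)
      emissions <- lapply(datasets, function(ds) {
        em0 <- vmf_emission_init(ds$dataset_id, K, ds$sessions, kappa0)
        d <- ds$dataset_id
        emission_m_step(em0, norms[[d]],
                        rep(list(resp), length(ds$data)))
      })
      return(list(arr = arr, emissions = emissions))
    }
  }
  list(arr = arr, emissions = lapply(datasets, function(ds) {
    vmf_emission_init(ds$dataset_id, K, ds$sessions, kappa0)
  }))
}

# one full EM run from a given initialization
em_run_ <- function(datasets, norms, arr, emissions, max_iter, tol,
                    update_emissions = TRUE) {
  trace <- numeric(0)
  converged <- FALSE
  model <- new_fused_model(arr, emissions, NULL, list())
  for (it in seq_len(max_iter)) {
    e <- e_step(model, datasets, norms)
    trace <- c(trace, e$loglik)
    if (it > 1) {
      rel <- abs(e$loglik - trace[it - 1]) / max(1, abs(trace[it - 1]))
      if (rel < tol) { converged <- TRUE; break }
    }
    model$arrangement <- arrangement_m_step(mean_posterior_(e$posteriors),
                                            model$arrangement)
    if (update_emissions) {
      for (d in names(datasets)) {
        model$emissions[[d]] <- emission_m_step(model$emissions[[d]],
                                                norms[[d]],
                                                e$posteriors[[d]])
      }
    }
  }
  list(arrangement = model$arrangement, emissions = model$emissions,
       loglik = trace, converged = converged)
}

#' Fit a fused parcellation model by multi-start EM
#'
#' Runs EM from `n_starts` random initializations (noise potentials around
#' the uniform prior; mean directions uniform on the sphere) and keeps the
#' start with the highest final marginal log-likelihood. Convergence is
#' declared when the relative log-likelihood change drops below `tol`.
#' The production-scale analyses this model family is used for employ on
#' the order of thousands of random starts; the default here is sized for
#' interactive use and simulation studies.
#'
#' @param datasets one [functional_dataset()] or a list of them.
#' @param space the [voxel_space()] shared by all datasets.
#' @param K number of parcels (even if `symmetric`).
#' @param symmetric fit the mirror-symmetric arrangement variant?
#' @param n_starts number of random initializations.
#' @param max_iter maximum EM iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed optional integer seed (local to this call).
#' @param kappa0 initial session concentration.
#' @param init `"kmeans"` seeds each start from a randomized k-means
#'   partition of the voxel profiles (concatenated over subjects and
#'   datasets), which reaches the high-likelihood basin far more reliably
#'   than fully random parameters; `"random"` draws noise potentials and
#'   uniform mean directions, the classical scheme that needs orders of
#'   magnitude more starts.
#' @return A [fused_model] with `fit_info` carrying the log-likelihood
#'   trace of the winning start, all starts' final log-likelihoods, seed,
#'   and convergence status.
#' @export
fit_fusion <- function(datasets, space, K, symmetric = FALSE, n_starts = 20,
                       max_iter = 200, tol = 1e-6, seed = NULL, kappa0 = 5,
                       init = c("kmeans", "random")) {
  datasets <- as_dataset_list_(datasets)
  init <- match.arg(init)
  stopifnot(n_starts >= 1)
  norms <- normalize_all_(datasets)
  profiles <- if (init == "kmeans") {
    do.call(cbind, unlist(lapply(norms, function(nd) {
      lapply(nd, function(nr) nr$dirs)
    }), recursive = FALSE))
  }
  with_seed_(seed, {
    best <- NULL
    start_ll <- numeric(n_starts)
    for (st in seq_len(n_starts)) {
      ini <- start_init_(init, K, space, symmetric, datasets, norms,
                         profiles, kappa0)
      run <- em_run_(datasets, norms, ini$arr, ini$emissions, max_iter, tol)
      start_ll[st] <- utils::tail(run$loglik, 1)
      if (is.null(best) || start_ll[st] > utils::tail(best$loglik, 1)) {
        best <- run
      }
    }
    improved <- utils::tail(best$loglik, 1) > best$loglik[1]
    new_fused_model(
      best$arrangement, best$emissions, space,
      list(loglik = best$loglik, start_logliks = start_ll, seed = seed,
           K = K, symmetric = symmetric, converged = best$converged,
           improved = improved)
    )
  })
}

#' Remove the symmetry constraint from a fitted model
#'
#' Builds the asymmetric companion of a symmetric atlas: the fitted
#' emission models (functional profiles) are frozen, and only the
#' arrangement model is refit by EM without the mirror tie. Each parcel
#' remains confined to its designated hemisphere, so left/right parcel
#' pairs keep their correspondence while boundaries are free to differ.
#' Relaxing a constraint with the same EM objective can only raise the
#' marginal log-likelihood.
#'
#' @param model a fitted symmetric [fused_model].
#' @param datasets the datasets the model was fit to.
#' @param max_iter,tol EM controls for the arrangement-only refit.
#' @return An asymmetric [fused_model] sharing the input's emissions.
#' @export
desymmetrize <- function(model, datasets, max_iter = 100, tol = 1e-8) {
  if (!model$arrangement$symmetric) stop("model is already asymmetric")
  datasets <- as_dataset_list_(datasets)
  norms <- normalize_all_(datasets)
  arr0 <- arrangement(model$arrangement$eta, model$space,
                      symmetric = FALSE, confined = TRUE)
  run <- em_run_(datasets, norms, arr0, model$emissions, max_iter, tol,
                 update_emissions = FALSE)
  new_fused_model(
    run$arrangement, model$emissions, model$space,
    list(loglik = run$loglik, converged = run$converged,
         K = model$arrangement$K, symmetric = FALSE,
         parent = "desymmetrized")
  )
}

#' Refit a coarse model at a finer resolution
#'
#' Transfers the fitted potentials to a finer voxel space through a
#' voxel-correspondence map (each fine voxel names its coarse source) and
#' continues EM on the fine-resolution data from that single start — the
#' coarse-to-fine strategy that makes high-resolution fits affordable.
#'
#' @param model a fitted [fused_model] on the coarse space.
#' @param fine_space the fine [voxel_space()].
#' @param datasets_fine datasets sampled on the fine space.
#' @param correspondence integer vector, length `P_fine`, of coarse voxel
#'   indices.
#' @param max_iter,tol EM controls.
#' @return A [fused_model] on the fine space.
#' @export
refit_at_resolution <- function(model, fine_space, datasets_fine,
                                correspondence, max_iter = 200, tol = 1e-6) {
  P_fine <- n_voxels(fine_space)
  if (length(correspondence) != P_fine || anyNA(correspondence)) {
    stop("need a complete coarse-voxel correspondence for every fine voxel")
  }
  datasets_fine <- as_dataset_list_(datasets_fine)
  norms <- normalize_all_(datasets_fine)
  arr_c <- model$arrangement
  eta_fine <- arr_c$eta[, correspondence, drop = FALSE]
  arr <- arrangement(eta_fine, fine_space, symmetric = arr_c$symmetric,
                     confined = arr_c$confined)
  run <- em_run_(datasets_fine, norms, arr, model$emissions, max_iter, tol)
  new_fused_model(
    run$arrangement, run$emissions, fine_space,
    list(loglik = run$loglik, converged = run$converged,
         K = arr_c$K, symmetric = arr_c$symmetric, parent = "refined")
  )
}

#' Winner-take-all labels from a probability map
#'
#' Ties break to the lowest parcel index, deterministically.
#'
#' @param prob `K x P` probability matrix.
#' @return Integer vector of length P.
#' @export
hard_parcellation <- function(prob) {
  max.col(t(prob), ties.method = "first")
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Parcel-level summary of a fused model
#'
#' @param x a [fused_model].
#' @param ... unused.
#' @return A tibble with one row per parcel: winner-take-all voxel count,
#'   total probability mass, and dominant hemisphere.
#' @export
tidy.fused_model <- function(x, ...) {
  prob <- group_prob(x$arrangement)
  lab <- hard_parcellation(prob)
  K <- nrow(prob)
  hemi <- x$space$hemisphere
  tibble::tibble(
    parcel = seq_len(K),
    n_voxels = vapply(seq_len(K), function(k) sum(lab == k), 0L),
    prob_mass = rowSums(prob),
    hemisphere = vapply(seq_len(K), function(k) {
      w <- lab == k
      if (!any(w)) return(NA_character_)
      names(sort(table(hemi[w]), decreasing = TRUE))[1]
    }, "")
  )
}

#' One-row fit summary of a fused model
#'
#' @param x a [fused_model].
#' @param ... unused.
#' @return A tibble with K, dataset count, final log-likelihood, iteration
#'   count, convergence flag and symmetry flag.
#' @export
glance.fused_model <- function(x, ...) {
  tibble::tibble(
    K = x$arrangement$K,
    n_datasets = length(x$emissions),
    logLik = utils::tail(x$fit_info$loglik, 1),
    n_iter = length(x$fit_info$loglik),
    converged = isTRUE(x$fit_info$converged),
    symmetric = isTRUE(x$arrangement$symmetric)
  )
}
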