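#' Configuration for the end-to-end pipeline
#'
#' Collects every knob of [run_pipeline()] with validated defaults sized
#' for simulation studies. All randomness flows from `seed` (stage seeds
#' are derived from it by fixed offsets); there is no wall-clock seeding,
#' so a config plus seed fully determines every output.
#'
#' @param out_dir output directory for the run.
#' @param seed master integer seed.
#' @param width,height grid size of the synthetic world.
#' @param K_true number of ground-truth parcels (even).
#' @param smoothness ground-truth boundary sharpness.
#' @param dataset_specs list of per-dataset specs, each a list with
#'   `n_subjects`, `sessions` (condition counts) and `kappa`.
#' @param K_ladder granularities to fit. The production ladder for the
#'   cerebellar atlas is 10/20/34/40/68; the default here is smaller.
#' @param K_atlas granularity used for the exported atlas, the asymmetric
#'   companion, and the hierarchy.
#' @param symmetric fit mirror-symmetric atlases?
#' @param n_starts,max_iter,tol EM controls (production fits of this model
#'   family use thousands of starts; scale up off-line).
#' @param n_domains domains for the hierarchy stage.
#' @param bin_width,max_dist DCBC binning.
#' @param connectivity logical: run the connectivity stage?
#' @return A validated `run_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            width = 12, height = 12, K_true = 6,
                            smoothness = 3,
                            dataset_specs = list(
                              list(n_subjects = 4, sessions = c(8, 8),
                                   kappa = c(20, 20)),
                              list(n_subjects = 4, sessions = c(8, 8),
                                   kappa = c(20, 20))
                            ),
                            K_ladder = c(4, 6), K_atlas = K_true,
                            symmetric = TRUE, n_starts = 5, max_iter = 100,
                            tol = 1e-6, n_domains = 2, bin_width = 1,
                            max_dist = 35, connectivity = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1, width %% 2 == 0,
            K_true %% 2 == 0, length(dataset_specs) >= 1, n_starts >= 1)
  if (!K_atlas %in% K_ladder) K_ladder <- sort(unique(c(K_ladder, K_atlas)))
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), width = width,
         height = height, K_true = K_true, smoothness = smoothness,
         dataset_specs = dataset_specs, K_ladder = K_ladder,
         K_atlas = K_atlas, symmetric = symmetric, n_starts = n_starts,
         max_iter = max_iter, tol = tol, n_domains = n_domains,
         bin_width = bin_width, max_dist = max_dist,
         connectivity = connectivity),
    class = "run_config"
  )
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Orchestrates the whole workflow end to end: simulate a symmetric
#' ground-truth world and sample its datasets; fit the fused model at
#' every granularity of the ladder; derive the asymmetric companion of
#' the atlas granularity; build the parcel hierarchy, domains and
#' colormap; evaluate recovery (ARI against the generating labels) and
#' boundary quality (group and individual DCBC); and, optionally, run the
#' connectivity stage on a matched synthetic connectivity world. Each
#' stage's outputs are written under `out_dir` as they complete; a
#' failure marks the stage in the manifest but retains earlier outputs.
#'
#' @param config a [pipeline_config()].
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("parcelfuse")),
    seed = config$seed,
    config = unclass(config),
    stages = list()
  )
  done <- function(name, summary = NULL) {
    manifest$stages[[name]] <<- list(status = "ok", summary = summary)
  }
  failed <- function(name, e) {
    manifest$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(e))
  }
  state <- new.env()

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) failed(name, e))
  }

  run_stage("simulate", function() {
    space <- make_symmetric_grid(config$width, config$height)
    gp <- sample_group_arrangement(space, config$K_true, config$smoothness,
                                   symmetric = TRUE, seed = config$seed)
    datasets <- lapply(seq_along(config$dataset_specs), function(d) {
      sp <- config$dataset_specs[[d]]
      truth <- ground_truth(gp, sp$sessions, sp$kappa,
                            seed = config$seed + 100L + d)
      sample_dataset(truth, space, sp$n_subjects, seed = config$seed + 200L + d,
                     dataset_id = sprintf("ds-%02d", d))
    })
    write_voxel_space(space, file.path(out, "world"))
    for (ds in datasets) {
      write_dataset(ds, file.path(out, "world", ds$dataset_id))
    }
    state$space <- space; state$gp <- gp; state$datasets <- datasets
    done("simulate", list(P = n_voxels(space), K_true = config$K_true,
                          n_datasets = length(datasets)))
  })

  run_stage("fit", function() {
    models <- list()
    fit_rows <- list()
    for (K in config$K_ladder) {
      m <- fit_fusion(state$datasets, state$space, K,
                      symmetric = config$symmetric,
                      n_starts = config$n_starts, max_iter = config$max_iter,
                      tol = config$tol, seed = config$seed + 300L + K)
      models[[as.character(K)]] <- m
      fit_rows[[as.character(K)]] <- glance(m)
    }
    state$models <- models
    fits <- dplyr::bind_rows(fit_rows)
    utils::write.table(as.data.frame(fits), file.path(out, "fit_ladder.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    done("fit", list(K_ladder = config$K_ladder,
                     logLik = fits$logLik, converged = fits$converged))
  })

  run_stage("desymmetrize", function() {
    msym <- state$models[[as.character(config$K_atlas)]]
    masym <- desymmetrize(msym, state$datasets)
    state$asym <- masym
    ll_sym <- utils::tail(msym$fit_info$loglik, 1)
    ll_asym <- utils::tail(masym$fit_info$loglik, 1)
    bs <- boundary_symmetry(msym, masym)
    done("desymmetrize", list(loglik_symmetric = ll_sym,
                              loglik_asymmetric = ll_asym,
                              mean_boundary_symmetry =
                                mean(bs$boundary_symmetry, na.rm = TRUE)))
  })

  run_stage("hierarchy", function() {
    msym <- state$models[[as.character(config$K_atlas)]]
    merged <- merge_until_winners(msym, state$datasets)
    sim <- parcel_similarity(merged$model, state$datasets)
    nd <- min(config$n_domains, nrow(sim))
    hier <- build_domains(sim, nd, merged$model)
    cols_half <- if (nrow(sim) >= 3) {
      anchors <- diag(3)
      rownames(anchors) <- seq_len(3)
      suppressWarnings(colormap_from_similarity(sim, anchors))
    } else {
      t(grDevices::col2rgb(grDevices::hcl.colors(nrow(sim), "Spectral")) / 255)
    }
    Kh <- nrow(cols_half)
    full <- merged$model$arrangement$K
    hier$colors <- if (full == 2 * Kh) rbind(cols_half, cols_half) else cols_half
    hier$names <- if (full == 2 * Kh) {
      c(paste0(hier$names, "L"), paste0(hier$names, "R"))
    } else hier$names
    export_atlas(merged$model, file.path(out, "atlas"), hierarchy = hier)
    state$merged <- merged
    done("hierarchy", list(K_merged = merged$model$arrangement$K,
                           n_merges = nrow(merged$steps),
                           domains = unname(hier$levels$domain)))
  })

  run_stage("evaluate", function() {
    space <- state$space
    binning <- distance_binning(space, config$bin_width, config$max_dist)
    truth_lab <- hard_parcellation(state$gp)
    rec <- lapply(names(state$models), function(k) {
      lab <- hard_parcellation(group_prob(state$models[[k]]$arrangement))
      tibble::tibble(K = as.integer(k),
                     recovery_ari = adjusted_rand_index(lab, truth_lab))
    })
    rec <- dplyr::bind_rows(rec)
    dc <- dcbc_individual(state$models[[as.character(config$K_atlas)]],
                          state$datasets[[1]], space, binning,
                          seed = config$seed + 400L)
    utils::write.table(as.data.frame(rec), file.path(out, "recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(dc), file.path(out, "dcbc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    done("evaluate", list(recovery_ari = rec$recovery_ari,
                          mean_group_dcbc = mean(dc$group_dcbc),
                          mean_individual_dcbc = mean(dc$individual_dcbc)))
  })

  if (config$connectivity) {
    run_stage("connectivity", function() {
      world <- simulate_connectivity_world(seed = config$seed + 500L)
      grid <- 10^seq(-1, 3)
      tuned <- tune_lambda(world$datasets, grid)
      nd <- length(world$datasets)
      score <- matrix(0, nd, nd)
      models <- lapply(seq_len(nd), function(d) {
        lam <- tuned$lambda[d]
        lapply(seq_along(world$datasets[[d]]$X), function(s) {
          fit_ridge(world$datasets[[d]]$X[[s]], world$datasets[[d]]$Y[[s]],
                    lam, world$datasets[[d]]$dataset_id, s)
        })
      })
      for (d in seq_len(nd)) {
        for (e in seq_len(nd)) {
          score[d, e] <- mean(evaluate_connectivity(
            models[[d]], world$datasets[[e]], same_dataset = d == e)$score)
        }
      }
      utils::write.table(score, file.path(out, "connectivity_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      done("connectivity", list(lambda = tuned$lambda,
                                score_matrix = score))
    })
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
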