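#' Individual parcellations
#'
#' A probabilistic parcellation for one subject (or the group), with its
#' provenance: `group` (arrangement prior only), `data_only` (emission
#' likelihood only) or `integrated` (Bayes combination of both).
#'
#' @param posterior `K x P` probability matrix (columns sum to 1).
#' @param source one of `"group"`, `"data_only"`, `"integrated"`.
#' @param minutes_of_data amount of individual data behind the map
#'   (bookkeeping for data-amount curves; `NA` for group maps).
#' @return An object of class `individual_parcellation`; winner-take-all
#'   labels (lowest index wins ties) are stored in `$hard_labels`.
#' @export
individual_parcellation <- function(posterior,
                                    source = c("group", "data_only",
                                               "integrated"),
                                    minutes_of_data = NA_real_) {
  source <- match.arg(source)
  structure(
    list(posterior = posterior, hard_labels = hard_parcellation(posterior),
         source = source, minutes_of_data = minutes_of_data),
    class = "individual_parcellation"
  )
}

#' @export
print.individual_parcellation <- function(x, ...) {
  cat(sprintf("<individual_parcellation> source = %s, K = %d, P = %d\n",
              x$source, nrow(x$posterior), ncol(x$posterior)))
  invisible(x)
}

#' Group parcellation of a fitted model
#'
#' The group map is the arrangement prior itself — what you use when no
#' individual data are available.
#'
#' @param model a [fused_model].
#' @return An [individual_parcellation()] with `source = "group"`.
#' @export
group_map <- function(model) {
  individual_parcellation(group_prob(model$arrangement), "group")
}

#' Individual parcellation from subject data
#'
#' `data_only` uses the emission likelihood alone (the classical
#' localizer-only approach); `integrated` multiplies likelihood and group
#' prior voxel-wise and renormalizes — the Bayes-optimal combination of
#' the individual's data with the group atlas. With uninformative data
#' (kappa near 0) the integrated map falls back to the group map; with a
#' flat prior it equals the data-only map.
#'
#' @param model a [fused_model].
#' @param subject_data `P x N` matrix for the subject.
#' @param dataset_id which emission model to use (defaults to the first).
#' @param mode `"integrated"` or `"data_only"`.
#' @param emission optionally, a [vmf_emission()] to use instead of one of
#'   the model's own (e.g. a freshly trained localizer emission).
#' @param minutes_of_data bookkeeping, see [individual_parcellation()].
#' @return An [individual_parcellation()].
#' @export
individual_map <- function(model, subject_data,
                           dataset_id = names(model$emissions)[1],
                           mode = c("integrated", "data_only"),
                           emission = NULL,
                           minutes_of_data = NA_real_) {
  mode <- match.arg(mode)
  em <- if (!is.null(emission)) emission else model$emissions[[dataset_id]]
  if (is.null(em)) stop(sprintf("no emission model '%s'", dataset_id))
  L <- emission_logprob(em, subject_data)
  A <- if (mode == "integrated") L + log(group_prob(model$arrangement)) else L
  individual_parcellation(softmax_cols(A), mode, minutes_of_data)
}

#' Train an emission model for a new localizer task set
#'
#' Fits a dataset-specific vMF emission model to a new dataset (all its
#' subjects) while keeping the fitted arrangement model frozen — the step
#' that adapts the atlas to a localizer whose tasks were not part of
#' training. The returned emission can then personalize the atlas for new
#' subjects via [individual_map()].
#'
#' @param model a fitted [fused_model] (not modified).
#' @param new_dataset a [functional_dataset()].
#' @param max_iter,tol EM controls.
#' @param kappa0 initial concentration.
#' @param seed optional seed for the emission initialization.
#' @return A fitted [vmf_emission()].
#' @export
train_localizer_emission <- function(model, new_dataset, max_iter = 100,
                                     tol = 1e-8, kappa0 = 5, seed = NULL) {
  norms <- lapply(new_dataset$data, normalize_profiles,
                  sessions = new_dataset$sessions)
  lp <- log(group_prob(model$arrangement))
  with_seed_(seed, {
    em <- vmf_emission_init(new_dataset$dataset_id, model$arrangement$K,
                            new_dataset$sessions, kappa0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      ll <- 0
      posts <- lapply(norms, function(nr) {
        A <- emission_logprob(em, nr) + lp
        ll <<- ll + sum(logsumexp_cols(A))
        softmax_cols(A)
      })
      em <- emission_m_step(em, norms, posts)
      if (abs(ll - ll_prev) < tol * max(1, abs(ll_prev))) break
      ll_prev <- ll
    }
    em
  })
}

#' Performance of individual maps as a function of data amount
#'
#' Reproduces the precision-mapping experiment: with increasing amounts of
#' localizer data (counted in runs/sessions), derive each subject's
#' group-only, data-only and integrated parcellation from the first data
#' half and score all three on the held-out second half, by DCBC and by
#' weighted cosine prediction error. The qualitative signature is that
#' data-only maps need substantial data to catch the group map, while the
#' integrated map is at least as good as both throughout.
#'
#' @param model a fitted [fused_model].
#' @param dataset a [functional_dataset()] with enough sessions; the first
#'   half of the sessions is the localizer pool, the second half the
#'   evaluation set.
#' @param amounts integer vector of run counts to evaluate (each must be
#'   at most the localizer pool size).
#' @param space the [voxel_space()].
#' @param binning a [distance_binning()] for `space`.
#' @param run_minutes minutes per run, for the `minutes` column.
#' @param seed optional seed (localizer emission initializations).
#' @return A tibble with columns `amount`, `minutes`, `source`, `subject`,
#'   `dcbc`, `pred_error`.
#' @export
data_amount_curve <- function(model, dataset, amounts, space,
                              binning = distance_binning(space),
                              run_minutes = 10, seed = NULL) {
  halves <- split_halves(dataset)
  pool <- halves$first
  evalset <- halves$second
  S <- n_subjects(dataset)
  if (max(amounts) > length(pool$sessions)) {
    stop("not enough localizer runs for the requested amounts")
  }
  grp <- group_map(model)
  rows <- list()
  with_seed_(seed, {
    for (a in amounts) {
      loc <- subset_sessions(pool, seq_len(a))
      em_loc <- train_localizer_emission(model, loc)
      for (s in seq_len(S)) {
        maps <- list(
          group = grp,
          data_only = individual_map(model, loc$data[[s]], emission = em_loc,
                                     mode = "data_only",
                                     minutes_of_data = a * run_minutes),
          integrated = individual_map(model, loc$data[[s]], emission = em_loc,
                                      mode = "integrated",
                                      minutes_of_data = a * run_minutes)
        )
        for (src in names(maps)) {
          lab <- maps[[src]]$hard_labels
          d <- tryCatch(dcbc(lab, evalset$data[[s]], space, binning),
                        error = function(e) NA_real_)
          pe <- prediction_error(lab, evalset$data[-s], evalset$data[[s]])
          rows[[length(rows) + 1]] <- tibble::tibble(
            amount = a, minutes = a * run_minutes, source = src,
            subject = dataset$subjects[s], dcbc = d,
            pred_error = as.numeric(pe)
          )
        }
      }
    }
  })
  dplyr::bind_rows(rows)
}

#' Cross-validated DCBC of group vs individual parcellations
#'
#' The localizer-style evaluation: one half of a held-out dataset serves
#' as localizer (a new emission model is trained on it across subjects,
#' arrangement frozen), each subject's integrated individual map is
#' derived from their own localizer half, and the resulting boundaries are
#' scored by DCBC on the subject's other half. Roles of the halves are
#' then reversed and the two folds averaged. The group map is scored on
#' the same halves so the comparison is like for like.
#'
#' @param model a fitted [fused_model]; for honest evaluation, fit without
#'   the test dataset (leave-one-dataset-out is orchestrated by the
#'   caller).
#' @param test_dataset a [functional_dataset()].
#' @param space the [voxel_space()].
#' @param binning a [distance_binning()].
#' @param seed optional seed (localizer emission initializations).
#' @return A tibble with one row per subject and fold-averaged columns
#'   `group_dcbc`, `individual_dcbc`.
#' @export
dcbc_individual <- function(model, test_dataset, space,
                            binning = distance_binning(space), seed = NULL) {
  halves <- split_halves(test_dataset)
  grp_lab <- group_map(model)$hard_labels
  S <- n_subjects(test_dataset)
  acc <- matrix(0, S, 2, dimnames = list(NULL, c("group", "individual")))
  with_seed_(seed, {
    for (fold in 1:2) {
      loc <- if (fold == 1) halves$first else halves$second
      ev <- if (fold == 1) halves$second else halves$first
      em_loc <- train_localizer_emission(model, loc)
      for (s in seq_len(S)) {
        ind <- individual_map(model, loc$data[[s]], emission = em_loc,
                              mode = "integrated")
        acc[s, "group"] <- acc[s, "group"] +
          dcbc(grp_lab, ev$data[[s]], space, binning) / 2
        acc[s, "individual"] <- acc[s, "individual"] +
          dcbc(ind$hard_labels, ev$data[[s]], space, binning) / 2
      }
    }
  })
  tibble::tibble(
    subject = test_dataset$subjects,
    group_dcbc = acc[, "group"],
    individual_dcbc = acc[, "individual"]
  )
}
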