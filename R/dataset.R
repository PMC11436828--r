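#' Functional datasets
#'
#' A `functional_dataset` holds one P x N matrix of normalized activation
#' estimates per subject, plus the partition of the N conditions into
#' sessions. All subjects of a dataset share the voxel count and session
#' structure; missing entries are `NA` and are carried through (degenerate
#' voxels are excluded from likelihood sums, not imputed).
#'
#' @param dataset_id identifier string.
#' @param data named list of `P x N` matrices, one per subject.
#' @param sessions integer vector of condition counts, one per session;
#'   must sum to N.
#' @param true_labels optional `P x S` matrix of generating parcel labels
#'   (synthetic data only; used for scoring).
#' @return An object of class `functional_dataset`.
#' @export
functional_dataset <- function(dataset_id, data, sessions,
                               true_labels = NULL) {
  stopifnot(is.list(data), length(data) >= 1)
  if (is.null(names(data))) names(data) <- sprintf("sub-%02d", seq_along(data))
  dims <- vapply(data, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- names(data)[which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]]
    stop(sprintf("subject '%s' has a different matrix shape", bad))
  }
  sessions <- as.integer(sessions)
  if (sum(sessions) != dims[2, 1]) {
    stop("session partition must cover all conditions exactly once")
  }
  structure(
    list(dataset_id = dataset_id, subjects = names(data), data = data,
         sessions = sessions, true_labels = true_labels),
    class = "functional_dataset"
  )
}

#' @export
print.functional_dataset <- function(x, ...) {
  cat(sprintf("<functional_dataset> '%s': %d subjects, %d voxels, %d conditions in %d sessions\n",
              x$dataset_id, length(x$subjects), nrow(x$data[[1]]),
              ncol(x$data[[1]]), length(x$sessions)))
  invisible(x)
}

#' Number of subjects in a dataset
#' @param dataset a [functional_dataset()].
#' @return Integer subject count.
#' @export
n_subjects <- function(dataset) length(dataset$data)

# list of condition-column indices, one element per session
session_cols <- function(sessions) {
  ends <- cumsum(sessions)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  Map(seq.int, starts, ends)
}

#' Restrict a dataset to a subset of sessions
#'
#' Used by half-splitting (localizer vs evaluation halves) and by
#' data-amount analyses that feed increasing numbers of runs into the
#' individual estimation.
#'
#' @param dataset a [functional_dataset()].
#' @param which_sessions integer indices of sessions to keep.
#' @return A [functional_dataset()] with the selected sessions only.
#' @export
subset_sessions <- function(dataset, which_sessions) {
  cols <- session_cols(dataset$sessions)
  keep <- unlist(cols[which_sessions])
  data <- lapply(dataset$data, function(m) m[, keep, drop = FALSE])
  functional_dataset(dataset$dataset_id, data,
                     dataset$sessions[which_sessions],
                     true_labels = dataset$true_labels)
}

#' Split a dataset's sessions into two halves
#'
#' Odd session counts are handled by a floor split (the first half gets the
#' smaller share).
#'
#' @param dataset a [functional_dataset()].
#' @return A list with elements `first` and `second`, both
#'   [functional_dataset()]s.
#' @export
split_halves <- function(dataset) {
  S <- length(dataset$sessions)
  if (S < 2) stop("need at least two sessions to split in half")
  h <- S %/% 2
  list(first = subset_sessions(dataset, seq_len(h)),
       second = subset_sessions(dataset, (h + 1):S))
}

#' Dataset as a tidy tibble
#'
#' One row per voxel x condition x subject, mainly for plotting and
#' interoperation with dplyr-based summaries.
#'
#' @param x a [functional_dataset()].
#' @param ... unused.
#' @return A tibble with columns `dataset`, `subject`, `voxel`, `session`,
#'   `condition`, `value`.
#' @export
as_tibble.functional_dataset <- function(x, ...) {
  sess <- rep(seq_along(x$sessions), x$sessions)
  purrr::imap_dfr(x$data, function(m, sub) {
    tibble::tibble(
      dataset = x$dataset_id,
      subject = sub,
      voxel = rep(seq_len(nrow(m)), times = ncol(m)),
      session = rep(sess, each = nrow(m)),
      condition = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m)
    )
  })
}
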