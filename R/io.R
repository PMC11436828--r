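# Matrices are serialized as plain TSV with %.17g formatting, which
# round-trips IEEE doubles exactly.
write_matrix_tsv <- function(m, path) {
  ch <- matrix(sprintf("%.17g", m), nrow(m))
  ch[is.na(m)] <- "NA"
  utils::write.table(ch, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write a voxel space to a directory
#'
#' Coordinates, hemisphere labels and mirror pairing go into one TSV.
#'
#' @param space a [voxel_space()].
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_voxel_space <- function(space, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(space$coords)
  names(df) <- paste0("coord", seq_len(ncol(df)))
  df$hemisphere <- space$hemisphere
  df$mirror <- space$mirror
  utils::write.table(df, file.path(path, "voxel_space.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(spacing = space$spacing),
                       file.path(path, "voxel_space.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel space written by [write_voxel_space()]
#' @param path directory.
#' @return A [voxel_space()].
#' @export
read_voxel_space <- function(path) {
  df <- utils::read.table(file.path(path, "voxel_space.tsv"), sep = "\t",
                          header = TRUE)
  meta <- jsonlite::read_json(file.path(path, "voxel_space.json"))
  cc <- grepl("^coord", names(df))
  voxel_space(as.matrix(df[, cc, drop = FALSE]), df$hemisphere, df$mirror,
              spacing = meta$spacing)
}

#' Write a functional dataset to a directory
#'
#' One TSV per subject plus a JSON sidecar with the session partition;
#' numeric values round-trip exactly.
#'
#' @param dataset a [functional_dataset()].
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(dataset_id = dataset$dataset_id, subjects = dataset$subjects,
         sessions = dataset$sessions,
         has_true_labels = !is.null(dataset$true_labels)),
    file.path(path, "dataset.json"), auto_unbox = TRUE, digits = NA
  )
  for (s in seq_along(dataset$data)) {
    write_matrix_tsv(dataset$data[[s]],
                     file.path(path, paste0(dataset$subjects[s], ".tsv")))
  }
  if (!is.null(dataset$true_labels)) {
    write_matrix_tsv(dataset$true_labels, file.path(path, "true_labels.tsv"))
  }
  invisible(path)
}

#' Read a functional dataset written by [write_dataset()]
#'
#' Validates that all subjects share the matrix shape and that the session
#' partition covers the conditions.
#'
#' @param path directory.
#' @return A [functional_dataset()].
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "dataset.json"),
                              simplifyVector = TRUE)
  data <- lapply(meta$subjects, function(s) {
    read_matrix_tsv(file.path(path, paste0(s, ".tsv")))
  })
  names(data) <- meta$subjects
  tl <- NULL
  if (isTRUE(meta$has_true_labels)) {
    tl <- read_matrix_tsv(file.path(path, "true_labels.tsv"))
    storage.mode(tl) <- "integer"
  }
  functional_dataset(meta$dataset_id, data, meta$sessions, true_labels = tl)
}

#' Write a vMF emission model to a directory
#' @param emission a [vmf_emission()].
#' @param path directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_emission <- function(emission, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(dataset_id = emission$dataset_id, sessions = emission$sessions,
         K = emission$K),
    file.path(path, "emission.json"), auto_unbox = TRUE, digits = NA
  )
  # kappa goes through the exact TSV path (JSON re-parsing loses ulps)
  write_matrix_tsv(rbind(emission$kappa), file.path(path, "kappa.tsv"))
  for (n in seq_along(emission$V)) {
    write_matrix_tsv(emission$V[[n]],
                     file.path(path, sprintf("V_session%02d.tsv", n)))
  }
  invisible(path)
}

#' Read a vMF emission model written by [write_emission()]
#' @param path directory.
#' @return A [vmf_emission()].
#' @export
read_emission <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "emission.json"),
                              simplifyVector = TRUE)
  V <- lapply(seq_along(meta$sessions), function(n) {
    read_matrix_tsv(file.path(path, sprintf("V_session%02d.tsv", n)))
  })
  kappa <- as.vector(read_matrix_tsv(file.path(path, "kappa.tsv")))
  vmf_emission(meta$dataset_id, V, kappa, meta$sessions)
}

#' Export an atlas to files
#'
#' Writes the probabilistic group map (TSV, and NIfTI when a volume
#' geometry is supplied), the winner-take-all label map, a lookup table
#' (index, name, RGB) and, when a hierarchy with an hclust tree is given,
#' a Newick serialization of the dendrogram.
#'
#' @param model a fitted [fused_model].
#' @param path output directory.
#' @param hierarchy optional [parcel_hierarchy()] (names, colors, tree).
#' @param geometry optional list with `dim` (3-vector) and `indices`
#'   (length-P linear voxel indices into the volume) enabling NIfTI
#'   export.
#' @return `path`, invisibly.
#' @export
export_atlas <- function(model, path, hierarchy = NULL, geometry = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  prob <- group_prob(model$arrangement)
  K <- nrow(prob)
  P <- ncol(prob)
  labels <- hard_parcellation(prob)
  write_matrix_tsv(prob, file.path(path, "prob.tsv"))
  utils::write.table(data.frame(voxel = seq_len(P), label = labels),
                     file.path(path, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nm <- if (!is.null(hierarchy$names) && length(hierarchy$names) == K) {
    hierarchy$names
  } else paste0("P", seq_len(K))
  col <- if (!is.null(hierarchy$colors) && nrow(hierarchy$colors) == K) {
    hierarchy$colors
  } else t(grDevices::col2rgb(grDevices::hcl.colors(K, "Spectral")) / 255)
  utils::write.table(
    data.frame(index = seq_len(K), name = nm,
               R = round(col[, 1], 6), G = round(col[, 2], 6),
               B = round(col[, 3], 6)),
    file.path(path, "lookup.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  if (!is.null(hierarchy$merge_tree) &&
      inherits(hierarchy$merge_tree, "hclust")) {
    writeLines(hclust_to_newick(hierarchy$merge_tree),
               file.path(path, "dendrogram.nwk"))
  }
  if (!is.null(geometry)) {
    if (length(geometry$indices) != P) {
      stop("geometry voxel count does not match the parcellation")
    }
    vol <- array(0L, dim = geometry$dim)
    vol[geometry$indices] <- labels
    RNifti::writeNifti(RNifti::asNifti(vol),
                       file.path(path, "atlas_dseg.nii.gz"))
    parr <- array(0, dim = c(geometry$dim, K))
    nvol <- prod(geometry$dim)
    for (k in seq_len(K)) {
      parr[geometry$indices + (k - 1) * nvol] <- prob[k, ]
    }
    RNifti::writeNifti(RNifti::asNifti(parr),
                       file.path(path, "atlas_probseg.nii.gz"))
  }
  invisible(path)
}

# Newick text from an hclust object (leaf labels = indices or tree labels)
hclust_to_newick <- function(hc) {
  labs <- if (is.null(hc$labels)) as.character(seq_len(nrow(hc$merge) + 1)) else hc$labels
  rec <- function(i) {
    if (i < 0) return(labs[-i])
    sprintf("(%s,%s):%.6g", rec(hc$merge[i, 1]), rec(hc$merge[i, 2]),
            hc$height[i])
  }
  root <- nrow(hc$merge)
  sprintf("(%s,%s);", rec(hc$merge[root, 1]), rec(hc$merge[root, 2]))
}

#' Read back a winner-take-all label export
#' @param path directory written by [export_atlas()].
#' @return Integer label vector.
#' @export
read_atlas_labels <- function(path) {
  utils::read.table(file.path(path, "labels.tsv"), sep = "\t",
                    header = TRUE)$label
}
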