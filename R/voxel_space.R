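#' Voxel spaces
#'
#' A `voxel_space` is the spatial substrate of a parcellation: voxel
#' coordinates in template units, a hemisphere label per voxel, and a mirror
#' pairing that maps every voxel to its anatomically mirrored counterpart.
#' The pairing is an involution (`mirror[mirror[i]] == i`); midline voxels
#' may be self-paired.
#'
#' @param coords numeric matrix, one row per voxel (P x d).
#' @param hemisphere character vector of `"left"`, `"right"` or `"midline"`.
#' @param mirror integer vector; `mirror[i]` is the index of voxel `i`'s
#'   mirrored counterpart (`i` itself for midline voxels).
#' @param spacing grid spacing in template units (metadata only).
#'
#' @return An object of class `voxel_space`.
#' @export
voxel_space <- function(coords, hemisphere, mirror, spacing = 1) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  P <- nrow(coords)
  stopifnot(length(hemisphere) == P, length(mirror) == P)
  if (!all(hemisphere %in% c("left", "right", "midline"))) {
    stop("hemisphere labels must be 'left', 'right' or 'midline'")
  }
  mirror <- as.integer(mirror)
  if (!all(mirror[mirror] == seq_len(P))) {
    stop("mirror pairing must be an involution")
  }
  if (sum(hemisphere == "left") != sum(hemisphere == "right")) {
    stop("left and right voxel counts must be equal")
  }
  structure(
    list(coords = coords, hemisphere = hemisphere, mirror = mirror,
         spacing = spacing),
    class = "voxel_space"
  )
}

#' Number of voxels in a space
#' @param space a [voxel_space()].
#' @return Integer voxel count.
#' @export
n_voxels <- function(space) nrow(space$coords)

#' Build a mirror-symmetric 2-D voxel grid
#'
#' Constructs a rectangular grid straddling a vertical midline at x = 0, the
#' synthetic stand-in for a left/right symmetric template space. Columns with
#' negative x are labelled `left`, positive x `right`; the mirror pairing
#' maps `(x, y)` to `(-x, y)`. The width must be even so the hemispheres have
#' equal voxel counts (no midline column, so no self-paired voxels).
#'
#' @param width number of columns (must be even).
#' @param height number of rows.
#' @param spacing grid spacing in template units.
#'
#' @return A [voxel_space()] with `width * height` voxels.
#' @examples
#' sp <- make_symmetric_grid(4, 2)
#' table(sp$hemisphere)
#' @export
make_symmetric_grid <- function(width, height, spacing = 1) {
  if (width %% 2 != 0) stop("no symmetric split: width must be even")
  xs <- (seq_len(width) - (width + 1) / 2) * spacing
  ys <- (seq_len(height) - (height + 1) / 2) * spacing
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  coords <- as.matrix(grid)
  hemisphere <- ifelse(coords[, 1] < 0, "left", "right")
  # mirrored voxel shares the row, column reflected about the midline
  key <- paste(round(-coords[, 1] / spacing, 9), round(coords[, 2] / spacing, 9))
  own <- paste(round(coords[, 1] / spacing, 9), round(coords[, 2] / spacing, 9))
  mirror <- match(key, own)
  voxel_space(coords, hemisphere, mirror, spacing)
}

#' @export
print.voxel_space <- function(x, ...) {
  cat(sprintf("<voxel_space> %d voxels, %d dims (%d left / %d right / %d midline)\n",
              n_voxels(x), ncol(x$coords),
              sum(x$hemisphere == "left"), sum(x$hemisphere == "right"),
              sum(x$hemisphere == "midline")))
  invisible(x)
}

#' Voxel space as a tibble
#'
#' One row per voxel with coordinates, hemisphere and mirror index; the
#' tidy view used by the plotting helpers.
#'
#' @param x a [voxel_space()].
#' @param ... unused.
#' @return A tibble with columns `voxel`, `x`, `y` (and further coordinate
#'   columns for d > 2), `hemisphere`, `mirror`.
#' @export
as_tibble.voxel_space <- function(x, ...) {
  cn <- colnames(x$coords)
  if (is.null(cn)) cn <- c("x", "y", "z", "w")[seq_len(ncol(x$coords))]
  out <- tibble::as_tibble(as.data.frame(x$coords))
  names(out) <- cn
  dplyr::bind_cols(
    tibble::tibble(voxel = seq_len(n_voxels(x))),
    out,
    tibble::tibble(hemisphere = x$hemisphere, mirror = x$mirror)
  )
}
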