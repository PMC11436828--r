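# Log-potential used to forbid a parcel at a voxel (hemisphere confinement).
# Large and negative rather than -Inf so column maxima stay finite; after
# softmax the forbidden probabilities underflow to exactly zero.
NEG_POTENTIAL <- -1e10

#' Arrangement models (group spatial prior)
#'
#' The arrangement model is a spatially independent prior over parcel
#' assignments: a K x P matrix of log-potentials eta whose column-wise
#' softmax gives the group probability of each parcel at each voxel.
#' The symmetric variant confines parcels `1..K/2` to the left hemisphere
#' and `K/2+1..K` to the right, and ties the potentials so that
#' `p[k, i] == p[k + K/2, mirror(i)]` exactly. A confined-but-untied
#' variant (used for the asymmetric atlas) keeps each parcel within its
#' designated hemisphere while letting the two sides differ.
#'
#' @param eta `K x P` matrix of log-potentials.
#' @param space the [voxel_space()] (required when `symmetric` or
#'   `confined`; supplies the mirror pairing and hemisphere labels).
#' @param symmetric mirror-tied potentials?
#' @param confined hemisphere-confined parcels? (implied by `symmetric`).
#' @return An object of class `arrangement`.
#' @export
arrangement <- function(eta, space = NULL, symmetric = FALSE,
                        confined = symmetric) {
  eta <- as.matrix(eta)
  if ((symmetric || confined) && is.null(space)) {
    stop("symmetric/confined arrangements need a voxel space")
  }
  if (symmetric && nrow(eta) %% 2 != 0) stop("symmetric arrangements need even K")
  structure(
    list(eta = eta, K = nrow(eta), symmetric = symmetric, confined = confined,
         mirror = space$mirror, hemisphere = space$hemisphere),
    class = "arrangement"
  )
}

#' @export
print.arrangement <- function(x, ...) {
  kind <- if (x$symmetric) "symmetric" else if (x$confined) "confined asymmetric" else "asymmetric"
  cat(sprintf("<arrangement> K = %d, P = %d (%s)\n", x$K, ncol(x$eta), kind))
  invisible(x)
}

#' Group probability map of an arrangement
#'
#' Column-wise softmax of the log-potentials; each column is the prior
#' parcel distribution of one voxel.
#'
#' @param arr an [arrangement()].
#' @return A `K x P` probability matrix with columns summing to 1.
#' @export
group_prob <- function(arr) {
  softmax_cols(arr$eta)
}

# mask of allowed (parcel, voxel) cells under hemisphere confinement
confinement_mask_ <- function(K, hemisphere) {
  Kh <- K %/% 2
  P <- length(hemisphere)
  mask <- matrix(TRUE, K, P)
  mask[(Kh + 1):K, hemisphere == "left"] <- FALSE
  mask[seq_len(Kh), hemisphere == "right"] <- FALSE
  mask
}

#' M-step update of the arrangement model
#'
#' The maximum-likelihood update of an independent-voxel prior is simply
#' the mean of the individual posterior maps; the potentials are the log of
#' that mean, floored at `eps` to avoid infinite potentials. The symmetric
#' variant first averages the posterior over the two hemispheres under the
#' parcel/voxel pairing and then tiles the result, which makes the updated
#' group map exactly mirror-symmetric. Confined variants keep forbidden
#' cells at the blocking potential (no probability leaks across the
#' midline).
#'
#' @param mean_posterior `K x P` matrix: the average over all subjects of
#'   all datasets of the posterior parcel probabilities (columns sum to 1).
#' @param template an [arrangement()] carrying the variant (symmetry,
#'   confinement, mirror pairing).
#' @param eps probability floor applied before taking logs.
#' @return The updated [arrangement()].
#' @export
arrangement_m_step <- function(mean_posterior, template, eps = 1e-10) {
  K <- template$K
  P <- ncol(mean_posterior)
  stopifnot(nrow(mean_posterior) == K)
  if (template$symmetric) {
    Kh <- K %/% 2
    mir <- template$mirror
    hemi <- template$hemisphere
    eta <- matrix(NEG_POTENTIAL, K, P)
    left <- which(hemi == "left")
    # tied estimate: average the posterior over the two paired cells
    q_half <- (mean_posterior[seq_len(Kh), left, drop = FALSE] +
                 mean_posterior[Kh + seq_len(Kh), mir[left], drop = FALSE]) / 2
    q_half <- sweep(pmax(q_half, eps), 2, colSums(pmax(q_half, eps)), "/")
    lh <- log(q_half)
    eta[seq_len(Kh), left] <- lh
    eta[Kh + seq_len(Kh), mir[left]] <- lh
    mid <- which(hemi == "midline")
    if (length(mid) > 0) {
      # self-paired voxels: equal split between the paired parcels
      q_mid <- (mean_posterior[seq_len(Kh), mid, drop = FALSE] +
                  mean_posterior[Kh + seq_len(Kh), mid, drop = FALSE]) / 2
      q_mid <- sweep(pmax(q_mid, eps), 2, 2 * colSums(pmax(q_mid, eps)), "/")
      eta[seq_len(Kh), mid] <- log(q_mid)
      eta[Kh + seq_len(Kh), mid] <- log(q_mid)
    }
  } else if (template$confined) {
    mask <- confinement_mask_(K, template$hemisphere)
    q <- pmax(mean_posterior, eps) * mask
    q <- sweep(q, 2, colSums(q), "/")
    eta <- matrix(NEG_POTENTIAL, K, P)
    eta[mask] <- log(q[mask])
  } else {
    q <- pmax(mean_posterior, eps)
    q <- sweep(q, 2, colSums(q), "/")
    eta <- log(q)
  }
  out <- template
  out$eta <- eta
  out
}

# random initialization of the arrangement: small noise around uniform,
# respecting symmetry ties / confinement of the template variant
arrangement_init <- function(K, space, symmetric, sd = 0.1) {
  P <- n_voxels(space)
  if (symmetric) {
    Kh <- K %/% 2
    left <- which(space$hemisphere == "left")
    eta <- matrix(NEG_POTENTIAL, K, P)
    noise <- matrix(rnorm(Kh * length(left), sd = sd), Kh, length(left))
    eta[seq_len(Kh), left] <- noise
    eta[Kh + seq_len(Kh), space$mirror[left]] <- noise
    mid <- which(space$hemisphere == "midline")
    if (length(mid) > 0) {
      nm <- matrix(rnorm(Kh * length(mid), sd = sd), Kh, length(mid))
      eta[seq_len(Kh), mid] <- nm + log(0.5)
      eta[Kh + seq_len(Kh), mid] <- nm + log(0.5)
    }
    arrangement(eta, space, symmetric = TRUE)
  } else {
    arrangement(matrix(rnorm(K * P, sd = sd), K, P), space,
                symmetric = FALSE, confined = FALSE)
  }
}

#' Check the mirror-symmetry invariant of a probability map
#'
#' Maximum absolute deviation between `p[k, i]` and
#' `p[k + K/2, mirror(i)]` over all left-hemisphere voxels and parcel
#' pairs; exactly 0 for maps built by the symmetric constructor.
#'
#' @param prob `K x P` probability matrix.
#' @param space the [voxel_space()].
#' @return Scalar maximum deviation.
#' @export
symmetry_deviation <- function(prob, space) {
  K <- nrow(prob)
  Kh <- K %/% 2
  left <- which(space$hemisphere == "left")
  max(abs(prob[seq_len(Kh), left, drop = FALSE] -
            prob[Kh + seq_len(Kh), space$mirror[left], drop = FALSE]))
}
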