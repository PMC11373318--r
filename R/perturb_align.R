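# Expression interpolation / perturbation experiments and CCA +
# Gaussian-mixture subspace alignment.

#' Linear interpolation between two expression vectors
#'
#' `v_i = (1 - t_i) p_a + t_i p_b` with `t_i = i/(steps - 1)`, endpoints
#' included, so `steps = 10` yields the two endpoints and eight intermediate
#' vectors on an exact affine path.
#'
#' @param p_a,p_b equal-length expression vectors.
#' @param steps total number of vectors including endpoints (`>= 2`).
#' @return `steps x length(p_a)` matrix, one vector per row.
#' @export
interpolate_expression <- function(p_a, p_b, steps = 10L) {
  if (length(p_a) != length(p_b)) stop("endpoint lengths differ")
  if (steps < 2L) stop("steps must be >= 2")
  t_i <- seq(0, 1, length.out = steps)
  out <- outer(1 - t_i, p_a) + outer(t_i, p_b)
  out[1L, ] <- p_a                   # endpoints exact despite rounding
  out[steps, ] <- p_b
  colnames(out) <- names(p_a)
  out
}

#' Perturb one marker of an expression vector
#'
#' @param p expression vector (named, or use integer position).
#' @param marker marker name or index.
#' @param delta shift in transformed space.
#' @return copy of `p` with the marker shifted; all other entries unchanged.
#' @export
perturb_expression <- function(p, marker, delta) {
  j <- if (is.character(marker)) match(marker, names(p)) else marker
  if (is.na(j) || j < 1L || j > length(p))
    stop("marker '", marker, "' not found in the panel")
  p[j] <- p[j] + delta
  p
}

#' Run an interpolation experiment with a trained generator
#'
#' Generates one patch per interpolation step. By default the noise vector
#' is drawn once and held fixed across steps, so image changes reflect
#' expression changes only. Per-step morphology (detected nucleus count and
#' mean nuclear area) is computed on the central spot crop.
#'
#' @param gen a trained `"generator_params"`.
#' @param p_a,p_b endpoint expression vectors (transformed space).
#' @param steps total interpolation steps (default 10).
#' @param seed integer seed for the noise draw.
#' @param z_policy `"fixed"` (one z for all steps) or `"per_step"`.
#' @param spot_size_px central crop used for morphology (default half the
#'   patch).
#' @return list of class `"ouro_interpolation"`: `vectors` (steps x markers),
#'   `images` (`H x W x 3 x steps` in `[0, 1]`), `morphology` (data frame
#'   with `step`, `n_nuclei`, `mean_area`).
#' @export
run_interpolation_experiment <- function(gen, p_a, p_b, steps = 10L,
                                         seed = 1L,
                                         z_policy = c("fixed", "per_step"),
                                         spot_size_px = NULL) {
  z_policy <- match.arg(z_policy)
  vec <- interpolate_expression(p_a, p_b, steps)
  zd <- gen$arch$noise_dim
  Z <- with_seed(seed, {
    if (z_policy == "fixed")
      matrix(rep(stats::rnorm(zd), steps), steps, byrow = TRUE)
    else matrix(stats::rnorm(steps * zd), steps)
  })
  imgs <- generate(gen, vec, Z)
  imgs <- model_to_patch(imgs)
  if (is.null(spot_size_px)) spot_size_px <- dim(imgs)[1L] %/% 2L
  morph <- data.frame(step = seq_len(steps), n_nuclei = 0L,
                      mean_area = NA_real_)
  for (i in seq_len(steps)) {
    crop <- center_crop(imgs[, , , i], spot_size_px)
    lab <- detect_nuclei(crop)
    morph$n_nuclei[i] <- attr(lab, "n")
    if (attr(lab, "n") > 0L)
      morph$mean_area[i] <- mean(tabulate(lab[lab > 0]))
  }
  structure(list(vectors = vec, images = imgs, morphology = morph),
            class = "ouro_interpolation")
}

#' Regularized canonical correlation analysis of two feature spaces
#'
#' Columns are standardized internally; covariances receive a small ridge
#' (`reg` times the mean diagonal) so near-singular morphology blocks stay
#' stable. Canonical directions maximise successive correlations subject to
#' orthogonality; correlations are clamped to `[0, 1]` and non-increasing.
#'
#' @param x spots x m expression matrix.
#' @param y spots x f morphology matrix (same row order: one-to-one spot
#'   correspondence).
#' @param dims number of canonical pairs (default 2).
#' @param reg relative ridge regularisation.
#' @return list with `psi` (projected x), `phi` (projected y), `cor`
#'   (canonical correlations), `a`, `b` (projection matrices).
#' @export
cca_project <- function(x, y, dims = 2L, reg = 1e-4) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (nrow(y) != n) stop("x and y must have the same rows")
  if (n <= dims) stop("need more spots than dimensions")
  xs <- scale(x); ys <- scale(y)
  xs[, attr(xs, "scaled:scale") == 0] <- 0
  ys[, attr(ys, "scaled:scale") == 0] <- 0
  xs[!is.finite(xs)] <- 0; ys[!is.finite(ys)] <- 0
  Sxx <- stats::cov(xs); Syy <- stats::cov(ys); Sxy <- stats::cov(xs, ys)
  Sxx <- Sxx + diag(reg * mean(diag(Sxx)) + 1e-10, ncol(xs))
  Syy <- Syy + diag(reg * mean(diag(Syy)) + 1e-10, ncol(ys))
  ex <- eigen(Sxx, symmetric = TRUE)
  ey <- eigen(Syy, symmetric = TRUE)
  wx <- ex$vectors %*% (1 / sqrt(pmax(ex$values, 1e-12)) * t(ex$vectors))
  wy <- ey$vectors %*% (1 / sqrt(pmax(ey$values, 1e-12)) * t(ey$vectors))
  M <- wx %*% Sxy %*% wy
  sv <- svd(M, nu = dims, nv = dims)
  a <- wx %*% sv$u
  b <- wy %*% sv$v
  list(psi = xs %*% a, phi = ys %*% b,
       cor = pmin(pmax(sv$d[seq_len(dims)], 0), 1), a = a, b = b)
}

#' Gaussian-mixture clustering of a projected feature space
#'
#' Full-covariance k-component Gaussian mixture fitted by EM
#' (model-based clustering); hard labels by maximum responsibility.
#' Deterministic given the seed.
#'
#' @param phi n x d matrix (e.g. projected morphology space).
#' @param k number of mixture components (default 8).
#' @param seed integer seed.
#' @return integer vector of cluster labels in `1..k`.
#' @export
gmm_cluster <- function(phi, k = 8L, seed = 1L) {
  phi <- as.matrix(phi)
  if (nrow(phi) < k) stop("need at least k observations")
  if (k == 1L) return(rep(1L, nrow(phi)))
  with_seed(seed, {
    fit <- tryCatch(
      mclust::Mclust(phi, G = k, modelNames = "VVV", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$classification)) {
      # degenerate EM: fall back to seeded k-means centres + spherical EM
      km <- stats::kmeans(phi, centers = k, nstart = 5L)
      return(as.integer(km$cluster))
    }
    as.integer(fit$classification)
  })
}

#' Concordance between expression and morphology subspaces
#'
#' Fits an independent k-component mixture on the expression projection
#' `psi` and scores its labels against the supplied morphology-space labels
#' with the adjusted Rand index (1 = identical partitions, about 0 =
#' unrelated).
#'
#' @param psi expression-side 2-D projection.
#' @param phi_labels cluster labels obtained from the morphology projection.
#' @param k number of mixture components.
#' @param seed integer seed for the expression-side fit.
#' @return adjusted Rand index in `[-1, 1]`.
#' @export
alignment_concordance <- function(psi, phi_labels, k = 8L, seed = 1L) {
  if (nrow(as.matrix(psi)) != length(phi_labels))
    stop("psi and phi_labels must be aligned one-to-one")
  psi_labels <- gmm_cluster(psi, k = k, seed = seed)
  mclust::adjustedRandIndex(psi_labels, phi_labels)
}
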