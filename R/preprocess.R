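# Spot-level preprocessing: grid geometry, per-cell aggregation, the
# zero-aware log/z transform and empirical-Bayes batch correction.

#' Partition a WSI into spot and patch geometry
#'
#' Non-overlapping spot tiles cover the largest inscribed grid; each context
#' patch is its spot expanded by `(patch - spot)/2` on every side. All
#' coordinates are 0-based with half-open pixel intervals
#' `[x0, x0 + w) x [y0, y0 + h)`.
#'
#' @param wsi_width,wsi_height WSI extent in pixels.
#' @param spot_size,patch_size spot / patch side in pixels; both even,
#'   `patch_size >= spot_size`.
#' @param border policy for spots whose context patch exits the WSI:
#'   `"drop"` (default) removes them, `"clamp"` shifts the patch window back
#'   inside the WSI (the spot is then off-centre within its patch).
#' @return data frame with grid `row`, `col` and pixel bounds `spot_x0`,
#'   `spot_y0`, `patch_x0`, `patch_y0` (sides implicit in the sizes).
#' @export
grid_partition <- function(wsi_width, wsi_height, spot_size = 128L,
                           patch_size = 256L, border = c("drop", "clamp")) {
  border <- match.arg(border)
  if (spot_size %% 2L || patch_size %% 2L) stop("sizes must be even")
  if (patch_size < spot_size) stop("patch_size must be >= spot_size")
  ncol_g <- wsi_width %/% spot_size
  nrow_g <- wsi_height %/% spot_size
  if (ncol_g < 1L || nrow_g < 1L || wsi_width < patch_size ||
      wsi_height < patch_size) {
    warning("WSI smaller than one patch; returning empty grid")
    if (ncol_g < 1L || nrow_g < 1L)
      return(data.frame(row = integer(0), col = integer(0),
                        spot_x0 = integer(0), spot_y0 = integer(0),
                        patch_x0 = integer(0), patch_y0 = integer(0)))
  }
  margin <- (patch_size - spot_size) %/% 2L
  g <- expand.grid(row = seq_len(nrow_g) - 1L, col = seq_len(ncol_g) - 1L)
  g <- g[order(g$row, g$col), , drop = FALSE]
  g$spot_x0 <- g$col * spot_size
  g$spot_y0 <- g$row * spot_size
  g$patch_x0 <- g$spot_x0 - margin
  g$patch_y0 <- g$spot_y0 - margin
  fits <- g$patch_x0 >= 0L & g$patch_y0 >= 0L &
    g$patch_x0 + patch_size <= wsi_width &
    g$patch_y0 + patch_size <= wsi_height
  if (border == "drop") {
    g <- g[fits, , drop = FALSE]
  } else {
    g$patch_x0 <- pmin(pmax(g$patch_x0, 0L), wsi_width - patch_size)
    g$patch_y0 <- pmin(pmax(g$patch_y0, 0L), wsi_height - patch_size)
  }
  rownames(g) <- NULL
  g
}

#' Aggregate per-cell counts into a spot expression vector
#'
#' Arithmetic mean per marker over the cells falling in one spot. An empty
#' cell list yields an all-zero vector flagged with `attr(, "empty")`.
#'
#' @param cells numeric matrix or data frame, cells x markers.
#' @param n_markers marker count, required only when `cells` has no rows and
#'   no columns to infer it from.
#' @return numeric marker vector with attribute `empty`.
#' @export
aggregate_spot <- function(cells, n_markers = NULL) {
  cells <- as.matrix(cells)
  if (nrow(cells) == 0L) {
    m <- if (!is.null(n_markers)) n_markers else ncol(cells)
    out <- numeric(m)
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- colMeans(cells)
  attr(out, "empty") <- FALSE
  out
}

#' Fit the zero-aware log/z expression transform
#'
#' Per marker, nonzero raw values `x` map to `(log x - mu) / sigma` with
#' `mu`, `sigma` estimated from that marker's nonzero log values. Zeros map
#' through the same affine map applied to a pseudo-count 1000 times smaller
#' than the marker's smallest observed positive value, which places them
#' strictly below every transformed nonzero value — a separate "not
#' expressed" category rather than a point on the positive scale.
#'
#' Degenerate markers: a marker with a single distinct nonzero value uses
#' `sigma = 1` (with a warning); a marker with no nonzero values maps
#' entirely to the documented floor value -10 (with a warning).
#'
#' @param raw numeric matrix, spots x markers, values `>= 0`.
#' @param sentinel_factor the pseudo-count divisor (default 1000).
#' @return list with `transformed` (matrix) and `state` (an
#'   `"ouro_transform_state"` reusable on held-out data).
#' @export
fit_transform_expression <- function(raw, sentinel_factor = 1000) {
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("raw expression must be >= 0")
  m <- ncol(raw)
  mu <- numeric(m); sigma <- numeric(m); minpos <- numeric(m)
  for (j in seq_len(m)) {
    x <- raw[, j]
    pos <- x[x > 0]
    if (length(pos) == 0L) {
      mu[j] <- 0; sigma[j] <- 1; minpos[j] <- NA_real_
      warning("marker ", j, " has no nonzero values; transformed to floor")
      next
    }
    lg <- log(pos)
    mu[j] <- mean(lg)
    if (length(unique(pos)) < 2L) {
      sigma[j] <- 1
      warning("marker ", j,
              " has a single distinct nonzero value; sigma fallback to 1")
    } else {
      sigma[j] <- stats::sd(lg)
      if (sigma[j] == 0) sigma[j] <- 1
    }
    minpos[j] <- min(pos)
  }
  state <- structure(list(mu = mu, sigma = sigma, min_positive = minpos,
                          sentinel_factor = sentinel_factor,
                          floor_value = -10,
                          marker_names = colnames(raw)),
                     class = "ouro_transform_state")
  list(transformed = apply_transform(raw, state), state = state)
}

#' Apply a fitted expression transform
#'
#' Uses the stored per-marker statistics, so held-out data are mapped with
#' training-set parameters only: `apply_transform(X, fit(X)$state)` equals
#' `fit(X)$transformed` exactly.
#'
#' @param raw numeric matrix, spots x markers, values `>= 0`.
#' @param state an `"ouro_transform_state"` from [fit_transform_expression()].
#' @return transformed matrix.
#' @export
apply_transform <- function(raw, state) {
  raw <- as.matrix(raw)
  if (ncol(raw) != length(state$mu))
    stop("marker count mismatch between data and transform state")
  if (!is.null(state$marker_names) && !is.null(colnames(raw)) &&
      !identical(colnames(raw), state$marker_names))
    stop("marker names do not match the fitted transform state")
  out <- raw
  for (j in seq_len(ncol(raw))) {
    if (is.na(state$min_positive[j])) {
      out[, j] <- state$floor_value
      next
    }
    sent <- (log(state$min_positive[j] / state$sentinel_factor) -
               state$mu[j]) / state$sigma[j]
    x <- raw[, j]
    v <- numeric(length(x))
    nz <- x > 0
    v[nz] <- (log(x[nz]) - state$mu[j]) / state$sigma[j]
    v[!nz] <- sent
    out[, j] <- v
  }
  out
}

#' Serialize / restore a transform state as JSON
#' @param state an `"ouro_transform_state"`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_transform_state()` returns the state.
#' @export
write_transform_state <- function(state, path) {
  jsonlite::write_json(unclass(state), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_transform_state
#' @export
read_transform_state <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  v$min_positive <- as.numeric(v$min_positive)
  structure(v, class = "ouro_transform_state")
}

#' Empirical-Bayes location/scale batch correction
#'
#' Removes per-batch additive and multiplicative effects per marker with the
#' parametric empirical-Bayes shrinkage scheme: markers are standardized with
#' the batch-size-weighted grand mean and pooled variance, per-batch
#' location/scale effects are estimated, shrunk toward common normal /
#' inverse-gamma priors by the iterative parametric EB solution, removed, and
#' the overall location/scale restored. The per-marker grand mean is restored
#' exactly. A single batch is returned unchanged.
#'
#' @param x numeric matrix, spots x markers (transformed expression).
#' @param batch batch (patient) labels, length `nrow(x)`; at least 2 spots
#'   per batch.
#' @return corrected matrix of identical dimensions.
#' @export
correct_batches <- function(x, batch) {
  x <- as.matrix(x)
  batch <- as.factor(batch)
  if (length(batch) != nrow(x)) stop("batch length must match rows of x")
  if (nlevels(batch) < 2L) return(x)
  nb <- table(batch)
  if (any(nb < 2L)) stop("each batch needs at least 2 spots")
  n <- nrow(x); m <- ncol(x)
  lev <- levels(batch)
  B <- length(lev)

  t_x <- t(x)                                  # markers x spots
  batch_means <- vapply(lev, function(l)
    rowMeans(t_x[, batch == l, drop = FALSE]), numeric(m))  # m x B
  grand <- as.numeric(batch_means %*% (as.numeric(nb) / n))
  # pooled variance is the residual variance around each batch's own mean
  resid <- t_x - batch_means[, as.integer(batch), drop = FALSE]
  pooled_var <- rowMeans(resid^2)
  zero_var <- pooled_var <= .Machine$double.eps
  if (any(zero_var)) pooled_var[zero_var] <- 1
  Z <- (t_x - grand) / sqrt(pooled_var)

  gamma_hat <- matrix(0, m, B); delta_hat <- matrix(1, m, B)
  for (b in seq_len(B)) {
    zb <- Z[, batch == lev[b], drop = FALSE]
    gamma_hat[, b] <- rowMeans(zb)
    dv <- apply(zb, 1L, stats::var)
    if (any(dv <= .Machine$double.eps)) {
      warning("zero within-batch variance for some marker(s); ",
              "scale effect fallback to 1")
      dv[dv <= .Machine$double.eps] <- 1
    }
    delta_hat[, b] <- dv
  }

  Zadj <- Z
  for (b in seq_len(B)) {
    g <- gamma_hat[, b]; d <- delta_hat[, b]
    gbar <- mean(g); tau2 <- stats::var(g)
    V <- mean(d); S2 <- stats::var(d)
    a_pr <- (2 * S2 + V^2) / S2
    b_pr <- (V * S2 + V^3) / S2
    nb_b <- as.numeric(nb[b])
    zb <- Z[, batch == lev[b], drop = FALSE]
    g_star <- g; d_star <- d
    for (it in seq_len(200L)) {
      g_new <- (nb_b * tau2 * g + d_star * gbar) / (nb_b * tau2 + d_star)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (b_pr + 0.5 * ss) / (nb_b / 2 + a_pr - 1)
      if (max(abs(g_new - g_star), abs(d_new - d_star)) < 1e-8) {
        g_star <- g_new; d_star <- d_new; break
      }
      g_star <- g_new; d_star <- d_new
    }
    Zadj[, batch == lev[b]] <- (zb - g_star) / sqrt(d_star)
  }

  out <- Zadj * sqrt(pooled_var) + grand
  out[zero_var, ] <- t_x[zero_var, ]
  # exact per-marker grand-mean restoration
  out <- out - (rowMeans(out) - rowMeans(t_x))
  res <- t(out)
  dimnames(res) <- dimnames(x)
  res
}
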