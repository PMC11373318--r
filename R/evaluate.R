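# Quantitative evaluation: spot cropping, image embeddings and Frechet
# distance, classical nucleus detection, the 63-feature nuclear morphometry
# profile, paired morphological distance testing and per-marker prediction
# metrics, plus a prediction-only CNN baseline.

#' Central crop of an image patch
#'
#' Axis-centred with half-open pixel bounds; a 256-px patch cropped to 128
#' spans rows and columns `[64, 192)`. Works on single images (`H x W x 3`
#' or `H x W`) and stacks (`H x W x 3 x n`).
#'
#' @param img image array.
#' @param size crop side in pixels, `<=` both image sides.
#' @return cropped array of the same arity.
#' @export
center_crop <- function(img, size) {
  d <- dim(img)
  if (size > d[1L] || size > d[2L])
    stop("crop size ", size, " exceeds image size ", d[1L], "x", d[2L])
  y0 <- (d[1L] - size) %/% 2L
  x0 <- (d[2L] - size) %/% 2L
  ri <- (y0 + 1L):(y0 + size)
  ci <- (x0 + 1L):(x0 + size)
  if (length(d) == 2L) img[ri, ci]
  else if (length(d) == 3L) img[ri, ci, , drop = FALSE]
  else img[ri, ci, , , drop = FALSE]
}

# ---- image embeddings and FID ----------------------------------------------

# fixed random conv weights for the seeded embedding
random_embed_weights <- function(seed) {
  with_seed(seed, list(
    w1 = nn_rand(3L * 9L, 12L, sqrt(2 / 27)),
    w2 = nn_rand(12L * 9L, 24L, sqrt(2 / 108)),
    w3 = nn_rand(24L * 9L, 32L, sqrt(2 / 216))))
}

#' Embed image patches for Frechet-distance evaluation
#'
#' `"seeded_random_conv"` (default): a fixed, seeded 3-layer random
#' convolutional network with average pooling; the embedding is the global
#' per-channel mean and standard deviation of the last feature map
#' (64 dimensions). Random convolutional features are a recognised
#' lightweight stand-in for pretrained embeddings; values are comparable
#' only within one embedding and seed.
#'
#' `"handcrafted"`: 21 documented closed-form features — per RGB channel the
#' mean, standard deviation and 10/50/90% quantiles (15), plus the mean and
#' standard deviation of the finite-difference gradient magnitude per
#' channel (6). On a constant-colour image the quantiles and means equal the
#' colour and every other entry is 0.
#'
#' `"external_pretrained"`: not bundled; raises an error explaining that
#' this path requires downloading pretrained weights.
#'
#' @param images `H x W x 3 x n` array in `[0, 1]` (or `H x W x 3` for a
#'   single image).
#' @param method embedding method.
#' @param seed integer seed of the random-conv embedding.
#' @return `n x d` embedding matrix.
#' @export
embed_images <- function(images, method = c("seeded_random_conv",
                                            "handcrafted",
                                            "external_pretrained"),
                         seed = 1L) {
  method <- match.arg(method)
  if (length(dim(images)) == 3L) images <- array(images, c(dim(images), 1L))
  n <- dim(images)[4L]
  if (method == "external_pretrained")
    stop("the external_pretrained embedding needs downloaded weights; ",
         "use 'seeded_random_conv' or 'handcrafted' for self-contained runs")
  if (method == "seeded_random_conv") {
    wts <- random_embed_weights(seed)
    x <- aperm(images, c(1L, 2L, 4L, 3L))                  # H W n 3
    h <- avgpool2_fw(relu_fw(conv_fw(x, wts$w1, numeric(12L)))$y)
    h <- avgpool2_fw(relu_fw(conv_fw(h, wts$w2, numeric(24L)))$y)
    h <- relu_fw(conv_fw(h, wts$w3, numeric(32L)))$y
    d <- dim(h)
    fm <- matrix(h, d[1L] * d[2L], d[3L] * d[4L])
    mu <- matrix(colMeans(fm), d[3L], d[4L])
    sdv <- matrix(sqrt(pmax(colMeans(fm^2) - colMeans(fm)^2, 0)),
                  d[3L], d[4L])
    return(cbind(mu, sdv))
  }
  # handcrafted
  emb <- matrix(0, n, 21L)
  for (i in seq_len(n)) {
    im <- images[, , , i]
    f <- numeric(0)
    for (ch in 1:3) {
      v <- im[, , ch]
      f <- c(f, mean(v), stats::sd(v),
             stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE))
    }
    for (ch in 1:3) {
      v <- im[, , ch]
      gx <- v[, -1] - v[, -ncol(v)]
      gy <- v[-1, ] - v[-nrow(v), ]
      gm <- sqrt(gx[-nrow(gx), ]^2 + gy[, -ncol(gy)]^2)
      f <- c(f, mean(gm), stats::sd(gm))
    }
    emb[i, ] <- f
  }
  emb
}

# symmetric PSD matrix square root via eigendecomposition
psd_sqrtm <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two embedded image sets
#'
#' `||mu_A - mu_B||^2 + Tr(S_A + S_B - 2 (S_A S_B)^{1/2})` under Gaussian
#' fits to the embeddings. Near-singular covariances are stabilised by a
#' small diagonal regulariser (added to both, reported via a message when it
#' exceeds the default).
#'
#' @param emb_a,emb_b `n x d` embedding matrices (same `d`, `n >= 2`).
#' @param reg diagonal regulariser.
#' @return non-negative Frechet distance (clamped at 0 against roundoff).
#' @export
compute_fid <- function(emb_a, emb_b, reg = 1e-6) {
  if (ncol(emb_a) != ncol(emb_b)) stop("embedding dimensions differ")
  if (nrow(emb_a) < 2L || nrow(emb_b) < 2L)
    stop("need at least 2 samples per side")
  mu_a <- colMeans(emb_a); mu_b <- colMeans(emb_b)
  S_a <- stats::cov(emb_a) + diag(reg, ncol(emb_a))
  S_b <- stats::cov(emb_b) + diag(reg, ncol(emb_b))
  ev <- eigen(S_a %*% S_b, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(Re(ev), 0)))
  fid <- sum((mu_a - mu_b)^2) + sum(diag(S_a)) + sum(diag(S_b)) - 2 * tr_sqrt
  max(fid, 0)
}

# ---- nucleus detection ------------------------------------------------------

# Ruifrok-Johnston H&E optical-density stain vectors (rows, unit norm)
he_stain_matrix <- function() {
  M <- rbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105),
             d = c(0.268, 0.570, 0.776))
  M / sqrt(rowSums(M^2))
}

# per-pixel optical density and stain concentrations
stain_concentrations <- function(img) {
  d <- dim(img)
  od <- -log10(pmax(matrix(img, d[1L] * d[2L], 3L), 1e-3))
  conc <- od %*% solve(he_stain_matrix())
  list(od = od, conc = conc, dim = d[1:2])
}

#' Detect nuclei in an H&E image with a classical pipeline
#'
#' Colour deconvolution with the standard H&E stain matrix, Gaussian
#' smoothing of the haematoxylin channel, Otsu thresholding, morphological
#' opening, distance-transform watershed splitting of touching blobs, and an
#' area filter. A pluggable alternative detector can be supplied wherever a
#' label matrix is accepted downstream.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param sigma Gaussian smoothing radius in pixels.
#' @param min_area,max_area connected-component area filter in px^2
#'   (defaults scale with the image area).
#' @param split_watershed split touching blobs by watershed (default TRUE).
#' @return integer `H x W` label matrix (0 = background) with attribute
#'   `n` (nucleus count); disjoint masks by construction.
#' @export
detect_nuclei <- function(img, sigma = 1, min_area = NULL, max_area = NULL,
                          split_watershed = TRUE) {
  d <- dim(img)
  if (is.null(min_area)) min_area <- max(5, round(0.002 * d[1L] * d[2L]))
  if (is.null(max_area)) max_area <- round(0.2 * d[1L] * d[2L])
  sc <- stain_concentrations(img)
  hm <- matrix(sc$conc[, 1L], d[1L], d[2L])
  rng <- range(hm)
  if (diff(rng) < 1e-3) {
    out <- matrix(0L, d[1L], d[2L]); attr(out, "n") <- 0L
    return(out)
  }
  hn <- (hm - rng[1L]) / diff(rng)
  hs <- as.matrix(EBImage::gblur(EBImage::Image(hn), sigma = sigma))
  thr <- EBImage::otsu(EBImage::Image(hs))
  mask <- hs > thr
  mask <- as.matrix(EBImage::opening(EBImage::Image(mask * 1),
                                     EBImage::makeBrush(3L, "disc"))) > 0.5
  if (!any(mask)) {
    out <- matrix(0L, d[1L], d[2L]); attr(out, "n") <- 0L
    return(out)
  }
  lab <- if (split_watershed) {
    EBImage::watershed(EBImage::distmap(EBImage::Image(mask * 1)),
                       tolerance = 1)
  } else {
    EBImage::bwlabel(EBImage::Image(mask * 1))
  }
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area & sizes <= max_area)
  out <- matrix(0L, d[1L], d[2L])
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  attr(out, "n") <- length(keep)
  out
}

# ---- 63-feature nuclear morphometry -----------------------------------------

morph_feature_names <- function() {
  shape <- c("area", "perimeter", "equiv_diameter", "major_axis",
             "minor_axis", "eccentricity", "solidity", "extent",
             "circularity")
  chans <- c("R", "G", "B", "hema", "eos", "od")
  stats <- c("mean", "sd", "min", "max", "median", "q10", "q90", "skewness",
             "kurtosis")
  c(shape, as.vector(outer(stats, chans, function(s, c) paste(c, s,
                                                              sep = "_"))))
}

nucleus_shape_features <- function(labels, id) {
  px <- which(labels == id, arr.ind = TRUE)
  area <- nrow(px)
  # perimeter: boundary pixel count (4-connectivity edge exposure)
  m <- labels == id
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L); pad[2:(H + 1L), 2:(W + 1L)] <- m
  inner <- pad[2:(H + 1L), 2:(W + 1L)]
  exposed <- (inner & !pad[1:H, 2:(W + 1L)]) + (inner & !pad[3:(H + 2L), 2:(W + 1L)]) +
    (inner & !pad[2:(H + 1L), 1:W]) + (inner & !pad[2:(H + 1L), 3:(W + 2L)])
  # pi/4 corrects the city-block boundary count toward the true contour
  # length (exact for discs)
  perimeter <- sum(exposed) * pi / 4
  cy <- mean(px[, 1L]); cx <- mean(px[, 2L])
  dy <- px[, 1L] - cy; dx <- px[, 2L] - cx
  # second moments (+1/12 pixel-square correction)
  syy <- mean(dy^2) + 1 / 12; sxx <- mean(dx^2) + 1 / 12; sxy <- mean(dx * dy)
  tr <- sxx + syy; dd <- sqrt(max((sxx - syy)^2 / 4 + sxy^2, 0))
  l1 <- tr / 2 + dd; l2 <- max(tr / 2 - dd, 1e-9)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(1 - l2 / l1, 0))
  hull_area <- if (area >= 3L) {
    hp <- grDevices::chull(px[, 2L], px[, 1L])
    xs <- px[hp, 2L]; ys <- px[hp, 1L]
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2 + perimeter / 2
  } else area
  solidity <- min(area / max(hull_area, area), 1)
  bbox <- (diff(range(px[, 1L])) + 1) * (diff(range(px[, 2L])) + 1)
  extent <- area / bbox
  circularity <- min(4 * pi * area / max(perimeter, 1)^2, 1.5)
  c(area = area, perimeter = perimeter,
    equiv_diameter = 2 * sqrt(area / pi), major_axis = major,
    minor_axis = minor, eccentricity = ecc, solidity = solidity,
    extent = extent, circularity = circularity)
}

stat9 <- function(v) {
  if (length(v) < 2L) {
    return(c(mean(v), 0, min(v), max(v), stats::median(v), v[1L], v[1L], 0,
             0))
  }
  sk <- e1071::skewness(v); ku <- e1071::kurtosis(v)
  c(mean(v), stats::sd(v), min(v), max(v), stats::median(v),
    stats::quantile(v, 0.1, names = FALSE),
    stats::quantile(v, 0.9, names = FALSE),
    if (is.finite(sk)) sk else 0, if (is.finite(ku)) ku else 0)
}

#' Nuclear morphometry profile of a patch
#'
#' 63 features: 9 shape descriptors (area, perimeter, equivalent diameter,
#' major/minor axis, eccentricity, solidity, extent, circularity) plus 9
#' order statistics (mean, sd, min, max, median, 10th/90th percentile,
#' skewness, kurtosis) of 6 intensity channels (R, G, B, haematoxylin,
#' eosin, optical density) over nuclear pixels — computed per detected
#' nucleus and averaged over the nuclei of the patch.
#'
#' @param img `H x W x 3` array in `[0, 1]`.
#' @param labels optional precomputed label matrix from [detect_nuclei()].
#' @param ... passed to [detect_nuclei()] when `labels` is missing.
#' @return named numeric vector of length 63; if no nucleus is detected the
#'   vector is `NA` with attribute `flagged = TRUE` (excluded from distance
#'   computations).
#' @export
morph_features <- function(img, labels = NULL, ...) {
  if (is.null(labels)) labels <- detect_nuclei(img, ...)
  nm <- morph_feature_names()
  n <- max(labels)
  if (n == 0L) {
    out <- stats::setNames(rep(NA_real_, 63L), nm)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  sc <- stain_concentrations(img)
  d <- dim(img)
  chans <- cbind(matrix(img, d[1L] * d[2L], 3L),
                 sc$conc[, 1L], sc$conc[, 2L], rowMeans(sc$od))
  acc <- matrix(0, n, 63L)
  for (i in seq_len(n)) {
    idx <- which(labels == i)
    f_shape <- nucleus_shape_features(labels, i)
    f_int <- as.vector(apply(chans[idx, , drop = FALSE], 2L, stat9))
    acc[i, ] <- c(f_shape, f_int)
  }
  out <- stats::setNames(colMeans(acc), nm)
  attr(out, "flagged") <- FALSE
  out
}

#' Standard deviations for morphological feature scaling
#'
#' @param feats matrix of feature vectors (rows = patches), e.g. from the
#'   real reference set; flagged (`NA`) rows are ignored.
#' @return per-feature standard deviation (zeros replaced by 1).
#' @export
morph_scaler <- function(feats) {
  s <- apply(feats, 2L, stats::sd, na.rm = TRUE)
  s[!is.finite(s) | s == 0] <- 1
  s
}

#' Standardized Euclidean morphological distance
#'
#' @param f1,f2 length-63 feature vectors.
#' @param scaler per-feature standard deviations from [morph_scaler()]
#'   fitted on the real reference set.
#' @return Euclidean distance between the standardized vectors.
#' @export
morph_distance <- function(f1, f2, scaler) {
  sqrt(sum(((f1 - f2) / scaler)^2))
}

#' Paired morphological distance test
#'
#' For every real patch: the distance to its matched synthetic counterpart
#' is compared with the mean distance to `n_random` other real patches from
#' the same WSI, followed by a one-sided Wilcoxon signed-rank test of
#' matched < baseline. Baseline patches are sampled without replacement when
#' the same-WSI pool is large enough, otherwise with replacement (noted via
#' a message).
#'
#' @param real_feats,synth_feats aligned feature matrices (rows = patches)
#'   from [morph_features()]; rows with `NA` (no nuclei) are dropped in
#'   pairs.
#' @param wsi per-patch WSI/patient labels defining the baseline pools.
#' @param n_random number of baseline patches per real patch (default 100).
#' @param seed integer seed for baseline sampling.
#' @param scaler optional feature scaler; default fitted on `real_feats`.
#' @return list with `mean_matched`, `mean_baseline`, `p_value`, `n_pairs`\n#'   and the per-pair distance vectors `d_matched`, `d_baseline`.
#' @export
paired_morph_test <- function(real_feats, synth_feats, wsi, n_random = 100L,
                              seed = 1L, scaler = NULL) {
  real_feats <- as.matrix(real_feats); synth_feats <- as.matrix(synth_feats)
  ok <- stats::complete.cases(real_feats) & stats::complete.cases(synth_feats)
  if (sum(ok) < 10L) stop("need at least 10 complete pairs, have ", sum(ok))
  real_feats <- real_feats[ok, , drop = FALSE]
  synth_feats <- synth_feats[ok, , drop = FALSE]
  wsi <- as.character(wsi)[ok]
  if (is.null(scaler)) scaler <- morph_scaler(real_feats)
  n <- nrow(real_feats)
  rs <- sweep(real_feats, 2L, scaler, "/")
  ss <- sweep(synth_feats, 2L, scaler, "/")
  d_matched <- sqrt(rowSums((rs - ss)^2))
  d_base <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      pool <- setdiff(which(wsi == wsi[i]), i)
      if (length(pool) == 0L) { d_base[i] <- NA_real_; next }
      replace <- length(pool) < n_random
      j <- sample(pool, n_random, replace = replace)
      diffs <- rs[j, , drop = FALSE] -
        matrix(rs[i, ], length(j), ncol(rs), byrow = TRUE)
      d_base[i] <- mean(sqrt(rowSums(diffs^2)))
    }
  })
  keep <- is.finite(d_base)
  d_matched <- d_matched[keep]; d_base <- d_base[keep]
  if (all(d_matched == d_base)) {
    warning("all paired distances tied; p = 1")
    return(list(mean_matched = mean(d_matched), mean_baseline = mean(d_base),
                p_value = 1, n_pairs = length(d_matched),
                d_matched = d_matched, d_baseline = d_base))
  }
  wt <- suppressWarnings(stats::wilcox.test(d_matched, d_base, paired = TRUE,
                                            alternative = "less"))
  list(mean_matched = mean(d_matched), mean_baseline = mean(d_base),
       p_value = wt$p.value, n_pairs = length(d_matched),
       d_matched = d_matched, d_baseline = d_base)
}

# ---- prediction metrics -----------------------------------------------------

# fast per-marker correlation vectors (no p-values)
marker_correlations <- function(true, pred) {
  m <- ncol(true)
  pe <- sp <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    if (stats::sd(true[, j]) == 0 || stats::sd(pred[, j]) == 0) next
    pe[j] <- stats::cor(true[, j], pred[, j])
    sp[j] <- stats::cor(true[, j], pred[, j], method = "spearman")
  }
  list(pearson = pe, spearman = sp)
}

#' Per-marker prediction performance
#'
#' Pearson and Spearman correlations (with p-values) between true and
#' predicted expression, per marker across spots. Markers with a constant
#' column yield undefined correlations, are recorded as `NA` and excluded
#' from the means (their count is reported).
#'
#' @param true,pred spots x markers matrices.
#' @return list with `per_marker` (data frame), `mean_pearson`,
#'   `mean_spearman`, `sd_pearson`, `sd_spearman`, `n_excluded`.
#' @export
prediction_metrics <- function(true, pred) {
  true <- as.matrix(true); pred <- as.matrix(pred)
  if (!all(dim(true) == dim(pred))) stop("dimension mismatch")
  if (nrow(true) < 3L) stop("need at least 3 spots")
  m <- ncol(true)
  out <- data.frame(marker = if (!is.null(colnames(true))) colnames(true)
                    else paste0("marker", seq_len(m)),
                    pearson_r = NA_real_, pearson_p = NA_real_,
                    spearman_rho = NA_real_, spearman_p = NA_real_)
  for (j in seq_len(m)) {
    if (stats::sd(true[, j]) == 0 || stats::sd(pred[, j]) == 0) next
    ct <- stats::cor.test(true[, j], pred[, j])
    cs <- suppressWarnings(stats::cor.test(true[, j], pred[, j],
                                           method = "spearman"))
    out$pearson_r[j] <- ct$estimate
    out$pearson_p[j] <- ct$p.value
    out$spearman_rho[j] <- cs$estimate
    out$spearman_p[j] <- cs$p.value
  }
  list(per_marker = out,
       mean_pearson = mean(out$pearson_r, na.rm = TRUE),
       mean_spearman = mean(out$spearman_rho, na.rm = TRUE),
       sd_pearson = stats::sd(out$pearson_r, na.rm = TRUE),
       sd_spearman = stats::sd(out$spearman_rho, na.rm = TRUE),
       n_excluded = sum(is.na(out$pearson_r)))
}

# ---- prediction-only baseline -----------------------------------------------

#' Train a prediction-only convolutional baseline
#'
#' A residual CNN regressor (same size-configurable residual down-sampling
#' design family, but trained purely with mean-squared error on (image,
#' expression) pairs — no generator, no adversarial signal). Evaluated under
#' the identical cross-validation protocol as the generative-predictive
#' model.
#'
#' @param dataset transformed `"ouro_dataset"` with patches (a training
#'   fold).
#' @param config an `"ouro_run_config"`.
#' @param epochs training epochs.
#' @param steps_per_epoch optional per-epoch step cap.
#' @param seed integer seed.
#' @return object of class `"ouro_baseline"`.
#' @export
baseline_regressor <- function(dataset, config, epochs = config$epochs,
                               steps_per_epoch = NULL, seed = config$seed) {
  if (is.null(dataset$patches)) stop("dataset has no patches")
  S <- dim(dataset$patches)[1L]
  m <- length(dataset$marker_names)
  arch <- nn_arch(S, n_markers = m, noise_dim = config$noise_dim,
                  base_width = config$base_width)
  net <- init_discriminator(arch, seed + 31L)
  opt <- adam_init(net$params)
  n <- nrow(dataset$expression)
  bs <- config$batch_size
  losses <- numeric(0)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 600L + ep, sample.int(n))
    nb <- ceiling(n / bs)
    if (!is.null(steps_per_epoch)) nb <- min(nb, steps_per_epoch)
    for (b in seq_len(nb)) {
      take <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
      P <- dataset$expression[take, , drop = FALSE]
      I <- patches_model_space(dataset$patches, take)
      fo <- d_forward(net$params, arch, I, want_cache = TRUE)
      L <- loss_expr(P, fo$pred)
      dpred <- 2 * (fo$pred - P) / length(P)
      gr <- d_backward(net$params, arch, fo$cache, numeric(length(take)),
                       dpred)$grads
      upd <- adam_step(net$params, gr, opt, config$learning_rate,
                       beta1 = config$adam_beta1)
      net$params <- upd$params; opt <- upd$state
      step <- step + 1L
      losses[step] <- L
    }
  }
  structure(list(net = net, arch = arch, losses = losses,
                 seed = as.integer(seed)), class = "ouro_baseline")
}

#' Predict expression with the baseline regressor
#' @param object an `"ouro_baseline"`.
#' @param patches `H x W x 3 x n` array in `[0, 1]`.
#' @param ... unused.
#' @return spots x markers prediction matrix.
#' @export
predict.ouro_baseline <- function(object, patches, ...) {
  predict_expression(object$net, patches)
}
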