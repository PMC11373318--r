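# Cropping, embeddings, Frechet distance, nucleus detection, morphometry,
# the paired distance test and prediction metrics.

test_that("center_crop uses half-open axis-centred bounds and composes", {
  img <- array(seq_len(256 * 256 * 3) / (256 * 256 * 3), c(256, 256, 3))
  cr <- center_crop(img, 128)
  expect_equal(dim(cr), c(128L, 128L, 3L))
  expect_equal(cr, img[65:192, 65:192, ])      # rows/cols [64, 192) 0-based
  expect_identical(center_crop(img, 256), img)
  expect_equal(center_crop(center_crop(img, 192), 128),
               center_crop(img, 128))
  expect_error(center_crop(img, 300), "exceeds")
})

test_that("embeddings are deterministic; handcrafted features have closed forms", {
  set.seed(4)
  imgs <- array(runif(16 * 16 * 3 * 5), c(16, 16, 3, 5))
  e1 <- embed_images(imgs, seed = 7)
  e2 <- embed_images(imgs, seed = 7)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(5L, 64L))
  expect_false(identical(e1, embed_images(imgs, seed = 8)))

  # constant-colour image: channel means/quantiles equal the colour, all
  # spreads and gradients are zero
  const <- array(rep(c(0.2, 0.5, 0.9), each = 64), c(8, 8, 3, 1))
  h <- embed_images(const, method = "handcrafted")[1, ]
  expect_equal(h[1:5], c(0.2, 0, 0.2, 0.2, 0.2))
  expect_equal(h[6:10], c(0.5, 0, 0.5, 0.5, 0.5))
  expect_equal(h[11:15], c(0.9, 0, 0.9, 0.9, 0.9))
  expect_equal(h[16:21], rep(0, 6))

  expect_error(embed_images(const, method = "external_pretrained"),
               "download")
})

test_that("embeddings linearly separate structured patches from noise", {
  ds <- small_cohort()
  n <- 50L
  real <- ds$patches[, , , seq_len(n), drop = FALSE]
  set.seed(9)
  noise <- array(runif(32 * 32 * 3 * n), c(32, 32, 3, n))
  emb <- rbind(embed_images(real, seed = 3), embed_images(noise, seed = 3))
  y <- rep(c(1, 0), each = n)
  tr <- c(1:35, n + 1:35); te <- setdiff(seq_len(2 * n), tr)
  keep <- apply(emb[tr, ], 2, sd) > 1e-8 &
    apply(emb[tr[1:35], ], 2, sd) > 1e-8 &
    apply(emb[tr[36:70], ], 2, sd) > 1e-8
  fit <- MASS::lda(emb[tr, keep], grouping = y[tr])
  acc <- mean(predict(fit, emb[te, keep])$class == y[te])
  expect_gt(acc, 0.9)
})

test_that("compute_fid matches the analytic Gaussian Frechet distance", {
  set.seed(11)
  a <- matrix(rnorm(5000), ncol = 1)
  b <- matrix(rnorm(5000, mean = 1), ncol = 1)
  # analytic: (mu diff)^2 + (sd_a - sd_b)^2 = 1
  expect_equal(compute_fid(a, b), 1.0, tolerance = 0.1)
  expect_lt(compute_fid(a, a), 1e-6)

  ma <- matrix(rnorm(600), 200, 3)
  mb <- matrix(rnorm(600), 200, 3) %*% diag(c(1, 2, 0.5))
  expect_equal(compute_fid(ma, mb), compute_fid(mb, ma), tolerance = 1e-8)
  expect_gte(compute_fid(ma, mb), 0)
  expect_error(compute_fid(ma, mb[, 1:2]), "dimensions")
})

test_that("nucleus detection counts well-separated rendered nuclei exactly", {
  cfg <- sim_config(patch_size_px = 64L, k_range = c(7L, 7L),
                    r_range = c(0.05, 0.06), seed = 2L)
  lat <- numeric(38)
  lat[cfg$driver_map[["density"]]] <- -1.5    # generous spacing
  lat[cfg$driver_map[["hema"]]] <- 1          # dark nuclei
  r <- render_patch(lat, cfg, seed = 14L)
  expect_equal(nrow(r$cells), 7L)
  lab <- detect_nuclei(r$img)
  expect_equal(attr(lab, "n"), 7L)
  # masks are disjoint positive-labelled components
  expect_equal(sort(unique(as.vector(lab))), 0:7)

  blank <- array(1, c(64, 64, 3))
  expect_equal(attr(detect_nuclei(blank), "n"), 0L)
})

test_that("morphometry recovers analytic shape values on a rasterized disc", {
  S <- 64L
  img <- array(0.95, c(S, S, 3))
  ys <- matrix(seq_len(S), S, S); xs <- t(ys)
  disc <- (xs - 32)^2 + (ys - 32)^2 <= 10^2
  for (ch in 1:3) {
    v <- img[, , ch]
    v[disc] <- c(0.3, 0.2, 0.5)[ch]
    img[, , ch] <- v
  }
  labels <- matrix(0L, S, S); labels[disc] <- 1L
  f <- morph_features(img, labels = labels)
  expect_length(f, 63L)
  expect_false(attr(f, "flagged"))
  expect_equal(unname(f["area"]), pi * 100, tolerance = 0.05)
  expect_equal(unname(f["equiv_diameter"]), 20, tolerance = 0.05)
  expect_lt(unname(f["eccentricity"]), 0.2)
  expect_gt(unname(f["solidity"]), 0.9)
  expect_equal(unname(f["major_axis"]), 20, tolerance = 0.1)
  expect_gt(unname(f["circularity"]), 0.8)
  # duplicated patch gives identical features
  expect_identical(f, morph_features(img, labels = labels))
})

test_that("mean nuclear area scales ~4x when the radius doubles", {
  base <- sim_config(patch_size_px = 64L, k_range = c(5L, 5L),
                     r_range = c(0.05, 0.05), seed = 2L)
  dbl <- sim_config(patch_size_px = 64L, k_range = c(5L, 5L),
                    r_range = c(0.10, 0.10), seed = 2L)
  lat <- numeric(38); lat[base$driver_map[["hema"]]] <- 1
  area_of <- function(cfg) {
    a <- vapply(1:8, function(s) {
      img <- render_patch(lat, cfg, seed = s)$img
      f <- morph_features(img)
      unname(f["area"])
    }, numeric(1))
    mean(a, na.rm = TRUE)
  }
  ratio <- area_of(dbl) / area_of(base)
  expect_gt(ratio, 2.8)
  expect_lt(ratio, 5.5)
})

test_that("morphological distance is a standardized Euclidean metric", {
  f1 <- c(1, 2, 3); f2 <- c(2, 0, 3); sc <- c(1, 2, 0.5)
  oracle <- sqrt(((1 - 2) / 1)^2 + ((2 - 0) / 2)^2 + 0)
  expect_equal(morph_distance(f1, f2, sc), oracle)
  expect_equal(morph_distance(f1, f1, sc), 0)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(5); b <- rnorm(5); c <- rnorm(5); s <- runif(5, 0.5, 2)
    expect_equal(morph_distance(a, b, s), morph_distance(b, a, s))
    expect_lte(morph_distance(a, c, s),
               morph_distance(a, b, s) + morph_distance(b, c, s) + 1e-12)
  }
  feats <- matrix(rnorm(60), 12, 5)
  sc2 <- morph_scaler(feats)
  expect_equal(sc2, apply(feats, 2, sd))
})

test_that("paired test: perfect synthesis is significant, and the signed-rank
           p matches an exact enumeration oracle", {
  set.seed(6)
  n <- 12L
  real <- matrix(rnorm(n * 5), n, 5)
  res <- paired_morph_test(real, real + rnorm(n * 5, sd = 0.01),
                           wsi = rep("w", n), n_random = 20, seed = 1)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$mean_matched, res$mean_baseline)

  synth <- real + matrix(rnorm(n * 5, sd = 1.0), n, 5)
  res2 <- paired_morph_test(real, synth, wsi = rep("w", n), n_random = 20,
                            seed = 1)
  # exact one-sided signed-rank p by enumerating all 2^n sign patterns
  d <- res2$d_matched - res2$d_baseline
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  stats_all <- as.matrix(signs) %*% r
  oracle_p <- mean(stats_all <= obs)
  expect_equal(res2$p_value, oracle_p, tolerance = 1e-10)

  expect_error(paired_morph_test(real[1:5, ], synth[1:5, ], rep("w", 5)),
               "10")
})

test_that("prediction metrics match rank-based oracles and handle constants", {
  set.seed(7)
  true <- matrix(rnorm(30), 10, 3)
  expect_equal(prediction_metrics(true, true)$per_marker$pearson_r,
               rep(1, 3))
  expect_equal(prediction_metrics(true, -true)$per_marker$pearson_r,
               rep(-1, 3))
  expect_equal(prediction_metrics(true, true)$per_marker$spearman_rho,
               rep(1, 3))

  # 6-point hand example vs explicit rank-correlation oracle
  x <- c(3, 1, 4, 1.5, 9, 2.6); y <- c(2, 0.5, 5, 1, 7, 2)
  pm <- prediction_metrics(cbind(x), cbind(y))
  rx <- rank(x); ry <- rank(y)
  oracle_rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(pm$per_marker$spearman_rho[1], oracle_rho)
  oracle_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pm$per_marker$pearson_r[1], oracle_r)

  # constant predicted column: excluded from the means, counted
  pred <- cbind(y, 0 * y)
  pm2 <- prediction_metrics(cbind(x, x), pred)
  expect_true(is.na(pm2$per_marker$pearson_r[2]))
  expect_equal(pm2$n_excluded, 1L)
  expect_equal(pm2$mean_pearson, oracle_r)
})

test_that("the baseline regressor trains and predicts the right shape", {
  ds <- tiny_train_dataset()
  cfg <- tiny_config(markers = ds$marker_names)
  bl <- baseline_regressor(ds, cfg, epochs = 4L, seed = 2L)
  pred <- predict(bl, ds$patches)
  expect_equal(dim(pred), dim(ds$expression))
  # training reduced the regression loss
  k <- length(bl$losses)
  expect_lt(mean(bl$losses[(k - 3):k]), bl$losses[1])
  # and fits its training data better than an untrained twin
  bl0 <- baseline_regressor(ds, cfg, epochs = 1L, steps_per_epoch = 0L,
                            seed = 2L)
  expect_lt(loss_expr(ds$expression, pred),
            loss_expr(ds$expression, predict(bl0, ds$patches)))
})
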