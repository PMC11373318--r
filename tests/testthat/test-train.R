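# Loss terms against brute-force oracles, the adversarial values, the update
# schedule and the cross-validation bookkeeping.

test_that("image loss equals the brute-force mean absolute error", {
  a <- array(-1, c(4, 4, 1, 3)); b <- array(1, c(4, 4, 1, 3))
  expect_equal(loss_image(a, a), 0)
  expect_equal(loss_image(a, b), 2)      # maximal for [-1, 1] images
  set.seed(1)
  x <- array(runif(48, -1, 1), c(4, 4, 1, 3))
  y <- array(runif(48, -1, 1), c(4, 4, 1, 3))
  oracle <- sum(abs(x - y)) / 48
  expect_equal(loss_image(x, y), oracle)
  expect_error(loss_image(x, array(0, c(2, 2, 1, 3))), "shapes")
})

test_that("expression loss equals the brute-force mean squared error", {
  expect_equal(loss_expr(c(1, 2), c(1, 2)), 0)
  expect_equal(loss_expr(c(0, 0), c(1, -1)), 1)
  set.seed(2)
  p <- rnorm(38); q <- rnorm(38)
  oracle <- sum((p - q)^2) / 38
  expect_equal(loss_expr(p, q), oracle)
  expect_error(loss_expr(1:3, 1:4), "length")
})

test_that("adversarial loss matches closed forms and limits", {
  # maximally uncertain discriminator: both logits 0 -> 2 log 2
  l <- loss_adversarial(0, 0)
  expect_equal(l$L_GAN_d, 2 * log(2), tolerance = 1e-12)
  expect_equal(l$L_GAN_g, log(2), tolerance = 1e-12)

  # perfect discriminator limit -> loss 0
  l2 <- loss_adversarial(40, -40)
  expect_lt(l2$L_GAN_d, 1e-10)

  # brute-force oracle on random logits
  set.seed(3)
  dr <- rnorm(16); df <- rnorm(16)
  s <- function(x) 1 / (1 + exp(-x))
  oracle_d <- -(mean(log(s(dr))) + mean(log(1 - s(df))))
  expect_equal(loss_adversarial(dr, df)$L_GAN_d, oracle_d,
               tolerance = 1e-10)
  expect_equal(loss_adversarial(dr, df)$L_GAN_g, -mean(log(s(df))),
               tolerance = 1e-10)
  expect_equal(loss_adversarial(dr, df, "saturating")$L_GAN_g,
               mean(log(1 - s(df))), tolerance = 1e-10)

  # both generator surrogates push d_fake in the same direction
  h <- 1e-6
  for (v in c(-2, 0, 2)) {
    g_ns <- (loss_adversarial(0, v + h)$L_GAN_g -
               loss_adversarial(0, v - h)$L_GAN_g) / (2 * h)
    g_sat <- (loss_adversarial(0, v + h, "saturating")$L_GAN_g -
                loss_adversarial(0, v - h, "saturating")$L_GAN_g) / (2 * h)
    expect_equal(sign(g_ns), sign(g_sat))
  }
})

test_that("loss breakdown totals equal the lambda-weighted sums", {
  ds <- tiny_train_dataset()
  cfg <- tiny_config()
  arch <- tiny_arch()
  gen <- init_generator(arch, 1L)
  disc <- init_discriminator(arch, 2L)
  batch <- list(P = ds$expression[1:8, ],
                I = aperm(ds$patches[, , , 1:8] * 2 - 1, c(1, 2, 4, 3)))
  for (k in 1:3) {
    res <- train_step(batch, gen, disc, cfg, seed = k)
    gen <- res$gen; disc <- res$disc
    L <- res$losses
    expect_equal(L$total_g,
                 L$L_I + cfg$lambda1 * L$L_r + cfg$lambda3 * L$L_GAN_g,
                 tolerance = 1e-6)
    expect_equal(L$total_d,
                 cfg$lambda2 * L$L_p + cfg$lambda3 * L$L_GAN_d,
                 tolerance = 1e-6)
    expect_true(all(c(L$L_I, L$L_r, L$L_p) >= 0))
  }
})

test_that("training steps are bit-reproducible given the seeds", {
  ds <- tiny_train_dataset()
  cfg <- tiny_config()
  arch <- tiny_arch()
  run <- function() {
    gen <- init_generator(arch, 1L)
    disc <- init_discriminator(arch, 2L)
    batch <- list(P = ds$expression[1:8, ],
                  I = aperm(ds$patches[, , , 1:8] * 2 - 1, c(1, 2, 4, 3)))
    for (k in 1:3) {
      res <- train_step(batch, gen, disc, cfg, seed = k)
      gen <- res$gen; disc <- res$disc
    }
    list(g = gen$params, d = disc$params)
  }
  expect_identical(run(), run())
})

test_that("a pure reconstruction objective descends the image loss", {
  ds <- tiny_train_dataset()
  cfg <- run_config(patch_size_px = 16L, spot_size_px = 8L, noise_dim = 8L,
                    batch_size = 8L, lambda1 = 0, lambda2 = 0, lambda3 = 0,
                    marker_names = ds$marker_names, base_width = 4L)
  arch <- tiny_arch(markers = ncol(ds$expression))
  gen <- init_generator(arch, 3L)
  disc <- init_discriminator(arch, 4L)
  batch <- list(P = ds$expression[1:8, ],
                I = aperm(ds$patches[, , , 1:8] * 2 - 1, c(1, 2, 4, 3)))
  first <- NULL
  for (k in 1:50) {
    res <- train_step(batch, gen, disc, cfg, seed = 100L + k)
    gen <- res$gen; disc <- res$disc
    if (k == 1) first <- res$losses$L_I
  }
  expect_lt(res$losses$L_I, first)
})

test_that("fit_gan bookkeeping: steps per epoch and validation history", {
  ds <- tiny_train_dataset()
  cfg <- tiny_config(markers = ds$marker_names)
  fit <- fit_gan(ds, cfg, epochs = 1L, val_fraction = 0.1, seed = 5L)
  # 32 spots minus max(2, 3) validation = 29 -> ceil(29 / 8) = 4 steps
  expect_equal(nrow(fit$history), 4L)
  expect_length(fit$val_r, 1L)
  expect_equal(fit$best_epoch, 1L)
  expect_s3_class(fit$gen, "generator_params")

  # seeds logged and sufficient to re-run identically
  fit2 <- fit_gan(ds, cfg, epochs = 1L, val_fraction = 0.1, seed = 5L)
  expect_identical(fit$gen$params, fit2$gen$params)
  expect_equal(fit$seed, 5L)
})

test_that("leave-one-patient-out folds partition the data exactly", {
  ds <- small_cohort()
  cfg <- run_config(patch_size_px = 32L, spot_size_px = 16L,
                    marker_names = ds$marker_names, base_width = 4L)
  # stub model: no training, predicts zeros; only the protocol is under test
  stub_fit <- function(tr, cfg, seed, ...) {
    expect_true(tr$transformed)
    list(n = nrow(tr$expression))
  }
  stub_pred <- function(fit, te)
    matrix(rnorm(nrow(te$expression) * 38), ncol = 38)
  set.seed(1)
  res <- loo_cv(ds, cfg, fit_fun = stub_fit, predict_fun = stub_pred)
  expect_length(res$folds, 2L)
  all_idx <- sort(unname(unlist(lapply(res$folds, `[[`, "test_idx"))))
  expect_equal(all_idx, seq_len(nrow(ds$expression)))
  expect_equal(length(intersect(res$folds[[1]]$test_idx,
                                res$folds[[2]]$test_idx)), 0L)
  # each fold's test set is exactly one patient
  for (f in res$folds)
    expect_length(unique(ds$patient[f$test_idx]), 1L)
})

test_that("fold preprocessing never uses held-out statistics", {
  ds <- small_cohort()
  tr_i <- which(ds$patient == unique(ds$patient)[1])
  te_i <- which(ds$patient != unique(ds$patient)[1])
  prep <- ouroboros:::preprocess_fold(ds, tr_i, te_i)
  # recompute the transform from training rows only: must agree exactly
  ft <- suppressWarnings(
    fit_transform_expression(ds$expression[tr_i, , drop = FALSE]))
  expect_identical(prep$state$mu, ft$state$mu)
  expect_identical(prep$state$min_positive, ft$state$min_positive)
  expect_equal(apply_transform(ds$expression[te_i[1], , drop = FALSE],
                               ft$state)[1, ],
               ouroboros:::apply_transform(
                 ds$expression[te_i[1], , drop = FALSE], prep$state)[1, ])
})
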