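# Loss terms and adversarial training.
#
# The composite objective L = L_I + lambda1 L_r + lambda2 L_p + lambda3 L_GAN
# mixes terms that depend on different players; each update minimises only
# the terms its parameters can influence:
#   generator:      L_I + lambda1 * L_r + lambda3 * L_GAN_g
#   discriminator:  lambda2 * L_p + lambda3 * L_GAN_d
# L_r back-propagates through the (frozen) discriminator into the generator.

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Image reconstruction loss (mean absolute error)
#'
#' @param real,generated same-shape image arrays in `[-1, 1]`.
#' @return mean over all pixels and channels of `|real - generated|`.
#' @export
loss_image <- function(real, generated) {
  if (!identical(dim(real), dim(generated)))
    stop("image shapes differ: ", paste(dim(real), collapse = "x"), " vs ",
         paste(dim(generated), collapse = "x"))
  mean(abs(real - generated))
}

#' Expression reconstruction / prediction loss (mean squared error)
#'
#' Used both for predictions from generated images (L_r) and from real
#' images (L_p).
#'
#' @param p true expression vector or matrix.
#' @param p_hat predicted expression, same shape.
#' @return mean of squared differences.
#' @export
loss_expr <- function(p, p_hat) {
  if (length(p) != length(p_hat))
    stop("expression lengths differ: ", length(p), " vs ", length(p_hat))
  mean((p - p_hat)^2)
}

#' Adversarial loss values from realism logits
#'
#' With `s = sigmoid`, the discriminator maximises
#' `log s(d_real) + log(1 - s(d_fake))`; its loss is the negative of that,
#' so a maximally uncertain discriminator (both logits 0) scores
#' `2 log 2`. The generator either minimises `log(1 - s(d_fake))`
#' (`"saturating"`, the min-max form) or the standard non-saturating
#' surrogate `-log s(d_fake)` (default). Both are evaluated in
#' log-sum-exp-stabilised form.
#'
#' @param d_real,d_fake realism logits for real and generated images.
#' @param generator_loss surrogate used for the generator part.
#' @return list with `L_GAN_d` and `L_GAN_g` (batch means).
#' @export
loss_adversarial <- function(d_real, d_fake,
                             generator_loss = c("non_saturating",
                                                "saturating")) {
  generator_loss <- match.arg(generator_loss)
  L_d <- mean(softplus(-d_real)) + mean(softplus(d_fake))
  L_g <- if (generator_loss == "non_saturating") mean(softplus(-d_fake))
  else -mean(softplus(d_fake))
  list(L_GAN_d = L_d, L_GAN_g = L_g)
}

loss_breakdown <- function(L_I, L_r, L_p, L_GAN_g, L_GAN_d, cfg) {
  list(L_I = L_I, L_r = L_r, L_p = L_p, L_GAN_g = L_GAN_g,
       L_GAN_d = L_GAN_d,
       total_g = L_I + cfg$lambda1 * L_r + cfg$lambda3 * L_GAN_g,
       total_d = cfg$lambda2 * L_p + cfg$lambda3 * L_GAN_d)
}

# draw a standard-normal noise matrix
draw_noise <- function(n, noise_dim) matrix(stats::rnorm(n * noise_dim), n)

#' One adversarial training step
#'
#' One discriminator update (minimising `lambda2 L_p + lambda3 L_GAN_d` on
#' the batch) followed by one generator update (minimising
#' `L_I + lambda1 L_r + lambda3 L_GAN_g`), with fresh noise per item and
#' Adam as configured. Optimiser state lives inside the parameter objects,
#' so repeated calls continue the same optimisation.
#'
#' @param batch list with `P` (n x markers transformed expression) and `I`
#'   (`H x W x n x 3` images in `[-1, 1]`).
#' @param gen a `"generator_params"` object.
#' @param disc a `"discriminator_params"` object.
#' @param config an `"ouro_run_config"`.
#' @param seed integer seed for this step's noise draws.
#' @param generator_loss adversarial surrogate, see [loss_adversarial()].
#' @return list with updated `gen`, `disc` and the `losses` breakdown; the
#'   breakdown totals equal the lambda-weighted sums of the parts.
#' @export
train_step <- function(batch, gen, disc, config, seed = 1L,
                       generator_loss = c("non_saturating", "saturating")) {
  generator_loss <- match.arg(generator_loss)
  arch_g <- gen$arch; arch_d <- disc$arch
  P <- batch$P; I <- batch$I
  n <- nrow(P); m <- ncol(P)
  if (is.null(gen$opt)) gen$opt <- adam_init(gen$params)
  if (is.null(disc$opt)) disc$opt <- adam_init(disc$params)
  l1 <- config$lambda1; l2 <- config$lambda2; l3 <- config$lambda3

  z <- with_seed(seed, draw_noise(n, arch_g$noise_dim))

  # one generator forward serves both updates (fresh z per item per step)
  gw <- g_forward(gen$params, arch_g, P, z, want_cache = TRUE)
  fake <- gw$img

  # ---- discriminator update (real and fake as one batch) --------------------
  comb <- array(0, c(dim(I)[1:2], 2L * n, 3L))
  comb[, , seq_len(n), ] <- I
  comb[, , n + seq_len(n), ] <- fake
  fc <- d_forward(disc$params, arch_d, comb, want_cache = TRUE)
  sr <- fc$score[seq_len(n)]; sf <- fc$score[n + seq_len(n)]
  pr <- fc$pred[seq_len(n), , drop = FALSE]
  L_p <- loss_expr(P, pr)
  adv <- loss_adversarial(sr, sf, generator_loss)

  ds_c <- c(l3 * (stats::plogis(sr) - 1) / n, l3 * stats::plogis(sf) / n)
  dp_c <- rbind(l2 * 2 * (pr - P) / (n * m), matrix(0, n, m))
  gr_d <- d_backward(disc$params, arch_d, fc$cache, ds_c, dp_c)$grads
  upd <- adam_step(disc$params, gr_d, disc$opt, config$learning_rate,
                   beta1 = config$adam_beta1)
  disc$params <- upd$params; disc$opt <- upd$state

  # ---- generator update (against the updated discriminator) ----------------
  fo <- d_forward(disc$params, arch_d, fake, want_cache = TRUE)
  L_I <- loss_image(I, fake)
  L_r <- loss_expr(P, fo$pred)
  adv_g <- loss_adversarial(sr, fo$score, generator_loss)

  dimg <- -sign(I - fake) / length(I)
  dscore <- if (generator_loss == "non_saturating")
    l3 * (stats::plogis(fo$score) - 1) / n
  else -l3 * stats::plogis(fo$score) / n
  dpred <- l1 * 2 * (fo$pred - P) / (n * m)
  din <- d_backward(disc$params, arch_d, fo$cache, dscore, dpred,
                    want_dx = TRUE, want_dw = FALSE)$dx
  gr_g <- g_backward(gen$params, arch_g, gw$cache, dimg + din)
  upd <- adam_step(gen$params, gr_g, gen$opt, config$learning_rate,
                   beta1 = config$adam_beta1)
  gen$params <- upd$params; gen$opt <- upd$state

  if (!all(vapply(c(L_I, L_r, L_p, adv$L_GAN_d, adv_g$L_GAN_g), is.finite,
                  logical(1))))
    stop("non-finite loss encountered: L_I=", L_I, " L_r=", L_r, " L_p=",
         L_p, " L_GAN_d=", adv$L_GAN_d, " L_GAN_g=", adv_g$L_GAN_g)
  list(gen = gen, disc = disc,
       losses = loss_breakdown(L_I, L_r, L_p, adv_g$L_GAN_g, adv$L_GAN_d,
                               config))
}

# dataset -> model-space image batch (H, W, n, 3)
patches_model_space <- function(patches, idx) {
  aperm(patch_to_model(patches[, , , idx, drop = FALSE]), c(1L, 2L, 4L, 3L))
}

#' Train the generative-predictive model on one training set
#'
#' Runs `epochs` passes of [train_step()] over shuffled mini-batches and
#' checkpoints the epoch with the best validation mean Pearson correlation
#' of the discriminator prediction head (a small validation split is carved
#' from the training spots).
#'
#' @param dataset an `"ouro_dataset"` with patches, in transformed
#'   (and batch-corrected) expression space.
#' @param config an `"ouro_run_config"` whose `patch_size_px` matches the
#'   dataset patches.
#' @param epochs number of epochs (default from `config`).
#' @param steps_per_epoch optional cap on steps per epoch.
#' @param val_fraction fraction of spots held out for epoch checkpointing.
#' @param seed integer seed controlling shuffling, noise and initialisation.
#' @param generator_loss see [loss_adversarial()].
#' @param verbose print per-epoch progress.
#' @return list with `gen`, `disc`, `history` (per-step loss data frame),
#'   `val_r` (per-epoch validation mean Pearson), `best_epoch`, `seed`.
#' @export
fit_gan <- function(dataset, config, epochs = config$epochs,
                    steps_per_epoch = NULL, val_fraction = 0.1,
                    seed = config$seed,
                    generator_loss = c("non_saturating", "saturating"),
                    verbose = FALSE) {
  generator_loss <- match.arg(generator_loss)
  if (is.null(dataset$patches)) stop("dataset has no patches")
  if (!dataset$transformed)
    warning("dataset expression is not flagged as transformed")
  n <- nrow(dataset$expression)
  if (n < 2L) stop("empty or degenerate training fold")
  S <- dim(dataset$patches)[1L]
  if (S != config$patch_size_px)
    stop("config patch_size_px (", config$patch_size_px,
         ") does not match dataset patches (", S, ")")
  m <- length(dataset$marker_names)
  arch <- nn_arch(S, n_markers = m, noise_dim = config$noise_dim,
                  base_width = config$base_width)
  gen <- init_generator(arch, seed)
  disc <- init_discriminator(arch, seed + 1L)

  n_val <- max(2L, min(floor(n * val_fraction), 200L))
  idx <- with_seed(seed + 2L, sample.int(n))
  val_idx <- idx[seq_len(n_val)]
  tr_idx <- idx[-seq_len(n_val)]
  Pval <- dataset$expression[val_idx, , drop = FALSE]
  Ival <- dataset$patches[, , , val_idx, drop = FALSE]

  bs <- config$batch_size
  hist <- list()
  val_r <- numeric(epochs)
  best <- list(r = -Inf, gen = NULL, disc = NULL, epoch = 0L)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + 1000L + ep, sample(tr_idx))
    nb <- ceiling(length(ord) / bs)
    if (!is.null(steps_per_epoch)) nb <- min(nb, steps_per_epoch)
    for (b in seq_len(nb)) {
      take <- ord[((b - 1L) * bs + 1L):min(b * bs, length(ord))]
      batch <- list(P = dataset$expression[take, , drop = FALSE],
                    I = patches_model_space(dataset$patches, take))
      step <- step + 1L
      res <- train_step(batch, gen, disc, config,
                        seed = seed + 10000L + step,
                        generator_loss = generator_loss)
      gen <- res$gen; disc <- res$disc
      hist[[step]] <- c(epoch = ep, step = step, unlist(res$losses))
    }
    pv <- predict_expression(disc, Ival)
    rr <- marker_correlations(Pval, pv)$pearson
    val_r[ep] <- mean(rr, na.rm = TRUE)
    if (verbose)
      message(sprintf("epoch %d/%d  val mean r = %.3f", ep, epochs,
                      val_r[ep]))
    if (val_r[ep] > best$r)
      best <- list(r = val_r[ep], gen = gen, disc = disc, epoch = ep)
  }
  list(gen = best$gen, disc = best$disc,
       history = as.data.frame(do.call(rbind, hist)),
       val_r = val_r, best_epoch = best$epoch, seed = as.integer(seed))
}

# discriminator prediction head over a [0,1]-space patch stack (H, W, 3, n)
predict_expression <- function(disc, patches) {
  x <- patches_model_space(patches, seq_len(dim(patches)[4L]))
  out <- matrix(NA_real_, dim(x)[3L], disc$arch$n_markers)
  bs <- 32L
  for (b in seq_len(ceiling(dim(x)[3L] / bs))) {
    take <- (((b - 1L) * bs + 1L):min(b * bs, dim(x)[3L]))
    out[take, ] <- d_forward(disc$params, disc$arch,
                             x[, , take, , drop = FALSE])$pred
  }
  out
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: the model trains on all other patients and is
#' evaluated on the held-out one. The expression transform and the batch
#' correction are estimated on training patients only and applied to the
#' held-out patient through their fitted states (no test leakage).
#'
#' @param dataset an `"ouro_dataset"` in raw expression space with patches.
#' @param config an `"ouro_run_config"`.
#' @param fit_fun function `(train_dataset, config, seed)` returning a
#'   fitted object; defaults to [fit_gan()].
#' @param predict_fun function `(fit, test_dataset)` returning a
#'   spots x markers prediction matrix; defaults to the discriminator
#'   prediction head.
#' @param seed integer seed.
#' @param folds optional subset of patients to run (default all).
#' @param ... passed to `fit_fun`.
#' @return list of per-fold results (`patient`, `test_idx`, `metrics`,
#'   `fit`, `test_dataset`) plus aggregated per-marker means.
#' @export
loo_cv <- function(dataset, config, fit_fun = NULL, predict_fun = NULL,
                   seed = config$seed, folds = NULL, ...) {
  pats <- unique(dataset$patient)
  if (length(pats) < 2L) stop("leave-one-patient-out needs >= 2 patients")
  if (is.null(fit_fun))
    fit_fun <- function(tr, cfg, seed, ...) fit_gan(tr, cfg, seed = seed, ...)
  if (is.null(predict_fun))
    predict_fun <- function(fit, te) predict_expression(fit$disc, te$patches)
  if (is.null(folds)) folds <- seq_along(pats)
  out <- list()
  for (k in folds) {
    pat <- pats[k]
    te_i <- which(dataset$patient == pat)
    tr_i <- which(dataset$patient != pat)
    if (length(te_i) == 0L) {
      warning("patient ", pat, " has zero spots; fold skipped")
      next
    }
    prep <- preprocess_fold(dataset, tr_i, te_i)
    fit <- fit_fun(prep$train, config, seed + k, ...)
    pred <- predict_fun(fit, prep$test)
    metrics <- prediction_metrics(prep$test$expression, pred)
    out[[as.character(pat)]] <- list(patient = pat, test_idx = te_i,
                                     metrics = metrics, fit = fit,
                                     test_dataset = prep$test,
                                     prediction = pred)
  }
  mm <- lapply(out, function(f) f$metrics$per_marker$pearson_r)
  agg <- if (length(mm)) rowMeans(do.call(cbind, mm), na.rm = TRUE) else NULL
  list(folds = out, mean_pearson_per_marker = agg)
}

# transform + batch-correct a train/test split without leakage
preprocess_fold <- function(dataset, tr_i, te_i) {
  ft <- fit_transform_expression(dataset$expression[tr_i, , drop = FALSE])
  tr_x <- ft$transformed
  te_x <- apply_transform(dataset$expression[te_i, , drop = FALSE], ft$state)
  tr_x <- correct_batches(tr_x, dataset$patient[tr_i])
  te_x <- center_scale_new_batch(te_x, tr_x)
  tr <- dataset[tr_i]; te <- dataset[te_i]
  tr$expression <- tr_x; tr$transformed <- TRUE
  te$expression <- te_x; te$transformed <- TRUE
  list(train = tr, test = te, state = ft$state)
}

# align a held-out batch to the corrected training distribution:
# location/scale moment matching per marker (the held-out batch's own
# moments may be used — they involve no training labels)
center_scale_new_batch <- function(x_new, x_ref) {
  mu_n <- colMeans(x_new); sd_n <- apply(x_new, 2L, stats::sd)
  mu_r <- colMeans(x_ref); sd_r <- apply(x_ref, 2L, stats::sd)
  sd_n[sd_n == 0] <- 1
  scaled <- sweep(x_new, 2L, mu_n, "-")
  scaled <- sweep(scaled, 2L, sd_r / sd_n, "*")
  sweep(scaled, 2L, mu_r, "+")
}
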