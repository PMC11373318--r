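# User-facing modelling interface: one fitting function returning a classed
# object with the usual methods.

#' Fit the generative-predictive model
#'
#' Takes a raw spot dataset (paired expression and patches), applies the
#' zero-aware log/z transform and empirical-Bayes batch correction, trains
#' the conditional GAN and returns a fitted model object. Preprocessing
#' states are stored so new data can be mapped consistently.
#'
#' @param dataset an `"ouro_dataset"` in raw expression space with patches.
#' @param config an `"ouro_run_config"`; its `patch_size_px` must match the
#'   dataset patches.
#' @param epochs training epochs (default from `config`).
#' @param correct_batches apply batch correction across patients (default
#'   TRUE when more than one patient is present).
#' @param seed integer seed.
#' @param ... passed to [fit_gan()] (`steps_per_epoch`, `val_fraction`,
#'   `generator_loss`, `verbose`).
#' @return an object of class `"ouroboros"`.
#' @export
ouroboros_fit <- function(dataset, config, epochs = config$epochs,
                          correct_batches = TRUE, seed = config$seed, ...) {
  if (is.null(dataset$patches)) stop("dataset has no patches")
  if (dataset$transformed)
    stop("expected raw expression; dataset is already transformed")
  ft <- fit_transform_expression(dataset$expression)
  x <- ft$transformed
  did_bc <- correct_batches && length(unique(dataset$patient)) > 1L
  if (did_bc) x <- correct_batches(x, dataset$patient)
  tds <- dataset
  tds$expression <- x
  tds$transformed <- TRUE
  fit <- fit_gan(tds, config, epochs = epochs, seed = seed, ...)
  structure(list(gen = fit$gen, disc = fit$disc, history = fit$history,
                 val_r = fit$val_r, best_epoch = fit$best_epoch,
                 transform_state = ft$state, batch_corrected = did_bc,
                 config = config, marker_names = dataset$marker_names,
                 train_expression = x, train_patient = dataset$patient,
                 seed = as.integer(seed)),
            class = "ouroboros")
}

#' @export
print.ouroboros <- function(x, ...) {
  cat("Generative-predictive expression/histology model\n")
  cat(sprintf("  patch %d px, %d markers, %d training spots (%d patients)\n",
              x$gen$arch$patch, length(x$marker_names),
              nrow(x$train_expression), length(unique(x$train_patient))))
  cat(sprintf("  best epoch %d (validation mean Pearson r = %.3f)\n",
              x$best_epoch, max(x$val_r)))
  invisible(x)
}

#' @export
summary.ouroboros <- function(object, ...) {
  h <- object$history
  last <- h[nrow(h), ]
  out <- list(
    n_spots = nrow(object$train_expression),
    n_markers = length(object$marker_names),
    patch_px = object$gen$arch$patch,
    n_params_gen = n_params(object$gen),
    n_params_disc = n_params(object$disc),
    steps = nrow(h),
    final_losses = last[c("L_I", "L_r", "L_p", "L_GAN_g", "L_GAN_d")],
    val_r = object$val_r, best_epoch = object$best_epoch,
    batch_corrected = object$batch_corrected)
  class(out) <- "summary.ouroboros"
  out
}

#' @export
print.summary.ouroboros <- function(x, ...) {
  cat(sprintf("Fitted on %d spots x %d markers (%d px patches)\n",
              x$n_spots, x$n_markers, x$patch_px))
  cat(sprintf("  generator %s / discriminator %s parameters, %d steps\n",
              format(x$n_params_gen, big.mark = ","),
              format(x$n_params_disc, big.mark = ","), x$steps))
  cat("  validation mean Pearson r by epoch:",
      paste(sprintf("%.3f", x$val_r), collapse = " "), "\n")
  cat("  best epoch:", x$best_epoch, "\n")
  invisible(x)
}

#' Predict expression from image patches
#'
#' Runs the discriminator prediction head; output is in transformed
#' expression space (the model's native space).
#'
#' @param object an `"ouroboros"` fit.
#' @param newdata an `"ouro_dataset"` with patches, or an `H x W x 3 x n`
#'   patch array in `[0, 1]`.
#' @param ... unused.
#' @return spots x markers matrix of predicted expression.
#' @export
predict.ouroboros <- function(object, newdata, ...) {
  patches <- if (inherits(newdata, "ouro_dataset")) newdata$patches
  else newdata
  if (length(dim(patches)) == 3L)
    patches <- array(patches, c(dim(patches), 1L))
  out <- predict_expression(object$disc, patches)
  colnames(out) <- object$marker_names
  out
}

#' Generate patches from expression vectors
#'
#' The `simulate` method of the fitted model: draws seeded noise and renders
#' one patch per supplied expression vector (recycled `nsim` times when a
#' single vector is given).
#'
#' @param object an `"ouroboros"` fit.
#' @param nsim number of images per expression vector.
#' @param seed integer seed for the noise draws.
#' @param expression matrix (rows = spots) or single vector in transformed
#'   space; defaults to the training expression.
#' @param ... unused.
#' @return `H x W x 3 x n` array in `[0, 1]`.
#' @export
simulate.ouroboros <- function(object, nsim = 1, seed = 1L,
                               expression = NULL, ...) {
  if (is.null(expression))
    expression <- object$train_expression
  if (is.null(dim(expression))) expression <- matrix(expression, 1L)
  P <- expression[rep(seq_len(nrow(expression)), each = nsim), ,
                  drop = FALSE]
  Z <- with_seed(seed, draw_noise(nrow(P), object$gen$arch$noise_dim))
  model_to_patch(generate(object$gen, P, Z))
}

#' Prediction-head residuals
#'
#' Residuals `true - predicted` in transformed expression space. Patches are
#' not stored inside the fit, so the dataset (or a patch stack aligned with
#' the training expression) must be supplied.
#'
#' @param object an `"ouroboros"` fit.
#' @param newdata an `"ouro_dataset"` with patches, or an `H x W x 3 x n`
#'   array aligned with `object$train_expression`.
#' @param ... unused.
#' @return spots x markers residual matrix.
#' @export
residuals.ouroboros <- function(object, newdata, ...) {
  if (missing(newdata))
    stop("patches are not stored in the fit; pass the dataset: ",
         "residuals(object, dataset)")
  pred <- predict(object, newdata)
  truth <- if (inherits(newdata, "ouro_dataset") && newdata$transformed)
    newdata$expression else object$train_expression
  if (nrow(truth) != nrow(pred))
    stop("newdata does not align with the stored training expression")
  truth - pred
}

#' Plot training loss curves
#' @param x an `"ouroboros"` fit.
#' @param ... passed to [graphics::matplot()].
#' @return invisibly, the history data frame.
#' @export
plot.ouroboros <- function(x, ...) {
  h <- x$history
  cols <- c("L_I", "L_r", "L_p")
  graphics::matplot(h$step, h[, cols], type = "l", lty = 1,
                    xlab = "step", ylab = "loss", ...)
  graphics::legend("topright", legend = c("L_I", "L_r", "L_p"), col = 1:3,
                   lty = 1, bty = "n")
  invisible(h)
}

#' Model coefficients (trainable parameter collections)
#' @param object an `"ouroboros"` fit.
#' @param ... unused.
#' @return list with `generator` and `discriminator` named parameter lists.
#' @export
coef.ouroboros <- function(object, ...) {
  list(generator = object$gen$params, discriminator = object$disc$params)
}
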