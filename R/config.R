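# Run configuration: hyperparameters of the generative-predictive pipeline.

#' Default 38-marker Hyperion-style panel
#'
#' Marker names used when none are supplied; the first entries include the
#' structural and nuclear markers commonly measured on glioblastoma panels.
#' @return character vector of length 38.
#' @export
default_marker_names <- function() {
  c("SMAa", "CDK4", "NESTIN", "DNA1", "DNA3", "CD68", "CD74", "IBA1",
    "P2RY12", "cMYC", "MET", "SOX2", "SOX10", "GFAP", "CD3", "CD4",
    "CD8a", "CD20", "CD45", "CD11b", "CD31", "CD56", "Ki67", "pERK",
    "pS6", "EGFR", "PDGFRA", "OLIG2", "TMEM119", "CD163", "HLADR", "VIM",
    "PTEN", "p53", "ATRX", "IDH1", "CD44", "CD133")
}

#' Create a validated run configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 1e-4 and first-moment decay 0.5, batch size 16, loss weights
#' `lambda1 = 1`, `lambda2 = 1`, `lambda3 = 0.01`, 256-px patches centred on
#' 128-px spots, 128-dimensional noise and a 38-marker panel.
#'
#' @param patch_size_px side of the context patch in pixels (even).
#' @param spot_size_px side of the central spot in pixels (even,
#'   `<= patch_size_px`).
#' @param noise_dim generator noise dimension.
#' @param lambda1,lambda2,lambda3 non-negative weights of the expression
#'   reconstruction, expression prediction and adversarial loss terms.
#' @param learning_rate positive Adam learning rate.
#' @param adam_beta1 Adam first-moment decay in `[0, 1)`.
#' @param batch_size positive integer batch size.
#' @param epochs positive integer number of training epochs.
#' @param seed integer seed.
#' @param marker_names ordered, unique marker names.
#' @param fid_embedding image embedding used for Frechet-distance evaluation;
#'   one of `"seeded_random_conv"`, `"handcrafted"`, `"external_pretrained"`.
#' @param base_width base channel width of the networks.
#' @return an object of class `"ouro_run_config"` (a validated list).
#' @export
run_config <- function(patch_size_px = 256L, spot_size_px = 128L,
                       noise_dim = 128L, lambda1 = 1, lambda2 = 1,
                       lambda3 = 0.01, learning_rate = 1e-4,
                       adam_beta1 = 0.5, batch_size = 16L, epochs = 5L,
                       seed = 1L, marker_names = default_marker_names(),
                       fid_embedding = c("seeded_random_conv", "handcrafted",
                                         "external_pretrained"),
                       base_width = 16L) {
  fid_embedding <- match.arg(fid_embedding)
  cfg <- list(patch_size_px = as.integer(patch_size_px),
              spot_size_px = as.integer(spot_size_px),
              noise_dim = as.integer(noise_dim),
              lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
              learning_rate = learning_rate, adam_beta1 = adam_beta1,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed),
              marker_names = as.character(marker_names),
              fid_embedding = fid_embedding,
              base_width = as.integer(base_width))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid run config field '", field, "': ",
                                    msg, call. = FALSE)
  if (cfg$patch_size_px < cfg$spot_size_px)
    fail("spot_size_px", "spot size exceeds patch size")
  if (cfg$patch_size_px %% 2L != 0L) fail("patch_size_px", "must be even")
  if (cfg$spot_size_px %% 2L != 0L) fail("spot_size_px", "must be even")
  for (f in c("lambda1", "lambda2", "lambda3"))
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) fail(f, "must be finite and >= 0")
  if (!is.finite(cfg$learning_rate) || cfg$learning_rate <= 0)
    fail("learning_rate", "must be positive")
  if (cfg$adam_beta1 < 0 || cfg$adam_beta1 >= 1)
    fail("adam_beta1", "must lie in [0, 1)")
  if (cfg$batch_size < 1L) fail("batch_size", "must be a positive integer")
  if (cfg$epochs < 1L) fail("epochs", "must be a positive integer")
  if (anyDuplicated(cfg$marker_names))
    fail("marker_names", "marker names must be unique")
  if (cfg$noise_dim < 1L) fail("noise_dim", "must be a positive integer")
  structure(cfg, class = "ouro_run_config")
}

#' Load a run configuration from a YAML file
#'
#' Fields absent from the file take the defaults of [run_config()]; unknown
#' fields raise an error naming them.
#'
#' @param path path to a YAML configuration file (an empty file yields the
#'   full default configuration).
#' @return an `"ouro_run_config"` object.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.ouro_run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  patch %d px / spot %d px, noise dim %d, %d markers\n",
              x$patch_size_px, x$spot_size_px, x$noise_dim,
              length(x$marker_names)))
  cat(sprintf("  lambda = (%g, %g, %g), lr %g, beta1 %g, batch %d, epochs %d\n",
              x$lambda1, x$lambda2, x$lambda3, x$learning_rate, x$adam_beta1,
              x$batch_size, x$epochs))
  cat("  FID embedding:", x$fid_embedding, " seed:", x$seed, "\n")
  invisible(x)
}
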