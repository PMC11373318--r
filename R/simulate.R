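# Synthetic multi-patient tissue simulator.
#
# Emulates the structure of paired Hyperion/H&E data: per-cell non-negative
# marker counts with zeros and per-patient batch shifts, paired with H&E-like
# patches whose morphology is causally driven by four designated markers —
# nuclear density, nuclear size, haematoxylin (nuclear darkness) and eosin
# (background pink). Non-driver markers are linear mixtures of the drivers
# plus independent noise, giving realistic marker correlation. The renderer
# is deliberately simple (elliptical nuclei over a textured eosin background)
# but carries enough causal signal for the generative-predictive task to be
# learnable and measurable.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Simulator configuration
#'
#' @param n_patients number of pseudo-patients (batches).
#' @param spots_per_patient spots simulated per patient.
#' @param patch_size_px rendered patch side in pixels; the spot is the
#'   central half.
#' @param n_markers marker panel size.
#' @param driver_map named integer vector with entries `density`, `size`,
#'   `hema`, `eos`: 1-based marker indices of the four causal drivers.
#' @param batch_shift_scale standard deviation of the fixed per-patient,
#'   per-marker additive shift on the log-count scale.
#' @param count_dispersion gamma-mixing dispersion of the counts
#'   (variance = mu + dispersion * mu^2).
#' @param seed integer seed fixing the patient shifts and mixing weights.
#' @param base_log_count baseline log mean count.
#' @param k_range nucleus count range `c(min, max)` across the density
#'   driver's logistic response, for the default 64-px patch (scaled by
#'   patch area for other sizes).
#' @param r_range mean nucleus radius range as a fraction of patch side.
#' @param marker_names marker names (defaults to the standard panel,
#'   truncated or padded to `n_markers`).
#' @return an object of class `"ouro_sim_config"`.
#' @export
sim_config <- function(n_patients = 4L, spots_per_patient = 400L,
                       patch_size_px = 64L, n_markers = 38L,
                       driver_map = c(density = 1L, size = 2L, hema = 3L,
                                      eos = 4L),
                       batch_shift_scale = 0.3, count_dispersion = 0.4,
                       seed = 1L, base_log_count = 1.0,
                       k_range = c(3L, 28L), r_range = c(0.035, 0.08),
                       marker_names = NULL) {
  if (spots_per_patient < 1L) stop("spots_per_patient must be >= 1")
  if (n_patients < 1L) stop("n_patients must be >= 1")
  need <- c("density", "size", "hema", "eos")
  if (!all(need %in% names(driver_map)))
    stop("driver_map must name ", paste(need, collapse = ", "))
  driver_map <- driver_map[need]
  if (anyDuplicated(driver_map)) stop("driver indices must be distinct")
  if (any(driver_map < 1L) || any(driver_map > n_markers))
    stop("driver indices must lie in 1..n_markers")
  if (batch_shift_scale < 0) stop("batch_shift_scale must be >= 0")
  if (count_dispersion <= 0) stop("count_dispersion must be > 0")
  if (is.null(marker_names)) {
    base <- default_marker_names()
    marker_names <- if (n_markers <= length(base)) base[seq_len(n_markers)]
    else c(base, paste0("marker", seq_len(n_markers - length(base))))
  }
  cfg <- list(n_patients = as.integer(n_patients),
              spots_per_patient = as.integer(spots_per_patient),
              patch_size_px = as.integer(patch_size_px),
              n_markers = as.integer(n_markers),
              driver_map = vapply(driver_map, as.integer, integer(1)),
              batch_shift_scale = batch_shift_scale,
              count_dispersion = count_dispersion, seed = as.integer(seed),
              base_log_count = base_log_count,
              k_range = k_range, r_range = r_range,
              marker_names = as.character(marker_names))
  structure(cfg, class = "ouro_sim_config")
}

# fixed per-config structural randomness: patient shifts and mixing weights
sim_structure <- function(config) {
  with_seed(config$seed + 777L, {
    shifts <- matrix(stats::rnorm(config$n_patients * config$n_markers,
                                  sd = config$batch_shift_scale),
                     config$n_patients, config$n_markers)
    mix <- matrix(stats::rnorm(config$n_markers * 4L, sd = 0.6),
                  config$n_markers, 4L)
    # drivers load purely on themselves
    mix[config$driver_map, ] <- 0
    for (k in seq_len(4L)) mix[config$driver_map[k], k] <- 1
    list(shifts = shifts, mix = mix)
  })
}

# latent marker values from the four driver latents
sim_latent_markers <- function(config, drivers, noise_sd = 0.4) {
  st <- sim_structure(config)
  lat <- as.numeric(st$mix %*% drivers)
  nondriver <- setdiff(seq_len(config$n_markers), config$driver_map)
  lat[nondriver] <- lat[nondriver] + stats::rnorm(length(nondriver),
                                                  sd = noise_sd)
  lat
}

#' Draw one spot's latent expression and batch-shifted raw counts
#'
#' Driver latents are standard normal; each marker's count is an
#' overdispersed (gamma-mixed Poisson) draw around
#' `exp(base_log_count + latent + patient_shift)`, so zeros occur naturally
#' at low means and per-patient shifts act on the log scale.
#'
#' @param config an `"ouro_sim_config"`.
#' @param patient patient index in `1..n_patients`.
#' @param seed integer seed for this draw.
#' @return list with `latent` (length-`n_markers` latent vector), `drivers`
#'   (the four driver latents), `counts` (integer raw counts) and `mean`
#'   (the count means).
#' @export
sample_spot_expression <- function(config, patient, seed = 1L) {
  if (patient < 1L || patient > config$n_patients)
    stop("patient index out of range")
  st <- sim_structure(config)
  with_seed(seed, {
    drivers <- stats::rnorm(4L)
    lat <- sim_latent_markers(config, drivers)
    mu <- exp(config$base_log_count + lat + st$shifts[patient, ])
    shape <- 1 / config$count_dispersion
    lam <- stats::rgamma(config$n_markers, shape = shape,
                         scale = mu / shape)
    counts <- stats::rpois(config$n_markers, lam)
    list(latent = lat, drivers = drivers, counts = counts, mean = mu,
         lambda = lam)
  })
}

#' Render an H&E-like patch from a latent expression vector
#'
#' The number of nuclei follows a logistic response of the density driver
#' between `k_range`, mean nuclear radius follows the size driver, nuclear
#' darkness (haematoxylin blue-purple) the hema driver and background pink
#' the eos driver. Positions, orientations and axis ratios are jittered from
#' the seeded RNG. Colours interpolate fixed RGB anchors: nucleus
#' (0.62, 0.52, 0.75) to (0.20, 0.10, 0.42); background white
#' (0.97, 0.95, 0.96) to eosin pink (0.91, 0.58, 0.70).
#'
#' @param latent length-`n_markers` latent expression vector (the `latent`
#'   element of [sample_spot_expression()]).
#' @param config an `"ouro_sim_config"`.
#' @param seed integer seed; the same seed and expression give a
#'   pixel-identical patch.
#' @return list with `img` (`H x W x 3` array in `[0, 1]`, 8-bit quantized)
#'   and `cells` (data frame of nucleus centres and radii, ground truth).
#' @export
render_patch <- function(latent, config, seed = 1L) {
  S <- config$patch_size_px
  dm <- config$driver_map
  d_density <- latent[dm[["density"]]]
  d_size <- latent[dm[["size"]]]
  d_hema <- latent[dm[["hema"]]]
  d_eos <- latent[dm[["eos"]]]

  area_scale <- (S / 64)^2
  kmin <- config$k_range[1L] * area_scale
  kmax <- config$k_range[2L] * area_scale
  K <- as.integer(round(kmin + sigmoid(d_density) * (kmax - kmin)))
  # nuclear crowding: in dense regions nuclei are smaller and pack closer,
  # so per-nucleus morphology also carries density information
  crowd <- 1.25 - 0.5 * sigmoid(d_density)
  r_mean <- (config$r_range[1L] +
               sigmoid(d_size) * diff(config$r_range)) * S * crowd
  if (S < 8L || r_mean >= S / 2)
    stop("patch too small to place a nucleus at this size setting")

  t_h <- sigmoid(d_hema)
  nuc_col <- (1 - t_h) * c(0.62, 0.52, 0.75) + t_h * c(0.20, 0.10, 0.42)
  t_e <- sigmoid(d_eos)
  bg_col <- (1 - t_e) * c(0.97, 0.95, 0.96) + t_e * c(0.91, 0.58, 0.70)

  with_seed(seed, {
    # low-frequency eosin texture: coarse grid, bilinear upsample
    g <- 8L
    coarse <- matrix(stats::rnorm(g * g, sd = 0.05), g, g)
    xi <- seq(1, g, length.out = S)
    lo <- pmin(floor(xi), g - 1L); fr <- xi - lo
    tex <- (1 - fr) * coarse[lo, , drop = FALSE] +
      fr * coarse[lo + 1L, , drop = FALSE]
    tex <- sweep(tex[, lo, drop = FALSE], 2L, 1 - fr, "*") +
      sweep(tex[, lo + 1L, drop = FALSE], 2L, fr, "*")
    img <- array(0, c(S, S, 3L))
    for (ch in 1:3) img[, , ch] <- bg_col[ch] * (1 + tex)

    # place nuclei with a minimum-distance heuristic
    cells <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                        ratio = numeric(0), theta = numeric(0))
    dmin <- (2.5 - 2.0 * sigmoid(d_density)) * r_mean
    tries <- 0L
    while (nrow(cells) < K && tries < 40L * K) {
      tries <- tries + 1L
      cx <- stats::runif(1, 1, S); cy <- stats::runif(1, 1, S)
      if (nrow(cells) &&
          min((cells$x - cx)^2 + (cells$y - cy)^2) < dmin^2) next
      cells[nrow(cells) + 1L, ] <-
        c(cx, cy, r_mean * exp(stats::rnorm(1, sd = 0.1)),
          stats::runif(1, 0.65, 1), stats::runif(1, 0, pi))
    }

    ys <- matrix(seq_len(S), S, S)          # row = y coordinate
    xs <- t(ys)
    for (i in seq_len(nrow(cells))) {
      ci <- cells[i, ]
      a <- ci$r; b <- ci$r * ci$ratio
      dx <- xs - ci$x; dy <- ys - ci$y
      u <- (dx * cos(ci$theta) + dy * sin(ci$theta)) / a
      v <- (-dx * sin(ci$theta) + dy * cos(ci$theta)) / b
      q <- sqrt(u^2 + v^2)
      alpha <- pmin(pmax((1.12 - q) / 0.24, 0), 1)     # soft rim
      if (!any(alpha > 0)) next
      shade <- 1 + 0.06 * stats::rnorm(1)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - alpha) + alpha * nuc_col[ch] * shade
    }
    img <- quantize8(img)
    list(img = img, cells = cells)
  })
}

#' Simulate a full multi-patient cohort
#'
#' For every spot: a latent expression draw, per-cell raw counts (one
#' overdispersed count vector per rendered nucleus, averaging to the spot's
#' raw expression through [aggregate_spot()]) and a rendered patch. Patient
#' id is recorded as the batch label.
#'
#' @param config an `"ouro_sim_config"`.
#' @param return_cells if `TRUE`, attach the per-cell count table.
#' @return an `"ouro_dataset"` in raw expression space with patches, plus
#'   attributes `drivers` (spots x 4 matrix of true driver latents) and,
#'   optionally, `cells`.
#' @export
simulate_cohort <- function(config, return_cells = FALSE) {
  S <- config$patch_size_px
  n <- config$n_patients * config$spots_per_patient
  expr <- matrix(0, n, config$n_markers)
  drivers <- matrix(0, n, 4L)
  patches <- array(0, c(S, S, 3L, n))
  patient <- integer(n)
  rows <- integer(n)
  cell_tabs <- if (return_cells) vector("list", n) else NULL
  st <- sim_structure(config)
  idx <- 0L
  for (pa in seq_len(config$n_patients)) {
    for (sp in seq_len(config$spots_per_patient)) {
      idx <- idx + 1L
      seed_i <- config$seed * 100000L + idx
      draw <- sample_spot_expression(config, pa, seed = seed_i)
      rp <- render_patch(draw$latent, config, seed = seed_i + 50000L)
      ncell <- max(1L, nrow(rp$cells))
      # per-cell counts: shared gamma intensity, Poisson per cell
      cellcounts <- with_seed(seed_i + 90000L, {
        matrix(stats::rpois(ncell * config$n_markers,
                            rep(draw$lambda, each = ncell)),
               ncell, config$n_markers)
      })
      expr[idx, ] <- aggregate_spot(cellcounts)
      drivers[idx, ] <- draw$drivers
      patches[, , , idx] <- rp$img
      patient[idx] <- pa
      rows[idx] <- sp
      if (return_cells) {
        tab <- cbind(data.frame(wsi_id = paste0("sim", pa), spot = sp,
                                x = c(rp$cells$x, recursive = TRUE)[seq_len(ncell)],
                                y = c(rp$cells$y, recursive = TRUE)[seq_len(ncell)]),
                     as.data.frame(cellcounts))
        names(tab)[-(1:4)] <- config$marker_names
        cell_tabs[[idx]] <- tab
      }
    }
  }
  ds <- ouro_dataset(expr, paste0("sim", patient), config$marker_names,
                     patches = patches,
                     meta = data.frame(wsi_id = paste0("sim", patient),
                                       row = rows, col = 0L))
  colnames(drivers) <- names(config$driver_map)
  attr(ds, "drivers") <- drivers
  if (return_cells) attr(ds, "cells") <- do.call(rbind, cell_tabs)
  ds
}
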