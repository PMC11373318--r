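# Conditional generator and dual-head discriminator.
#
# The generator maps (p, z) to an H&E-like image in [-1, 1]; it starts from a
# learned 4x4 seed grid and doubles resolution through residual up-sampling
# blocks, so a patch of side S needs s = log2(S/4) stages. The expression
# vector p conditions every stage through conditional instance normalisation
# and is also concatenated with z at the input. One nonlocal self-attention
# block sits at the S/4-resolution feature map (omitted for models with fewer
# than three stages, where that map does not exist).
#
# The discriminator mirrors the design with residual down-sampling blocks and
# ends in two heads on a globally sum-pooled feature vector: a realism logit
# and an n_markers-dimensional expression prediction. In both networks the
# attention block sits at the 8x8 feature map (models smaller than 16 px have
# no attention); the generator's output stage is a 1x1 convolution followed
# by a fixed binomial antialiasing filter after the final nearest-neighbour
# up-sampling.

#' Architecture descriptor for generator or discriminator
#'
#' @param patch_size_px output (input) image side in pixels; must be `4 * 2^s`
#'   for an integer number of stages `s >= 1`.
#' @param n_markers length of the conditioning / predicted expression vector.
#' @param noise_dim length of the generator noise input.
#' @param base_width base channel width; stage widths are derived from it.
#' @return a list describing the network shape.
#' @export
nn_arch <- function(patch_size_px = 64L, n_markers = 38L, noise_dim = 128L,
                    base_width = 16L) {
  s <- log2(patch_size_px / 4)
  if (s < 1 || s != round(s))
    stop("patch_size_px must be 4 * 2^s for integer s >= 1, got ",
         patch_size_px)
  s <- as.integer(s)
  list(patch = as.integer(patch_size_px), stages = s,
       n_markers = as.integer(n_markers), noise_dim = as.integer(noise_dim),
       base = as.integer(base_width),
       ch_seed = as.integer(base_width * 4L),
       ch_g = vapply(seq_len(s), function(i)
         as.integer(max(base_width, base_width * 2^(s - i - 1))), integer(1)),
       ch_d = vapply(seq_len(s), function(i)
         as.integer(min(base_width * 2^(i - 1), base_width * 4L)), integer(1)),
       z_chunk = as.integer(noise_dim %/% max(s, 1L)),
       attn_g = if (s >= 2) 1L else NA_integer_,
       attn_d = if (s >= 2) as.integer(log2(patch_size_px) - 3L)
       else NA_integer_)
}

#' Initialise generator parameters
#'
#' @param arch descriptor from [nn_arch()].
#' @param seed integer seed; initialisation is deterministic given the seed.
#' @return an object of class `"generator_params"`.
#' @export
init_generator <- function(arch, seed = 1L) {
  m <- arch$n_markers
  mc <- m + arch$z_chunk        # CIN conditioning: [p; stage z-chunk]
  with_seed(seed, {
    p <- list()
    fan <- arch$noise_dim + m
    p[["fc.w"]] <- nn_rand(fan, 16L * arch$ch_seed, sqrt(1 / fan))
    p[["fc.b"]] <- numeric(16L * arch$ch_seed)
    ci <- arch$ch_seed
    for (i in seq_len(arch$stages)) {
      co <- arch$ch_g[i]
      pre <- sprintf("s%d.", i)
      p[[paste0(pre, "cin1.wg")]] <- nn_rand(mc, ci, 0.05)
      p[[paste0(pre, "cin1.wb")]] <- nn_rand(mc, ci, 0.05)
      # convolutions feeding a normalisation layer carry no bias (it would
      # receive an identically-zero gradient)
      p[[paste0(pre, "conv1.w")]] <- nn_rand(ci * 9L, co, sqrt(2 / (ci * 9)))
      p[[paste0(pre, "cin2.wg")]] <- nn_rand(mc, co, 0.05)
      p[[paste0(pre, "cin2.wb")]] <- nn_rand(mc, co, 0.05)
      p[[paste0(pre, "conv2.w")]] <- nn_rand(co * 9L, co, sqrt(2 / (co * 9)))
      p[[paste0(pre, "skip.w")]] <- nn_rand(ci, co, sqrt(1 / ci))
      if (!is.na(arch$attn_g) && i == arch$attn_g) {
        dk <- max(2L, co %/% 8L)
        p[["attn.wq"]] <- nn_rand(co, dk, sqrt(1 / co))
        p[["attn.wk"]] <- nn_rand(co, dk, sqrt(1 / co))
        p[["attn.wv"]] <- nn_rand(co, co, sqrt(1 / co))
        p[["attn.g"]] <- 0.1
      }
      ci <- co
    }
    p[["out.g"]] <- numeric(ci)
    p[["out.b"]] <- numeric(ci)
    p[["out.conv.w"]] <- nn_rand(ci, 3L, sqrt(1 / ci))   # 1x1 projection
    p[["out.conv.b"]] <- numeric(3L)
    p <- p[!vapply(p, is.null, logical(1))]
    structure(list(params = p, arch = arch, seed = as.integer(seed)),
              class = "generator_params")
  })
}

#' Initialise discriminator parameters
#'
#' @inheritParams init_generator
#' @return an object of class `"discriminator_params"`.
#' @export
init_discriminator <- function(arch, seed = 1L) {
  m <- arch$n_markers
  with_seed(seed, {
    p <- list()
    c1 <- arch$base
    p[["in.w"]] <- nn_rand(3L * 9L, c1, sqrt(2 / 27))
    p[["in.b"]] <- numeric(c1)
    ci <- c1
    for (i in seq_len(arch$stages)) {
      co <- arch$ch_d[i]
      pre <- sprintf("s%d.", i)
      p[[paste0(pre, "conv1.w")]] <- nn_rand(ci * 9L, co, sqrt(2 / (ci * 9)))
      p[[paste0(pre, "conv1.b")]] <- numeric(co)
      p[[paste0(pre, "conv2.w")]] <- nn_rand(co * 9L, co, sqrt(2 / (co * 9)))
      p[[paste0(pre, "conv2.b")]] <- numeric(co)
      p[[paste0(pre, "skip.w")]] <- nn_rand(ci, co, sqrt(1 / ci))
      p[[paste0(pre, "skip.b")]] <- numeric(co)
      if (!is.na(arch$attn_d) && i == arch$attn_d) {
        dk <- max(2L, co %/% 8L)
        p[["attn.wq"]] <- nn_rand(co, dk, sqrt(1 / co))
        p[["attn.wk"]] <- nn_rand(co, dk, sqrt(1 / co))
        p[["attn.wv"]] <- nn_rand(co, co, sqrt(1 / co))
        p[["attn.g"]] <- 0.1
      }
      ci <- co
    }
    hw16 <- 16L                      # sum-pooled 4x4 map scale
    p[["head_r.w"]] <- nn_rand(ci, 1L, sqrt(1 / ci) / hw16)
    p[["head_r.b"]] <- 0
    p[["head_p.w"]] <- nn_rand(ci, m, sqrt(1 / ci) / hw16)
    p[["head_p.b"]] <- numeric(m)
    structure(list(params = p, arch = arch, seed = as.integer(seed)),
              class = "discriminator_params")
  })
}

n_params <- function(x) sum(vapply(x$params, length, numeric(1)))

# ---- generator forward / backward -------------------------------------------

# conditioning matrix of stage i: [p; i-th z chunk] (chunks tile the noise)
stage_cond <- function(P, Z, arch, i) {
  zc <- arch$z_chunk
  if (zc < 1L) return(P)
  j0 <- ((i - 1L) * zc) %% ncol(Z)
  cbind(P, Z[, (j0 + 1L):(j0 + zc), drop = FALSE])
}

g_forward <- function(p, arch, P, Z, want_cache = FALSE) {
  n <- nrow(P)
  cache <- list(P = P, Z = Z)
  x0 <- cbind(Z, P) %*% p[["fc.w"]]
  x0 <- sweep(x0, 2L, p[["fc.b"]], "+")
  cache$zin <- cbind(Z, P)
  x <- aperm(array(t(x0), c(4L, 4L, arch$ch_seed, n)), c(1L, 2L, 4L, 3L))
  for (i in seq_len(arch$stages)) {
    pre <- sprintf("s%d.", i)
    PZ <- stage_cond(P, Z, arch, i)
    st <- list(xin = x, PZ = PZ)
    c1 <- cin_fw(x, PZ, p[[paste0(pre, "cin1.wg")]], p[[paste0(pre, "cin1.wb")]])
    r1 <- relu_fw(c1$y)
    st$cin1 <- c1$cache; st$r1 <- r1$mask; st$a1 <- r1$y
    h <- conv_fw(r1$y, p[[paste0(pre, "conv1.w")]],
                 numeric(ncol(p[[paste0(pre, "conv1.w")]])))
    c2 <- cin_fw(h, PZ, p[[paste0(pre, "cin2.wg")]], p[[paste0(pre, "cin2.wb")]])
    r2 <- relu_fw(c2$y)
    st$h1 <- h; st$cin2 <- c2$cache; st$r2 <- r2$mask; st$a2 <- r2$y
    h2 <- conv_fw(r2$y, p[[paste0(pre, "conv2.w")]],
                  numeric(ncol(p[[paste0(pre, "conv2.w")]])))
    sk <- conv_fw(x, p[[paste0(pre, "skip.w")]],
                  numeric(ncol(p[[paste0(pre, "skip.w")]])))
    x <- upsample2_fw(h2 + sk)
    cache[[paste0(pre, "st")]] <- st
    if (!is.na(arch$attn_g) && i == arch$attn_g) {
      at <- attn_fw(x, p[["attn.wq"]], p[["attn.wk"]], p[["attn.wv"]],
                    p[["attn.g"]])
      cache$attn_in <- x
      cache$attn <- at$cache
      x <- at$y
    }
  }
  on <- inorm_fw(x, p[["out.g"]], p[["out.b"]])
  rn <- relu_fw(on$y)
  cache$out_in <- x; cache$onorm <- on$cache; cache$orelu <- rn$mask
  yl <- conv_fw(rn$y, p[["out.conv.w"]], p[["out.conv.b"]])
  cache$orelu_y <- rn$y
  img <- tanh(.nn_blur3(yl, FALSE))
  cache$img <- img
  list(img = img, cache = if (want_cache) cache else NULL)
}

g_backward <- function(p, arch, cache, dimg) {
  gr <- grad_env()
  n <- nrow(cache$P)
  dyl <- .nn_blur3(dimg * (1 - cache$img^2), TRUE)
  cb <- conv_bw(cache$orelu_y, p[["out.conv.w"]], dyl)
  grad_acc(gr, "out.conv.w", cb$dw); grad_acc(gr, "out.conv.b", cb$db)
  dr <- relu_bw(cb$dx, cache$orelu)
  ib <- inorm_bw(dr, cache$onorm, n)
  grad_acc(gr, "out.g", ib$dg); grad_acc(gr, "out.b", ib$db)
  dx <- ib$dx
  for (i in rev(seq_len(arch$stages))) {
    pre <- sprintf("s%d.", i)
    if (!is.na(arch$attn_g) && i == arch$attn_g) {
      ab <- attn_bw(dx, cache$attn, p[["attn.wq"]], p[["attn.wk"]],
                    p[["attn.wv"]], p[["attn.g"]])
      grad_acc(gr, "attn.wq", ab$dwq); grad_acc(gr, "attn.wk", ab$dwk)
      grad_acc(gr, "attn.wv", ab$dwv); grad_acc(gr, "attn.g", ab$dg)
      dx <- ab$dx
    }
    st <- cache[[paste0(pre, "st")]]
    dsum <- upsample2_bw(dx)
    skb <- conv_bw(st$xin, p[[paste0(pre, "skip.w")]], dsum)
    grad_acc(gr, paste0(pre, "skip.w"), skb$dw)
    c2b <- conv_bw(st$a2, p[[paste0(pre, "conv2.w")]], dsum)
    grad_acc(gr, paste0(pre, "conv2.w"), c2b$dw)
    dr2 <- relu_bw(c2b$dx, st$r2)
    n2 <- cin_bw(dr2, st$cin2, st$PZ)
    grad_acc(gr, paste0(pre, "cin2.wg"), n2$dwg)
    grad_acc(gr, paste0(pre, "cin2.wb"), n2$dwb)
    c1b <- conv_bw(st$a1, p[[paste0(pre, "conv1.w")]], n2$dx)
    grad_acc(gr, paste0(pre, "conv1.w"), c1b$dw)
    dr1 <- relu_bw(c1b$dx, st$r1)
    n1 <- cin_bw(dr1, st$cin1, st$PZ)
    grad_acc(gr, paste0(pre, "cin1.wg"), n1$dwg)
    grad_acc(gr, paste0(pre, "cin1.wb"), n1$dwb)
    dx <- n1$dx + skb$dx
  }
  d <- dim(dx)
  dxm <- t(matrix(aperm(dx, c(1L, 2L, 4L, 3L)), 16L * arch$ch_seed, n))
  grad_acc(gr, "fc.w", crossprod(cache$zin, dxm))
  grad_acc(gr, "fc.b", colSums(dxm))
  as.list(gr)
}

# ---- discriminator forward / backward ---------------------------------------

d_forward <- function(p, arch, x, want_cache = FALSE) {
  n <- dim(x)[3L]
  cache <- list(xin = x, n = n)
  h <- conv_fw(x, p[["in.w"]], p[["in.b"]])
  cache$in_x <- x
  for (i in seq_len(arch$stages)) {
    pre <- sprintf("s%d.", i)
    st <- list(hin = h)
    r0 <- relu_fw(h)
    st$r0 <- r0$mask
    hp <- avgpool2_fw(r0$y)
    st$hp <- hp
    h1 <- conv_fw(hp, p[[paste0(pre, "conv1.w")]], p[[paste0(pre, "conv1.b")]])
    r1 <- relu_fw(h1)
    st$r1 <- r1$mask; st$a1 <- r1$y
    h2 <- conv_fw(r1$y, p[[paste0(pre, "conv2.w")]], p[[paste0(pre, "conv2.b")]])
    skp <- avgpool2_fw(h)
    st$skp <- skp
    sk <- conv_fw(skp, p[[paste0(pre, "skip.w")]], p[[paste0(pre, "skip.b")]])
    h <- h2 + sk
    cache[[paste0(pre, "st")]] <- st
    if (!is.na(arch$attn_d) && i == arch$attn_d) {
      at <- attn_fw(h, p[["attn.wq"]], p[["attn.wk"]], p[["attn.wv"]],
                    p[["attn.g"]])
      cache$attn <- at$cache
      h <- at$y
    }
  }
  rf <- relu_fw(h)
  cache$rf <- rf$mask
  d <- dim(rf$y)
  fm <- matrix(rf$y, d[1L] * d[2L], d[3L] * d[4L])
  pooled <- matrix(colSums(fm), d[3L], d[4L])          # n x C (global sum pool)
  cache$pool_dim <- d
  score <- as.numeric(pooled %*% p[["head_r.w"]] + p[["head_r.b"]])
  pred <- sweep(pooled %*% p[["head_p.w"]], 2L, p[["head_p.b"]], "+")
  cache$pooled <- pooled
  list(score = score, pred = pred, cache = if (want_cache) cache else NULL)
}

d_backward <- function(p, arch, cache, dscore, dpred, want_dx = FALSE,
                       want_dw = TRUE) {
  gr <- grad_env()
  n <- cache$n
  if (want_dw) {
    grad_acc(gr, "head_r.w", crossprod(cache$pooled, matrix(dscore, n, 1L)))
    grad_acc(gr, "head_r.b", sum(dscore))
    grad_acc(gr, "head_p.w", crossprod(cache$pooled, dpred))
    grad_acc(gr, "head_p.b", colSums(dpred))
  }
  dpool <- matrix(dscore, n, 1L) %*% t(p[["head_r.w"]]) +
    tcrossprod(dpred, p[["head_p.w"]])                  # n x C
  d <- cache$pool_dim
  dfm <- matrix(rep(as.vector(dpool), each = d[1L] * d[2L]),
                d[1L] * d[2L], d[3L] * d[4L])
  dh <- relu_bw(array(dfm, d), cache$rf)
  for (i in rev(seq_len(arch$stages))) {
    pre <- sprintf("s%d.", i)
    if (!is.na(arch$attn_d) && i == arch$attn_d) {
      ab <- attn_bw(dh, cache$attn, p[["attn.wq"]], p[["attn.wk"]],
                    p[["attn.wv"]], p[["attn.g"]])
      if (want_dw) {
        grad_acc(gr, "attn.wq", ab$dwq); grad_acc(gr, "attn.wk", ab$dwk)
        grad_acc(gr, "attn.wv", ab$dwv); grad_acc(gr, "attn.g", ab$dg)
      }
      dh <- ab$dx
    }
    st <- cache[[paste0(pre, "st")]]
    skb <- conv_bw(st$skp, p[[paste0(pre, "skip.w")]], dh, want_dw = want_dw)
    if (want_dw) {
      grad_acc(gr, paste0(pre, "skip.w"), skb$dw)
      grad_acc(gr, paste0(pre, "skip.b"), skb$db)
    }
    dskin <- avgpool2_bw(skb$dx, dim(st$hin))
    c2b <- conv_bw(st$a1, p[[paste0(pre, "conv2.w")]], dh, want_dw = want_dw)
    if (want_dw) {
      grad_acc(gr, paste0(pre, "conv2.w"), c2b$dw)
      grad_acc(gr, paste0(pre, "conv2.b"), c2b$db)
    }
    dr1 <- relu_bw(c2b$dx, st$r1)
    c1b <- conv_bw(st$hp, p[[paste0(pre, "conv1.w")]], dr1, want_dw = want_dw)
    if (want_dw) {
      grad_acc(gr, paste0(pre, "conv1.w"), c1b$dw)
      grad_acc(gr, paste0(pre, "conv1.b"), c1b$db)
    }
    dhp <- avgpool2_bw(c1b$dx, dim(st$hin))
    dh <- relu_bw(dhp, st$r0) + dskin
  }
  res <- list(grads = as.list(gr), dx = NULL)
  ib <- conv_bw(cache$in_x, p[["in.w"]], dh, want_dx = want_dx,
                want_dw = want_dw)
  if (want_dw) {
    grad_acc(gr, "in.w", ib$dw); grad_acc(gr, "in.b", ib$db)
    res$grads <- as.list(gr)
  }
  if (want_dx) res$dx <- ib$dx
  res
}

# ---- public API -------------------------------------------------------------

#' Generate image patches from expression vectors
#'
#' Deterministic function of the parameters, expression and noise: the same
#' `(params, p, z)` always yields the same image. Pixel values lie in
#' `[-1, 1]` (tanh output).
#'
#' @param params a `"generator_params"` object.
#' @param p expression vector (length `n_markers`) or matrix (rows = spots)
#'   in transformed expression space.
#' @param z noise vector (length `noise_dim`) or matrix with rows matching
#'   `p`; the caller draws it, conventionally from N(0, I).
#' @return an `H x W x 3` array, or `H x W x 3 x n` for matrix input.
#' @export
generate <- function(params, p, z) {
  arch <- params$arch
  single <- is.null(dim(p))
  P <- if (single) matrix(p, 1L) else as.matrix(p)
  Z <- if (is.null(dim(z))) matrix(z, 1L) else as.matrix(z)
  if (ncol(P) != arch$n_markers)
    stop("expression vector p has length ", ncol(P), ", expected ",
         arch$n_markers)
  if (ncol(Z) != arch$noise_dim)
    stop("noise vector z has length ", ncol(Z), ", expected ", arch$noise_dim)
  if (nrow(Z) != nrow(P)) stop("p and z must have matching rows")
  n <- nrow(P)
  out <- array(0, c(arch$patch, arch$patch, 3L, n))
  bs <- 32L                       # bound peak memory for large batches
  for (b in seq_len(ceiling(n / bs))) {
    take <- (((b - 1L) * bs + 1L):min(b * bs, n))
    img <- g_forward(params$params, arch, P[take, , drop = FALSE],
                     Z[take, , drop = FALSE])$img     # H W n 3
    out[, , , take] <- aperm(img, c(1L, 2L, 4L, 3L))
  }
  if (single) array(out[, , , 1L], dim(out)[1:3]) else out
}

#' Score realism and predict expression from image patches
#'
#' Single forward trunk with two heads: an unbounded realism logit and a
#' predicted expression vector in transformed space.
#'
#' @param params a `"discriminator_params"` object.
#' @param img an `H x W x 3` array in `[-1, 1]`, or `H x W x 3 x n` batch.
#' @return list with `score` (numeric) and `p_hat` (vector or matrix).
#' @export
discriminate <- function(params, img) {
  arch <- params$arch
  single <- length(dim(img)) == 3L
  x <- if (single) array(img, c(dim(img), 1L)) else img
  if (dim(x)[1L] != arch$patch || dim(x)[2L] != arch$patch)
    stop("image size ", dim(x)[1L], "x", dim(x)[2L], " does not match ",
         "discriminator patch size ", arch$patch)
  xb <- aperm(x, c(1L, 2L, 4L, 3L))                  # H W n 3
  out <- d_forward(params$params, arch, xb)
  if (single) list(score = out$score[1L], p_hat = out$pred[1L, ])
  else list(score = out$score, p_hat = out$pred)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Conditional generator:", x$arch$patch, "x", x$arch$patch,
      "px,", x$arch$stages, "up-sampling stages,",
      format(n_params(x), big.mark = ","), "parameters\n")
  invisible(x)
}

#' @export
print.discriminator_params <- function(x, ...) {
  cat("Dual-head discriminator:", x$arch$patch, "x", x$arch$patch,
      "px,", x$arch$stages, "down-sampling stages,",
      format(n_params(x), big.mark = ","), "parameters\n")
  invisible(x)
}
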