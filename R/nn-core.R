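# Low-level neural-network primitives used by the generator and discriminator.
# Feature maps are arrays with dim c(H, W, N, C); the convolution kernels live
# in src/conv.cpp. Everything here is deterministic given R's RNG state.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

nn_rand <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

# ---- convolution (stride 1, 'same') -----------------------------------------

conv_fw <- function(x, w, b) {
  d <- dim(x)
  if (nrow(w) == d[4L]) {                       # 1x1 conv: plain matmul
    xm <- matrix(x, prod(d[1:3]), d[4L])
    y <- xm %*% w
    y <- sweep(y, 2L, b, "+")
    return(array(y, c(d[1:3], ncol(w))))
  }
  .nn_conv_fw(x, w, as.numeric(b))
}

conv_bw <- function(x, w, dy, want_dx = TRUE, want_dw = TRUE) {
  d <- dim(x)
  if (nrow(w) == d[4L]) {
    dym <- matrix(dy, prod(d[1:3]), ncol(w))
    res <- list(dx = NULL, dw = NULL, db = colSums(dym))
    if (want_dw) {
      xm <- matrix(x, prod(d[1:3]), d[4L])
      res$dw <- crossprod(xm, dym)
    }
    if (want_dx) res$dx <- array(dym %*% t(w), d)
    return(res)
  }
  .nn_conv_bw(x, w, dy, want_dx, want_dw)
}

# ---- resampling -------------------------------------------------------------

avgpool2_fw <- function(x) .nn_pool2_fw(x)
avgpool2_bw <- function(dy, dim_in) .nn_pool2_bw(dy)
upsample2_fw <- function(x) .nn_up2_fw(x)
upsample2_bw <- function(dy) .nn_up2_bw(dy)

# ---- pointwise --------------------------------------------------------------

relu_fw <- function(x) { y <- .nn_relu_fw(x); list(y = y, mask = y) }
relu_bw <- function(dy, mask) .nn_relu_bw(dy, mask)

# ---- conditional instance normalisation -------------------------------------
# Per-sample, per-channel normalisation over spatial positions; gain and bias
# are affine functions of the conditioning vector p: gamma = 1 + P Wg,
# beta = P Wb (P is N x m). Plain learned instance norm is the special case
# gamma = 1 + g[c], beta = b[c].

cin_fw <- function(x, P, wg, wb, eps = 1e-5) {
  d <- dim(x); hw <- d[1L] * d[2L]
  gamma <- 1 + P %*% wg                      # N x C
  beta <- P %*% wb
  gf <- as.vector(gamma); bf <- as.vector(beta)   # (n, c) order matches columns
  r <- .nn_in_fw(matrix(x, hw, d[3L] * d[4L]), gf, bf, eps)
  list(y = array(r$y, d),
       cache = list(xhat = r$xhat, inv = r$inv, gf = gf, d = d))
}

cin_bw <- function(dy, cache, P) {
  d <- cache$d; hw <- d[1L] * d[2L]; nc <- d[3L] * d[4L]
  r <- .nn_in_bw(matrix(dy, hw, nc), cache$xhat, cache$inv, cache$gf)
  dgm <- matrix(r$dgam, d[3L], d[4L]); dbm <- matrix(r$dbet, d[3L], d[4L])
  list(dx = array(r$dx, d), dwg = crossprod(P, dgm), dwb = crossprod(P, dbm))
}

inorm_fw <- function(x, g, b, eps = 1e-5) {
  d <- dim(x)
  P1 <- matrix(1, d[3L], 1L)
  cin_fw(x, P1, matrix(g, 1L), matrix(b, 1L), eps)
}

inorm_bw <- function(dy, cache, n) {
  r <- cin_bw(dy, cache, matrix(1, n, 1L))
  list(dx = r$dx, dg = as.numeric(r$dwg), db = as.numeric(r$dwb))
}

# ---- self-attention (single nonlocal block, SAGAN-style) --------------------

attn_fw <- function(x, wq, wk, wv, g) {
  d <- dim(x); hw <- d[1L] * d[2L]; n <- d[3L]; C <- d[4L]
  dk <- ncol(wq); sc <- 1 / sqrt(dk)
  y <- x
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    X <- matrix(x[, , i, ], hw, C)
    Q <- X %*% wq; K <- X %*% wk; V <- X %*% wv
    S <- tcrossprod(Q, K) * sc
    S <- S - apply(S, 1L, max)
    A <- exp(S); A <- A / rowSums(A)
    O <- A %*% V
    y[, , i, ] <- X + g * O
    caches[[i]] <- list(X = X, Q = Q, K = K, V = V, A = A, O = O)
  }
  list(y = y, cache = list(per = caches, d = d, sc = sc))
}

attn_bw <- function(dy, cache, wq, wk, wv, g) {
  d <- cache$d; hw <- d[1L] * d[2L]; n <- d[3L]; C <- d[4L]
  dwq <- matrix(0, nrow(wq), ncol(wq)); dwk <- dwq
  dwv <- matrix(0, C, C); dg <- 0
  dx <- dy
  for (i in seq_len(n)) {
    cc <- cache$per[[i]]
    dY <- matrix(dy[, , i, ], hw, C)
    dO <- g * dY
    dg <- dg + sum(dY * cc$O)
    dV <- crossprod(cc$A, dO)
    dA <- tcrossprod(dO, cc$V)
    dS <- (dA - rowSums(dA * cc$A)) * cc$A * cache$sc
    dQ <- dS %*% cc$K
    dK <- crossprod(dS, cc$Q)
    dXi <- dY + tcrossprod(dQ, wq) + tcrossprod(dK, wk) + tcrossprod(dV, wv)
    dwq <- dwq + crossprod(cc$X, dQ)
    dwk <- dwk + crossprod(cc$X, dK)
    dwv <- dwv + crossprod(cc$X, dV)
    dx[, , i, ] <- dXi
  }
  list(dx = dx, dwq = dwq, dwk = dwk, dwv = dwv, dg = dg)
}

# ---- gradient store and Adam ------------------------------------------------

grad_env <- function() new.env(parent = emptyenv())

grad_acc <- function(gr, name, val) {
  if (is.null(val)) return(invisible(NULL))
  cur <- if (exists(name, envir = gr, inherits = FALSE)) get(name, envir = gr) else 0
  assign(name, cur + val, envir = gr)
  invisible(NULL)
}

grads_as_list <- function(gr) {
  out <- as.list(gr)
  out[order(names(out))]
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
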