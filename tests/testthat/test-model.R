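# Generator / discriminator contracts: shapes, determinism, conditioning and
# gradient flow.

test_that("architecture stage counts follow 4 * 2^s = patch size", {
  expect_equal(nn_arch(16)$stages, 2L)
  expect_equal(nn_arch(64)$stages, 4L)    # 4 -> 8 -> 16 -> 32 -> 64
  expect_equal(nn_arch(256)$stages, 6L)   # paper-scale 256 px
  expect_error(nn_arch(100), "4 \\* 2\\^s")
  expect_error(nn_arch(2), "4 \\* 2\\^s")
})

test_that("initialisation is deterministic given the seed", {
  arch <- tiny_arch()
  g1 <- init_generator(arch, 42L)
  g2 <- init_generator(arch, 42L)
  expect_identical(g1$params, g2$params)
  g3 <- init_generator(arch, 43L)
  expect_false(identical(g1$params, g3$params))
  d1 <- init_discriminator(arch, 42L)
  d2 <- init_discriminator(arch, 42L)
  expect_identical(d1$params, d2$params)
})

test_that("generate is deterministic, bounded and conditioned on p", {
  arch <- tiny_arch()
  gen <- init_generator(arch, 1L)
  set.seed(3)
  p <- rnorm(6); z <- rnorm(8)
  i1 <- generate(gen, p, z)
  i2 <- generate(gen, p, z)
  expect_identical(i1, i2)
  expect_equal(dim(i1), c(16L, 16L, 3L))
  expect_true(min(i1) >= -1 && max(i1) <= 1)

  # distinct p with identical z yields distinct output (conditioning enters
  # every stage)
  p2 <- p + c(2, 0, 0, 0, 0, 0)
  expect_gt(mean(abs(generate(gen, p2, z) - i1)), 0)

  # batched input
  ib <- generate(gen, rbind(p, p2), rbind(z, z))
  expect_equal(dim(ib), c(16L, 16L, 3L, 2L))
  expect_equal(ib[, , , 1L], i1)

  expect_error(generate(gen, p[1:3], z), "length")
  expect_error(generate(gen, p, z[1:3]), "length")
})

test_that("discriminate returns a scalar logit and an n_markers prediction", {
  arch <- tiny_arch()
  disc <- init_discriminator(arch, 2L)
  set.seed(4)
  img <- array(tanh(rnorm(16 * 16 * 3)), c(16, 16, 3))
  o1 <- discriminate(disc, img)
  o2 <- discriminate(disc, img)
  expect_identical(o1, o2)
  expect_length(o1$score, 1L)
  expect_length(o1$p_hat, 6L)
  expect_error(discriminate(disc, array(0, c(8, 8, 3))), "size")

  # default panel: prediction head emits 38 values
  d38 <- init_discriminator(nn_arch(16, n_markers = 38, noise_dim = 8,
                                    base_width = 4), 1L)
  expect_length(discriminate(d38, img)$p_hat, 38L)
})

test_that("untrained predictions carry no spot-specific signal", {
  # raw random-init conv features already share colour information with the
  # colour-driving markers, so the uncorrelatedness null is evaluated under
  # row permutation (breaking the spot pairing) and against a trained head
  ds <- small_cohort()
  ft <- suppressWarnings(fit_transform_expression(ds$expression))
  arch <- nn_arch(32, n_markers = 38, noise_dim = 16, base_width = 4)
  disc <- init_discriminator(arch, 5L)
  idx <- seq_len(60)
  pred <- t(vapply(idx, function(i)
    discriminate(disc, ds$patches[, , , i] * 2 - 1)$p_hat, numeric(38)))
  set.seed(77)
  shuf <- sample(idx)
  rr <- suppressWarnings(
    vapply(1:38, function(j) cor(ft$transformed[shuf, j], pred[, j]),
           numeric(1)))
  expect_lt(mean(abs(rr), na.rm = TRUE), 0.2)
})

test_that("every parameter receives a nonzero gradient from the total loss", {
  ds <- tiny_train_dataset()
  cfg <- tiny_config()
  arch <- tiny_arch()
  gen <- init_generator(arch, 7L)
  disc <- init_discriminator(arch, 8L)
  n <- 8L
  batch <- list(P = ds$expression[1:n, ],
                I = aperm(ds$patches[, , , 1:n] * 2 - 1, c(1, 2, 4, 3)))
  # one step must touch every parameter of both networks
  res <- train_step(batch, gen, disc, cfg, seed = 1L)
  moved_g <- mapply(function(a, b) any(a != b), gen$params, res$gen$params)
  moved_d <- mapply(function(a, b) any(a != b), disc$params,
                    res$disc$params)
  expect_true(all(moved_g))
  expect_true(all(moved_d))
})

test_that("backpropagation matches finite differences on a tiny model", {
  arch <- tiny_arch(markers = 3L)
  gen <- init_generator(arch, 1L)
  disc <- init_discriminator(arch, 2L)
  set.seed(3)
  n <- 2L
  P <- matrix(rnorm(n * 3), n)
  Z <- matrix(rnorm(n * 8), n)
  W <- array(rnorm(16 * 16 * n * 3), c(16, 16, n, 3))

  loss_g <- function(params) sum(ouroboros:::g_forward(params, arch, P,
                                                       Z)$img * W)
  fw <- ouroboros:::g_forward(gen$params, arch, P, Z, want_cache = TRUE)
  gr <- ouroboros:::g_backward(gen$params, arch, fw$cache, W)
  eps <- 1e-6
  for (nm in c("fc.w", "s1.cin1.wg", "s1.conv1.w", "s2.skip.w", "out.g",
               "out.conv.w")) {
    i <- 1L
    up <- gen$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- gen$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_g(up) - loss_g(dn)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }

  a <- rnorm(n); B <- matrix(rnorm(n * 3), n)
  x <- array(tanh(rnorm(16 * 16 * n * 3)), c(16, 16, n, 3))
  loss_d <- function(params) {
    o <- ouroboros:::d_forward(params, arch, x)
    sum(o$score * a) + sum(o$pred * B)
  }
  fo <- ouroboros:::d_forward(disc$params, arch, x, want_cache = TRUE)
  db <- ouroboros:::d_backward(disc$params, arch, fo$cache, a, B,
                               want_dx = TRUE)
  for (nm in c("in.w", "s1.conv1.w", "s2.conv2.b", "head_r.w", "head_p.w")) {
    i <- 1L
    up <- disc$params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- disc$params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (loss_d(up) - loss_d(dn)) / (2 * eps)
    expect_equal(db$grads[[nm]][i], num, tolerance = 1e-4)
  }
  # gradient w.r.t. the input image (used by the generator update)
  i <- 17L
  x2 <- x; x2[i] <- x2[i] + eps
  x3 <- x; x3[i] <- x3[i] - eps
  f2 <- ouroboros:::d_forward(disc$params, arch, x2)
  f3 <- ouroboros:::d_forward(disc$params, arch, x3)
  num <- (sum(f2$score * a) + sum(f2$pred * B) -
            sum(f3$score * a) - sum(f3$pred * B)) / (2 * eps)
  expect_equal(db$dx[i], num, tolerance = 1e-4)
})

test_that("the same code instantiates 16 and 64 px models via the descriptor", {
  for (S in c(16L, 64L)) {
    arch <- nn_arch(S, n_markers = 4L, noise_dim = 8L, base_width = 4L)
    gen <- init_generator(arch, 1L)
    img <- generate(gen, rnorm(4), rnorm(8))
    expect_equal(dim(img), c(S, S, 3L))
  }
})

test_that("checkpoints round-trip parameters through a single file", {
  arch <- tiny_arch()
  gen <- init_generator(arch, 9L)
  f <- withr::local_tempfile(fileext = ".rds")
  expect_message(save_checkpoint(gen, f), "checksum")
  expect_message(g2 <- load_checkpoint(f), "checksum")
  expect_identical(g2$params, gen$params)
  expect_identical(g2$arch, gen$arch)
})
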