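test_that("generator and discriminator scores follow their definitions", {
  # ideal equilibrium
  expect_equal(generator_score(rep(0.5, 10)), 0.5)
  expect_equal(generator_score(c(0, 1)), 0.5)
  expect_equal(generator_score(c(0.2, 0.4, 0.9)), 0.5)
  # perfect / chance / inverted discriminator endpoints
  expect_equal(discriminator_score(rep(1, 5), rep(0, 5)), 1)
  expect_equal(discriminator_score(rep(0.5, 5), rep(0.5, 5)), 0.5)
  expect_equal(discriminator_score(rep(0, 5), rep(1, 5)), 0)
  # 0.5 * 0.8 + 0.5 * (1 - 0.3) = 0.75
  expect_equal(discriminator_score(c(0.7, 0.9), c(0.1, 0.5)), 0.75)
  expect_error(generator_score(numeric()), "empty")
  expect_error(discriminator_score(numeric(), 0.5), "empty")
})

test_that("training items normalise to [-1, 1] and invert exactly", {
  ts <- smoke_training_set()
  expect_equal(dim(ts$items), c(16, 16, 1, 204))
  expect_true(all(ts$items >= -1 & ts$items <= 1))
  # round trip on one item
  x <- ts$items[, , 1, 5]
  back <- denormalize_items(x, c(ts$lo[5], ts$hi[5]))
  orig <- (x + 1) / 2 * (ts$hi[5] - ts$lo[5]) + ts$lo[5]
  expect_equal(back, orig, tolerance = 1e-6)
  # constant item flagged degenerate, mapped to 0
  const <- array(3, c(16, 16, 4))
  ts2 <- build_training_set(const)
  expect_true(all(ts2$degenerate))
  expect_true(all(ts2$items == 0))
})

test_that("one discriminator step reduces its minimax loss term", {
  ts <- smoke_training_set()
  cfg <- gan_config(image_size = 16, n_planes = 1, latent_len = 32,
                    base_channels = 4, batch_size = 8, iterations = 1,
                    d_warmup = 0L, seed = 3)
  m <- gan_init(cfg)
  d_loss <- function(model, x_real, x_fake) {
    p_r <- spiralmea:::d_prob(nn_forward(model$D, x_real)$out)
    p_f <- spiralmea:::d_prob(nn_forward(model$D, x_fake)$out)
    -mean(log(p_r)) - mean(log(1 - p_f))
  }
  set.seed(4)
  x_real <- ts$items[, , , 1:8, drop = FALSE]
  z <- matrix(rnorm(32 * 8, 0, 25), 32, 8)
  x_fake <- nn_forward(m$G, z)$out
  before <- d_loss(m, x_real, x_fake)
  # a fixed tiny batch, many inner repetitions of the same update direction
  tr <- gan_train(m, ts, iterations = 3)
  after <- d_loss(tr$model, x_real, x_fake)
  expect_lt(after, before)
})

test_that("training is seeded, bounded, and reproducible", {
  ts <- smoke_training_set()
  cfg <- gan_config(image_size = 16, n_planes = 1, latent_len = 32,
                    base_channels = 4, batch_size = 8, iterations = 12,
                    d_warmup = 5L, log_every = 4, seed = 7)
  tr1 <- gan_train(gan_init(cfg), ts)
  tr2 <- gan_train(gan_init(cfg), ts)
  expect_identical(tr1$history, tr2$history)
  expect_true(all(tr1$history$s_g >= 0 & tr1$history$s_g <= 1))
  expect_true(all(tr1$history$s_d >= 0 & tr1$history$s_d <= 1))

  # sampling: shapes, determinism, range within the training data
  x1 <- gan_sample(tr1$model, 5, seed = 9)
  x2 <- gan_sample(tr1$model, 5, seed = 9)
  expect_identical(x1, x2)
  expect_equal(dim(x1), c(16, 16, 1, 5))
  expect_true(all(x1 >= ts$range[1] - 1e-9 & x1 <= ts$range[2] + 1e-9))
  expect_error(gan_sample(tr1$model, 0), "n > 0")
})

test_that("checkpoints round-trip through the JSON format", {
  ts <- smoke_training_set()
  cfg <- gan_config(image_size = 16, n_planes = 1, latent_len = 32,
                    base_channels = 4, batch_size = 8, iterations = 3,
                    d_warmup = 0L, seed = 5)
  tr <- gan_train(gan_init(cfg), ts)
  path <- tempfile(fileext = ".json")
  save_gan(tr$model, path)
  m2 <- load_gan(path)
  # decimal serialisation may perturb the last bit of a double
  expect_equal(gan_sample(tr$model, 3, seed = 2),
               gan_sample(m2, 3, seed = 2), tolerance = 1e-10)
})

test_that("Frechet distance matches its closed form", {
  set.seed(8)
  A <- matrix(rnorm(400 * 4), ncol = 4)
  expect_equal(frechet_distance(A, A), 0, tolerance = 1e-8)
  # two unit-variance Gaussians with mean distance d: FID -> d^2
  d <- 3
  B1 <- matrix(rnorm(20000 * 2), ncol = 2)
  B2 <- matrix(rnorm(20000 * 2), ncol = 2)
  B2[, 1] <- B2[, 1] + d
  expect_equal(frechet_distance(B1, B2), d^2, tolerance = 0.05)
  # oracle: closed form for diagonal Gaussians
  # |mu1-mu2|^2 + sum(s1 + s2 - 2 sqrt(s1 s2))
  C1 <- matrix(rnorm(40000 * 2, 0, 1), ncol = 2)
  C2 <- cbind(rnorm(40000, 2, 2), rnorm(40000, 0, 0.5))
  expected <- 4 + (1 + 4 - 2 * sqrt(4)) + (1 + 0.25 - 2 * sqrt(0.25))
  expect_equal(frechet_distance(C1, C2), expected, tolerance = 0.05)
})

test_that("inception-style score rewards confident diverse classifiers", {
  # identical rows: zero KL, score 1
  P <- matrix(rep(c(0.2, 0.3, 0.5), each = 10), nrow = 10)
  expect_equal(inception_style_score(P), 1)
  # hand-computed two-class case
  Q <- rbind(c(1, 0), c(0, 1))
  # KL(each || (0.5, 0.5)) = log 2 -> score = 2
  expect_equal(inception_style_score(Q), 2, tolerance = 1e-6)
  expect_error(inception_style_score(matrix(c(0.5, 0.2), 1)), "sum to 1")
})
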