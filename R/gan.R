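#' Configuration of the adversarial snapshot model
#'
#' A deep convolutional generator/discriminator pair for synthesising
#' full-array activity snapshots.  The generator has six hidden
#' convolutional layers with rectified-linear activations and a hyperbolic
#' tangent output; the discriminator has eight hidden convolutional layers
#' with leaky rectified-linear activations and a hyperbolic tangent output
#' head (mapped to a probability as `p = (h + 1) / 2` before the log loss).
#' Training uses Adam with a discriminator learning rate of 2e-4 and a
#' generator learning rate of 1e-3; latent noise is Gaussian with mean 0 and
#' SD 25.
#'
#' The full-scale profile is 64 x 64 x 6 volumes (six evenly spaced
#' snapshots per wave) trained for 10,000 iterations; a reduced profile
#' (e.g. `image_size = 16`, `n_planes = 1`, a few hundred iterations) is
#' used for desk-scale experiments and tests.
#'
#' @param image_size output spatial size (power-of-two multiple of 4).
#' @param n_planes output planes (snapshots per item).
#' @param latent_len latent vector length.
#' @param noise_mean,noise_sd latent Gaussian parameters.
#' @param base_channels width multiplier for the generator stack.
#' @param disc_channels width multiplier for the discriminator stack
#'   (default half of `base_channels`); a discriminator much wider than the
#'   generator memorises small training sets and starves the generator of
#'   gradient.
#' @param lr_d,lr_g Adam learning rates for discriminator and generator.
#' @param d_every update the discriminator only every `d_every`-th
#'   iteration (1 = every iteration); a standard balance control when the
#'   discriminator would otherwise overpower the generator on small
#'   training sets.
#' @param d_warmup discriminator-only warm-up updates performed before the
#'   alternating phase, so the generator faces a competent critic (and a
#'   meaningful gradient) from its first step.
#' @param iterations training iterations.
#' @param batch_size minibatch size.
#' @param log_every score-logging interval (iterations).
#' @param seed integer seed.
#' @return A `gan_config` list.
#' @export
gan_config <- function(image_size = 64L, n_planes = 6L, latent_len = 100L,
                       noise_mean = 0, noise_sd = 25, base_channels = 16L,
                       disc_channels = max(4L, base_channels %/% 2L),
                       lr_d = 2e-4, lr_g = 1e-3, d_every = 1L,
                       d_warmup = 60L, iterations = 10000L,
                       batch_size = 32L, log_every = 25L, seed = 1L) {
  stopifnot(lr_d > 0, lr_g > 0, iterations >= 1, batch_size >= 1)
  n_up <- log2(image_size / 4)
  if (n_up != round(n_up) || n_up < 1)
    stop("image_size must be a power-of-two multiple of 8 (8, 16, 32, 64, ...)")
  structure(as.list(environment()), class = "gan_config")
}

## generator: dense projection to a 4x4 seed map, then six hidden conv+ReLU
## layers (nearest-neighbour upsampling interleaved until the target size),
## and a linear conv to n_planes followed by tanh
build_generator <- function(cfg) {
  n_up <- as.integer(log2(cfg$image_size / 4))
  ch <- cfg$base_channels * 2^pmin(n_up, 3)
  ## the input layer is scaled to the reference latent SD so the stack sees
  ## O(1) activations at the configured operating point instead of
  ## saturating its tanh output from the first iteration
  layers <- list(
    nn_dense(cfg$latent_len, 4 * 4 * ch, activation = "relu",
             init_gain = 1 / max(cfg$noise_sd, 1)),
    nn_reshape(4, 4, ch)
  )
  n_conv <- 6L
  for (i in seq_len(n_conv)) {
    if (i <= n_up) layers <- c(layers, list(nn_upsample()))
    out_ch <- if (i <= n_up) max(cfg$base_channels, ch %/% 2) else ch
    layers <- c(layers, list(nn_conv2d(ch, out_ch, kernel = 3L, stride = 1L,
                                       pad = 1L, activation = "relu")))
    ch <- out_ch
  }
  c(layers, list(nn_conv2d(ch, cfg$n_planes, kernel = 3L, stride = 1L,
                           pad = 1L, activation = "tanh", init_gain = 0.5)))
}

## discriminator: eight hidden conv + leaky-ReLU layers (stride-2 downsampling
## until a 4x4 map), then a dense htan head
build_discriminator <- function(cfg) {
  n_down <- as.integer(log2(cfg$image_size / 4))
  ch_in <- cfg$n_planes
  ch <- cfg$disc_channels
  layers <- list()
  n_conv <- 8L
  for (i in seq_len(n_conv)) {
    stride <- if (i <= n_down) 2L else 1L
    layers <- c(layers, list(nn_conv2d(ch_in, ch, kernel = 3L,
                                       stride = stride, pad = 1L,
                                       activation = "lrelu")))
    ch_in <- ch
    if (i <= n_down) ch <- min(ch * 2L, cfg$disc_channels * 8L)
  }
  c(layers, list(nn_flatten(),
                 nn_dense(4 * 4 * ch_in, 1L, activation = "tanh",
                          init_gain = 0.5)))
}

#' Initialise an adversarial snapshot model
#'
#' @param config a [gan_config()].
#' @return A `gan_model`: generator and discriminator layer stacks, Adam
#'   states, iteration counter, and the training-data value range used to
#'   denormalise samples (set by [gan_train()]).
#' @export
gan_init <- function(config = gan_config()) {
  stopifnot(inherits(config, "gan_config"))
  with_seed(config$seed, {
    G <- build_generator(config)
    D <- build_discriminator(config)
  })
  structure(list(G = G, D = D, config = config,
                 adam_G = adam_state(G), adam_D = adam_state(D),
                 iter = 0L, t_g = 0L, t_d = 0L,
                 data_range = c(-1, 1)),
            class = "gan_model")
}

#' Assemble an adversarial-network training set from wave snapshots
#'
#' Selects `k` evenly spaced snapshots per wave ([select_evenly_spaced()])
#' and linearly rescales each item to the `[-1, 1]` tanh range, recording
#' the per-item transform for inversion.  Waves with fewer than `k` frames
#' are skipped with a message; constant items map to 0 and are flagged
#' degenerate.
#'
#' @param stacks list of [snapshot_stack()]s, one per wave; alternatively a
#'   3-D array (h, w, n) of individual snapshots, each becoming one
#'   single-plane item (the reduced desk-scale profile).
#' @param k snapshots per item (default 6).
#' @return A `gan_training_set`: `items` array (h, w, k, n), `lo` / `hi`
#'   per-item bounds, `degenerate` flags, and the pooled `range`.
#' @export
build_training_set <- function(stacks, k = 6L) {
  if (is.array(stacks) && length(dim(stacks)) == 3) {
    stacks <- lapply(seq_len(dim(stacks)[3]), function(i)
      snapshot_stack(stacks[, , i, drop = FALSE]))
    k <- 1L
  }
  stopifnot(length(stacks) >= 1)
  keep <- vapply(stacks, function(s) n_frames(s) >= k, logical(1))
  if (any(!keep))
    message(sum(!keep), " wave(s) with fewer than ", k, " frames skipped")
  stacks <- stacks[keep]
  if (!length(stacks)) stop("no wave has enough frames")
  d1 <- dim(stacks[[1]]$frames)
  n <- length(stacks)
  items <- array(0, c(d1[1], d1[2], k, n))
  lo <- hi <- numeric(n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    x <- if (n_frames(stacks[[i]]) == k) stacks[[i]]$frames
    else select_evenly_spaced(stacks[[i]], k)$frames
    lo[i] <- min(x); hi[i] <- max(x)
    if (hi[i] > lo[i]) {
      items[, , , i] <- 2 * (x - lo[i]) / (hi[i] - lo[i]) - 1
    } else {
      items[, , , i] <- 0
      degen[i] <- TRUE
    }
  }
  structure(list(items = items, lo = lo, hi = hi, degenerate = degen,
                 range = c(min(lo), max(hi)), k = k),
            class = "gan_training_set")
}

#' Invert the training-set normalisation
#' @param x values in `[-1, 1]`.
#' @param range `c(lo, hi)` target range.
#' @return values mapped linearly onto `range`.
#' @export
denormalize_items <- function(x, range) {
  (x + 1) / 2 * (range[2] - range[1]) + range[1]
}

## discriminator probability head: htan output mapped to [0, 1]
d_prob <- function(h, eps = 1e-6) {
  pmin(pmax((h + 1) / 2, eps), 1 - eps)
}

#' Generator score
#'
#' `S_G = mean(Y_generated)`: the mean discriminator probability assigned to
#' generated images.  0.5 is the ideal-equilibrium value.
#'
#' @param p_generated probabilities in `[0, 1]` (non-empty).
#' @return scalar score.
#' @export
generator_score <- function(p_generated) {
  if (!length(p_generated)) stop("empty probability vector")
  stopifnot(all(p_generated >= 0 & p_generated <= 1))
  mean(p_generated)
}

#' Discriminator score
#'
#' `S_D = 0.5 mean(Y_real) + 0.5 mean(1 - Y_generated)`: 1 for a perfect
#' discriminator, 0.5 at chance.
#'
#' @param p_real,p_generated probabilities in `[0, 1]` (non-empty).
#' @return scalar score.
#' @export
discriminator_score <- function(p_real, p_generated) {
  if (!length(p_real) || !length(p_generated)) stop("empty probability vector")
  stopifnot(all(p_real >= 0 & p_real <= 1),
            all(p_generated >= 0 & p_generated <= 1))
  0.5 * mean(p_real) + 0.5 * mean(1 - p_generated)
}

#' Train the adversarial snapshot model
#'
#' Alternating minibatch updates of discriminator and generator under the
#' minimax objective `min_G max_D E[log D(x)] + E[log(1 - D(G(z)))]` with
#' Adam at the configured learning rates.  The generator step uses the
#' standard non-saturating surrogate (`min_G -E[log D(G(z))]`), which has
#' the same fixed point but usable early gradients.  Scores `S_G` and `S_D`
#' and both losses are logged every `log_every` iterations.  Fully seeded:
#' identical seeds give identical histories.
#'
#' @param model a `gan_model` from [gan_init()].
#' @param data a `gan_training_set` from [build_training_set()].
#' @param iterations optional override of `config$iterations`.
#' @return list with the updated `model` and `history` (data.frame:
#'   iteration, s_g, s_d, loss_d, loss_g).
#' @export
gan_train <- function(model, data, iterations = NULL) {
  stopifnot(inherits(model, "gan_model"), inherits(data, "gan_training_set"))
  cfg <- model$config
  iters <- if (is.null(iterations)) cfg$iterations else iterations
  d <- dim(data$items)
  if (d[1] != cfg$image_size || d[3] != cfg$n_planes)
    stop("training items do not match the configured output shape")
  n_items <- d[4]
  bs <- min(cfg$batch_size, n_items)
  model$data_range <- data$range
  hist <- list()
  with_seed(derive_seed(cfg$seed, "train"), {
    ## discriminator warm-up: D-only updates on real/fake batches
    for (wu in seq_len(cfg$d_warmup %||% 0L)) {
      idx <- sample.int(n_items, bs, replace = n_items < bs)
      x_real <- data$items[, , , idx, drop = FALSE]
      z <- matrix(stats::rnorm(cfg$latent_len * bs, cfg$noise_mean,
                               cfg$noise_sd), cfg$latent_len, bs)
      x_fake <- nn_forward(model$G, z)$out
      dfwd_r <- nn_forward(model$D, x_real)
      dfwd_f <- nn_forward(model$D, x_fake)
      p_r <- d_prob(dfwd_r$out)
      p_f <- d_prob(dfwd_f$out)
      dh_r <- -1 / (2 * bs * p_r)
      dh_f <- 1 / (2 * bs * (1 - p_f))
      gr_r <- nn_backward(model$D, dfwd_r$caches, dh_r)$grads
      gr_f <- nn_backward(model$D, dfwd_f$caches, dh_f)$grads
      gsum <- mapply(function(a, b) {
        if (is.null(a)) NULL else list(W = a$W + b$W, b = a$b + b$b)
      }, gr_r, gr_f, SIMPLIFY = FALSE)
      model$t_d <- model$t_d + 1L
      up <- adam_step(model$D, gsum, model$adam_D, cfg$lr_d, model$t_d)
      model$D <- up$layers; model$adam_D <- up$state
    }
    for (it in seq_len(iters)) {
      idx <- sample.int(n_items, bs, replace = n_items < bs)
      x_real <- data$items[, , , idx, drop = FALSE]

      ## ---- discriminator step
      z <- matrix(stats::rnorm(cfg$latent_len * bs, cfg$noise_mean,
                               cfg$noise_sd), cfg$latent_len, bs)
      gfwd <- nn_forward(model$G, z)
      x_fake <- gfwd$out
      dfwd_r <- nn_forward(model$D, x_real)
      dfwd_f <- nn_forward(model$D, x_fake)
      p_r <- d_prob(dfwd_r$out)
      p_f <- d_prob(dfwd_f$out)
      loss_d <- -mean(log(p_r)) - mean(log(1 - p_f))
      if (!is.finite(loss_d)) stop("non-finite discriminator loss at iteration ", it)
      ## d loss / d h  (h = tanh head output, p = (h+1)/2)
      dh_r <- -1 / (2 * bs * p_r)
      dh_f <- 1 / (2 * bs * (1 - p_f))
      if (it %% max(1L, cfg$d_every %||% 1L) == 0) {
        gr_r <- nn_backward(model$D, dfwd_r$caches, dh_r)$grads
        gr_f <- nn_backward(model$D, dfwd_f$caches, dh_f)$grads
        gsum <- mapply(function(a, b) {
          if (is.null(a)) NULL else list(W = a$W + b$W, b = a$b + b$b)
        }, gr_r, gr_f, SIMPLIFY = FALSE)
        model$t_d <- model$t_d + 1L
        up <- adam_step(model$D, gsum, model$adam_D, cfg$lr_d, model$t_d)
        model$D <- up$layers; model$adam_D <- up$state
      }

      ## ---- generator step (non-saturating)
      z <- matrix(stats::rnorm(cfg$latent_len * bs, cfg$noise_mean,
                               cfg$noise_sd), cfg$latent_len, bs)
      gfwd <- nn_forward(model$G, z)
      dfwd <- nn_forward(model$D, gfwd$out)
      p_g <- d_prob(dfwd$out)
      loss_g <- -mean(log(p_g))
      if (!is.finite(loss_g)) stop("non-finite generator loss at iteration ", it)
      dh_g <- -1 / (2 * bs * p_g)
      dback <- nn_backward(model$D, dfwd$caches, dh_g)
      gr_g <- nn_backward(model$G, gfwd$caches, dback$dinput)$grads
      model$t_g <- model$t_g + 1L
      up <- adam_step(model$G, gr_g, model$adam_G, cfg$lr_g, model$t_g)
      model$G <- up$layers; model$adam_G <- up$state

      model$iter <- model$iter + 1L
      if (it == 1 || it %% cfg$log_every == 0 || it == iters) {
        hist[[length(hist) + 1L]] <- data.frame(
          iteration = model$iter,
          s_g = generator_score(as.vector(p_g)),
          s_d = discriminator_score(as.vector(p_r), as.vector(p_f)),
          loss_d = loss_d, loss_g = loss_g)
      }
    }
  })
  list(model = model, history = do.call(rbind, hist))
}

#' Sample snapshot volumes from the generator
#'
#' Feeds seeded Gaussian latents through the generator and denormalises the
#' tanh output onto the training-data value range.
#'
#' @param model a trained `gan_model`.
#' @param n number of samples (> 0).
#' @param noise_mean,noise_sd latent statistics (defaults from the config).
#' @param seed integer seed.
#' @param denormalize map outputs back to data units.
#' @return array (h, w, planes, n).
#' @export
gan_sample <- function(model, n, noise_mean = NULL, noise_sd = NULL,
                       seed = 1L, denormalize = TRUE) {
  stopifnot(inherits(model, "gan_model"), n > 0)
  cfg <- model$config
  if (is.null(noise_mean)) noise_mean <- cfg$noise_mean
  if (is.null(noise_sd)) noise_sd <- cfg$noise_sd
  z <- with_seed(seed, matrix(stats::rnorm(cfg$latent_len * n, noise_mean,
                                           noise_sd), cfg$latent_len, n))
  out <- nn_forward(model$G, z)$out
  if (denormalize) out <- denormalize_items(out, model$data_range)
  out
}

#' Participation ratio of generated snapshots under varied input noise
#'
#' For every (mean, sd) latent setting, generates `n_per_setting` snapshot
#' volumes and computes the PR of each (spatial-SVD pooled over planes),
#' reporting mean and SD per setting.
#'
#' @param model a trained `gan_model`.
#' @param sds,means latent noise settings to sweep.
#' @param n_per_setting samples per setting.
#' @param seed integer seed.
#' @return data.frame: noise_mean, noise_sd, mean_pr, sd_pr, n.
#' @export
gan_noise_sweep <- function(model, sds = c(25, 50, 100), means = 0,
                            n_per_setting = 100L, seed = 1L) {
  grid <- expand.grid(noise_mean = means, noise_sd = sds)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    x <- gan_sample(model, n_per_setting, grid$noise_mean[g],
                    grid$noise_sd[g],
                    seed = derive_seed(seed, paste0("sweep", g)))
    prs <- vapply(seq_len(dim(x)[4]), function(i)
      stack_pr(snapshot_stack(array(x[, , , i], dim(x)[1:3]))), numeric(1))
    data.frame(noise_mean = grid$noise_mean[g], noise_sd = grid$noise_sd[g],
               mean_pr = mean(prs), sd_pr = stats::sd(prs),
               n = n_per_setting)
  })
  do.call(rbind, rows)
}

#' Frechet distance between two feature distributions
#'
#' Gaussian-fit Frechet distance
#' `|mu_a - mu_b|^2 + Tr(S_a + S_b - 2 (S_a S_b)^{1/2})`, computed against a
#' pluggable feature embedding (no pretrained classifier is involved).
#' Covariances that are numerically non-PSD are regularised by a small
#' diagonal jitter with a warning.
#'
#' @param features_a,features_b matrices, one sample per row (>= 2 rows).
#' @return scalar distance (>= 0).
#' @export
frechet_distance <- function(features_a, features_b) {
  stopifnot(is.matrix(features_a), is.matrix(features_b),
            nrow(features_a) >= 2, nrow(features_b) >= 2,
            ncol(features_a) == ncol(features_b))
  mu_a <- colMeans(features_a); mu_b <- colMeans(features_b)
  S_a <- stats::cov(features_a); S_b <- stats::cov(features_b)
  sqa <- sqrtm_sym(S_a)
  M <- sqa %*% S_b %*% sqa
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    warning("non-PSD cross-covariance; adding diagonal jitter")
    M <- M + diag(1e-8 * max(abs(ev), 1), nrow(M))
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  }
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  max(0, sum((mu_a - mu_b)^2) + sum(diag(S_a)) + sum(diag(S_b)) - 2 * tr_sqrt)
}

## symmetric PSD matrix square root via eigendecomposition
sqrtm_sym <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Inception-style score from class probabilities
#'
#' `exp(mean KL(p(y|x) || mean_x p(y|x)))` over samples, against a pluggable
#' classifier's class-probability rows.  1 when every sample yields the same
#' distribution; larger when per-sample distributions are confident and
#' diverse.
#'
#' @param class_probs matrix, one probability row per sample (rows sum to 1).
#' @return scalar score (>= 1 up to numerical tolerance).
#' @export
inception_style_score <- function(class_probs) {
  stopifnot(is.matrix(class_probs), nrow(class_probs) >= 1)
  if (any(abs(rowSums(class_probs) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  pbar <- colMeans(class_probs)
  eps <- 1e-12
  kl <- rowSums(class_probs * (log(class_probs + eps) -
                                 rep(log(pbar + eps), each = nrow(class_probs))))
  exp(mean(kl))
}

#' Save / load a model checkpoint as JSON
#'
#' Architecture and flat parameter arrays in a single documented text file.
#'
#' @param model a `gan_model`.
#' @param path output file.
#' @return `save_gan` returns `path` invisibly; `load_gan` returns the model.
#' @export
save_gan <- function(model, path) {
  stopifnot(inherits(model, "gan_model"))
  strip <- function(layers) lapply(layers, function(l) {
    l$W <- if (!is.null(l$W)) list(dim = dim(l$W), data = as.vector(l$W))
    l
  })
  obj <- list(config = unclass(model$config),
              iter = model$iter, t_g = model$t_g, t_d = model$t_d,
              data_range = model$data_range,
              G = strip(model$G), D = strip(model$D))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- structure(lapply(obj$config, function(f)
    if (length(f) > 1) unlist(f) else f[[1]] %||% f), class = "gan_config")
  restore <- function(layers) lapply(layers, function(l) {
    out <- lapply(l, function(f) if (is.list(f)) unlist(f) else f)
    if (!is.null(l$W))
      out$W <- matrix(unlist(l$W$data), unlist(l$W$dim)[1],
                      unlist(l$W$dim)[2])
    if (is.null(out$b) && !is.null(l$b)) out$b <- unlist(l$b)
    out
  })
  G <- restore(obj$G); D <- restore(obj$D)
  structure(list(G = G, D = D, config = cfg,
                 adam_G = adam_state(G), adam_D = adam_state(D),
                 iter = obj$iter[[1]], t_g = obj$t_g[[1]],
                 t_d = obj$t_d[[1]],
                 data_range = unlist(obj$data_range)),
            class = "gan_model")
}
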