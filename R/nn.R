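## -- minimal tensor network engine -------------------------------------------
##
## Just enough machinery for the adversarial snapshot model: dense and 2-D
## convolution layers (im2col), nearest-neighbour upsampling, ReLU /
## leaky-ReLU / tanh activations, manual backprop, and Adam.  Tensors are
## (h, w, c, n) arrays; dense activations are (features, n) matrices.
## Everything is plain R matrix algebra (BLAS does the heavy lifting); the
## model scales the field actually exercises here (16x16 to 64x64 images,
## thousands of iterations) does not need compiled code.

## zero padding on the spatial dims of an (h, w, c, n) array
pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

unpad_hw <- function(x, p, h, w) {
  if (p == 0) return(x)
  x[p + seq_len(h), p + seq_len(w), , , drop = FALSE]
}

## linear-index machinery shared by im2col and col2im
conv_geom <- function(hp, wp, kh, kw, stride) {
  oh <- (hp - kh) %/% stride + 1L
  ow <- (wp - kw) %/% stride + 1L
  offs <- as.vector(outer(0:(kh - 1), (0:(kw - 1)) * hp, `+`))
  starts <- as.vector(outer(seq(1, by = stride, length.out = oh),
                            (seq(1, by = stride, length.out = ow) - 1) * hp,
                            `+`))
  list(oh = oh, ow = ow, offs = offs, starts = starts)
}

## (kh*kw*c) x (oh*ow*n) patch matrix from a padded (hp, wp, c, n) array
im2col <- function(xp, kh, kw, stride, geom = NULL) {
  d <- dim(xp)
  g <- if (is.null(geom)) conv_geom(d[1], d[2], kh, kw, stride) else geom
  X2 <- matrix(xp, d[1] * d[2], d[3] * d[4])
  idx <- outer(g$offs, g$starts, `+`)                  # (kh*kw) x (oh*ow)
  cols <- X2[as.vector(idx), , drop = FALSE]           # (kh*kw*oh*ow) x (c*n)
  cols <- array(cols, c(kh * kw, g$oh * g$ow, d[3], d[4]))
  cols <- aperm(cols, c(1, 3, 2, 4))
  dim(cols) <- c(kh * kw * d[3], g$oh * g$ow * d[4])
  cols
}

## scatter-add inverse of im2col; returns a padded-shape gradient array
col2im <- function(dcols, dpad, kh, kw, stride, geom) {
  g <- geom
  c <- dpad[3]; n <- dpad[4]
  dc <- array(dcols, c(kh * kw, c, g$oh * g$ow, n))
  dc <- aperm(dc, c(1, 3, 2, 4))                       # (kh*kw, oh*ow, c, n)
  out <- matrix(0, dpad[1] * dpad[2], c * n)
  for (q in seq_len(kh * kw)) {
    sl <- matrix(dc[q, , , ], g$oh * g$ow, c * n)
    tgt <- g$starts + g$offs[q]
    out[tgt, ] <- out[tgt, ] + sl
  }
  array(out, dpad)
}

## -- layers ------------------------------------------------------------------

## init_gain rescales the He initialisation: < 1 keeps saturating
## activations (tanh heads, large-variance latent inputs) in their linear
## range at the start of training
nn_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L,
                      activation = c("relu", "lrelu", "tanh", "linear"),
                      init_gain = 1) {
  activation <- match.arg(activation)
  fan_in <- kernel * kernel * in_ch
  list(type = "conv2d", kernel = kernel, stride = stride, pad = pad,
       in_ch = in_ch, out_ch = out_ch, activation = activation,
       W = matrix(stats::rnorm(out_ch * fan_in, 0,
                               init_gain * sqrt(2 / fan_in)),
                  out_ch, fan_in),
       b = numeric(out_ch))
}

nn_dense <- function(in_dim, out_dim,
                     activation = c("relu", "lrelu", "tanh", "linear"),
                     init_gain = 1) {
  activation <- match.arg(activation)
  list(type = "dense", in_dim = in_dim, out_dim = out_dim,
       activation = activation,
       W = matrix(stats::rnorm(out_dim * in_dim, 0,
                               init_gain * sqrt(2 / in_dim)),
                  out_dim, in_dim),
       b = numeric(out_dim))
}

nn_upsample <- function() list(type = "upsample")

nn_reshape <- function(h, w, c) list(type = "reshape", h = h, w = w, c = c)

nn_flatten <- function() list(type = "flatten")

act_forward <- function(a, act) {
  switch(act,
         relu = pmax(a, 0),
         lrelu = ifelse(a > 0, a, 0.2 * a),
         tanh = tanh(a),
         linear = a)
}

act_backward <- function(d, a_pre, a_post, act) {
  switch(act,
         relu = d * (a_pre > 0),
         lrelu = d * ifelse(a_pre > 0, 1, 0.2),
         tanh = d * (1 - a_post^2),
         linear = d)
}

## forward pass through a layer list; returns output and per-layer caches
nn_forward <- function(layers, x) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv2d") {
      d <- dim(x)
      xp <- pad_hw(x, l$pad)
      dp <- dim(xp)
      g <- conv_geom(dp[1], dp[2], l$kernel, l$kernel, l$stride)
      cols <- im2col(xp, l$kernel, l$kernel, l$stride, g)
      pre_m <- l$W %*% cols + l$b
      pre <- aperm(array(pre_m, c(l$out_ch, g$oh, g$ow, d[4])), c(2, 3, 1, 4))
      post <- act_forward(pre, l$activation)
      caches[[i]] <- list(cols = cols, geom = g, dpad = dp, in_dim = d,
                          pre = pre, post = post)
      x <- post
    } else if (l$type == "dense") {
      pre <- l$W %*% x + l$b
      post <- act_forward(pre, l$activation)
      caches[[i]] <- list(x = x, pre = pre, post = post)
      x <- post
    } else if (l$type == "upsample") {
      d <- dim(x)
      out <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
               drop = FALSE]
      caches[[i]] <- list(in_dim = d)
      x <- out
    } else if (l$type == "reshape") {
      caches[[i]] <- list(in_dim = dim(x))
      x <- array(x, c(l$h, l$w, l$c, ncol(x)))
    } else if (l$type == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(in_dim = d)
      x <- matrix(x, prod(d[1:3]), d[4])
    }
  }
  list(out = x, caches = caches)
}

## backward pass; returns gradient lists (same shape as layer params) and
## the gradient w.r.t. the input
nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  d <- dout
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cc <- caches[[i]]
    if (l$type == "conv2d") {
      d <- act_backward(d, cc$pre, cc$post, l$activation)
      n <- cc$in_dim[4]
      dm <- matrix(aperm(d, c(3, 1, 2, 4)), l$out_ch,
                   cc$geom$oh * cc$geom$ow * n)
      grads[[i]] <- list(W = dm %*% t(cc$cols), b = rowSums(dm))
      dcols <- t(l$W) %*% dm
      dpadded <- col2im(dcols, cc$dpad, l$kernel, l$kernel, l$stride, cc$geom)
      d <- unpad_hw(dpadded, l$pad, cc$in_dim[1], cc$in_dim[2])
    } else if (l$type == "dense") {
      d <- act_backward(d, cc$pre, cc$post, l$activation)
      grads[[i]] <- list(W = d %*% t(cc$x), b = rowSums(d))
      d <- t(l$W) %*% d
    } else if (l$type == "upsample") {
      di <- cc$in_dim
      acc <- array(0, di)
      for (a in 1:2) for (b in 1:2) {
        acc <- acc + d[seq(a, by = 2, length.out = di[1]),
                       seq(b, by = 2, length.out = di[2]), , , drop = FALSE]
      }
      d <- acc
    } else if (l$type == "reshape") {
      d <- matrix(d, prod(cc$in_dim[-length(cc$in_dim)]),
                  dim(d)[4])
      dim(d) <- cc$in_dim
    } else if (l$type == "flatten") {
      d <- array(d, cc$in_dim)
    }
  }
  list(grads = grads, dinput = d)
}

## -- Adam --------------------------------------------------------------------

adam_state <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W))
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)
    else NULL
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mWh <- s$mW / (1 - beta1^t); vWh <- s$vW / (1 - beta2^t)
    mbh <- s$mb / (1 - beta1^t); vbh <- s$vb / (1 - beta2^t)
    layers[[i]]$W <- layers[[i]]$W - lr * mWh / (sqrt(vWh) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * mbh / (sqrt(vbh) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
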