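# Layer objects for the network engine.
#
# A layer is a mutable environment with fields:
#   type    -- string used for parameter walks and architecture audits
#   params  -- named list of numeric arrays (absent for activation layers)
#   grads   -- named list matching params, accumulated by layer_backward()
#   cache   -- whatever the forward pass must retain for the backward pass
# Feature blocks are arrays with dim (H, W, C, N).

new_layer <- function(type, params = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) p * 0)
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ConvNeXt-style small-normal init (sd 0.02), zero biases. With layer
# normalization throughout, the function is insensitive to weight MAGNITUDE,
# so a small init maximizes how fast Adam (whose per-step displacement is
# bounded by the learning rate) can reorient feature directions.
init_w <- function(dims, sd = 0.02) array(rnorm(prod(dims), 0, sd), dims)

layer_conv <- function(k, cin, cout, stride = 1, pad = 0) {
  new_layer("conv",
            params = list(w = init_w(c(k, k, cin, cout)), b = numeric(cout)),
            extra = list(stride = stride, pad = pad))
}

layer_dwconv <- function(k, ch, pad = (k - 1L) %/% 2L) {
  new_layer("dwconv",
            params = list(w = init_w(c(k, k, ch)), b = numeric(ch)),
            extra = list(pad = pad))
}

layer_layernorm <- function(ch, eps = 1e-6) {
  new_layer("layernorm",
            params = list(gamma = rep(1, ch), beta = numeric(ch)),
            extra = list(eps = eps))
}

layer_batchnorm <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("batchnorm",
            params = list(gamma = rep(1, ch), beta = numeric(ch)),
            extra = list(eps = eps, momentum = momentum,
                         run_mean = numeric(ch), run_var = rep(1, ch)))
}

layer_gelu <- function() new_layer("gelu")

layer_leakyrelu <- function(slope = 0.2) {
  new_layer("leakyrelu", extra = list(slope = slope))
}

layer_linear <- function(din, dout) {
  new_layer("linear",
            params = list(w = init_w(c(din, dout)), b = numeric(dout)))
}

# learnable scalar output gain + offset (y = s*x + b). Placed after a
# sigmoid head's 1x1 convolution: the gain supplies the logit dynamic range
# that small-magnitude weights cannot reach within a short Adam schedule.
layer_scale <- function(init_gain = 1) {
  new_layer("scale", params = list(s = init_gain, b = 0))
}

# per-sample spatial standardization of a 1-channel logit map: removes the
# map's DC component so an L1-through-sigmoid objective cannot collapse the
# whole map into the sigmoid's saturated regime under class imbalance.
layer_mapnorm <- function(eps = 1e-6) {
  new_layer("mapnorm", extra = list(eps = eps))
}

# channel-first matrix view (C x H*W*N) used by both norm layers
.to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(3L, 1L, 2L, 4L)), nrow = d[3])
}
.from_cmat <- function(m, d) {
  aperm(array(m, c(d[3], d[1], d[2], d[4])), c(2L, 3L, 1L, 4L))
}

layer_forward <- function(l, x, train = TRUE) {
  switch(l$type,
    conv = {
      l$cache <- x
      .conv2d_forward(x, l$params$w, l$params$b, l$stride, l$pad)
    },
    dwconv = {
      l$cache <- x
      .dwconv_forward(x, l$params$w, l$params$b, l$pad)
    },
    layernorm = {
      d <- dim(x)
      xm <- .to_cmat(x)
      mu <- colMeans(xm)
      xc <- sweep(xm, 2L, mu)
      v <- colMeans(xc * xc)
      inv <- 1 / sqrt(v + l$eps)
      xhat <- sweep(xc, 2L, inv, `*`)
      l$cache <- list(xhat = xhat, inv = inv, d = d)
      .from_cmat(xhat * l$params$gamma + l$params$beta, d)
    },
    batchnorm = {
      d <- dim(x)
      xm <- .to_cmat(x)
      if (train) {
        mu <- rowMeans(xm)
        xc <- xm - mu
        v <- rowMeans(xc * xc)
        l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
        l$run_var <- (1 - l$momentum) * l$run_var + l$momentum * v
      } else {
        mu <- l$run_mean
        v <- l$run_var
        xc <- xm - mu
      }
      inv <- 1 / sqrt(v + l$eps)
      xhat <- xc * inv
      l$cache <- list(xhat = xhat, inv = inv, d = d, train = train)
      .from_cmat(xhat * l$params$gamma + l$params$beta, d)
    },
    gelu = {
      l$cache <- x
      x * pnorm(x)
    },
    leakyrelu = {
      l$cache <- x
      ifelse(x > 0, x, l$slope * x)
    },
    linear = {
      l$cache <- x  # x: matrix N x din
      sweep(x %*% l$params$w, 2L, l$params$b, `+`)
    },
    scale = {
      l$cache <- x
      l$params$s * x + l$params$b
    },
    mapnorm = {
      d <- dim(x)
      xm <- matrix(x, ncol = d[4])            # (H*W*C) x N, C = 1
      mu <- colMeans(xm)
      xc <- sweep(xm, 2L, mu)
      v <- colMeans(xc * xc)
      inv <- 1 / sqrt(v + l$eps)
      xhat <- sweep(xc, 2L, inv, `*`)
      l$cache <- list(xhat = xhat, inv = inv, d = d)
      array(xhat, d)
    },
    stopf("unknown layer type '%s'", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      g <- .conv2d_backward(l$cache, l$params$w, dy, l$stride, l$pad)
      l$grads$w <- l$grads$w + g$dw
      l$grads$b <- l$grads$b + g$db
      g$dx
    },
    dwconv = {
      g <- .dwconv_backward(l$cache, l$params$w, dy, l$pad)
      l$grads$w <- l$grads$w + g$dw
      l$grads$b <- l$grads$b + g$db
      g$dx
    },
    layernorm = {
      cc <- l$cache
      dym <- .to_cmat(dy)
      l$grads$gamma <- l$grads$gamma + rowSums(dym * cc$xhat)
      l$grads$beta <- l$grads$beta + rowSums(dym)
      dxh <- dym * l$params$gamma
      C <- nrow(dxh)
      s1 <- colSums(dxh)
      s2 <- colSums(dxh * cc$xhat)
      dxm <- sweep(dxh * C - matrix(s1, C, length(s1), byrow = TRUE) -
                     sweep(cc$xhat, 2L, s2, `*`), 2L, cc$inv / C, `*`)
      .from_cmat(dxm, cc$d)
    },
    batchnorm = {
      cc <- l$cache
      dym <- .to_cmat(dy)
      l$grads$gamma <- l$grads$gamma + rowSums(dym * cc$xhat)
      l$grads$beta <- l$grads$beta + rowSums(dym)
      dxh <- dym * l$params$gamma
      if (cc$train) {
        M <- ncol(dxh)
        dxm <- (dxh * M - rowSums(dxh) - cc$xhat * rowSums(dxh * cc$xhat)) *
          (cc$inv / M)
      } else {
        dxm <- dxh * cc$inv
      }
      .from_cmat(dxm, cc$d)
    },
    gelu = {
      x <- l$cache
      dy * (pnorm(x) + x * dnorm(x))
    },
    leakyrelu = {
      dy * ifelse(l$cache > 0, 1, l$slope)
    },
    linear = {
      l$grads$w <- l$grads$w + crossprod(l$cache, dy)
      l$grads$b <- l$grads$b + colSums(dy)
      dy %*% t(l$params$w)
    },
    scale = {
      l$grads$s <- l$grads$s + sum(dy * l$cache)
      l$grads$b <- l$grads$b + sum(dy)
      l$params$s * dy
    },
    mapnorm = {
      cc <- l$cache
      dym <- matrix(dy, ncol = cc$d[4])
      M <- nrow(dym)
      s1 <- colSums(dym)
      s2 <- colSums(dym * cc$xhat)
      dxm <- sweep(dym * M - matrix(s1, M, length(s1), byrow = TRUE) -
                     sweep(cc$xhat, 2L, s2, `*`), 2L, cc$inv / M, `*`)
      array(dxm, cc$d)
    },
    stopf("unknown layer type '%s'", l$type))
}

# Flatten any nested list structure into the layer environments it contains.
flatten_layers <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$type) && is.null(x$layers)) return(list(x))
    x <- as.list(x)$layers
  }
  if (is.list(x)) return(unlist(lapply(x, flatten_layers), recursive = FALSE))
  list()
}

zero_grads <- function(layers) {
  for (l in flatten_layers(layers)) {
    for (nm in names(l$grads)) l$grads[[nm]][] <- 0
  }
  invisible(NULL)
}

# Deep copies of trainable state, for checkpointing and freeze audits.
get_params <- function(layers) {
  lapply(flatten_layers(layers), function(l) l$params)
}
set_params <- function(layers, snapshot) {
  ll <- flatten_layers(layers)
  stopifnot(length(ll) == length(snapshot))
  for (i in seq_along(ll)) ll[[i]]$params <- snapshot[[i]]
  invisible(NULL)
}

# Adam optimizer over a set of layers (beta1 per the training configuration;
# bias-corrected moments, epsilon 1e-8).
optim_adam <- function(layers, lr = 1e-4, beta1 = 0.9, beta2 = 0.99,
                       eps = 1e-8) {
  ll <- flatten_layers(layers)
  st <- lapply(ll, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
  e <- new.env(parent = emptyenv())
  e$layers <- ll
  e$state <- st
  e$lr <- lr
  e$beta1 <- beta1
  e$beta2 <- beta2
  e$eps <- eps
  e$t <- 0L
  e
}

adam_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      s <- opt$state[[i]][[nm]]
      s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
      s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g * g
      opt$state[[i]][[nm]] <- s
      l$params[[nm]] <- l$params[[nm]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + opt$eps)
    }
  }
  invisible(NULL)
}
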