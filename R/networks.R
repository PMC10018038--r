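# Network architectures: ConvNeXt U-shape segmentation network, mask
# reconstruction auto-encoder, and the latent-space discriminator.

#' Network configuration
#'
#' Describes the scalable ConvNeXt backbone: per-stage block counts, per-stage
#' channel widths, class count and input geometry. The default follows the
#' ConvNeXt-Tiny convention: depths (3,3,9,3) with widths (96,192,384,768).
#' The stem downsamples by 4 and each of the three inter-stage downsamplers by
#' 2, so the input size must be divisible by 32.
#'
#' @param depths integer vector of length 4; ConvNeXt blocks per stage.
#' @param dims integer vector of length 4; channel width per stage.
#' @param num_classes number of segmentation classes (default 2:
#'   background/LAA).
#' @param input_size `(height, width)` in pixels, both divisible by 32.
#' @param in_channels input image channels (1 for grayscale TEE).
#' @return A `laa_network_config` list.
#' @export
network_config <- function(depths = c(3L, 3L, 9L, 3L),
                           dims = c(96L, 192L, 384L, 768L),
                           num_classes = 2L,
                           input_size = c(448L, 448L),
                           in_channels = 1L) {
  if (length(depths) != 4L || length(dims) != 4L)
    stopf("depths and dims must each have length 4")
  if (any(dims <= 0) || any(depths <= 0))
    stopf("depths and dims must be positive")
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (any(input_size %% 32L != 0L))
    stopf("input_size must be divisible by 32 (stem /4 then three /2 stages)")
  structure(list(depths = as.integer(depths), dims = as.integer(dims),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels)),
            class = "laa_network_config")
}

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  m
}

#' ConvNeXt block
#'
#' One inverted-bottleneck ConvNeXt block: depthwise 7x7 convolution, layer
#' normalization, 1x1 convolution expanding to `4*dim`, GELU, 1x1 convolution
#' back to `dim`, then a residual addition with the block input. Layer
#' normalization is the only normalization used (no batch norm).
#'
#' @param dim channel width of the block input and output.
#' @return A block module usable with [cnx_forward()].
#' @export
convnext_block <- function(dim) {
  m <- new_module("convnext_block")
  m$dim <- as.integer(dim)
  m$layers <- list(dw = layer_dwconv(7L, dim),
                   ln = layer_layernorm(dim),
                   pw1 = layer_conv(1L, dim, 4L * dim),
                   act = layer_gelu(),
                   pw2 = layer_conv(1L, 4L * dim, dim))
  m
}

#' @rdname convnext_block
#' @param block a module from [convnext_block()].
#' @param x feature block, array `(H, W, dim, N)`.
#' @param train logical; training mode (kept for interface symmetry).
#' @export
cnx_forward <- function(block, x, train = TRUE) {
  if (dim(x)[3] != block$dim)
    stopf("convnext_block: input width %d != block dim %d",
          dim(x)[3], block$dim)
  t <- layer_forward(block$layers$dw, x, train)
  t <- layer_forward(block$layers$ln, t, train)
  t <- layer_forward(block$layers$pw1, t, train)
  t <- layer_forward(block$layers$act, t, train)
  t <- layer_forward(block$layers$pw2, t, train)
  t + x
}

cnx_backward <- function(block, dy) {
  d <- layer_backward(block$layers$pw2, dy)
  d <- layer_backward(block$layers$act, d)
  d <- layer_backward(block$layers$pw1, d)
  d <- layer_backward(block$layers$ln, d)
  d <- layer_backward(block$layers$dw, d)
  d + dy
}

#' Build the ConvNeXt encoder
#'
#' Stem (4x4 convolution, stride 4, then layer normalization), four stages of
#' ConvNeXt blocks, and between stages a downsampler of layer normalization
#' followed by a 2x2 stride-2 convolution. Returns per-stage feature blocks
#' (used as U-shape skips) plus the bottleneck latent at 1/32 resolution.
#' Contains no batch normalization anywhere.
#'
#' @param cfg a [network_config()].
#' @return An encoder module for [encoder_forward()].
#' @export
build_encoder <- function(cfg) {
  m <- new_module("encoder")
  m$cfg <- cfg
  d <- cfg$dims
  stages <- lapply(1:4, function(s)
    lapply(seq_len(cfg$depths[s]), function(i) convnext_block(d[s])))
  downs <- lapply(1:3, function(s)
    list(ln = layer_layernorm(d[s]),
         conv = layer_conv(2L, d[s], d[s + 1L], stride = 2L)))
  m$layers <- list(stem = list(conv = layer_conv(4L, cfg$in_channels, d[1],
                                                 stride = 4L),
                               ln = layer_layernorm(d[1])),
                   stages = stages, downs = downs)
  m
}

#' @rdname build_encoder
#' @param enc encoder module.
#' @param x image batch, array `(H, W, in_channels, N)` with H, W divisible
#'   by 32.
#' @param train logical; training mode.
#' @return list with `latent` (array `(H/32, W/32, dims[4], N)`) and `skips`
#'   (stage outputs at 1/4, 1/8, 1/16 resolution).
#' @export
encoder_forward <- function(enc, x, train = TRUE) {
  dm <- dim(x)
  if (any(dm[1:2] %% 32L != 0L))
    stopf("encoder input size %dx%d is not divisible by 32", dm[1], dm[2])
  if (dm[3] != enc$cfg$in_channels)
    stopf("encoder expects %d input channel(s), got %d",
          enc$cfg$in_channels, dm[3])
  t <- layer_forward(enc$layers$stem$conv, x, train)
  t <- layer_forward(enc$layers$stem$ln, t, train)
  skips <- vector("list", 3L)
  for (s in 1:4) {
    for (b in enc$layers$stages[[s]]) t <- cnx_forward(b, t, train)
    if (s < 4L) {
      skips[[s]] <- t
      t <- layer_forward(enc$layers$downs[[s]]$ln, t, train)
      t <- layer_forward(enc$layers$downs[[s]]$conv, t, train)
    }
  }
  list(latent = t, skips = skips)
}

encoder_backward <- function(enc, d_latent, d_skips = NULL) {
  d <- d_latent
  for (s in 4:1) {
    if (s < 4L) {
      d <- layer_backward(enc$layers$downs[[s]]$conv, d)
      d <- layer_backward(enc$layers$downs[[s]]$ln, d)
      if (!is.null(d_skips) && !is.null(d_skips[[s]])) d <- d + d_skips[[s]]
    }
    for (b in rev(enc$layers$stages[[s]])) d <- cnx_backward(b, d)
  }
  d <- layer_backward(enc$layers$stem$ln, d)
  layer_backward(enc$layers$stem$conv, d)
}

# Two-convolution residual block used by the decoder stages.
res_block <- function(cin, cout) {
  m <- new_module("res_block")
  m$cin <- cin
  m$cout <- cout
  m$layers <- list(conv1 = layer_conv(3L, cin, cout, pad = 1L),
                   ln1 = layer_layernorm(cout),
                   act1 = layer_gelu(),
                   conv2 = layer_conv(3L, cout, cout, pad = 1L),
                   ln2 = layer_layernorm(cout),
                   act2 = layer_gelu())
  if (cin != cout) m$layers$proj <- layer_conv(1L, cin, cout)
  m
}

res_forward <- function(m, x, train = TRUE) {
  h <- layer_forward(m$layers$conv1, x, train)
  h <- layer_forward(m$layers$ln1, h, train)
  h <- layer_forward(m$layers$act1, h, train)
  h <- layer_forward(m$layers$conv2, h, train)
  h <- layer_forward(m$layers$ln2, h, train)
  r <- if (is.null(m$layers$proj)) x else layer_forward(m$layers$proj, x, train)
  layer_forward(m$layers$act2, h + r, train)
}

res_backward <- function(m, dy) {
  d <- layer_backward(m$layers$act2, dy)
  dh <- layer_backward(m$layers$ln2, d)
  dh <- layer_backward(m$layers$conv2, dh)
  dh <- layer_backward(m$layers$act1, dh)
  dh <- layer_backward(m$layers$ln1, dh)
  dh <- layer_backward(m$layers$conv1, dh)
  dr <- if (is.null(m$layers$proj)) d else layer_backward(m$layers$proj, d)
  dh + dr
}

concat_ch <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Build the decoder
#'
#' Three stages of (bilinear x2 upsampling, optional skip concatenation,
#' two-convolution residual block) lifting the bottleneck from 1/32 back to
#' 1/4 resolution, then a final bilinear x4 upsample and 1x1 convolution head
#' to `out_channels` at full input resolution. With `with_skips = FALSE`
#' (the reconstruction decoder) no concatenations occur, so all information
#' must pass through the latent.
#'
#' @param cfg a [network_config()].
#' @param with_skips use U-shape skip connections from the encoder stages.
#' @param out_channels channels of the head (class count for segmentation,
#'   1 for mask reconstruction).
#' @param sigmoid_head apply a sigmoid to the head output (reconstruction).
#' @return A decoder module for [decoder_forward()].
#' @export
build_decoder <- function(cfg, with_skips = TRUE,
                          out_channels = cfg$num_classes,
                          sigmoid_head = FALSE) {
  m <- new_module("decoder")
  m$cfg <- cfg
  m$with_skips <- with_skips
  m$sigmoid_head <- sigmoid_head
  d <- cfg$dims
  res <- vector("list", 3L)
  for (i in 1:3) {
    cin_up <- d[5L - i]                       # channels arriving from below
    cskip <- if (with_skips) d[4L - i] else 0L
    res[[i]] <- res_block(cin_up + cskip, d[4L - i])
  }
  m$layers <- list(res = res,
                   head = layer_conv(1L, d[1], out_channels))
  if (sigmoid_head) m$layers$mapnorm <- layer_mapnorm()
  m$layers$gain <- layer_scale(if (sigmoid_head) 4 else 8)
  m
}

#' @rdname build_decoder
#' @param dec decoder module.
#' @param latent bottleneck feature block `(H/32, W/32, dims[4], N)`.
#' @param skips list of three encoder stage outputs (ignored when the decoder
#'   was built with `with_skips = FALSE`).
#' @param train logical; training mode.
#' @return array `(H, W, out_channels, N)`.
#' @export
decoder_forward <- function(dec, latent, skips = NULL, train = TRUE) {
  t <- latent
  up_dims <- vector("list", 3L)
  for (i in 1:3) {
    up_dims[[i]] <- dim(t)[1:2]
    t <- .upsample_forward(t, 2L)
    if (dec$with_skips) {
      sk <- skips[[4L - i]]
      if (is.null(sk) || !all(dim(sk)[1:2] == dim(t)[1:2]))
        stopf("decoder stage %d: skip feature size mismatch", i)
      dec$cache_up_ch <- dim(t)[3]
      t <- concat_ch(t, sk)
    }
    t <- res_forward(dec$layers$res[[i]], t, train)
  }
  dec$cache_updims <- up_dims
  dec$cache_quarter <- dim(t)[1:2]
  t <- .upsample_forward(t, 4L)
  t <- layer_forward(dec$layers$head, t, train)
  if (dec$sigmoid_head) t <- layer_forward(dec$layers$mapnorm, t, train)
  t <- layer_forward(dec$layers$gain, t, train)
  if (dec$sigmoid_head) {
    s <- 1 / (1 + exp(-t))
    dec$cache_sig <- s
    t <- s
  }
  t
}

decoder_backward <- function(dec, dy) {
  d <- dy
  if (dec$sigmoid_head) d <- d * dec$cache_sig * (1 - dec$cache_sig)
  d <- layer_backward(dec$layers$gain, d)
  if (dec$sigmoid_head) d <- layer_backward(dec$layers$mapnorm, d)
  d <- layer_backward(dec$layers$head, d)
  q <- dec$cache_quarter
  d <- .upsample_backward(d, 4L, q[1], q[2])
  d_skips <- if (dec$with_skips) vector("list", 3L) else NULL
  for (i in 3:1) {
    d <- res_backward(dec$layers$res[[i]], d)
    if (dec$with_skips) {
      cin_up <- dec$cfg$dims[5L - i]
      d_skips[[4L - i]] <- d[, , cin_up + seq_len(dim(d)[3] - cin_up), ,
                             drop = FALSE]
      d <- d[, , seq_len(cin_up), , drop = FALSE]
    }
    ud <- dec$cache_updims[[i]]
    d <- .upsample_backward(d, 2L, ud[1], ud[2])
  }
  list(d_latent = d, d_skips = d_skips)
}

#' Build the segmentation network
#'
#' The U-shape network: ConvNeXt encoder plus skip-connected decoder ending in
#' a `num_classes`-channel logit head.
#'
#' @param cfg a [network_config()].
#' @return A module with `$encoder` and `$decoder`.
#' @export
build_segmentation_network <- function(cfg) {
  m <- new_module("seg_network")
  m$cfg <- cfg
  m$encoder <- build_encoder(cfg)
  m$decoder <- build_decoder(cfg, with_skips = TRUE,
                             out_channels = cfg$num_classes)
  m$layers <- list(m$encoder$layers, m$decoder$layers)
  m
}

#' Segmentation forward pass
#'
#' @param net module from [build_segmentation_network()].
#' @param image array `(H, W, 1, N)` (a plain `(H, W)` matrix or `(H, W, N)`
#'   array is promoted).
#' @param train logical; training mode.
#' @return list with `logits` `(H, W, num_classes, N)` and `latent`
#'   `(H/32, W/32, dims[4], N)`.
#' @export
seg_forward <- function(net, image, train = TRUE) {
  image <- as_batch(image, net$cfg$in_channels)
  e <- encoder_forward(net$encoder, image, train)
  logits <- decoder_forward(net$decoder, e$latent, e$skips, train)
  net$cache_skips <- TRUE
  list(logits = logits, latent = e$latent)
}

# Backward through the whole segmentation network. d_latent_extra carries
# gradients injected directly at the bottleneck (adversarial + contrastive).
seg_backward <- function(net, d_logits, d_latent_extra = NULL) {
  dd <- decoder_backward(net$decoder, d_logits)
  d_latent <- dd$d_latent
  if (!is.null(d_latent_extra)) d_latent <- d_latent + d_latent_extra
  encoder_backward(net$encoder, d_latent, dd$d_skips)
}

#' Build the mask reconstruction auto-encoder
#'
#' Same ConvNeXt encoder architecture, decoder WITHOUT skip connections and
#' with a 1-channel sigmoid head, so the binary mask must be reconstructed
#' from the bottleneck latent alone -- this is what makes the latent a shape
#' prior.
#'
#' @param cfg a [network_config()] (its `in_channels` is overridden to 1:
#'   masks are single-channel).
#' @return A module with `$encoder` and `$decoder`.
#' @export
build_reconstruction_network <- function(cfg) {
  rcfg <- cfg
  rcfg$in_channels <- 1L
  m <- new_module("recon_network")
  m$cfg <- rcfg
  m$encoder <- build_encoder(rcfg)
  m$decoder <- build_decoder(rcfg, with_skips = FALSE, out_channels = 1L,
                             sigmoid_head = TRUE)
  m$layers <- list(m$encoder$layers, m$decoder$layers)
  m
}

#' Reconstruction forward pass
#'
#' @param net module from [build_reconstruction_network()].
#' @param mask binary array `(H, W, 1, N)` (matrix/3-D promoted); values must
#'   be exactly 0 or 1.
#' @param train logical; training mode.
#' @return list with `recon` (per-pixel values in `[0, 1]`) and `latent`.
#' @export
recon_forward <- function(net, mask, train = TRUE) {
  mask <- as_batch(mask, 1L)
  if (!all(mask %in% c(0, 1)))
    stopf("recon_forward: mask must be exactly binary {0, 1}")
  e <- encoder_forward(net$encoder, mask, train)
  recon <- decoder_forward(net$decoder, e$latent, NULL, train)
  list(recon = recon, latent = e$latent)
}

recon_backward <- function(net, d_recon) {
  dd <- decoder_backward(net$decoder, d_recon)
  encoder_backward(net$encoder, dd$d_latent, NULL)
}

#' Build the latent-space discriminator
#'
#' Five 3x3 stride-1 convolution layers, each followed by LeakyReLU (slope
#' 0.2) and batch normalization, then a flatten and one fully connected layer
#' to a single raw score per sample (no squashing: the least-squares
#' adversarial objective acts on raw scores).
#'
#' @param cfg a [network_config()]; the discriminator reads bottleneck
#'   latents of shape `(input_size/32, dims[4])`.
#' @return A discriminator module for [disc_forward()].
#' @export
build_discriminator <- function(cfg) {
  m <- new_module("discriminator")
  m$cfg <- cfg
  cin <- cfg$dims[4]
  cs <- pmax(8L, cin %/% c(2L, 4L, 8L, 8L, 8L))
  chans <- c(cin, cs)
  convs <- lapply(1:5, function(i)
    list(conv = layer_conv(3L, chans[i], chans[i + 1L], pad = 1L),
         act = layer_leakyrelu(0.2),
         bn = layer_batchnorm(chans[i + 1L])))
  sp <- cfg$input_size %/% 32L
  m$feat_dim <- as.integer(cs[5] * sp[1] * sp[2])
  m$layers <- list(convs = convs, fc = layer_linear(m$feat_dim, 1L))
  m
}

#' Discriminator forward pass
#'
#' @param disc module from [build_discriminator()].
#' @param latent bottleneck feature block `(H/32, W/32, dims[4], N)`.
#' @param train logical; batch normalization uses batch statistics when
#'   `TRUE` (requires `N >= 2`), running statistics when `FALSE`.
#' @return numeric vector of N raw scores.
#' @export
disc_forward <- function(disc, latent, train = TRUE) {
  if (dim(latent)[3] != disc$cfg$dims[4])
    stopf("discriminator expects %d latent channels, got %d",
          disc$cfg$dims[4], dim(latent)[3])
  if (train && dim(latent)[4] < 2L)
    stopf("discriminator batch norm needs a training batch of >= 2")
  t <- latent
  for (cv in disc$layers$convs) {
    t <- layer_forward(cv$conv, t, train)
    t <- layer_forward(cv$act, t, train)
    t <- layer_forward(cv$bn, t, train)
  }
  disc$cache_featdim <- dim(t)
  tm <- t(matrix(t, ncol = dim(t)[4]))      # N x (H*W*C)
  as.numeric(layer_forward(disc$layers$fc, tm, train))
}

disc_backward <- function(disc, d_score) {
  d <- layer_backward(disc$layers$fc, matrix(d_score, ncol = 1L))
  d <- array(t(d), disc$cache_featdim)
  for (cv in rev(disc$layers$convs)) {
    d <- layer_backward(cv$bn, d)
    d <- layer_backward(cv$act, d)
    d <- layer_backward(cv$conv, d)
  }
  d
}

#' Pool a latent map to a unit-norm vector
#'
#' Global average pooling over the spatial grid followed by L2 normalization.
#' These pooled vectors are the q (image) and k (mask) embeddings of the
#' contrastive objective. An all-zero latent pools to the zero vector and is
#' flagged via the `"degenerate"` attribute (its cosine is undefined).
#'
#' @param latent feature block `(H, W, C, N)`.
#' @return matrix `(N, C)` of unit-norm rows.
#' @export
pool_latent <- function(latent) {
  raw <- t(apply(latent, c(3L, 4L), mean))   # N x C
  if (dim(latent)[3] == 1L) raw <- matrix(raw, ncol = 1L)
  nrm <- sqrt(rowSums(raw * raw))
  q <- raw / ifelse(nrm > 0, nrm, 1)
  attr(q, "degenerate") <- nrm == 0
  q
}

# backward of pool_latent: dq (N x C) -> d latent (H, W, C, N)
pool_latent_backward <- function(latent, dq) {
  d <- dim(latent)
  raw <- t(apply(latent, c(3L, 4L), mean))
  if (d[3] == 1L) raw <- matrix(raw, ncol = 1L)
  nrm <- sqrt(rowSums(raw * raw))
  safe <- ifelse(nrm > 0, nrm, 1)
  q <- raw / safe
  # d/draw of raw/||raw||: (dq - q * <dq, q>) / ||raw||
  draw <- (dq - q * rowSums(dq * q)) / safe
  draw[nrm == 0, ] <- 0
  m <- d[1] * d[2]
  dl <- array(0, d)
  for (n in seq_len(d[4]))
    dl[, , , n] <- rep(draw[n, ] / m, each = m)
  dl
}

as_batch <- function(x, channels = 1L) {
  d <- dim(x)
  if (is.null(d)) stopf("expected a matrix or array input")
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) {
    # (H, W, N) stacks of single-channel images
    x <- aperm(array(x, c(d[1], d[2], d[3], 1L)), c(1L, 2L, 4L, 3L))
  }
  if (dim(x)[3] != channels)
    stopf("expected %d channel(s), got %d", channels, dim(x)[3])
  x
}

#' Audit the layer composition of a network
#'
#' Counts layer types over all layers of a module tree. Used to verify the
#' architecture contracts: no batch normalization in the encoders, exactly
#' five convolutions plus one fully connected layer in the discriminator.
#'
#' @param net any network module.
#' @return named integer table of layer type counts.
#' @export
audit_layers <- function(net) {
  tab <- table(vapply(flatten_layers(net$layers), function(l) l$type, ""))
  tab
}
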