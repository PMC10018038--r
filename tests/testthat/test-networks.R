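# Architecture contracts: shapes, layer composition, residual identities,
# latent pooling, and gradient correctness of the assembled networks.

test_that("network_config validates its invariants", {
  expect_error(network_config(depths = c(1, 1, 1)), "length 4")
  expect_error(network_config(input_size = c(100, 100)), "divisible by 32")
  expect_error(network_config(dims = c(0, 1, 2, 3)), "positive")
})

test_that("encoder/decoder shape contract holds across input sizes", {
  set.seed(20)
  for (sz in c(32L, 64L, 128L)) {
    cfg <- tiny_net_cfg(input = c(sz, sz))
    net <- build_segmentation_network(cfg)
    x <- array(runif(sz * sz), c(sz, sz, 1, 1))
    fw <- seg_forward(net, x, train = FALSE)
    expect_equal(dim(fw$logits), c(sz, sz, 2, 1))
    expect_equal(dim(fw$latent), c(sz / 32, sz / 32, 16, 1))
  }
})

test_that("stage resolutions follow the stride arithmetic /4, /8, /16, /32", {
  cfg <- desk_net_cfg()
  enc <- build_encoder(cfg)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  e <- encoder_forward(enc, x, train = FALSE)
  expect_equal(dim(e$skips[[1]])[1:2], c(16, 16))
  expect_equal(dim(e$skips[[2]])[1:2], c(8, 8))
  expect_equal(dim(e$skips[[3]])[1:2], c(4, 4))
  expect_equal(dim(e$latent), c(2, 2, 128, 1))
})

test_that("encoder contains layer norm but no batch norm; depths follow config", {
  cfg <- desk_net_cfg()
  enc <- build_encoder(cfg)
  tab <- audit_layers(enc)
  expect_false("batchnorm" %in% names(tab))
  expect_gt(tab[["layernorm"]], 0)
  n_blocks <- sum(vapply(enc$layers$stages, length, 0L))
  expect_equal(n_blocks, sum(cfg$depths))
  expect_equal(vapply(enc$layers$stages, length, 0L), cfg$depths)
})

test_that("discriminator has exactly five conv layers, one FC layer, LeakyReLU 0.2", {
  cfg <- tiny_net_cfg()
  d <- build_discriminator(cfg)
  tab <- audit_layers(d)
  expect_equal(tab[["conv"]], 5L)
  expect_equal(tab[["linear"]], 1L)
  expect_equal(tab[["batchnorm"]], 5L)
  expect_equal(tab[["leakyrelu"]], 5L)
  # activation slope: -1 -> -0.2
  lr <- laalign:::layer_leakyrelu(0.2)
  expect_equal(laalign:::layer_forward(lr, array(-1, c(1, 1, 1, 1))),
               array(-0.2, c(1, 1, 1, 1)))
})

test_that("discriminator returns one raw score per sample, deterministic in eval", {
  set.seed(21)
  cfg <- tiny_net_cfg()
  d <- build_discriminator(cfg)
  lat <- array(rnorm(1 * 1 * 16 * 8), c(1, 1, 16, 8))
  s <- disc_forward(d, lat, train = TRUE)   # populates running stats
  expect_length(s, 8)
  s1 <- disc_forward(d, lat, train = FALSE)
  s2 <- disc_forward(d, lat, train = FALSE)
  expect_identical(s1, s2)
  expect_error(disc_forward(d, lat[, , 1:8, , drop = FALSE], train = TRUE),
               "latent channels")
  expect_error(disc_forward(d, lat[, , , 1, drop = FALSE], train = TRUE),
               ">= 2")
})

test_that("convnext block is the identity when its final projection is zero", {
  set.seed(22)
  blk <- convnext_block(8L)
  blk$layers$pw2$params$w[] <- 0
  blk$layers$pw2$params$b[] <- 0
  x <- array(rnorm(16 * 16 * 8 * 2), c(16, 16, 8, 2))
  expect_equal(cnx_forward(blk, x), x)
})

test_that("convnext block expands to 4x dim internally and keeps its shape", {
  blk <- convnext_block(96L)
  expect_equal(dim(blk$layers$pw1$params$w), c(1, 1, 96, 384))
  expect_equal(dim(blk$layers$pw2$params$w), c(1, 1, 384, 96))
  set.seed(23)
  x <- array(rnorm(8 * 8 * 96), c(8, 8, 96, 1))
  expect_equal(dim(cnx_forward(blk, x)), dim(x))
})

test_that("convnext block parameter count matches the hand-enumerated formula", {
  dim_ <- 96L
  blk <- convnext_block(dim_)
  got <- sum(vapply(laalign:::flatten_layers(blk$layers),
                    function(l) sum(lengths(l$params)), 0))
  # dw 7x7: 49*dim + dim; LN: 2*dim; pw1: dim*4dim + 4dim; pw2: 4dim*dim + dim
  want <- (49 * dim_ + dim_) + 2 * dim_ +
    (dim_ * 4 * dim_ + 4 * dim_) + (4 * dim_ * dim_ + dim_)
  expect_equal(got, want)
})

test_that("reconstruction network rejects non-binary input and stays in [0,1]", {
  set.seed(24)
  cfg <- tiny_net_cfg()
  rn <- build_reconstruction_network(cfg)
  m <- array(0, c(32, 32, 1, 1))
  fw <- recon_forward(rn, m, train = FALSE)
  expect_true(all(is.finite(fw$recon)))
  expect_true(all(fw$recon >= 0 & fw$recon <= 1))
  expect_equal(dim(fw$recon), c(32, 32, 1, 1))
  expect_error(recon_forward(rn, m + 0.5), "binary")
})

test_that("reconstruction decoder has no skip concatenations", {
  cfg <- tiny_net_cfg()
  rn <- build_reconstruction_network(cfg)
  expect_false(rn$decoder$with_skips)
  # first decoder stage consumes exactly dims[4] channels (no skip widths)
  expect_equal(rn$decoder$layers$res[[1]]$cin, cfg$dims[4])
  sn <- build_segmentation_network(cfg)
  expect_equal(sn$decoder$layers$res[[1]]$cin, cfg$dims[4] + cfg$dims[3])
})

test_that("pool_latent averages spatially and L2-normalizes", {
  # constant latent: pre-normalization vector equals the per-channel constants
  lat <- array(0, c(2, 2, 3, 1))
  lat[, , 1, ] <- 3; lat[, , 2, ] <- 4; lat[, , 3, ] <- 0
  q <- pool_latent(lat)
  expect_equal(as.numeric(q), c(3, 4, 0) / 5)
  # any nonzero latent has unit norm
  set.seed(25)
  lat <- array(rnorm(4 * 4 * 8 * 5), c(4, 4, 8, 5))
  q <- pool_latent(lat)
  expect_equal(unname(sqrt(rowSums(q^2))), rep(1, 5), tolerance = 1e-5)
  # orthogonal one-hot channels stay orthogonal
  lat <- array(0, c(1, 1, 4, 3))
  lat[1, 1, 1, 1] <- 1; lat[1, 1, 2, 2] <- 1; lat[1, 1, 3, 3] <- 1
  q <- pool_latent(lat)
  expect_equal(max(abs(q %*% t(q) - diag(3))), 0, tolerance = 1e-12)
  # all-zero latent: zero vector, flagged degenerate
  q0 <- pool_latent(array(0, c(2, 2, 3, 1)))
  expect_equal(as.numeric(q0), c(0, 0, 0))
  expect_true(attr(q0, "degenerate"))
})

test_that("every loss has finite gradients through the assembled networks", {
  set.seed(26)
  cfg <- tiny_net_cfg()
  net <- build_segmentation_network(cfg)
  disc <- build_discriminator(cfg)
  rn <- build_reconstruction_network(cfg)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  g <- array((matrix(runif(32 * 32 * 2), 32) > 0.8) * 1, c(32, 32, 1, 2))
  w <- loss_weights()
  fw <- seg_forward(net, x, train = TRUE)
  k_lat <- encoder_forward(rn$encoder, g, train = FALSE)$latent
  d_logits <- laalign:::.grad_segmentation(fw$logits, g, w)
  sfk <- disc_forward(disc, fw$latent, train = TRUE)
  d_lat <- laalign:::disc_backward(disc, laalign:::.grad_lsgan_g(sfk))
  q <- pool_latent(fw$latent)
  k <- pool_latent(k_lat)
  gcl <- laalign:::.grad_contrastive(q, k, w$tau)
  d_lat <- d_lat + laalign:::pool_latent_backward(fw$latent, gcl$dq)
  laalign:::zero_grads(net$layers)
  laalign:::seg_backward(net, d_logits, d_lat)
  for (l in laalign:::flatten_layers(net$layers))
    for (nm in names(l$grads)) expect_true(all(is.finite(l$grads[[nm]])))
})

test_that("segmentation loss gradient matches finite differences end to end", {
  set.seed(27)
  cfg <- tiny_net_cfg()
  net <- build_segmentation_network(cfg)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  g <- array((matrix(runif(32 * 32), 32) > 0.8) * 1, c(32, 32, 1, 1))
  w <- loss_weights()
  L <- function() {
    fw <- seg_forward(net, x, train = TRUE)
    segmentation_loss(fw$logits, g, w)
  }
  fw <- seg_forward(net, x, train = TRUE)
  laalign:::zero_grads(net$layers)
  laalign:::seg_backward(net, laalign:::.grad_segmentation(fw$logits, g, w))
  ll <- Filter(function(l) length(l$params) > 0,
               laalign:::flatten_layers(net$layers))
  for (l in ll[sample(length(ll), 5)]) {
    nm <- names(l$params)[1]
    i <- sample(length(l$params[[nm]]), 1)
    eps <- 1e-5
    old <- l$params[[nm]][i]
    l$params[[nm]][i] <- old + eps; Lp <- L()
    l$params[[nm]][i] <- old - eps; Lm <- L()
    l$params[[nm]][i] <- old
    fd <- (Lp - Lm) / (2 * eps)
    expect_equal(l$grads[[nm]][i], fd,
                 tolerance = max(1e-4, 1e-3 * abs(fd)))
  }
})
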