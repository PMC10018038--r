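# Loss functions: segmentation (cross-entropy + soft Dice), reconstruction
# L1, least-squares adversarial alignment, and the InfoNCE contrastive loss.
#
# Cross-entropy and L1 are averaged per pixel so magnitudes are independent
# of input resolution; the Dice ratio needs no normalization (the pixel count
# cancels). Gradient companions (.grad_*) are used by the trainers.

#' Loss weights and constants
#'
#' Weighting of the joint objective. Defaults: lambda_ce = lambda_dice = 1
#' for the segmentation loss, lambda_gan = lambda_cl = 1 for the latent
#' alignment loss, temperature tau = 0.1 for the contrastive term, and
#' epsilon = 1e-6 stabilizing the Dice ratio.
#'
#' @param lambda_ce,lambda_dice,lambda_gan,lambda_cl non-negative weights.
#' @param tau contrastive temperature (> 0).
#' @param epsilon small positive Dice stabilizer.
#' @param num_classes class count C.
#' @return A `laa_loss_weights` list.
#' @export
loss_weights <- function(lambda_ce = 1, lambda_dice = 1, lambda_gan = 1,
                         lambda_cl = 1, tau = 0.1, epsilon = 1e-6,
                         num_classes = 2L) {
  if (tau <= 0) stopf("tau must be > 0")
  if (epsilon <= 0) stopf("epsilon must be > 0")
  if (any(c(lambda_ce, lambda_dice, lambda_gan, lambda_cl) < 0))
    stopf("loss weights must be >= 0")
  structure(list(lambda_ce = lambda_ce, lambda_dice = lambda_dice,
                 lambda_gan = lambda_gan, lambda_cl = lambda_cl,
                 tau = tau, epsilon = epsilon,
                 num_classes = as.integer(num_classes)),
            class = "laa_loss_weights")
}

# softmax over the class (3rd) dimension of (H, W, C, N) logits,
# max-shifted for stability
softmax_ch <- function(logits) {
  d <- dim(logits)
  xm <- .to_cmat(logits)                 # C x (H*W*N)
  xm <- sweep(xm, 2L, apply(xm, 2L, max))
  e <- exp(xm)
  .from_cmat(sweep(e, 2L, colSums(e), `/`), d)
}

as_onehot <- function(gt, C) {
  gt <- as_batch(gt, 1L)
  vals <- unique(as.vector(gt))
  if (any(!(vals %in% 0:(C - 1))))
    stopf("ground-truth labels must lie in {0..%d}", C - 1)
  d <- dim(gt)
  oh <- array(0, c(d[1], d[2], C, d[4]))
  for (k in 0:(C - 1)) oh[, , k + 1, ] <- (gt[, , 1, ] == k)
  oh
}

#' Cross-entropy segmentation loss
#'
#' Softmax over C classes, then the negative log-probability of the true
#' class, averaged over all pixels (and batch). Zero iff the prediction is
#' exactly one-hot correct everywhere.
#'
#' @param logits array `(H, W, C, N)` of per-pixel class scores.
#' @param gt label mask with values in `{0..C-1}` (matrix, `(H, W, N)` array
#'   or `(H, W, 1, N)` array).
#' @param C number of classes.
#' @return scalar loss, >= 0.
#' @export
cross_entropy_loss <- function(logits, gt, C = dim(logits)[3]) {
  p <- softmax_ch(logits)
  oh <- as_onehot(gt, C)
  if (!all(dim(oh) == dim(p))) stopf("logits/ground-truth shape mismatch")
  eps <- 1e-12
  -sum(oh * log(pmax(p, eps))) / (dim(p)[1] * dim(p)[2] * dim(p)[4])
}

# gradient of cross_entropy_loss w.r.t. logits (same mean aggregation)
.grad_cross_entropy <- function(logits, gt, C = dim(logits)[3]) {
  p <- softmax_ch(logits)
  oh <- as_onehot(gt, C)
  (p - oh) / (dim(p)[1] * dim(p)[2] * dim(p)[4])
}

#' Soft Dice loss
#'
#' `1 - (2*sum(p*g) + eps) / (sum(p^2) + sum(g^2) + eps)` over the foreground
#' probability map. Computed per sample and averaged over the batch.
#'
#' @param probs foreground probabilities in `[0, 1]` (matrix, `(H, W, N)` or
#'   `(H, W, 1, N)`).
#' @param gt binary mask of the same spatial shape.
#' @param epsilon small positive stabilizer.
#' @return scalar in `[0, 1]` (up to epsilon effects).
#' @export
dice_loss <- function(probs, gt, epsilon = 1e-6) {
  p <- as_batch(probs, 1L)
  g <- as_batch(gt, 1L)
  if (!all(dim(p) == dim(g))) stopf("dice_loss: shape mismatch")
  n <- dim(p)[4]
  v <- vapply(seq_len(n), function(i) {
    pi <- p[, , 1, i]
    gi <- g[, , 1, i]
    1 - (2 * sum(pi * gi) + epsilon) / (sum(pi * pi) + sum(gi * gi) + epsilon)
  }, 0)
  mean(v)
}

# gradient of dice_loss w.r.t. probs
.grad_dice <- function(probs, gt, epsilon = 1e-6) {
  p <- as_batch(probs, 1L)
  g <- as_batch(gt, 1L)
  n <- dim(p)[4]
  dp <- array(0, dim(p))
  for (i in seq_len(n)) {
    pi <- p[, , 1, i]
    gi <- g[, , 1, i]
    num <- 2 * sum(pi * gi) + epsilon
    den <- sum(pi * pi) + sum(gi * gi) + epsilon
    dp[, , 1, i] <- (-2 * gi / den + num * 2 * pi / den^2) / n
  }
  dp
}

#' Combined segmentation loss
#'
#' `lambda_ce * CE + lambda_dice * Dice`, with the Dice term computed on the
#' softmax foreground-channel probability (class index C-1), keeping it
#' differentiable.
#'
#' @param logits array `(H, W, C, N)`.
#' @param gt label mask.
#' @param w a [loss_weights()].
#' @return scalar loss.
#' @export
segmentation_loss <- function(logits, gt, w = loss_weights()) {
  p <- softmax_ch(logits)
  fg <- p[, , dim(p)[3], , drop = FALSE]
  gt4 <- as_batch(gt, 1L)
  w$lambda_ce * cross_entropy_loss(logits, gt, dim(logits)[3]) +
    w$lambda_dice * dice_loss(fg, (gt4 == dim(logits)[3] - 1) * 1, w$epsilon)
}

# gradient of segmentation_loss w.r.t. logits (CE + Dice-through-softmax)
.grad_segmentation <- function(logits, gt, w = loss_weights()) {
  C <- dim(logits)[3]
  p <- softmax_ch(logits)
  g <- w$lambda_ce * .grad_cross_entropy(logits, gt, C)
  if (w$lambda_dice > 0) {
    fg <- p[, , C, , drop = FALSE]
    gt4 <- as_batch(gt, 1L)
    dfg <- w$lambda_dice * .grad_dice(fg, (gt4 == C - 1) * 1, w$epsilon)
    # route d/dfg through the softmax: dlogit_c = fg*(delta_{c,fg} - p_c)*dfg
    for (cc in seq_len(C)) {
      ind <- as.numeric(cc == C)
      g[, , cc, ] <- g[, , cc, ] +
        dfg[, , 1, ] * fg[, , 1, ] * (ind - p[, , cc, ])
    }
  }
  g
}

#' L1 reconstruction loss
#'
#' Mean absolute difference between reconstruction and mask over all pixels.
#'
#' @param recon reconstruction in `[0, 1]`.
#' @param gt_mask binary mask of the same shape.
#' @return scalar >= 0.
#' @export
l1_reconstruction_loss <- function(recon, gt_mask) {
  r <- as_batch(recon, 1L)
  g <- as_batch(gt_mask, 1L)
  if (!all(dim(r) == dim(g))) stopf("l1 loss: shape mismatch")
  mean(abs(r - g))
}

.grad_l1 <- function(recon, gt_mask) {
  r <- as_batch(recon, 1L)
  g <- as_batch(gt_mask, 1L)
  sign(r - g) / length(r)
}

#' Least-squares adversarial losses
#'
#' Discriminator objective: `0.5*mean((d_real - 1)^2) + 0.5*mean(d_fake^2)`
#' pushes mask-latent scores to 1 and image-latent scores to 0. Generator
#' objective: `0.5*mean((d_fake - 1)^2)` pushes image-latent scores toward
#' the mask-latent target 1.
#'
#' @param d_real discriminator scores on mask (reconstruction-encoder)
#'   latents.
#' @param d_fake discriminator scores on image (segmentation-encoder)
#'   latents.
#' @return scalar >= 0.
#' @export
lsgan_discriminator_loss <- function(d_real, d_fake) {
  if (length(d_real) == 0 || length(d_fake) == 0)
    stopf("lsgan: empty score batch")
  0.5 * mean((d_real - 1)^2) + 0.5 * mean(d_fake^2)
}

#' @rdname lsgan_discriminator_loss
#' @export
lsgan_generator_loss <- function(d_fake) {
  if (length(d_fake) == 0) stopf("lsgan: empty score batch")
  0.5 * mean((d_fake - 1)^2)
}

.grad_lsgan_d <- function(d_real, d_fake) {
  list(d_real = (d_real - 1) / length(d_real),
       d_fake = d_fake / length(d_fake))
}

.grad_lsgan_g <- function(d_fake) (d_fake - 1) / length(d_fake)

#' InfoNCE contrastive loss on pooled latents
#'
#' For each unit-norm image embedding q_i the positive key is the same-index
#' mask embedding k_i; the denominator sums `exp(q_i . k_j / tau)` over all B
#' in-batch mask embeddings (positive included). Returns the batch mean of
#' `-log softmax`. Equal similarities give exactly `log(B)`.
#'
#' @param q_batch matrix `(B, d)` of unit-norm image embeddings.
#' @param k_batch matrix `(B, d)` of unit-norm mask embeddings, row-aligned
#'   with `q_batch`.
#' @param tau temperature (> 0).
#' @return scalar >= 0.
#' @export
contrastive_loss <- function(q_batch, k_batch, tau = 0.1) {
  q_batch <- as.matrix(q_batch)
  k_batch <- as.matrix(k_batch)
  B <- nrow(q_batch)
  if (B < 2L) stopf("contrastive loss needs a batch of >= 2 (no negatives)")
  if (!all(dim(q_batch) == dim(k_batch)))
    stopf("contrastive loss: q/k shape mismatch")
  s <- q_batch %*% t(k_batch) / tau            # B x B similarity logits
  m <- apply(s, 1L, max)
  lse <- m + log(rowSums(exp(s - m)))          # max-shifted log-sum-exp
  mean(lse - diag(s))
}

# gradients w.r.t. q and k (k gradient unused when the mask encoder is frozen)
.grad_contrastive <- function(q_batch, k_batch, tau = 0.1) {
  B <- nrow(q_batch)
  s <- q_batch %*% t(k_batch) / tau
  m <- apply(s, 1L, max)
  p <- exp(s - m)
  p <- p / rowSums(p)
  ds <- (p - diag(B)) / B                      # d loss / d s
  list(dq = ds %*% k_batch / tau,
       dk = t(ds) %*% q_batch / tau)
}

#' Joint latent alignment loss
#'
#' `lambda_gan * gan_term + lambda_cl * cl_term`, where `gan_term` is the
#' generator-side least-squares loss and `cl_term` the contrastive loss.
#'
#' @param gan_term scalar adversarial term.
#' @param cl_term scalar contrastive term.
#' @param w a [loss_weights()].
#' @return scalar.
#' @export
latent_alignment_loss <- function(gan_term, cl_term, w = loss_weights()) {
  w$lambda_gan * gan_term + w$lambda_cl * cl_term
}
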