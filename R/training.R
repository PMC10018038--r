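# Two-stage training: (1) mask auto-encoder reconstruction, (2) segmentation
# with latent-space alignment (least-squares adversarial + contrastive)
# against the frozen reconstruction encoder. Plus the patient-level split
# and the rotation augmentation.

#' Training configuration
#'
#' @param lr_init initial Adam learning rate.
#' @param beta1 Adam first-moment coefficient (the "momentum").
#' @param batch_size stage-2 batch size B (>= 2: the contrastive loss needs
#'   in-batch negatives).
#' @param steps stage-2 optimization steps.
#' @param recon_steps stage-1 (reconstruction) optimization steps.
#' @param recon_batch stage-1 batch size (the reconstruction stage has no
#'   in-batch-negative constraint; a larger batch gives smoother gradients).
#' @param input_size network input size (pixels, divisible by 32).
#' @param rot_range_deg symmetric rotation augmentation range in degrees.
#' @param seed integer seed controlling initialization, batch order and
#'   augmentation.
#' @param lr_power exponent of the polynomial learning-rate decay
#'   `lr = lr_init * (1 - step/steps)^lr_power`.
#' @param val_every validation cadence in steps (0 disables monitoring).
#' @param select_best keep the checkpoint with the best validation Dice.
#' @return A `laa_train_config` list.
#' @export
train_config <- function(lr_init = 1e-4, beta1 = 0.9, batch_size = 8L,
                         steps = 300L, recon_steps = 300L, recon_batch = 32L,
                         input_size = c(448L, 448L),
                         rot_range_deg = c(-10, 10), seed = 0L,
                         lr_power = 0.9, val_every = 50L,
                         select_best = TRUE) {
  if (batch_size < 2L) stopf("batch_size must be >= 2")
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (!isTRUE(all.equal(rot_range_deg[1], -rot_range_deg[2])))
    stopf("rotation range must be symmetric")
  structure(list(lr_init = lr_init, beta1 = beta1,
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps),
                 recon_steps = as.integer(recon_steps),
                 recon_batch = as.integer(recon_batch),
                 input_size = as.integer(input_size),
                 rot_range_deg = rot_range_deg, seed = as.integer(seed),
                 lr_power = lr_power, val_every = as.integer(val_every),
                 select_best = isTRUE(select_best)),
            class = "laa_train_config")
}

#' Assign a patient-level train/val/test split
#'
#' Patients (never single images) are assigned to splits so the image counts
#' approximate the requested ratio. For cohorts of up to 10 patients the
#' deviation-minimizing assignment is found by exhaustive enumeration (with
#' seeded random tie-breaking among co-optimal assignments); larger cohorts
#' use a seeded greedy largest-first placement (each patient goes to the
#' split with the largest relative remaining deficit) refined by
#' single-move and pairwise-swap local search. Every split receives at
#' least one patient.
#'
#' @param manifest a `laa_manifest`.
#' @param ratio `(train, val, test)` image-count ratio, default `c(4, 1, 1)`.
#' @param seed integer seed randomizing the placement order (ties between
#'   equally good assignments land randomly).
#' @return The manifest with `records$split` filled in.
#' @export
split_by_patient <- function(manifest, ratio = c(4, 1, 1), seed = 0L) {
  df <- manifest$records
  pats <- unique(df$patient_id)
  if (length(pats) < 3L) stopf("need >= 3 patients to split")
  if (any(ratio <= 0)) stopf("split ratios must be positive")
  counts <- table(df$patient_id)[pats]
  total <- sum(counts)
  target <- ratio / sum(ratio) * total

  with_seed(seed, {
    if (length(pats) <= 10L) {
      df$split <- .split_exhaustive(pats, as.numeric(counts), target,
                                    df$patient_id)
      return(new_manifest(df, manifest$image_size, manifest$seed))
    }
    shuffled <- sample(seq_along(pats))
    ord <- shuffled[order(-as.numeric(counts)[shuffled])]
    assign_of <- integer(length(pats))
    nsplit <- numeric(3L)
    npat <- integer(3L)
    for (p in ord) {
      deficit <- (target - nsplit) / target
      s <- which.max(deficit)
      assign_of[p] <- s
      nsplit[s] <- nsplit[s] + as.numeric(counts)[p]
      npat[s] <- npat[s] + 1L
    }
    # guarantee non-empty splits: move the smallest patient of the fullest
    # split into any empty one
    repeat {
      empty <- which(npat == 0L)
      if (length(empty) == 0L) break
      donor <- which.max(npat)
      cand <- which(assign_of == donor)
      mv <- cand[which.min(as.numeric(counts)[cand])]
      assign_of[mv] <- empty[1]
      npat[donor] <- npat[donor] - 1L
      npat[empty[1]] <- npat[empty[1]] + 1L
      nsplit[donor] <- nsplit[donor] - as.numeric(counts)[mv]
      nsplit[empty[1]] <- nsplit[empty[1]] + as.numeric(counts)[mv]
    }
    # local improvement: single-patient moves and pairwise swaps while the
    # absolute deviation from the target image counts decreases (splits stay
    # non-empty)
    dev <- function(ns) sum(abs(ns - target))
    cnt <- as.numeric(counts)
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (p in seq_along(pats)) {
        from <- assign_of[p]
        if (npat[from] > 1L) {
          for (to in setdiff(1:3, from)) {
            ns <- nsplit
            ns[from] <- ns[from] - cnt[p]
            ns[to] <- ns[to] + cnt[p]
            if (dev(ns) < dev(nsplit) - 1e-9) {
              nsplit <- ns
              npat[from] <- npat[from] - 1L
              npat[to] <- npat[to] + 1L
              assign_of[p] <- to
              from <- to
              improved <- TRUE
            }
          }
        }
      }
      for (p in seq_along(pats)) {
        for (q in seq_along(pats)) {
          if (q <= p || assign_of[p] == assign_of[q]) next
          sp_ <- assign_of[p]
          sq_ <- assign_of[q]
          ns <- nsplit
          ns[sp_] <- ns[sp_] - cnt[p] + cnt[q]
          ns[sq_] <- ns[sq_] - cnt[q] + cnt[p]
          if (dev(ns) < dev(nsplit) - 1e-9) {
            nsplit <- ns
            assign_of[p] <- sq_
            assign_of[q] <- sp_
            improved <- TRUE
          }
        }
      }
    }
    labels <- c("train", "val", "test")[assign_of]
    names(labels) <- pats
    df$split <- labels[df$patient_id]
    new_manifest(df, manifest$image_size, manifest$seed)
  })
}


# exact deviation-minimizing assignment for small cohorts: enumerate all
# 3^n split assignments with every split non-empty, pick a random optimum
.split_exhaustive <- function(pats, cnt, target, patient_ids) {
  n <- length(pats)
  A <- as.matrix(expand.grid(rep(list(1:3), n)))
  ns <- sapply(1:3, function(s) (A == s) %*% cnt)
  valid <- sapply(1:3, function(s) rowSums(A == s) > 0)
  ok <- valid[, 1] & valid[, 2] & valid[, 3]
  dev <- rowSums(abs(ns - matrix(target, nrow(A), 3, byrow = TRUE)))
  dev[!ok] <- Inf
  best <- which(dev <= min(dev) + 1e-9)
  pick <- A[best[sample.int(length(best), 1L)], ]
  labels <- c("train", "val", "test")[pick]
  names(labels) <- pats
  unname(labels[patient_ids])
}

#' Rotate an image/mask pair (online augmentation)
#'
#' Applies one random rotation, drawn uniformly from `rot_range_deg`, to
#' both the image (bilinear interpolation) and its mask (nearest neighbor,
#' so the mask stays exactly binary). Out-of-frame pixels are filled with 0.
#'
#' @param image grayscale image matrix.
#' @param mask binary mask matrix, same shape.
#' @param cfg a [train_config()] (supplies the rotation range).
#' @param angle optional fixed angle in degrees (otherwise drawn from the
#'   current RNG stream).
#' @return list `(image, mask, angle)`.
#' @export
augment_pair <- function(image, mask, cfg = train_config(), angle = NULL) {
  if (is.null(angle))
    angle <- runif(1, cfg$rot_range_deg[1], cfg$rot_range_deg[2])
  if (angle == 0) return(list(image = image, mask = mask, angle = 0))
  list(image = .rotate2d(image, angle, 1L),
       mask = .rotate2d(mask, angle, 0L),
       angle = angle)
}

resize_bilinear <- function(x, oh, ow) {
  h <- nrow(x)
  w <- ncol(x)
  if (h == oh && w == ow) return(x)
  si <- pmin(pmax((seq_len(oh) - 0.5) * h / oh - 0.5, 0), h - 1)
  sj <- pmin(pmax((seq_len(ow) - 0.5) * w / ow - 0.5, 0), w - 1)
  i0 <- floor(si); ai <- si - i0; i1 <- pmin(i0 + 1, h - 1)
  j0 <- floor(sj); aj <- sj - j0; j1 <- pmin(j0 + 1, w - 1)
  outer(1 - ai, 1 - aj) * x[i0 + 1, j0 + 1, drop = FALSE] +
    outer(ai, 1 - aj) * x[i1 + 1, j0 + 1, drop = FALSE] +
    outer(1 - ai, aj) * x[i0 + 1, j1 + 1, drop = FALSE] +
    outer(ai, aj) * x[i1 + 1, j1 + 1, drop = FALSE]
}

resize_nearest <- function(x, oh, ow) {
  h <- nrow(x)
  w <- ncol(x)
  if (h == oh && w == ow) return(x)
  si <- round(pmin(pmax((seq_len(oh) - 0.5) * h / oh - 0.5, 0), h - 1))
  sj <- round(pmin(pmax((seq_len(ow) - 0.5) * w / ow - 0.5, 0), w - 1))
  x[si + 1, sj + 1, drop = FALSE]
}

# load one split of a manifest into memory, resized to the network input
.load_split <- function(manifest, split, input_size) {
  df <- manifest$records
  rows <- if (identical(split, "all")) seq_len(nrow(df))
          else which(df$split == split)
  lapply(rows, function(i) {
    img <- resize_bilinear(read_image_png(df$image_path[i]),
                           input_size[1], input_size[2])
    msk <- resize_nearest(read_mask_png(df$mask_path[i]),
                          input_size[1], input_size[2])
    list(image = img, mask = msk, row = i)
  })
}

.stack_batch <- function(items, field, input_size) {
  arr <- array(0, c(input_size[1], input_size[2], 1L, length(items)))
  for (i in seq_along(items)) arr[, , 1, i] <- items[[i]][[field]]
  arr
}

.prior_logit <- function(data) {
  prev <- mean(vapply(data, function(it) mean(it$mask), 0))
  prev <- min(max(prev, 1e-3), 1 - 1e-3)
  log(prev / (1 - prev))
}

.poly_lr <- function(cfg, step, total) {
  cfg$lr_init * (1 - (step - 1) / total)^cfg$lr_power
}

#' Stage 1: train the mask reconstruction auto-encoder
#'
#' Optimizes the per-pixel L1 reconstruction loss with Adam over the
#' train-split masks, with rotation augmentation and a polynomially decaying
#' learning rate. The resulting bottleneck latent is the shape prior used by
#' stage 2.
#'
#' @param manifest a split `laa_manifest` (records with `split == "train"`
#'   are used; if no split is assigned, all records are used).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()] (`recon_steps` is the step budget).
#' @return list with `network` (the trained auto-encoder), `history`
#'   (data.frame of step, loss, lr) and `final_loss`.
#' @export
train_reconstruction <- function(manifest, net_cfg, train_cfg) {
  cfg <- train_cfg
  with_seed(cfg$seed, {
    net <- build_reconstruction_network(net_cfg)
    split <- if (any(manifest$records$split == "train")) "train" else "all"
    data <- .load_split(manifest, split, cfg$input_size)
    if (length(data) == 0) stopf("train split is empty")
    # start the sigmoid head at the foreground-prevalence logit so the
    # strong class imbalance does not drive an early background collapse
    net$decoder$layers$gain$params$b <- .prior_logit(data)
    opt <- optim_adam(net$layers, lr = cfg$lr_init, beta1 = cfg$beta1)
    hist <- vector("list", cfg$recon_steps)
    loss <- NA_real_
    bsz <- cfg$recon_batch %||% cfg$batch_size
    for (step in seq_len(cfg$recon_steps)) {
      idx <- sample.int(length(data), min(bsz, length(data)),
                        replace = length(data) < bsz)
      batch <- lapply(data[idx], function(it) {
        ag <- augment_pair(it$mask, it$mask, cfg)
        ag$mask
      })
      g <- array(0, c(cfg$input_size, 1L, length(idx)))
      for (i in seq_along(batch)) g[, , 1, i] <- batch[[i]]
      fw <- recon_forward(net, g, train = TRUE)
      loss <- l1_reconstruction_loss(fw$recon, g)
      if (!is.finite(loss)) stopf("reconstruction training diverged (NaN)")
      zero_grads(net$layers)
      recon_backward(net, .grad_l1(fw$recon, g))
      lr <- .poly_lr(cfg, step, cfg$recon_steps)
      adam_step(opt, lr)
      hist[[step]] <- data.frame(step = step, loss = loss, lr = lr)
    }
    list(network = net,
         history = if (cfg$recon_steps > 0) do.call(rbind, hist)
                   else data.frame(step = integer(), loss = numeric(),
                                   lr = numeric()),
         final_loss = loss)
  })
}

# median cosine between pooled image latents (segmentation encoder) and
# pooled mask latents (frozen reconstruction encoder) over a record list
.val_cosine <- function(seg_net, recon_net, data, input_size) {
  if (length(data) == 0) return(NA_real_)
  cs <- vapply(data, function(it) {
    x <- array(it$image, c(input_size, 1L, 1L))
    g <- array(it$mask, c(input_size, 1L, 1L))
    q <- pool_latent(encoder_forward(seg_net$encoder, x, train = FALSE)$latent)
    k <- pool_latent(encoder_forward(recon_net$encoder, g,
                                     train = FALSE)$latent)
    sum(q * k)
  }, 0)
  stats::median(cs)
}

.val_dice <- function(seg_net, data, input_size) {
  if (length(data) == 0) return(NA_real_)
  mean(vapply(data, function(it) {
    x <- array(it$image, c(input_size, 1L, 1L))
    fw <- seg_forward(seg_net, x, train = FALSE)
    p <- softmax_ch(fw$logits)
    pm <- (p[, , dim(p)[3], 1] > 0.5) * 1
    metric_dice(confusion_counts(pm, it$mask))
  }, 0))
}

#' Stage 2: train the segmentation network with latent alignment
#'
#' Per batch: (a) a discriminator step minimizing the least-squares loss with
#' mask latents (frozen reconstruction encoder) as real and image latents as
#' fake; (b) a generator step minimizing the segmentation loss plus the
#' latent alignment loss (generator-side adversarial term and the InfoNCE
#' contrastive term between pooled latents), at a 1:1 update ratio. The
#' reconstruction network is frozen throughout: no gradient ever reaches it.
#' With `lambda_gan = lambda_cl = 0` the procedure reduces exactly to plain
#' segmentation training (no discriminator is built, no alignment pass runs).
#'
#' @param manifest a split `laa_manifest`.
#' @param recon_fit result of [train_reconstruction()] (or its `$network`).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param w a [loss_weights()].
#' @return list with `network`, `discriminator` (NULL when disabled),
#'   `history` (per-step loss components), `val_history` (validation Dice
#'   and latent cosine), and `best_val_dice`.
#' @export
train_segmentation <- function(manifest, recon_fit, net_cfg,
                               train_cfg = train_config(),
                               w = loss_weights()) {
  cfg <- train_cfg
  recon_net <- if (!is.null(recon_fit$network)) recon_fit$network
               else recon_fit
  use_gan <- w$lambda_gan > 0
  use_cl <- w$lambda_cl > 0
  with_seed(cfg$seed, {
    net <- build_segmentation_network(net_cfg)
    disc <- if (use_gan) build_discriminator(net_cfg) else NULL
    split <- if (any(manifest$records$split == "train")) "train" else "all"
    data <- .load_split(manifest, split, cfg$input_size)
    if (length(data) == 0) stopf("train split is empty")
    val <- .load_split(manifest, "val", cfg$input_size)
    opt_g <- optim_adam(net$layers, lr = cfg$lr_init, beta1 = cfg$beta1)
    opt_d <- if (use_gan) optim_adam(disc$layers, lr = cfg$lr_init,
                                     beta1 = cfg$beta1) else NULL

    vh <- list()
    note_val <- function(step) {
      if (cfg$val_every <= 0 || length(val) == 0) return()
      vh[[length(vh) + 1L]] <<- data.frame(
        step = step,
        dice = .val_dice(net, val, cfg$input_size),
        cos = .val_cosine(net, recon_net, val, cfg$input_size))
    }
    note_val(0L)
    best <- list(dice = -Inf, params = NULL)
    if (length(vh) > 0 && cfg$select_best)
      best <- list(dice = vh[[1]]$dice, params = get_params(net$layers))

    hist <- vector("list", cfg$steps)
    for (step in seq_len(cfg$steps)) {
      idx <- sample.int(length(data), min(cfg$batch_size, length(data)),
                        replace = length(data) < cfg$batch_size)
      B <- length(idx)
      xs <- array(0, c(cfg$input_size, 1L, B))
      gs <- array(0, c(cfg$input_size, 1L, B))
      for (i in seq_along(idx)) {
        ag <- augment_pair(data[[idx[i]]]$image, data[[idx[i]]]$mask, cfg)
        xs[, , 1, i] <- ag$image
        gs[, , 1, i] <- ag$mask
      }

      fw <- seg_forward(net, xs, train = TRUE)
      loss_seg <- segmentation_loss(fw$logits, gs, w)
      if (!is.finite(loss_seg)) stopf("segmentation training diverged (NaN)")

      k_lat <- NULL
      if (use_gan || use_cl)
        k_lat <- encoder_forward(recon_net$encoder, gs, train = FALSE)$latent

      loss_d <- NA_real_
      if (use_gan) {
        # discriminator step: real = mask latents, fake = image latents
        zero_grads(disc$layers)
        s_real <- disc_forward(disc, k_lat, train = TRUE)
        disc_backward(disc, (s_real - 1) / length(s_real))
        s_fake <- disc_forward(disc, fw$latent, train = TRUE)
        disc_backward(disc, s_fake / length(s_fake))
        loss_d <- lsgan_discriminator_loss(s_real, s_fake)
        adam_step(opt_d, .poly_lr(cfg, step, cfg$steps))
      }

      # generator step
      d_logits <- .grad_segmentation(fw$logits, gs, w)
      d_lat <- NULL
      loss_gan_g <- NA_real_
      loss_cl <- NA_real_
      if (use_gan) {
        zero_grads(disc$layers)
        s_fake2 <- disc_forward(disc, fw$latent, train = TRUE)
        loss_gan_g <- lsgan_generator_loss(s_fake2)
        d_lat <- disc_backward(disc,
                               w$lambda_gan * .grad_lsgan_g(s_fake2))
      }
      if (use_cl) {
        q <- pool_latent(fw$latent)
        k <- pool_latent(k_lat)
        loss_cl <- contrastive_loss(q, k, w$tau)
        gcl <- .grad_contrastive(q, k, w$tau)
        d_cl <- pool_latent_backward(fw$latent, w$lambda_cl * gcl$dq)
        d_lat <- if (is.null(d_lat)) d_cl else d_lat + d_cl
      }
      zero_grads(net$layers)
      seg_backward(net, d_logits, d_lat)
      adam_step(opt_g, .poly_lr(cfg, step, cfg$steps))

      hist[[step]] <- data.frame(step = step, loss_seg = loss_seg,
                                 loss_d = loss_d, loss_gan_g = loss_gan_g,
                                 loss_cl = loss_cl,
                                 lr = .poly_lr(cfg, step, cfg$steps))
      if (cfg$val_every > 0 && (step %% cfg$val_every == 0L ||
                                step == cfg$steps)) {
        note_val(step)
        if (cfg$select_best && length(vh) > 0) {
          vd <- vh[[length(vh)]]$dice
          if (!is.na(vd) && vd > best$dice)
            best <- list(dice = vd, params = get_params(net$layers))
        }
      }
    }
    if (cfg$select_best && !is.null(best$params) && best$dice > -Inf)
      set_params(net$layers, best$params)
    list(network = net, discriminator = disc,
         history = do.call(rbind, hist),
         val_history = if (length(vh) > 0) do.call(rbind, vh) else NULL,
         best_val_dice = if (is.finite(best$dice)) best$dice else NA_real_)
  })
}

#' Predict a segmentation
#'
#' Resizes the image to the network input size (bilinear), runs the network
#' in evaluation mode, and returns the softmax foreground probability map
#' plus its 0.5-threshold binary mask, both resized back to the original
#' resolution by nearest neighbor.
#'
#' @param net a trained segmentation network (or a [train_segmentation()]
#'   result).
#' @param image grayscale image matrix in `[0, 1]`.
#' @return list with `prob` and `mask` matrices at the input resolution.
#' @export
laa_predict <- function(net, image) {
  if (!is.null(net$network)) net <- net$network
  insz <- net$cfg$input_size
  x <- resize_bilinear(image, insz[1], insz[2])
  fw <- seg_forward(net, array(x, c(insz, 1L, 1L)), train = FALSE)
  p <- softmax_ch(fw$logits)[, , net$cfg$num_classes, 1]
  prob <- resize_nearest(p, nrow(image), ncol(image))
  list(prob = prob, mask = (prob > 0.5) * 1)
}
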