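# Patient-level splitting, augmentation, the two training stages and
# prediction contracts. Training runs here use deliberately tiny budgets;
# the full-scale behavior is exercised in test-acceptance.R.

manifest_from_counts <- function(counts) {
  rows <- do.call(rbind, lapply(seq_along(counts), function(p)
    data.frame(image_path = sprintf("p%02d_i%02d.png", p, seq_len(counts[p])),
               mask_path = sprintf("p%02d_m%02d.png", p, seq_len(counts[p])),
               patient_id = sprintf("P%02d", p),
               thrombus = p %% 2 == 0, split = "unassigned")))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  load_manifest(path)
}

test_that("6 patients x 10 images split exactly 4:1:1 by patients and images", {
  man <- manifest_from_counts(rep(10L, 6))
  sp <- split_by_patient(man, seed = 1)
  tab <- table(sp$records$split)
  expect_equal(as.integer(tab[c("train", "val", "test")]), c(40L, 10L, 10L))
  pat_split <- unique(sp$records[, c("patient_id", "split")])
  expect_equal(sort(as.integer(table(pat_split$split))), c(1L, 1L, 4L))
})

test_that("splits partition the patients for any seed", {
  man <- manifest_from_counts(c(8L, 12L, 5L, 9L, 14L, 6L, 10L))
  for (seed in 1:10) {
    sp <- split_by_patient(man, seed = seed)
    ps <- unique(sp$records[, c("patient_id", "split")])
    expect_equal(nrow(ps), 7L)                 # no patient in two splits
    expect_setequal(unique(ps$split), c("train", "val", "test"))
  }
  expect_error(split_by_patient(manifest_from_counts(c(5L, 5L))), ">= 3")
})

test_that("split image-count deviation matches the exhaustive optimum (<= 8 patients)", {
  exhaustive_dev <- function(counts, target) {
    n <- length(counts)
    best <- Inf
    for (code in 0:(3^n - 1)) {
      a <- integer(n)
      c0 <- code
      for (i in seq_len(n)) {
        a[i] <- c0 %% 3 + 1
        c0 <- c0 %/% 3
      }
      if (length(unique(a)) < 3) next
      ns <- vapply(1:3, function(s) sum(counts[a == s]), 0)
      best <- min(best, sum(abs(ns - target)))
    }
    best
  }
  set.seed(60)
  for (rep in 1:5) {
    counts <- sample(4:15, sample(5:8, 1), replace = TRUE)
    man <- manifest_from_counts(counts)
    sp <- split_by_patient(man, seed = rep)
    ns <- as.numeric(table(factor(sp$records$split,
                                  c("train", "val", "test"))))
    target <- c(4, 1, 1) / 6 * sum(counts)
    expect_equal(sum(abs(ns - target)), exhaustive_dev(counts, target),
                 tolerance = 1e-9)
  }
})

test_that("augmentation rotates image and mask together; masks stay binary", {
  set.seed(61)
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(0, 64, 64)
  msk[20:40, 25:45] <- 1
  cfg <- train_config(input_size = c(64, 64))
  ag0 <- augment_pair(img, msk, cfg, angle = 0)
  expect_identical(ag0$image, img)
  expect_identical(ag0$mask, msk)
  ag <- augment_pair(img, msk, cfg, angle = 8.5)
  expect_true(all(ag$mask %in% c(0, 1)))
  expect_equal(dim(ag$image), dim(img))
  # centered disk: area preserved within 2% under +10 then -10 degrees
  disk <- ((row(msk) - 32.5)^2 + (col(msk) - 32.5)^2 <= 15^2) * 1
  d1 <- augment_pair(disk, disk, cfg, angle = 10)$mask
  d2 <- augment_pair(d1, d1, cfg, angle = -10)$mask
  expect_lt(abs(sum(d2) - sum(disk)) / sum(disk), 0.02)
})

test_that("zero training steps leave the reconstruction network unchanged", {
  man <- shared_dataset()
  man <- split_by_patient(man, seed = 0)
  cfg <- tiny_net_cfg()
  tc <- train_config(input_size = c(32, 32), recon_steps = 0L, steps = 2L,
                     batch_size = 2L, seed = 1, val_every = 0L)
  fit <- train_reconstruction(man, cfg, tc)
  ref <- laalign:::with_seed(1, build_reconstruction_network(cfg))
  # identical initialization (same seed), no updates applied
  expect_equal(laalign:::get_params(fit$network$layers)[1:5],
               laalign:::get_params(ref$layers)[1:5], tolerance = 1e-15)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training runs are reproducible and the frozen encoder never moves", {
  man <- shared_dataset()
  man <- split_by_patient(man, seed = 0)
  cfg <- tiny_net_cfg()
  tc <- train_config(input_size = c(32, 32), recon_steps = 6L, steps = 6L,
                     batch_size = 4L, recon_batch = 4L, seed = 2,
                     val_every = 0L, select_best = FALSE)
  r1 <- train_reconstruction(man, cfg, tc)
  r2 <- train_reconstruction(man, cfg, tc)
  expect_identical(r1$history$loss, r2$history$loss)

  before <- laalign:::get_params(r1$network$layers)
  s1 <- train_segmentation(man, r1, cfg, tc, loss_weights())
  after <- laalign:::get_params(r1$network$layers)
  expect_identical(before, after)   # freeze contract, bit-identical
  s2 <- train_segmentation(man, r2, cfg, tc, loss_weights())
  expect_identical(s1$history$loss_seg, s2$history$loss_seg)
  expect_identical(s1$history$loss_d, s2$history$loss_d)
  # history carries every loss component
  expect_true(all(c("loss_seg", "loss_d", "loss_gan_g", "loss_cl", "lr")
                  %in% names(s1$history)))
  expect_true(all(is.finite(s1$history$loss_cl)))
})

test_that("doubling reconstruction steps does not raise the final loss beyond noise", {
  man <- shared_dataset()
  man <- split_by_patient(man, seed = 0)
  cfg <- tiny_net_cfg()
  short <- train_reconstruction(man, cfg, train_config(
    input_size = c(32, 32), recon_steps = 15L, recon_batch = 8L, seed = 3,
    val_every = 0L))
  long <- train_reconstruction(man, cfg, train_config(
    input_size = c(32, 32), recon_steps = 30L, recon_batch = 8L, seed = 3,
    val_every = 0L))
  expect_lt(mean(tail(long$history$loss, 5)),
            mean(tail(short$history$loss, 5)) + 0.05)
})

test_that("with zero alignment weights no discriminator is built", {
  man <- shared_dataset()
  man <- split_by_patient(man, seed = 0)
  cfg <- tiny_net_cfg()
  tc <- train_config(input_size = c(32, 32), recon_steps = 2L, steps = 2L,
                     batch_size = 2L, recon_batch = 2L, seed = 4,
                     val_every = 0L, select_best = FALSE)
  rf <- train_reconstruction(man, cfg, tc)
  fit <- train_segmentation(man, rf, cfg, tc,
                            loss_weights(lambda_gan = 0, lambda_cl = 0))
  expect_null(fit$discriminator)
  expect_true(all(is.na(fit$history$loss_d)))
  fit2 <- train_segmentation(man, rf, cfg, tc, loss_weights())
  expect_false(is.null(fit2$discriminator))
})

test_that("on easy synthetic data the training Dice component decreases", {
  man <- shared_dataset()
  man <- split_by_patient(man, seed = 0)
  cfg <- desk_net_cfg()
  tc <- train_config(input_size = c(64, 64), recon_steps = 10L, steps = 40L,
                     batch_size = 4L, recon_batch = 8L, seed = 5,
                     val_every = 0L, select_best = FALSE)
  rf <- train_reconstruction(man, cfg, tc)
  fit <- train_segmentation(man, rf, cfg, tc, loss_weights())
  expect_lt(mean(tail(fit$history$loss_seg, 5)),
            mean(head(fit$history$loss_seg, 5)))
})

test_that("prediction returns a calibrated probability map and binary mask", {
  man <- shared_dataset()
  man <- split_by_patient(man, seed = 0)
  cfg <- tiny_net_cfg()
  tc <- train_config(input_size = c(32, 32), recon_steps = 2L, steps = 2L,
                     batch_size = 2L, recon_batch = 2L, seed = 6,
                     val_every = 0L, select_best = FALSE)
  rf <- train_reconstruction(man, cfg, tc)
  fit <- train_segmentation(man, rf, cfg, tc, loss_weights())
  img <- read_image_png(man$records$image_path[1])  # 64x64, resized internally
  p1 <- laa_predict(fit, img)
  p2 <- laa_predict(fit$network, img)
  expect_identical(p1, p2)                       # deterministic given weights
  expect_equal(dim(p1$prob), dim(img))
  expect_true(all(p1$prob >= 0 & p1$prob <= 1))
  expect_true(all(p1$mask %in% c(0, 1)))
})

test_that("training configuration validates", {
  expect_error(train_config(batch_size = 1), ">= 2")
  expect_error(train_config(rot_range_deg = c(-5, 10)), "symmetric")
  tc <- train_config()
  expect_equal(tc$lr_init, 1e-4)
  expect_equal(tc$beta1, 0.9)
  expect_equal(tc$batch_size, 8L)
  expect_equal(tc$input_size, c(448L, 448L))
  expect_equal(tc$rot_range_deg, c(-10, 10))
})
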