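# Synthetic TEE generator: geometry oracles, noise model contracts,
# determinism, and dataset-level structure.

test_that("shape and speckle parameter validation", {
  expect_error(shape_params(body_axes = c(0, 10)), "degenerate")
  expect_error(shape_params(n_lobes = 0), "n_lobes")
  expect_error(shape_params(neck_width_frac = 1.2), "neck_width_frac")
  expect_error(shape_params(curvature = NaN), "finite")
  expect_error(speckle_params(tissue_level = 0.2, cavity_level = 0.5),
               "hypoechoic")
})

test_that("mask generation is deterministic under a fixed seed", {
  sh <- shape_params(n_lobes = 3, body_axes = c(18, 10), center = c(60, 70),
                     curvature = 0.2)
  m1 <- generate_laa_mask(sh, c(128, 128), seed = 5)
  m2 <- generate_laa_mask(sh, c(128, 128), seed = 5)
  expect_identical(m1, m2)
  m3 <- generate_laa_mask(sh, c(128, 128), seed = 6)
  expect_false(identical(m1, m3))
})

test_that("single-lobe straight mask area matches the analytic ellipse + neck", {
  sh <- shape_params(n_lobes = 1, curvature = 0, body_axes = c(20, 10),
                     orientation = 0, center = c(64, 64),
                     neck_width_frac = 0.3)
  m <- generate_laa_mask(sh, c(128, 128), seed = 1)
  # analytic: pi*a*b plus the neck rectangle part protruding beyond the body
  neck <- 0.4 * 20 * (2 * 0.3 * 10)
  expected <- pi * 20 * 10 + neck
  expect_lt(abs(sum(m) - expected) / expected, 0.15)
  expect_true(all(m %in% c(0, 1)))
})

test_that("masks are single connected components across 1000 seeded draws", {
  set.seed(50)
  ncomp_pkg <- integer(1000)
  for (i in 1:1000) {
    sh <- shape_params(n_lobes = sample(1:4, 1),
                       neck_width_frac = runif(1, 0.1, 0.5),
                       body_axes = sort(runif(2, 8, 24), decreasing = TRUE),
                       orientation = runif(1, -pi, pi),
                       center = c(runif(1, 45, 80), runif(1, 45, 80)),
                       curvature = runif(1, -0.3, 0.3))
    m <- generate_laa_mask(sh, c(128, 128))
    lab <- laalign:::.label_components(matrix(as.integer(m), 128, 128))
    ncomp_pkg[i] <- max(lab)
  }
  expect_true(all(ncomp_pkg == 1L))
})

test_that("noise-free render is piecewise constant at the two tissue levels", {
  sh <- shape_params(body_axes = c(15, 9), center = c(64, 64))
  m <- generate_laa_mask(sh, c(128, 128), seed = 2)
  sp <- speckle_params(speckle_scale = 0, psf_sigma = 0,
                       tissue_level = 0.65, cavity_level = 0.15)
  img <- render_tee_image(m, sp, seed = 1)
  sector <- laalign:::.sector_mask(c(128, 128), sp$sector_angle)
  expect_setequal(unique(as.vector(img[sector == 1])), c(0.15, 0.65))
  expect_true(all(img[sector == 0] == 0))
})

test_that("the cavity is darker than the tissue in >= 99% of 200 seeded renders", {
  sh <- shape_params(body_axes = c(15, 9), center = c(64, 64))
  m <- generate_laa_mask(sh, c(128, 128), seed = 3)
  sector <- laalign:::.sector_mask(c(128, 128), pi / 2)
  ok <- vapply(1:200, function(s) {
    img <- render_tee_image(m, speckle_params(), seed = s)
    mean(img[m == 1]) < mean(img[m == 0 & sector == 1])
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("thrombus renders as a bright connected region strictly inside the cavity", {
  sh <- shape_params(body_axes = c(16, 10), center = c(64, 64))
  m <- generate_laa_mask(sh, c(128, 128), seed = 4)
  sp <- speckle_params(thrombus = TRUE)
  img <- render_tee_image(m, sp, seed = 9)
  bright <- (img > sp$tissue_level) * m
  expect_gt(sum(bright), 0)
  lab <- laalign:::.label_components(matrix(as.integer(bright), 128, 128))
  sizes <- tabulate(lab[lab > 0])
  blob <- which(lab == which.max(sizes), arr.ind = TRUE)
  expect_gt(mean(img[blob]), sp$tissue_level)
  # all bright-blob pixels lie inside the mask by construction
  expect_true(all(m[blob] == 1))
})

test_that("a mask entirely outside the sector is rejected", {
  m <- matrix(0, 128, 128)
  m[1:6, 1:6] <- 1   # top-left corner, outside the wedge
  expect_error(render_tee_image(m, speckle_params(), seed = 1),
               "unusable geometry")
})

test_that("dataset generation: counts, determinism, and byte-identical PNGs", {
  man <- generate_dataset(6, 10, 0.5, c(64, 64), seed = 3,
                          out_dir = file.path(tempdir(), "ds_a"))
  expect_equal(nrow(man$records), 60)
  expect_equal(length(unique(man$records$patient_id)), 6)
  expect_error(generate_dataset(2, 5), ">= 3")
  expect_error(generate_dataset(5, 5, thrombus_fraction = 1.5), "thrombus")

  man2 <- generate_dataset(6, 10, 0.5, c(64, 64), seed = 3,
                           out_dir = file.path(tempdir(), "ds_b"))
  expect_equal(basename(man$records$image_path),
               basename(man2$records$image_path))
  expect_equal(man$records$patient_id, man2$records$patient_id)
  expect_equal(man$records$thrombus, man2$records$thrombus)
  for (i in c(1, 17, 42)) {
    expect_identical(readBin(man$records$image_path[i], "raw", 1e6),
                     readBin(man2$records$image_path[i], "raw", 1e6))
    expect_identical(readBin(man$records$mask_path[i], "raw", 1e6),
                     readBin(man2$records$mask_path[i], "raw", 1e6))
  }
})

test_that("PNG round trip reproduces mask bits exactly; prevalence in [1%, 25%]", {
  man <- shared_dataset()
  for (i in seq_len(nrow(man$records))) {
    m <- read_mask_png(man$records$mask_path[i])
    expect_true(all(m %in% c(0, 1)))
    expect_gte(mean(m), 0.01)
    expect_lte(mean(m), 0.25)
    img <- read_image_png(man$records$image_path[i])
    expect_true(all(img >= 0 & img <= 1))
  }
  m <- read_mask_png(man$records$mask_path[1])
  p <- tempfile(fileext = ".png")
  write_mask_png(m, p)
  expect_identical(read_mask_png(p), m)
})

test_that("thrombus flag is constant per patient", {
  man <- shared_dataset()
  per_pat <- tapply(man$records$thrombus, man$records$patient_id,
                    function(v) length(unique(v)))
  expect_true(all(per_pat == 1))
})

test_that("within-patient mask overlap exceeds cross-patient overlap", {
  man <- generate_dataset(10, 4, 0.5, c(64, 64), seed = 21,
                          out_dir = file.path(tempdir(), "ds_iou"))
  masks <- lapply(man$records$mask_path, read_mask_png)
  # center each mask on its centroid before IoU, per the dataset contract
  center_mask <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    sh <- round(c(32, 32) - colMeans(idx))
    out <- matrix(0, 64, 64)
    src_r <- max(1, 1 - sh[1]):min(64, 64 - sh[1])
    src_c <- max(1, 1 - sh[2]):min(64, 64 - sh[2])
    out[src_r + sh[1], src_c + sh[2]] <- m[src_r, src_c]
    out
  }
  cm <- lapply(masks, center_mask)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  pid <- man$records$patient_id
  within <- c()
  cross <- c()
  n <- length(cm)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- iou(cm[[i]], cm[[j]])
    if (pid[i] == pid[j]) within <- c(within, v) else cross <- c(cross, v)
  }
  expect_gt(mean(within), mean(cross))
})
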