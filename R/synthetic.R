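# Synthetic TEE data generator.
#
# Emulates the statistical structure of a clinical TEE LAA dataset: a
# sector-shaped B-mode field of view with multiplicative speckle, a
# hypoechoic (dark) lobed cavity with a narrow neck as the segmentation
# target, per-patient anatomical correlation (small parameter jitter around
# a patient-level base shape), and a per-patient thrombus flag rendered as a
# bright blob inside the cavity.

#' LAA shape parameters
#'
#' Parametrizes the finger-like LAA cavity: an elliptical body that may be
#' bent (curvature), decorated with 0 or more accessory lobes, and attached
#' to a narrow neck.
#'
#' @param n_lobes total number of elliptical lobes (1-4; 1 = body only).
#' @param neck_width_frac neck width as a fraction of the body width `2*b`,
#'   in (0, 1).
#' @param body_axes `(a, b)` semi-axes of the body ellipse in pixels.
#' @param orientation body major-axis angle in radians.
#' @param center `(row, col)` center in pixels (0-based convention).
#' @param curvature signed bending factor for the hook-like shape
#'   (0 = straight).
#' @return A `laa_shape_params` list.
#' @export
shape_params <- function(n_lobes = 1L, neck_width_frac = 0.3,
                         body_axes = c(20, 10), orientation = 0,
                         center = c(64, 64), curvature = 0) {
  if (!all(is.finite(c(n_lobes, neck_width_frac, body_axes, orientation,
                       center, curvature))))
    stopf("shape parameters must all be finite")
  if (n_lobes < 1) stopf("n_lobes must be >= 1")
  if (neck_width_frac <= 0 || neck_width_frac >= 1)
    stopf("neck_width_frac must lie in (0, 1)")
  if (any(body_axes <= 0)) stopf("degenerate shape: body axes must be > 0")
  structure(list(n_lobes = as.integer(n_lobes),
                 neck_width_frac = neck_width_frac,
                 body_axes = body_axes, orientation = orientation,
                 center = center, curvature = curvature),
            class = "laa_shape_params")
}

#' Speckle/rendering parameters
#'
#' @param speckle_scale dispersion of the unit-mean multiplicative Gamma
#'   speckle (0 = noise-free).
#' @param psf_sigma Gaussian point-spread blur std in pixels (0 = none).
#' @param tissue_level,cavity_level mean intensities in `[0, 1]`; the cavity
#'   must be hypoechoic (`cavity_level < tissue_level`).
#' @param sector_angle field-of-view wedge angle in radians.
#' @param thrombus render a bright thrombus blob inside the cavity.
#' @param thrombus_level blob intensity.
#' @return A `laa_speckle_params` list.
#' @export
speckle_params <- function(speckle_scale = 0.35, psf_sigma = 1.0,
                           tissue_level = 0.65, cavity_level = 0.15,
                           sector_angle = pi / 2, thrombus = FALSE,
                           thrombus_level = 0.9) {
  if (cavity_level >= tissue_level)
    stopf("cavity_level must be < tissue_level (the LAA cavity is hypoechoic)")
  if (speckle_scale < 0 || psf_sigma < 0) stopf("noise parameters must be >= 0")
  structure(list(speckle_scale = speckle_scale, psf_sigma = psf_sigma,
                 tissue_level = tissue_level, cavity_level = cavity_level,
                 sector_angle = sector_angle, thrombus = thrombus,
                 thrombus_level = thrombus_level),
            class = "laa_speckle_params")
}

# body-frame coordinates (u along the major axis, v across) of every pixel
.body_frame <- function(size, shape) {
  y <- matrix(0:(size[1] - 1L), size[1], size[2])
  x <- matrix(0:(size[2] - 1L), size[1], size[2], byrow = TRUE)
  dy <- y - shape$center[1]
  dx <- x - shape$center[2]
  co <- cos(shape$orientation)
  si <- sin(shape$orientation)
  list(u = co * dx + si * dy, v = -si * dx + co * dy)
}

#' Generate a synthetic LAA mask
#'
#' Rasterizes the shape as a binary mask: bent body ellipse, accessory lobes
#' overlapping the body (so the mask is a single connected component by
#' construction), and a neck rectangle of width
#' `neck_width_frac * 2 * b` extending from the body center outward beyond
#' the body boundary.
#'
#' @param shape a [shape_params()].
#' @param size `(h, w)` in pixels, at least 32x32.
#' @param seed optional integer; when given, lobe placement is drawn under
#'   this seed (and the caller's RNG state is untouched).
#' @return binary matrix `(h, w)` with values 0/1.
#' @export
generate_laa_mask <- function(shape, size = c(128L, 128L), seed = NULL) {
  if (!inherits(shape, "laa_shape_params"))
    shape <- do.call(shape_params, shape)
  if (length(size) == 1L) size <- rep(size, 2L)
  if (any(size < 32L)) stopf("mask size must be at least 32x32")
  run <- function() .generate_laa_mask(shape, size)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.generate_laa_mask <- function(shape, size) {
  a <- shape$body_axes[1]
  b <- shape$body_axes[2]
  bf <- .body_frame(size, shape)
  vb <- bf$v - shape$curvature * bf$u^2 / a    # bend across the major axis
  m <- (bf$u / a)^2 + (vb / b)^2 <= 1
  # neck: from the body center along -u, protruding 40% of a beyond the rim
  half <- shape$neck_width_frac * b
  m <- m | (bf$u <= 0 & bf$u >= -1.4 * a & abs(vb) <= half)
  if (shape$n_lobes > 1L) {
    for (i in seq_len(shape$n_lobes - 1L)) {
      phi <- runif(1, -pi, pi)
      scl <- runif(1, 0.35, 0.55)
      # lobe center strictly inside the body rim -> overlap -> connectivity
      cu <- 0.9 * a * cos(phi)
      cv <- 0.9 * b * sin(phi)
      m <- m | (((bf$u - cu) / (scl * a))^2 +
                  ((vb - cv) / (scl * b))^2 <= 1)
    }
  }
  m <- m * 1
  # keep the component containing the body center (numerical safety; the
  # construction overlaps every part with the body)
  lab <- .label_components(matrix(as.integer(m), nrow(m), ncol(m)))
  ci <- round(shape$center[1]) + 1L
  cj <- round(shape$center[2]) + 1L
  ci <- min(max(ci, 1L), size[1])
  cj <- min(max(cj, 1L), size[2])
  keep <- lab[ci, cj]
  if (keep == 0) keep <- lab[which(lab > 0)[1]]
  (lab == keep) * 1
}

.sector_mask <- function(size, angle) {
  h <- size[1]
  w <- size[2]
  y <- matrix(0:(h - 1L), h, w)
  x <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  ay <- -0.02 * h                      # apex slightly above the frame
  ax <- (w - 1) / 2
  dy <- y - ay
  dx <- x - ax
  th <- atan2(dx, dy)                  # 0 along the beam axis (downwards)
  r <- sqrt(dx^2 + dy^2)
  (dy > 0 & abs(th) <= angle / 2 & r <= 1.12 * h) * 1
}

.gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  g <- dnorm(seq(-(k %/% 2L), k %/% 2L), sd = sigma)
  ker <- outer(g, g)
  ker <- ker / sum(ker)
  x <- array(img, c(dim(img), 1L, 1L))
  out <- .dwconv_forward(x, array(ker, c(k, k, 1L)), 0, k %/% 2L)
  matrix(out, dim(img)[1], dim(img)[2])
}

#' Render a synthetic TEE image from a mask
#'
#' Paints tissue at `tissue_level` inside the sector wedge and the cavity at
#' `cavity_level`, optionally places a bright thrombus blob strictly inside
#' the cavity, applies unit-mean multiplicative Gamma speckle and a Gaussian
#' point-spread blur, clips to `[0, 1]` and zeroes everything outside the
#' sector.
#'
#' @param mask binary cavity mask `(h, w)`.
#' @param sp a [speckle_params()].
#' @param seed optional integer seed for the speckle draw.
#' @return grayscale image matrix in `[0, 1]`, 0 outside the sector.
#' @export
render_tee_image <- function(mask, sp = speckle_params(), seed = NULL) {
  run <- function() .render_tee_image(mask, sp)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.render_tee_image <- function(mask, sp) {
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary {0, 1}")
  size <- dim(mask)
  sector <- .sector_mask(size, sp$sector_angle)
  if (sum(mask) > 0 && sum(mask * sector) == 0)
    stopf("unusable geometry: mask lies entirely outside the imaging sector")
  img <- matrix(sp$tissue_level, size[1], size[2])
  img[mask == 1] <- sp$cavity_level
  if (sp$thrombus && sum(mask) > 0) {
    idx <- which(mask == 1, arr.ind = TRUE)
    cen <- colMeans(idx)
    d2 <- (idx[, 1] - cen[1])^2 + (idx[, 2] - cen[2])^2
    seedpt <- idx[which.min(d2), ]                 # mask pixel nearest centroid
    rb <- 0.35 * sqrt(sum(mask) / pi)
    blob <- (row(mask) - seedpt[1])^2 + (col(mask) - seedpt[2])^2 <= rb^2
    img[blob & mask == 1] <- sp$thrombus_level     # strictly inside the cavity
  }
  if (sp$speckle_scale > 0) {
    k <- 1 / sp$speckle_scale^2
    img <- img * matrix(rgamma(length(img), shape = k, scale = 1 / k),
                        size[1], size[2])
  }
  img <- .gaussian_blur(img, sp$psf_sigma)
  img <- pmin(pmax(img, 0), 1)
  img * sector
}

#' Generate a full synthetic TEE dataset
#'
#' Draws one base [shape_params()] per patient, then renders
#' `images_per_patient` image/mask pairs with small (<= 10%) per-image
#' parameter jitter, so masks of one patient resemble each other more than
#' masks across patients. The thrombus flag is constant per patient;
#' `round(thrombus_fraction * n_patients)` patients are thrombotic. Writes
#' 8-bit PNG pairs plus `manifest.csv` under `out_dir`.
#'
#' @param n_patients number of patients (>= 3 so a patient-level 4:1:1 split
#'   exists).
#' @param images_per_patient images per patient.
#' @param thrombus_fraction fraction of thrombotic patients in `[0, 1]`.
#' @param size `(h, w)` image size in pixels.
#' @param seed integer seed; the whole dataset is a pure function of the
#'   arguments and this seed.
#' @param out_dir output directory (created if needed).
#' @return A `laa_manifest` (see [load_manifest()]).
#' @export
generate_dataset <- function(n_patients, images_per_patient,
                             thrombus_fraction = 0.5, size = c(128L, 128L),
                             seed = 1L, out_dir = tempfile("laa_synth_")) {
  if (n_patients < 3L)
    stopf("need >= 3 patients for a patient-level train/val/test split")
  if (thrombus_fraction < 0 || thrombus_fraction > 1)
    stopf("thrombus_fraction must lie in [0, 1]")
  if (length(size) == 1L) size <- rep(size, 2L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)

  with_seed(seed, {
    h <- size[1]
    w <- size[2]
    s <- min(h, w)
    n_th <- round(thrombus_fraction * n_patients)
    th_flags <- logical(n_patients)
    th_flags[sample.int(n_patients, n_th)] <- TRUE
    rows <- list()
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      a <- runif(1, 0.14, 0.20) * s
      base <- list(n_lobes = sample(1:3, 1),
                   neck_width_frac = runif(1, 0.2, 0.4),
                   body_axes = c(a, runif(1, 0.5, 0.75) * a),
                   orientation = runif(1, -pi, pi),
                   center = c(runif(1, 0.45, 0.62) * h,
                              runif(1, 0.40, 0.60) * w),
                   curvature = runif(1, -0.25, 0.25))
      sp <- speckle_params(thrombus = th_flags[p])
      for (i in seq_len(images_per_patient)) {
        jit <- function(x) x * (1 + runif(length(x), -0.1, 0.1))
        shp <- shape_params(n_lobes = base$n_lobes,
                            neck_width_frac = jit(base$neck_width_frac),
                            body_axes = jit(base$body_axes),
                            orientation = base$orientation +
                              runif(1, -0.1, 0.1) * pi,
                            center = base$center + runif(2, -0.02, 0.02) * s,
                            curvature = jit(base$curvature))
        mask <- .generate_laa_mask(shp, size)
        img <- .render_tee_image(mask, sp)
        ip <- file.path(out_dir, sprintf("%s_%03d_img.png", pid, i))
        mp <- file.path(out_dir, sprintf("%s_%03d_mask.png", pid, i))
        write_image_png(img, ip)
        write_mask_png(mask, mp)
        rows[[length(rows) + 1L]] <- data.frame(
          image_path = ip, mask_path = mp, patient_id = pid,
          thrombus = th_flags[p], split = "unassigned")
      }
    }
    man <- new_manifest(do.call(rbind, rows), image_size = size, seed = seed)
    save_manifest(man, file.path(out_dir, "manifest.csv"))
    man
  })
}
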