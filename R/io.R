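# File formats: 8-bit grayscale PNG for images and masks, CSV manifests,
# YAML run configuration.

#' Read / write TEE images and masks as 8-bit grayscale PNG
#'
#' Images are scaled to `[0, 1]`. Masks must contain only the byte values
#' 0 and 255 on disk, mapped to 0/1 in memory (255 = LAA foreground); any
#' other value is rejected.
#'
#' @param path file path.
#' @return `read_image_png`: numeric matrix in `[0, 1]`; `read_mask_png`:
#'   binary 0/1 matrix.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] > 1 &&
        !all(abs(x[, , 1] - x[, , 2]) < 1e-9)) # nocov
      stopf("expected a grayscale PNG: %s", path)
    x <- x[, , 1]
  }
  x
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  x <- read_image_png(path)
  b <- round(x * 255)
  bad <- setdiff(unique(as.vector(b)), c(0, 255))
  if (length(bad) > 0)
    stopf("mask %s contains illegal byte value(s): %s", path,
          paste(bad, collapse = ", "))
  (b == 255) * 1
}

#' @rdname read_image_png
#' @param image numeric matrix in `[0, 1]`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname read_image_png
#' @param mask binary 0/1 matrix.
#' @export
write_mask_png <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary {0, 1}")
  png::writePNG(mask, path)
  invisible(path)
}

manifest_cols <- c("image_path", "mask_path", "patient_id", "thrombus",
                   "split")

#' Dataset manifest I/O
#'
#' A manifest is the dataset index: one row per image/mask pair with patient
#' identity, thrombus status and split assignment. On disk it is a CSV with
#' header `image_path,mask_path,patient_id,thrombus,split`.
#'
#' @param path CSV path.
#' @param check_files verify that referenced image/mask files exist.
#' @return A `laa_manifest`: list with `records` (data.frame), `image_size`
#'   and `seed` (the latter two `NA` when not recorded by a generator).
#' @export
load_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path)) stopf("no such manifest: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stopf("manifest %s is empty", path)
  if (!identical(names(df), manifest_cols))
    stopf("manifest %s: header must be exactly %s", path,
          paste(manifest_cols, collapse = ","))
  bad <- which(df$patient_id == "" | is.na(df$patient_id))
  if (length(bad) > 0)
    stopf("manifest %s: empty patient_id at line(s) %s", path,
          paste(bad + 1L, collapse = ", "))
  dup <- which(duplicated(df$image_path))
  if (length(dup) > 0)
    stopf("manifest %s: duplicate image_path at line(s) %s", path,
          paste(dup + 1L, collapse = ", "))
  if (!all(df$split %in% c("train", "val", "test", "unassigned")))
    stopf("manifest %s: illegal split labels", path)
  df$thrombus <- as.logical(df$thrombus)
  if (check_files) {
    missing <- c(df$image_path, df$mask_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing) > 0)
      stopf("manifest %s: missing files: %s", path,
            paste(utils::head(missing, 5), collapse = ", "))
  }
  new_manifest(df)
}

#' @rdname load_manifest
#' @param manifest a `laa_manifest`.
#' @export
save_manifest <- function(manifest, path) {
  df <- manifest$records[, manifest_cols]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

new_manifest <- function(records, image_size = NA, seed = NA) {
  structure(list(records = records, image_size = image_size, seed = seed),
            class = "laa_manifest")
}

#' @export
print.laa_manifest <- function(x, ...) {
  cat(sprintf("LAA dataset manifest: %d images, %d patients (%d thrombus)\n",
              nrow(x$records), length(unique(x$records$patient_id)),
              sum(tapply(x$records$thrombus, x$records$patient_id, any))))
  print(table(split = x$records$split))
  invisible(x)
}

#' Run configuration I/O
#'
#' Serializes the network configuration, training configuration and loss
#' weights as one YAML document and reads it back losslessly.
#'
#' @param cfg list with elements `network` ([network_config()]), `train`
#'   ([train_config()]) and `losses` ([loss_weights()]).
#' @param path YAML file path.
#' @return `load_run_config` returns the same structure with classes
#'   restored.
#' @export
save_run_config <- function(cfg, path) {
  yaml::write_yaml(lapply(cfg, unclass), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config: %s", path)
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$network)) out$network <- do.call(network_config, y$network)
  if (!is.null(y$train)) out$train <- do.call(train_config, y$train)
  if (!is.null(y$losses)) out$losses <- do.call(loss_weights, y$losses)
  extra <- setdiff(names(y), c("network", "train", "losses"))
  out[extra] <- y[extra]
  out
}
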