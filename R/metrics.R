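# Evaluation metrics: per-image confusion counts and the derived suite
# (Dice, IoU, accuracy, G-mean, Cohen's kappa, AUC), aggregated as
# mean +/- standard deviation overall and per thrombus subgroup.

#' Pixel confusion counts
#'
#' @param pred binary predicted mask (matrix of 0/1).
#' @param gt binary ground-truth mask, same shape. Foreground (1) is the
#'   positive class.
#' @return list with integer `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stopf("confusion_counts: shape mismatch")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stopf("confusion_counts: masks must be binary {0, 1}")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  tn <- sum(pred == 0 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Segmentation metrics from confusion counts
#'
#' `dice = 2*TP / (FP + FN + 2*TP)`, `iou = TP / (FP + FN + TP)`,
#' `acc = (TP + TN) / N`, `gmean = sqrt(sensitivity * specificity)` with
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`.
#'
#' Degenerate conventions: with empty ground truth AND empty prediction,
#' dice and iou are 1 (perfect agreement); empty ground truth with a
#' non-empty prediction gives 0. Sensitivity (specificity) with no positive
#' (negative) pixels is taken as 1 when the prediction agrees.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return scalar metric value.
#' @export
metric_dice <- function(c) {
  den <- c$fp + c$fn + 2 * c$tp
  if (den == 0) return(1)
  2 * c$tp / den
}

#' @rdname metric_dice
#' @export
metric_iou <- function(c) {
  den <- c$fp + c$fn + c$tp
  if (den == 0) return(1)
  c$tp / den
}

#' @rdname metric_dice
#' @export
metric_acc <- function(c) (c$tp + c$tn) / (c$tp + c$tn + c$fp + c$fn)

#' @rdname metric_dice
#' @export
metric_gmean <- function(c) {
  sens <- if (c$tp + c$fn == 0) 1 else c$tp / (c$tp + c$fn)
  spec <- if (c$tn + c$fp == 0) 1 else c$tn / (c$tn + c$fp)
  sqrt(sens * spec)
}

#' Cohen's kappa from confusion counts
#'
#' Chance agreement `p_e = ((TP+FN)(TP+FP) + (TN+FP)(TN+FN)) / N^2`, kappa
#' `(acc - p_e) / (1 - p_e)`. When `p_e = 1` (both masks are all one class)
#' kappa is 1 if prediction equals ground truth and 0 otherwise.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return scalar in `[-1, 1]`.
#' @export
metric_kappa <- function(c) {
  c <- lapply(c, as.numeric)   # marginal products overflow integer range
  n <- c$tp + c$tn + c$fp + c$fn
  pe <- ((c$tp + c$fn) * (c$tp + c$fp) + (c$tn + c$fp) * (c$tn + c$fn)) / n^2
  acc <- metric_acc(c)
  if (abs(1 - pe) < .Machine$double.eps * 4)
    return(if (c$fp + c$fn == 0) 1 else 0)
  (acc - pe) / (1 - pe)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC curve swept over the distinct score values
#' of the probability map (exact, not binned); with ties handled this equals
#' the normalized Mann-Whitney statistic.
#'
#' @param prob foreground probability map.
#' @param gt binary ground-truth mask, same shape.
#' @return scalar in `[0, 1]`, or `NA` with a warning when `gt` contains a
#'   single class (AUC undefined).
#' @export
metric_auc <- function(prob, gt) {
  if (!all(dim(prob) == dim(gt))) stopf("auc: shape mismatch")
  g <- as.vector(gt)
  p <- as.vector(prob)
  npos <- sum(g == 1)
  nneg <- sum(g == 0)
  if (npos == 0 || nneg == 0) {
    warning("AUC undefined for single-class ground truth; returning NA")
    return(NA_real_)
  }
  # sweep thresholds over distinct scores, descending; accumulate ROC points
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  gs <- g[ord]
  distinct <- c(which(diff(ps) != 0), length(ps))
  ctp <- cumsum(gs)[distinct]
  cfp <- cumsum(1 - gs)[distinct]
  tpr <- c(0, ctp / npos)
  fpr <- c(0, cfp / nneg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Evaluate predictions against a manifest's test records
#'
#' Computes per-image Dice, IoU, accuracy, G-mean, kappa and AUC at a 0.5
#' binarization threshold, then aggregates mean +/- standard deviation
#' (population, n divisor) overall and by thrombus subgroup. Metrics are per
#' image and then averaged, never pooled over the dataset.
#'
#' @param predictions list, one element per record: `list(prob = <probability
#'   map>, mask = <binary mask>)`. `mask` may be omitted (thresholded from
#'   `prob` at 0.5).
#' @param manifest a dataset manifest ([load_manifest()] /
#'   [generate_dataset()]); ground-truth masks are read from its
#'   `mask_path`s.
#' @param records optional subset of manifest rows to evaluate (default: the
#'   rows whose `split == "test"`, or all rows if no split is assigned).
#' @param csv_path optional path; when given, per-image rows plus summary
#'   rows are written as CSV.
#' @return A `laa_metric_report`: list with `per_image` (data.frame) and
#'   `summary` (data.frame of mean/sd by group).
#' @export
evaluate <- function(predictions, manifest, records = NULL, csv_path = NULL) {
  df <- manifest$records
  if (is.null(records)) {
    records <- if (any(df$split == "test")) which(df$split == "test")
               else seq_len(nrow(df))
  }
  if (length(predictions) != length(records))
    stopf("got %d predictions for %d records",
          length(predictions), length(records))
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- df[records[i], ]
    pr <- predictions[[i]]
    if (is.null(pr) || is.null(pr$prob))
      stopf("missing prediction for sample '%s'", r$image_path)
    gt <- read_mask_png(r$mask_path)
    pm <- if (!is.null(pr$mask)) pr$mask else (pr$prob > 0.5) * 1
    cc <- confusion_counts(pm, gt)
    rows[[i]] <- data.frame(
      sample = basename(r$image_path), patient_id = r$patient_id,
      thrombus = r$thrombus,
      dice = metric_dice(cc), iou = metric_iou(cc), acc = metric_acc(cc),
      gmean = metric_gmean(cc), kappa = metric_kappa(cc),
      auc = suppressWarnings(metric_auc(pr$prob, gt)))
  }
  per_image <- do.call(rbind, rows)
  metric_cols <- c("dice", "iou", "acc", "gmean", "kappa", "auc")
  pop_sd <- function(x) {
    x <- x[!is.na(x)]
    sqrt(mean((x - mean(x))^2))
  }
  summarize <- function(sub, label) {
    data.frame(group = label, n = nrow(sub),
               metric = metric_cols,
               mean = vapply(metric_cols,
                             function(m) mean(sub[[m]], na.rm = TRUE), 0),
               sd = vapply(metric_cols, function(m) pop_sd(sub[[m]]), 0),
               row.names = NULL)
  }
  summary <- summarize(per_image, "overall")
  if (any(per_image$thrombus)) summary <- rbind(
    summary, summarize(per_image[per_image$thrombus, ], "thrombus"))
  if (any(!per_image$thrombus)) summary <- rbind(
    summary, summarize(per_image[!per_image$thrombus, ], "non_thrombus"))
  rep <- structure(list(per_image = per_image, summary = summary),
                   class = "laa_metric_report")
  if (!is.null(csv_path)) {
    out <- per_image
    out$group <- "per_image"
    smry <- summary
    names(smry)[names(smry) == "group"] <- "sample"
    write.csv(per_image, csv_path, row.names = FALSE)
    write.csv(summary, sub("\\.csv$", "_summary.csv", csv_path),
              row.names = FALSE)
  }
  rep
}

#' @export
print.laa_metric_report <- function(x, ...) {
  cat("LAA segmentation metric report\n")
  s <- x$summary
  for (g in unique(s$group)) {
    sg <- s[s$group == g, ]
    cat(sprintf("  %s (n = %d):\n", g, sg$n[1]))
    for (i in seq_len(nrow(sg)))
      cat(sprintf("    %-6s %.3f +/- %.3f\n", sg$metric[i], sg$mean[i],
                  sg$sd[i]))
  }
  invisible(x)
}
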