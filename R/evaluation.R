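# Analytical-performance metrics: intersection-over-union, detection rate and
# false-alarm rate per class as functions of the confidence threshold, in
# both a pixel-level and an object-level reading (the two are always computed
# side by side; figure captions alone cannot adjudicate which one a given
# report used).

#' Pixel intersection-over-union between prediction and reference
#'
#' |pred & gt| / |pred | gt|; defined as 1 when both are empty.
#'
#' @param pred,gt logical matrices (or `binary_mask`s) of the same shape.
#' @return fraction in \[0, 1\].
#' @export
pixel_iou <- function(pred, gt) {
  p <- if (inherits(pred, "binary_mask")) pred$values else pred
  g <- if (inherits(gt, "binary_mask")) gt$values else gt
  if (!all(dim(p) == dim(g))) stop("shape mismatch", call. = FALSE)
  u <- sum(p | g)
  if (u == 0L) return(1)
  sum(p & g) / u
}

#' Detection rate (how much of the reference the prediction recovers)
#'
#' Pixel mode: recall, |pred & gt| / |gt|. Object mode: the fraction of
#' reference components having at least `theta` of their pixels covered by
#' the prediction. 1 when the reference is empty.
#'
#' @param pred logical matrix or `binary_mask` (pixel mode), or
#'   [labeled_regions] of predictions (object mode accepts either; only the
#'   foreground is used in pixel mode).
#' @param gt logical matrix/`binary_mask` (pixel mode) or [labeled_regions]
#'   (object mode).
#' @param mode `"pixel"` or `"object"`.
#' @param theta object-mode coverage threshold, in (0, 1].
#' @return fraction in \[0, 1\].
#' @export
detection_rate <- function(pred, gt, mode = c("pixel", "object"), theta = 0.5) {
  mode <- match.arg(mode)
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]", call. = FALSE)
  p <- as_fg(pred); g <- as_fg(gt)
  if (!all(dim(p) == dim(g))) stop("shape mismatch", call. = FALSE)
  if (mode == "pixel") {
    if (!any(g)) return(1)
    return(sum(p & g) / sum(g))
  }
  greg <- as_regions(gt)
  if (length(greg$areas) == 0L) return(1)
  covered <- vapply(region_pixels(greg),
                    function(idx) mean(p[idx]) >= theta, logical(1))
  mean(covered)
}

#' False-alarm rate (how much of the prediction is wrong)
#'
#' Pixel mode: false-discovery fraction, |pred \\ gt| / |pred|. Object mode:
#' the fraction of predicted components with less than `theta` of their
#' pixels inside the reference. 0 when the prediction is empty.
#'
#' @inheritParams detection_rate
#' @return fraction in \[0, 1\].
#' @export
false_alarm_rate <- function(pred, gt, mode = c("pixel", "object"),
                             theta = 0.5) {
  mode <- match.arg(mode)
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]", call. = FALSE)
  p <- as_fg(pred); g <- as_fg(gt)
  if (!all(dim(p) == dim(g))) stop("shape mismatch", call. = FALSE)
  if (mode == "pixel") {
    if (!any(p)) return(0)
    return(sum(p & !g) / sum(p))
  }
  preg <- as_regions(pred)
  if (length(preg$areas) == 0L) return(0)
  false_comp <- vapply(region_pixels(preg),
                       function(idx) mean(g[idx]) < theta, logical(1))
  mean(false_comp)
}

as_fg <- function(x) {
  if (inherits(x, "labeled_regions")) return(x$labels > 0L)
  if (inherits(x, "binary_mask")) return(x$values)
  stopifnot(is.logical(x), is.matrix(x))
  x
}

as_regions <- function(x, connectivity = 8) {
  if (inherits(x, "labeled_regions")) return(x)
  label_components(as_fg(x), connectivity)
}

#' Threshold sweep of all three metrics for both classes
#'
#' For each threshold, every probability map is binarized, labeled, and
#' passed through the small-focus filter; metrics are then pooled over the
#' whole image set before ratio-taking (pixel mode pools pixel counts, object
#' mode pools component verdicts), which keeps empty images harmless. Both
#' the pixel-level and object-level readings of detection/false alarm are
#' reported; object-mode IOU is the Jaccard index of matched components
#' (reference components covered at `theta` over the union of reference and
#' predicted components not double-counting matches).
#'
#' @param maps list of [probability_map]s.
#' @param gts list of [ground_truth]s (or integer class masks) aligned with
#'   `maps`.
#' @param thresholds ascending confidence cutoffs in \[0, 1\].
#' @param min_area per-class minimum focus area, named vector
#'   `c(tumor =, nerve =)`; applied to predictions.
#' @param connectivity component connectivity.
#' @param theta object-mode coverage threshold.
#' @return a `metric_curves` data.frame with columns class, metric, mode,
#'   threshold, value, min_area.
#' @export
sweep_metrics <- function(maps, gts, thresholds = seq(0, 1, by = 0.1),
                          min_area = c(tumor = 10000, nerve = 10000),
                          connectivity = 8, theta = 0.5) {
  if (length(maps) == 0L) stop("empty image set", call. = FALSE)
  if (length(maps) != length(gts)) stop("maps/gts length mismatch", call. = FALSE)
  thresholds <- as.numeric(thresholds)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  classes <- c("tumor", "nerve")
  gmask <- lapply(gts, function(g) {
    m <- if (inherits(g, "ground_truth")) g$class_mask else g
    list(tumor = m == CLASS_CODES[["tumor"]], nerve = m == CLASS_CODES[["nerve"]])
  })
  rows <- list()
  for (t in thresholds) {
    for (cl in classes) {
      ma <- unname(min_area[cl])
      inter <- uni <- gt_n <- pred_n <- pred_fp <- 0
      n_gt_comp <- n_det_comp <- n_pred_comp <- n_fp_comp <- 0
      for (i in seq_along(maps)) {
        pred <- filter_small(
          label_components(binarize(maps[[i]], cl, t), connectivity), ma)
        pm <- regions_mask(pred)
        gm <- gmask[[i]][[cl]]
        inter <- inter + sum(pm & gm)
        uni <- uni + sum(pm | gm)
        gt_n <- gt_n + sum(gm)
        pred_n <- pred_n + sum(pm)
        pred_fp <- pred_fp + sum(pm & !gm)
        greg <- label_components(gm, connectivity)
        gpx <- region_pixels(greg)
        det <- vapply(gpx, function(idx) mean(pm[idx]) >= theta, logical(1))
        n_gt_comp <- n_gt_comp + length(gpx)
        n_det_comp <- n_det_comp + sum(det)
        ppx <- region_pixels(pred)
        fp <- vapply(ppx, function(idx) mean(gm[idx]) < theta, logical(1))
        n_pred_comp <- n_pred_comp + length(ppx)
        n_fp_comp <- n_fp_comp + sum(fp)
      }
      vals <- c(
        iou_pixel = if (uni > 0) inter / uni else 1,
        detection_rate_pixel = if (gt_n > 0) inter / gt_n else 1,
        false_alarm_pixel = if (pred_n > 0) pred_fp / pred_n else 0,
        iou_object = {
          den <- n_gt_comp + n_pred_comp - n_det_comp
          if (den > 0) n_det_comp / den else 1
        },
        detection_rate_object = if (n_gt_comp > 0) n_det_comp / n_gt_comp else 1,
        false_alarm_object = if (n_pred_comp > 0) n_fp_comp / n_pred_comp else 0
      )
      for (metric in c("iou", "detection_rate", "false_alarm")) {
        for (mode in c("pixel", "object")) {
          rows[[length(rows) + 1L]] <- data.frame(
            class = cl, metric = metric, mode = mode, threshold = t,
            value = unname(vals[paste(metric, mode, sep = "_")]),
            min_area = ma)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metric_curves", "data.frame")
  out
}

#' Write / read metric curves as CSV
#'
#' Columns (class, metric, mode, threshold, value, min_area); numeric values
#' are written at full precision so a round trip reproduces the curves
#' exactly.
#'
#' @param curves a `metric_curves` data.frame.
#' @param path CSV file path.
#' @export
export_curves <- function(curves, path) {
  df <- as.data.frame(curves)
  cols <- c("class", "metric", "mode", "threshold", "value", "min_area")
  df <- df[, cols, drop = FALSE]
  for (cc in c("threshold", "value", "min_area")) {
    df[[cc]] <- formatC(df[[cc]], digits = 17, format = "g")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_curves
#' @export
read_curves <- function(path) {
  df <- read.csv(path, colClasses = c(class = "character",
                                      metric = "character",
                                      mode = "character",
                                      threshold = "numeric",
                                      value = "numeric",
                                      min_area = "numeric"))
  class(df) <- c("metric_curves", "data.frame")
  df
}

#' Plot metric curves against the confidence threshold
#'
#' Three panels (IOU, detection rate, false alarm), one line per class, for
#' the selected mode.
#'
#' @param x a `metric_curves` data.frame.
#' @param mode `"pixel"` or `"object"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.metric_curves <- function(x, mode = "pixel", ...) {
  metrics <- c(iou = "IOU", detection_rate = "Detection rate",
               false_alarm = "False alarm rate")
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old), add = TRUE)
  for (m in names(metrics)) {
    sub <- x[x$metric == m & x$mode == mode, ]
    th <- sort(unique(sub$threshold))
    mat <- cbind(tumor = sub$value[sub$class == "tumor"][order(sub$threshold[sub$class == "tumor"])],
                 nerve = sub$value[sub$class == "nerve"][order(sub$threshold[sub$class == "nerve"])])
    graphics::matplot(th, mat, type = "l", lty = 1, lwd = 2,
                      col = c("firebrick", "steelblue"),
                      xlab = "confidence threshold", ylab = metrics[m],
                      ylim = c(0, 1), main = metrics[m], ...)
    graphics::legend("topright", legend = colnames(mat), lty = 1, lwd = 2,
                     col = c("firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}
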