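# Post-processing of per-class confidence maps: thresholding, connected
# components, and the small-focus filter.

#' Threshold one class of a probability map into a binary mask
#'
#' A pixel is included when its confidence is greater than *or equal to* the
#' threshold. The equality rule keeps `binarize(map, class, 0)` total (every
#' pixel included) and records a score of 1 for any pixel at the set
#' confidence level, 0 below it.
#'
#' @param map a [probability_map].
#' @param class_name `"tumor"` or `"nerve"`.
#' @param threshold confidence cutoff in \[0, 1\].
#' @return a `binary_mask`: list with `values` (logical matrix),
#'   `class_name`, and `threshold_used`.
#' @export
binarize <- function(map, class_name, threshold = 0.5) {
  stopifnot(inherits(map, "probability_map"))
  threshold <- check_fraction(threshold, "threshold")
  ch <- match(class_name, map$channels)
  if (is.na(ch)) {
    stop(sprintf("unknown class_name '%s' (have: %s)", class_name,
                 paste(map$channels, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(values = map$values[, , ch] >= threshold,
         class_name = class_name,
         threshold_used = threshold),
    class = "binary_mask"
  )
}

#' Construct a binary mask directly from a logical matrix
#'
#' Convenience constructor used when a mask comes from ground truth rather
#' than from thresholding a probability map.
#'
#' @param values logical matrix.
#' @param class_name class label of the mask.
#' @param threshold_used threshold to record (NA when not applicable).
#' @export
binary_mask <- function(values, class_name = "tumor", threshold_used = NA_real_) {
  stopifnot(is.logical(values), is.matrix(values))
  structure(list(values = values, class_name = class_name,
                 threshold_used = threshold_used),
            class = "binary_mask")
}

#' Label connected components of a binary mask
#'
#' Standard connected-component labeling. Labels are consecutive from 1 and
#' deterministic: components are numbered in the order of their first pixel
#' in a row-major raster scan.
#'
#' @param mask a `binary_mask` or a logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return a `labeled_regions`: list with `labels` (integer matrix, 0 =
#'   background), `areas` (named integer vector, pixel counts per component),
#'   and `connectivity`.
#' @export
label_components <- function(mask, connectivity = 8) {
  values <- if (inherits(mask, "binary_mask")) mask$values else mask
  stopifnot(is.logical(values), is.matrix(values))
  if (!connectivity %in% c(4, 8)) {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  labels <- .label_cc(values, as.integer(connectivity))
  k <- max(labels)
  areas <- if (k > 0L) tabulate(labels[labels > 0L], nbins = k) else integer(0)
  names(areas) <- if (k > 0L) as.character(seq_len(k)) else character(0)
  structure(list(labels = labels, areas = areas,
                 connectivity = as.integer(connectivity)),
            class = "labeled_regions")
}

#' Remove components below a minimum pixel area
#'
#' Implements the small-focus filter: components whose area is strictly less
#' than `min_area` pixels are discarded (the operational default of 10,000
#' pixels removes the spurious very small foci that dominate false alarms).
#' Survivors are relabeled consecutively, preserving their original order.
#'
#' @param regions a [labeled_regions] object.
#' @param min_area minimum pixel count a component must have to survive.
#' @return a `labeled_regions` with only the surviving components.
#' @export
filter_small <- function(regions, min_area = 10000) {
  stopifnot(inherits(regions, "labeled_regions"))
  if (!is.numeric(min_area) || length(min_area) != 1L || min_area < 0) {
    stop("min_area must be a single number >= 0", call. = FALSE)
  }
  keep <- which(regions$areas >= min_area)
  remap <- integer(length(regions$areas))
  remap[keep] <- seq_along(keep)
  labels <- regions$labels
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  areas <- regions$areas[keep]
  names(areas) <- if (length(keep)) as.character(seq_along(keep)) else character(0)
  structure(list(labels = labels, areas = as.integer(areas) |>
                   stats::setNames(names(areas)),
                 connectivity = regions$connectivity),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("labeled_regions: %d component(s), connectivity %d, %d x %d\n",
              length(x$areas), x$connectivity, nrow(x$labels), ncol(x$labels)))
  if (length(x$areas)) {
    cat("areas:", paste(utils::head(x$areas, 10), collapse = ", "),
        if (length(x$areas) > 10) "..." else "", "\n")
  }
  invisible(x)
}

# Logical foreground of labeled regions.
regions_mask <- function(regions) regions$labels > 0L

# Pixel indices (linear) per component, as a list.
region_pixels <- function(regions) {
  k <- length(regions$areas)
  if (k == 0L) return(list())
  split(which(regions$labels > 0L), regions$labels[regions$labels > 0L])
}
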