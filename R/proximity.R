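# The proximity core: exact nerve-tumor component distances, encirclement,
# candidate construction, overlap suppression, top-k ranking, field crops.
# Detecting the two entities separately and then reasoning about their
# spatial relationship is what mimics the pathologist's workflow.

#' Ranking configuration for candidate presentation
#'
#' @param k fields presented per case (40 by default; clinical practice used
#'   20 for the tumor-only cases, see `k_tumor_only`).
#' @param k_tumor_only fields presented for tumor-only cases.
#' @param max_distance candidate pairs farther apart than this many pixels
#'   are dropped ("close proximity" cutoff).
#' @param field_size side (pixels) of the square presentation field.
#' @param overlap_iou window intersection-over-union above which a
#'   lower-ranked candidate is suppressed as a near-duplicate.
#' @param contact_distance distances at or below this count as contact (2 px
#'   absorbs rasterization: abutting pixel centers are 1 or sqrt(2) apart),
#'   triggering encirclement measurement.
#' @param encirclement_epsilon boundary-to-tumor distance (px) within which a
#'   nerve boundary pixel counts as abutted.
#' @return a `ranking_config` object.
#' @export
ranking_config <- function(k = 40, k_tumor_only = 20, max_distance = 100,
                           field_size = 512, overlap_iou = 0.5,
                           contact_distance = 2, encirclement_epsilon = 3) {
  structure(list(k = check_count(k, "k", 1L),
                 k_tumor_only = check_count(k_tumor_only, "k_tumor_only", 1L),
                 max_distance = as.numeric(max_distance),
                 field_size = check_count(field_size, "field_size", 1L),
                 overlap_iou = check_fraction(overlap_iou, "overlap_iou"),
                 contact_distance = as.numeric(contact_distance),
                 encirclement_epsilon = as.numeric(encirclement_epsilon)),
            class = "ranking_config")
}

#' Minimum distances between all nerve and tumor components
#'
#' For every (nerve component, tumor component) pair within `max_distance`,
#' the exact minimum Euclidean distance between pixel centers, found via a
#' per-nerve-component exact distance transform sampled at tumor pixels
#' (equal to the brute-force pairwise minimum). Overlapping components have
#' distance 0.
#'
#' @param nerve,tumor [labeled_regions] on the same raster.
#' @param max_distance drop pairs farther than this (default Inf: keep all).
#' @return data.frame with columns nerve_id, tumor_id, min_distance, and the
#'   closest pixel pair (nerve_row, nerve_col, tumor_row, tumor_col; 1-based).
#' @export
component_min_distances <- function(nerve, tumor, max_distance = Inf) {
  stopifnot(inherits(nerve, "labeled_regions"), inherits(tumor, "labeled_regions"))
  if (!all(dim(nerve$labels) == dim(tumor$labels))) {
    stop("nerve and tumor rasters differ in shape", call. = FALSE)
  }
  empty <- data.frame(nerve_id = integer(0), tumor_id = integer(0),
                      min_distance = numeric(0),
                      nerve_row = integer(0), nerve_col = integer(0),
                      tumor_row = integer(0), tumor_col = integer(0))
  if (length(nerve$areas) == 0L || length(tumor$areas) == 0L) return(empty)
  H <- nrow(nerve$labels)
  tpx <- region_pixels(tumor)
  rows <- list()
  for (nk in seq_along(nerve$areas)) {
    comp <- nerve$labels == nk
    d2 <- edt_squared(comp)
    npix <- which(comp)
    nr <- (npix - 1L) %% H + 1L
    nc <- (npix - 1L) %/% H + 1L
    for (tk in seq_along(tpx)) {
      idx <- tpx[[tk]]
      at <- which.min(d2[idx])
      dmin <- sqrt(d2[idx[at]])
      if (dmin > max_distance) next
      ti <- idx[at]
      tr <- (ti - 1L) %% H + 1L
      tc <- (ti - 1L) %/% H + 1L
      if (dmin == 0) {
        # shared pixel: the closest pair is the pixel itself
        nb <- ti
      } else {
        nb <- npix[which.min((nr - tr)^2 + (nc - tc)^2)]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        nerve_id = nk, tumor_id = tk, min_distance = dmin,
        nerve_row = (nb - 1L) %% H + 1L, nerve_col = (nb - 1L) %/% H + 1L,
        tumor_row = tr, tumor_col = tc)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Fraction of a nerve's circumference abutted by tumor
#'
#' Boundary pixels of the nerve component (pixels 8-adjacent to any
#' non-component pixel or to the image edge) whose distance to the nearest
#' tumor pixel is at most `epsilon`, as a fraction of all boundary pixels.
#' The clinically proposed criterion calls a nerve inside the tumor body
#' invaded when this fraction reaches 1/3.
#'
#' @param nerve_id component label in `nerve`.
#' @param nerve a [labeled_regions] of nerve components.
#' @param tumor_mask a `binary_mask` or logical matrix of tumor pixels.
#' @param epsilon abutment distance in pixels (> 0).
#' @return fraction in \[0, 1\].
#' @export
measure_encirclement <- function(nerve_id, nerve, tumor_mask, epsilon = 3) {
  stopifnot(inherits(nerve, "labeled_regions"))
  tm <- if (inherits(tumor_mask, "binary_mask")) tumor_mask$values else tumor_mask
  stopifnot(is.logical(tm), all(dim(tm) == dim(nerve$labels)))
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (!nerve_id %in% seq_along(nerve$areas)) {
    stop(sprintf("no nerve component with label %s", nerve_id), call. = FALSE)
  }
  comp <- nerve$labels == nerve_id
  bnd <- which(.boundary_px(comp))
  if (!length(bnd)) return(0)
  if (!any(tm)) return(0)
  d2t <- edt_squared(tm)
  mean(sqrt(d2t[bnd]) <= epsilon)
}

#' Build presentation candidates from component pairs
#'
#' One candidate per pair within `max_distance`. Encirclement is measured for
#' contact pairs (distance at most `config$contact_distance`) and is 0
#' otherwise. The presentation field window is centered on the midpoint of
#' the closest pixel pair and clamped to the slide.
#'
#' @param pairs output of [component_min_distances()].
#' @param nerve,tumor the [labeled_regions] the pairs refer to.
#' @param tumor_mask logical matrix (or `binary_mask`) of all predicted tumor.
#' @param config a [ranking_config].
#' @param slide_id identifier recorded on each candidate.
#' @return a `pni_candidates` data.frame: slide_id, nerve_id, tumor_id,
#'   min_distance, closest pair coordinates, encirclement, field window
#'   (row0, col0, height, width; 1-based origin), nerve_area, tumor_area.
#' @export
build_candidates <- function(pairs, nerve, tumor, tumor_mask,
                             config = ranking_config(), slide_id = "slide") {
  tm <- if (inherits(tumor_mask, "binary_mask")) tumor_mask$values else tumor_mask
  H <- nrow(nerve$labels); W <- ncol(nerve$labels)
  pairs <- pairs[pairs$min_distance <= config$max_distance, , drop = FALSE]
  n <- nrow(pairs)
  enc <- numeric(n)
  row0 <- integer(n); col0 <- integer(n)
  fh <- min(config$field_size, H); fw <- min(config$field_size, W)
  for (i in seq_len(n)) {
    if (pairs$min_distance[i] <= config$contact_distance) {
      enc[i] <- measure_encirclement(pairs$nerve_id[i], nerve, tm,
                                     config$encirclement_epsilon)
    }
    mr <- (pairs$nerve_row[i] + pairs$tumor_row[i]) / 2
    mc <- (pairs$nerve_col[i] + pairs$tumor_col[i]) / 2
    row0[i] <- min(max(1L, as.integer(round(mr - fh / 2))), H - fh + 1L)
    col0[i] <- min(max(1L, as.integer(round(mc - fw / 2))), W - fw + 1L)
  }
  out <- data.frame(
    slide_id = rep(as.character(slide_id), n),
    nerve_id = pairs$nerve_id, tumor_id = pairs$tumor_id,
    min_distance = pairs$min_distance,
    nerve_row = pairs$nerve_row, nerve_col = pairs$nerve_col,
    tumor_row = pairs$tumor_row, tumor_col = pairs$tumor_col,
    encirclement = enc,
    row0 = if (n) row0 else integer(0), col0 = if (n) col0 else integer(0),
    height = rep(fh, n), width = rep(fw, n),
    nerve_area = if (n) as.integer(nerve$areas[pairs$nerve_id]) else integer(0),
    tumor_area = if (n) as.integer(tumor$areas[pairs$tumor_id]) else integer(0)
  )
  class(out) <- c("pni_candidates", "data.frame")
  out
}

window_iou <- function(a, b) {
  r0 <- max(a["row0"], b["row0"]); c0 <- max(a["col0"], b["col0"])
  r1 <- min(a["row0"] + a["height"], b["row0"] + b["height"])
  c1 <- min(a["col0"] + a["width"], b["col0"] + b["width"])
  inter <- max(0, r1 - r0) * max(0, c1 - c0)
  uni <- a["height"] * a["width"] + b["height"] * b["width"] - inter
  unname(inter / uni)
}

candidate_order <- function(cands) {
  order(cands$min_distance, -(cands$nerve_area + cands$tumor_area),
        cands$slide_id, cands$row0, cands$col0)
}

#' Suppress near-duplicate candidate fields
#'
#' Greedy keep-best by ascending distance: a candidate is dropped when its
#' field window overlaps an already-kept window of the same slide with
#' intersection-over-union above `iou_threshold`.
#'
#' @param candidates a `pni_candidates` data.frame.
#' @param iou_threshold window IoU above which the later candidate is dropped.
#' @return the surviving candidates, in the greedy (ranked) order.
#' @export
suppress_overlaps <- function(candidates, iou_threshold = 0.5) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- candidate_order(candidates)
  cands <- candidates[ord, , drop = FALSE]
  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (cands$slide_id[j] != cands$slide_id[i]) next
      a <- c(row0 = cands$row0[i], col0 = cands$col0[i],
             height = cands$height[i], width = cands$width[i])
      b <- c(row0 = cands$row0[j], col0 = cands$col0[j],
             height = cands$height[j], width = cands$width[j])
      if (window_iou(a, b) > iou_threshold) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidates and keep the top k
#'
#' Ascending by minimum distance (the most suspicious fields first); ties are
#' broken by descending combined component area, then by (slide_id, row0,
#' col0), so the ranking is deterministic under any permutation of the input.
#'
#' @param candidates a `pni_candidates` data.frame, pooled over all slides of
#'   a case.
#' @param k number of fields to present.
#' @return the top `min(k, n)` candidates in rank order.
#' @export
rank_top_k <- function(candidates, k = 40) {
  k <- check_count(k, "k", 1L)
  ord <- candidate_order(candidates)
  out <- candidates[ord[seq_len(min(k, length(ord)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pni_candidates <- function(x, ...) {
  cat(sprintf("pni_candidates: %d field(s)\n", nrow(x)))
  if (nrow(x)) {
    print.data.frame(utils::head(
      x[, c("slide_id", "nerve_id", "tumor_id", "min_distance",
            "encirclement", "row0", "col0")], 10))
    if (nrow(x) > 10) cat("...\n")
  }
  invisible(x)
}

#' Crop a candidate's presentation field from its slide
#'
#' @param tile H x W x 3 RGB array (or H x W matrix).
#' @param candidate one-row `pni_candidates` data.frame.
#' @return list with `image` (the pixel-exact crop) and `window` (row0, col0,
#'   height, width; 1-based) for traceability back to slide coordinates.
#' @export
crop_field <- function(tile, candidate) {
  stopifnot(nrow(candidate) == 1L)
  w <- c(row0 = candidate$row0, col0 = candidate$col0,
         height = candidate$height, width = candidate$width)
  dims <- dim(tile)
  if (w["height"] < 1 || w["width"] < 1) {
    stop("degenerate field window", call. = FALSE)
  }
  if (w["row0"] < 1 || w["col0"] < 1 ||
      w["row0"] + w["height"] - 1 > dims[1] ||
      w["col0"] + w["width"] - 1 > dims[2]) {
    stop("field window exceeds slide bounds", call. = FALSE)
  }
  rows <- w["row0"]:(w["row0"] + w["height"] - 1)
  cols <- w["col0"]:(w["col0"] + w["width"] - 1)
  img <- if (length(dims) == 3L) tile[rows, cols, , drop = FALSE]
         else tile[rows, cols, drop = FALSE]
  list(image = img, window = w)
}
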