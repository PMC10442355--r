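# Segmentation: per-class {tumor, nerve} confidence maps from RGB tiles.
# Three routes share one output contract: a trainable pixel classifier, and a
# ground-truth-corrupting oracle-noise segmenter used to exercise the
# downstream pipeline under controlled error modes.

CLASS_CODES <- c(background = 0L, tumor = 1L, nerve = 2L, benign_gland = 3L)

#' Construct a per-class probability map
#'
#' @param values numeric H x W x 2 array of confidences in \[0, 1\]; channel
#'   order is fixed as (tumor, nerve).
#' @param provenance free-form identifier of the segmenter and seed that
#'   produced the map.
#' @return a `probability_map` object.
#' @export
probability_map <- function(values, provenance = "unknown") {
  stopifnot(is.array(values), length(dim(values)) == 3L, dim(values)[3] == 2L)
  if (any(values < 0 | values > 1, na.rm = TRUE) || anyNA(values)) {
    stop("probability map values must all lie in [0, 1]", call. = FALSE)
  }
  structure(list(values = values, channels = c("tumor", "nerve"),
                 provenance = provenance),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("probability_map %d x %d (tumor, nerve), provenance: %s\n",
              d[1], d[2], x$provenance))
  invisible(x)
}

#' Randomly augment a tile/mask pair
#'
#' Draws one transform uniformly from {identity, horizontal flip, vertical
#' flip, 90/180/270 degree rotation, brightness jitter, hue jitter}. A
#' geometric transform is applied identically to tile and mask; photometric
#' jitter touches the tile only. Class codes are never altered.
#'
#' @param tile numeric H x W x 3 RGB array in \[0, 1\].
#' @param mask integer H x W class mask (codes 0-3).
#' @param seed integer seed.
#' @return list with elements `tile`, `mask`, and `op` (name of the draw).
#' @export
augment_tile <- function(tile, mask, seed) {
  stopifnot(is.array(tile), length(dim(tile)) == 3L, is.matrix(mask))
  if (!all(dim(tile)[1:2] == dim(mask))) {
    stop("tile and mask shapes differ", call. = FALSE)
  }
  ops <- c("identity", "flip_h", "flip_v", "rot90", "rot180", "rot270",
           "brightness", "hue")
  with_seed(seed, {
    op <- sample(ops, 1L)
    g <- function(m) switch(op,
      identity   = m,
      flip_h     = m[, rev(seq_len(ncol(m))), drop = FALSE],
      flip_v     = m[rev(seq_len(nrow(m))), , drop = FALSE],
      rot90      = t(m)[, rev(seq_len(nrow(m))), drop = FALSE],
      rot180     = m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE],
      rot270     = t(m)[rev(seq_len(ncol(m))), , drop = FALSE],
      m)
    if (op %in% c("brightness", "hue")) {
      t2 <- tile
      if (op == "brightness") {
        t2 <- clamp01(tile * runif(1, 0.8, 1.2))
      } else {
        gains <- runif(3, 0.92, 1.08)
        for (ch in 1:3) t2[, , ch] <- clamp01(tile[, , ch] * gains[ch])
      }
      list(tile = t2, mask = mask, op = op)
    } else {
      t2 <- array(0, c(dim(g(mask)), 3L))
      for (ch in 1:3) t2[, , ch] <- g(tile[, , ch])
      list(tile = t2, mask = g(mask), op = op)
    }
  })
}

#' Noise model for the oracle-noise segmenter
#'
#' Describes how a ground-truth mask is corrupted into a realistic prediction:
#' whole true components dropped at `miss_rate`, spurious components added at
#' a Poisson `spurious_rate` per tile per class (disk-shaped, areas drawn
#' from `spurious_area_range`, placed disjoint from all true structures),
#' component boundaries inflated/deflated by up to `boundary_jitter` pixels,
#' and per-pixel confidences drawn uniformly from `confidence_in` on
#' predicted-positive pixels and `confidence_out` elsewhere. All rates zero
#' (the default) reproduces ground truth exactly.
#'
#' @param miss_rate probability that a true component is dropped.
#' @param spurious_rate expected number of false components per tile per class.
#' @param spurious_area_range (lo, hi) pixel areas for spurious components.
#' @param boundary_jitter maximum boundary shift in pixels.
#' @param confidence_in (lo, hi) confidence range on predicted pixels.
#' @param confidence_out (lo, hi) confidence range off predicted pixels.
#' @param rng_seed integer seed.
#' @return a `noise_model` object.
#' @export
noise_model <- function(miss_rate = 0, spurious_rate = 0,
                        spurious_area_range = c(200, 5000),
                        boundary_jitter = 0,
                        confidence_in = c(1, 1), confidence_out = c(0, 0),
                        rng_seed = 1L) {
  miss_rate <- check_fraction(miss_rate, "miss_rate")
  if (!is.numeric(spurious_rate) || spurious_rate < 0) {
    stop("spurious_rate must be >= 0", call. = FALSE)
  }
  structure(list(
    miss_rate = miss_rate,
    spurious_rate = as.numeric(spurious_rate),
    spurious_area_range = check_range(spurious_area_range, "spurious_area_range"),
    boundary_jitter = as.numeric(boundary_jitter),
    confidence_in = check_range(confidence_in, "confidence_in"),
    confidence_out = check_range(confidence_out, "confidence_out"),
    rng_seed = as.integer(rng_seed)
  ), class = "noise_model")
}

#' Segment by corrupting ground truth with a controlled noise model
#'
#' The pipeline-testing segmenter: it knows the true classes and produces a
#' probability map whose error modes (missed components, small spurious foci,
#' jittered boundaries, graded confidences) are fully parameterized. With the
#' zero-noise default, confidence is exactly 1.0 on each class's pixels and
#' 0.0 elsewhere, so thresholding at 0.5 reproduces the truth bit for bit.
#' Benign glands (code 3) are background to the segmenter, mirroring
#' negative-labeled training.
#'
#' @param gt a [ground_truth] object.
#' @param noise a [noise_model].
#' @return a [probability_map].
#' @export
oracle_noise_segment <- function(gt, noise = noise_model()) {
  stopifnot(inherits(gt, "ground_truth"), inherits(noise, "noise_model"))
  mask <- gt$class_mask
  H <- nrow(mask); W <- ncol(mask)
  vals <- array(0, c(H, W, 2L))
  true_any <- mask == CLASS_CODES[["tumor"]] | mask == CLASS_CODES[["nerve"]]
  with_seed(noise$rng_seed, {
    for (ci in 1:2) {
      code <- if (ci == 1L) CLASS_CODES[["tumor"]] else CLASS_CODES[["nerve"]]
      cls <- mask == code
      regs <- label_components(cls, 8)
      pred <- matrix(FALSE, H, W)
      px <- region_pixels(regs)
      for (k in seq_along(px)) {
        if (runif(1) < noise$miss_rate) next
        kept <- px[[k]]
        if (noise$boundary_jitter > 0) {
          comp <- matrix(FALSE, H, W); comp[kept] <- TRUE
          delta <- runif(1, -noise$boundary_jitter, noise$boundary_jitter)
          if (delta > 0) {
            comp <- edt_squared(comp) <= delta^2
          } else if (delta < 0) {
            comp <- comp & !(edt_squared(!comp) <= delta^2)
          }
          pred <- pred | comp
        } else {
          pred[kept] <- TRUE
        }
      }
      n_sp <- rpois(1, noise$spurious_rate)
      for (s in seq_len(n_sp)) {
        a <- runif(1, noise$spurious_area_range[1], noise$spurious_area_range[2])
        rad <- sqrt(a / pi)
        placed <- FALSE
        for (try in 1:100) {
          r0 <- runif(1, 1 + rad, H - rad); c0 <- runif(1, 1 + rad, W - rad)
          cand <- matrix(FALSE, H, W)
          cand <- fill_disks(cand, cbind(r0, c0), rad)
          if (!any(cand & true_any) && !any(cand & pred)) {
            pred <- pred | cand
            placed <- TRUE
            break
          }
        }
      }
      conf <- if (diff(noise$confidence_out) == 0) {
        matrix(noise$confidence_out[1], H, W)
      } else {
        matrix(runif(H * W, noise$confidence_out[1], noise$confidence_out[2]),
               H, W)
      }
      n_in <- sum(pred)
      if (n_in > 0) {
        conf[pred] <- if (diff(noise$confidence_in) == 0) noise$confidence_in[1]
                      else runif(n_in, noise$confidence_in[1],
                                 noise$confidence_in[2])
      }
      vals[, , ci] <- conf
    }
  })
  probability_map(vals, provenance = sprintf("oracle_noise(seed=%d)",
                                             noise$rng_seed))
}

# ---- trainable feature-based pixel classifier ------------------------------

#' Configuration for the trainable segmenter
#'
#' @param scales radii (pixels) of the local box-mean features.
#' @param sd_scale radius of the local-texture (standard deviation) feature.
#' @param samples_per_tile pixels sampled per training tile (stratified over
#'   classes).
#' @param augment also train on one augmented copy of each tile.
#' @param rng_seed integer seed controlling pixel sampling and augmentation.
#' @return a `segmenter_config` object.
#' @export
segmenter_config <- function(scales = c(2, 6), sd_scale = 4,
                             samples_per_tile = 1500, augment = FALSE,
                             rng_seed = 1L) {
  structure(list(scales = as.numeric(scales), sd_scale = as.numeric(sd_scale),
                 samples_per_tile = check_count(samples_per_tile,
                                                "samples_per_tile", min = 10L),
                 augment = isTRUE(augment), rng_seed = as.integer(rng_seed)),
            class = "segmenter_config")
}

# Per-pixel feature matrix: raw RGB, box means at each scale, and a local
# luminance standard deviation. Returns (H*W) x p.
tile_features <- function(tile, config) {
  H <- dim(tile)[1]; W <- dim(tile)[2]
  feats <- list()
  for (ch in 1:3) feats[[length(feats) + 1L]] <- as.vector(tile[, , ch])
  for (r in config$scales) {
    for (ch in 1:3) {
      feats[[length(feats) + 1L]] <- as.vector(box_mean(tile[, , ch], r))
    }
  }
  lum <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  m1 <- box_mean(lum, config$sd_scale)
  m2 <- box_mean(lum^2, config$sd_scale)
  feats[[length(feats) + 1L]] <- as.vector(sqrt(pmax(m2 - m1^2, 0)))
  do.call(cbind, feats)
}

#' Train the pixel-level nerve/tumor segmenter
#'
#' Fits two independent per-class detectors (tumor-vs-rest and
#' nerve-vs-rest binomial regressions on local colour and texture features),
#' matching the downstream design in which nerve and tumor are separately
#' thresholded detectors with separate metric curves. Benign glands (code 3)
#' are trained as background: unmarked tissue is negative for both classes.
#'
#' @param tiles list of H x W x 3 RGB arrays in \[0, 1\].
#' @param masks list of integer class masks (codes 0-3) matching `tiles`.
#' @param config a [segmenter_config].
#' @return a `pni_segmenter` model object; see [predict.pni_segmenter()].
#' @export
train_segmenter <- function(tiles, masks, config = segmenter_config()) {
  if (length(tiles) == 0L) stop("empty training set", call. = FALSE)
  if (length(tiles) < 8L) {
    stop("at least 8 training tiles are required", call. = FALSE)
  }
  if (length(tiles) != length(masks)) {
    stop("tiles and masks differ in length", call. = FALSE)
  }
  X <- list(); yt <- list(); yn <- list()
  with_seed(config$rng_seed, {
    idx_out <- 0L
    for (i in seq_along(tiles)) {
      pairs <- list(list(tile = tiles[[i]], mask = masks[[i]]))
      if (config$augment) {
        pairs[[2]] <- augment_tile(tiles[[i]], masks[[i]],
                                   seed = sample.int(2^30, 1))[c("tile", "mask")]
      }
      for (p in pairs) {
        f <- tile_features(p$tile, config)
        cls <- as.vector(p$mask)
        # benign glands count as background
        cls[cls == CLASS_CODES[["benign_gland"]]] <- 0L
        take <- integer(0)
        for (code in unique(cls)) {
          at <- which(cls == code)
          n <- min(length(at), ceiling(config$samples_per_tile / 3))
          take <- c(take, sample(at, n))
        }
        idx_out <- idx_out + 1L
        X[[idx_out]] <- f[take, , drop = FALSE]
        yt[[idx_out]] <- as.integer(cls[take] == CLASS_CODES[["tumor"]])
        yn[[idx_out]] <- as.integer(cls[take] == CLASS_CODES[["nerve"]])
      }
    }
  })
  X <- do.call(rbind, X)
  yt <- unlist(yt); yn <- unlist(yn)
  Xi <- cbind(1, X)
  fit_one <- function(y) {
    fit <- suppressWarnings(glm.fit(Xi, y, family = binomial()))
    if (!all(is.finite(fit$coefficients))) {
      stop("segmenter training produced non-finite coefficients; ",
           "deviance = ", format(fit$deviance), call. = FALSE)
    }
    fit
  }
  ft <- fit_one(yt); fn <- fit_one(yn)
  null_dev <- function(y) {
    p0 <- mean(y)
    if (p0 %in% c(0, 1)) return(0)
    -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
  }
  structure(list(
    coef_tumor = ft$coefficients,
    coef_nerve = fn$coefficients,
    deviance = c(tumor = ft$deviance, nerve = fn$deviance),
    null_deviance = c(tumor = null_dev(yt), nerve = null_dev(yn)),
    n_train = nrow(X),
    config = config
  ), class = "pni_segmenter")
}

#' @export
print.pni_segmenter <- function(x, ...) {
  cat(sprintf(paste0("pni_segmenter: %d training pixels; residual/null ",
                     "deviance tumor %.0f/%.0f, nerve %.0f/%.0f\n"),
              x$n_train, x$deviance["tumor"], x$null_deviance["tumor"],
              x$deviance["nerve"], x$null_deviance["nerve"]))
  invisible(x)
}

#' Predict per-class confidence maps for a tile
#'
#' @param object a `pni_segmenter` from [train_segmenter()].
#' @param tile H x W x 3 RGB array in \[0, 1\].
#' @param ... unused.
#' @return a [probability_map] with channels (tumor, nerve).
#' @export
predict.pni_segmenter <- function(object, tile, ...) {
  stopifnot(is.array(tile), length(dim(tile)) == 3L)
  if (dim(tile)[3] != 3L) {
    stop("tile must have 3 channels to match the trained model", call. = FALSE)
  }
  f <- cbind(1, tile_features(tile, object$config))
  H <- dim(tile)[1]; W <- dim(tile)[2]
  vals <- array(0, c(H, W, 2L))
  vals[, , 1] <- matrix(plogis(drop(f %*% object$coef_tumor)), H, W)
  vals[, , 2] <- matrix(plogis(drop(f %*% object$coef_nerve)), H, W)
  probability_map(vals, provenance = "pni_segmenter")
}

#' Save / load a trained segmenter
#'
#' The model artifact is a single file holding the configuration and fitted
#' weights.
#'
#' @param model a `pni_segmenter`.
#' @param path file path.
#' @return `load_segmenter` returns the restored `pni_segmenter`.
#' @export
save_segmenter <- function(model, path) {
  stopifnot(inherits(model, "pni_segmenter"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pni_segmenter")) stop("not a pni_segmenter artifact",
                                          call. = FALSE)
  m
}
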