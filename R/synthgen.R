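# Synthetic H&E-like tiles with planted perineural-invasion events, and
# multi-slide synthetic cases/studies mirroring the clinical workload
# (27 +/- 9.4 slides per full case, 6.1 +/- 1.8 for tumor-only cases, PNI a
# rare event on a minority of slides).

#' Specification of one synthetic tile
#'
#' Geometry is procedural: nerves are wavy ribbons (or round bundles for
#' encircled events), malignant glands form one connected irregular cluster,
#' and benign glands are regular rings kept at least 50 px away from any
#' nerve (benign glands do not occur hard against nerves, which is what makes
#' them a harmless confounder for proximity screening). Structure sizes
#' default to the scale at which the operational small-focus filter (10,000
#' px) keeps true nerves and tumor clusters.
#'
#' @param height,width tile size in pixels (>= 64).
#' @param n_nerves number of nerves.
#' @param n_malignant_glands glands in the malignant cluster (0 = no tumor).
#' @param n_benign_glands number of benign gland rings.
#' @param nerve_thickness_range (lo, hi) ribbon thickness in px.
#' @param gland_radius_range (lo, hi) malignant gland radii in px.
#' @param background_noise_sd stain-noise amplitude (intensity units, 0-1
#'   scale).
#' @param min_component_area minimum pixel area enforced for each nerve and
#'   for the tumor cluster (default 10,500, just above the screening filter;
#'   set low for small tiles).
#' @param rng_seed integer seed; identical seed gives a bit-identical tile.
#' @return a `tile_spec` object.
#' @export
tile_spec <- function(height = 512, width = 512, n_nerves = 2,
                      n_malignant_glands = 10, n_benign_glands = 2,
                      nerve_thickness_range = c(22, 34),
                      gland_radius_range = c(22, 36),
                      background_noise_sd = 0.035,
                      min_component_area = 10500,
                      rng_seed = 1L) {
  height <- check_count(height, "height", 64L)
  width <- check_count(width, "width", 64L)
  spec <- structure(list(
    height = height, width = width,
    n_nerves = check_count(n_nerves, "n_nerves"),
    n_malignant_glands = check_count(n_malignant_glands, "n_malignant_glands"),
    n_benign_glands = check_count(n_benign_glands, "n_benign_glands"),
    nerve_thickness_range = check_range(nerve_thickness_range,
                                        "nerve_thickness_range"),
    gland_radius_range = check_range(gland_radius_range, "gland_radius_range"),
    background_noise_sd = as.numeric(background_noise_sd),
    min_component_area = as.numeric(min_component_area),
    rng_seed = as.integer(rng_seed)
  ), class = "tile_spec")
  spec
}

#' A planted perineural-invasion event
#'
#' `target_distance` is the nerve-tumor minimum distance to realize (0 means
#' contact; rasterized contact measures ~1 px between pixel centers).
#' `target_encirclement > 0` plants a nerve inside the main tumor body with
#' that fraction of its circumference abutted by tumor (the 33% criterion's
#' geometry); such events must have `target_distance = 0`.
#'
#' @param target_distance pixels, >= 0.
#' @param target_encirclement fraction in \[0, 1\].
#' @param inside_tumor_body logical; defaults to TRUE exactly when
#'   `target_encirclement > 0`.
#' @return a `pni_event` object. After [generate_tile()] the realized event
#'   additionally carries `nerve_id`, `tumor_id`, `measured_distance`, and
#'   `measured_encirclement`.
#' @export
pni_event <- function(target_distance = 0, target_encirclement = 0,
                      inside_tumor_body = target_encirclement > 0) {
  if (!is.numeric(target_distance) || target_distance < 0) {
    stop("target_distance must be >= 0", call. = FALSE)
  }
  target_encirclement <- check_fraction(target_encirclement,
                                        "target_encirclement")
  if (target_encirclement > 0 && target_distance != 0) {
    stop("target_distance must be 0 whenever target_encirclement > 0",
         call. = FALSE)
  }
  structure(list(target_distance = as.numeric(target_distance),
                 target_encirclement = target_encirclement,
                 inside_tumor_body = isTRUE(inside_tumor_body),
                 nerve_id = NA_integer_, tumor_id = NA_integer_,
                 measured_distance = NA_real_,
                 measured_encirclement = NA_real_),
            class = "pni_event")
}

#' Ground truth for a tile
#'
#' @param class_mask integer matrix with codes 0 background, 1 tumor,
#'   2 nerve, 3 benign gland.
#' @param events list of realized [pni_event] objects.
#' @export
ground_truth <- function(class_mask, events = list()) {
  stopifnot(is.matrix(class_mask))
  if (!all(class_mask %in% 0:3)) {
    stop("class_mask codes must be in 0..3", call. = FALSE)
  }
  structure(list(class_mask = class_mask, events = events),
            class = "ground_truth")
}

# ---- internal geometry ------------------------------------------------------

# Stamp disks of one radius at a set of (row, col) centers; index arithmetic
# only, no distance transform.
stamp_disks <- function(H, W, rows, cols, radius) {
  rad <- ceiling(radius)
  span <- -rad:rad
  off <- expand.grid(dr = span, dc = span)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  K <- nrow(off)
  rr <- rep(rows, each = K) + off$dr
  cc <- rep(cols, each = K) + off$dc
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  mask <- matrix(FALSE, H, W)
  mask[cbind(rr[ok], cc[ok])] <- TRUE
  mask
}

# Wavy ribbon crossing the tile; returns NULL when no draw reaches min_area.
make_ribbon <- function(H, W, thickness, min_area, avoid = NULL,
                        avoid_dist = 12, max_tries = 25) {
  d2avoid <- if (!is.null(avoid) && any(avoid)) edt_squared(avoid) else NULL
  for (t in seq_len(max_tries)) {
    side <- sample(4L, 1L)
    if (side == 1L) { pos <- c(runif(1, 0.15 * H, 0.85 * H), 1); ang0 <- runif(1, -0.5, 0.5) }
    if (side == 2L) { pos <- c(runif(1, 0.15 * H, 0.85 * H), W); ang0 <- pi + runif(1, -0.5, 0.5) }
    if (side == 3L) { pos <- c(1, runif(1, 0.15 * W, 0.85 * W)); ang0 <- pi / 2 + runif(1, -0.5, 0.5) }
    if (side == 4L) { pos <- c(H, runif(1, 0.15 * W, 0.85 * W)); ang0 <- -pi / 2 + runif(1, -0.5, 0.5) }
    step <- 2.5
    wig <- 0
    pts <- matrix(NA_real_, 600L, 2L)
    n <- 0L
    p <- pos
    repeat {
      n <- n + 1L
      pts[n, ] <- p
      wig <- 0.93 * wig + rnorm(1, 0, 0.09)
      a <- ang0 + wig
      p <- p + step * c(sin(a), cos(a))
      if (n >= 600L || p[1] < 1 || p[1] > H || p[2] < 1 || p[2] > W) break
    }
    pts <- pts[seq_len(n), , drop = FALSE]
    pr <- pmin(pmax(round(pts[, 1]), 1), H)
    pc <- pmin(pmax(round(pts[, 2]), 1), W)
    cl <- matrix(FALSE, H, W)
    cl[cbind(pr, pc)] <- TRUE
    mask <- stamp_disks(H, W, pr, pc, thickness / 2)
    if (sum(mask) < min_area) next
    if (!is.null(d2avoid) && min(d2avoid[mask]) < avoid_dist^2) next
    return(list(mask = mask, centerline = cl))
  }
  NULL
}

# Slightly irregular disk.
make_blob <- function(H, W, center, radius, irregularity = 0.06) {
  rr <- max(1L, floor(center[1] - radius * 1.3)):min(H, ceiling(center[1] + radius * 1.3))
  cc <- max(1L, floor(center[2] - radius * 1.3)):min(W, ceiling(center[2] + radius * 1.3))
  dr <- outer(rr - center[1], rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - center[2])
  theta <- atan2(dr, dc)
  phase <- runif(1, 0, 2 * pi)
  lim <- radius * (1 + irregularity * sin(3 * theta + phase))
  mask <- matrix(FALSE, H, W)
  mask[rr, cc] <- sqrt(dr^2 + dc^2) <= lim
  mask
}

# Gland-cluster footprint: offsets/radii template rasterized at a center.
rasterize_cluster <- function(H, W, center, offsets, radii) {
  fill_disks(matrix(FALSE, H, W),
             cbind(center[1] + offsets[, 1], center[2] + offsets[, 2]),
             radii)
}

# Tumor cluster abutting (or at distance target_d from) one nerve. `occupied`
# holds every pixel that will overwrite tumor in the final mask (all nerves),
# so the surviving cluster area can be guaranteed.
place_contact_cluster <- function(nerve_mask, centerline, H, W, offsets,
                                  radii, target_d, min_area,
                                  occupied = nerve_mask) {
  d2n <- edt_squared(nerve_mask)
  spread <- max(sqrt(offsets[, 1]^2 + offsets[, 2]^2) + radii)
  margin <- ceiling(spread + target_d + 10)
  b_all <- which(.boundary_px(nerve_mask))
  br <- (b_all - 1L) %% H + 1L
  bc <- (b_all - 1L) %/% H + 1L
  ok <- br > margin & br < H - margin & bc > margin & bc < W - margin
  if (!any(ok)) return(NULL)
  b_all <- b_all[ok]; br <- br[ok]; bc <- bc[ok]
  cl_idx <- which(centerline)
  cr <- (cl_idx - 1L) %% H + 1L
  cc <- (cl_idx - 1L) %/% H + 1L
  for (anchor_try in 1:6) {
    j <- sample(length(b_all), 1L)
    b <- c(br[j], bc[j])
    nearest <- which.min((cr - b[1])^2 + (cc - b[2])^2)
    u <- b - c(cr[nearest], cc[nearest])
    nu <- sqrt(sum(u^2))
    if (nu < 1e-9) next
    u <- u / nu
    ctr <- b + u * (target_d + spread * 0.55)
    for (it in 1:20) {
      P <- rasterize_cluster(H, W, ctr, offsets, radii)
      pidx <- which(P)
      if (!length(pidx)) break
      dmin <- sqrt(min(d2n[pidx]))
      if (target_d == 0) {
        ov <- sum(d2n[pidx] == 0)
        if (ov >= 40 && ov <= 400) {
          if (sum(P & !occupied) >= min_area) return(P)
          break
        }
        shift <- if (ov < 40) -max(1, round(dmin)) else 2
        ctr <- ctr + u * shift
      } else {
        if (abs(dmin - target_d) <= 1) {
          if (sum(P & !occupied) >= min_area && dmin > 0) return(P)
          break
        }
        ctr <- ctr - u * (dmin - target_d)
      }
    }
  }
  NULL
}

# Nerve bundle inside the main tumor body, encircled over fraction f.
place_encirclement <- function(H, W, f, min_area) {
  if (min(H, W) < 384) {
    stop("tile too small to place an encirclement event (need >= 384 px)",
         call. = FALSE)
  }
  ctr <- c(runif(1, 0.38 * H, 0.62 * H), runif(1, 0.38 * W, 0.62 * W))
  rn <- 58 + runif(1, 0, 8)
  nerve <- make_blob(H, W, ctr, rn, 0.05)
  body <- make_blob(H, W, ctr + runif(2, -8, 8), min(H, W) * 0.29, 0.07)
  d2b <- edt_squared(nerve)
  gap <- d2b <= 6.5^2
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  theta <- atan2(rows - ctr[1], cols - ctr[2])
  phi <- runif(1, 0, 2 * pi)
  covered <- ((theta - phi) %% (2 * pi)) <= 2 * pi * f
  tumor <- body & !nerve & !(gap & !covered)
  if (sum(nerve) < min_area || sum(tumor) < min_area) return(NULL)
  list(nerve = nerve, tumor = tumor, center = ctr)
}

# ---- tile generation --------------------------------------------------------

#' Generate one synthetic tile with its ground truth
#'
#' Renders an H&E-like RGB tile and the matching class mask with any
#' requested PNI events planted. Each realized event is measured back on the
#' generated mask: its nerve-tumor minimum distance must land within 2 px of
#' the target and its encirclement within 0.1 of the target, otherwise the
#' geometry is redrawn (up to 100 attempts before an explicit error).
#' Identical spec + seed gives bit-identical output.
#'
#' @param spec a [tile_spec].
#' @param events list of [pni_event] to plant (at most one per nerve).
#' @param render if FALSE, skip the RGB rendering and return `tile = NULL`
#'   (the pipeline only needs the mask; skipping rendering makes large
#'   simulated studies cheap).
#' @return list with `tile` (H x W x 3 array or NULL), `gt` (a
#'   [ground_truth] with realized events), and `spec`.
#' @export
generate_tile <- function(spec, events = list(), render = TRUE) {
  stopifnot(inherits(spec, "tile_spec"))
  if (inherits(events, "pni_event")) events <- list(events)
  for (e in events) stopifnot(inherits(e, "pni_event"))
  if (length(events) > spec$n_nerves) {
    stop("more events than nerves: each event needs its own nerve",
         call. = FALSE)
  }
  if (length(events) > 0 && spec$n_malignant_glands == 0) {
    stop("events need malignant glands (n_malignant_glands = 0)",
         call. = FALSE)
  }
  H <- spec$height; W <- spec$width
  with_seed(spec$rng_seed, {
    for (attempt in 1:100) {
      out <- try_tile_geometry(spec, events, H, W)
      if (!is.null(out)) {
        tile <- if (render) render_tile(out$mask, out$centerline, spec) else NULL
        return(list(tile = tile,
                    gt = ground_truth(out$mask, out$events),
                    spec = spec))
      }
    }
    stop(sprintf(paste0("failed to realize the requested geometry after 100 ",
                        "attempts (%d event(s); first event: distance %.1f, ",
                        "encirclement %.2f)"),
                 length(events),
                 if (length(events)) events[[1]]$target_distance else NA,
                 if (length(events)) events[[1]]$target_encirclement else NA),
         call. = FALSE)
  })
}

try_tile_geometry <- function(spec, events, H, W) {
  nerve_all <- matrix(FALSE, H, W)
  tumor_all <- matrix(FALSE, H, W)
  centerline_all <- matrix(FALSE, H, W)
  nerve_probe <- vector("list", max(spec$n_nerves, length(events)))
  tumor_probe <- vector("list", length(events))
  min_area <- spec$min_component_area

  is_enc <- vapply(events, function(e) e$target_encirclement > 0, logical(1))

  # encircled events first: nerve bundle + enclosing tumor body are coupled
  for (j in which(is_enc)) {
    pe <- place_encirclement(H, W, events[[j]]$target_encirclement, min_area)
    if (is.null(pe)) return(NULL)
    nerve_all <- nerve_all | pe$nerve
    tumor_all <- tumor_all | pe$tumor
    ctr_px <- cbind(round(pe$center[1]), round(pe$center[2]))
    centerline_all[ctr_px] <- TRUE
    nerve_probe[[j]] <- which(pe$nerve)[1]
    tumor_probe[[j]] <- which(pe$tumor)[1]
  }

  # ribbon nerves (event nerves first so event j uses nerve j)
  ribbons <- vector("list", spec$n_nerves)
  for (i in seq_len(spec$n_nerves)) {
    if (i <= length(events) && is_enc[i]) next  # already a bundle
    th <- runif(1, spec$nerve_thickness_range[1], spec$nerve_thickness_range[2])
    rb <- make_ribbon(H, W, th, min_area, avoid = tumor_all)
    if (is.null(rb)) return(NULL)
    ribbons[[i]] <- rb
    nerve_all <- nerve_all | rb$mask
    centerline_all <- centerline_all | rb$centerline
    if (i <= length(events)) nerve_probe[[i]] <- which(rb$centerline)[1]
  }

  # gland template shared by all clusters on this tile
  n_g <- spec$n_malignant_glands
  mean_r <- mean(spec$gland_radius_range)
  if (n_g > 0) {
    spread <- 1.5 * mean_r
    offsets <- cbind(runif(n_g, -spread, spread), runif(n_g, -spread, spread))
    radii <- runif(n_g, spec$gland_radius_range[1], spec$gland_radius_range[2])
  }

  # contact/distance events
  for (j in which(!is_enc)) {
    rb <- ribbons[[j]]
    P <- place_contact_cluster(rb$mask, rb$centerline, H, W, offsets, radii,
                               events[[j]]$target_distance, min_area,
                               occupied = nerve_all)
    if (is.null(P)) return(NULL)
    tumor_all <- tumor_all | P
    free <- which(P & !nerve_all)
    d2 <- edt_squared(rb$mask)
    tumor_probe[[j]] <- free[which.max(d2[free])]
  }

  # one non-event cluster on tiles without planted tumor
  if (n_g > 0 && length(events) == 0) {
    d2n <- if (any(nerve_all)) edt_squared(nerve_all) else NULL
    placed <- FALSE
    margin <- ceiling(1.5 * mean_r + max(spec$gland_radius_range) + 2)
    for (try in 1:40) {
      ctr <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      P <- rasterize_cluster(H, W, ctr, offsets, radii)
      if (sum(P) < min_area) next
      if (!is.null(d2n) && min(d2n[which(P)]) < 12^2) next
      tumor_all <- tumor_all | P
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }

  # benign gland rings, >= 50 px from any nerve, not overlapping anything
  benign_all <- matrix(FALSE, H, W)
  lumen_all <- matrix(FALSE, H, W)
  occupied <- nerve_all | tumor_all
  d2n_all <- if (any(nerve_all)) edt_squared(nerve_all) else NULL
  for (g in seq_len(spec$n_benign_glands)) {
    r <- runif(1, 0.5, 0.75) * mean_r
    for (try in 1:40) {
      ctr <- c(runif(1, r + 2, H - r - 2), runif(1, r + 2, W - r - 2))
      ci <- cbind(round(ctr[1]), round(ctr[2]))
      # +2 px guard so that, after rounding, every ring pixel stays >= 50 px
      # from nerve tissue
      if (!is.null(d2n_all) && d2n_all[ci] < (52 + r)^2) next
      ring <- fill_disks(matrix(FALSE, H, W), cbind(ctr[1], ctr[2]), r)
      lum <- fill_disks(matrix(FALSE, H, W), cbind(ctr[1], ctr[2]),
                        max(r - 6, 2))
      rim <- ring & !lum
      if (any(ring & (occupied | benign_all | lumen_all))) next
      benign_all <- benign_all | rim
      lumen_all <- lumen_all | lum
      break
    }
  }

  mask <- matrix(0L, H, W)
  mask[benign_all] <- CLASS_CODES[["benign_gland"]]
  mask[tumor_all] <- CLASS_CODES[["tumor"]]
  mask[nerve_all] <- CLASS_CODES[["nerve"]]

  # realize + verify the events on the final mask
  realized <- events
  if (length(events)) {
    nreg <- label_components(mask == CLASS_CODES[["nerve"]], 8)
    treg <- label_components(mask == CLASS_CODES[["tumor"]], 8)
    tmask <- mask == CLASS_CODES[["tumor"]]
    for (j in seq_along(events)) {
      nid <- nreg$labels[nerve_probe[[j]]]
      tid <- treg$labels[tumor_probe[[j]]]
      if (nid == 0L || tid == 0L) return(NULL)
      # both event components must survive the operational size filter
      if (nreg$areas[nid] < min_area || treg$areas[tid] < min_area) {
        return(NULL)
      }
      d2 <- edt_squared(nreg$labels == nid)
      tpix <- which(treg$labels == tid)
      d <- sqrt(min(d2[tpix]))
      enc <- measure_encirclement(nid, nreg, tmask, epsilon = 3)
      if (abs(d - events[[j]]$target_distance) > 2) return(NULL)
      if (abs(enc - events[[j]]$target_encirclement) > 0.1) return(NULL)
      realized[[j]]$nerve_id <- as.integer(nid)
      realized[[j]]$tumor_id <- as.integer(tid)
      realized[[j]]$measured_distance <- d
      realized[[j]]$measured_encirclement <- enc
    }
  }
  list(mask = mask, centerline = centerline_all, events = realized)
}

# H&E-like rendering driven entirely by the class mask (plus the nerve
# centerlines, which modulate fiber stripes).
render_tile <- function(mask, centerline, spec) {
  H <- nrow(mask); W <- ncol(mask)
  noise <- 0.45 * upscale(matrix(rnorm(16 * 16), 16, 16), H, W) +
    0.30 * upscale(matrix(rnorm(48 * 48), 48, 48), H, W) +
    0.25 * matrix(rnorm(H * W), H, W)
  noise <- noise * spec$background_noise_sd / 0.035 * 0.05
  stripes <- if (any(centerline)) {
    0.05 * sin(sqrt(edt_squared(centerline)) * 0.9 + runif(1, 0, 2 * pi))
  } else matrix(0, H, W)
  speckle <- matrix(runif(H * W) < 0.18, H, W)

  bg <- c(0.92, 0.77, 0.85)
  tum <- c(0.58, 0.40, 0.64)
  nrv <- c(0.89, 0.62, 0.67)
  ben <- c(0.68, 0.52, 0.72)

  is_t <- mask == CLASS_CODES[["tumor"]]
  is_n <- mask == CLASS_CODES[["nerve"]]
  is_b <- mask == CLASS_CODES[["benign_gland"]]
  tile <- array(0, c(H, W, 3L))
  for (ch in 1:3) {
    v <- bg[ch] + noise
    v[is_t] <- tum[ch] + 0.6 * noise[is_t] - 0.12 * speckle[is_t]
    v[is_n] <- nrv[ch] + 0.5 * noise[is_n] + stripes[is_n]
    v[is_b] <- ben[ch] + 0.6 * noise[is_b]
    tile[, , ch] <- clamp01(v)
  }
  tile
}

# ---- cases and studies ------------------------------------------------------

#' Specification of one synthetic case
#'
#' A case is a set of slides (tiles). When `n_slides` is NULL it is drawn at
#' generation time from a rounded normal truncated at 1: mean 27, sd 9.4
#' slides for full cases, mean 6.1, sd 1.8 for tumor-only cases (cases where
#' only the tumor-bearing slides were scanned).
#'
#' @param case_id identifier.
#' @param n_slides fixed slide count, or NULL to sample.
#' @param tumor_only logical.
#' @param pni_positive logical; positive cases carry `n_events` planted
#'   contact events.
#' @param n_events number of planted events (must be >= 1 iff positive).
#' @param slides_mean,slides_sd slide-count distribution for full cases.
#' @param tumor_only_mean,tumor_only_sd slide-count distribution for
#'   tumor-only cases.
#' @param rng_seed integer seed.
#' @export
case_spec <- function(case_id, n_slides = NULL, tumor_only = FALSE,
                      pni_positive = FALSE,
                      n_events = if (pni_positive) 1L else 0L,
                      slides_mean = 27, slides_sd = 9.4,
                      tumor_only_mean = 6.1, tumor_only_sd = 1.8,
                      rng_seed = 1L) {
  n_events <- check_count(n_events, "n_events")
  if (pni_positive != (n_events >= 1L)) {
    stop("n_events must be >= 1 exactly when pni_positive", call. = FALSE)
  }
  if (!is.null(n_slides)) n_slides <- check_count(n_slides, "n_slides", 1L)
  structure(list(case_id = as.character(case_id), n_slides = n_slides,
                 tumor_only = isTRUE(tumor_only),
                 pni_positive = isTRUE(pni_positive), n_events = n_events,
                 slides_mean = slides_mean, slides_sd = slides_sd,
                 tumor_only_mean = tumor_only_mean,
                 tumor_only_sd = tumor_only_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "case_spec")
}

#' Sample per-case slide counts
#'
#' Rounded normal truncated at 1, the model behind the 27 +/- 9.4 (full case)
#' and 6.1 +/- 1.8 (tumor-only) slide counts.
#'
#' @param n number of draws.
#' @param mean,sd distribution parameters.
#' @param seed integer seed.
#' @return integer vector of length `n`.
#' @export
sample_case_sizes <- function(n, mean = 27, sd = 9.4, seed = 1L) {
  with_seed(seed, pmax(1L, as.integer(round(rnorm(n, mean, sd)))))
}

#' Generate a full synthetic case
#'
#' Draws the slide count (unless fixed), assigns each planted event to a
#' uniformly chosen slide (events are rare: at most one per slide while
#' slides remain), and generates every slide tile. Deterministic in `seed`.
#'
#' @param spec a [case_spec].
#' @param seed integer seed (defaults to the spec's).
#' @param tile a [tile_spec] template for the slides.
#' @param render render RGB tiles (FALSE keeps only ground truth; much
#'   cheaper for large studies).
#' @return a `synthetic_case`: list with `spec` (with realized `n_slides`)
#'   and `slides`, a list of `list(tile, gt)`.
#' @export
generate_case <- function(spec, seed = spec$rng_seed, tile = tile_spec(),
                          render = FALSE) {
  stopifnot(inherits(spec, "case_spec"), inherits(tile, "tile_spec"))
  plan <- with_seed(seed, {
    n_slides <- spec$n_slides
    if (is.null(n_slides)) {
      m <- if (spec$tumor_only) spec$tumor_only_mean else spec$slides_mean
      s <- if (spec$tumor_only) spec$tumor_only_sd else spec$slides_sd
      n_slides <- max(1L, as.integer(round(rnorm(1, m, s))))
    }
    ev_count <- integer(n_slides)
    if (spec$n_events > 0) {
      picks <- sample.int(n_slides, min(spec$n_events, n_slides))
      ev_count[picks] <- 1L
      extra <- spec$n_events - length(picks)
      if (extra > 0) {
        more <- sample(rep(seq_len(n_slides), length.out = extra))
        for (s2 in more) ev_count[s2] <- ev_count[s2] + 1L
      }
    }
    list(n_slides = n_slides, ev_count = ev_count,
         slide_seeds = sample.int(2^30, n_slides))
  })
  slides <- vector("list", plan$n_slides)
  for (i in seq_len(plan$n_slides)) {
    tsp <- tile
    tsp$rng_seed <- plan$slide_seeds[i]
    evs <- replicate(plan$ev_count[i], pni_event(), simplify = FALSE)
    g <- generate_tile(tsp, evs, render = render)
    slides[[i]] <- list(tile = g$tile, gt = g$gt)
  }
  spec$n_slides <- plan$n_slides
  structure(list(spec = spec, slides = slides), class = "synthetic_case")
}

#' Lay out a synthetic study (truth labels and seeds; no pixels)
#'
#' @param n_cases number of cases.
#' @param prevalence fraction of PNI-positive cases; `round(n_cases *
#'   prevalence)` cases are positive.
#' @param seed integer seed.
#' @param tumor_only_fraction fraction of cases with only tumor slides
#'   scanned (default 10/59, the clinical mix).
#' @param n_events_per_positive planted events in each positive case.
#' @return data.frame manifest: case_id, pni_positive, tumor_only, n_events,
#'   seed.
#' @export
study_manifest <- function(n_cases, prevalence, seed = 1L,
                           tumor_only_fraction = 10 / 59,
                           n_events_per_positive = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  prevalence <- check_fraction(prevalence, "prevalence")
  if (n_cases == 0L) {
    return(data.frame(case_id = character(0), pni_positive = logical(0),
                      tumor_only = logical(0), n_events = integer(0),
                      seed = integer(0)))
  }
  with_seed(seed, {
    n_pos <- round(n_cases * prevalence)
    pos <- logical(n_cases)
    pos[sample.int(n_cases, n_pos)] <- TRUE
    n_to <- round(n_cases * tumor_only_fraction)
    tonly <- logical(n_cases)
    if (n_to > 0) tonly[sample.int(n_cases, n_to)] <- TRUE
    data.frame(
      case_id = sprintf("case%03d", seq_len(n_cases)),
      pni_positive = pos,
      tumor_only = tonly,
      n_events = ifelse(pos, as.integer(n_events_per_positive), 0L),
      seed = sample.int(2^30, n_cases)
    )
  })
}

#' Generate a synthetic study
#'
#' Generates `round(n_cases * prevalence)` PNI-positive cases among
#' `n_cases`, with the tumor-only mix and slide-count distributions of the
#' clinical workload. With `dir` set, tiles and masks are written to disk
#' (PNG) together with a YAML manifest and cases are not kept in memory.
#'
#' @inheritParams study_manifest
#' @param tile [tile_spec] template.
#' @param dir output directory, or NULL to keep cases in memory.
#' @param render render RGB tiles (forced TRUE when writing to disk).
#' @return list with `manifest` (data.frame), `cases` (list of
#'   `synthetic_case`, NULL when written to disk), and `dir`.
#' @export
generate_study <- function(n_cases = 59, prevalence = 31 / 59, seed = 1L,
                           tumor_only_fraction = 10 / 59,
                           n_events_per_positive = 1L,
                           tile = tile_spec(), dir = NULL,
                           render = !is.null(dir)) {
  manifest <- study_manifest(n_cases, prevalence, seed, tumor_only_fraction,
                             n_events_per_positive)
  if (!is.null(dir)) {
    render <- TRUE
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  }
  keep <- is.null(dir)
  cases <- if (keep) vector("list", nrow(manifest)) else NULL
  n_slides <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cs <- case_spec(manifest$case_id[i], tumor_only = manifest$tumor_only[i],
                    pni_positive = manifest$pni_positive[i],
                    n_events = manifest$n_events[i],
                    rng_seed = manifest$seed[i])
    case <- generate_case(cs, tile = tile, render = render)
    n_slides[i] <- case$spec$n_slides
    if (keep) {
      cases[[i]] <- case
    } else {
      write_case(case, dir)
    }
  }
  manifest$n_slides <- n_slides
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.yaml"))
  list(manifest = manifest, cases = cases, dir = dir)
}
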