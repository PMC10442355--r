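# On-disk artifacts: RGB tiles (PNG / uncompressed TIFF), 8-bit class masks,
# 2-channel 32-bit float probability maps, YAML manifests and configs, CSV
# and GeoJSON candidate exports.

tile_ext <- function(path) tolower(tools::file_ext(path))

#' Read / write an RGB tile
#'
#' PNG and uncompressed TIFF are supported; both round-trip 8-bit data
#' losslessly (values are quantized to 8 bits on write).
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param tile H x W x 3 numeric array in \[0, 1\].
#' @return `read_tile` returns the H x W x 3 array.
#' @export
read_tile <- function(path) {
  ext <- tile_ext(path)
  img <- tryCatch(switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported tile format '.%s' (use .png/.tif/.tiff)", ext),
         call. = FALSE)
  ), error = function(e) {
    stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  img
}

#' @rdname read_tile
#' @export
write_tile <- function(tile, path) {
  stopifnot(is.array(tile), length(dim(tile)) == 3L)
  ext <- tile_ext(path)
  switch(ext,
    png = png::writePNG(clamp01(tile), path),
    tif = ,
    tiff = tiff::writeTIFF(clamp01(tile), path, bits.per.sample = 8L,
                           compression = "none"),
    stop(sprintf("unsupported tile format '.%s' (use .png/.tif/.tiff)", ext),
         call. = FALSE)
  )
  invisible(path)
}

#' Read / write an integer class mask
#'
#' Single-channel 8-bit PNG with codes 0 background, 1 tumor, 2 nerve,
#' 3 benign gland. Round trips are code-exact; codes outside 0-3 and
#' multi-channel inputs are rejected.
#'
#' @param path PNG file path.
#' @param mask integer matrix of codes 0-3.
#' @return `read_mask` returns the integer matrix.
#' @export
read_mask <- function(path) {
  img <- tryCatch(png::readPNG(path), error = function(e) {
    stop(sprintf("failed to parse '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(img)) != 2L) {
    stop("class masks must be single-channel PNG", call. = FALSE)
  }
  codes <- round(img * 255)
  if (any(codes > 3)) {
    stop(sprintf("mask contains codes outside 0-3 (max %d)", max(codes)),
         call. = FALSE)
  }
  storage.mode(codes) <- "integer"
  codes
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% 0:3)) stop("mask codes must be in 0..3", call. = FALSE)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Read / write a probability map as 2-channel 32-bit float TIFF
#'
#' @param map a [probability_map].
#' @param path TIFF file path.
#' @return `read_probability_map` returns a [probability_map].
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "probability_map"))
  tiff::writeTIFF(map$values, path, bits.per.sample = 32L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_probability_map
#' @export
read_probability_map <- function(path) {
  # libtiff flags the 2-sample layout as "extra samples"; that is expected
  # for a (tumor, nerve) confidence raster
  v <- suppressWarnings(tiff::readTIFF(path))
  probability_map(v, provenance = path)
}

#' Write / read a study manifest (YAML)
#'
#' @param manifest data.frame as produced by [study_manifest()] (optionally
#'   with a `slides` list column of relative paths).
#' @param path YAML file path.
#' @export
write_manifest <- function(manifest, path) {
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- lapply(manifest[i, , drop = FALSE], function(col) {
      v <- if (is.list(col)) col[[1]] else col
      if (is.factor(v)) as.character(v) else v
    })
    names(row) <- names(manifest)
    row
  })
  yaml::write_yaml(list(cases = cases), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(y$cases, function(cs) {
    slides <- cs$slides
    cs$slides <- NULL
    df <- as.data.frame(cs, stringsAsFactors = FALSE)
    if (!is.null(slides)) df$slides <- I(list(unlist(slides)))
    df
  })
  do.call(rbind, rows)
}

# Write one generated case under dir/<case_id>/ as slide PNGs + mask PNGs.
write_case <- function(case, dir) {
  cdir <- file.path(dir, case$spec$case_id)
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(case$slides)) {
    s <- case$slides[[i]]
    if (!is.null(s$tile)) {
      write_tile(s$tile, file.path(cdir, sprintf("slide_%03d.png", i)))
    }
    write_mask(s$gt$class_mask, file.path(cdir, sprintf("mask_%03d.png", i)))
  }
  invisible(cdir)
}

#' Pipeline configuration
#'
#' Bundles the operating constants of the screening pipeline: the 50%
#' confidence threshold, the 10,000-px small-focus filter, component
#' connectivity, ranking parameters and the review rule. Unknown fields are
#' rejected on load.
#'
#' @param threshold confidence threshold.
#' @param min_area_tumor,min_area_nerve per-class small-focus cutoffs (px).
#' @param connectivity 4 or 8.
#' @param k,k_tumor_only,max_distance,field_size,overlap_iou,contact_distance,encirclement_epsilon
#'   see [ranking_config()].
#' @param encirclement_min,require_encirclement_inside_tumor see
#'   [review_rule()].
#' @param seed top-level seed.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(threshold = 0.5, min_area_tumor = 10000,
                            min_area_nerve = 10000, connectivity = 8,
                            k = 40, k_tumor_only = 20, max_distance = 100,
                            field_size = 512, overlap_iou = 0.5,
                            contact_distance = 2, encirclement_epsilon = 3,
                            encirclement_min = 0.33,
                            require_encirclement_inside_tumor = TRUE,
                            seed = 1L) {
  structure(list(
    threshold = check_fraction(threshold, "threshold"),
    min_area_tumor = as.numeric(min_area_tumor),
    min_area_nerve = as.numeric(min_area_nerve),
    connectivity = if (connectivity %in% c(4, 8)) as.integer(connectivity)
                   else stop("connectivity must be 4 or 8", call. = FALSE),
    k = check_count(k, "k", 1L),
    k_tumor_only = check_count(k_tumor_only, "k_tumor_only", 1L),
    max_distance = as.numeric(max_distance),
    field_size = check_count(field_size, "field_size", 1L),
    overlap_iou = check_fraction(overlap_iou, "overlap_iou"),
    contact_distance = as.numeric(contact_distance),
    encirclement_epsilon = as.numeric(encirclement_epsilon),
    encirclement_min = check_fraction(encirclement_min, "encirclement_min"),
    require_encirclement_inside_tumor = isTRUE(require_encirclement_inside_tumor),
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(pipeline_config, y)
}

# Split a pipeline_config into the ranking/review/postprocess pieces.
config_parts <- function(config) {
  list(
    ranking = ranking_config(config$k, config$k_tumor_only,
                             config$max_distance, config$field_size,
                             config$overlap_iou, config$contact_distance,
                             config$encirclement_epsilon),
    rule = review_rule(config$contact_distance, config$encirclement_min,
                       config$require_encirclement_inside_tumor,
                       config$encirclement_epsilon),
    threshold = config$threshold,
    min_area = c(tumor = config$min_area_tumor, nerve = config$min_area_nerve),
    connectivity = config$connectivity
  )
}

#' Export candidates as CSV
#'
#' Window origin and closest-pair coordinates are written 0-based (row, col),
#' the convention of the on-disk interchange formats.
#'
#' @param candidates a `pni_candidates` data.frame.
#' @param path CSV file path.
#' @export
export_candidates_csv <- function(candidates, path) {
  df <- as.data.frame(candidates)
  for (cc in c("nerve_row", "nerve_col", "tumor_row", "tumor_col",
               "row0", "col0")) {
    df[[cc]] <- df[[cc]] - 1L
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export candidates as GeoJSON
#'
#' One polygon per candidate field window, in image coordinates (x = column,
#' y = row, origin at the top-left pixel, 0-based), stated in the
#' FeatureCollection's properties block. Properties carry distance,
#' encirclement and component ids.
#'
#' @param candidates a `pni_candidates` data.frame.
#' @param path output path.
#' @export
export_candidates_geojson <- function(candidates, path) {
  feats <- lapply(seq_len(nrow(candidates)), function(i) {
    cd <- candidates[i, ]
    x0 <- cd$col0 - 1L; y0 <- cd$row0 - 1L
    x1 <- x0 + cd$width; y1 <- y0 + cd$height
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(list(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1),
                                c(x0, y0)))
      ),
      properties = list(slide_id = cd$slide_id, rank = i,
                        min_distance = cd$min_distance,
                        encirclement = cd$encirclement,
                        nerve_id = cd$nerve_id, tumor_id = cd$tumor_id)
    )
  })
  obj <- list(
    type = "FeatureCollection",
    properties = list(
      coordinate_system = "image pixels; x = column, y = row, origin top-left, 0-based"
    ),
    features = feats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a study summary as JSON
#'
#' @param summary a `study_summary`.
#' @param path output path.
#' @export
export_study_summary <- function(summary, path) {
  stopifnot(inherits(summary, "study_summary"))
  obj <- list(
    n_cases = summary$n_cases,
    report_positive = summary$report_positive,
    algorithm_positive = summary$algorithm_positive,
    report_positive_pct = summary$report_positive_pct,
    algorithm_positive_pct = summary$algorithm_positive_pct,
    missed = summary$missed,
    newly_detected = summary$newly_detected,
    sensitivity_vs_report = summary$sensitivity_vs_report,
    z = unname(summary$test$statistic),
    p_value = summary$test$p.value,
    cases = summary$cases
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
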