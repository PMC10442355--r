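# Glue: probability map -> candidates for one slide, slides -> case call,
# and the fully synthetic end-to-end study.

#' Screen one slide's probability map for PNI candidates
#'
#' Binarizes both classes at `threshold`, labels components, applies the
#' per-class small-focus filter, computes all nerve-tumor component distances
#' within the configured proximity, builds candidate fields and suppresses
#' near-duplicates.
#'
#' @param map a [probability_map].
#' @param config a [ranking_config].
#' @param threshold confidence threshold (the operational default is 0.5).
#' @param min_area per-class small-focus cutoff, `c(tumor =, nerve =)`.
#' @param connectivity component connectivity.
#' @param slide_id identifier recorded on candidates.
#' @return list with `candidates` (a `pni_candidates` data.frame) and the
#'   filtered `nerve` and `tumor` [labeled_regions].
#' @export
screen_slide <- function(map, config = ranking_config(), threshold = 0.5,
                         min_area = c(tumor = 10000, nerve = 10000),
                         connectivity = 8, slide_id = "slide") {
  treg <- filter_small(label_components(binarize(map, "tumor", threshold),
                                        connectivity), min_area[["tumor"]])
  nreg <- filter_small(label_components(binarize(map, "nerve", threshold),
                                        connectivity), min_area[["nerve"]])
  pairs <- component_min_distances(nreg, treg, config$max_distance)
  cands <- build_candidates(pairs, nreg, treg, regions_mask(treg), config,
                            slide_id)
  cands <- suppress_overlaps(cands, config$overlap_iou)
  list(candidates = cands, nerve = nreg, tumor = treg)
}

#' Screen a synthetic case end to end
#'
#' Segments every slide (oracle-noise segmenter by default, or a trained
#' `pni_segmenter` when the case was generated with rendered tiles), pools
#' candidates over the case's slides, ranks the top k (20 for tumor-only
#' cases, 40 otherwise), reviews each presented field with the simulated
#' pathologist, and aggregates the case call.
#'
#' @param case a `synthetic_case` from [generate_case()].
#' @param segmenter a [noise_model] (oracle-noise segmentation of ground
#'   truth) or a trained `pni_segmenter`.
#' @param config a [ranking_config].
#' @param rule a [review_rule].
#' @param threshold,min_area,connectivity post-processing parameters.
#' @param seed integer seed for the per-slide segmentation noise.
#' @return list with `result` (a `case_result`) and `ranked` (the presented
#'   candidates).
#' @export
screen_case <- function(case, segmenter = noise_model(),
                        config = ranking_config(), rule = review_rule(),
                        threshold = 0.5,
                        min_area = c(tumor = 10000, nerve = 10000),
                        connectivity = 8, seed = 1L) {
  stopifnot(inherits(case, "synthetic_case"))
  slides <- case$slides
  per <- vector("list", length(slides))
  sids <- sprintf("%s_s%03d", case$spec$case_id, seq_along(slides))
  for (i in seq_along(slides)) {
    map <- if (inherits(segmenter, "noise_model")) {
      ns <- segmenter
      ns$rng_seed <- derive_seed(seed, paste0(case$spec$case_id, "/", i))
      oracle_noise_segment(slides[[i]]$gt, ns)
    } else if (inherits(segmenter, "pni_segmenter")) {
      if (is.null(slides[[i]]$tile)) {
        stop("trained segmenter needs rendered tiles (generate with render = TRUE)",
             call. = FALSE)
      }
      predict(segmenter, slides[[i]]$tile)
    } else {
      stop("segmenter must be a noise_model or a pni_segmenter", call. = FALSE)
    }
    per[[i]] <- screen_slide(map, config, threshold, min_area, connectivity,
                             slide_id = sids[i])
  }
  all_c <- do.call(rbind, lapply(per, `[[`, "candidates"))
  class(all_c) <- c("pni_candidates", "data.frame")
  k <- if (case$spec$tumor_only) config$k_tumor_only else config$k
  ranked <- rank_top_k(all_c, k)
  reviews <- logical(nrow(ranked))
  for (j in seq_len(nrow(ranked))) {
    i <- match(ranked$slide_id[j], sids)
    reviews[j] <- review_candidate(ranked[j, , drop = FALSE],
                                   per[[i]]$nerve, per[[i]]$tumor,
                                   slides[[i]]$gt, rule)
  }
  list(result = aggregate_case(ranked, reviews, case$spec$case_id),
       ranked = ranked, reviews = reviews)
}

#' Run a fully synthetic clinical study
#'
#' Generates cases one at a time (ground truth only; slides are discarded
#' after screening to bound memory), screens each with the given segmenter,
#' and summarizes case-level performance against the planted truth.
#'
#' @inheritParams study_manifest
#' @param tile [tile_spec] template for slides.
#' @param segmenter a [noise_model] or trained `pni_segmenter`.
#' @param config,rule,threshold,min_area,connectivity screening parameters.
#' @return a `pni_study` object: per-case results data.frame (`cases`),
#'   `sensitivity` and `specificity` against the planted truth, and a
#'   [study_summary] treating the planted truth as the report label.
#' @export
run_synthetic_study <- function(n_cases = 59, prevalence = 31 / 59, seed = 1L,
                                tumor_only_fraction = 10 / 59,
                                n_events_per_positive = 1L,
                                tile = tile_spec(),
                                segmenter = noise_model(),
                                config = ranking_config(),
                                rule = review_rule(), threshold = 0.5,
                                min_area = c(tumor = 10000, nerve = 10000),
                                connectivity = 8) {
  manifest <- study_manifest(n_cases, prevalence, seed, tumor_only_fraction,
                             n_events_per_positive)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cs <- case_spec(manifest$case_id[i], tumor_only = manifest$tumor_only[i],
                    pni_positive = manifest$pni_positive[i],
                    n_events = manifest$n_events[i],
                    rng_seed = manifest$seed[i])
    case <- generate_case(cs, tile = tile, render = FALSE)
    sc <- screen_case(case, segmenter, config, rule, threshold, min_area,
                      connectivity, seed = derive_seed(seed, manifest$case_id[i]))
    rows[[i]] <- data.frame(
      case_id = manifest$case_id[i],
      report = manifest$pni_positive[i],
      tumor_only = manifest$tumor_only[i],
      n_slides = case$spec$n_slides,
      called = sc$result$pni_called,
      first_positive_rank = sc$result$first_positive_rank,
      n_confirmed = sc$result$n_confirmed,
      n_reviewed = sc$result$n_candidates_reviewed
    )
  }
  cases <- do.call(rbind, rows)
  pos <- cases$report
  structure(list(
    cases = cases,
    sensitivity = if (any(pos)) mean(cases$called[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(!cases$called[!pos]) else NA_real_,
    summary = study_summary(cases),
    seed = seed
  ), class = "pni_study")
}

#' @export
print.pni_study <- function(x, ...) {
  cat(sprintf("synthetic PNI study: %d cases (seed %d)\n", nrow(x$cases),
              x$seed))
  cat(sprintf("  case-level sensitivity %.3f, specificity %.3f\n",
              x$sensitivity, x$specificity))
  print(x$summary)
  invisible(x)
}
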