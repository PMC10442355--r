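# Case-level PNI calling: a simulated pathologist reviews the top-ranked
# candidate fields against ground truth, and study-level comparison
# statistics summarize report-vs-algorithm positivity.

#' Rule used by the simulated reviewer
#'
#' Mirrors the accepted diagnostic convention: tumor abutting a nerve outside
#' the main tumor body is PNI; for a nerve inside the main tumor body, the
#' tumor must encircle at least a third of the nerve circumference to count
#' as invasion rather than focal abutment.
#'
#' @param contact_distance maximum nerve-tumor distance (px) counting as
#'   abutment; 2 px absorbs rasterization (abutting pixel centers are 1 or
#'   sqrt(2) apart).
#' @param encirclement_min minimum encircled fraction for intratumoral
#'   nerves (default 1/3).
#' @param require_encirclement_inside_tumor apply the encirclement criterion
#'   to intratumoral nerves (TRUE) or treat contact as sufficient everywhere.
#' @param epsilon abutment distance for the encirclement measurement.
#' @return a `review_rule` object.
#' @export
review_rule <- function(contact_distance = 2, encirclement_min = 0.33,
                        require_encirclement_inside_tumor = TRUE,
                        epsilon = 3) {
  structure(list(contact_distance = as.numeric(contact_distance),
                 encirclement_min = check_fraction(encirclement_min,
                                                   "encirclement_min"),
                 require_encirclement_inside_tumor =
                   isTRUE(require_encirclement_inside_tumor),
                 epsilon = as.numeric(epsilon)),
            class = "review_rule")
}

dominant_label <- function(labels_at) {
  labels_at <- labels_at[labels_at > 0L]
  if (!length(labels_at)) return(NA_integer_)
  tab <- tabulate(labels_at)
  which.max(tab)
}

# Is the nerve component inside the main tumor body? Operationalized as the
# majority (>= 50%) of the nerve's pixels lying within the filled convex
# hull of the tumor component. (A centroid-only test misclassifies long wavy
# nerves whose centroid happens to fall over a tangentially abutting tumor
# cluster; an embedded nerve, by contrast, has most of its extent inside the
# tumor mass.)
nerve_inside_tumor <- function(nerve_comp, tumor_comp, majority = 0.5) {
  tpix <- which(tumor_comp)
  if (!length(tpix)) return(FALSE)
  H <- nrow(tumor_comp)
  ty <- (tpix - 1L) %% H + 1L
  tx <- (tpix - 1L) %/% H + 1L
  h <- grDevices::chull(tx, ty)
  if (length(h) < 3L) return(FALSE)
  xs <- tx[h]; ys <- ty[h]
  # orient the hull counterclockwise in (x right, y down) coordinates
  if (sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys) < 0) {
    xs <- rev(xs); ys <- rev(ys)
  }
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  npix <- which(nerve_comp)
  ny <- (npix - 1L) %% H + 1L
  nx <- (npix - 1L) %/% H + 1L
  inside <- rep(TRUE, length(npix))
  for (e in seq_along(xs)) {
    cr <- (x2[e] - xs[e]) * (ny - ys[e]) - (y2[e] - ys[e]) * (nx - xs[e])
    inside <- inside & cr >= -1e-9
    if (!any(inside)) break
  }
  mean(inside) >= majority
}

#' Simulated pathologist review of one candidate field
#'
#' The reviewer consults ground truth: the candidate's predicted nerve and
#' tumor components must each overlap a true component of their class (a
#' benign gland misread as tumor therefore never confirms), and the *true*
#' spatial relationship of those components must satisfy the rule — contact
#' when the nerve lies outside the main tumor body, or encirclement of at
#' least `rule$encirclement_min` when it lies inside.
#'
#' @param candidate one-row `pni_candidates` data.frame.
#' @param pred_nerve,pred_tumor the predicted [labeled_regions] the candidate
#'   indexes into.
#' @param gt the slide's [ground_truth].
#' @param rule a [review_rule].
#' @return TRUE when the candidate is confirmed as PNI.
#' @export
review_candidate <- function(candidate, pred_nerve, pred_tumor, gt,
                             rule = review_rule()) {
  stopifnot(inherits(gt, "ground_truth"), nrow(candidate) == 1L)
  if (!all(dim(pred_nerve$labels) == dim(gt$class_mask))) {
    stop("candidate and ground truth come from different slides",
         call. = FALSE)
  }
  gn <- label_components(gt$class_mask == CLASS_CODES[["nerve"]], 8)
  gtm <- label_components(gt$class_mask == CLASS_CODES[["tumor"]], 8)
  nid <- dominant_label(gn$labels[pred_nerve$labels == candidate$nerve_id])
  tid <- dominant_label(gtm$labels[pred_tumor$labels == candidate$tumor_id])
  if (is.na(nid) || is.na(tid)) return(FALSE)
  ncomp <- gn$labels == nid
  tcomp <- gtm$labels == tid
  d <- sqrt(min(edt_squared(ncomp)[which(tcomp)]))
  inside <- nerve_inside_tumor(ncomp, tcomp)
  if (!inside || !rule$require_encirclement_inside_tumor) {
    return(d <= rule$contact_distance)
  }
  enc <- measure_encirclement(nid, gn, gt$class_mask == CLASS_CODES[["tumor"]],
                              rule$epsilon)
  enc >= rule$encirclement_min
}

#' Aggregate ranked reviews into a case-level result
#'
#' @param ranked ranked `pni_candidates` of the case.
#' @param reviews logical vector of confirmations, aligned 1:1 with `ranked`.
#' @param case_id identifier.
#' @return a `case_result`: case_id, pni_called, first_positive_rank (NA
#'   when negative), n_confirmed, n_candidates_reviewed.
#' @export
aggregate_case <- function(ranked, reviews, case_id = "case") {
  if (nrow(ranked) != length(reviews)) {
    stop("reviews must align 1:1 with ranked candidates", call. = FALSE)
  }
  conf <- which(reviews)
  structure(list(case_id = as.character(case_id),
                 pni_called = length(conf) > 0L,
                 first_positive_rank = if (length(conf)) conf[1] else NA_integer_,
                 n_confirmed = length(conf),
                 n_candidates_reviewed = length(reviews)),
            class = "case_result")
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("case %s: PNI %s (%d/%d fields confirmed%s)\n", x$case_id,
              if (x$pni_called) "POSITIVE" else "negative",
              x$n_confirmed, x$n_candidates_reviewed,
              if (x$pni_called) sprintf(", first at rank %d",
                                        x$first_positive_rank) else ""))
  invisible(x)
}

#' Pooled two-proportion z-test
#'
#' Two-sided z-test for the difference of two independent proportions using
#' the pooled variance estimate, without continuity correction; z squared
#' equals the Pearson chi-square statistic of the 2x2 table. This is the
#' comparison used for report-positivity versus algorithm-assisted
#' positivity.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return an object of class `htest` with the z statistic and two-sided
#'   p-value.
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("need 0 <= x <= n and n >= 1 for both groups", call. = FALSE)
  }
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) {
    z <- 0; p <- 1
  } else {
    z <- (p2 - p1) / se
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(`proportion 1` = p1, `proportion 2` = p2),
                 method = "Pooled two-proportion z-test (no continuity correction)",
                 data.name = sprintf("%d/%d vs %d/%d", x1, n1, x2, n2)),
            class = "htest")
}

#' Rank-sum (Mann-Whitney U) test
#'
#' Two-sided Mann-Whitney U. Small samples (n_a + n_b <= 12) without ties use
#' exact enumeration; otherwise a tie-corrected normal approximation without
#' continuity correction. Fully tied data returns p = 1.
#'
#' @param x,y numeric samples (both nonempty).
#' @return an object of class `htest` with the U statistic and two-sided
#'   p-value.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  tt <- table(c(x, y))
  sigma2 <- m * n / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  ties <- any(tt > 1)
  if (sigma2 <= 0) {
    p <- 1
    method <- "Mann-Whitney U (degenerate: all observations tied)"
  } else if (N <= 12 && !ties) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "Mann-Whitney U (exact)"
  } else {
    z <- (U - m * n / 2) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Mann-Whitney U (tie-corrected normal approximation)"
  }
  structure(list(statistic = c(U = U), p.value = p,
                 method = method,
                 data.name = sprintf("x (n=%d) vs y (n=%d)", m, n)),
            class = "htest")
}

#' Study-level summary of report versus algorithm-assisted positivity
#'
#' Tallies case positivity under the original pathology report and under the
#' algorithm-assisted review, the discordant counts, and attaches the pooled
#' two-proportion z-test comparing the two positivity proportions.
#'
#' @param results either a data.frame with logical columns `report` and
#'   `called` (plus `case_id`), or a list of `case_result` objects.
#' @param report when `results` is a list: one logical report label per case.
#' @return a `study_summary` object.
#' @export
study_summary <- function(results, report = NULL) {
  if (is.data.frame(results)) {
    stopifnot(all(c("report", "called") %in% names(results)))
    df <- results
    if (!"case_id" %in% names(df)) df$case_id <- as.character(seq_len(nrow(df)))
  } else {
    if (is.null(report) || length(report) != length(results)) {
      stop("need exactly one report label per case result", call. = FALSE)
    }
    df <- data.frame(
      case_id = vapply(results, function(r) r$case_id, character(1)),
      report = as.logical(report),
      called = vapply(results, function(r) r$pni_called, logical(1)),
      first_positive_rank = vapply(results, function(r)
        as.integer(r$first_positive_rank %||% NA_integer_), integer(1))
    )
  }
  n <- nrow(df)
  rp <- sum(df$report); ap <- sum(df$called)
  missed <- sum(df$report & !df$called)
  newly <- sum(!df$report & df$called)
  structure(list(
    n_cases = n,
    report_positive = rp, algorithm_positive = ap,
    report_positive_pct = if (n) 100 * rp / n else NA_real_,
    algorithm_positive_pct = if (n) 100 * ap / n else NA_real_,
    missed = missed, newly_detected = newly,
    sensitivity_vs_report = if (rp > 0) (rp - missed) / rp else NA_real_,
    test = if (n) two_proportion_test(rp, n, ap, n) else NULL,
    cases = df
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("PNI study summary (%d cases)\n", x$n_cases))
  cat(sprintf("  report-positive:    %d (%.1f%%)\n", x$report_positive,
              x$report_positive_pct))
  cat(sprintf("  algorithm-positive: %d (%.1f%%)\n", x$algorithm_positive,
              x$algorithm_positive_pct))
  cat(sprintf("  discordant: %d newly detected, %d missed by algorithm\n",
              x$newly_detected, x$missed))
  if (!is.na(x$sensitivity_vs_report)) {
    cat(sprintf("  sensitivity vs report-positive cases: %.1f%%\n",
                100 * x$sensitivity_vs_report))
  }
  if (!is.null(x$test)) {
    cat(sprintf("  two-proportion z = %.3f, p = %.2g\n",
                x$test$statistic, x$test$p.value))
  }
  invisible(x)
}

#' @export
summary.study_summary <- function(object, ...) {
  print(object)
  invisible(object)
}
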