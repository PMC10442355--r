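# Independent brute-force oracles used to verify the compiled primitives and
# the metric implementations. These deliberately share no code with the
# package internals.

# Flood-fill connected components, recursive queue on an R matrix.
bf_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  nxt <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(r, c))
      lab[r, c] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(nb))) {
          r2 <- p[1] + nb[k, 1]; c2 <- p[2] + nb[k, 2]
          if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
              mask[r2, c2] && lab[r2, c2] == 0L) {
            lab[r2, c2] <- nxt
            queue[[length(queue) + 1]] <- c(r2, c2)
          }
        }
      }
    }
  }
  lab
}

# Exhaustive minimum pairwise pixel-center distance between two pixel sets
# (1-based linear indices into an H-row raster). Squared-integer arithmetic
# before the square root, so it is bitwise comparable to the package's
# distance-transform route.
bf_min_distance <- function(idx_a, idx_b, H) {
  ra <- (idx_a - 1L) %% H + 1L; ca <- (idx_a - 1L) %/% H + 1L
  rb <- (idx_b - 1L) %% H + 1L; cb <- (idx_b - 1L) %/% H + 1L
  d2 <- outer(ra, rb, function(x, y) (x - y)^2) +
    outer(ca, cb, function(x, y) (x - y)^2)
  sqrt(min(d2))
}

# All-pairs component distances via brute force.
bf_pair_distances <- function(nerve_lab, tumor_lab) {
  H <- nrow(nerve_lab)
  out <- list()
  for (nk in seq_len(max(nerve_lab))) {
    for (tk in seq_len(max(tumor_lab))) {
      out[[length(out) + 1]] <- data.frame(
        nerve_id = nk, tumor_id = tk,
        min_distance = bf_min_distance(which(nerve_lab == nk),
                                       which(tumor_lab == tk), H))
    }
  }
  if (!length(out)) {
    return(data.frame(nerve_id = integer(0), tumor_id = integer(0),
                      min_distance = numeric(0)))
  }
  do.call(rbind, out)
}

# Set-arithmetic metric oracles.
bf_iou <- function(p, g) {
  u <- sum(p | g)
  if (u == 0) 1 else sum(p & g) / u
}
bf_detection_pixel <- function(p, g) if (!any(g)) 1 else sum(p & g) / sum(g)
bf_false_alarm_pixel <- function(p, g) if (!any(p)) 0 else sum(p & !g) / sum(p)
bf_detection_object <- function(p, g, connectivity = 8, theta = 0.5) {
  lab <- bf_label(g, connectivity)
  if (max(lab) == 0) return(1)
  mean(vapply(seq_len(max(lab)),
              function(k) mean(p[lab == k]) >= theta, logical(1)))
}
bf_false_alarm_object <- function(p, g, connectivity = 8, theta = 0.5) {
  lab <- bf_label(p, connectivity)
  if (max(lab) == 0) return(0)
  mean(vapply(seq_len(max(lab)),
              function(k) mean(g[lab == k]) < theta, logical(1)))
}

# Random blobby binary mask: a few disks on a small raster.
random_blob_mask <- function(H, W, n_blobs = 3, rmax = 6) {
  m <- matrix(FALSE, H, W)
  if (n_blobs == 0) return(m)
  for (i in seq_len(n_blobs)) {
    r0 <- runif(1, 1, H); c0 <- runif(1, 1, W); rad <- runif(1, 1, rmax)
    rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    m <- m | ((rr - r0)^2 + (cc - c0)^2 <= rad^2)
  }
  m
}

# A tiny ground-truth mask with one nerve bar and one tumor block at a given
# gap (columns between them); gap 0 means adjacent columns.
two_bar_gt <- function(H = 40, W = 40, gap = 0) {
  m <- matrix(0L, H, W)
  m[10:30, 5:10] <- 2L
  m[10:30, (11 + gap):(16 + gap)] <- 1L
  ground_truth(m)
}
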