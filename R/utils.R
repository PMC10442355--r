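# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a top-level seed
#'
#' All randomness in the package flows from one top-level seed; each module
#' and each slide draws from a named substream derived with this function, so
#' that, e.g., changing how many cases a study has does not reshuffle the
#' tiles of earlier cases. Results stay below 2^31 - 1.
#'
#' @param seed integer top-level seed.
#' @param name character substream name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(as.character(name)) *
             (seq_along(utf8ToInt(as.character(name))) %% 97 + 1))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483563) + 1L
}

# Squared EDT wrapped so that "no sites" becomes Inf.
edt_squared <- function(sites) {
  stopifnot(is.logical(sites), is.matrix(sites))
  d <- .edt_sq(sites)
  d[d > 1e19] <- Inf
  d
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Mean over a (2r+1)x(2r+1) box, borders handled by local box size
# (integral-image implementation, O(HW)).
box_mean <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(H) - r, 1L); r2 <- pmin(seq_len(H) + r, H)
  c1 <- pmax(seq_len(W) - r, 1L); c2 <- pmin(seq_len(W) + r, W)
  tot <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  n <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  tot / n
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2]) {
    stop(sprintf("%s must be a numeric (lo, hi) pair with lo <= hi", name),
         call. = FALSE)
  }
  as.numeric(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("%s must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single number in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

# Fill disks (centers in 1-based (row, col), radii in px) into a logical
# matrix; returns the updated matrix. Disk = pixels whose center lies within
# `radius` of the disk center.
fill_disks <- function(mask, centers, radii) {
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1L]; c0 <- centers[i, 2L]; rad <- radii[i]
    rr <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    if (!length(rr) || !length(cc)) next
    sub <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= rad^2
    mask[rr, cc] <- mask[rr, cc] | sub
  }
  mask
}

# Nearest-neighbour upscaling of a coarse noise grid to H x W.
upscale <- function(m, H, W) {
  m[ceiling(seq_len(H) / H * nrow(m)), ceiling(seq_len(W) / W * ncol(m)),
    drop = FALSE]
}
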