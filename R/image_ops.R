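#' Otsu threshold of an intensity image
#'
#' Classic between-class-variance-maximising threshold on a 256-bin
#' histogram. Used as the default "certain threshold" for stain masks; on
#' sections with steep stain gradients the downstream boundary estimates are
#' insensitive to its exact value.
#'
#' @param x Numeric matrix or vector of intensities.
#' @param nbins Number of histogram bins.
#' @return Threshold on the intensity scale of `x`.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop_invalid("no finite intensities")
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Connected-component labelling (4-connectivity) by alternating directional
# minimum-label sweeps until a fixed point. Fast for the blob-like masks that
# arise here (converges in a handful of passes).
label_components <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(Inf, nr, nc)
  lab[bw] <- which(bw)
  repeat {
    old <- lab
    for (i in 2:nr) { # down
      ok <- bw[i, ] & bw[i - 1L, ]
      if (any(ok)) lab[i, ok] <- pmin(lab[i, ok], lab[i - 1L, ok])
    }
    for (i in (nr - 1L):1) { # up
      ok <- bw[i, ] & bw[i + 1L, ]
      if (any(ok)) lab[i, ok] <- pmin(lab[i, ok], lab[i + 1L, ok])
    }
    for (j in 2:nc) { # right
      ok <- bw[, j] & bw[, j - 1L]
      if (any(ok)) lab[ok, j] <- pmin(lab[ok, j], lab[ok, j - 1L])
    }
    for (j in (nc - 1L):1) { # left
      ok <- bw[, j] & bw[, j + 1L]
      if (any(ok)) lab[ok, j] <- pmin(lab[ok, j], lab[ok, j + 1L])
    }
    if (identical(lab, old)) break
  }
  out <- matrix(0L, nr, nc)
  ids <- lab[bw]
  out[bw] <- match(ids, sort(unique(ids)))
  out
}

# Fill holes: background components not touching the image border become
# foreground.
fill_holes <- function(bw) {
  bg <- !bw
  lab <- label_components(bg)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  holes <- bg & !(lab %in% border)
  dim(holes) <- dim(bw)
  bw | holes
}

# Separable Gaussian blur with reflecting edges.
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) { # along rows (dimension 1)
    nr <- nrow(m)
    out <- matrix(0, nr, ncol(m))
    for (o in -half:half) {
      idx <- pmin(pmax(seq_len(nr) + o, 1L), nr)
      out <- out + k[o + half + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(x))))
}

# Bilinear interpolation of a matrix at fractional (x = col, y = row)
# positions; pixel centres at integer coordinates; outside -> 0.
interp_bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v00 <- get(y0, x0); v01 <- get(y0, x0 + 1)
  v10 <- get(y0 + 1, x0); v11 <- get(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Segment a spheroid section and locate its centroid
#'
#' Thresholds the union of the stain channels, removes small detached
#' components (stain artefacts dislodged during sectioning), fills interior
#' holes (the unstained anoxic core) and returns the spheroid mask together
#' with the intensity-weighted centroid.
#'
#' @param image A [section_image()].
#' @param threshold Either `"otsu"` (default) or a numeric threshold on the
#'   \[0, 1\] intensity scale.
#' @param min_area_frac Connected components smaller than this fraction of
#'   the largest component are discarded as artefacts (default 0.01).
#' @param mask Optional manual logical mask applied before segmentation
#'   (TRUE = keep pixel).
#' @return A list with `mask` (logical matrix), `centroid` (c(x, y) pixel
#'   coordinates), and `threshold` (the value used).
#' @export
segment_and_centroid <- function(image, threshold = "otsu",
                                 min_area_frac = 0.01, mask = NULL) {
  if (!inherits(image, "section_image")) stop_invalid("not a section_image")
  intens <- stain_union(image)
  if (!is.null(mask)) intens[!mask] <- 0
  thr <- if (identical(threshold, "otsu")) otsu_threshold(intens)
         else assert_scalar_pos(threshold, "threshold", allow_zero = TRUE)
  bw <- intens > thr
  if (!any(bw)) stop_measurement("no spheroid detected (empty mask)")
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_frac * max(sizes))
  bw <- matrix(lab %in% keep, nrow(bw), ncol(bw))
  bw <- fill_holes(bw)
  w <- intens * bw
  # fill the core with the stain threshold weight so the centroid is that of
  # the whole spheroid, not just the stained annulus
  w[bw & intens <= thr] <- thr
  tot <- sum(w)
  cols <- matrix(seq_len(ncol(bw)), nrow(bw), ncol(bw), byrow = TRUE)
  rows <- matrix(seq_len(nrow(bw)), nrow(bw), ncol(bw))
  centroid <- c(x = sum(w * cols) / tot, y = sum(w * rows) / tot)
  list(mask = bw, centroid = centroid, threshold = thr)
}
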