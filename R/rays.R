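# Ray geometry shared by the boundary detectors: 360 rays at 1 degree steps,
# angle origin along the image +x axis, counter-clockwise (y axis points
# down, so the y direction component is negated). Radial sampling step
# 0.25 px with bilinear interpolation, for sub-pixel stability.

RAY_STEP_PX <- 0.25

ray_directions <- function(angles_deg = 0:359) {
  th <- angles_deg * pi / 180
  cbind(dx = cos(th), dy = -sin(th))
}

# Distance from the centroid to the image border along each ray.
ray_max_radius <- function(dim_img, centroid, dirs) {
  nr <- dim_img[1]; nc <- dim_img[2]
  lim <- function(d, lo, hi, c0) {
    out <- rep(Inf, length(d))
    pos <- d > 1e-12; neg <- d < -1e-12
    out[pos] <- (hi - c0) / d[pos]
    out[neg] <- (lo - c0) / d[neg]
    out
  }
  pmax(0, pmin(lim(dirs[, "dx"], 1, nc, centroid[["x"]]),
               lim(dirs[, "dy"], 1, nr, centroid[["y"]])))
}

# Sample a matrix along all rays at once; returns list(radii, values matrix
# [n_angles x n_steps], rmax per angle).
sample_rays <- function(m, centroid, angles_deg = 0:359, step = RAY_STEP_PX) {
  dirs <- ray_directions(angles_deg)
  rmax <- ray_max_radius(dim(m), centroid, dirs)
  radii <- seq(0, max(rmax), by = step)
  xs <- outer(dirs[, "dx"], radii) + centroid[["x"]]
  ys <- outer(dirs[, "dy"], radii) + centroid[["y"]]
  vals <- matrix(interp_bilinear(m, as.numeric(xs), as.numeric(ys)),
                 nrow = length(angles_deg))
  valid <- outer(rmax, radii, `>=`)
  vals[!valid] <- NA_real_
  list(radii = radii, values = vals, rmax = rmax, angles_deg = angles_deg)
}

#' Detect the outer spheroid boundary along 360 rays
#'
#' For every 1-degree ray from the centroid, the outer radius is the largest
#' radius at which the spheroid mask is occupied, found by stepping back from
#' the image edge towards the centroid.
#'
#' @param mask Logical spheroid mask (from [segment_and_centroid()]).
#' @param centroid Pixel coordinates `c(x, y)` of the spheroid centroid.
#' @return Numeric vector of 360 per-angle radii in pixels (NA where the ray
#'   never meets the mask); a warning is issued if more than 10\% of rays are
#'   flagged.
#' @export
detect_outer_boundary <- function(mask, centroid) {
  s <- sample_rays(mask * 1, centroid)
  occ <- !is.na(s$values) & s$values >= 0.5
  r_o <- apply(occ, 1L, function(z) {
    i <- which(z)
    if (length(i) == 0L) NA_real_ else s$radii[max(i)]
  })
  if (mean(is.na(r_o)) > 0.10)
    warning("more than 10% of rays never intersect the spheroid mask")
  r_o
}

#' Detect the anoxic-core boundary along 360 rays
#'
#' For every 1-degree ray, the core radius r_n is the smallest radius at
#' which the stain intensity (union of stain channels by default) exceeds the
#' threshold, marching outward from the centroid. A spheroid without an
#' unstained core yields radii at (sub-pixel) zero.
#'
#' @param image A [section_image()].
#' @param centroid Pixel coordinates `c(x, y)`.
#' @param threshold `"otsu"` or numeric intensity threshold.
#' @param channels Channel names defining "stained"; default all stain
#'   channels.
#' @return Numeric vector of 360 per-angle radii in pixels (NA where no
#'   supra-threshold intensity is found along the ray).
#' @export
detect_anoxic_boundary <- function(image, centroid, threshold = "otsu",
                                   channels = NULL) {
  if (!inherits(image, "section_image")) stop_invalid("not a section_image")
  if (is.null(channels)) channels <- stain_channels(image)
  intens <- Reduce(pmax, image$channels[channels])
  thr <- if (identical(threshold, "otsu")) otsu_threshold(intens)
         else assert_scalar_pos(threshold, "threshold", allow_zero = TRUE)
  s <- sample_rays(intens, centroid)
  above <- !is.na(s$values) & s$values > thr
  vapply(seq_len(nrow(above)), function(i) {
    j <- which(above[i, ])
    if (length(j) == 0L) NA_real_ else s$radii[min(j)]
  }, numeric(1))
}

#' Detect the hypoxic/oxic stain interface along 360 rays
#'
#' Along each ray the normalised proliferation- and hypoxia-stain profiles
#' are compared at radii where stain is actually present (above threshold).
#' The detected interface is the outermost point of hypoxia-stain dominance:
#' where the profile hands over to proliferation-stain dominance the
#' crossing radius is interpolated. Detached hypoxia-stain artefacts beyond
#' the spheroid produce detections outside the viable rim; any detection
#' beyond the per-angle r_o or inside r_n is counted as an artefact and
#' excluded with a recorded reason, and rays with no hypoxia-dominant stain
#' at all are flagged missing. A cohort-level orientation sanity check
#' (proliferation stain must on average lie outside the hypoxia stain)
#' rejects swapped channel assignments outright.
#'
#' @param image A [section_image()].
#' @param centroid Pixel coordinates `c(x, y)`.
#' @param r_o,r_n Per-angle boundary radii in pixels (from the other
#'   detectors).
#' @param hypoxia,proliferation Channel names.
#' @param threshold `"otsu"` or numeric: minimum stain level for a radius to
#'   be considered part of the section.
#' @return List with `r_interface` (360 radii in px, NA where missing or
#'   excluded) and `excluded` (character vector of reasons, NA where none).
#' @export
detect_stain_interface <- function(image, centroid, r_o, r_n,
                                   hypoxia = "hypoxia",
                                   proliferation = "proliferation",
                                   threshold = "otsu") {
  if (!inherits(image, "section_image")) stop_invalid("not a section_image")
  for (nm in c(hypoxia, proliferation))
    if (!nm %in% names(image$channels))
      stop_invalid(sprintf("channel '%s' not present", nm))
  hyp <- image$channels[[hypoxia]]
  pro <- image$channels[[proliferation]]
  norm <- function(m) if (max(m) > 0) m / max(m) else m
  hyp_n <- norm(hyp); pro_n <- norm(pro)
  present <- pmax(hyp_n, pro_n)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(present)
         else assert_scalar_pos(threshold, "threshold", allow_zero = TRUE)

  sh <- sample_rays(hyp_n, centroid)
  sp <- sample_rays(pro_n, centroid)
  diffs <- sp$values - sh$values
  cand <- !is.na(diffs) & pmax(sp$values, sh$values, na.rm = FALSE) > thr

  # orientation sanity check: over the whole section, proliferation-dominant
  # stain must sit at larger radii than hypoxia-dominant stain
  radii <- sh$radii
  rmat <- matrix(radii, nrow = nrow(diffs), ncol = length(radii), byrow = TRUE)
  red_r <- rmat[cand & diffs <= 0]
  green_r <- rmat[cand & diffs > 0]
  if (length(red_r) == 0L || length(green_r) == 0L ||
      mean(green_r) <= mean(red_r))
    stop_measurement(
      "stain channels appear swapped: proliferation stain does not lie outside hypoxia stain")

  n <- length(sh$angles_deg)
  r_int <- rep(NA_real_, n)
  excluded <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    d <- diffs[i, ]
    ok <- cand[i, ]
    red <- which(ok & d <= 0)
    if (length(red) == 0L) next # missing: no hypoxia-dominant stain
    jj <- max(red) # outermost hypoxia-dominant sample
    if (jj < length(d) && isTRUE(ok[jj + 1L]) && d[jj + 1L] > 0) {
      # interpolate the dominance crossing
      frac <- (0 - d[jj]) / (d[jj + 1L] - d[jj])
      r <- radii[jj] + frac * (radii[jj + 1L] - radii[jj])
    } else {
      r <- radii[jj]
    }
    if (!is.na(r_o[i]) && r > r_o[i] + 0.5) {
      excluded[i] <- "beyond_r_o"
    } else if (!is.na(r_n[i]) && r < r_n[i] - 0.5) {
      excluded[i] <- "inside_r_n"
    } else {
      r_int[i] <- r
    }
  }
  if (all(is.na(r_int)))
    stop_measurement("stain interface undetectable on every ray")
  list(r_interface = r_int, excluded = excluded)
}

#' Measure all boundaries of one section
#'
#' Convenience wrapper running segmentation, centroid location and the three
#' 360-ray boundary detectors.
#'
#' @param image A [section_image()].
#' @param threshold `"otsu"` or numeric intensity threshold.
#' @param min_area_frac Artefact-size pre-filter, see [segment_and_centroid()].
#' @param interface Logical: also detect the hypoxic/oxic stain interface
#'   (requires both stain channels).
#' @return An object of class `ray_measurements`: a list with `angles_deg`,
#'   `r_o_px`, `r_n_px`, `r_interface_px`, `excluded`, `centroid`, `scale`.
#' @export
measure_section <- function(image, threshold = "otsu", min_area_frac = 0.01,
                            interface = TRUE) {
  seg <- segment_and_centroid(image, threshold, min_area_frac)
  r_o <- detect_outer_boundary(seg$mask, seg$centroid)
  r_n <- detect_anoxic_boundary(image, seg$centroid, threshold)
  # a stained centroid pixel means there is no unstained core
  r_n[!is.na(r_n) & r_n <= 2 * RAY_STEP_PX] <- 0
  res <- list(angles_deg = 0:359, r_o_px = r_o, r_n_px = r_n,
              r_interface_px = rep(NA_real_, 360),
              excluded = rep(NA_character_, 360),
              centroid = seg$centroid, threshold = seg$threshold,
              scale = image$scale)
  if (interface &&
      all(c("hypoxia", "proliferation") %in% names(image$channels))) {
    int <- detect_stain_interface(image, seg$centroid, r_o, r_n,
                                  threshold = threshold)
    res$r_interface_px <- int$r_interface
    res$excluded <- int$excluded
  }
  structure(res, class = "ray_measurements")
}

#' @export
print.ray_measurements <- function(x, ...) {
  cat(sprintf("360-ray boundary measurements (centroid %.1f, %.1f px):\n",
              x$centroid[["x"]], x$centroid[["y"]]))
  print(summarize_rays(x))
  invisible(x)
}

#' Summarise per-ray boundary measurements
#'
#' Means and population standard deviations over the non-excluded rays, for
#' r_o, r_n, r_c (= r_o - r_n per ray) and the stain interface, converted to
#' micrometres.
#'
#' @param rays A `ray_measurements` object from [measure_section()].
#' @param scale Micrometres per pixel; defaults to the scale recorded in
#'   `rays`.
#' @return A data frame with columns `quantity`, `mean_um`, `sd_um`, `n_rays`.
#' @export
summarize_rays <- function(rays, scale = rays$scale) {
  if (!inherits(rays, "ray_measurements")) stop_invalid("not ray_measurements")
  assert_scalar_pos(scale, "scale")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  row <- function(name, v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(data.frame(quantity = name, mean_um = NA_real_, sd_um = NA_real_,
                        n_rays = 0L))
    data.frame(quantity = name, mean_um = mean(v) * scale,
               sd_um = pop_sd(v) * scale, n_rays = length(v))
  }
  r_c <- rays$r_o_px - rays$r_n_px
  out <- rbind(row("r_o", rays$r_o_px), row("r_n", rays$r_n_px),
               row("r_c", r_c), row("r_interface", rays$r_interface_px))
  if (out$n_rays[1] == 0L)
    stop_measurement("no valid rays to summarise")
  out
}
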