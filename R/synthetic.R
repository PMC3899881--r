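# Seeded, ground-truthed synthetic dual-stained spheroid sections. The
# rendered geometry follows the oxygen model exactly: an unstained anoxic
# core out to r_n, a hypoxia-stain annulus from r_n to the isobar radius at
# the interface pressure, and a proliferation-stain annulus out to r_o.
# Section-deformation realism comes from smooth low-order angular jitter,
# an elliptical warp, Gaussian optical blur, background noise and detached
# stain artefacts.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic spheroid section
#'
#' Ground-truth geometry plus rendering parameters for [render_section()].
#'
#' @param r_o_um Outer radius, micrometres.
#' @param r_l_um Ground-truth diffusion limit, micrometres.
#' @param p_interface_mmHg Partial pressure defining the hypoxic/oxic stain
#'   interface (default 10, the maximal-binding threshold of common
#'   2-nitroimidazole hypoxia markers).
#' @param scale_um_per_px Physical pixel size of the rendered image.
#' @param ellipticity Axis ratio in (0.7, 1\]; default 0.95, a slight
#'   sectioning deformation; 1 = circular section.
#' @param jitter_um RMS amplitude (micrometres, on the outer boundary) of the
#'   smooth angular boundary perturbation. The default of 20 um matches the
#'   16-30 um per-image boundary standard deviations reported for real
#'   dual-stained sections.
#' @param jitter_orders Angular orders of the perturbation sinusoids.
#' @param noise_sd Gaussian background noise s.d. on the \[0, 1\] intensity
#'   scale.
#' @param n_artifacts Number of detached stain blobs rendered outside the
#'   spheroid (sectioning debris that real analyses must exclude).
#' @param blur_px Gaussian optical blur sigma in pixels.
#' @param seed RNG seed; rendering is fully deterministic given the spec.
#' @param params An [oxygen_params()] object.
#' @return An object of class `synthetic_spheroid_spec`.
#' @export
synthetic_spheroid_spec <- function(r_o_um, r_l_um = 233,
                                    p_interface_mmHg = 10,
                                    scale_um_per_px = 2.5,
                                    ellipticity = 0.95,
                                    jitter_um = 20,
                                    jitter_orders = 2:6,
                                    noise_sd = 0.05,
                                    n_artifacts = 2L,
                                    blur_px = 2,
                                    seed = 1L,
                                    params = oxygen_params()) {
  assert_scalar_pos(r_o_um, "r_o_um")
  assert_scalar_pos(r_l_um, "r_l_um")
  assert_scalar_pos(scale_um_per_px, "scale_um_per_px")
  if (ellipticity <= 0.7 || ellipticity > 1)
    stop_invalid("ellipticity must lie in (0.7, 1]")
  assert_scalar_pos(jitter_um, "jitter_um", allow_zero = TRUE)
  assert_scalar_pos(noise_sd, "noise_sd", allow_zero = TRUE)
  assert_scalar_pos(blur_px, "blur_px", allow_zero = TRUE)
  assert_params(params)
  if (p_interface_mmHg <= 0 || p_interface_mmHg >= params$p_o)
    stop_invalid("p_interface_mmHg must lie strictly between 0 and p_o")
  structure(list(r_o_um = r_o_um, r_l_um = r_l_um,
                 p_interface_mmHg = p_interface_mmHg,
                 scale_um_per_px = scale_um_per_px,
                 ellipticity = ellipticity, jitter_um = jitter_um,
                 jitter_orders = as.integer(jitter_orders),
                 noise_sd = noise_sd, n_artifacts = as.integer(n_artifacts),
                 blur_px = blur_px, seed = as.integer(seed), params = params),
            class = "synthetic_spheroid_spec")
}

#' Render a synthetic dual-stained spheroid section
#'
#' Renders the three concentric stain regions implied by the oxygen model for
#' the spec's geometry, applies angular jitter, elliptical warp, blur, noise
#' and detached stain artefacts, and records the exact per-angle ground-truth
#' boundaries.
#'
#' @param spec A [synthetic_spheroid_spec()].
#' @return A list with `image` (a [section_image()]) and `truth` (per-angle
#'   ground-truth radii in px and um, plus the generating geometry and
#'   consumption rate).
#' @export
render_section <- function(spec) {
  if (!inherits(spec, "synthetic_spheroid_spec"))
    stop_invalid("not a synthetic_spheroid_spec")
  params <- spec$params
  r_o <- spec$r_o_um * 1e-6
  r_l <- spec$r_l_um * 1e-6
  geom <- solve_anoxic_radius(r_o, r_l)
  a <- estimate_consumption(r_l, params)
  p_c <- partial_pressure(0, geom, params)
  if (geom$r_n == 0 && p_c >= spec$p_interface_mmHg)
    stop_invalid(sprintf(
      "invalid spec: interface pressure %.3g mmHg is below the central pressure %.3g mmHg (no hypoxic region)",
      spec$p_interface_mmHg, p_c))
  r_int <- isobar_radius(spec$p_interface_mmHg, geom, params)
  r_n_um <- geom$r_n * 1e6
  r_int_um <- r_int * 1e6
  if (!(r_int_um > r_n_um && r_int_um < spec$r_o_um))
    stop_invalid("invalid spec: interface radius outside (r_n, r_o)")

  scale <- spec$scale_um_per_px
  half <- ceiling(spec$r_o_um * 1.2 / scale)
  npx <- 2L * half + 1L
  cx <- half + 1; cy <- half + 1

  with_seed(spec$seed, {
    ks <- spec$jitter_orders
    amp_k <- stats::runif(length(ks), 0.5, 1)
    phi_k <- stats::runif(length(ks), 0, 2 * pi)
    rms <- sqrt(sum(amp_k^2) / 2)
    jitter_rel <- if (spec$jitter_um > 0) spec$jitter_um / spec$r_o_um else 0
    deform <- function(theta) {
      s <- 0
      for (m in seq_along(ks))
        s <- s + amp_k[m] * sin(ks[m] * theta + phi_k[m])
      1 + jitter_rel * s / rms
    }
    e <- spec$ellipticity
    ell <- function(theta) sqrt(cos(theta)^2 + sin(theta)^2 / e^2)

    # per-pixel region assignment
    cols <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
    rows <- matrix(seq_len(npx), npx, npx)
    dx <- cols - cx; dy <- rows - cy
    theta <- atan2(-dy, dx)
    t_px <- sqrt(dx^2 + dy^2)
    warp <- deform(theta) / (scale * ell(theta)) # um -> px at each pixel
    t_o <- spec$r_o_um * warp
    t_n <- r_n_um * warp
    t_i <- r_int_um * warp

    hyp <- 0.9 * (t_px > t_n & t_px <= t_i)
    pro <- 0.9 * (t_px > t_i & t_px <= t_o)
    nuc <- 0.7 * (t_px <= t_o)
    if (r_n_um == 0) hyp <- 0.9 * (t_px <= t_i)

    if (spec$n_artifacts > 0L) {
      edge <- half
      for (k in seq_len(spec$n_artifacts)) {
        th <- stats::runif(1, 0, 2 * pi)
        rmin <- min(max(t_o) * 1.05, edge * 0.85)
        rad <- stats::runif(1, rmin, edge * 0.95)
        bx <- cx + rad * cos(th); by <- cy - rad * sin(th)
        br <- stats::runif(1, 2, 5)
        blob <- (cols - bx)^2 + (rows - by)^2 <= br^2
        if (stats::runif(1) < 0.5) hyp[blob] <- 0.8 else pro[blob] <- 0.8
      }
    }

    chans <- list(hypoxia = hyp, proliferation = pro, nuclear = nuc)
    chans <- lapply(chans, gaussian_blur, sigma = spec$blur_px)
    if (spec$noise_sd > 0)
      chans <- lapply(chans, function(m)
        m + matrix(stats::rnorm(length(m), 0, spec$noise_sd), nrow(m)))
    chans <- lapply(chans, function(m) pmin(pmax(m, 0), 1))

    th_deg <- (0:359) * pi / 180
    warp_deg <- deform(th_deg) / (scale * ell(th_deg))
    truth <- list(
      angles_deg = 0:359,
      r_o_px = spec$r_o_um * warp_deg,
      r_n_px = r_n_um * warp_deg,
      r_interface_px = r_int_um * warp_deg,
      centroid = c(x = cx, y = cy),
      r_o_um = spec$r_o_um, r_n_um = r_n_um, r_interface_um = r_int_um,
      r_l_um = spec$r_l_um, a_volumetric = a$a_volumetric,
      geometry = geom, spec = spec
    )
    list(image = section_image(chans, scale), truth = truth)
  })
}

#' Generate a cohort of synthetic spheroid sections
#'
#' Renders `n` sections with outer radii evenly covering `r_o_range` (in
#' ascending size order) under a single ground-truth diffusion limit, the
#' situation the estimation pipeline assumes when consumption is constant.
#'
#' @param n Number of spheroids (>= 1).
#' @param r_o_range Range of outer radii, micrometres (length 2, increasing;
#'   equal values permitted only for n = 1).
#' @param r_l_um Ground-truth diffusion limit, micrometres.
#' @param seed Cohort-level seed; each section gets a derived sub-seed.
#' @param ... Further fields passed to [synthetic_spheroid_spec()].
#' @return An object of class `spheroid_cohort`: list of `sections`
#'   (render_section outputs) and a `manifest` data frame (columns `id`,
#'   `file`, `r_o_um`, `r_n_um`, `r_interface_um`, `r_l_um`, `a_vol`, `seed`).
#' @export
generate_cohort <- function(n, r_o_range = c(250, 500), r_l_um = 233,
                            seed = 1L, ...) {
  n <- as.integer(assert_scalar_pos(n, "n"))
  if (length(r_o_range) != 2L || !is.numeric(r_o_range) ||
      r_o_range[2] < r_o_range[1] || (n > 1L && r_o_range[2] == r_o_range[1]))
    stop_invalid("degenerate r_o_range")
  r_os <- if (n == 1L) mean(r_o_range) else
    seq(r_o_range[1], r_o_range[2], length.out = n)
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- synthetic_spheroid_spec(r_o_um = r_os[i], r_l_um = r_l_um,
                                  seed = (seed + 7919L * i) %% .Machine$integer.max,
                                  ...)
    sections[[i]] <- render_section(sp)
  }
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- sections[[i]]$truth
    data.frame(id = i, file = NA_character_, r_o_um = tr$r_o_um,
               r_n_um = tr$r_n_um, r_interface_um = tr$r_interface_um,
               r_l_um = tr$r_l_um, a_vol = tr$a_volumetric,
               seed = tr$spec$seed)
  }))
  structure(list(sections = sections, manifest = manifest,
                 r_l_um = r_l_um, seed = seed),
            class = "spheroid_cohort")
}

#' Re-render a cohort under a linear consumption-rate drift
#'
#' Emulates a consumption rate that decreases linearly across the
#' size-ordered dataset by a total fraction `drop_fraction`: spheroid i of n
#' is re-rendered with \eqn{a_i = a_1 (1 - f (i-1)/(n-1))}, hence a diffusion
#' limit growing as \eqn{r_{l,i} = r_{l,1} / \sqrt{1 - f (i-1)/(n-1)}}.
#' Used to test the consumption-drift sensitivity analysis against data whose
#' generating model is known.
#'
#' @param cohort A `spheroid_cohort` from [generate_cohort()].
#' @param drop_fraction Total fractional drop in \[0, 1).
#' @return A new `spheroid_cohort` with drifted ground truth.
#' @export
apply_consumption_drift <- function(cohort, drop_fraction) {
  if (!inherits(cohort, "spheroid_cohort")) stop_invalid("not a spheroid_cohort")
  if (!is.numeric(drop_fraction) || length(drop_fraction) != 1L ||
      drop_fraction < 0 || drop_fraction >= 1)
    stop_invalid("drop_fraction must lie in [0, 1)")
  n <- length(cohort$sections)
  frac <- if (n == 1L) 0 else drop_fraction * (seq_len(n) - 1) / (n - 1)
  sections <- vector("list", n)
  for (i in seq_len(n)) {
    sp0 <- cohort$sections[[i]]$truth$spec
    sp <- sp0
    sp$r_l_um <- sp0$r_l_um / sqrt(1 - frac[i])
    class(sp) <- class(sp0)
    sections[[i]] <- render_section(sp)
  }
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- sections[[i]]$truth
    data.frame(id = i, file = NA_character_, r_o_um = tr$r_o_um,
               r_n_um = tr$r_n_um, r_interface_um = tr$r_interface_um,
               r_l_um = tr$r_l_um, a_vol = tr$a_volumetric,
               seed = tr$spec$seed)
  }))
  structure(list(sections = sections, manifest = manifest,
                 r_l_um = cohort$r_l_um, seed = cohort$seed,
                 drop_fraction = drop_fraction),
            class = "spheroid_cohort")
}

#' Write a cohort to disk
#'
#' Writes one image per section (PNG by default, or plain-text PPM) plus a
#' `manifest.csv` with the ground truth per image.
#'
#' @param cohort A `spheroid_cohort`.
#' @param dir Output directory (created if needed).
#' @param format `"png"` or `"ppm"`.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("png", "ppm")) {
  if (!inherits(cohort, "spheroid_cohort")) stop_invalid("not a spheroid_cohort")
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  for (i in seq_along(cohort$sections)) {
    f <- file.path(dir, sprintf("spheroid_%02d.%s", i, format))
    write_section(cohort$sections[[i]]$image, f)
    manifest$file[i] <- f
  }
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  invisible(mf)
}
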