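#' Analyse one spheroid section
#'
#' Full per-spheroid estimation chain: measure the boundaries (360-ray
#' detection), convert the mean radii to metres, estimate the diffusion limit
#' from the boundaries, invert it to a consumption rate, and predict the
#' radius of the interface isobar.
#'
#' @param x A [section_image()], a `render_section()` result, or a path to an
#'   image file (in which case `scale` is mandatory).
#' @param scale Micrometres per pixel (required for paths; defaults to the
#'   image's own scale otherwise).
#' @param params An [oxygen_params()] object.
#' @param p_interface Interface pressure used for the isobar prediction,
#'   mmHg.
#' @param threshold Threshold passed to the detectors (`"otsu"` or numeric).
#' @return An object of class `spheroid_estimate` with the boundary summary,
#'   `r_l_um`, the consumption rate `a`, the predicted interface radius
#'   `r_p_pred_um`, the measured interface radius `r_interface_um` and a
#'   `sub_limit` flag (TRUE when no anoxic core was found, in which case
#'   `r_l_um` equals the outer radius and is only a lower bound).
#' @export
analyze_section <- function(x, scale = NULL, params = oxygen_params(),
                            p_interface = 10, threshold = "otsu") {
  assert_params(params)
  file <- NA_character_
  if (is.character(x)) {
    if (is.null(scale)) stop_invalid("'scale' is mandatory when reading from file")
    file <- x
    x <- read_section(x, scale)
  } else if (is.list(x) && !inherits(x, "section_image") &&
             !is.null(x$image)) {
    x <- x$image
  }
  if (!inherits(x, "section_image")) stop_invalid("cannot interpret input image")
  if (is.null(scale)) scale <- x$scale

  rays <- measure_section(x, threshold = threshold)
  summ <- summarize_rays(rays, scale)
  g <- function(q) summ$mean_um[summ$quantity == q]
  r_o_um <- g("r_o")
  r_n_um <- g("r_n")
  if (is.na(r_n_um)) r_n_um <- 0
  sub_limit <- r_n_um < scale # less than one pixel of core
  if (sub_limit) r_n_um <- 0

  r_o <- r_o_um * 1e-6
  r_n <- r_n_um * 1e-6
  r_l <- estimate_rl_from_boundaries(r_o, r_n)
  a <- estimate_consumption(r_l, params)
  geom <- spheroid_geometry(r_o, r_n, r_l)
  r_p_pred <- if (sub_limit && p_interface < partial_pressure(0, geom, params))
    NA_real_ else isobar_radius(p_interface, geom, params)

  structure(list(file = file, summary = summ, rays = rays,
                 r_o_um = r_o_um, r_n_um = r_n_um,
                 r_l_um = r_l * 1e6, a = a,
                 p_interface = p_interface,
                 r_p_pred_um = r_p_pred * 1e6,
                 r_interface_um = g("r_interface"),
                 sub_limit = sub_limit, params = params),
            class = "spheroid_estimate")
}

#' @export
print.spheroid_estimate <- function(x, ...) {
  cat(sprintf("Spheroid estimate%s:\n",
              if (!is.na(x$file)) paste0(" (", basename(x$file), ")") else ""))
  cat(sprintf("  r_o = %.1f um, r_n = %.1f um%s\n", x$r_o_um, x$r_n_um,
              if (x$sub_limit) " [sub-limit: no anoxic core]" else ""))
  cat(sprintf("  r_l = %.1f um%s, a = %.3g m^3 kg^-1 s^-1 (%.3g mol kg^-1 min^-1)\n",
              x$r_l_um, if (x$sub_limit) " (lower bound)" else "",
              x$a$a_volumetric, x$a$a_molar))
  cat(sprintf("  predicted r_p(%g mmHg) = %.1f um, measured interface = %.1f um\n",
              x$p_interface, x$r_p_pred_um, x$r_interface_um))
  invisible(x)
}

#' Aggregate per-spheroid estimates
#'
#' Pools per-spheroid diffusion limits into a cohort estimate: mean and
#' (sample) standard deviation of r_l, the consumption rate evaluated at the
#' mean, and the rate re-evaluated at mean +/- 1 s.d. — the asymmetric bounds
#' a three-row consumption table presents. The s.d. is reported as NA (not
#' zero) for a single spheroid.
#'
#' @param estimates List of `spheroid_estimate` objects (or a single one).
#' @param params An [oxygen_params()] object.
#' @return An object of class `cohort_result` with `per_spheroid` (data
#'   frame), `r_l_mean_um`, `r_l_sd_um`, `a` (a [consumption_rate()] at the
#'   mean) and `table1` (the three-row rate table).
#' @export
aggregate_cohort <- function(estimates, params = oxygen_params()) {
  if (inherits(estimates, "spheroid_estimate")) estimates <- list(estimates)
  if (!is.list(estimates) || length(estimates) == 0L ||
      !all(vapply(estimates, inherits, logical(1), "spheroid_estimate")))
    stop_invalid("'estimates' must be a non-empty list of spheroid_estimate")
  per <- do.call(rbind, lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(id = i, file = e$file, r_o_um = e$r_o_um, r_n_um = e$r_n_um,
               r_l_um = e$r_l_um, a_vol = e$a$a_volumetric,
               r_p_pred_um = e$r_p_pred_um,
               r_interface_um = e$r_interface_um, sub_limit = e$sub_limit)
  }))
  rl_mean <- mean(per$r_l_um)
  rl_sd <- if (nrow(per) > 1L) stats::sd(per$r_l_um) else NA_real_
  a_mean <- estimate_consumption(rl_mean * 1e-6, params)
  rows <- data.frame(value = "mean", r_l_um = rl_mean,
                     a_vol = a_mean$a_volumetric, a_molar = a_mean$a_molar)
  if (!is.na(rl_sd) && rl_sd > 0) {
    a_lo <- estimate_consumption((rl_mean - rl_sd) * 1e-6, params)
    a_hi <- estimate_consumption((rl_mean + rl_sd) * 1e-6, params)
    rows <- rbind(rows,
      data.frame(value = "mean - 1 s.d.", r_l_um = rl_mean - rl_sd,
                 a_vol = a_lo$a_volumetric, a_molar = a_lo$a_molar),
      data.frame(value = "mean + 1 s.d.", r_l_um = rl_mean + rl_sd,
                 a_vol = a_hi$a_volumetric, a_molar = a_hi$a_molar))
  }
  structure(list(per_spheroid = per, r_l_mean_um = rl_mean,
                 r_l_sd_um = rl_sd, a = a_mean, table1 = rows,
                 estimates = estimates, params = params),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort of %d spheroids:\n", nrow(x$per_spheroid)))
  cat(sprintf("  r_l = %.1f +/- %.1f um\n", x$r_l_mean_um, x$r_l_sd_um))
  cat(sprintf("  a   = %.3g m^3 kg^-1 s^-1 (%.3g mol kg^-1 min^-1)\n",
              x$a$a_volumetric, x$a$a_molar))
  cat("Consumption-rate table:\n")
  print(x$table1, row.names = FALSE)
  invisible(x)
}

# Model-predicted interface radii for the cohort's measured r_o under a
# given per-spheroid consumption schedule (um in, um out).
predict_interfaces <- function(r_o_um, a_vol, p_interface, params) {
  vapply(seq_along(r_o_um), function(i) {
    r_l <- diffusion_limit(a_vol[i], params)
    geom <- solve_anoxic_radius(r_o_um[i] * 1e-6, r_l)
    if (geom$r_n == 0 && p_interface < partial_pressure(0, geom, params))
      return(NA_real_)
    isobar_radius(p_interface, geom, params) * 1e6
  }, numeric(1))
}

r_squared <- function(measured, predicted) {
  ok <- !is.na(measured) & !is.na(predicted)
  measured <- measured[ok]; predicted <- predicted[ok]
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) {
    warning("zero-variance measurements: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Compare model-predicted and measured interface radii
#'
#' Predicts the interface isobar radius for each spheroid from its measured
#' outer radius and the cohort-aggregate diffusion limit, and quantifies the
#' agreement with the measured interface radii as the coefficient of
#' determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (which may be negative
#' when the model fits worse than the measurement mean).
#'
#' @param result A `cohort_result` from [aggregate_cohort()].
#' @param p_interface Interface pressure, mmHg.
#' @param r_l_um Diffusion limit to use for prediction; defaults to the
#'   cohort aggregate.
#' @return List with `r_squared`, and a `table` of per-spheroid measured and
#'   predicted radii (um).
#' @export
compare_interface <- function(result, p_interface = 10, r_l_um = NULL) {
  if (!inherits(result, "cohort_result")) stop_invalid("not a cohort_result")
  per <- result$per_spheroid
  per <- per[!is.na(per$r_interface_um), , drop = FALSE]
  if (nrow(per) < 2L)
    stop_invalid("need >= 2 spheroids with measured interfaces")
  if (is.null(r_l_um)) r_l_um <- result$r_l_mean_um
  a_agg <- estimate_consumption(r_l_um * 1e-6, result$params)$a_volumetric
  pred <- predict_interfaces(per$r_o_um, rep(a_agg, nrow(per)),
                             p_interface, result$params)
  tab <- data.frame(id = per$id, r_o_um = per$r_o_um,
                    measured_um = per$r_interface_um, predicted_um = pred)
  list(r_squared = r_squared(tab$measured_um, tab$predicted_um), table = tab)
}

#' Sensitivity of the interface fit to a drifting consumption rate
#'
#' Re-fits the interface predictions under consumption rates that drop
#' linearly across the size-ordered cohort by each stated total fraction,
#' anchored at the cohort-aggregate rate for the smallest spheroid (a drop of
#' 0 reproduces [compare_interface()] exactly). On measurements generated
#' under constant consumption the fit degrades monotonically as the imposed
#' drop grows, turning negative at large drops.
#'
#' @param result A `cohort_result`.
#' @param drops Fractions in \[0, 1) to evaluate.
#' @param p_interface Interface pressure, mmHg.
#' @return Data frame with columns `drop` and `r_squared`.
#' @export
sensitivity_consumption_drift <- function(result,
                                          drops = c(0, 0.10, 0.20, 0.50, 0.75),
                                          p_interface = 10) {
  if (!inherits(result, "cohort_result")) stop_invalid("not a cohort_result")
  if (any(drops < 0 | drops >= 1)) stop_invalid("drops must lie in [0, 1)")
  per <- result$per_spheroid
  per <- per[!is.na(per$r_interface_um), , drop = FALSE]
  if (nrow(per) < 2L)
    stop_invalid("need >= 2 spheroids with measured interfaces")
  ord <- order(per$r_o_um)
  per <- per[ord, , drop = FALSE]
  n <- nrow(per)
  a0 <- result$a$a_volumetric
  out <- lapply(drops, function(f) {
    a_i <- a0 * (1 - f * (seq_len(n) - 1) / (n - 1))
    pred <- predict_interfaces(per$r_o_um, a_i, p_interface, result$params)
    data.frame(drop = f, r_squared = r_squared(per$r_interface_um, pred))
  })
  do.call(rbind, out)
}

#' Sensitivity of the interface radius to the interface-pressure threshold
#'
#' Evaluates, per spheroid, the isobar radius at both ends of a pressure
#' range (default 8-12 mmHg, i.e. a 20\% error band around the nominal
#' hypoxia-marker binding threshold) and reports the largest absolute
#' difference.
#'
#' @param result A `cohort_result`.
#' @param p_range Length-2 pressure range, mmHg, inside \[0, p_o\].
#' @return List with `max_delta_um` and a per-spheroid `table` (radii at each
#'   endpoint and their difference, um).
#' @export
sensitivity_interface_pressure <- function(result, p_range = c(8, 12)) {
  if (!inherits(result, "cohort_result")) stop_invalid("not a cohort_result")
  if (length(p_range) != 2L || any(p_range < 0 | p_range > result$params$p_o))
    stop_invalid("p_range must be two pressures inside [0, p_o]")
  p_range <- sort(p_range)
  per <- result$per_spheroid
  a_agg <- result$a$a_volumetric
  lo <- predict_interfaces(per$r_o_um, rep(a_agg, nrow(per)), p_range[1],
                           result$params)
  hi <- predict_interfaces(per$r_o_um, rep(a_agg, nrow(per)), p_range[2],
                           result$params)
  tab <- data.frame(id = per$id, r_o_um = per$r_o_um,
                    r_p_lo_um = lo, r_p_hi_um = hi,
                    delta_um = abs(hi - lo))
  list(max_delta_um = max(tab$delta_um, na.rm = TRUE), table = tab)
}

#' Simulated oxygen profiles for spheroids of various sizes
#'
#' Computes (and optionally writes/plots) radial partial-pressure profiles
#' for a set of outer radii at a fixed diffusion limit. Spheroids below the
#' limit retain positive central pressure; larger ones are anoxic out to
#' their core radius.
#'
#' @param r_o_um Vector of outer radii, micrometres.
#' @param r_l_um Diffusion limit, micrometres.
#' @param params An [oxygen_params()] object.
#' @param n Grid points per profile.
#' @param file Optional CSV output path (long format: `r_o_um`, `radius_um`,
#'   `pO2_mmHg`).
#' @param plot If TRUE, draw the profiles on the current graphics device.
#' @return Long-format data frame of the profiles, invisibly when `file` is
#'   given.
#' @export
export_profiles <- function(r_o_um, r_l_um, params = oxygen_params(),
                            n = 401, file = NULL, plot = FALSE) {
  assert_params(params)
  if (!is.numeric(r_o_um) || length(r_o_um) == 0L || any(r_o_um <= 0))
    stop_invalid("r_o_um must be positive")
  assert_scalar_pos(r_l_um, "r_l_um")
  out <- do.call(rbind, lapply(r_o_um, function(ro) {
    geom <- solve_anoxic_radius(ro * 1e-6, r_l_um * 1e-6)
    pr <- oxygen_profile(geom, params, n = n)
    data.frame(r_o_um = ro, radius_um = pr$radius_um, pO2_mmHg = pr$pO2_mmHg)
  }))
  if (plot) {
    graphics::plot(NA, xlim = c(0, max(r_o_um)), ylim = c(0, params$p_o),
                   xlab = "radius (um)", ylab = "pO2 (mmHg)",
                   main = sprintf("Oxygen profiles, r_l = %g um", r_l_um))
    cols <- grDevices::hcl.colors(length(r_o_um), "Dark 2")
    for (i in seq_along(r_o_um)) {
      d <- out[out$r_o_um == r_o_um[i], ]
      graphics::lines(d$radius_um, d$pO2_mmHg, col = cols[i], lwd = 2)
    }
    graphics::legend("topleft", legend = sprintf("r_o = %g um", r_o_um),
                     col = cols, lwd = 2, bty = "n")
  }
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Estimate from tabulated boundary radii
#'
#' Runs the estimation chain on already-measured boundaries (e.g. a CSV with
#' columns `r_o_um` and `r_n_um`, one row per spheroid) instead of images.
#'
#' @param boundaries Data frame with numeric columns `r_o_um` and `r_n_um`
#'   (and optionally `r_interface_um`).
#' @param params An [oxygen_params()] object.
#' @param p_interface Interface pressure for the isobar prediction, mmHg.
#' @return A `cohort_result`.
#' @export
estimate_from_boundaries <- function(boundaries, params = oxygen_params(),
                                     p_interface = 10) {
  if (!is.data.frame(boundaries) ||
      !all(c("r_o_um", "r_n_um") %in% names(boundaries)))
    stop_invalid("boundaries must be a data frame with r_o_um and r_n_um")
  ests <- lapply(seq_len(nrow(boundaries)), function(i) {
    r_o_um <- boundaries$r_o_um[i]
    r_n_um <- boundaries$r_n_um[i]
    r_o <- r_o_um * 1e-6; r_n <- r_n_um * 1e-6
    r_l <- estimate_rl_from_boundaries(r_o, r_n)
    a <- estimate_consumption(r_l, params)
    geom <- spheroid_geometry(r_o, r_n, r_l)
    sub_limit <- r_n_um <= 0
    r_p <- if (sub_limit && p_interface < partial_pressure(0, geom, params))
      NA_real_ else isobar_radius(p_interface, geom, params)
    structure(list(file = NA_character_, summary = NULL, rays = NULL,
                   r_o_um = r_o_um, r_n_um = r_n_um, r_l_um = r_l * 1e6,
                   a = a, p_interface = p_interface,
                   r_p_pred_um = r_p * 1e6,
                   r_interface_um = if ("r_interface_um" %in% names(boundaries))
                     boundaries$r_interface_um[i] else NA_real_,
                   sub_limit = sub_limit, params = params),
              class = "spheroid_estimate")
  })
  aggregate_cohort(ests, params)
}
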