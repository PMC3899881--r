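#' Spherical oxygen diffusion limit
#'
#' The diffusion limit r_l is the largest radius a spheroid can reach while
#' remaining fully oxygenated: the radius at which the central partial
#' pressure just reaches zero. For constant volumetric consumption `a`
#' (m^3 O2 per kg tissue per s),
#' \deqn{r_l = \sqrt{6 D p_o / (a \Omega)}.}
#' It is independent of the actual spheroid radius and inversely related to
#' the square root of the consumption rate.
#'
#' @param a Volumetric oxygen consumption rate, m^3 kg^-1 s^-1, or a
#'   [consumption_rate()] object.
#' @param params An [oxygen_params()] object.
#' @return Diffusion limit in metres.
#' @examples
#' diffusion_limit(7.29e-7) * 1e6  # ~233 um
#' @export
diffusion_limit <- function(a, params = oxygen_params()) {
  assert_params(params)
  if (inherits(a, "consumption_rate")) a <- a$a_volumetric
  assert_scalar_pos(a, "a")
  sqrt(6 * params$D * params$p_o / (a * params$Omega))
}

#' Estimate the consumption rate from the diffusion limit
#'
#' Inverts [diffusion_limit()]: given r_l, the volumetric oxygen consumption
#' rate is \eqn{a = 6 D p_o / (\Omega r_l^2)}.
#'
#' @param r_l Diffusion limit, m.
#' @param params An [oxygen_params()] object.
#' @return A [consumption_rate()] object.
#' @examples
#' estimate_consumption(233e-6)$a_volumetric  # ~7.29e-7 m^3 kg^-1 s^-1
#' @export
estimate_consumption <- function(r_l, params = oxygen_params()) {
  assert_params(params)
  assert_scalar_pos(r_l, "r_l")
  a <- 6 * params$D * params$p_o / (params$Omega * r_l^2)
  consumption_rate(a, params)
}

#' Asymptotic viable-rim limit
#'
#' As a spheroid grows far beyond the diffusion limit, the thickness of its
#' viable (oxygenated) rim decreases asymptotically towards
#' \eqn{r_m = r_l / \sqrt{3}}.
#'
#' @param r_l Diffusion limit, m.
#' @return Rim limit r_m in metres.
#' @export
rim_limit <- function(r_l) {
  assert_scalar_pos(r_l, "r_l")
  r_l / sqrt(3)
}

#' Spheroid geometry container
#'
#' Holds the radial structure of one spheroid: outer radius `r_o`, anoxic
#' core radius `r_n` (0 when the spheroid is below the diffusion limit),
#' viable rim thickness `r_c = r_o - r_n`, the diffusion limit `r_l` and the
#' asymptotic rim limit `r_m = r_l/sqrt(3)`. All lengths in metres.
#'
#' @param r_o Outer radius, m.
#' @param r_n Anoxic core radius, m.
#' @param r_l Diffusion limit, m.
#' @return An object of class `spheroid_geometry`.
#' @export
spheroid_geometry <- function(r_o, r_n, r_l) {
  assert_scalar_pos(r_o, "r_o")
  assert_scalar_pos(r_l, "r_l")
  assert_scalar_pos(r_n, "r_n", allow_zero = TRUE)
  if (r_n >= r_o) stop_invalid("r_n must be smaller than r_o")
  structure(list(r_o = r_o, r_n = r_n, r_c = r_o - r_n,
                 r_l = r_l, r_m = rim_limit(r_l)),
            class = "spheroid_geometry")
}

#' @export
print.spheroid_geometry <- function(x, ...) {
  um <- function(v) sprintf("%.1f um", v * 1e6)
  cat("Spheroid geometry:\n")
  cat(sprintf("  r_o = %s, r_n = %s, r_c = %s\n", um(x$r_o), um(x$r_n), um(x$r_c)))
  cat(sprintf("  r_l = %s (diffusion limit), r_m = %s (rim limit)\n",
              um(x$r_l), um(x$r_m)))
  invisible(x)
}

# Characteristic cubic in normalised variables x = r_n/r_o, lambda = r_l/r_o:
#   g(x) = 2 x^3 - 3 x^2 + 1 - lambda^2
# The physical root lies in (0, 1) whenever lambda < 1 (r_o > r_l):
# g(0) = 1 - lambda^2 > 0 and g(1) = -lambda^2 < 0.
characteristic_cubic <- function(r_n, r_o, r_l) {
  2 * r_n^3 - 3 * r_o * r_n^2 + (r_o^3 - r_l^2 * r_o)
}

#' Solve for the anoxic core radius
#'
#' For a spheroid of outer radius `r_o` with diffusion limit `r_l`, finds the
#' anoxic core radius r_n. Below the limit (`r_o <= r_l`) there is no core
#' (r_n = 0). Above it, r_n is the unique root of the characteristic cubic
#' \deqn{2 r_n^3 - 3 r_o r_n^2 + (r_o^3 - r_l^2 r_o) = 0}
#' in the open interval (0, r_o); it is solved by safeguarded root bracketing
#' in the normalised variable x = r_n/r_o (the bracket is guaranteed by sign
#' analysis of the cubic at the endpoints).
#'
#' @param r_o Outer radius, m.
#' @param r_l Diffusion limit, m.
#' @return A [spheroid_geometry()] with the solved `r_n`.
#' @examples
#' g <- solve_anoxic_radius(300e-6, 233e-6)
#' g$r_n * 1e6  # ~129.2 um
#' @export
solve_anoxic_radius <- function(r_o, r_l) {
  assert_scalar_pos(r_o, "r_o")
  assert_scalar_pos(r_l, "r_l")
  if (r_o <= r_l) return(spheroid_geometry(r_o, 0, r_l))
  lambda2 <- (r_l / r_o)^2
  g <- function(x) 2 * x^3 - 3 * x^2 + 1 - lambda2
  # tol on x translates to ~1e-14 * r_o in metres, well below 1e-12 m
  root <- stats::uniroot(g, c(0, 1), tol = 1e-14)
  x <- root$root
  if (x <= 0 || x >= 1)
    stop("internal error: cubic root escaped (0, r_o)") # nocov
  spheroid_geometry(r_o, x * r_o, r_l)
}

#' Estimate the diffusion limit from measured boundaries
#'
#' Inverts the characteristic cubic: given the measured outer radius and
#' anoxic core radius of a spheroid,
#' \deqn{r_l = \sqrt{r_o^2 + 2 r_n^3/r_o - 3 r_n^2}.}
#' This is the exact inverse of [solve_anoxic_radius()]. With no core
#' (r_n = 0) it returns r_o, which is then only a lower bound on the true
#' diffusion limit.
#'
#' @param r_o Outer radius, m.
#' @param r_n Anoxic core radius, m (0 when absent).
#' @return Diffusion limit in metres.
#' @export
estimate_rl_from_boundaries <- function(r_o, r_n) {
  assert_scalar_pos(r_o, "r_o")
  assert_scalar_pos(r_n, "r_n", allow_zero = TRUE)
  if (r_n >= r_o) stop_invalid("invalid geometry: r_n must be < r_o")
  sqrt(r_o^2 + 2 * r_n^3 / r_o - 3 * r_n^2)
}

# Consumption consistent with a geometry, unless explicitly supplied.
resolve_consumption <- function(geom, a, params) {
  if (is.null(a)) return(estimate_consumption(geom$r_l, params)$a_volumetric)
  if (inherits(a, "consumption_rate")) a <- a$a_volumetric
  assert_scalar_pos(a, "a")
  a
}

#' Oxygen partial pressure at a radius
#'
#' Evaluates the steady-state analytical solution of the spherical
#' reaction-diffusion equation with constant consumption. With an anoxic
#' core (r_n > 0), for r_n < r <= r_o:
#' \deqn{p(r) = \frac{a \Omega}{6 D}\left(r^2 + \frac{2 r_n^3}{r} - 3 r_n^2\right)}
#' and p(r) = 0 for r <= r_n. Without a core the symmetric solution
#' \eqn{p(r) = p_o - (a \Omega / 6D)(r_o^2 - r^2)} applies (clipped at 0).
#'
#' @param r Radius or vector of radii, m, each in \[0, r_o\].
#' @param geom A [spheroid_geometry()].
#' @param params An [oxygen_params()] object.
#' @param a Volumetric consumption rate, m^3 kg^-1 s^-1, or NULL to use the
#'   rate consistent with `geom$r_l` (which makes p(r_o) = p_o exact).
#' @return Partial pressure(s), mmHg.
#' @export
partial_pressure <- function(r, geom, params = oxygen_params(), a = NULL) {
  assert_params(params)
  if (!inherits(geom, "spheroid_geometry"))
    stop_invalid("'geom' must be a spheroid_geometry object")
  if (!is.numeric(r) || any(!is.finite(r)))
    stop_invalid("'r' must be finite numeric")
  if (any(r < 0 | r > geom$r_o * (1 + 1e-12)))
    stop_invalid("radius outside [0, r_o]")
  a <- resolve_consumption(geom, a, params)
  k <- a * params$Omega / (6 * params$D)
  if (geom$r_n > 0) {
    p <- ifelse(r <= geom$r_n, 0,
                k * (r^2 + 2 * geom$r_n^3 / pmax(r, geom$r_n) - 3 * geom$r_n^2))
  } else {
    p <- pmax(0, params$p_o - k * (geom$r_o^2 - r^2))
  }
  p
}

#' Radius of an oxygen isobar
#'
#' Finds the radius r_p at which the modelled partial pressure equals `p`,
#' the unique solution in \[r_n, r_o\] of
#' \deqn{r^3 - \left(3 r_n^2 + r_l^2 \frac{p}{p_o}\right) r + 2 r_n^3 = 0.}
#' Strictly increasing in p; p = 0 gives r_n and p = p_o gives r_o. For a
#' spheroid below the diffusion limit, pressures below the central pressure
#' have no isobar and NA is returned with a warning.
#'
#' @param p Partial pressure(s), mmHg, each in \[0, p_o\].
#' @param geom A [spheroid_geometry()].
#' @param params An [oxygen_params()] object.
#' @param a Volumetric consumption rate (see [partial_pressure()]).
#' @return Radius in metres (vectorised over `p`).
#' @export
isobar_radius <- function(p, geom, params = oxygen_params(), a = NULL) {
  assert_params(params)
  if (!inherits(geom, "spheroid_geometry"))
    stop_invalid("'geom' must be a spheroid_geometry object")
  if (!is.numeric(p) || any(!is.finite(p)))
    stop_invalid("'p' must be finite numeric")
  if (any(p < 0 | p > params$p_o))
    stop_invalid("pressure outside [0, p_o]")
  a <- resolve_consumption(geom, a, params)
  one <- function(pi) {
    f <- function(r) partial_pressure(r, geom, params, a) - pi
    lo <- geom$r_n
    hi <- geom$r_o
    flo <- f(lo)
    fhi <- f(hi)
    if (flo > 0) {
      # below-limit spheroid with central pressure above pi
      if (pi < flo) {
        warning("pressure below the central pressure: no isobar exists")
        return(NA_real_)
      }
      lo <- 0
      flo <- f(0)
      if (flo > 0) {
        warning("pressure below the central pressure: no isobar exists")
        return(NA_real_)
      }
    }
    if (abs(flo) < 1e-12) return(lo)
    if (abs(fhi) < 1e-12) return(hi)
    stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
  }
  vapply(p, one, numeric(1))
}

#' Radial oxygen profile
#'
#' Samples the analytical partial-pressure solution on an even radial grid
#' spanning \[0, r_o\].
#'
#' @param geom A [spheroid_geometry()].
#' @param params An [oxygen_params()] object.
#' @param a Volumetric consumption rate (see [partial_pressure()]).
#' @param n Number of grid points.
#' @return A data frame with columns `radius_m`, `radius_um`, `pO2_mmHg`.
#' @export
oxygen_profile <- function(geom, params = oxygen_params(), a = NULL, n = 401) {
  n <- as.integer(assert_scalar_pos(n, "n"))
  r <- seq(0, geom$r_o, length.out = n)
  data.frame(radius_m = r, radius_um = r * 1e6,
             pO2_mmHg = partial_pressure(r, geom, params, a))
}
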