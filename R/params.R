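#' Physical parameters of the oxygen transport problem
#'
#' Bundles the physical constants entering the spherical reaction-diffusion
#' model: the oxygen diffusion coefficient of the tissue, the partial
#' pressure of oxygen at the spheroid surface, and the Henry's-law constants
#' used to convert between oxygen content per tissue mass and partial
#' pressure. Defaults describe tumour tissue whose transport properties are
#' close to water, bathed in medium at 100 mmHg.
#'
#' @param D Oxygen diffusion coefficient of the tissue, m^2 s^-1.
#' @param p_o External oxygen partial pressure at the spheroid surface, mmHg.
#' @param Omega Lumped Henry's-law conversion constant relating volumetric
#'   oxygen content per tissue mass to partial pressure, mmHg kg m^-3.
#' @param K Henry's constant for oxygen at body temperature,
#'   m^3 mmHg kg^-1 (informational; not used in pressure computations).
#' @param rho_O2 Density of oxygen gas, kg m^-3.
#' @param rho_T Tissue density, kg m^-3 (water by default).
#' @param M_O2 Molar mass of O2, kg mol^-1.
#'
#' @return An object of class `oxygen_params` (a validated list).
#' @examples
#' p <- oxygen_params()
#' p$D
#' @export
oxygen_params <- function(D = 2e-9, p_o = 100, Omega = 3.0318e7,
                          K = 2.2779e-4, rho_O2 = 1.331, rho_T = 1000,
                          M_O2 = 0.032) {
  vals <- list(D = D, p_o = p_o, Omega = Omega, K = K,
               rho_O2 = rho_O2, rho_T = rho_T, M_O2 = M_O2)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_invalid(sprintf("parameter '%s' must be a finite numeric scalar", nm))
  }
  if (vals$p_o < 0) stop_invalid("p_o must be non-negative")
  for (nm in setdiff(names(vals), "p_o"))
    if (vals[[nm]] <= 0)
      stop_invalid(sprintf("parameter '%s' must be strictly positive", nm))
  structure(vals, class = "oxygen_params")
}

#' @export
print.oxygen_params <- function(x, ...) {
  cat("Oxygen transport parameters:\n")
  cat(sprintf("  D      = %g m^2 s^-1 (diffusion coefficient)\n", x$D))
  cat(sprintf("  p_o    = %g mmHg (surface partial pressure)\n", x$p_o))
  cat(sprintf("  Omega  = %g mmHg kg m^-3 (Henry's-law conversion)\n", x$Omega))
  cat(sprintf("  rho_O2 = %g kg m^-3, rho_T = %g kg m^-3, M_O2 = %g kg mol^-1\n",
              x$rho_O2, x$rho_T, x$M_O2))
  invisible(x)
}

#' Read oxygen parameters from a YAML file
#'
#' Reads a YAML mapping with any subset of the keys `D`, `p_o`, `Omega`, `K`,
#' `rho_O2`, `rho_T`, `M_O2`; unspecified keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An [oxygen_params()] object.
#' @export
read_oxygen_params <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("parameter file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_invalid("parameter file must contain a YAML mapping")
  allowed <- names(formals(oxygen_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop_invalid(sprintf("unknown parameter keys: %s",
                         paste(unknown, collapse = ", ")))
  do.call(oxygen_params, cfg)
}

# Classed conditions so callers (and the CLI) can map failures to exit codes.
stop_invalid <- function(msg) {
  stop(structure(class = c("spheroido2_invalid", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_measurement <- function(msg) {
  stop(structure(class = c("spheroido2_measurement", "spheroido2_invalid",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_params <- function(params) {
  if (!inherits(params, "oxygen_params"))
    stop_invalid("'params' must be an oxygen_params object")
  params
}

assert_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  if (allow_zero) {
    if (x < 0) stop_invalid(sprintf("'%s' must be non-negative", name))
  } else if (x <= 0) {
    stop_invalid(sprintf("'%s' must be strictly positive", name))
  }
  x
}
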