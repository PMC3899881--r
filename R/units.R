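#' Oxygen consumption rate in three unit systems
#'
#' The model works with the volumetric rate `a` (m^3 of O2 gas consumed per
#' kg of tissue per second). Two derived forms are carried along: the mass
#' rate (kg O2 per kg tissue per s, via the O2 gas density) and the molar
#' rate (mol O2 per kg tissue per minute, the unit plate-based flux assays
#' report in).
#'
#' @param a_volumetric Volumetric rate, m^3 kg^-1 s^-1 (non-negative).
#' @param params An [oxygen_params()] object (supplies rho_O2 and M_O2).
#' @return Object of class `consumption_rate` with fields `a_volumetric`,
#'   `a_mass` and `a_molar`.
#' @export
consumption_rate <- function(a_volumetric, params = oxygen_params()) {
  assert_params(params)
  assert_scalar_pos(a_volumetric, "a_volumetric", allow_zero = TRUE)
  a_mass <- a_volumetric * params$rho_O2
  structure(list(a_volumetric = a_volumetric,
                 a_mass = a_mass,
                 a_molar = a_mass * 60 / params$M_O2),
            class = "consumption_rate")
}

#' @export
print.consumption_rate <- function(x, ...) {
  cat(sprintf("Oxygen consumption rate:\n  %.4g m^3 kg^-1 s^-1 | %.4g kg kg^-1 s^-1 | %.4g mol kg^-1 min^-1\n",
              x$a_volumetric, x$a_mass, x$a_molar))
  invisible(x)
}

#' Convert a volumetric consumption rate to a molar rate
#'
#' @param a_volumetric Volumetric rate, m^3 kg^-1 s^-1.
#' @param params An [oxygen_params()] object.
#' @return Molar rate, mol O2 per kg tissue per minute.
#' @examples
#' convert_volumetric_to_molar(7.29e-7)  # ~1.82e-3
#' @export
convert_volumetric_to_molar <- function(a_volumetric, params = oxygen_params()) {
  consumption_rate(a_volumetric, params)$a_molar
}

#' Per-cell volumetric oxygen consumption from a plate-level flux
#'
#' Converts a plate (e.g. extracellular flux analyser) measurement of moles
#' of O2 consumed per minute by a known number of cells into the volume of
#' O2 gas consumed per second by a single cell.
#'
#' @param molar_rate_per_well Plate-level O2 flux, mol min^-1.
#' @param cells_per_well Number of cells generating that flux.
#' @param params An [oxygen_params()] object.
#' @return Per-cell volumetric rate, m^3 s^-1.
#' @examples
#' per_cell_rate_from_plate(250e-12, 8e4)  # ~1.25e-18 m^3 s^-1
#' @export
per_cell_rate_from_plate <- function(molar_rate_per_well, cells_per_well,
                                     params = oxygen_params()) {
  assert_params(params)
  assert_scalar_pos(molar_rate_per_well, "molar_rate_per_well", allow_zero = TRUE)
  assert_scalar_pos(cells_per_well, "cells_per_well")
  (molar_rate_per_well / cells_per_well) * params$M_O2 / params$rho_O2 / 60
}

#' Equivalent cell radius implied by a per-cell consumption rate
#'
#' If a single cell consumes oxygen at `per_cell_rate` (m^3 s^-1) and tissue
#' consumes at the volumetric rate `a` (m^3 per kg per s), the mass of tissue
#' equivalent to one cell is `per_cell_rate / a`. Assuming the cell has the
#' density of water and is spherical, this yields a cell radius — a
#' cross-check between spheroid-derived and monolayer-derived consumption.
#'
#' @param per_cell_rate Per-cell volumetric rate, m^3 s^-1.
#' @param a Volumetric consumption rate, m^3 kg^-1 s^-1, or a
#'   [consumption_rate()] object.
#' @param params An [oxygen_params()] object (supplies rho_T).
#' @return Equivalent cell radius, m.
#' @examples
#' equivalent_cell_radius(1.25e-18, 7.29e-7) * 1e6  # ~7.4 um
#' @export
equivalent_cell_radius <- function(per_cell_rate, a, params = oxygen_params()) {
  assert_params(params)
  if (inherits(a, "consumption_rate")) a <- a$a_volumetric
  assert_scalar_pos(per_cell_rate, "per_cell_rate")
  assert_scalar_pos(a, "a")
  volume <- per_cell_rate / a / params$rho_T
  (3 * volume / (4 * pi))^(1 / 3)
}
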