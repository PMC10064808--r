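#' Soil composition
#'
#' Volumetric composition and moisture of the soil column. The defaults
#' describe a loam-like profile (mineral fraction 0.45, organic fraction
#' 0.05, volumetric water content 0.10) consistent with a rocky loam from
#' coastal sage scrub; all values are overridable through the run
#' configuration.
#'
#' @param bulk_density Bulk density, g cm^-3. Default 1.40.
#' @param theta Volumetric water content, m^3 m^-3. Default 0.10.
#' @param x_mineral Mineral volume fraction. Default 0.45.
#' @param x_organic Organic-matter volume fraction. Default 0.05.
#' @return An object of class `soil_composition`.
#' @export
soil_composition <- function(bulk_density = 1.40, theta = 0.10,
                             x_mineral = 0.45, x_organic = 0.05) {
  for (f in c("bulk_density", "theta", "x_mineral", "x_organic")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop_param(f, "must be a single non-negative number")
    }
  }
  if (theta + x_mineral + x_organic > 1 + 1e-12) {
    stop_data("composition error: theta + x_mineral + x_organic must be <= 1")
  }
  structure(list(bulk_density = bulk_density, theta = theta,
                 x_mineral = x_mineral, x_organic = x_organic),
            class = "soil_composition")
}

#' Volumetric heat capacity of a soil mixture
#'
#' de Vries-style volumetric mixing of the phase heat capacities:
#' `1.92 * x_mineral + 2.51 * x_organic + 4.18 * theta` in MJ m^-3 K^-1
#' (mineral 1.92, organic matter 2.51, water 4.18 MJ m^-3 K^-1; the air
#' fraction contributes negligibly and is ignored).
#'
#' @param comp A [soil_composition()].
#' @return Heat capacity, MJ m^-3 K^-1.
#' @examples
#' volumetric_heat_capacity(soil_composition()) # 1.4075
#' @export
volumetric_heat_capacity <- function(comp) {
  stopifnot(inherits(comp, "soil_composition"))
  1.92 * comp$x_mineral + 2.51 * comp$x_organic + 4.18 * comp$theta
}

#' Soil thermal properties
#'
#' Bundles the thermal conductivity (constant over depth and temperature)
#' with the volumetric heat capacity, and derives the thermal diffusivity.
#' The default conductivity is 0.03 W cm^-1 K^-1 (3 W m^-1 K^-1); the
#' default heat capacity comes from the default [soil_composition()].
#'
#' @param conductivity Thermal conductivity, W cm^-1 K^-1. Default 0.03.
#' @param heat_capacity Volumetric heat capacity, MJ m^-3 K^-1. If `NULL`,
#'   computed from `comp`.
#' @param comp A [soil_composition()] used when `heat_capacity` is `NULL`.
#' @return An object of class `thermal_properties` with fields
#'   `conductivity` (W cm^-1 K^-1), `heat_capacity` (MJ m^-3 K^-1) and
#'   `diffusivity` (m^2 s^-1).
#' @export
thermal_properties <- function(conductivity = 0.03, heat_capacity = NULL,
                               comp = soil_composition()) {
  if (!is.numeric(conductivity) || length(conductivity) != 1L ||
      !is.finite(conductivity) || conductivity <= 0) {
    stop_param("conductivity", "must be a single positive number")
  }
  if (is.null(heat_capacity)) heat_capacity <- volumetric_heat_capacity(comp)
  if (!is.numeric(heat_capacity) || length(heat_capacity) != 1L ||
      !is.finite(heat_capacity) || heat_capacity <= 0) {
    stop_param("heat_capacity", "must be a single positive number")
  }
  props <- structure(list(conductivity = conductivity,
                          heat_capacity = heat_capacity,
                          diffusivity = NA_real_),
                     class = "thermal_properties")
  props$diffusivity <- thermal_diffusivity(props)
  props
}

#' Thermal diffusivity from conductivity and heat capacity
#'
#' Unit bridge between the cm-based conductivity convention and SI solver
#' units: `alpha = (conductivity * 100) / (heat_capacity * 1e6)` with
#' conductivity in W cm^-1 K^-1 and heat capacity in MJ m^-3 K^-1, giving
#' m^2 s^-1.
#'
#' @param props A `thermal_properties` object (the `diffusivity` field may
#'   be unset).
#' @return Diffusivity, m^2 s^-1.
#' @examples
#' thermal_diffusivity(thermal_properties(0.03, heat_capacity = 1.5)) # 2e-6
#' @export
thermal_diffusivity <- function(props) {
  stopifnot(inherits(props, "thermal_properties"))
  if (props$conductivity <= 0) stop_param("conductivity", "must be > 0")
  if (props$heat_capacity <= 0) stop_param("heat_capacity", "must be > 0")
  (props$conductivity * 100) / (props$heat_capacity * 1e6)
}

#' @export
print.thermal_properties <- function(x, ...) {
  cat(sprintf(
    "<thermal_properties> k = %g W/cm/K, C = %g MJ/m3/K, alpha = %.3g m2/s\n",
    x$conductivity, x$heat_capacity, x$diffusivity))
  invisible(x)
}
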