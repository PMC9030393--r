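# Material constants and temperature-dependent constitutive laws for vessel
# tissue and the copper electrodes.  Tissue thermal and electrical
# conductivity follow affine laws about a 25 degC reference:
#   k(T)     = k0 + 0.0013 (T - T0)            [W/m K]
#   sigma(T) = sigma0 (1 + 0.02 (T - T0))      [S/m]
# Electrode properties are constant over the experimental range.

#' Material property set
#'
#' Container for the thermophysical and electrical properties of one solid
#' region of the weld model.  Temperatures are carried in degrees Celsius
#' throughout the package; the constitutive laws only use temperature
#' differences, so no Kelvin conversion is needed.
#'
#' @param density Mass density (kg/m^3), > 0.
#' @param heat_capacity Specific heat capacity at constant pressure
#'   (J/kg K), > 0.
#' @param k0 Baseline thermal conductivity at `reference_temperature`
#'   (W/m K), > 0.
#' @param sigma0 Baseline electrical conductivity at `reference_temperature`
#'   (S/m), >= 0.
#' @param k_temp_coefficient Linear temperature coefficient of the thermal
#'   conductivity (W/m K per degC).
#' @param sigma_temp_fraction Fractional temperature coefficient of the
#'   electrical conductivity (1/degC).
#' @param reference_temperature Reference temperature T0 (degC).
#' @param temperature_dependent Logical; if `FALSE` the baselines are used
#'   at every temperature (electrodes).
#' @param name Optional label.
#' @return An object of class `material_properties`.
#' @seealso [tissue_properties()], [electrode_properties()],
#'   [thermal_conductivity()], [electrical_conductivity()]
#' @export
material_properties <- function(density, heat_capacity, k0, sigma0,
                                k_temp_coefficient = 0,
                                sigma_temp_fraction = 0,
                                reference_temperature = 25,
                                temperature_dependent = FALSE,
                                name = "material") {
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(heat_capacity), is.numeric(k0), is.numeric(sigma0))
  if (density <= 0) stop("density must be > 0")
  if (heat_capacity <= 0) stop("heat_capacity must be > 0")
  if (k0 <= 0) stop("k0 must be > 0")
  if (sigma0 < 0) stop("sigma0 must be >= 0")
  structure(
    list(density = density, heat_capacity = heat_capacity, k0 = k0,
         sigma0 = sigma0, k_temp_coefficient = k_temp_coefficient,
         sigma_temp_fraction = sigma_temp_fraction,
         reference_temperature = reference_temperature,
         temperature_dependent = isTRUE(temperature_dependent),
         name = name),
    class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("<material_properties: %s>\n", x$name))
  cat(sprintf("  rho = %g kg/m^3, c_p = %g J/kg.K\n", x$density,
              x$heat_capacity))
  cat(sprintf("  k0 = %g W/m.K, sigma0 = %g S/m (T0 = %g degC, %s)\n",
              x$k0, x$sigma0, x$reference_temperature,
              if (x$temperature_dependent) "temperature-dependent"
              else "constant"))
  invisible(x)
}

#' Default vessel-tissue properties
#'
#' Porcine vessel tissue at the 25 degC reference: density 1101.5 kg/m^3,
#' heat capacity 3306 J/kg K, baseline thermal conductivity 0.462 W/m K
#' (coefficient 0.0013 W/m K per degC) and baseline electrical conductivity
#' 0.24567 S/m (fractional coefficient 0.02 per degC).
#'
#' @return A `material_properties` object.
#' @export
tissue_properties <- function() {
  material_properties(density = 1101.5, heat_capacity = 3306,
                      k0 = 0.462, sigma0 = 0.24567,
                      k_temp_coefficient = 0.0013,
                      sigma_temp_fraction = 0.02,
                      reference_temperature = 25,
                      temperature_dependent = TRUE, name = "tissue")
}

#' Default electrode (copper) properties
#'
#' Copper electrodes, treated as constant over the experimental range:
#' density 8960 kg/m^3, heat capacity 381.875 J/kg K, thermal conductivity
#' 401 W/m K, electrical conductivity 57,142,857 S/m.
#'
#' @return A `material_properties` object.
#' @export
electrode_properties <- function() {
  material_properties(density = 8960, heat_capacity = 381.875,
                      k0 = 401, sigma0 = 57142857,
                      temperature_dependent = FALSE, name = "electrode")
}

.check_temperature <- function(T) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature must be finite")
}

#' Thermal conductivity at temperature
#'
#' Evaluates k(T) = k0 + a (T - T0) for temperature-dependent materials and
#' k0 otherwise.  Out-of-range temperatures that would drive the
#' conductivity non-positive raise an error rather than being clamped, so
#' that solver instabilities surface immediately.
#'
#' @param props A [material_properties()] object.
#' @param T Temperature(s), degC. Vectorised.
#' @return Thermal conductivity (W/m K).
#' @examples
#' thermal_conductivity(tissue_properties(), 25)   # 0.462
#' thermal_conductivity(tissue_properties(), 72.2) # 0.52336
#' @export
thermal_conductivity <- function(props, T) {
  stopifnot(inherits(props, "material_properties"))
  .check_temperature(T)
  k <- if (props$temperature_dependent)
    props$k0 + props$k_temp_coefficient * (T - props$reference_temperature)
  else rep(props$k0, length(T))
  if (any(k <= 0))
    stop("degenerate material property: thermal conductivity <= 0 at T = ",
         paste(T[k <= 0], collapse = ", "))
  k
}

#' Electrical conductivity at temperature
#'
#' Evaluates sigma(T) = sigma0 (1 + b (T - T0)) for temperature-dependent
#' materials and sigma0 otherwise.  An optional thermal-damage cutoff
#' divides the conductivity by 10,000 above `damage_temperature`, mimicking
#' the collapse of conduction in desiccated tissue; it is off by default.
#'
#' @param props A [material_properties()] object.
#' @param T Temperature(s), degC. Vectorised.
#' @param damage_cutoff Logical; apply the 1/10,000 damage cutoff.
#' @param damage_temperature Cutoff onset (degC) when `damage_cutoff`.
#' @return Electrical conductivity (S/m).
#' @examples
#' electrical_conductivity(tissue_properties(), 25) # 0.24567
#' electrical_conductivity(tissue_properties(), 75) # doubled
#' @export
electrical_conductivity <- function(props, T, damage_cutoff = FALSE,
                                    damage_temperature = 100) {
  stopifnot(inherits(props, "material_properties"))
  .check_temperature(T)
  s <- if (props$temperature_dependent)
    props$sigma0 *
      (1 + props$sigma_temp_fraction * (T - props$reference_temperature))
  else rep(props$sigma0, length(T))
  if (any(s < 0))
    stop("degenerate material property: electrical conductivity < 0 at T = ",
         paste(T[s < 0], collapse = ", "))
  if (isTRUE(damage_cutoff)) s <- ifelse(T >= damage_temperature, s / 1e4, s)
  s
}

#' Blood-perfusion / metabolic source parameters
#'
#' Parameters of the bio-heat source
#' Q_bio = rho_b C_pb omega_b (T_b - T) + Q_met.  The experiments this
#' package models are ex vivo, so perfusion is disabled by default and the
#' source then evaluates to exactly zero.
#'
#' @param enabled Logical, default `FALSE`.
#' @param blood_density rho_b (kg/m^3).
#' @param blood_heat_capacity C_pb (J/kg K).
#' @param perfusion_rate omega_b (1/s), >= 0.
#' @param arterial_temperature T_b (degC).
#' @param metabolic_source Q_met (W/m^3).
#' @return An object of class `perfusion_parameters`.
#' @export
perfusion_parameters <- function(enabled = FALSE, blood_density = 1050,
                                 blood_heat_capacity = 3617,
                                 perfusion_rate = 0,
                                 arterial_temperature = 37,
                                 metabolic_source = 0) {
  if (isTRUE(enabled)) {
    if (blood_density <= 0 || blood_heat_capacity <= 0)
      stop("blood density and heat capacity must be > 0 when enabled")
    if (perfusion_rate < 0) stop("perfusion rate must be >= 0")
  }
  structure(
    list(enabled = isTRUE(enabled), blood_density = blood_density,
         blood_heat_capacity = blood_heat_capacity,
         perfusion_rate = perfusion_rate,
         arterial_temperature = arterial_temperature,
         metabolic_source = metabolic_source),
    class = "perfusion_parameters")
}

#' Perfusion heat source
#'
#' @param params A [perfusion_parameters()] object.
#' @param T Tissue temperature(s), degC.
#' @return Volumetric heat source (W/m^3); exactly 0 when disabled.
#' @export
perfusion_source <- function(params, T) {
  stopifnot(inherits(params, "perfusion_parameters"))
  .check_temperature(T)
  if (!params$enabled) return(rep(0, length(T)))
  params$blood_density * params$blood_heat_capacity * params$perfusion_rate *
    (params$arterial_temperature - T) + params$metabolic_source
}

#' Material set lookup by region label
#'
#' @param label One of `"tissue"`, `"upper_electrode"`, `"lower_electrode"`.
#' @param materials Optional named list overriding the bundled defaults
#'   (names `tissue`, `upper_electrode`, `lower_electrode`).
#' @return A `material_properties` object.
#' @export
material_for_region <- function(label, materials = default_materials()) {
  if (!is.character(label) || length(label) != 1L ||
      !label %in% names(materials))
    stop("unknown region label: ", paste(label, collapse = ", "))
  materials[[label]]
}

#' Default material set for the weld model
#'
#' @return Named list with `tissue`, `upper_electrode` and
#'   `lower_electrode` entries.
#' @export
default_materials <- function() {
  el <- electrode_properties()
  list(tissue = tissue_properties(),
       upper_electrode = el,
       lower_electrode = el)
}

#' Load a material set from a config file
#'
#' Reads a JSON file with optional sections `tissue`, `upper_electrode`,
#' `lower_electrode` and (for convenience) `electrode`, each holding
#' name-value pairs matching [material_properties()] arguments.  Missing
#' fields fall back to the bundled defaults.
#'
#' @param path Path to a JSON file.
#' @return Named list as [default_materials()].
#' @export
load_materials <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  mats <- default_materials()
  patch <- function(base, over) {
    args <- utils::modifyList(base[setdiff(names(base), "name")],
                              as.list(over))
    do.call(material_properties, c(args, list(name = base$name)))
  }
  if (!is.null(cfg$electrode)) {
    mats$upper_electrode <- patch(mats$upper_electrode, cfg$electrode)
    mats$lower_electrode <- patch(mats$lower_electrode, cfg$electrode)
  }
  for (nm in intersect(names(cfg),
                       c("tissue", "upper_electrode", "lower_electrode")))
    mats[[nm]] <- patch(mats[[nm]], cfg[[nm]])
  mats
}
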