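#' Thermal material description
#'
#' One homogeneous region of the conduction problem (the CNT or the
#' surrounding tissue). Only the thermal conductivity enters the
#' steady-state solution; density and specific heat are required by the
#' transient solver and may be left `NA` for steady-only use.
#'
#' @param thermal_conductivity Thermal conductivity k (W m^-1 K^-1), > 0.
#' @param density Density rho (kg m^-3), > 0 or `NA`.
#' @param specific_heat Specific heat capacity c (J kg^-1 K^-1), > 0 or `NA`.
#' @return An object of class `cnt_material`.
#' @export
material <- function(thermal_conductivity, density = NA_real_,
                     specific_heat = NA_real_) {
  thermal_conductivity <- as.numeric(thermal_conductivity)
  density <- as.numeric(density)
  specific_heat <- as.numeric(specific_heat)
  if (length(thermal_conductivity) != 1L || !is.finite(thermal_conductivity) ||
      thermal_conductivity <= 0) {
    stop("validation error: thermal_conductivity must be a single finite value > 0",
         call. = FALSE)
  }
  for (nm in c("density", "specific_heat")) {
    v <- get(nm)
    if (length(v) != 1L || (!is.na(v) && (!is.finite(v) || v <= 0))) {
      stop(sprintf("validation error: %s must be > 0 (or NA for steady-only use)", nm),
           call. = FALSE)
    }
  }
  structure(list(thermal_conductivity = thermal_conductivity,
                 density = density, specific_heat = specific_heat),
            class = "cnt_material")
}

#' Laser source description
#'
#' Continuous (time-averaged) laser illumination of the absorber. The
#' volumetric heating it deposits is `(1 - R) * I0 * alpha * exp(-alpha * z)`
#' with depth `z` measured radially inward from the CNT surface; see
#' [heating_function()].
#'
#' @param intensity Incident intensity I0 (W m^-2), >= 0.
#' @param absorption_coefficient Optical absorption coefficient alpha (m^-1), >= 0.
#' @param reflectivity Fraction of incident light reflected, R in \[0, 1\].
#' @return An object of class `cnt_laser`.
#' @export
laser_source <- function(intensity, absorption_coefficient, reflectivity) {
  intensity <- as.numeric(intensity)
  absorption_coefficient <- as.numeric(absorption_coefficient)
  reflectivity <- as.numeric(reflectivity)
  if (length(intensity) != 1L || !is.finite(intensity) || intensity < 0) {
    stop("validation error: intensity must be >= 0", call. = FALSE)
  }
  if (length(absorption_coefficient) != 1L || !is.finite(absorption_coefficient) ||
      absorption_coefficient < 0) {
    stop("validation error: absorption_coefficient must be >= 0", call. = FALSE)
  }
  if (length(reflectivity) != 1L || !is.finite(reflectivity) ||
      reflectivity < 0 || reflectivity > 1) {
    stop("validation error: reflectivity must lie in [0, 1]", call. = FALSE)
  }
  structure(list(intensity = intensity,
                 absorption_coefficient = absorption_coefficient,
                 reflectivity = reflectivity),
            class = "cnt_laser")
}

#' Problem geometry
#'
#' Radial geometry of the two-region problem: CNT radius `a`, far-field
#' radius `b` held at body temperature, and that temperature `Tb`. When
#' `far_radius` is not supplied it defaults to `100 * cnt_radius`, the
#' convention used throughout the model.
#'
#' @param cnt_radius CNT radius a (m), > 0.
#' @param far_radius Far-field radius b (m), > `cnt_radius`; default `100 * a`.
#' @param far_temperature Far-field (body) temperature Tb in kelvin;
#'   default 310.15 K (37 C).
#' @return An object of class `cnt_geometry`.
#' @export
geometry <- function(cnt_radius, far_radius = NULL, far_temperature = 310.15) {
  cnt_radius <- as.numeric(cnt_radius)
  if (length(cnt_radius) != 1L || !is.finite(cnt_radius) || cnt_radius <= 0) {
    stop("validation error: cnt_radius must be > 0", call. = FALSE)
  }
  if (is.null(far_radius)) far_radius <- 100 * cnt_radius
  far_radius <- as.numeric(far_radius)
  far_temperature <- as.numeric(far_temperature)
  if (length(far_radius) != 1L || !is.finite(far_radius) ||
      far_radius <= cnt_radius) {
    stop("validation error: far_radius must exceed cnt_radius", call. = FALSE)
  }
  if (length(far_temperature) != 1L || !is.finite(far_temperature) ||
      far_temperature <= 0) {
    stop("validation error: far_temperature must be a positive kelvin value",
         call. = FALSE)
  }
  structure(list(cnt_radius = cnt_radius, far_radius = far_radius,
                 far_temperature = far_temperature),
            class = "cnt_geometry")
}

#' Full model specification
#'
#' Aggregates the materials, laser and geometry into one validated problem
#' statement. All values are SI; temperatures are kelvin.
#'
#' @param cnt,tissue [material()] objects for the CNT and the tissue.
#' @param laser A [laser_source()].
#' @param geometry A [geometry()].
#' @return An object of class `cnt_model_spec`.
#' @export
model_spec <- function(cnt, tissue, laser, geometry) {
  stopifnot(inherits(cnt, "cnt_material"), inherits(tissue, "cnt_material"),
            inherits(laser, "cnt_laser"), inherits(geometry, "cnt_geometry"))
  structure(list(cnt = cnt, tissue = tissue, laser = laser,
                 geometry = geometry),
            class = "cnt_model_spec")
}

#' Default physical parameters
#'
#' The reference parameter set for a single-walled CNT in human tissue:
#' tissue conductivity 0.567 W m^-1 K^-1, CNT conductivity 3000
#' W m^-1 K^-1 (the low end of the commonly quoted 3000-3500 range for
#' CNTs), reflectivity 0.1, absorption coefficient 2.4e7 m^-1, intensity
#' 1e6 W cm^-2 (1e10 W m^-2), CNT radius 5 nm, far-field radius 100 a at
#' body temperature 37 C.
#'
#' Densities and specific heats are not part of the steady-state problem;
#' the defaults supplied here (CNT 1400 kg m^-3 / 700 J kg^-1 K^-1, tissue
#' 1000 / 4000) are order-of-magnitude literature-style values used only by
#' the transient solver's time scale, and are freely overridable.
#'
#' @return A `cnt_model_spec`.
#' @examples
#' spec <- default_model_spec()
#' spec$tissue$thermal_conductivity  # 0.567
#' @export
default_model_spec <- function() {
  model_spec(
    cnt = material(3000, density = 1400, specific_heat = 700),
    tissue = material(0.567, density = 1000, specific_heat = 4000),
    laser = laser_source(intensity = 1e10, absorption_coefficient = 2.4e7,
                         reflectivity = 0.1),
    geometry = geometry(cnt_radius = 5e-9, far_temperature = 310.15)
  )
}

#' @export
print.cnt_model_spec <- function(x, ...) {
  g <- x$geometry
  cat("<cnt_model_spec>\n")
  cat(sprintf("  CNT:    k = %g W/mK, rho = %g kg/m3, c = %g J/kgK\n",
              x$cnt$thermal_conductivity, x$cnt$density, x$cnt$specific_heat))
  cat(sprintf("  tissue: k = %g W/mK, rho = %g kg/m3, c = %g J/kgK\n",
              x$tissue$thermal_conductivity, x$tissue$density,
              x$tissue$specific_heat))
  cat(sprintf("  laser:  I0 = %g W/m2, alpha = %g 1/m, R = %g\n",
              x$laser$intensity, x$laser$absorption_coefficient,
              x$laser$reflectivity))
  cat(sprintf("  domain: a = %g nm, b = %g nm (b/a = %g), Tb = %.2f C\n",
              g$cnt_radius * 1e9, g$far_radius * 1e9,
              g$far_radius / g$cnt_radius, K_to_C(g$far_temperature)))
  invisible(x)
}

# Unit-suffixed configuration keys, per section. Each entry maps an accepted
# key name to the factor converting it to SI. Temperatures are special-cased
# (offset, not factor).
.unit_registry <- list(
  material = list(
    thermal_conductivity = c(thermal_conductivity_W_per_mK = 1),
    density = c(density_kg_per_m3 = 1, density_g_per_cm3 = 1000),
    specific_heat = c(specific_heat_J_per_kgK = 1)
  ),
  laser = list(
    intensity = c(intensity_W_per_m2 = 1, intensity_W_per_cm2 = 1e4),
    absorption_coefficient = c(absorption_coefficient_per_m = 1,
                               absorption_coefficient_per_cm = 1e2),
    reflectivity = c(reflectivity = 1)
  ),
  geometry = list(
    cnt_radius = c(cnt_radius_m = 1, cnt_radius_um = 1e-6, cnt_radius_nm = 1e-9),
    far_radius = c(far_radius_m = 1, far_radius_um = 1e-6, far_radius_nm = 1e-9),
    far_temperature = c(far_temperature_K = NA, far_temperature_C = NA)
  )
)

.parse_section <- function(section, values, kind) {
  registry <- .unit_registry[[kind]]
  out <- list()
  for (key in names(values)) {
    v <- values[[key]]
    matched <- FALSE
    for (field in names(registry)) {
      units <- registry[[field]]
      if (key %in% names(units)) {
        # YAML 1.1 reads exponent forms like "2.5e5" (no sign) as strings
        if (is.character(v)) v <- suppressWarnings(as.numeric(v))
        if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
          stop(sprintf("configuration error: key '%s.%s' must be a single finite number",
                       section, key), call. = FALSE)
        }
        if (field == "far_temperature") {
          out[[field]] <- if (endsWith(key, "_C")) C_to_K(v) else v
        } else {
          out[[field]] <- v * units[[key]]
        }
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("configuration error: unknown key '%s.%s' (valid keys: %s)",
                   section, key,
                   paste(unlist(lapply(registry, names)), collapse = ", ")),
           call. = FALSE)
    }
  }
  out
}

.spec_from_config_list <- function(cfg) {
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop("configuration error: document must be a mapping of sections",
         call. = FALSE)
  }
  known <- c("cnt", "tissue", "laser", "geometry")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop(sprintf("configuration error: unknown section '%s' (valid: %s)",
                 bad[[1L]], paste(known, collapse = ", ")), call. = FALSE)
  }
  d <- default_model_spec()
  cnt_v <- .parse_section("cnt", cfg$cnt, "material")
  tis_v <- .parse_section("tissue", cfg$tissue, "material")
  las_v <- .parse_section("laser", cfg$laser, "laser")
  geo_v <- .parse_section("geometry", cfg$geometry, "geometry")

  pick <- function(vals, field, default) {
    if (!is.null(vals[[field]])) vals[[field]] else default
  }
  cnt <- material(pick(cnt_v, "thermal_conductivity", d$cnt$thermal_conductivity),
                  pick(cnt_v, "density", d$cnt$density),
                  pick(cnt_v, "specific_heat", d$cnt$specific_heat))
  tissue <- material(pick(tis_v, "thermal_conductivity", d$tissue$thermal_conductivity),
                     pick(tis_v, "density", d$tissue$density),
                     pick(tis_v, "specific_heat", d$tissue$specific_heat))
  laser <- laser_source(pick(las_v, "intensity", d$laser$intensity),
                        pick(las_v, "absorption_coefficient",
                             d$laser$absorption_coefficient),
                        pick(las_v, "reflectivity", d$laser$reflectivity))
  a <- pick(geo_v, "cnt_radius", d$geometry$cnt_radius)
  # when b is not supplied it follows the b = 100 a rule for the supplied a
  b <- if (!is.null(geo_v$far_radius)) geo_v$far_radius else 100 * a
  geom <- geometry(a, b, pick(geo_v, "far_temperature",
                              d$geometry$far_temperature))
  model_spec(cnt, tissue, laser, geom)
}

#' Load a model specification from a YAML document
#'
#' Reads a configuration with sections `cnt`, `tissue`, `laser`,
#' `geometry`; keys carry unit suffixes (e.g. `cnt_radius_nm`,
#' `intensity_W_per_cm2`, `far_temperature_C`) and are converted to SI on
#' load. Unsupplied fields take the [default_model_spec()] values; an
#' unsupplied far radius follows the `b = 100 a` rule applied to the
#' (possibly supplied) CNT radius.
#'
#' @param config Path to a YAML file, or a YAML document as a string.
#' @return A validated `cnt_model_spec` in SI units.
#' @examples
#' load_spec("geometry: {cnt_radius_nm: 10}")$geometry$far_radius  # 1e-6
#' @export
load_spec <- function(config) {
  cfg <- if (length(config) == 1L && is.character(config) &&
             !grepl("[:\n]", config) && file.exists(config)) {
    tryCatch(yaml::read_yaml(config),
             error = function(e) stop(sprintf(
               "configuration error: cannot parse '%s': %s",
               config, conditionMessage(e)), call. = FALSE))
  } else {
    tryCatch(yaml::yaml.load(paste(config, collapse = "\n")),
             error = function(e) stop(sprintf(
               "configuration error: cannot parse document: %s",
               conditionMessage(e)), call. = FALSE))
  }
  .spec_from_config_list(cfg)
}

#' Serialize a model specification
#'
#' Writes the spec as a YAML document with canonical SI keys, such that
#' [load_spec()] on the output reproduces the object to full double
#' precision.
#'
#' @param spec A `cnt_model_spec`.
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to a file.
#' @export
write_spec <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "cnt_model_spec"))
  mat_list <- function(m) {
    out <- list(thermal_conductivity_W_per_mK = m$thermal_conductivity)
    if (!is.na(m$density)) out$density_kg_per_m3 <- m$density
    if (!is.na(m$specific_heat)) out$specific_heat_J_per_kgK <- m$specific_heat
    out
  }
  doc <- list(
    cnt = mat_list(spec$cnt),
    tissue = mat_list(spec$tissue),
    laser = list(intensity_W_per_m2 = spec$laser$intensity,
                 absorption_coefficient_per_m = spec$laser$absorption_coefficient,
                 reflectivity = spec$laser$reflectivity),
    geometry = list(cnt_radius_m = spec$geometry$cnt_radius,
                    far_radius_m = spec$geometry$far_radius,
                    far_temperature_K = spec$geometry$far_temperature)
  )
  # emitted directly: %.17g round-trips doubles exactly, whereas the yaml
  # emitter's precision counts decimal places and truncates small values
  num <- function(x) {
    s <- sprintf("%.17g", x)
    # integer-looking literals would be parsed as (possibly overflowing)
    # 32-bit ints; force a float literal
    ifelse(grepl("^-?[0-9]+$", s), paste0(s, ".0"), s)
  }
  txt <- paste(vapply(names(doc), function(sec) {
    paste0(sec, ":\n",
           paste(sprintf("  %s: %s", names(doc[[sec]]),
                         num(unlist(doc[[sec]]))), collapse = "\n"))
  }, character(1)), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
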