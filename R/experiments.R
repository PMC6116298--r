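#' Interface temperature versus CNT radius
#'
#' Evaluates the closed-form interface and centre temperatures over a range
#' of CNT radii. With `fixed_ratio = TRUE` the far radius tracks
#' `b = (b/a) * a` (the 100a convention), so the rise above body
#' temperature scales exactly as `a^2` — the basis for preferring
#' larger-diameter CNTs as heating agents. With `fixed_ratio = FALSE` the
#' far radius stays at the spec's value.
#'
#' @param spec A `cnt_model_spec`.
#' @param radii Increasing positive CNT radii (m); default 0.5-10 nm.
#' @param fixed_ratio Keep `b/a` at the spec's ratio per point (default),
#'   or hold `b` fixed.
#' @return A data frame of class `sweep_table` with columns `a_m`, `b_m`,
#'   `T_interface_K`, `T_interface_C`, `T_center_K`, `T_center_C`,
#'   `rise_K`.
#' @export
radius_sweep <- function(spec, radii = seq(0.5e-9, 10e-9, length.out = 20L),
                         fixed_ratio = TRUE) {
  if (any(radii <= 0) || any(diff(radii) <= 0)) {
    stop("radii must be positive and increasing", call. = FALSE)
  }
  g <- spec$geometry
  ratio <- g$far_radius / g$cnt_radius
  rows <- lapply(radii, function(a) {
    b <- if (fixed_ratio) ratio * a else g$far_radius
    if (b <= a) {
      stop(sprintf("domain error: far radius %.3e m <= CNT radius %.3e m in sweep row",
                   b, a), call. = FALSE)
    }
    s <- model_spec(spec$cnt, spec$tissue, spec$laser,
                    geometry(a, b, g$far_temperature))
    Ti <- interface_temperature(s)
    Tc <- center_temperature(s)
    data.frame(a_m = a, b_m = b, T_interface_K = Ti, T_interface_C = K_to_C(Ti),
               T_center_K = Tc, T_center_C = K_to_C(Tc),
               rise_K = Ti - g$far_temperature)
  })
  structure(do.call(rbind, rows), class = c("sweep_table", "data.frame"))
}

#' Attenuation of the heating function with depth
#'
#' The exponential factor `exp(-alpha z)` of the Beer-Lambert source over
#' the depth range `z` in `[0, a]` (surface to axis). For the default
#' parameters `alpha a = 0.12`, so the factor only falls to
#' `exp(-0.12) ~ 0.887` at the axis — the weak-attenuation regime that
#' justifies the constant-source simplification.
#'
#' @param spec A `cnt_model_spec`.
#' @param n_points Number of depths (>= 2).
#' @return Data frame with columns `z_m` and `attenuation`.
#' @export
source_decay_curve <- function(spec, n_points = 101L) {
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  a <- spec$geometry$cnt_radius
  z <- seq(0, a, length.out = n_points)
  data.frame(z_m = z, attenuation = exp(-spec$laser$absorption_coefficient * z))
}

#' Constant-source versus exponential-source comparison
#'
#' Quantifies what the constant-source simplification overestimates: the
#' closed form (constant source) versus the quadrature solution with the
#' full exponential deposition, at the centre and the interface. Because
#' the exponential source is bounded above by the constant source
#' pointwise, the constant-source temperatures are upper bounds everywhere
#' — the computed interior temperature exceeds the true one.
#'
#' @param spec A `cnt_model_spec`.
#' @param n_quad Quadrature subdivision limit for the exponential-source
#'   solve.
#' @return An object of class `approximation_report`: centre/interface
#'   temperatures (kelvin) under each source, their differences, and the
#'   maximum pointwise difference over the sampled interior radii.
#' @export
approximation_report <- function(spec, n_quad = 200L) {
  radii <- .profile_radii(spec, 101L, "uniform")
  exp_prof <- general_steady_solve(source_field(spec, "exponential"), spec,
                                   n_quad = n_quad, radii = radii)
  const_T <- steady_temperature(radii, spec)
  const_center <- center_temperature(spec)
  const_interface <- interface_temperature(spec)
  exp_center <- exp_prof$T_K[1L]
  exp_interface <- exp_prof$T_K[exp_prof$region == "interface"][1L]
  structure(list(
    constant = list(center_K = const_center, interface_K = const_interface),
    exponential = list(center_K = exp_center, interface_K = exp_interface),
    diff_center_K = const_center - exp_center,
    diff_interface_K = const_interface - exp_interface,
    max_pointwise_diff_K = max(const_T - exp_prof$T_K),
    radii = radii, constant_T_K = const_T, exponential_T_K = exp_prof$T_K
  ), class = "approximation_report")
}

#' @export
print.approximation_report <- function(x, ...) {
  cat("<approximation_report>\n")
  cat(sprintf("  centre:    constant %.4f C, exponential %.4f C (diff %.4g K)\n",
              K_to_C(x$constant$center_K), K_to_C(x$exponential$center_K),
              x$diff_center_K))
  cat(sprintf("  interface: constant %.4f C, exponential %.4f C (diff %.4g K)\n",
              K_to_C(x$constant$interface_K), K_to_C(x$exponential$interface_K),
              x$diff_interface_K))
  invisible(x)
}

#' Classify the interface temperature against the hyperthermia window
#'
#' Photothermal therapy aims to raise the cell-contact temperature into
#' the 41-47 C hyperthermia window; below it the treatment is ineffective,
#' above it heating is stronger than required. Classifies
#' [interface_temperature()] against the window (inclusive bounds).
#'
#' @param spec A `cnt_model_spec`.
#' @param window_low,window_high Window bounds in kelvin
#'   (defaults 41 C and 47 C).
#' @return A list with `classification` (`"below-window"`, `"in-window"`,
#'   `"above-window"`), the interface temperature, and the window used.
#' @export
hyperthermia_check <- function(spec, window_low = C_to_K(41),
                               window_high = C_to_K(47)) {
  if (window_low >= window_high) {
    stop("window_low must be below window_high", call. = FALSE)
  }
  Ti <- interface_temperature(spec)
  cls <- if (Ti < window_low) "below-window"
         else if (Ti > window_high) "above-window"
         else "in-window"
  list(classification = cls, interface_K = Ti, interface_C = K_to_C(Ti),
       window_K = c(window_low, window_high))
}

#' Laser intensity for a target interface temperature
#'
#' Inverts the interface-temperature relation for I0:
#' `I0 = 2 kt (T_target - Tb) / ((1 - R) alpha a^2 ln(b/a))`. Useful for
#' dosing the laser so the cell-contact temperature lands in the
#' hyperthermia window.
#'
#' @param spec A `cnt_model_spec` (its intensity is ignored).
#' @param target_K Desired interface temperature (kelvin), > Tb.
#' @return Intensity I0 in W m^-2.
#' @export
intensity_for_interface <- function(spec, target_K) {
  g <- spec$geometry
  rise <- target_K - g$far_temperature
  if (rise <= 0) stop("target temperature must exceed the far-field temperature",
                      call. = FALSE)
  denom <- (1 - spec$laser$reflectivity) * spec$laser$absorption_coefficient *
    g$cnt_radius^2 * log(g$far_radius / g$cnt_radius)
  if (denom <= 0) stop("laser or geometry leaves no heating path to the target",
                       call. = FALSE)
  2 * spec$tissue$thermal_conductivity * rise / denom
}
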