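#' Volumetric laser heating function
#'
#' Beer-Lambert deposition inside the absorber:
#' `q(r) = (1 - R) * I0 * alpha * exp(-alpha * z)` with depth `z = a - r`
#' measured radially inward from the CNT surface. At the surface (`r = a`)
#' this equals [constant_heating()].
#'
#' @param r Radial coordinate(s) in metres, within `[0, a]`.
#' @param source A [laser_source()].
#' @param geometry A [geometry()].
#' @return Volumetric power density (W m^-3), same length as `r`.
#' @examples
#' spec <- default_model_spec()
#' heating_function(spec$geometry$cnt_radius, spec$laser, spec$geometry)  # 2.16e17
#' @export
heating_function <- function(r, source, geometry) {
  a <- geometry$cnt_radius
  if (any(!is.finite(r)) || any(r < 0 | r > a)) {
    stop("domain error: r must lie in [0, a]", call. = FALSE)
  }
  constant_heating(source) * exp(-source$absorption_coefficient * (a - r))
}

#' Constant-source approximation of the heating function
#'
#' The weak-attenuation simplification `q = (1 - R) * I0 * alpha`,
#' i.e. the heating function evaluated at the surface and applied
#' uniformly. For the default parameters `alpha * a = 0.12`, so the
#' exponential factor never drops below `exp(-0.12) ~ 0.887` and the
#' approximation overestimates the interior deposition by at most ~11%.
#'
#' @param source A [laser_source()].
#' @return Volumetric power density q (W m^-3).
#' @export
constant_heating <- function(source) {
  (1 - source$reflectivity) * source$intensity * source$absorption_coefficient
}

#' Steady-state radial temperature
#'
#' Closed-form solution of the two-region steady conduction problem with a
#' constant volumetric source q confined to the cylinder:
#' \deqn{T(r) = \frac{q}{4 k_c}(a^2 - r^2) + \frac{q a^2}{2 k_t}\ln(b/a) + T_b,
#'   \quad 0 \le r \le a}
#' \deqn{T(r) = \frac{q a^2}{2 k_t}\ln(b/r) + T_b, \quad a < r \le b}
#' The profile is continuous at `r = a`, has zero slope at the axis, and
#' equals `Tb` at `r = b`.
#'
#' @param r Radial coordinate(s) (m) in `[0, b]`.
#' @param spec A `cnt_model_spec`.
#' @param q Volumetric source (W m^-3); defaults to
#'   `constant_heating(spec$laser)`.
#' @return Temperature(s) in kelvin.
#' @export
steady_temperature <- function(r, spec, q = constant_heating(spec$laser)) {
  g <- spec$geometry
  a <- g$cnt_radius; b <- g$far_radius; Tb <- g$far_temperature
  if (any(!is.finite(r)) || any(r < 0 | r > b)) {
    stop("domain error: r must lie in [0, b]", call. = FALSE)
  }
  kc <- spec$cnt$thermal_conductivity
  kt <- spec$tissue$thermal_conductivity
  inside <- r <= a
  out <- numeric(length(r))
  out[inside] <- q / (4 * kc) * (a^2 - r[inside]^2) +
    q * a^2 / (2 * kt) * log(b / a) + Tb
  out[!inside] <- q * a^2 / (2 * kt) * log(b / r[!inside]) + Tb
  out
}

#' Steady-state radial temperature gradient
#'
#' Closed-form `dT/dr`: `-q r / (2 kc)` inside the cylinder and
#' `-q a^2 / (2 kt r)` outside. The gradient itself jumps at the interface
#' (the conductive flux `k dT/dr` is what is continuous there); `side`
#' selects the branch used at `r == a`.
#'
#' @inheritParams steady_temperature
#' @param side Branch at exactly `r == a`: `"inside"` (default) or
#'   `"outside"`.
#' @return Gradient(s) in K m^-1.
#' @export
steady_gradient <- function(r, spec, q = constant_heating(spec$laser),
                            side = c("inside", "outside")) {
  side <- match.arg(side)
  g <- spec$geometry
  a <- g$cnt_radius; b <- g$far_radius
  if (any(!is.finite(r)) || any(r < 0 | r > b)) {
    stop("domain error: r must lie in [0, b]", call. = FALSE)
  }
  kc <- spec$cnt$thermal_conductivity
  kt <- spec$tissue$thermal_conductivity
  inside <- if (side == "inside") r <= a else r < a
  out <- numeric(length(r))
  out[inside] <- -q * r[inside] / (2 * kc)
  out[!inside] <- -q * a^2 / (2 * kt * r[!inside])
  out
}

#' Radial heat flow per unit cylinder length
#'
#' `-k(r) * 2 pi r * dT/dr` (W m^-1) for the closed-form steady solution.
#' Outside the absorber this is conserved and equals the total generated
#' power per unit length, `pi a^2 q` — the energy-balance invariant of the
#' model.
#'
#' @inheritParams steady_gradient
#' @return Heat flow(s) in W per metre of cylinder length.
#' @export
radial_heat_flow <- function(r, spec, q = constant_heating(spec$laser),
                             side = c("inside", "outside")) {
  side <- match.arg(side)
  a <- spec$geometry$cnt_radius
  inside <- if (side == "inside") r <= a else r < a
  k <- ifelse(inside, spec$cnt$thermal_conductivity,
              spec$tissue$thermal_conductivity)
  -k * 2 * pi * r * steady_gradient(r, spec, q, side = side)
}

#' Interface temperature
#'
#' Temperature at the CNT-tissue boundary,
#' `T(a) = q a^2 / (2 kt) * ln(b/a) + Tb` — the value in direct contact
#' with the cells being heated. With `b/a` held fixed the rise above body
#' temperature scales as `a^2`.
#'
#' @inheritParams steady_temperature
#' @return Interface temperature in kelvin.
#' @export
interface_temperature <- function(spec, q = constant_heating(spec$laser)) {
  g <- spec$geometry
  q * g$cnt_radius^2 / (2 * spec$tissue$thermal_conductivity) *
    log(g$far_radius / g$cnt_radius) + g$far_temperature
}

#' Centre-to-interface temperature excess
#'
#' `T(0) - T(a) = q a^2 / (4 kc)`. Because the CNT conductivity dwarfs the
#' tissue conductivity (kc/kt ~ 5000 for the defaults) this excess is tiny
#' — the cylinder interior is nearly isothermal.
#'
#' @inheritParams steady_temperature
#' @return Temperature excess in kelvin (nonnegative for q >= 0).
#' @export
center_excess <- function(spec, q = constant_heating(spec$laser)) {
  q * spec$geometry$cnt_radius^2 / (4 * spec$cnt$thermal_conductivity)
}

#' Centre (maximum) temperature
#'
#' @inheritParams steady_temperature
#' @return `interface_temperature(spec, q) + center_excess(spec, q)`, kelvin.
#' @export
center_temperature <- function(spec, q = constant_heating(spec$laser)) {
  interface_temperature(spec, q) + center_excess(spec, q)
}

# Sampling radii for profiles: always include 0, a and b exactly; roughly
# half the points resolve each region.
.profile_radii <- function(spec, n_points, spacing = c("uniform", "log-outside")) {
  spacing <- match.arg(spacing)
  if (n_points < 3L) stop("n_points must be >= 3", call. = FALSE)
  a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
  k_out <- as.integer(ceiling((n_points + 1L) / 2))
  k_in <- n_points + 1L - k_out
  r_in <- seq(0, a, length.out = k_in)
  r_out <- if (spacing == "log-outside") {
    exp(seq(log(a), log(b), length.out = k_out))
  } else {
    seq(a, b, length.out = k_out)
  }
  r_in[k_in] <- a; r_out[1L] <- a; r_out[k_out] <- b
  c(r_in, r_out[-1L])
}

#' Build a radial temperature profile object
#'
#' @param r Strictly increasing radii (m).
#' @param T_K Temperatures (kelvin), same length.
#' @param spec The `cnt_model_spec` the profile belongs to (supplies `a`
#'   for region labelling and `r/a` scaling).
#' @return A data frame of class `radial_profile` with columns `r_m`,
#'   `r_over_a`, `T_K`, `T_C`, `region` (`inside`, `interface`, `outside`).
#' @export
radial_profile <- function(r, T_K, spec) {
  if (length(r) != length(T_K)) stop("r and T_K lengths differ", call. = FALSE)
  if (any(diff(r) <= 0)) stop("radii must be strictly increasing", call. = FALSE)
  if (any(!is.finite(T_K))) stop("temperatures must be finite", call. = FALSE)
  a <- spec$geometry$cnt_radius
  region <- ifelse(r < a, "inside", ifelse(r == a, "interface", "outside"))
  structure(data.frame(r_m = r, r_over_a = r / a, T_K = T_K,
                       T_C = K_to_C(T_K), region = region,
                       stringsAsFactors = FALSE),
            class = c("radial_profile", "data.frame"))
}

#' Sampled steady-state profile
#'
#' Evaluates the closed form on a radial grid spanning `[0, b]` that always
#' contains `r = 0`, `r = a` and `r = b` exactly.
#'
#' @inheritParams steady_temperature
#' @param n_points Number of sample radii (>= 3).
#' @param spacing `"uniform"` within each region, or `"log-outside"` for
#'   logarithmic sampling of the tissue shell (resolves the steep
#'   near-interface decay).
#' @return A [radial_profile()].
#' @export
steady_profile <- function(spec, n_points = 201L,
                           spacing = c("uniform", "log-outside"),
                           q = constant_heating(spec$laser)) {
  r <- .profile_radii(spec, n_points, spacing)
  radial_profile(r, steady_temperature(r, spec, q), spec)
}

#' Write a profile as delimited text
#'
#' CSV with columns `r_m`, `r_over_a`, `T_C`, `region`, full double
#' precision.
#'
#' @param profile A [radial_profile()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  out <- data.frame(r_m = sprintf("%.17g", profile$r_m),
                    r_over_a = sprintf("%.17g", profile$r_over_a),
                    T_C = sprintf("%.17g", profile$T_C),
                    region = profile$region, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
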