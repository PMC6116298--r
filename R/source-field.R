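#' Radial volumetric source field
#'
#' Wraps a volumetric heating profile q(r) on `[0, a]` (zero outside) for
#' use by [general_steady_solve()] and the transient solver. Built-in
#' descriptors: `"constant"` is the simplified surface-value source
#' ([constant_heating()]); `"exponential"` is the full Beer-Lambert
#' deposition ([heating_function()]), which the constant source bounds
#' from above pointwise.
#'
#' @param spec A `cnt_model_spec`.
#' @param type `"constant"`, `"exponential"` or `"custom"`.
#' @param fun For `type = "custom"`: a vectorized function of `r` (m)
#'   returning W m^-3, nonnegative on `[0, a]`.
#' @return An object of class `cnt_source` with elements `fun`
#'   (vectorized, zero outside `[0, a]`) and `descriptor`.
#' @export
source_field <- function(spec, type = c("constant", "exponential", "custom"),
                         fun = NULL) {
  type <- match.arg(type)
  a <- spec$geometry$cnt_radius
  base <- switch(type,
    constant = {
      q0 <- constant_heating(spec$laser)
      function(r) rep(q0, length(r))
    },
    exponential = {
      q0 <- constant_heating(spec$laser)
      alpha <- spec$laser$absorption_coefficient
      function(r) q0 * exp(-alpha * (a - r))
    },
    custom = {
      if (!is.function(fun)) {
        stop("type = 'custom' requires a function of r", call. = FALSE)
      }
      probe <- fun(seq(0, a, length.out = 65L))
      if (any(!is.finite(probe)) || any(probe < 0)) {
        stop("custom source must be finite and nonnegative on [0, a]",
             call. = FALSE)
      }
      fun
    })
  wrapped <- function(r) {
    out <- numeric(length(r))
    ok <- r >= 0 & r <= a
    if (any(ok)) out[ok] <- base(r[ok])
    out
  }
  structure(list(fun = wrapped, descriptor = type, cnt_radius = a),
            class = "cnt_source")
}

#' Steady solver for an arbitrary radial source
#'
#' Solves the steady two-region conduction problem for any radial source
#' field by quadrature, without the constant-source simplification the
#' closed form relies on. Integrating the conduction equation once gives
#' `dT/dr = -(1/(kc r)) * Q(r)` inside, with `Q(r) = int_0^r q(s) s ds`
#' (the removable singularity at the axis enforces zero slope there);
#' flux continuity at `r = a` and `T(b) = Tb` fix the outer logarithmic
#' branch. A second integration, with the order of the double integral
#' exchanged, yields single smooth integrals:
#' \deqn{T(r) - T(a) = \frac{\ln(a/r)}{k_c} Q(r) +
#'   \frac{1}{k_c}\int_r^a q(u)\, u \ln(a/u)\, du}
#' evaluated by adaptive quadrature. With a constant source the result
#' coincides with [steady_temperature()]; this equivalence is the central
#' cross-validation between the two solution paths.
#'
#' @param source A [source_field()].
#' @param spec A `cnt_model_spec`.
#' @param n_quad Subdivision limit for the adaptive quadrature.
#' @param radii Radii (m) at which to evaluate; default is the
#'   [steady_profile()] sampling with 201 points.
#' @param rel_tol Relative tolerance of the quadrature (default 1e-12).
#' @return A [radial_profile()].
#' @export
general_steady_solve <- function(source, spec, n_quad = 200L, radii = NULL,
                                 rel_tol = 1e-12) {
  stopifnot(inherits(source, "cnt_source"))
  g <- spec$geometry
  a <- g$cnt_radius; b <- g$far_radius; Tb <- g$far_temperature
  kc <- spec$cnt$thermal_conductivity
  kt <- spec$tissue$thermal_conductivity
  if (is.null(radii)) radii <- .profile_radii(spec, 201L, "uniform")
  radii <- sort(radii)
  if (radii[1L] < 0 || radii[length(radii)] > b) {
    stop("domain error: radii must lie in [0, b]", call. = FALSE)
  }

  q <- source$fun
  err_budget <- 0
  quad <- function(f, lo, hi, abs_tol) {
    if (hi <= lo) return(0)
    res <- stats::integrate(f, lo, hi, rel.tol = rel_tol, abs.tol = abs_tol,
                            subdivisions = max(n_quad, 10L),
                            stop.on.error = FALSE)
    if (!res$message %in% c("OK", "the integral is probably divergent")) {
      stop(sprintf(
        "numerical-accuracy error: quadrature did not converge (%s), achieved tolerance %.3e",
        res$message, res$abs.error), call. = FALSE)
    }
    err_budget <<- err_budget + res$abs.error
    res$value
  }

  Qa <- quad(function(s) q(s) * s, 0, a, abs_tol = 0)
  atol <- max(rel_tol * abs(Qa), .Machine$double.xmin)
  Ta <- Tb + Qa / kt * log(b / a)

  temps <- numeric(length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    if (r >= a) {
      temps[i] <- Tb + Qa / kt * log(b / r)
    } else {
      I2 <- quad(function(u) q(u) * u * log(a / u), r, a, abs_tol = atol)
      if (r == 0) {
        temps[i] <- Ta + I2 / kc
      } else {
        I1 <- quad(function(s) q(s) * s, 0, r, abs_tol = atol)
        temps[i] <- Ta + log(a / r) / kc * I1 + I2 / kc
      }
    }
  }

  scale <- max(abs(Qa) / kt * log(b / a), abs(Qa) / kc, 1e-300)
  if (err_budget / max(kt, kc) > 1e3 * rel_tol * scale + 1e-30) {
    stop(sprintf(
      "numerical-accuracy error: accumulated quadrature error %.3e exceeds tolerance",
      err_budget), call. = FALSE)
  }
  radial_profile(radii, temps, spec)
}
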