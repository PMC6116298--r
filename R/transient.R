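#' Interface-conforming radial grid
#'
#' Finite-volume grid on `[0, b]` with a cell edge exactly at the CNT
#' radius `a`, so the material discontinuity coincides with a face and the
#' harmonic-mean face conductivity reproduces flux continuity exactly for
#' piecewise-linear profiles. The tissue shell may be meshed uniformly or
#' geometrically; geometric spacing matches the first tissue cell width to
#' the CNT cell width and grows by a constant ratio, concentrating
#' resolution where the logarithmic profile is steepest.
#'
#' @param spec A `cnt_model_spec`.
#' @param n_inside Cells in `[0, a]` (>= 2).
#' @param n_outside Cells in `[a, b]` (>= 2).
#' @param outside_spacing `"geometric"` (default) or `"uniform"`.
#' @return An object of class `radial_grid`: `edges` (length
#'   `n_inside + n_outside + 1`), `centers`, `region` per cell, and the
#'   grid parameters.
#' @export
build_grid <- function(spec, n_inside = 100L, n_outside = 300L,
                       outside_spacing = c("geometric", "uniform")) {
  outside_spacing <- match.arg(outside_spacing)
  n_inside <- as.integer(n_inside); n_outside <- as.integer(n_outside)
  if (n_inside < 2L || n_outside < 2L) {
    stop("n_inside and n_outside must each be >= 2", call. = FALSE)
  }
  a <- spec$geometry$cnt_radius; b <- spec$geometry$far_radius
  edges_in <- seq(0, a, length.out = n_inside + 1L)
  edges_in[n_inside + 1L] <- a
  if (outside_spacing == "uniform") {
    edges_out <- seq(a, b, length.out = n_outside + 1L)[-1L]
  } else {
    w1 <- a / n_inside
    target <- b - a
    span <- function(lg) w1 * sum(exp(lg * (0:(n_outside - 1L)))) - target
    if (abs(span(0)) < 1e-12 * target) {
      ratio <- 1
    } else {
      # ratio stays well below 2 in practice; the bracket keeps g^n finite
      ratio <- exp(stats::uniroot(span, c(-2, log(2)), tol = 1e-15)$root)
    }
    widths <- w1 * ratio^(0:(n_outside - 1L))
    edges_out <- a + cumsum(widths)
  }
  edges_out[n_outside] <- b
  .grid_from_edges(c(edges_in, edges_out), a, b, outside_spacing)
}

.grid_from_edges <- function(edges, a, b, spacing) {
  if (any(diff(edges) <= 0)) stop("grid edges must be strictly increasing",
                                  call. = FALSE)
  if (!any(edges == a)) stop("grid must have an edge exactly at r = a",
                             call. = FALSE)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  region <- ifelse(centers < a, "inside", "outside")
  structure(list(edges = edges, centers = centers, region = region,
                 n_inside = sum(region == "inside"),
                 n_outside = sum(region == "outside"),
                 cnt_radius = a, far_radius = b, spacing = spacing),
            class = "radial_grid")
}

#' Halve the spacing of a radial grid
#'
#' Splits every cell at its midpoint, for grid-convergence (Richardson)
#' studies: each local width halves, preserving the edge at `r = a`.
#'
#' @param grid A [build_grid()] result.
#' @return A `radial_grid` with twice as many cells.
#' @export
refine_grid <- function(grid) {
  e <- grid$edges
  mids <- (e[-1L] + e[-length(e)]) / 2
  .grid_from_edges(sort(c(e, mids)), grid$cnt_radius, grid$far_radius,
                   grid$spacing)
}

# Nondimensionalization: xi = r/a, theta = (T - Tb)/dT_ref with
# dT_ref = q0 a^2/(2 kt) (1 K when the laser is off), tau = t kt/(a^2 rho_t c_t).
# Raw SI assembly at nm scale is badly scaled; in these variables all
# coefficients are O(1) except the conductivity ratio kc/kt itself.
.transient_scales <- function(spec) {
  kt <- spec$tissue$thermal_conductivity
  rt <- spec$tissue$density; ct <- spec$tissue$specific_heat
  if (is.na(rt) || is.na(ct) || is.na(spec$cnt$density) ||
      is.na(spec$cnt$specific_heat)) {
    stop("transient solver requires density and specific_heat for both materials",
         call. = FALSE)
  }
  a <- spec$geometry$cnt_radius
  q0 <- constant_heating(spec$laser)
  dT_ref <- if (q0 > 0) q0 * a^2 / (2 * kt) else 1
  list(a = a, dT_ref = dT_ref, t_star = a^2 * rt * ct / kt, q0 = q0, kt = kt)
}

# Scaled FV system pieces shared by step() and solve_to_steady().
.fv_system <- function(grid, spec, source, sc) {
  a <- sc$a
  xi_e <- grid$edges / a
  xi_c <- grid$centers / a
  n <- length(xi_c)
  kc <- spec$cnt$thermal_conductivity
  kt <- spec$tissue$thermal_conductivity
  inside <- grid$region == "inside"
  ktil <- ifelse(inside, kc / kt, 1)
  rhoc <- ifelse(inside,
                 (spec$cnt$density * spec$cnt$specific_heat) /
                   (spec$tissue$density * spec$tissue$specific_heat), 1)
  V <- pi * diff(xi_e^2)
  # interior faces (between cells i and i+1, at xi_e[i+1]); harmonic mean
  # conductivity weighted by the half-widths on each side
  dl <- xi_e[2:n] - xi_c[1:(n - 1L)]
  dr <- xi_c[2:n] - xi_e[2:n]
  kf <- (dl + dr) / (dl / ktil[1:(n - 1L)] + dr / ktil[2:n])
  G <- 2 * pi * xi_e[2:n] * kf / (dl + dr)
  # Dirichlet face at the outer edge (theta = 0 there)
  Gb <- 2 * pi * xi_e[n + 1L] * ktil[n] / (xi_e[n + 1L] - xi_c[n])
  # scaled source: rho~ c~ dtheta/dtau = div(k~ grad theta) + s,
  # s = q(r) a^2 / (kt dT_ref)
  s <- source$fun(grid$centers) * a^2 / (sc$kt * sc$dT_ref)
  list(n = n, V = V, G = G, Gb = Gb, rhoc = rhoc, SV = s * V)
}

.thomas <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1L] <- upper[1L] / diag[1L]
  dp[1L] <- rhs[1L] / diag[1L]
  for (i in 2:n) {
    m <- diag[i] - lower[i - 1L] * cp[i - 1L]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

.fv_tridiag <- function(sys, inv_dtau) {
  n <- sys$n
  aP <- sys$rhoc * sys$V * inv_dtau
  diagv <- aP + c(sys$G, 0) + c(0, sys$G)
  diagv[n] <- diagv[n] + sys$Gb
  list(lower = -sys$G, diag = diagv, upper = -sys$G, aP = aP)
}

#' One implicit time step
#'
#' Advances the cell-centre temperature field by one backward-Euler step of
#' the axisymmetric two-region conduction equation (zero-flux at the axis,
#' fixed `Tb` at `r = b`, harmonic-mean flux continuity at `r = a`). The
#' implicit discretization is unconditionally stable, so `dt` is limited by
#' accuracy of the transient path, not stability.
#'
#' @param state Temperatures (kelvin) at the grid cell centres.
#' @param dt Time step in seconds (> 0).
#' @param spec A `cnt_model_spec` (must carry densities and specific heats).
#' @param source A [source_field()].
#' @param grid A [build_grid()] result.
#' @return Updated temperature vector (kelvin).
#' @export
step <- function(state, dt, spec, source, grid) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number of seconds", call. = FALSE)
  }
  sc <- .transient_scales(spec)
  if (length(state) != length(grid$centers)) {
    stop("state length does not match the grid", call. = FALSE)
  }
  sys <- .fv_system(grid, spec, source, sc)
  inv_dtau <- sc$t_star / dt
  tri <- .fv_tridiag(sys, inv_dtau)
  theta <- (state - spec$geometry$far_temperature) / sc$dT_ref
  rhs <- tri$aP * theta + sys$SV
  theta_new <- .thomas(tri$lower, tri$diag, tri$upper, rhs)
  spec$geometry$far_temperature + sc$dT_ref * theta_new
}

#' March the transient problem to its steady state
#'
#' Backward-Euler time integration from a uniform body-temperature initial
#' condition until the max-norm temperature change per step, normalized by
#' the current rise `max(T) - Tb`, falls below `rel_tol`. This is the
#' numerical companion of the closed form: its converged profile must agree
#' with [steady_temperature()] to discretization error, which quantifies
#' what the steady-state simplification of the governing equations
#' discards.
#'
#' @param spec A `cnt_model_spec` with densities and specific heats.
#' @param source A [source_field()]; default the constant source.
#' @param grid A [build_grid()]; default the 400-cell geometric grid.
#' @param rel_tol Convergence tolerance on the normalized per-step change
#'   (default 1e-10).
#' @param max_steps Step limit before declaring non-convergence.
#' @param dt Time step in seconds; default 1/100 of the tissue-shell
#'   diffusion time `b^2 rho_t c_t / kt`.
#' @param store_every Store a profile snapshot every this many steps
#'   (0 = first and final only).
#' @return An object of class `transient_solution`: `times` (s),
#'   `profiles` (list of [radial_profile()] at stored times), `final_K`,
#'   `residual_history`, `steps`, `time_to_steady_s`, `converged`, plus the
#'   grid and time step used.
#' @export
solve_to_steady <- function(spec, source = source_field(spec, "constant"),
                            grid = build_grid(spec), rel_tol = 1e-10,
                            max_steps = 50000L, dt = NULL, store_every = 0L) {
  if (!is.numeric(rel_tol) || rel_tol <= 0) stop("rel_tol must be > 0",
                                                 call. = FALSE)
  sc <- .transient_scales(spec)
  b <- spec$geometry$far_radius
  t_diff <- b^2 * spec$tissue$density * spec$tissue$specific_heat /
    spec$tissue$thermal_conductivity
  if (is.null(dt)) dt <- t_diff / 100
  sys <- .fv_system(grid, spec, source, sc)
  inv_dtau <- sc$t_star / dt
  tri <- .fv_tridiag(sys, inv_dtau)
  n <- sys$n
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- tri$diag
  A[cbind(2:n, 1:(n - 1L))] <- tri$lower
  A[cbind(1:(n - 1L), 2:n)] <- tri$upper
  Ainv <- tryCatch(solve(A), error = function(e) {
    stop(sprintf("numerical error: implicit system is singular (%s)",
                 conditionMessage(e)), call. = FALSE)
  })

  Tb <- spec$geometry$far_temperature
  theta <- numeric(n)
  residuals <- numeric(0)
  times <- 0
  profiles <- list(radial_profile(grid$centers, rep(Tb, n), spec))
  converged <- FALSE
  steps <- 0L
  while (steps < max_steps) {
    steps <- steps + 1L
    theta_new <- drop(Ainv %*% (tri$aP * theta + sys$SV))
    res <- max(abs(theta_new - theta)) /
      max(max(theta_new), .Machine$double.eps)
    residuals <- c(residuals, res)
    theta <- theta_new
    if (store_every > 0L && steps %% store_every == 0L) {
      times <- c(times, steps * dt)
      profiles <- c(profiles, list(radial_profile(grid$centers,
                                                  Tb + sc$dT_ref * theta,
                                                  spec)))
    }
    if (res < rel_tol) { converged <- TRUE; break }
  }
  final_K <- Tb + sc$dT_ref * theta
  if (!converged) {
    stop(sprintf(
      "non-convergence: %d steps reached with normalized residual %.3e (rel_tol %.3e)",
      steps, residuals[length(residuals)], rel_tol), call. = FALSE)
  }
  if (store_every <= 0L || steps %% store_every != 0L) {
    times <- c(times, steps * dt)
    profiles <- c(profiles, list(radial_profile(grid$centers, final_K, spec)))
  }
  structure(list(times = times, profiles = profiles, final_K = final_K,
                 residual_history = residuals, steps = steps,
                 time_to_steady_s = steps * dt, converged = TRUE,
                 grid = grid, dt = dt, spec = spec),
            class = "transient_solution")
}

#' @export
print.transient_solution <- function(x, ...) {
  cat("<transient_solution>\n")
  cat(sprintf("  %d cells, %d steps of dt = %.3e s (t = %.3e s)\n",
              length(x$grid$centers), x$steps, x$dt, x$time_to_steady_s))
  cat(sprintf("  final residual %.3e, interface T = %.4f C\n",
              x$residual_history[length(x$residual_history)],
              K_to_C(fv_interface_temperature(x))))
  invisible(x)
}

#' Interface temperature of a finite-volume solution
#'
#' Face value at `r = a` reconstructed from the two adjacent cell centres
#' with conductivity-over-distance weights — the interpolation that is
#' exact for the piecewise-linear profiles the harmonic-mean flux assumes.
#'
#' @param solution A [solve_to_steady()] result, or a numeric temperature
#'   vector (then `grid` and `spec` are required).
#' @param grid,spec Grid and spec when `solution` is a bare vector.
#' @return Interface temperature in kelvin.
#' @export
fv_interface_temperature <- function(solution, grid = NULL, spec = NULL) {
  if (inherits(solution, "transient_solution")) {
    grid <- solution$grid; spec <- solution$spec
    temps <- solution$final_K
  } else {
    temps <- solution
  }
  a <- grid$cnt_radius
  iL <- grid$n_inside; iR <- iL + 1L
  dL <- a - grid$centers[iL]; dR <- grid$centers[iR] - a
  wL <- spec$cnt$thermal_conductivity / dL
  wR <- spec$tissue$thermal_conductivity / dR
  (wL * temps[iL] + wR * temps[iR]) / (wL + wR)
}

#' Conductive heat flow through each grid face
#'
#' Per unit cylinder length (W m^-1), from the discrete two-point fluxes
#' with harmonic-mean face conductivity; the axis face carries zero flow.
#' At discrete steady state every face outside the CNT carries the total
#' generated power per unit length, `pi a^2 q`.
#'
#' @inheritParams fv_interface_temperature
#' @return Numeric vector, one value per grid edge.
#' @export
fv_face_heat_flow <- function(solution, grid = NULL, spec = NULL) {
  if (inherits(solution, "transient_solution")) {
    grid <- solution$grid; spec <- solution$spec
    temps <- solution$final_K
  } else {
    temps <- solution
  }
  kc <- spec$cnt$thermal_conductivity
  kt <- spec$tissue$thermal_conductivity
  a <- grid$cnt_radius
  e <- grid$edges; cc <- grid$centers; n <- length(cc)
  ktil <- ifelse(grid$region == "inside", kc, kt)
  dl <- e[2:n] - cc[1:(n - 1L)]
  dr <- cc[2:n] - e[2:n]
  kf <- (dl + dr) / (dl / ktil[1:(n - 1L)] + dr / ktil[2:n])
  F_int <- 2 * pi * e[2:n] * kf * (temps[1:(n - 1L)] - temps[2:n]) / (dl + dr)
  Tb <- spec$geometry$far_temperature
  F_out <- 2 * pi * e[n + 1L] * kt * (temps[n] - Tb) / (e[n + 1L] - cc[n])
  c(0, F_int, F_out)
}

#' Write transient snapshots as delimited text
#'
#' Long-format CSV with columns `t_s`, `r_m`, `T_C`.
#'
#' @param solution A [solve_to_steady()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transient <- function(solution, path) {
  stopifnot(inherits(solution, "transient_solution"))
  rows <- do.call(rbind, lapply(seq_along(solution$times), function(i) {
    p <- solution$profiles[[i]]
    data.frame(t_s = sprintf("%.17g", solution$times[i]),
               r_m = sprintf("%.17g", p$r_m),
               T_C = sprintf("%.17g", p$T_C), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
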