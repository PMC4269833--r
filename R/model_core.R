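#' Model parameters of the thin-film active chiral fluid
#'
#' The cortex is described as a thin film of an active chiral fluid. Under
#' azimuthal symmetry the AP velocity \eqn{v_x} and the orthogonal (chiral)
#' velocity \eqn{v_y} obey
#' \deqn{\ell\,\partial_x^2 v_x - v_x/\ell = \partial_x T, \qquad
#'       \tfrac{\ell}{2}\,\partial_x^2 v_y - v_y/\ell = \partial_x \tau,}
#' where the active tension \eqn{T = \alpha I} and the active torque
#' density \eqn{\tau = \beta I} are proportional to the local myosin
#' intensity \eqn{I(x)}. The hydrodynamic length \eqn{\ell = \eta/\gamma}
#' sets the screening of flow by friction with membrane and cytoplasm; the
#' 2D viscosity \eqn{\eta} and friction \eqn{\gamma} are not separately
#' identifiable, so tension and torque are carried in velocity units
#' (physical stress divided by \eqn{\gamma}). The chirality index
#' \eqn{c = \tau/T = \beta/\alpha} measures how much motor activity goes
#' into torque relative to tension.
#'
#' @param ell hydrodynamic length \eqn{\ell} in micrometres, positive.
#' @param alpha tension coefficient \eqn{\alpha} (velocity per intensity
#'   unit).
#' @param beta torque coefficient \eqn{\beta} (same units as `alpha`).
#' @return An object of class `model_params` with fields `ell`, `alpha`,
#'   `beta` and the derived chirality index `c`.
#' @examples
#' model_params(ell = 16, alpha = 1, beta = 0.58)
#' @export
model_params <- function(ell, alpha, beta) {
  stopifnot(is.numeric(ell), length(ell) == 1L, is.finite(ell),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (ell <= 0) stop("`ell` must be positive", call. = FALSE)
  structure(list(ell = ell, alpha = alpha, beta = beta,
                 c = if (alpha != 0) beta / alpha else NA_real_),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("Active chiral fluid parameters:\n  ell = %.4g um, alpha = %.4g, beta = %.4g, c = beta/alpha = %.4g\n",
              x$ell, x$alpha, x$beta, x$c))
  invisible(x)
}

#' Solver configuration
#'
#' Discretisation settings for the two-point boundary-value solver. The
#' solver grid is uniform on the span of the input profile.
#'
#' @param n_nodes number of solver nodes (at least 11; default 201).
#' @param interp interpolation used to resample the measured intensity
#'   profile onto the solver grid and the solution back to the measurement
#'   bins: `"monotone"` (shape-preserving cubic, default) or `"linear"`.
#' @param bc_vx,bc_vy length-2 Dirichlet boundary velocities
#'   (micrometres/min) at the anterior and posterior ends of the domain.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(n_nodes = 201L, interp = c("monotone", "linear"),
                          bc_vx = c(0, 0), bc_vy = c(0, 0)) {
  interp <- match.arg(interp)
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(bc_vx) == 2L, length(bc_vy) == 2L,
            all(is.finite(bc_vx)), all(is.finite(bc_vy)))
  if (n_nodes < 11L) stop("`n_nodes` must be at least 11", call. = FALSE)
  structure(list(n_nodes = n_nodes, interp = interp,
                 bc_vx = as.numeric(bc_vx), bc_vy = as.numeric(bc_vy)),
            class = "solver_config")
}

#' Active tension (or torque density) profile from myosin intensity
#'
#' Pointwise linear coupling \eqn{T(x) = \alpha I(x)}; with `alpha` set to
#' the torque coefficient the same function returns \eqn{\tau(x)}.
#'
#' @param intensity an intensity [axial_profile()].
#' @param alpha coupling coefficient.
#' @return A velocity-kind `axial_profile` with values `alpha * I(x)` on
#'   the same grid.
#' @export
tension_profile <- function(intensity, alpha) {
  stopifnot(inherits(intensity, "axial_profile"),
            identical(intensity$kind, "intensity"),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  axial_profile(intensity$x, alpha * intensity$values, kind = "velocity")
}

# Thomas algorithm for a tridiagonal system; `lower` and `upper` have
# length n-1, `diagonal` length n.  Written out because the system is
# solved thousands of times inside the profiled fit.
solve_tridiagonal <- function(lower, diagonal, upper, rhs) {
  n <- length(diagonal)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  cp[1L] <- upper[1L] / diagonal[1L]
  dp[1L] <- rhs[1L] / diagonal[1L]
  for (i in 2:n) {
    denom <- diagonal[i] - lower[i - 1L] * cp[i - 1L]
    if (denom == 0) stop("singular tridiagonal system", call. = FALSE)
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# d/dx by second-order central differences on a uniform grid, one-sided
# second-order stencils at the two boundary nodes
uniform_gradient <- function(values, h) {
  n <- length(values)
  g <- numeric(n)
  g[2:(n - 1L)] <- (values[3:n] - values[1:(n - 2L)]) / (2 * h)
  g[1L] <- (-3 * values[1L] + 4 * values[2L] - values[3L]) / (2 * h)
  g[n] <- (3 * values[n] - 4 * values[n - 1L] + values[n - 2L]) / (2 * h)
  g
}

# Core finite-difference solve of  visc_factor * ell * v'' - v/ell = g(x)
# with Dirichlet boundary values bc = c(left, right) on a uniform grid.
# visc_factor is 1 for the axial equation and 1/2 for the chiral one.
solve_screened_ode <- function(gx, h, ell, visc_factor, bc) {
  n <- length(gx)
  v <- numeric(n)
  v[1L] <- bc[1L]
  v[n] <- bc[2L]
  m <- n - 2L
  a <- visc_factor * ell / h^2
  diagonal <- rep(-2 * a - 1 / ell, m)
  off <- rep(a, m - 1L)
  rhs <- gx[2:(n - 1L)]
  rhs[1L] <- rhs[1L] - a * bc[1L]
  rhs[m] <- rhs[m] - a * bc[2L]
  v[2:(n - 1L)] <- solve_tridiagonal(off, diagonal, off, rhs)
  v
}

# resample the intensity onto the uniform solver grid; returns list with
# grid x, step h, and intensity values
solver_grid <- function(intensity, cfg) {
  xg <- seq(min(intensity$x), max(intensity$x), length.out = cfg$n_nodes)
  f <- profile_interpolant(intensity, cfg$interp)
  Ig <- f(xg)
  Ig[Ig < 0] <- 0  # monotone interpolation keeps sign, guard anyway
  list(x = xg, h = xg[2L] - xg[1L], I = Ig)
}

solve_flow_component <- function(intensity, coupling, ell, visc_factor,
                                 bc, cfg) {
  if (anyNA(intensity$values) || any(!is.finite(intensity$values))) {
    stop("intensity profile contains non-finite values", call. = FALSE)
  }
  g <- solver_grid(intensity, cfg)
  src <- uniform_gradient(coupling * g$I, g$h)
  v <- solve_screened_ode(src, g$h, ell, visc_factor, bc)
  axial_profile(g$x, v, kind = "velocity")
}

#' Solve the axial (AP) flow equation
#'
#' Solves \eqn{\ell\,\partial_x^2 v_x - v_x/\ell = \partial_x(\alpha I)}
#' as a two-point boundary-value problem with Dirichlet boundary
#' velocities `cfg$bc_vx` at the two ends of the intensity profile's
#' domain, by second-order central finite differences on a uniform grid.
#'
#' @param intensity myosin intensity [axial_profile()].
#' @param params [model_params()].
#' @param cfg [solver_config()].
#' @return The axial velocity \eqn{v_x} as an `axial_profile` on the
#'   solver grid.
#' @export
solve_axial_flow <- function(intensity, params, cfg = solver_config()) {
  stopifnot(inherits(params, "model_params"), inherits(cfg, "solver_config"))
  solve_flow_component(intensity, params$alpha, params$ell, 1, cfg$bc_vx, cfg)
}

#' Solve the chiral (orthogonal) flow equation
#'
#' Solves \eqn{\tfrac{\ell}{2}\,\partial_x^2 v_y - v_y/\ell =
#' \partial_x(\beta I)} with Dirichlet boundary velocities `cfg$bc_vy`.
#' The factor 1/2 on the viscous term gives the chiral component an
#' effective screening length \eqn{\ell/\sqrt{2}}, shorter than the axial
#' one.
#'
#' @inheritParams solve_axial_flow
#' @return The chiral velocity \eqn{v_y} as an `axial_profile` on the
#'   solver grid.
#' @export
solve_chiral_flow <- function(intensity, params, cfg = solver_config()) {
  stopifnot(inherits(params, "model_params"), inherits(cfg, "solver_config"))
  solve_flow_component(intensity, params$beta, params$ell, 0.5, cfg$bc_vy, cfg)
}

#' Forward model: both velocity components on the measurement grid
#'
#' Runs both flow solves on a fine uniform grid and resamples the
#' solutions back onto the grid of the input intensity profile (the 18
#' AP bins for measured data).
#'
#' @inheritParams solve_axial_flow
#' @return A list with `vx` and `vy`, both velocity `axial_profile`s on
#'   the measurement grid of `intensity`.
#' @export
forward_model <- function(intensity, params, cfg = solver_config()) {
  vx_fine <- solve_axial_flow(intensity, params, cfg)
  vy_fine <- solve_chiral_flow(intensity, params, cfg)
  resample <- function(fine) {
    f <- profile_interpolant(fine, cfg$interp)
    axial_profile(intensity$x, f(intensity$x), kind = "velocity")
  }
  list(vx = resample(vx_fine), vy = resample(vy_fine))
}
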