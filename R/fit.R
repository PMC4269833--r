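#' Fit the active chiral fluid model to measured velocity profiles
#'
#' Estimates the hydrodynamic length \eqn{\ell}, the tension coefficient
#' \eqn{\alpha} and the torque coefficient \eqn{\beta} (hence the
#' chirality index \eqn{c = \beta/\alpha}) by least squares: the model
#' velocity profiles computed from the measured myosin intensity are
#' matched to the observed AP (\eqn{v_x}) and chiral (\eqn{v_y}) velocity
#' profiles, minimising
#' \deqn{RSS(\ell, \alpha, \beta) = \sum_i (v_x^{mod} - v_x^{obs})_i^2 +
#'       \sum_i (v_y^{mod} - v_y^{obs})_i^2}
#' over interior bins. The two extreme points of each measured velocity
#' profile are imposed as Dirichlet boundary conditions and are therefore
#' excluded from the residual.
#'
#' Because the model is linear in \eqn{\alpha} and \eqn{\beta} for fixed
#' \eqn{\ell}, the fit is profiled: an outer 1D minimisation over
#' \eqn{\ell} with the inner linear least-squares problem for
#' \eqn{(\alpha, \beta)} solved exactly at each step, followed by a
#' Nelder-Mead polish of the full three-parameter objective. Standard
#' errors come from the curvature (Hessian) of half the residual sum of
#' squares at the optimum; the standard error of \eqn{c} follows by
#' first-order error propagation from \eqn{(\alpha, \beta)} including
#' their covariance.
#'
#' @param intensity myosin intensity [axial_profile()] on the measurement
#'   bins.
#' @param vx_obs,vy_obs observed velocity [axial_profile()]s on the same
#'   bins as `intensity`.
#' @param cfg [solver_config()]; its boundary values are overwritten with
#'   the endpoints of `vx_obs` and `vy_obs`.
#' @param ell_interval search interval for \eqn{\ell} (micrometres);
#'   default `c(0.05, 5)` times the domain length.
#' @param hessian_step relative step of the central finite-difference
#'   Hessian used for the uncertainties.
#' @param weight_vy weight of the \eqn{v_y} residuals relative to
#'   \eqn{v_x} (default 1: equal weighting).
#' @return An object of class `chiral_fit` with components
#'   \describe{
#'     \item{params}{fitted [model_params()]}
#'     \item{stderr}{named standard errors for `ell`, `alpha`, `beta`, `c`}
#'     \item{rss}{residual sum of squares at the optimum}
#'     \item{n_obs}{number of fitted samples (interior vx + interior vy)}
#'     \item{sigma2}{residual variance estimate `rss / (n_obs - 3)`}
#'     \item{converged, identifiable}{diagnostic flags}
#'     \item{fitted}{model `vx`/`vy` profiles on the measurement grid}
#'   }
#'   with `print`, `summary`, `coef`, `vcov`, `confint`, `predict`,
#'   `fitted`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' I <- make_intensity_profile(synthetic_spec())
#' truth <- model_params(ell = 16, alpha = 10, beta = 5.8)
#' vel <- forward_model(I, truth)
#' fit <- chiral_fit(I, vel$vx, vel$vy)
#' coef(fit)
#' @export
chiral_fit <- function(intensity, vx_obs, vy_obs, cfg = solver_config(),
                       ell_interval = NULL, hessian_step = 1e-4,
                       weight_vy = 1) {
  stopifnot(inherits(intensity, "axial_profile"),
            inherits(vx_obs, "axial_profile"),
            inherits(vy_obs, "axial_profile"),
            inherits(cfg, "solver_config"))
  if (!isTRUE(all.equal(intensity$x, vx_obs$x)) ||
      !isTRUE(all.equal(intensity$x, vy_obs$x))) {
    stop("intensity and velocity profiles must share the same grid",
         call. = FALSE)
  }
  n <- intensity$n
  interior <- 2:(n - 1L)
  cfg$bc_vx <- vx_obs$values[c(1L, n)]
  cfg$bc_vy <- vy_obs$values[c(1L, n)]
  L <- diff(range(intensity$x))
  if (is.null(ell_interval)) ell_interval <- c(0.05, 5) * L

  vx_int <- vx_obs$values[interior]
  vy_int <- vy_obs$values[interior]
  n_obs <- 2L * length(interior)

  g <- solver_grid(intensity, cfg)
  to_bins <- function(v_fine) {
    stats::splinefun(g$x, v_fine, method = "monoH.FC")(intensity$x)[interior]
  }

  # unit responses and boundary-driven parts on the measurement bins;
  # model_x = alpha * Ux + Bx, model_y = beta * Uy + By (linear in each)
  responses <- function(ell) {
    src <- uniform_gradient(g$I, g$h)
    zero <- numeric(length(g$x))
    list(
      Ux = to_bins(solve_screened_ode(src, g$h, ell, 1, c(0, 0))),
      Bx = to_bins(solve_screened_ode(zero, g$h, ell, 1, cfg$bc_vx)),
      Uy = to_bins(solve_screened_ode(src, g$h, ell, 0.5, c(0, 0))),
      By = to_bins(solve_screened_ode(zero, g$h, ell, 0.5, cfg$bc_vy))
    )
  }

  profiled <- function(ell) {
    r <- responses(ell)
    sxx <- sum(r$Ux^2)
    syy <- sum(r$Uy^2)
    alpha <- if (sxx > 0) sum(r$Ux * (vx_int - r$Bx)) / sxx else 0
    beta <- if (syy > 0) sum(r$Uy * (vy_int - r$By)) / syy else 0
    rss <- sum((alpha * r$Ux + r$Bx - vx_int)^2) +
      weight_vy * sum((beta * r$Uy + r$By - vy_int)^2)
    list(rss = rss, alpha = alpha, beta = beta, sxx = sxx, syy = syy)
  }

  objective <- function(theta) {
    ell <- theta[1L]
    if (ell < ell_interval[1L] || ell > ell_interval[2L]) return(Inf)
    r <- responses(ell)
    sum((theta[2L] * r$Ux + r$Bx - vx_int)^2) +
      weight_vy * sum((theta[3L] * r$Uy + r$By - vy_int)^2)
  }

  degenerate <- all(vx_obs$values == 0) && all(vy_obs$values == 0)
  opt <- stats::optimize(function(e) profiled(e)$rss,
                         interval = ell_interval, tol = 1e-7 * L)
  prof <- profiled(opt$minimum)
  start <- c(opt$minimum, prof$alpha, prof$beta)

  nm <- stats::optim(start, objective, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 2000))
  theta <- if (nm$value <= opt$objective) nm$par else start
  rss <- min(nm$value, opt$objective)
  converged <- nm$convergence == 0L

  identifiable <- prof$sxx > 1e-12 * max(1, sum(vx_int^2)) && !degenerate
  params <- model_params(theta[1L], theta[2L], theta[3L])
  sigma2 <- rss / (n_obs - 3L)

  half_rss <- function(th) 0.5 * objective(th)
  H <- numeric_hessian(half_rss, theta, rel_step = hessian_step)
  unc <- fit_uncertainties(rss, H, n_obs, n_params = 3L)
  covm <- attr(unc, "cov")
  stderr_c <- propagate_ratio_se(theta[2L], theta[3L], covm)
  if (!identifiable) {
    unc[] <- NaN
    stderr_c <- NaN
  }

  fitted_prof <- forward_model(intensity, params, cfg)
  structure(list(
    params = params,
    stderr = c(ell = unc[[1L]], alpha = unc[[2L]], beta = unc[[3L]],
               c = stderr_c),
    rss = rss, n_obs = n_obs, sigma2 = sigma2,
    converged = converged, identifiable = identifiable,
    hessian = H, cov = covm,
    fitted = fitted_prof,
    observed = list(intensity = intensity, vx = vx_obs, vy = vy_obs),
    interior = interior, cfg = cfg, weight_vy = weight_vy,
    call = match.call()
  ), class = "chiral_fit")
}

# central finite-difference Hessian with per-coordinate relative steps
numeric_hessian <- function(f, theta, rel_step = 1e-4) {
  p <- length(theta)
  h <- rel_step * pmax(abs(theta), 1e-3)
  H <- matrix(NA_real_, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j <= i) next
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
           f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Standard errors from the curvature of the least-squares residual
#'
#' Given the Hessian \eqn{H} of half the residual sum of squares at the
#' optimum, the parameter covariance is estimated as
#' \eqn{s^2 H^{-1}} with \eqn{s^2 = RSS/(n_{obs} - n_{par})}, and the
#' standard errors are the square roots of its diagonal.
#'
#' @param rss residual sum of squares at the optimum.
#' @param hessian Hessian matrix of `0.5 * RSS` with respect to the
#'   parameters, e.g. by central finite differences.
#' @param n_obs number of fitted observations.
#' @param n_params number of free parameters.
#' @return Numeric vector of standard errors (one per parameter), with the
#'   covariance matrix attached as attribute `"cov"`. If the Hessian is
#'   not positive definite the fit has a flat direction: all standard
#'   errors are `NaN` and a warning is raised.
#' @export
fit_uncertainties <- function(rss, hessian, n_obs, n_params = 3L) {
  stopifnot(rss >= 0, n_obs > n_params)
  p <- nrow(hessian)
  ev <- if (all(is.finite(hessian))) {
    eigen(hessian, symmetric = TRUE, only.values = TRUE)$values
  } else {
    NaN
  }
  if (any(!is.finite(ev)) || min(ev) <= 0) {
    warning("Hessian not positive definite: flat direction in the fit; ",
            "standard errors are undefined", call. = FALSE)
    out <- rep(NaN, p)
    attr(out, "cov") <- matrix(NaN, p, p)
    return(out)
  }
  s2 <- rss / (n_obs - n_params)
  covm <- s2 * solve(hessian)
  out <- sqrt(pmax(diag(covm), 0))
  attr(out, "cov") <- covm
  out
}

# first-order propagation for c = beta/alpha given cov of (ell,alpha,beta)
propagate_ratio_se <- function(alpha, beta, covm) {
  if (alpha == 0 || any(!is.finite(covm))) return(NaN)
  grad <- c(0, -beta / alpha^2, 1 / alpha)
  v <- drop(t(grad) %*% covm %*% grad)
  if (v < 0) return(NaN)
  sqrt(v)
}

#' @export
print.chiral_fit <- function(x, ...) {
  cat("Active chiral fluid model fit\n")
  cat(sprintf("  ell   = %8.4g +/- %.3g um\n", x$params$ell, x$stderr["ell"]))
  cat(sprintf("  alpha = %8.4g +/- %.3g\n", x$params$alpha, x$stderr["alpha"]))
  cat(sprintf("  beta  = %8.4g +/- %.3g\n", x$params$beta, x$stderr["beta"]))
  cat(sprintf("  c     = %8.4g +/- %.3g\n", x$params$c, x$stderr["c"]))
  cat(sprintf("  RSS = %.4g on %d observations%s%s\n", x$rss, x$n_obs,
              if (!x$converged) " (not converged)" else "",
              if (!x$identifiable) " (parameters not identifiable)" else ""))
  invisible(x)
}

#' @export
summary.chiral_fit <- function(object, level = 0.99, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- coef(object)
  se <- object$stderr[names(est)]
  tab <- cbind(Estimate = est, `Std. Error` = se,
               Lower = est - z * se, Upper = est + z * se)
  out <- list(coefficients = tab, level = level, rss = object$rss,
              sigma = sqrt(object$sigma2), n_obs = object$n_obs,
              converged = object$converged,
              identifiable = object$identifiable)
  class(out) <- "summary.chiral_fit"
  out
}

#' @export
print.summary.chiral_fit <- function(x, ...) {
  cat("Active chiral fluid model fit\n\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("\nIntervals at %.0f%% confidence (normal approximation)\n",
              100 * x$level))
  cat(sprintf("Residual sd %.4g on %d observations (RSS %.4g)\n",
              x$sigma, x$n_obs, x$rss))
  invisible(x)
}

#' @export
coef.chiral_fit <- function(object, ...) {
  c(ell = object$params$ell, alpha = object$params$alpha,
    beta = object$params$beta, c = object$params$c)
}

#' @export
vcov.chiral_fit <- function(object, ...) {
  covm <- object$cov
  dimnames(covm) <- list(c("ell", "alpha", "beta"),
                         c("ell", "alpha", "beta"))
  covm
}

#' @export
confint.chiral_fit <- function(object, parm, level = 0.99, ...) {
  est <- coef(object)
  se <- object$stderr[names(est)]
  if (missing(parm)) parm <- names(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est[parm] - z * se[parm], est[parm] + z * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
fitted.chiral_fit <- function(object, ...) object$fitted

#' @export
residuals.chiral_fit <- function(object, ...) {
  i <- object$interior
  list(vx = object$observed$vx$values[i] - object$fitted$vx$values[i],
       vy = object$observed$vy$values[i] - object$fitted$vy$values[i])
}

#' @export
#' @param newdata optional intensity `axial_profile` at which to evaluate
#'   the fitted model; defaults to the intensity used in the fit.
#' @rdname chiral_fit
predict.chiral_fit <- function(object, newdata = NULL, ...) {
  intensity <- if (is.null(newdata)) object$observed$intensity else newdata
  forward_model(intensity, object$params, object$cfg)
}

#' @export
simulate.chiral_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(object$sigma2)
  base <- object$fitted
  lapply(seq_len(nsim), function(k) {
    list(vx = axial_profile(base$vx$x,
                            base$vx$values + stats::rnorm(base$vx$n, 0, sd),
                            "velocity"),
         vy = axial_profile(base$vy$x,
                            base$vy$values + stats::rnorm(base$vy$n, 0, sd),
                            "velocity"))
  })
}

#' @export
plot.chiral_fit <- function(x, ...) {
  obs <- x$observed
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (comp in c("vx", "vy")) {
    yl <- range(obs[[comp]]$values, x$fitted[[comp]]$values)
    graphics::plot(obs[[comp]]$x, obs[[comp]]$values, pch = 16,
                   xlab = "AP position (um)",
                   ylab = sprintf("%s (um/min)", comp),
                   main = sprintf("%s: data and model", comp), ylim = yl, ...)
    graphics::lines(x$fitted[[comp]]$x, x$fitted[[comp]]$values, col = 2,
                    lwd = 2)
  }
  invisible(x)
}
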