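# Independent oracles used across test files.

# Infinite-domain Green's-function solution of
#   visc_factor * ell * v'' - v/ell = d/dx (coupling * I)
# for a Gaussian intensity bump I = exp(-(x-x0)^2/(2*sigma^2)), by
# numerical quadrature of the analytic source derivative on a fine grid.
# Kernel: A * exp(-mu |x - x'|) with mu = sqrt(1/(visc_factor))/ell and
# jump condition visc_factor*ell*(-2*A*mu) = 1.
green_gaussian_solution <- function(xs, x0, sigma, ell, visc_factor,
                                    coupling = 1, n_quad = 20001L) {
  mu <- sqrt(1 / visc_factor) / ell
  A <- -1 / (2 * visc_factor * ell * mu)
  lo <- min(xs)
  hi <- max(xs)
  xq <- seq(lo, hi, length.out = n_quad)
  dq <- xq[2] - xq[1]
  src <- -coupling * (xq - x0) / sigma^2 * exp(-(xq - x0)^2 / (2 * sigma^2))
  vapply(xs, function(x) {
    A * sum(exp(-mu * abs(x - xq)) * src) * dq
  }, numeric(1))
}

# 3x3 rotation matrix about a unit axis (Rodrigues form), independent of
# the package's internal rotation helper
rotation_matrix3 <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# default 18-bin profile grid on a 50 um embryo
bin_centers_50 <- function(n_bins = 18L, L = 50) {
  breaks <- seq(0, L, length.out = n_bins + 1L)
  (breaks[-1L] + breaks[-length(breaks)]) / 2
}
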