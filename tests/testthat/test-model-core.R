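test_that("tension profile is the pointwise linear coupling T = alpha * I", {
  x <- bin_centers_50()
  ones <- axial_profile(x, rep(1, 18), "intensity")
  expect_equal(tension_profile(ones, 2)$values, rep(2, 18))
  expect_equal(tension_profile(ones, 0)$values, rep(0, 18))
  set.seed(7)
  I <- axial_profile(x, runif(18, 0, 3), "intensity")
  expect_identical(tension_profile(I, 1.7)$values, 1.7 * I$values)
})

test_that("uniform intensity with zero boundary velocities yields no flow", {
  x <- bin_centers_50()
  I <- axial_profile(x, rep(2.5, 18), "intensity")
  p <- model_params(16, 3, 1.7)
  expect_lt(max(abs(solve_axial_flow(I, p)$values)), 1e-12)
  expect_lt(max(abs(solve_chiral_flow(I, p)$values)), 1e-12)
})

test_that("axial and chiral solutions match the Green's-function oracle", {
  xs <- seq(0, 200, length.out = 401)
  I <- axial_profile(xs, exp(-(xs - 100)^2 / (2 * 0.5^2)), "intensity")
  p <- model_params(16, 1, 1)
  cfg <- solver_config(n_nodes = 2001)
  vx <- solve_axial_flow(I, p, cfg)
  vy <- solve_chiral_flow(I, p, cfg)
  ox <- green_gaussian_solution(vx$x, 100, 0.5, 16, 1)
  oy <- green_gaussian_solution(vy$x, 100, 0.5, 16, 0.5)
  expect_lt(rel_l2(vx$values, ox), 0.005)
  expect_lt(rel_l2(vy$values, oy), 0.005)
})

test_that("solutions converge under grid refinement", {
  xs <- bin_centers_50()
  I <- axial_profile(xs, ifelse(xs < 25, 2, 0.5), "intensity")
  p <- model_params(16, 1, 0.58)
  coarse <- forward_model(I, p, solver_config(n_nodes = 201))
  fine <- forward_model(I, p, solver_config(n_nodes = 2001))
  expect_lt(rel_l2(coarse$vx$values, fine$vx$values), 0.001)
  expect_lt(rel_l2(coarse$vy$values, fine$vy$values), 0.001)
})

test_that("interior nodes satisfy the discretised equation to 1e-10", {
  xs <- bin_centers_50()
  set.seed(11)
  I <- axial_profile(xs, runif(18, 0.5, 2), "intensity")
  p <- model_params(12, 2, 1)
  cfg <- solver_config(n_nodes = 201)
  for (comp in c("axial", "chiral")) {
    vf <- if (comp == "axial") 1 else 0.5
    coupling <- if (comp == "axial") p$alpha else p$beta
    v <- if (comp == "axial") solve_axial_flow(I, p, cfg)
         else solve_chiral_flow(I, p, cfg)
    h <- v$x[2] - v$x[1]
    f <- chiralflow:::profile_interpolant(I, cfg$interp)
    src <- chiralflow:::uniform_gradient(coupling * f(v$x), h)
    n <- length(v$x)
    lhs <- vf * p$ell * diff(diff(v$values)) / h^2 -
      v$values[2:(n - 1)] / p$ell
    expect_lt(max(abs(lhs - src[2:(n - 1)])),
              1e-10 * max(1, max(abs(src))))
  }
})

test_that("the solver is linear: superposition and (alpha, bc) scaling", {
  xs <- bin_centers_50()
  set.seed(3)
  I1 <- axial_profile(xs, runif(18, 0, 2), "intensity")
  I2 <- axial_profile(xs, runif(18, 0, 2), "intensity")
  Isum <- axial_profile(xs, I1$values + I2$values, "intensity")
  p <- model_params(16, 2, 1.2)
  # linear resampling: the whole solve is then exactly linear in I
  lin <- solver_config(interp = "linear")
  f1 <- forward_model(I1, p, lin)
  f2 <- forward_model(I2, p, lin)
  fs <- forward_model(Isum, p, lin)
  expect_lt(rel_l2(fs$vx$values, f1$vx$values + f2$vx$values), 1e-10)
  expect_lt(rel_l2(fs$vy$values, f1$vy$values + f2$vy$values), 1e-10)

  cfg1 <- solver_config(bc_vx = c(0.5, -1))
  cfg2 <- solver_config(bc_vx = c(1, -2))
  v1 <- solve_axial_flow(I1, model_params(16, 2, 0), cfg1)
  v2 <- solve_axial_flow(I1, model_params(16, 4, 0), cfg2)
  expect_lt(rel_l2(v2$values, 2 * v1$values), 1e-10)
})

test_that("finite-difference path equals a dense linear solve on small grids", {
  xs <- seq(0, 50, length.out = 7)
  set.seed(5)
  I <- axial_profile(xs, runif(7, 0.5, 2), "intensity")
  p <- model_params(10, 1.5, 0)
  cfg <- solver_config(n_nodes = 21)
  v <- solve_axial_flow(I, p, cfg)
  # dense brute-force solve of the same discretisation
  g <- chiralflow:::solver_grid(I, cfg)
  src <- chiralflow:::uniform_gradient(p$alpha * g$I, g$h)
  n <- cfg$n_nodes
  a <- p$ell / g$h^2
  A <- diag(-2 * a - 1 / p$ell, n - 2)
  A[cbind(1:(n - 3), 2:(n - 2))] <- a
  A[cbind(2:(n - 2), 1:(n - 3))] <- a
  dense <- c(0, solve(A, src[2:(n - 1)]), 0)
  expect_equal(v$values, dense, tolerance = 1e-13)
})

test_that("far-field decay lengths are ell (axial) and ell/sqrt(2) (chiral)", {
  for (ell in c(8, 16, 32)) {
    L <- 25 * ell
    xs <- seq(0, L, length.out = 801)
    I <- axial_profile(xs, exp(-(xs - L / 2)^2 / (2 * (ell / 8)^2)),
                       "intensity")
    p <- model_params(ell, 1, 1)
    cfg <- solver_config(n_nodes = 4001)
    vx <- solve_axial_flow(I, p, cfg)
    vy <- solve_chiral_flow(I, p, cfg)
    window <- function(v) v$x > L / 2 + 3 * ell & v$x < L / 2 + 8 * ell
    slope <- function(v) {
      k <- window(v)
      -1 / unname(coef(lm(log(abs(v$values[k])) ~ v$x[k]))[2])
    }
    expect_equal(slope(vx), ell, tolerance = 0.02)
    expect_equal(slope(vy), ell / sqrt(2), tolerance = 0.02)
  }
})

test_that("forward model returns bin-grid profiles consistent with the fine solution", {
  xs <- bin_centers_50()
  set.seed(9)
  I <- axial_profile(xs, runif(18, 0.5, 2), "intensity")
  expect_equal(max(abs(forward_model(I, model_params(16, 0, 0))$vx$values)),
               0)
  p <- model_params(16, -10, -5.8)
  fm <- forward_model(I, p, solver_config(n_nodes = 201))
  fine <- solve_axial_flow(I, p, solver_config(n_nodes = 201))
  resampled <- splinefun(fine$x, fine$values, method = "monoH.FC")(xs)
  expect_lt(max(abs(fm$vx$values - resampled)), 1e-6)
})

test_that("a myosin stripe drives inward axial flow and counter-rotating vy", {
  spec <- synthetic_spec(profile_family = "stripe", noise_sd = 0)
  I <- make_intensity_profile(spec)
  fm <- forward_model(I, spec$truth)
  n <- I$n
  left <- 2:(n / 2 - 1)
  right <- rev((n / 2 + 2):(n - 1))
  # antisymmetry about the stripe centre
  expect_equal(fm$vx$values[left], -fm$vx$values[right], tolerance = 1e-8)
  expect_equal(fm$vy$values[left], -fm$vy$values[right], tolerance = 1e-8)
  # axial flow directed toward the stripe from both sides
  expect_true(all(fm$vx$values[left] > 0))
  expect_true(all(fm$vx$values[right] < 0))
  # chiral flow counter-rotates across the stripe
  expect_true(all(fm$vy$values[left] > 0))
  expect_true(all(fm$vy$values[right] < 0))
})

test_that("anterior-high myosin with positive chirality gives negative v_c", {
  spec <- synthetic_spec(noise_sd = 0)   # sigmoid, c = 0.58
  fm <- forward_model(make_intensity_profile(spec), spec$truth)
  sch <- bin_scheme(c(0, spec$embryo_length))
  vc <- mean(fm$vy$values[sch$posterior_bins]) -
    mean(fm$vy$values[sch$anterior_bins])
  expect_lt(vc, 0)
})

test_that("non-finite intensities and bad configs are rejected", {
  xs <- bin_centers_50()
  I <- axial_profile(xs, runif(18), "intensity")
  I$values[4] <- NaN   # corrupt after construction
  expect_error(solve_axial_flow(I, model_params(16, 1, 1)), "non-finite")
  expect_error(solver_config(n_nodes = 5), "at least 11")
  expect_error(model_params(-1, 1, 1), "positive")
})
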