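grid_field <- function(vx, vy, L = 50, H = 13, spacing = 1, frame = 1) {
  pts <- expand.grid(x = seq(spacing / 2, L - spacing / 2, by = spacing),
                     y = seq(-H / 2 + 0.1, H / 2 - 0.1, length.out = 5))
  vxv <- if (is.function(vx)) vx(pts$x, pts$y) else rep(vx, nrow(pts))
  vyv <- if (is.function(vy)) vy(pts$x, pts$y) else rep(vy, nrow(pts))
  vector_field(frame, pts$x, pts$y, vxv, vyv)
}

test_that("binned profiles average the stripe-restricted velocities per bin", {
  sch <- bin_scheme(c(0, 50))
  f <- grid_field(0, 1)
  expect_equal(bin_velocity_profile(f, sch, "y")$values, rep(1, 18))

  f2 <- grid_field(0, function(x, y) ifelse(x < 25, 2, -3))
  p2 <- bin_velocity_profile(f2, sch, "y")
  expect_equal(p2$values, c(rep(2, 9), rep(-3, 9)))

  # brute-force re-aggregation oracle on a random field
  set.seed(31)
  f3 <- vector_field(1, runif(500, 0, 50), runif(500, -10, 10),
                     rnorm(500), rnorm(500))
  p3 <- bin_velocity_profile(f3, sch, "x")
  breaks <- seq(0, 50, length.out = 19)
  for (b in 1:18) {
    keep <- abs(f3$y) <= 6.5 & f3$x >= breaks[b] &
      (f3$x < breaks[b + 1] | (b == 18 & f3$x <= breaks[19]))
    expected <- if (any(keep)) mean(f3$vx[keep]) else NA_real_
    expect_equal(p3$values[b], expected)
  }
})

test_that("profile averaging is time-first within embryo, then across embryos", {
  x <- bin_centers_50()
  mk <- function(v) axial_profile(x, rep(v, 18), "velocity")
  # identical frames: average is any frame, sem 0 across identical embryos
  avg <- average_profiles(list(mk(1), mk(1), mk(1), mk(1)),
                          embryo = c(1, 1, 2, 2))
  expect_equal(avg$mean$values, rep(1, 18))
  expect_equal(avg$sem, rep(0, 18))
  # two embryos at 0 and 2: mean 1, sem 1
  avg2 <- average_profiles(list(mk(0), mk(2)), embryo = c(1, 2))
  expect_equal(avg2$mean$values, rep(1, 18))
  expect_equal(avg2$sem, rep(1, 18))
  # unbalanced frame counts: embryo-first differs from frame pooling
  avg3 <- average_profiles(list(mk(0), mk(0), mk(0), mk(3)),
                           embryo = c(1, 1, 1, 2))
  expect_equal(avg3$mean$values, rep(1.5, 18))  # pooled would give 0.75
  # single embryo: sem undefined
  expect_true(all(is.na(average_profiles(list(mk(1)))$sem)))
})

test_that("v_c is posterior-minus-anterior mean y-velocity", {
  sch <- bin_scheme(c(0, 50))
  in_bins <- function(x, bins) {
    idx <- findInterval(x, sch$breaks, rightmost.closed = TRUE)
    idx %in% bins
  }
  f <- grid_field(0, function(x, y) {
    ifelse(in_bins(x, sch$anterior_bins), 1,
           ifelse(in_bins(x, sch$posterior_bins), -2.5, 0))
  })
  expect_equal(counter_rotation_velocity(f, sch), -3.5)
  expect_equal(counter_rotation_velocity(grid_field(0, 2), sch), 0)
})

test_that("v_c is offset-invariant, sign-flips under mirror, scales linearly", {
  set.seed(17)
  f <- grid_field(0, function(x, y) sin(x / 7) + 0.3 * y)
  sch <- bin_scheme(c(0, 50))
  vc <- counter_rotation_velocity(f, sch)
  # constant vy offset shifts both regions equally
  f_off <- f; f_off$vy <- f$vy + 5
  expect_equal(counter_rotation_velocity(f_off, sch), vc,
               tolerance = 1e-12)
  # mirror y -> -y flips the chirality
  f_mir <- f; f_mir$y <- -f$y; f_mir$vy <- -f$vy
  expect_equal(counter_rotation_velocity(f_mir, sch), -vc,
               tolerance = 1e-12)
  # velocity rescaling commutes with binning and averaging
  f_sc <- f; f_sc$vx <- 3 * f$vx; f_sc$vy <- 3 * f$vy
  expect_equal(counter_rotation_velocity(f_sc, sch), 3 * vc,
               tolerance = 1e-12)
  p <- bin_velocity_profile(f, sch, "y")
  p_sc <- bin_velocity_profile(f_sc, sch, "y")
  expect_equal(p_sc$values, 3 * p$values, tolerance = 1e-12)
})

test_that("v_c from a model-driven field with c > 0 is negative", {
  spec <- synthetic_spec(noise_sd = 0)
  vf <- make_vector_field(spec, n_frames = 1)
  expect_lt(counter_rotation_velocity(vf$fields[[1]], vf$scheme), 0)
})

test_that("4-cell v_c measures shear across the cleavage plane", {
  # plane through origin along y; left of +y direction is x < 0
  mkpts <- expand.grid(x = seq(-4.75, 4.75, by = 0.5),
                       y = seq(-10, 10, by = 1))
  s <- 1.3
  f <- vector_field(1, mkpts$x, mkpts$y, 0, ifelse(mkpts$x < 0, s, -s))
  res <- counter_rotation_velocity_4cell(list(f), c(0, 0), c(0, 1))
  expect_equal(res$v_c, 2 * s, tolerance = 1e-12)

  # velocity purely along the plane normal contributes nothing
  fn <- vector_field(1, mkpts$x, mkpts$y, 2.2, 0)
  expect_equal(counter_rotation_velocity_4cell(list(fn), c(0, 0),
                                               c(0, 1))$v_c, 0)

  # rotating field and plane together leaves v_c unchanged
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- R %*% rbind(f$x, f$y)
  uv <- R %*% rbind(f$vx, f$vy)
  fr <- vector_field(1, xy[1, ], xy[2, ], uv[1, ], uv[2, ])
  res_r <- counter_rotation_velocity_4cell(list(fr), c(0, 0),
                                           drop(R %*% c(0, 1)))
  expect_equal(res_r$v_c, res$v_c, tolerance = 1e-10)

  # empty box drops the frame with a warning
  far <- vector_field(1, mkpts$x + 100, mkpts$y, 0, 1)
  expect_warning(res_e <- counter_rotation_velocity_4cell(
    list(far), c(0, 0), c(0, 1)), "dropped")
  expect_true(is.na(res_e$v_c))
})

test_that("half-embryo intensity differences match direct pixel averages", {
  img <- matrix(1, 20, 30)
  expect_equal(half_intensity_difference(img), 0)
  img2 <- cbind(matrix(1, 20, 15), matrix(2, 20, 15))
  expect_equal(half_intensity_difference(img2, split = "ap-halves"), 1)
  set.seed(13)
  img3 <- matrix(runif(600), 20, 30)
  mask <- matrix(runif(600) > 0.2, 20, 30)
  d <- half_intensity_difference(img3, mask, "top-bottom-posterior")
  post <- col(img3) > 15
  top <- row(img3) <= 10
  expect_equal(d, mean(img3[mask & post & top]) -
                 mean(img3[mask & post & !top]))
  expect_error(half_intensity_difference(img3, matrix(FALSE, 20, 30)),
               "empty")
})

test_that("condition comparisons use the two-sided rank-sum test", {
  set.seed(23)
  a <- rnorm(30)
  expect_false(compare_conditions(a, a)$significant)
  b <- rnorm(30, mean = 50)
  cmp <- compare_conditions(a, b, alpha_level = 0.01)
  expect_true(cmp$significant)
  expect_equal(cmp$a$ci_halfwidth / cmp$a$sem, qnorm(0.995),
               tolerance = 1e-12)
  # independent computation of the normal-approximation rank-sum p-value
  x <- c(1.2, 3.4, 0.5, 2.2, 5.1, 0.3, 2.8)
  y <- c(2.0, 4.1, 3.3, 6.0, 1.9, 4.4)
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  m <- length(x) * length(y) / 2
  v <- length(x) * length(y) * (length(x) + length(y) + 1) / 12
  p_manual <- 2 * min(pnorm((W + 0.5 - m) / sqrt(v)),
                      1 - pnorm((W - 0.5 - m) / sqrt(v)))
  cmp2 <- compare_conditions(x, y)
  p_ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_ref, p_manual, tolerance = 1e-6)
  # and the exact small-sample p used by the package
  expect_equal(cmp2$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
})
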