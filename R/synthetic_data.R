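#' Specification of a synthetic dataset
#'
#' Bundles the ground truth and noise/geometry settings for every
#' generator in the package, so that each pipeline stage can be tested
#' against known parameters without any microscopy data. Defaults emulate
#' an unperturbed C. elegans zygote: a 50 um embryo, an anterior-high
#' myosin gradient, a hydrodynamic length of 16 um with chirality index
#' 0.58, per-bin velocity noise of about half a micrometre per minute
#' (the scale of the SEM bars on measured profiles), a 0.1 um pixel size
#' and myosin foci of about 2 um.
#'
#' @param truth ground-truth [model_params()]; default
#'   `model_params(16, -10, -5.8)` (c = 0.58). Under the sign convention
#'   of the flow equations, negative coefficients make the AP flow run
#'   toward the myosin-rich anterior and give the chiral flow the
#'   observed handedness (negative counter-rotation velocity); the
#'   magnitude is scaled so peak speeds are a few um/min, as measured.
#' @param embryo_length,embryo_height embryo footprint (um).
#' @param n_bins number of AP bins of generated profiles (default 18).
#' @param profile_family `"sigmoid"` (anterior-high AP gradient) or
#'   `"stripe"` (Gaussian stripe of high myosin, emulating a cleavage
#'   furrow).
#' @param profile_base,profile_amp baseline and amplitude of the
#'   intensity profile (arbitrary units).
#' @param profile_center,profile_width centre and width (um) of the
#'   sigmoid step or Gaussian stripe; the sigmoid boundary defaults to
#'   60% egg length (the anterior myosin domain extends past mid-embryo
#'   in polarized zygotes), a stripe to mid-embryo. Width defaults to
#'   5 um.
#' @param noise_sd per-sample Gaussian velocity noise (um/min).
#' @param n_frames,n_embryos dataset size.
#' @param grid_spacing spacing of generated 2D vector grids (um).
#' @param pixel_size image pixel size (um/px).
#' @param corr_length imposed image correlation length (um).
#' @param skew_truth_deg,skew_axis ground-truth skew rotation (degrees)
#'   and body axis (`"dv"` for an AP-LR skew, `"ap"` for DV-LR,
#'   `"lr"`).
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-identical across runs.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(truth = model_params(ell = 16, alpha = -10,
                                                beta = -5.8),
                           embryo_length = 50, embryo_height = 30,
                           n_bins = 18L,
                           profile_family = c("sigmoid", "stripe"),
                           profile_base = 0.2, profile_amp = 1,
                           profile_center = NULL, profile_width = 5,
                           noise_sd = 0.5, n_frames = 30L, n_embryos = 5L,
                           grid_spacing = 1, pixel_size = 0.1,
                           corr_length = 2,
                           skew_truth_deg = 20,
                           skew_axis = c("dv", "ap", "lr"),
                           seed = 1L) {
  profile_family <- match.arg(profile_family)
  skew_axis <- match.arg(skew_axis)
  stopifnot(inherits(truth, "model_params"), embryo_length > 0,
            noise_sd >= 0, n_bins >= 3L, n_frames >= 1L, n_embryos >= 1L,
            pixel_size > 0, corr_length > 0)
  if (is.null(profile_center)) {
    profile_center <- if (profile_family == "sigmoid") {
      0.6 * embryo_length
    } else {
      embryo_length / 2
    }
  }
  structure(list(truth = truth, embryo_length = embryo_length,
                 embryo_height = embryo_height, n_bins = as.integer(n_bins),
                 profile_family = profile_family,
                 profile_base = profile_base, profile_amp = profile_amp,
                 profile_center = profile_center,
                 profile_width = profile_width,
                 noise_sd = noise_sd, n_frames = as.integer(n_frames),
                 n_embryos = as.integer(n_embryos),
                 grid_spacing = grid_spacing, pixel_size = pixel_size,
                 corr_length = corr_length,
                 skew_truth_deg = skew_truth_deg, skew_axis = skew_axis,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic myosin intensity profile
#'
#' `"sigmoid"` produces a smooth anterior-high AP gradient (high myosin
#' in the anterior, the configuration of polarizing flow); `"stripe"` a
#' Gaussian band of high myosin emulating a cleavage furrow. Profiles are
#' sampled at the centres of `n_bins` equal AP bins.
#'
#' @param spec a [synthetic_spec()].
#' @return An intensity [axial_profile()].
#' @export
make_intensity_profile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$embryo_length
  breaks <- seq(0, L, length.out = spec$n_bins + 1L)
  x <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  values <- switch(spec$profile_family,
    sigmoid = {
      steep <- if (spec$profile_width > 0) 1 / spec$profile_width else 0
      spec$profile_base + spec$profile_amp /
        (1 + exp(steep * (x - spec$profile_center)))
    },
    stripe = spec$profile_base + spec$profile_amp *
      exp(-(x - spec$profile_center)^2 / (2 * spec$profile_width^2))
  )
  axial_profile(x, values, kind = "intensity")
}

#' Model-conforming velocity profiles with per-bin noise
#'
#' Generates per-frame observed velocity profiles whose expectation is
#' the forward model evaluated at the ground-truth parameters (zero
#' boundary velocities), with i.i.d. Gaussian noise of sd `spec$noise_sd`
#' added independently per bin and frame.
#'
#' @param spec a [synthetic_spec()].
#' @param n_frames number of frames (default `spec$n_frames`).
#' @param cfg [solver_config()] used for the forward solve.
#' @return A list with `intensity`, `vx_true`, `vy_true` (noiseless
#'   profiles) and `frames`, a list of `list(vx = , vy = )` noisy
#'   profiles.
#' @export
make_velocity_profiles <- function(spec, n_frames = spec$n_frames,
                                   cfg = solver_config()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  I <- make_intensity_profile(spec)
  model <- forward_model(I, spec$truth, cfg)
  frames <- lapply(seq_len(n_frames), function(k) {
    list(vx = axial_profile(model$vx$x,
                            model$vx$values +
                              stats::rnorm(I$n, 0, spec$noise_sd),
                            "velocity"),
         vy = axial_profile(model$vy$x,
                            model$vy$values +
                              stats::rnorm(I$n, 0, spec$noise_sd),
                            "velocity"))
  })
  list(intensity = I, vx_true = model$vx, vy_true = model$vy,
       frames = frames)
}

#' Synthetic 2D PIV vector fields
#'
#' Tiles the 1D model velocity profiles across a regular 2D grid
#' covering the embryo footprint (every vector in an AP bin carries that
#' bin's model velocity, so binning recovers the generating profile
#' exactly at zero noise), adds i.i.d. Gaussian noise, and optionally
#' injects constant y-velocity offsets in the anterior and posterior
#' counter-rotation regions for exercising the v_c statistic.
#'
#' @param spec a [synthetic_spec()].
#' @param n_frames number of frames.
#' @param vy_offset_anterior,vy_offset_posterior constant vy offsets
#'   (um/min) applied inside the anterior/posterior bin regions of
#'   `scheme`.
#' @param scheme the [bin_scheme()] defining those regions; defaults to
#'   the embryo-wide 18-bin scheme.
#' @param cfg [solver_config()].
#' @return A list with `fields` (list of [vector_field()]), `scheme`,
#'   and the generating `vx_true`, `vy_true` profiles on the bin centres.
#' @export
make_vector_field <- function(spec, n_frames = spec$n_frames,
                              vy_offset_anterior = 0,
                              vy_offset_posterior = 0,
                              scheme = NULL, cfg = solver_config()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  L <- spec$embryo_length
  H <- spec$embryo_height
  if (is.null(scheme)) scheme <- bin_scheme(c(0, L))
  spec_bins <- spec
  spec_bins$n_bins <- scheme$n_bins
  I <- make_intensity_profile(spec_bins)
  model <- forward_model(I, spec$truth, cfg)
  vx_true <- axial_profile(scheme$centers, model$vx$values, "velocity")
  vy_true <- axial_profile(scheme$centers, model$vy$values, "velocity")

  gx <- seq(spec$grid_spacing / 2, L - spec$grid_spacing / 2,
            by = spec$grid_spacing)
  gy <- seq(-H / 2 + spec$grid_spacing / 2, H / 2 - spec$grid_spacing / 2,
            by = spec$grid_spacing)
  pts <- expand.grid(x = gx, y = gy)
  idx <- bin_index(pts$x, scheme)
  offset <- numeric(nrow(pts))
  offset[idx %in% scheme$anterior_bins] <- vy_offset_anterior
  offset[idx %in% scheme$posterior_bins] <- vy_offset_posterior

  fields <- lapply(seq_len(n_frames), function(k) {
    vector_field(k, pts$x, pts$y,
                 vx_true$values[idx] +
                   stats::rnorm(nrow(pts), 0, spec$noise_sd),
                 vy_true$values[idx] + offset +
                   stats::rnorm(nrow(pts), 0, spec$noise_sd))
  })
  list(fields = fields, scheme = scheme, vx_true = vx_true,
       vy_true = vy_true)
}

#' Gaussian random field with exponential spatial correlation
#'
#' Synthesises a square intensity image whose autocorrelation decays as
#' \eqn{e^{-r/\lambda}} with \eqn{\lambda} = `spec$corr_length`, by
#' spectral filtering of white noise with the 2D spectral density of the
#' exponential covariance (a Matern spectrum with smoothness 1/2). The
#' field is standardised and shifted to a positive mean so it resembles a
#' fluorescence image of myosin foci of characteristic size
#' \eqn{\lambda}.
#'
#' @param spec a [synthetic_spec()].
#' @param n image side length in pixels (default 256).
#' @param mean_intensity,sd_intensity affine scaling of the output.
#' @return An `n` by `n` numeric matrix.
#' @export
make_correlated_image <- function(spec, n = 256L, mean_intensity = 5,
                                  sd_intensity = 1) {
  stopifnot(inherits(spec, "synthetic_spec"), n >= 16L)
  set.seed(spec$seed + 2L)
  lambda_px <- spec$corr_length / spec$pixel_size
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  k2 <- outer((2 * pi * freq)^2, (2 * pi * freq)^2, `+`)
  spectrum <- (1 + k2 * lambda_px^2)^(-1.5)
  white <- matrix(stats::rnorm(n * n), n, n)
  field <- Re(stats::fft(stats::fft(white) * sqrt(spectrum),
                         inverse = TRUE)) / (n * n)
  field <- (field - mean(field)) / stats::sd(field)
  mean_intensity + sd_intensity * field
}

# Rodrigues rotation of v about unit axis by angle (degrees)
rotate_about_axis <- function(v, axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  v * cos(th) + cross3(a, v) * sin(th) + a * sum(a * v) * (1 - cos(th))
}

#' Synthetic nuclei/pole configuration with a known skew
#'
#' Builds an axis-aligned embryo (poles on the x axis, EMS displaced
#' ventrally) and a division-axis pair rotated by the ground-truth skew
#' angle about the requested body axis. Rotating about the DV axis
#' produces a pure AP-LR skew, the plane in which embryonic handedness is
#' established.
#'
#' @param spec a [synthetic_spec()]; uses `skew_truth_deg` and
#'   `skew_axis`.
#' @param initial_axis initial division-axis direction (length-3) in
#'   body-frame coordinates; the default lies in the AP-LR plane, tilted
#'   off the AP axis so that every projection is nondegenerate.
#' @return A labeled point table in the format of [read_points_csv()].
#' @export
make_skewed_nuclei <- function(spec, initial_axis = c(1, 0, 0.4)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$embryo_length
  anterior <- c(0, 0, 0)
  posterior <- c(L, 0, 0)
  ems <- c(L / 2, L / 10, 0)  # ventral displacement defines DV
  frame <- build_body_frame(anterior, posterior, ems)
  axis <- switch(spec$skew_axis, dv = frame$dv, ap = frame$ap,
                 lr = frame$lr)
  center <- c(L / 3, -L / 10, L / 20)  # ABa-like position, arbitrary
  half <- (L / 10) * initial_axis / sqrt(sum(initial_axis^2))
  skewed_half <- rotate_about_axis(half, axis, spec$skew_truth_deg)
  pt <- function(label, p) {
    data.frame(label = label, t = 0, x_um = p[1L], y_um = p[2L],
               z_um = p[3L])
  }
  rbind(pt("anterior_pole", anterior), pt("posterior_pole", posterior),
        pt("ems", ems),
        pt("aba_axis_initial_a", center - half),
        pt("aba_axis_initial_b", center + half),
        pt("aba_axis_skewed_a", center - skewed_half),
        pt("aba_axis_skewed_b", center + skewed_half))
}
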