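#' A single frame of a PIV velocity field
#'
#' One frame of particle-image-velocimetry output: vector positions in
#' the image plane (micrometres, AP axis along x), velocity components
#' (micrometres/min) and an inclusion mask.
#'
#' @param frame frame index (integer).
#' @param x,y vector positions (micrometres).
#' @param vx,vy velocity components (micrometres/min).
#' @param mask logical inclusion flag per vector; defaults to all `TRUE`.
#' @return An object of class `vector_field`, a data.frame with columns
#'   `frame`, `x`, `y`, `vx`, `vy`, `mask`.
#' @export
vector_field <- function(frame, x, y, vx, vy, mask = NULL) {
  n <- length(x)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(vx) == 1L) vx <- rep(vx, n)
  if (length(vy) == 1L) vy <- rep(vy, n)
  stopifnot(length(y) == n, length(vx) == n, length(vy) == n,
            length(mask) == n)
  if (any(!is.finite(vx[mask])) || any(!is.finite(vy[mask])))
    stop("non-finite velocities at masked-in points", call. = FALSE)
  structure(data.frame(frame = as.integer(frame), x = x, y = y,
                       vx = vx, vy = vy, mask = as.logical(mask)),
            class = c("vector_field", "data.frame"))
}

#' Read PIV tables from CSV
#'
#' Expected columns: `frame`, `x_um`, `y_um`, `vx_um_min`, `vy_um_min`
#' and optionally `mask` (0/1).
#'
#' @param path file path.
#' @return A list of `vector_field` objects, one per frame, in frame
#'   order.
#' @export
read_piv_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "x_um", "y_um", "vx_um_min", "vy_um_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("PIV table ", path, " lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$mask)) df$mask <- TRUE
  lapply(split(df, df$frame), function(d) {
    vector_field(d$frame[1L], d$x_um, d$y_um, d$vx_um_min, d$vy_um_min,
                 as.logical(d$mask))
  })
}

#' @rdname read_piv_csv
#' @param fields list of `vector_field` objects.
#' @export
write_piv_csv <- function(fields, path) {
  df <- do.call(rbind, lapply(fields, function(f) {
    data.frame(frame = f$frame, x_um = f$x, y_um = f$y,
               vx_um_min = f$vx, vy_um_min = f$vy,
               mask = as.integer(f$mask))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' AP binning scheme for flow profiles
#'
#' The embryo is divided into equal-width bins along the AP axis
#' (18 by default); velocities entering a profile are restricted in y to
#' a stripe around the embryo midline (about 13 um tall by default).
#' Anterior and posterior regions used for the counter-rotation velocity
#' are fixed bin sets (1-based): bins 3-6 and 13-16.
#'
#' @param ap_extent numeric length-2, AP span `(x_min, x_max)` in
#'   micrometres.
#' @param n_bins number of AP bins (default 18).
#' @param stripe_center y coordinate of the stripe midline (um).
#' @param stripe_halfwidth half-height of the stripe (um, default 6.5 for
#'   a ~13 um stripe).
#' @param anterior_bins,posterior_bins 1-based bin indices of the two
#'   averaging regions.
#' @return An object of class `bin_scheme`.
#' @export
bin_scheme <- function(ap_extent, n_bins = 18L, stripe_center = 0,
                       stripe_halfwidth = 6.5,
                       anterior_bins = 3:6, posterior_bins = 13:16) {
  stopifnot(length(ap_extent) == 2L, ap_extent[2L] > ap_extent[1L],
            n_bins >= 2L, stripe_halfwidth > 0)
  if (length(intersect(anterior_bins, posterior_bins)))
    stop("anterior and posterior bin sets must be disjoint", call. = FALSE)
  breaks <- seq(ap_extent[1L], ap_extent[2L], length.out = n_bins + 1L)
  structure(list(ap_extent = as.numeric(ap_extent),
                 n_bins = as.integer(n_bins), breaks = breaks,
                 centers = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                 stripe_center = stripe_center,
                 stripe_halfwidth = stripe_halfwidth,
                 anterior_bins = as.integer(anterior_bins),
                 posterior_bins = as.integer(posterior_bins)),
            class = "bin_scheme")
}

in_stripe <- function(field, scheme) {
  field$mask &
    abs(field$y - scheme$stripe_center) <= scheme$stripe_halfwidth
}

bin_index <- function(x, scheme) {
  i <- findInterval(x, scheme$breaks, rightmost.closed = TRUE,
                    all.inside = FALSE)
  i[i < 1L | i > scheme$n_bins] <- NA_integer_
  i
}

#' AP-binned velocity profile of one frame
#'
#' Spatial mean of the x- or y-velocity component in each AP bin,
#' restricted to the midline stripe. Empty bins yield `NA`, which
#' downstream averaging drops.
#'
#' @param field a [vector_field()].
#' @param scheme a [bin_scheme()].
#' @param component `"x"` or `"y"`.
#' @return A velocity [axial_profile()] on the bin centres; `NA` marks
#'   bins without vectors.
#' @export
bin_velocity_profile <- function(field, scheme, component = c("x", "y")) {
  component <- match.arg(component)
  keep <- in_stripe(field, scheme)
  idx <- bin_index(field$x[keep], scheme)
  v <- if (component == "x") field$vx[keep] else field$vy[keep]
  means <- rep(NA_real_, scheme$n_bins)
  ok <- !is.na(idx)
  agg <- tapply(v[ok], idx[ok], mean)
  means[as.integer(names(agg))] <- agg
  structure(list(x = scheme$centers, values = as.numeric(means),
                 kind = "velocity", n = scheme$n_bins),
            class = "axial_profile")
}

#' Average binned profiles: time within embryo, then across embryos
#'
#' Follows the measurement hierarchy: per-frame bin profiles are first
#' averaged over time within each embryo, and the per-embryo profiles are
#' then averaged (unweighted) across embryos. The SEM per bin is computed
#' across embryos.
#'
#' @param per_frame list of `axial_profile`s (one per frame), all on the
#'   same bin grid.
#' @param embryo integer/character vector assigning each frame to an
#'   embryo; defaults to a single embryo.
#' @return A list with `mean` (an `axial_profile`), `sem` (numeric per
#'   bin; `NA` with a single embryo) and `n_embryos`.
#' @export
average_profiles <- function(per_frame, embryo = NULL) {
  stopifnot(length(per_frame) >= 1L)
  if (is.null(embryo)) embryo <- rep(1L, length(per_frame))
  stopifnot(length(embryo) == length(per_frame))
  x0 <- per_frame[[1L]]$x
  mat <- vapply(per_frame, function(p) {
    if (!isTRUE(all.equal(p$x, x0)))
      stop("profiles on different bin grids", call. = FALSE)
    p$values
  }, numeric(length(x0)))
  per_embryo <- vapply(split(seq_along(per_frame), embryo), function(ix) {
    rowMeans(mat[, ix, drop = FALSE], na.rm = TRUE)
  }, numeric(length(x0)))
  per_embryo <- as.matrix(per_embryo)
  m <- rowMeans(per_embryo, na.rm = TRUE)
  ne <- ncol(per_embryo)
  sem <- if (ne > 1L) {
    apply(per_embryo, 1L, stats::sd, na.rm = TRUE) / sqrt(ne)
  } else {
    rep(NA_real_, length(x0))
  }
  list(mean = structure(list(x = x0, values = as.numeric(m),
                             kind = "velocity", n = length(x0)),
                        class = "axial_profile"),
       sem = as.numeric(sem), n_embryos = ne)
}

#' Chiral counter-rotation velocity of one frame
#'
#' \eqn{v_c = \langle v_y\rangle_P - \langle v_y\rangle_A}: the mean
#' y-velocity over the posterior bins minus the mean over the anterior
#' bins (bin means averaged with equal weight). A negative value is the
#' handedness observed in unperturbed embryos: the posterior half rotates
#' counterclockwise when viewed from the posterior pole.
#'
#' @param field a [vector_field()].
#' @param scheme a [bin_scheme()].
#' @return `v_c` in micrometres/min, or `NA` with a warning if either
#'   region has no vectors.
#' @export
counter_rotation_velocity <- function(field, scheme) {
  prof <- bin_velocity_profile(field, scheme, "y")
  a <- prof$values[scheme$anterior_bins]
  p <- prof$values[scheme$posterior_bins]
  if (all(is.na(a)) || all(is.na(p))) {
    warning("empty anterior or posterior region; v_c undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mean(p, na.rm = TRUE) - mean(a, na.rm = TRUE)
}

#' Counter-rotation velocity at the 4-cell stage (ABa)
#'
#' During ABa cytokinesis the two nascent daughter cells counter-rotate
#' along the cleavage plane. Per frame, velocity vectors are projected on
#' the cleavage-plane direction and averaged within a slab on each side
#' of the plane; \eqn{v_c} is the left-side mean minus the right-side
#' mean ("left" is the side to the left when looking along the plane
#' direction).
#'
#' @param fields list of [vector_field()] frames.
#' @param plane_point,plane_dir a point on the cleavage plane and its
#'   (not necessarily unit) in-plane direction, each length-2 (um).
#' @param box_halfwidth slab width on each side of the plane (um,
#'   default 2.5 for a 5 um-wide averaging box).
#' @return A list with `v_c` (time-averaged), `per_frame` (one value per
#'   frame; frames with an empty side are `NA` and excluded from the
#'   average) and `n_frames` used.
#' @export
counter_rotation_velocity_4cell <- function(fields, plane_point, plane_dir,
                                            box_halfwidth = 2.5) {
  stopifnot(length(plane_point) == 2L, length(plane_dir) == 2L,
            box_halfwidth > 0)
  d <- plane_dir / sqrt(sum(plane_dir^2))
  nrm <- c(-d[2L], d[1L])  # left of the direction of travel
  per_frame <- vapply(fields, function(f) {
    keep <- f$mask
    rx <- f$x[keep] - plane_point[1L]
    ry <- f$y[keep] - plane_point[2L]
    s <- rx * nrm[1L] + ry * nrm[2L]
    vpar <- f$vx[keep] * d[1L] + f$vy[keep] * d[2L]
    left <- s > 0 & s <= box_halfwidth
    right <- s < 0 & s >= -box_halfwidth
    if (!any(left) || !any(right)) return(NA_real_)
    mean(vpar[left]) - mean(vpar[right])
  }, numeric(1L))
  ok <- !is.na(per_frame)
  if (!all(ok)) {
    warning(sum(!ok), " frame(s) dropped: empty averaging box",
            call. = FALSE)
  }
  list(v_c = if (any(ok)) mean(per_frame[ok]) else NA_real_,
       per_frame = per_frame, n_frames = sum(ok))
}

#' Half-embryo intensity difference
#'
#' Difference of spatially averaged fluorescence intensity between two
#' halves of the masked embryo region: either the posterior minus the
#' anterior half (AP split at the domain midpoint), or, within the
#' posterior half only, the top minus the bottom half (the azimuthal
#' symmetry check).
#'
#' @param image numeric matrix of intensities, row index = y, column
#'   index = x (AP axis along columns).
#' @param mask logical matrix of the same shape selecting embryo pixels;
#'   defaults to all pixels.
#' @param split `"ap-halves"` or `"top-bottom-posterior"`.
#' @return The mean-intensity difference (arbitrary units).
#' @export
half_intensity_difference <- function(image, mask = NULL,
                                      split = c("ap-halves",
                                                "top-bottom-posterior")) {
  split <- match.arg(split)
  stopifnot(is.matrix(image))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(identical(dim(mask), dim(image)))
  col_mid <- ncol(image) / 2
  cols <- col(image)
  posterior <- cols > col_mid
  if (split == "ap-halves") {
    r1 <- mask & posterior
    r2 <- mask & !posterior
  } else {
    rows <- row(image)
    row_mid <- nrow(image) / 2
    r1 <- mask & posterior & rows <= row_mid   # top (low row index)
    r2 <- mask & posterior & rows > row_mid    # bottom
  }
  if (!any(r1) || !any(r2))
    stop("a half-region is empty under the given mask", call. = FALSE)
  mean(image[r1]) - mean(image[r2])
}

#' Compare two samples of a flow statistic between conditions
#'
#' Two-sided Wilcoxon rank-sum test between two samples (e.g. per-frame
#' counter-rotation velocities under two RNAi conditions), with
#' condition means reported alongside the error of the mean at the
#' requested confidence (99% confidence = 2.576 SEM; 95% = 1.96 SEM).
#'
#' @param sample_a,sample_b numeric vectors.
#' @param alpha_level significance level (0.01 for 1-cell flow
#'   comparisons, 0.05 for skew comparisons).
#' @return A list with `p_value`, `significant`, `alpha_level` and per
#'   sample `mean`, `sem` and `ci_halfwidth`.
#' @export
compare_conditions <- function(sample_a, sample_b, alpha_level = 0.01) {
  stopifnot(length(sample_a) >= 1L, length(sample_b) >= 1L,
            alpha_level > 0, alpha_level < 1)
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = length(sample_a) < 50 &&
                         length(sample_b) < 50)
  )
  z <- stats::qnorm(1 - alpha_level / 2)
  describe <- function(s) {
    sem <- if (length(s) > 1L) stats::sd(s) / sqrt(length(s)) else NA_real_
    list(mean = mean(s), sem = sem, ci_halfwidth = z * sem, n = length(s))
  }
  list(p_value = unname(wt$p.value),
       significant = unname(wt$p.value < alpha_level),
       alpha_level = alpha_level,
       a = describe(sample_a), b = describe(sample_b))
}
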