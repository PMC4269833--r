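#' Embryo body frame from pole and EMS positions
#'
#' Builds the right-handed orthonormal body frame (AP, DV, LR) used for
#' skew-angle measurements at the 4-cell stage. The AP unit vector points
#' from the anterior to the posterior pole; the DV unit vector is the
#' component of the EMS nucleus position orthogonal to the AP axis
#' (pointing from the axis toward EMS, i.e. ventrally), and LR completes
#' the right-handed triad `lr = ap x dv`.
#'
#' @param anterior_pole,posterior_pole,ems_nucleus numeric length-3
#'   positions (micrometres).
#' @return An object of class `body_frame` with unit vectors `ap`, `dv`,
#'   `lr`.
#' @export
build_body_frame <- function(anterior_pole, posterior_pole, ems_nucleus) {
  stopifnot(length(anterior_pole) == 3L, length(posterior_pole) == 3L,
            length(ems_nucleus) == 3L,
            all(is.finite(c(anterior_pole, posterior_pole, ems_nucleus))))
  ap <- posterior_pole - anterior_pole
  nap <- sqrt(sum(ap^2))
  if (nap == 0) stop("pole positions coincide", call. = FALSE)
  ap <- ap / nap
  rel <- ems_nucleus - anterior_pole
  dv <- rel - sum(rel * ap) * ap   # remove AP component (Gram-Schmidt)
  ndv <- sqrt(sum(dv^2))
  if (ndv < 1e-9 * max(1, nap)) {
    stop("EMS nucleus is collinear with the AP axis; DV axis undefined",
         call. = FALSE)
  }
  dv <- dv / ndv
  lr <- cross3(ap, dv)
  structure(list(ap = ap, dv = dv, lr = lr), class = "body_frame")
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @export
print.body_frame <- function(x, ...) {
  cat("Embryo body frame (unit vectors):\n")
  for (nm in c("ap", "dv", "lr")) {
    cat(sprintf("  %s: [% .4f, % .4f, % .4f]\n", nm,
                x[[nm]][1L], x[[nm]][2L], x[[nm]][3L]))
  }
  invisible(x)
}

#' Skew angle between the initial and skewed division axes
#'
#' Measures the reorientation of a cell's division axis (the vector
#' joining its two daughter nuclei) between the beginning and the end of
#' telophase, in one of three modes:
#' \describe{
#'   \item{`"ap-lr"`}{both vectors projected onto the AP-LR plane; signed
#'     angle, positive for a clockwise skew as viewed dorsally (the plane
#'     in which the ~20 degree handedness-establishing skew of ABa/ABp is
#'     classically reported).}
#'   \item{`"dv-lr"`}{projection onto the DV-LR plane; signed, positive
#'     clockwise in the anterior view.}
#'   \item{`"full3d"`}{unsigned 3D angle from the arccosine of the
#'     normalised dot product.}
#' }
#' The DV axis points ventrally (toward EMS), so the dorsal view looks
#' along +DV and the anterior view along +AP; a rotation that is
#' clockwise for such a viewer is counterclockwise seen from the axis
#' tip, which fixes the sign via the scalar triple product.
#'
#' @param initial_vec,skewed_vec numeric length-3 division-axis vectors
#'   (need not be normalised).
#' @param frame a [build_body_frame()] result.
#' @param plane one of `"ap-lr"`, `"dv-lr"`, `"full3d"`.
#' @return Angle in degrees; signed for the planar modes, in `[0, 180]`
#'   for `"full3d"`.
#' @export
skew_angle <- function(initial_vec, skewed_vec, frame,
                       plane = c("ap-lr", "dv-lr", "full3d")) {
  plane <- match.arg(plane)
  stopifnot(inherits(frame, "body_frame"),
            length(initial_vec) == 3L, length(skewed_vec) == 3L)
  if (sum(initial_vec^2) == 0 || sum(skewed_vec^2) == 0)
    stop("zero-length division axis vector", call. = FALSE)
  if (plane == "full3d") {
    ct <- sum(initial_vec * skewed_vec) /
      sqrt(sum(initial_vec^2) * sum(skewed_vec^2))
    return(acos(max(-1, min(1, ct))) * 180 / pi)
  }
  viewer_axis <- if (plane == "ap-lr") frame$dv else frame$ap
  project <- function(v) v - sum(v * viewer_axis) * viewer_axis
  u <- project(initial_vec)
  w <- project(skewed_vec)
  if (sqrt(sum(u^2)) < 1e-12 || sqrt(sum(w^2)) < 1e-12)
    stop("degenerate projection: vector orthogonal to the ", plane,
         " plane", call. = FALSE)
  atan2(sum(cross3(u, w) * viewer_axis), sum(u * w)) * 180 / pi
}

#' Read labeled 3D point tables
#'
#' Expected columns: `label`, `t`, `x_um`, `y_um`, `z_um`. Labels used by
#' the skew pipeline: `anterior_pole`, `posterior_pole`, `ems`,
#' `<cell>_axis_initial_a/b`, `<cell>_axis_skewed_a/b` for cells `aba`
#' and `abp`.
#'
#' @param path file path.
#' @return The table as a data.frame.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("label", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("points table ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

point_of <- function(points, label) {
  r <- points[points$label == label, , drop = FALSE]
  if (nrow(r) != 1L)
    stop("expected exactly one point labeled `", label, "`", call. = FALSE)
  c(r$x_um, r$y_um, r$z_um)
}

#' Skew angles of one video from a labeled point table
#'
#' Convenience wrapper: builds the body frame from the pole and EMS
#' points and computes all three skew angles for the requested cell.
#'
#' @param points data.frame from [read_points_csv()].
#' @param cell `"aba"` or `"abp"`.
#' @return A one-row data.frame with `cell`, `angle_ap_lr_deg`,
#'   `angle_dv_lr_deg`, `angle_3d_deg`.
#' @export
skew_angles_from_points <- function(points, cell = c("aba", "abp")) {
  cell <- match.arg(cell)
  frame <- build_body_frame(point_of(points, "anterior_pole"),
                            point_of(points, "posterior_pole"),
                            point_of(points, "ems"))
  init <- point_of(points, paste0(cell, "_axis_initial_b")) -
    point_of(points, paste0(cell, "_axis_initial_a"))
  skew <- point_of(points, paste0(cell, "_axis_skewed_b")) -
    point_of(points, paste0(cell, "_axis_skewed_a"))
  data.frame(cell = cell,
             angle_ap_lr_deg = skew_angle(init, skew, frame, "ap-lr"),
             angle_dv_lr_deg = skew_angle(init, skew, frame, "dv-lr"),
             angle_3d_deg = skew_angle(init, skew, frame, "full3d"))
}
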