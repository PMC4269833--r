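#' Axial profile along the AP axis
#'
#' Container for a scalar quantity sampled along the anteroposterior (AP)
#' axis of the embryo: a myosin fluorescence intensity profile (arbitrary
#' units, nonnegative) or a velocity profile (micrometres per minute).
#' This is the 1D workhorse shared by the flow solver, the fitting routine
#' and the binned flow statistics.
#'
#' @param x numeric vector of positions along the AP axis (micrometres),
#'   strictly increasing; bin centres for measured data, solver nodes for
#'   model output.
#' @param values numeric vector, one value per position.
#' @param kind either `"intensity"` or `"velocity"`. Intensity profiles
#'   must be nonnegative.
#' @return An object of class `axial_profile`: a list with elements `x`,
#'   `values`, `kind` and `n`.
#' @examples
#' p <- axial_profile(seq(0, 50, length.out = 18), rep(1, 18), "intensity")
#' p$n
#' @export
axial_profile <- function(x, values, kind = c("intensity", "velocity")) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  values <- as.numeric(values)
  if (length(x) != length(values)) {
    stop("`x` and `values` must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("an axial profile needs at least 3 samples", call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("positions must be finite", call. = FALSE)
  }
  if (any(diff(x) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (kind == "intensity") {
    if (anyNA(values) || any(!is.finite(values))) {
      stop("intensity values must be finite", call. = FALSE)
    }
    if (any(values < 0)) {
      stop("intensity values must be nonnegative", call. = FALSE)
    }
  }
  structure(list(x = x, values = values, kind = kind, n = length(x)),
            class = "axial_profile")
}

#' @export
print.axial_profile <- function(x, ...) {
  cat(sprintf("Axial %s profile: %d samples on [%.3g, %.3g] um\n",
              x$kind, x$n, min(x$x), max(x$x)))
  cat(sprintf("  values: [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.axial_profile <- function(x, ...) {
  data.frame(x_um = x$x, value = x$values)
}

#' Read or write an axial profile as CSV
#'
#' The on-disk format is a headered CSV with columns `x_um` and `value`.
#'
#' @param path file path.
#' @param kind profile kind, see [axial_profile()].
#' @return `read_axial_profile` returns an `axial_profile`;
#'   `write_axial_profile` returns `path` invisibly.
#' @export
read_axial_profile <- function(path, kind = c("intensity", "velocity")) {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "value") %in% names(df))) {
    stop("expected columns `x_um` and `value` in ", path, call. = FALSE)
  }
  axial_profile(df$x_um, df$value, match.arg(kind))
}

#' @rdname read_axial_profile
#' @param profile an `axial_profile`.
#' @export
write_axial_profile <- function(profile, path) {
  stopifnot(inherits(profile, "axial_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

# interpolant used to move profiles between the measurement grid and the
# solver grid; monotone cubic avoids overshoot that would fabricate
# spurious tension gradients from a coarse 18-bin intensity profile
profile_interpolant <- function(profile, method = c("monotone", "linear")) {
  method <- match.arg(method)
  if (method == "monotone") {
    stats::splinefun(profile$x, profile$values, method = "monoH.FC")
  } else {
    function(xout) {
      stats::approx(profile$x, profile$values, xout, rule = 2)$y
    }
  }
}
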