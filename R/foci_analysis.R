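#' Radially averaged spatial intensity autocorrelation
#'
#' Computes the mean-subtracted, variance-normalised 2D spatial
#' autocorrelation of an intensity image (or a rectangular ROI of it) and
#' radially averages it into a 1D curve in physical units. The
#' correlation is estimated by FFT with zero padding and divided by the
#' per-lag overlap count (unbiased estimator), then normalised so the
#' zero-lag value is exactly 1.
#'
#' @param image numeric matrix of intensities.
#' @param pixel_size pixel size in micrometres per pixel.
#' @param roi optional `list(rows = , cols = )` of index ranges selecting
#'   a rectangular region (e.g. the ~27 x 13 um anterior stripe used for
#'   foci sizing); default whole image.
#' @param max_lag_um largest lag retained (default a quarter of the ROI
#'   diagonal, where the unbiased estimator is still well supported).
#' @return An object of class `correlation_curve`: list with `lag`
#'   (micrometres, starting at 0) and `corr` (dimensionless,
#'   `corr[1] == 1`).
#' @export
spatial_autocorrelation <- function(image, pixel_size, roi = NULL,
                                    max_lag_um = NULL) {
  stopifnot(is.matrix(image), pixel_size > 0)
  if (!is.null(roi)) image <- image[roi$rows, roi$cols, drop = FALSE]
  nr <- nrow(image)
  nc <- ncol(image)
  v <- stats::var(as.vector(image)) * (length(image) - 1) / length(image)
  if (v == 0) stop("constant image: autocorrelation undefined",
                   call. = FALSE)
  z <- image - mean(image)
  # zero-padded FFT autocorrelation, unbiased via the overlap count
  pr <- 2L * nr
  pc <- 2L * nc
  zp <- matrix(0, pr, pc)
  zp[seq_len(nr), seq_len(nc)] <- z
  acf2 <- Re(stats::fft(Mod(stats::fft(zp))^2, inverse = TRUE)) / (pr * pc)
  counts <- outer(nr - abs(lag_coords(pr, nr)),
                  nc - abs(lag_coords(pc, nc)))
  good <- counts > 0
  acf2[good] <- acf2[good] / counts[good]
  acf2[!good] <- NA_real_
  acf2 <- acf2 / acf2[1L, 1L]

  dr <- lag_coords(pr, nr)
  dc <- lag_coords(pc, nc)
  rad <- sqrt(outer(dr^2, dc^2, `+`)) * pixel_size
  if (is.null(max_lag_um)) {
    max_lag_um <- 0.25 * sqrt(nr^2 + nc^2) * pixel_size
  }
  keep <- good & rad <= max_lag_um
  bins <- round(rad[keep] / pixel_size)
  prof <- tapply(acf2[keep], bins, mean)
  lag <- as.numeric(names(prof)) * pixel_size
  o <- order(lag)
  structure(list(lag = lag[o], corr = as.numeric(prof)[o]),
            class = "correlation_curve")
}

# signed lag coordinate of each index of a length-`padded` FFT axis for an
# original extent `n`
lag_coords <- function(padded, n) {
  k <- seq_len(padded) - 1L
  ifelse(k < padded / 2, k, k - padded)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Spatial autocorrelation curve: %d lags up to %.3g um\n",
              length(x$lag), max(x$lag)))
  invisible(x)
}

#' Characteristic foci size from an autocorrelation curve
#'
#' Fits a single exponential \eqn{A\,e^{-r/\lambda} + b} to the radial
#' autocorrelation over a lag window and returns the decay length
#' \eqn{\lambda}, defined as the characteristic foci size. The additive
#' baseline `b` absorbs the finite-field-of-view offset of the empirical
#' correlation (subtracting the sample mean removes fluctuations at the
#' window scale and shifts the whole curve); without it the decay length
#' of strongly correlated images is underestimated. Set
#' `baseline = FALSE` for the pure exponential. The default window
#' excludes the zero-lag point (dominated by pixel noise) and very long
#' lags (poorly estimated).
#'
#' @param curve a [spatial_autocorrelation()] result.
#' @param fit_range numeric length-2 lag window in micrometres (default
#'   `c(0.5, 5)`).
#' @param baseline include the additive offset term (default `TRUE`).
#' @return A list with `lambda_um` (decay length), `amplitude`, `offset`
#'   and `converged`. A non-decaying curve yields `converged = FALSE`
#'   with `lambda_um = NA`.
#' @export
foci_size <- function(curve, fit_range = c(0.5, 5), baseline = TRUE) {
  stopifnot(inherits(curve, "correlation_curve"), length(fit_range) == 2L,
            fit_range[2L] > fit_range[1L])
  keep <- curve$lag >= fit_range[1L] & curve$lag <= fit_range[2L] &
    is.finite(curve$corr)
  r <- curve$lag[keep]
  y <- curve$corr[keep]
  if (length(r) < 4L)
    stop("fewer than 4 lag points inside `fit_range`", call. = FALSE)
  failed <- list(lambda_um = NA_real_, amplitude = NA_real_,
                 offset = NA_real_, converged = FALSE)
  if (stats::cor(r, y) >= 0) return(failed)
  # start values from a log-linear fit after lifting above zero
  shift <- if (baseline) min(y) - 1e-3 else 0
  pos <- y - shift > 0
  if (sum(pos) < 2L) return(failed)
  lf <- stats::lm(log(y[pos] - shift) ~ r[pos])
  lam0 <- -1 / stats::coef(lf)[[2L]]
  if (!is.finite(lam0) || lam0 <= 0) lam0 <- diff(range(r)) / 2
  a0 <- exp(stats::coef(lf)[[1L]])
  # warnOnly + own validation below; nls warns about the singular
  # gradient of a zero baseline on noise-free curves
  fit <- tryCatch(suppressWarnings(
    if (baseline) {
      stats::nls(y ~ A * exp(-r / lambda) + b,
                 start = list(A = a0, lambda = lam0, b = shift),
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = TRUE))
    } else {
      stats::nls(y ~ A * exp(-r / lambda),
                 start = list(A = a0, lambda = lam0),
                 control = stats::nls.control(maxiter = 500,
                                              warnOnly = TRUE))
    }),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  lam <- unname(cf[["lambda"]])
  A <- unname(cf[["A"]])
  if (!is.finite(lam) || lam <= 0 || !is.finite(A) || A <= 0) {
    return(failed)
  }
  # require an actual decay over the window, beyond the residual scatter
  drop_over_window <- A * (exp(-min(r) / lam) - exp(-max(r) / lam))
  resid_sd <- stats::sd(stats::resid(fit))
  if (drop_over_window < 2 * resid_sd) return(failed)
  list(lambda_um = lam, amplitude = A,
       offset = if (baseline) unname(cf[["b"]]) else 0,
       converged = TRUE)
}

#' Read a TIFF intensity image as a numeric matrix
#'
#' Thin wrapper for loading fluorescence frames for the foci analysis;
#' multi-channel images are averaged to one channel. Requires the
#' `tiff` package.
#'
#' @param path TIFF file path.
#' @return A numeric matrix (rows = y, columns = x).
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("reading TIFF images requires the `tiff` package", call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  img
}

#' Foci size of an image series
#'
#' Per-frame foci sizes averaged within an embryo (the analysis window is
#' typically the first 75 s of cortical flow), ready for ensemble
#' averaging across embryos.
#'
#' @param images list of intensity matrices (frames of one embryo).
#' @param pixel_size micrometres per pixel.
#' @param roi,fit_range passed to [spatial_autocorrelation()] and
#'   [foci_size()].
#' @return A list with `lambda_um` (mean over frames with a converged
#'   fit), `per_frame` and `n_frames` used.
#' @export
foci_size_series <- function(images, pixel_size, roi = NULL,
                             fit_range = c(0.5, 5)) {
  per_frame <- vapply(images, function(img) {
    fs <- foci_size(spatial_autocorrelation(img, pixel_size, roi),
                    fit_range)
    if (isTRUE(fs$converged)) fs$lambda_um else NA_real_
  }, numeric(1L))
  ok <- is.finite(per_frame)
  list(lambda_um = if (any(ok)) mean(per_frame[ok]) else NA_real_,
       per_frame = per_frame, n_frames = sum(ok))
}
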