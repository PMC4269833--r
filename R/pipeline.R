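#' Read and write run configurations
#'
#' Configurations are plain YAML mappings; paths are interpreted relative
#' to the configuration file's directory unless absolute. The round trip
#' through [write_run_config()] and [read_run_config()] is lossless.
#'
#' @param path YAML file path.
#' @return `read_run_config` returns the configuration as a named list
#'   with attribute `dir` (the config directory); `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "dir") <- dirname(normalizePath(path))
  cfg
}

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

resolve_path <- function(p, dir) {
  if (is.null(dir) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(dir, p)
}

#' Flag outliers by robust z-score
#'
#' Values whose distance from the median exceeds `threshold` in units of
#' the scaled median absolute deviation are flagged. Flagged values are
#' never removed automatically: exclusion is an explicit configuration
#' decision, mirroring how embryos or videos are excluded by stated
#' qualitative criteria rather than by an automatic rule.
#'
#' @param x numeric vector.
#' @param threshold robust z threshold (default 3.5).
#' @return Logical vector, `TRUE` where flagged.
#' @export
flag_outliers <- function(x, threshold = 3.5) {
  m <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
  abs(x - m) / s > threshold
}

#' Write a synthetic 1-cell dataset to disk
#'
#' Emits, per embryo, a PIV table in the format of [read_piv_csv()],
#' plus the shared myosin intensity profile — the same file formats the
#' analysis consumes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of file paths written.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  I <- make_intensity_profile(spec)
  ip <- file.path(dir, "intensity.csv")
  write_axial_profile(I, ip)
  paths <- c(paths, ip)
  for (e in seq_len(spec$n_embryos)) {
    spec_e <- spec
    spec_e$seed <- spec$seed + 100L * e
    vf <- make_vector_field(spec_e)
    pp <- file.path(dir, sprintf("piv_embryo%02d.csv", e))
    write_piv_csv(vf$fields, pp)
    paths <- c(paths, pp)
  }
  invisible(paths)
}

#' One-cell stage analysis: profiles, v_c and the model fit
#'
#' End-to-end 1-cell workflow: per-frame AP-binned velocity profiles from
#' each embryo's PIV table, time-then-embryo averaged profiles with SEM,
#' pooled per-frame counter-rotation velocities, and the active chiral
#' fluid model fit of (ell, alpha, beta, c) to the averaged profiles
#' using the measured intensity profile. Outputs are written as CSV/JSON
#' under `config$out_dir`; re-running the same configuration is
#' byte-identical.
#'
#' @param config named list (or path to a YAML file) with entries
#'   `piv_files` (character vector), `intensity_file`, `out_dir`, and
#'   optionally `ap_extent` (default from the data), `n_bins`,
#'   `stripe_center`, `stripe_halfwidth`, `n_nodes`.
#' @return A report list with `profiles`, `vc` (per-frame values and
#'   summary), `fit` (a [chiral_fit()]) and `outputs` (paths written).
#' @export
run_onecell_analysis <- function(config) {
  cfg_dir <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_dir <- attr(config <- read_run_config(config), "dir")
  }
  piv_files <- vapply(config$piv_files, resolve_path, "", dir = cfg_dir)
  intensity_file <- resolve_path(config$intensity_file, cfg_dir)
  missing <- c(piv_files, intensity_file)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- resolve_path(config$out_dir, cfg_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  intensity <- read_axial_profile(intensity_file, "intensity")
  fields_by_embryo <- lapply(piv_files, read_piv_csv)
  ap_extent <- config$ap_extent
  if (is.null(ap_extent)) ap_extent <- range(intensity$x) +
      c(-1, 1) * diff(intensity$x[1:2]) / 2
  scheme <- bin_scheme(
    ap_extent,
    n_bins = config$n_bins %||% 18L,
    stripe_center = config$stripe_center %||% 0,
    stripe_halfwidth = config$stripe_halfwidth %||% 6.5
  )

  per_frame_vx <- list(); per_frame_vy <- list()
  embryo_id <- integer(0)
  vc <- data.frame(embryo = integer(0), frame = integer(0),
                   v_c_um_min = numeric(0))
  for (e in seq_along(fields_by_embryo)) {
    for (f in fields_by_embryo[[e]]) {
      per_frame_vx[[length(per_frame_vx) + 1L]] <-
        bin_velocity_profile(f, scheme, "x")
      per_frame_vy[[length(per_frame_vy) + 1L]] <-
        bin_velocity_profile(f, scheme, "y")
      embryo_id <- c(embryo_id, e)
      vc <- rbind(vc, data.frame(embryo = e, frame = f$frame[1L],
                                 v_c_um_min =
                                   counter_rotation_velocity(f, scheme)))
    }
  }
  avg_vx <- average_profiles(per_frame_vx, embryo_id)
  avg_vy <- average_profiles(per_frame_vy, embryo_id)

  solver <- solver_config(n_nodes = config$n_nodes %||% 201L)
  fit <- chiral_fit(intensity, avg_vx$mean, avg_vy$mean, solver)

  profiles <- data.frame(
    x_um = scheme$centers,
    intensity = profile_interpolant(intensity)(scheme$centers),
    vx_um_min = avg_vx$mean$values, vx_sem = avg_vx$sem,
    vy_um_min = avg_vy$mean$values, vy_sem = avg_vy$sem,
    vx_model_um_min = fit$fitted$vx$values,
    vy_model_um_min = fit$fitted$vy$values
  )
  vc_ok <- vc$v_c_um_min[is.finite(vc$v_c_um_min)]
  vc_summary <- list(mean = mean(vc_ok),
                     sem = stats::sd(vc_ok) / sqrt(length(vc_ok)),
                     ci99_halfwidth = stats::qnorm(0.995) *
                       stats::sd(vc_ok) / sqrt(length(vc_ok)),
                     n_frames = length(vc_ok),
                     n_embryos = length(fields_by_embryo))

  p_profiles <- file.path(out_dir, "profiles.csv")
  p_vc <- file.path(out_dir, "vc_frames.csv")
  p_fit <- file.path(out_dir, "fit.json")
  utils::write.csv(profiles, p_profiles, row.names = FALSE)
  utils::write.csv(vc, p_vc, row.names = FALSE)
  jsonlite::write_json(
    list(params = coef(fit), stderr = fit$stderr, rss = fit$rss,
         n_obs = fit$n_obs, converged = fit$converged,
         identifiable = fit$identifiable, vc = vc_summary),
    p_fit, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(profiles = profiles, vc = list(per_frame = vc, summary = vc_summary),
       fit = fit, scheme = scheme,
       outputs = c(profiles = p_profiles, vc = p_vc, fit = p_fit))
}

#' Four-cell stage analysis: ABa counter-rotation and division skew
#'
#' Mirrors the 4-cell workflow: the counter-rotation velocity along the
#' ABa cleavage plane per video, robust-z outlier flags (flag only;
#' exclusion requires an explicit `exclude` list in the configuration),
#' skew angles per video from labeled nuclei/pole points, and per-group
#' summaries.
#'
#' @param config named list (or YAML path) with `piv_files`,
#'   `plane_point`, `plane_dir` (length-2 each), `points_files`
#'   (labeled 3D point CSVs, one per video), `out_dir`, and optionally
#'   `box_halfwidth`, `cell` ("aba"/"abp"), `exclude` (video indices to
#'   drop from summaries).
#' @return A report list with `vc` (per video + summary + outlier flags)
#'   and `skew` (per-video angle table + summary).
#' @export
run_fourcell_analysis <- function(config) {
  cfg_dir <- NULL
  if (is.character(config) && length(config) == 1L) {
    cfg_dir <- attr(config <- read_run_config(config), "dir")
  }
  piv_files <- vapply(config$piv_files, resolve_path, "", dir = cfg_dir)
  points_files <- vapply(config$points_files, resolve_path, "",
                         dir = cfg_dir)
  missing <- c(piv_files, points_files)
  missing <- missing[!file.exists(missing)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- resolve_path(config$out_dir, cfg_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cell <- config$cell %||% "aba"
  bhw <- config$box_halfwidth %||% 2.5

  vc_video <- vapply(unname(piv_files), function(p) {
    counter_rotation_velocity_4cell(read_piv_csv(p),
                                    unlist(config$plane_point),
                                    unlist(config$plane_dir),
                                    box_halfwidth = bhw)$v_c
  }, numeric(1L), USE.NAMES = FALSE)
  flags <- flag_outliers(vc_video)
  keep <- !(seq_along(vc_video) %in% (config$exclude %||% integer(0)))
  vc_used <- vc_video[keep & is.finite(vc_video)]

  skew_tab <- do.call(rbind, lapply(seq_along(points_files), function(i) {
    cbind(video = i,
          skew_angles_from_points(read_points_csv(points_files[i]), cell))
  }))
  ang <- skew_tab$angle_ap_lr_deg
  summarise <- function(v) {
    list(mean = mean(v), median = stats::median(v),
         sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
               else NA_real_,
         n = length(v))
  }

  p_vc <- file.path(out_dir, "vc_videos.csv")
  p_skew <- file.path(out_dir, "skew_angles.csv")
  p_sum <- file.path(out_dir, "fourcell_summary.json")
  utils::write.csv(data.frame(video = seq_along(vc_video),
                              v_c_um_min = vc_video,
                              outlier_flag = flags,
                              excluded = !keep),
                   p_vc, row.names = FALSE)
  utils::write.csv(skew_tab, p_skew, row.names = FALSE)
  out <- list(vc = c(summarise(vc_used), list(outlier_flags = flags)),
              skew = summarise(ang))
  jsonlite::write_json(out, p_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(vc = list(per_video = vc_video, flags = flags,
                 summary = summarise(vc_used)),
       skew = list(per_video = skew_tab, summary = summarise(ang)),
       outputs = c(vc = p_vc, skew = p_skew, summary = p_sum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
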