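#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain into one validated object
#' that serializes to YAML and back without loss.
#'
#' @param pixel_size um/px of the input stack.
#' @param frame_interval min between frames.
#' @param n_bins angular bins for polar profiles (default 180, i.e. 2 deg).
#' @param velocity_dt velocity sampling interval (min, default 30).
#' @param min_area_um2,closing_radius_px,max_jump_um segmentation knobs.
#' @param max_lag_min correlation lag cap (NULL: half the duration).
#' @param d_bin_um,angle_bin_deg deformation-PDF bins.
#' @param noise_floor_um displacement floor for directed frames.
#' @param seed integer seed governing any stochastic stage.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size = 0.5, frame_interval = 10,
                            n_bins = 180, velocity_dt = 30,
                            min_area_um2 = 20, closing_radius_px = 3,
                            max_jump_um = 20, max_lag_min = NULL,
                            d_bin_um = 1, angle_bin_deg = 10,
                            noise_floor_um = 0.5, seed = 1L) {
  cfg <- list(pixel_size = pixel_size, frame_interval = frame_interval,
              n_bins = as.integer(n_bins), velocity_dt = velocity_dt,
              min_area_um2 = min_area_um2,
              closing_radius_px = as.integer(closing_radius_px),
              max_jump_um = max_jump_um, max_lag_min = max_lag_min,
              d_bin_um = d_bin_um, angle_bin_deg = angle_bin_deg,
              noise_floor_um = noise_floor_um, seed = as.integer(seed))
  for (nm in setdiff(names(cfg), "max_lag_min"))
    stop_if_not_scalar_num(cfg[[nm]], nm, positive = nm != "seed")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param cfg a [pipeline_config()]; `path` file path.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`; `write_config` the
#'   path, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

# Order-independent content hash of the configuration (polynomial
# rolling hash over the serialized key=value string, mod 2^31 - 1);
# stamped into every output.
config_hash <- function(cfg) {
  vals <- unclass(cfg)[order(names(unclass(cfg)))]
  txt <- paste(names(vals), vapply(vals, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Reads an image stack (TIFF path or [image_sequence()]) or a
#' pre-extracted contour series (CSV path or [contour_series()]), then
#' runs segmentation (skipped for contour input), shape descriptors,
#' amplitude map, autocorrelation with peak localization, center-of-mass
#' tracking with mean velocity, and the deformation-direction
#' distribution. All result files carry the configuration hash and
#' package version; the run is deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param input path (`.tif`/`.tiff`/`.csv`) or an in-memory
#'   `image_sequence` / `contour_series`.
#' @param output_dir directory for result files (created if needed);
#'   `NULL` skips writing.
#' @return list: `series`, `descriptors`, `amplitude`, `correlation`,
#'   `peaks_deg`, `trajectory`, `velocity`, `deformation` (NULL when no
#'   frame passes the motion floor), `symmetry_break_um`, `log`.
#' @export
run_pipeline <- function(config, input, output_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must come from pipeline_config()")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.character(input)) {
    if (!file.exists(input)) stop("input file not found: ", input)
    ext <- tolower(tools::file_ext(input))
    input <- switch(ext,
      tif = , tiff = read_stack(input, pixel_size = config$pixel_size,
                                frame_interval = config$frame_interval),
      csv = read_contour_csv(input),
      stop("unsupported input extension: ", ext))
  }
  if (inherits(input, "image_sequence")) {
    series <- segment_sequence(input, min_area_um2 = config$min_area_um2,
                               closing_radius_px = config$closing_radius_px,
                               max_jump_um = config$max_jump_um)
    note("segmentation: %d/%d frames with a linked cell",
         length(series$vertices), length(input$frames))
  } else if (inherits(input, "contour_series")) {
    series <- input
    note("contour input: %d frames, segmentation skipped",
         length(series$vertices))
  } else stop("'input' must be an image_sequence, contour_series or file path")

  desc <- data.frame(
    frame = seq_along(series$vertices), time_min = series$time_min,
    com_x_um = series$center[, 1], com_y_um = series$center[, 2],
    area_um2 = series$area_um2, perimeter_um = series$perimeter_um,
    circularity = circularity(series$area_um2, series$perimeter_um),
    elongation = vapply(series$vertices, elongation, numeric(1)))
  note("descriptors: %d frames", nrow(desc))

  amp <- amplitude_map(series, n_bins = config$n_bins)
  corr <- autocorrelation(amp, max_lag_min = config$max_lag_min)
  peaks <- locate_peaks(corr, at_lag_min = 0)
  note("correlation: %d peaks at zero lag", length(peaks))

  traj <- track_centers(series)
  vel <- mean_velocity(traj, dt_min = config$velocity_dt)
  note("velocity: %.3f um/h over %d samples", vel$mean_um_h, vel$n_samples)

  defo <- tryCatch(
    deformation_direction_pdf(series, traj, dt_min = config$velocity_dt,
                              noise_floor_um = config$noise_floor_um,
                              d_bin_um = config$d_bin_um,
                              angle_bin_deg = config$angle_bin_deg,
                              n_theta = config$n_bins),
    error = function(e) { note("deformation pdf skipped: %s",
                               conditionMessage(e)); NULL })
  if (!is.null(defo)) note("deformation pdf: %d contour lines", defo$n_contours)
  offset <- if (!is.null(defo) && defo$n_contours >= 55)
    symmetry_break_offset(defo) else NA_real_

  res <- list(series = series, descriptors = desc, amplitude = amp,
              correlation = corr, peaks_deg = peaks, trajectory = traj,
              velocity = vel, deformation = defo,
              symmetry_break_um = offset, log = log)
  if (!is.null(output_dir)) write_results(res, config, output_dir)
  res
}

# Write the result bundle; every file carries the config hash + version.
write_results <- function(res, config, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  ver <- as.character(utils::packageVersion("contourdyn"))
  stamp <- function(path) {
    con <- file(path, "w")
    writeLines(sprintf("# contourdyn %s config %s", ver, hash), con)
    con
  }
  p <- function(f) file.path(output_dir, f)

  con <- stamp(p("contours.csv"))
  write_contour_csv_con(res$series, con); close(con)
  con <- stamp(p("descriptors.csv"))
  write.csv(format(res$descriptors, digits = 12, trim = TRUE), con,
            row.names = FALSE, quote = FALSE); close(con)
  write_map_csv(res$amplitude, p("amplitude_map.csv"))
  write_map_csv(res$correlation, p("correlation_map.csv"))
  con <- stamp(p("trajectory.csv"))
  write.csv(format(as.data.frame(res$trajectory), digits = 12, trim = TRUE),
            con, row.names = FALSE, quote = FALSE); close(con)
  if (!is.null(res$deformation)) {
    d <- res$deformation
    df <- data.frame(d_um = d$d_um, d$pdf)
    names(df) <- c("d_um", paste0("angle_deg_", d$rel_angle_deg))
    con <- stamp(p("deformation_pdf.csv"))
    write.csv(format(df, digits = 12, trim = TRUE), con,
              row.names = FALSE, quote = FALSE); close(con)
    con <- stamp(p("deformation_marginal.csv"))
    write.csv(format(d$marginal, digits = 12, trim = TRUE), con,
              row.names = FALSE, quote = FALSE); close(con)
  }
  summary <- list(
    package_version = ver, config_hash = hash, config = unclass(config),
    n_frames = length(res$series$vertices),
    mean_velocity_um_h = res$velocity$mean_um_h,
    sd_mean_velocity_um_h = res$velocity$sd_mean_um_h,
    zero_lag_peaks_deg = res$peaks_deg,
    symmetry_break_um = res$symmetry_break_um,
    log = res$log)
  jsonlite::write_json(summary, p("summary.json"), digits = NA,
                       auto_unbox = TRUE, null = "null", na = "null",
                       pretty = TRUE)
  invisible(output_dir)
}

# write_contour_csv onto an open connection (for stamped output files).
write_contour_csv_con <- function(series, con) {
  rows <- lapply(seq_along(series$vertices), function(j) {
    v <- series$vertices[[j]]
    if (is.null(v)) return(NULL)
    data.frame(frame = j, time_min = series$time_min[j],
               vertex_index = seq_len(nrow(v)) - 1L,
               x_um = v[, 1], y_um = v[, 2])
  })
  df <- do.call(rbind, rows)
  write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
            con, row.names = FALSE, quote = FALSE)
}
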