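#' Parameters for the single-cell contour simulator
#'
#' Defines the generative model behind [simulate_cell()]: a star-shaped
#' contour `r(theta, t) = R0 * (1 + sum_k a_k cos(k*theta - phi_k(t)))`
#' with `phi_k(t) = phase_k + k * rotation_rate * t`, an optional
#' motion-aligned protrusion bump, smooth stochastic radial noise, and a
#' persistent-random-walk translocation of the center. All generator laws
#' are synthetic stand-ins chosen for testability: live-cell recordings of
#' the kind this pipeline analyses carry no published generative model.
#'
#' @param base_radius mean contour radius R0 (um).
#' @param fourier_modes data.frame (or list coercible to one) with columns
#'   `k` (integer order >= 2), `a` (amplitude fraction, in `[0, 1)`) and
#'   `phase_deg`. The sum of `a` must stay below 1 so the contour remains
#'   star-shaped about its center.
#' @param rotation_rate rigid rotation rate of the mode pattern (deg/min).
#' @param mode_noise_sd per-frame stochastic radial perturbation (um),
#'   realized as a fresh random superposition of Fourier orders 2-8 each
#'   frame, scaled so the radial standard deviation equals this value.
#' @param speed translocation speed (um/h).
#' @param persistence_time direction decorrelation time of the persistent
#'   random walk (min); required positive whenever `speed > 0`.
#' @param protrusion_amplitude peak height of an extra radial bump (um).
#' @param protrusion_alignment in `[0, 1]`: 1 locks the bump to the
#'   instantaneous motion direction, 0 randomizes its position each frame.
#' @param protrusion_width_deg full angular width of the raised-cosine
#'   bump (deg, default 60).
#' @param seed integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @return A validated list of class `cell_sim_params`.
#' @export
cell_sim_params <- function(base_radius = 12,
                            fourier_modes = NULL,
                            rotation_rate = 0,
                            mode_noise_sd = 0,
                            speed = 0,
                            persistence_time = 600,
                            protrusion_amplitude = 0,
                            protrusion_alignment = 1,
                            protrusion_width_deg = 60,
                            seed = 1L) {
  stop_if_not_scalar_num(base_radius, "base_radius", positive = TRUE)
  if (is.null(fourier_modes)) {
    fourier_modes <- data.frame(k = integer(), a = numeric(),
                                phase_deg = numeric())
  } else {
    fourier_modes <- as.data.frame(fourier_modes)
    if (!all(c("k", "a", "phase_deg") %in% names(fourier_modes)))
      stop("'fourier_modes' needs columns k, a, phase_deg")
    if (any(fourier_modes$k < 2) || any(fourier_modes$k != round(fourier_modes$k)))
      stop("mode orders k must be integers >= 2")
    if (any(fourier_modes$a < 0))
      stop("mode amplitudes must be non-negative")
  }
  if (sum(fourier_modes$a) >= 1)
    stop("sum of mode amplitudes must be < 1 (contour must stay star-shaped)")
  stop_if_not_scalar_num(rotation_rate, "rotation_rate")
  stop_if_not_scalar_num(mode_noise_sd, "mode_noise_sd")
  if (mode_noise_sd < 0) stop("'mode_noise_sd' must be >= 0")
  stop_if_not_scalar_num(speed, "speed")
  if (speed < 0) stop("'speed' must be >= 0")
  if (speed > 0) stop_if_not_scalar_num(persistence_time, "persistence_time",
                                        positive = TRUE)
  stop_if_not_scalar_num(protrusion_amplitude, "protrusion_amplitude")
  if (protrusion_amplitude < 0) stop("'protrusion_amplitude' must be >= 0")
  if (protrusion_alignment < 0 || protrusion_alignment > 1)
    stop("'protrusion_alignment' must lie in [0, 1]")
  stop_if_not_scalar_num(protrusion_width_deg, "protrusion_width_deg",
                         positive = TRUE)
  structure(list(base_radius = base_radius, fourier_modes = fourier_modes,
                 rotation_rate = rotation_rate, mode_noise_sd = mode_noise_sd,
                 speed = speed, persistence_time = persistence_time,
                 protrusion_amplitude = protrusion_amplitude,
                 protrusion_alignment = protrusion_alignment,
                 protrusion_width_deg = protrusion_width_deg,
                 seed = as.integer(seed)),
            class = "cell_sim_params")
}

#' Simulate a persistent random walk
#'
#' Constant speed, direction evolving by wrapped-normal increments with
#' variance `2 * dt / persistence_time`, which gives the directional
#' autocorrelation `<cos(phi(t) - phi(0))> = exp(-t / persistence_time)`.
#'
#' @param speed um/h; `persistence_min` direction decorrelation time (min);
#'   `n_steps` number of frames; `dt_min` frame interval (min).
#' @param speed,persistence_min,n_steps,dt_min see description.
#' @param start starting position (x, y) um.
#' @param seed RNG seed (NULL uses the current stream).
#' @return A `trajectory` (data.frame: frame, time_min, x_um, y_um) with
#'   attribute `direction_deg`, the per-frame heading in lab angles.
#' @export
simulate_prw <- function(speed, persistence_min, n_steps, dt_min,
                         start = c(0, 0), seed = NULL) {
  stopifnot(n_steps >= 1, dt_min > 0)
  with_seed(seed, {
    if (speed > 0) {
      dirs <- cumsum(c(runif(1, -180, 180),
                       rnorm(n_steps - 1, 0,
                             sqrt(2 * dt_min / persistence_min) / DEG2RAD)))
      dirs <- wrap_angle(dirs)
      step <- speed * dt_min / 60
      u <- angle_to_unit(dirs)
      pos <- if (n_steps == 1) matrix(0, 1, 2) else
        rbind(c(0, 0),
              cbind(cumsum(u[-n_steps, "x"] * step),
                    cumsum(u[-n_steps, "y"] * step)))
    } else {
      dirs <- rep(NA_real_, n_steps)
      pos <- matrix(0, n_steps, 2)
    }
    traj <- data.frame(frame = seq_len(n_steps),
                       time_min = (seq_len(n_steps) - 1) * dt_min,
                       x_um = start[1] + pos[, 1],
                       y_um = start[2] + pos[, 2])
    structure(traj, direction_deg = dirs, gaps = integer(0),
              class = c("trajectory", "data.frame"))
  })
}

# Raised-cosine bump of full width w centered at angle c0 (all deg).
protrusion_bump <- function(theta_deg, center_deg, amplitude, width_deg) {
  d <- wrap_angle(theta_deg - center_deg)
  h <- width_deg / 2
  ifelse(abs(d) <= h, amplitude * 0.5 * (1 + cos(pi * d / h)), 0)
}

#' Simulate a single-cell contour time series with ground truth
#'
#' Generates one closed contour per frame following the generative model in
#' [cell_sim_params()]. The emitted per-frame centers are the *true*
#' generative centers (not the area centroid, which an asymmetric
#' protrusion pulls off-center); the ground-truth attribute records center,
#' heading and configured speed per frame.
#'
#' @param params a [cell_sim_params()] object.
#' @param n_frames number of frames (>= 1).
#' @param frame_interval frame spacing (min).
#' @param n_vertices vertices per contour (default 512).
#' @return A [contour_series()] with attribute `ground_truth`, a data.frame
#'   (frame, time_min, center_x_um, center_y_um, direction_deg,
#'   speed_um_h).
#' @examples
#' p <- cell_sim_params(base_radius = 10,
#'                      fourier_modes = data.frame(k = 3, a = 0.3,
#'                                                 phase_deg = 0))
#' s <- simulate_cell(p, n_frames = 5, frame_interval = 10)
#' s
#' @export
simulate_cell <- function(params, n_frames, frame_interval, n_vertices = 512) {
  if (!inherits(params, "cell_sim_params"))
    stop("'params' must come from cell_sim_params()")
  stopifnot(n_frames >= 1, frame_interval > 0)
  with_seed(params$seed, {
    times <- (seq_len(n_frames) - 1) * frame_interval
    traj <- simulate_prw(params$speed, params$persistence_time,
                         n_frames, frame_interval, seed = NULL)
    dirs <- attr(traj, "direction_deg")
    theta <- seq(0, 360, length.out = n_vertices + 1)[-(n_vertices + 1)]
    u <- angle_to_unit(theta)
    km <- params$fourier_modes
    noise_k <- 2:8
    contours <- vector("list", n_frames)
    for (j in seq_len(n_frames)) {
      r <- rep(params$base_radius, n_vertices)
      if (nrow(km)) {
        for (m in seq_len(nrow(km))) {
          phi <- km$phase_deg[m] + km$k[m] * params$rotation_rate * times[j]
          r <- r + params$base_radius * km$a[m] *
            cos((km$k[m] * theta - phi) * DEG2RAD)
        }
      }
      if (params$mode_noise_sd > 0) {
        amp <- rnorm(length(noise_k), 0,
                     params$mode_noise_sd * sqrt(2 / length(noise_k)))
        ph <- runif(length(noise_k), 0, 360)
        for (m in seq_along(noise_k))
          r <- r + amp[m] * cos((noise_k[m] * theta - ph[m]) * DEG2RAD)
      }
      if (params$protrusion_amplitude > 0) {
        base_dir <- if (is.finite(dirs[j])) dirs[j] else runif(1, -180, 180)
        jitter <- (1 - params$protrusion_alignment) * runif(1, -180, 180)
        r <- r + protrusion_bump(theta, base_dir + jitter,
                                 params$protrusion_amplitude,
                                 params$protrusion_width_deg)
      }
      if (any(r <= 0))
        stop(sprintf("contour radius became non-positive at frame %d", j))
      contours[[j]] <- cbind(x = traj$x_um[j] + r * u[, "x"],
                             y = traj$y_um[j] + r * u[, "y"])
    }
    series <- contour_series(contours, times,
                             centers = cbind(traj$x_um, traj$y_um))
    attr(series, "ground_truth") <- data.frame(
      frame = seq_len(n_frames), time_min = times,
      center_x_um = traj$x_um, center_y_um = traj$y_um,
      direction_deg = dirs, speed_um_h = params$speed)
    series
  })
}

#' Parameters for the population adhesion-kinetics simulator
#'
#' @param n_cells_total number of cells in the field of view.
#' @param plateau_fraction long-time expected adhered fraction, in `[0, 1]`.
#' @param attachment_halftime half-time of the saturating attachment law
#'   (min, > 0).
#' @param frame_interval,n_frames observation grid (min, count).
#' @param seed integer RNG seed.
#' @return A validated list of class `adhesion_sim_params`.
#' @export
adhesion_sim_params <- function(n_cells_total, plateau_fraction,
                                attachment_halftime, frame_interval = 10,
                                n_frames = 60, seed = 1L) {
  stopifnot(n_cells_total >= 1, n_frames >= 1)
  if (plateau_fraction < 0 || plateau_fraction > 1)
    stop("'plateau_fraction' must lie in [0, 1]")
  stop_if_not_scalar_num(attachment_halftime, "attachment_halftime",
                         positive = TRUE)
  stop_if_not_scalar_num(frame_interval, "frame_interval", positive = TRUE)
  structure(list(n_cells_total = as.integer(n_cells_total),
                 plateau_fraction = plateau_fraction,
                 attachment_halftime = attachment_halftime,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "adhesion_sim_params")
}

#' Simulate population adhesion kinetics
#'
#' Each cell independently adheres with probability `plateau_fraction`;
#' adhering cells draw an exponential attachment time with the configured
#' half-time. Per-frame counts are cumulative, hence monotone
#' non-decreasing within a realization. This saturating law is a synthetic
#' stand-in: adhesion read-outs of this kind are reported as empirical
#' curves without a kinetic model.
#'
#' @param params an [adhesion_sim_params()] object.
#' @return data.frame: frame, time_min, n_adhered, n_total.
#' @export
simulate_adhesion_series <- function(params) {
  if (!inherits(params, "adhesion_sim_params"))
    stop("'params' must come from adhesion_sim_params()")
  with_seed(params$seed, {
    n <- params$n_cells_total
    adheres <- runif(n) < params$plateau_fraction
    t_attach <- rep(Inf, n)
    rate <- log(2) / params$attachment_halftime
    t_attach[adheres] <- rexp(sum(adheres), rate)
    times <- (seq_len(params$n_frames) - 1) * params$frame_interval
    n_adhered <- vapply(times, function(t) sum(t_attach <= t), integer(1))
    data.frame(frame = seq_len(params$n_frames), time_min = times,
               n_adhered = n_adhered, n_total = n)
  })
}
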