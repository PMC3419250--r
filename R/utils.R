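# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rexp sd median mvfft lm coef approx
#' @importFrom utils read.csv write.csv head tail
NULL

DEG2RAD <- pi / 180

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's RNG stream. `seed = NULL` leaves the stream untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Wrap angles (degrees) into (-180, 180].
wrap_angle <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

# Unit vector for the lab angle convention: 0 deg = +y (vertical),
# increasing counterclockwise.
angle_to_unit <- function(theta_deg) {
  t <- theta_deg * DEG2RAD
  cbind(x = -sin(t), y = cos(t))
}

# Lab angle (deg, 0 = +y, CCW) of displacement vectors.
vector_to_angle <- function(dx, dy) {
  wrap_angle(atan2(-dx, dy) / DEG2RAD)
}

## ---- polygon geometry (closed polygons, vertices as n x 2 matrix) ----

# Signed area (positive for counterclockwise orientation).
polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(v) abs(polygon_signed_area(v))

polygon_perimeter <- function(v) {
  d <- rbind(diff(v), v[1, ] - v[nrow(v), ])
  sum(sqrt(rowSums(d^2)))
}

polygon_centroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(v))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second central moments (per unit area) of the filled polygon interior,
# via Green's theorem; exact for the polygon, orientation-independent.
polygon_central_moments <- function(v) {
  c0 <- polygon_centroid(v)
  x <- v[, 1] - c0[1]; y <- v[, 2] - c0[2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  ixx <- sum(cr * (x^2 + x * xn + xn^2)) / 12
  iyy <- sum(cr * (y^2 + y * yn + yn^2)) / 12
  ixy <- sum(cr * (x * yn + 2 * x * y + 2 * xn * yn + xn * y)) / 24
  list(area = abs(a), ixx = ixx / a, iyy = iyy / a, ixy = ixy / a)
}

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
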