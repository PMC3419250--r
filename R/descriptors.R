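#' Dimensionless circularity of an adhesion footprint
#'
#' The isoperimetric ratio `4 * pi * A / L^2`: exactly 1 for a circle,
#' decreasing toward 0 for increasingly convoluted or elongated contours.
#'
#' @param area footprint area A (um^2, > 0).
#' @param perimeter contour length L (um, > 0).
#' @return circularity in (0, 1] (discretized contours may exceed 1 by a
#'   small tolerance).
#' @examples
#' circularity(pi * 10^2, 2 * pi * 10)  # circle: 1
#' circularity(4, 8)                    # unit square: pi/4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("'area' and 'perimeter' must be > 0")
  4 * pi * area / perimeter^2
}

#' Elongation of a contour
#'
#' Minor-to-major axis ratio of the filled region, from the principal axes
#' of its second central area moments (computed exactly on the polygon via
#' Green's theorem). 1 for a circle, `b/a` for an ellipse with semi-axes
#' `a >= b`; invariant to translation, rotation and uniform scaling.
#'
#' @param contour n x 2 vertex matrix of a closed polygon (um).
#' @return elongation in (0, 1].
#' @export
elongation <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 3) stop("contour needs at least 3 vertices")
  m <- polygon_central_moments(contour)
  if (m$area < .Machine$double.eps)
    stop("degenerate contour: near-zero area")
  cov <- matrix(c(m$ixx, m$ixy, m$ixy, m$iyy), 2, 2)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) stop("degenerate contour: vanishing principal moment")
  sqrt(max(ev[2], 0) / ev[1])
}

#' Shape-descriptor table for a cohort of cells
#'
#' Evaluates area, elongation and circularity for each cell at (the frame
#' nearest to) a common time point, and appends mean and sample (n-1)
#' standard deviation rows.
#'
#' @param cells list of [contour_series()], one per cell.
#' @param at_time_min target time (min). Each cell must have a frame
#'   within half its median frame interval of this time.
#' @return data.frame with columns sample, area_um2, elongation,
#'   circularity; the last two rows are "mean" and "sd".
#' @export
descriptor_table <- function(cells, at_time_min) {
  if (!length(cells)) {
    warning("no cells supplied: returning empty table")
    return(data.frame(sample = character(), area_um2 = numeric(),
                      elongation = numeric(), circularity = numeric()))
  }
  rows <- lapply(seq_along(cells), function(i) {
    s <- cells[[i]]
    if (!inherits(s, "contour_series"))
      stop("'cells' must be a list of contour_series")
    dtime <- abs(s$time_min - at_time_min)
    j <- which.min(dtime)
    half <- if (length(s$time_min) > 1) median(diff(s$time_min)) / 2 else Inf
    if (dtime[j] > half)
      stop(sprintf("cell %d has no frame within %.1f min of t = %.1f", i,
                   half, at_time_min))
    v <- s$vertices[[j]]
    if (is.null(v)) stop(sprintf("cell %d has no contour at t = %.1f", i,
                                 at_time_min))
    data.frame(sample = sprintf("cell_%d", i),
               area_um2 = s$area_um2[j],
               elongation = elongation(v),
               circularity = circularity(s$area_um2[j], s$perimeter_um[j]))
  })
  tab <- do.call(rbind, rows)
  sd <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  stats_rows <- data.frame(
    sample = c("mean", "sd"),
    area_um2 = c(mean(tab$area_um2), sd(tab$area_um2)),
    elongation = c(mean(tab$elongation), sd(tab$elongation)),
    circularity = c(mean(tab$circularity), sd(tab$circularity)))
  rbind(tab, stats_rows)
}
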