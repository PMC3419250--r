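#' Segment one frame into a binary adhesion-footprint mask
#'
#' Subtracts the background, thresholds the (inverted, dark-footprint)
#' difference with Otsu's method, closes with a small disk, fills holes and
#' removes objects below a minimum physical area. The threshold method is
#' a documented choice: published descriptions of this kind of read-out
#' state only that backgrounds were subtracted and images binarized.
#'
#' @param frame 2D numeric intensity matrix.
#' @param background matrix of the same shape (e.g. a blank frame or the
#'   temporal median of the stack), or a single intensity value.
#' @param pixel_size um/px, used to convert `min_area_um2` to pixels.
#' @param min_area_um2 objects smaller than this are discarded (default 20).
#' @param closing_radius_px radius of the morphological closing brush
#'   (default 3 px; 0 disables).
#' @return Logical matrix; `TRUE` marks the adhesion footprint. A constant
#'   (or fully saturated) frame yields an empty mask with a warning.
#' @export
segment_frame <- function(frame, background, pixel_size,
                          min_area_um2 = 20, closing_radius_px = 3) {
  frame <- as.matrix(frame)
  if (length(background) == 1) {
    background <- matrix(background, nrow(frame), ncol(frame))
  }
  if (!all(dim(background) == dim(frame)))
    stop("'frame' and 'background' must have the same shape")
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  # footprint is darker than background -> positive difference
  diffim <- background - frame
  rng <- range(diffim)
  if (diff(rng) < .Machine$double.eps^0.5) {
    warning("constant frame: returning empty mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  # no-footprint guard: a frame of pure background noise has no pixels
  # standing clearly out of the noise band, and thresholding it would
  # binarize the noise itself
  noise_scale <- median(abs(diffim - median(diffim)))
  if ((rng[2] - median(diffim)) < 8 * max(noise_scale,
                                          .Machine$double.eps)) {
    warning("no footprint contrast above the noise: returning empty mask")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  scaled <- (diffim - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
  mask <- scaled > thr
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
    mask <- EBImage::closing(mask, brush) > 0
  }
  mask <- EBImage::fillHull(mask) > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    min_px <- min_area_um2 / pixel_size^2
    drop <- which(sizes < min_px)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

#' Extract the cell contour and geometry from a binary mask
#'
#' Takes the largest connected component (with a message if several are
#' present), fills interior holes, and reports the area as the pixel count
#' times `pixel_size^2`, the center of mass as the pixel centroid, and the
#' perimeter as the polygon length of a sub-pixel boundary traced on a
#' Gaussian-smoothed copy of the mask. The smoothing (sigma 2 px) removes
#' the staircase bias that would otherwise inflate the perimeter and bias
#' circularity downward.
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size um/px.
#' @return list: `contour` (n x 2 matrix, um, y up), `center_of_mass`
#'   (x, y um), `area_um2`, `perimeter_um`. An empty mask raises a
#'   condition of class `contourdyn_no_cell`.
#' @export
extract_contour <- function(mask, pixel_size) {
  mask <- as.matrix(mask) > 0
  stop_if_not_scalar_num(pixel_size, "pixel_size", positive = TRUE)
  if (!any(mask))
    stop(structure(class = c("contourdyn_no_cell", "error", "condition"),
                   list(message = "no cell: mask is empty", call = NULL)))
  lab <- EBImage::bwlabel(mask)
  n_comp <- max(lab)
  if (n_comp > 1) {
    sizes <- tabulate(lab[lab > 0])
    message(sprintf("mask has %d components; taking the largest", n_comp))
    mask <- lab == which.max(sizes)
  }
  mask <- EBImage::fillHull(mask) > 0
  nr <- nrow(mask); nc <- ncol(mask)
  xs <- pixel_centers_x(nc, pixel_size)
  ys <- pixel_centers_y(nr, pixel_size)
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx) * pixel_size^2
  com <- c(mean(xs[idx[, 2]]), mean(ys[idx[, 1]]))
  contour <- trace_subpixel_boundary(mask, pixel_size)
  list(contour = contour, center_of_mass = com,
       area_um2 = area, perimeter_um = polygon_perimeter(contour))
}

# Sub-pixel boundary of a binary component: Gaussian blur then the 0.5
# isocontour via marching squares (grDevices::contourLines).
trace_subpixel_boundary <- function(mask, pixel_size, sigma = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(mask * 1), sigma = sigma,
                                 boundary = 0))
  # contourLines wants z[i, j] at (x[i], y[j]) with ascending x and y;
  # feed z = t(mask rows flipped) so i indexes x (cols) and j indexes y up.
  z <- t(sm[nr:1, , drop = FALSE])
  cl <- grDevices::contourLines(x = pixel_centers_x(nc, pixel_size),
                                y = (seq_len(nr) - 0.5) * pixel_size,
                                z = z, levels = 0.5)
  if (!length(cl)) {
    # component too small for the blur to reach 0.5: fall back to pixel hull
    idx <- which(mask, arr.ind = TRUE)
    xs <- pixel_centers_x(nc, pixel_size)[idx[, 2]]
    ys <- pixel_centers_y(nr, pixel_size)[idx[, 1]]
    h <- grDevices::chull(xs, ys)
    return(cbind(x = xs[h], y = ys[h]))
  }
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  p <- cl[[which.max(lens)]]
  v <- cbind(x = p$x, y = p$y)
  # drop duplicated closing vertex if present
  if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

#' Per-frame adhered-cell fraction
#'
#' @param n_adhered,n_total integer vectors (per frame); requires
#'   `0 <= n_adhered <= n_total` and `n_total > 0`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
adhered_fraction <- function(n_adhered, n_total) {
  if (length(n_adhered) != length(n_total))
    stop("'n_adhered' and 'n_total' must have equal length")
  if (any(n_total <= 0)) stop("'n_total' must be > 0 in every frame")
  if (any(n_adhered < 0)) stop("'n_adhered' must be >= 0")
  if (any(n_adhered > n_total))
    stop("'n_adhered' exceeds 'n_total'")
  n_adhered / n_total
}

#' Segment an image sequence and track one cell
#'
#' Applies [segment_frame()] to every frame (background: per-pixel temporal
#' median of the stack by default), extracts all components, and follows a
#' single cell by nearest-centroid linking: frame 1 takes the largest
#' component, later frames the component whose centroid is nearest the
#' previous center, up to `max_jump_um`. Frames with no linkable component
#' are recorded as gaps (`NULL` contour).
#'
#' @param seq an [image_sequence()].
#' @param background `"median"` (default), or an explicit matrix / scalar.
#' @param min_area_um2,closing_radius_px passed to [segment_frame()].
#' @param max_jump_um maximum allowed center jump between frames
#'   (default 20).
#' @return A [contour_series()] (centers = measured centers of mass) with
#'   attribute `gap_frames`, the indices of frames without a linked cell.
#' @export
segment_sequence <- function(seq, background = "median",
                             min_area_um2 = 20, closing_radius_px = 3,
                             max_jump_um = 20) {
  if (!inherits(seq, "image_sequence"))
    stop("'seq' must be an image_sequence")
  if (identical(background, "median")) {
    stack <- simplify2array(seq$frames)
    background <- apply(stack, c(1, 2), median)
  }
  n <- length(seq$frames)
  contours <- vector("list", n)
  centers <- matrix(NA_real_, n, 2)
  prev <- NULL
  for (j in seq_len(n)) {
    mask <- suppressWarnings(
      segment_frame(seq$frames[[j]], background, seq$pixel_size,
                    min_area_um2, closing_radius_px))
    lab <- EBImage::bwlabel(mask)
    n_comp <- max(lab)
    if (n_comp == 0) { prev <- prev; next }
    cands <- lapply(seq_len(n_comp), function(k)
      extract_contour(lab == k, seq$pixel_size))
    pick <- if (is.null(prev)) {
      which.max(vapply(cands, `[[`, numeric(1), "area_um2"))
    } else {
      d <- vapply(cands, function(cc)
        sqrt(sum((cc$center_of_mass - prev)^2)), numeric(1))
      if (min(d) > max_jump_um) NA_integer_ else which.min(d)
    }
    if (is.na(pick)) next
    contours[[j]] <- cands[[pick]]$contour
    centers[j, ] <- cands[[pick]]$center_of_mass
    prev <- centers[j, ]
  }
  keep <- !vapply(contours, is.null, logical(1))
  if (!any(keep)) stop("no cell found in any frame")
  series <- contour_series(contours[keep], seq$time_min[keep],
                           centers = centers[keep, , drop = FALSE])
  attr(series, "gap_frames") <- which(!keep)
  series
}
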