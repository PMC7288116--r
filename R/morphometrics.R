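# Per-tree canopy morphometrics: height, hull projected area, ellipsoid
# volume.

#' Canopy height of a tree region
#'
#' `H = Zmax - Zmin` over the region's points. With ground returns present
#' `Zmin` sits at the ground, so `H` is the total tree height.
#'
#' @param z numeric vector of point heights, metres.
#' @return a list with `H` (metres, `NA` when fewer than 2 points) and `ok`.
#' @export
tree_height <- function(z) {
  if (length(z) < 2L) return(list(H = NA_real_, ok = FALSE))
  list(H = max(z) - min(z), ok = TRUE)
}

# signed shoelace area of an ordered polygon (positive when
# counter-clockwise); closes x_{N+1} = x_1
shoelace <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - y * xn)
}

#' Convex-hull projected area of a point set (XOY plane)
#'
#' Projects points onto the XOY plane, takes their 2-D convex hull and
#' evaluates the shoelace formula
#' `S = 1/2 * sum(x_i * y_{i+1} - y_i * x_{i+1})` over the hull vertices in
#' counter-clockwise order. Fewer than three points, or a collinear set,
#' yields area 0 with `degenerate = TRUE`.
#'
#' @param xy two-column matrix of projected coordinates, metres.
#' @return a list with `S` (m^2), `hull` (counter-clockwise vertex matrix or
#'   `NULL`), `degenerate`.
#' @export
hull_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L)
    return(list(S = 0, hull = NULL, degenerate = TRUE))
  idx <- grDevices::chull(xy[, 1], xy[, 2])   # clockwise order
  if (length(idx) < 3L)
    return(list(S = 0, hull = NULL, degenerate = TRUE))
  idx <- rev(idx)                             # counter-clockwise
  hull <- xy[idx, , drop = FALSE]
  S <- shoelace(hull[, 1], hull[, 2])
  if (abs(S) < .Machine$double.eps * nrow(xy))
    return(list(S = 0, hull = NULL, degenerate = TRUE))
  list(S = abs(S), hull = hull, degenerate = FALSE)
}

#' Circumscribed-ellipsoid canopy volume
#'
#' The canopy is approximated by a spheroid whose vertical semi-axis is
#' `(H - trunk_height) / 2` and whose horizontal radius comes from the
#' equivalent circle of the projected area (`pi * r^2 = S_XOY`):
#' `V = (4/3) * pi * ((H - trunk_height)/2) * (S_XOY / pi)
#'    = (2/3) * (H - trunk_height) * S_XOY`.
#'
#' @param H canopy (total tree) height, metres.
#' @param S_XOY projected convex-hull area, m^2.
#' @param trunk_height trunk height, metres (default 0.6).
#' @return volume in m^3; 0 (with a warning) when `H < trunk_height`.
#' @export
ellipsoid_volume <- function(H, S_XOY, trunk_height = 0.6) {
  if (any(S_XOY < 0, na.rm = TRUE) || trunk_height < 0)
    stop("`S_XOY` and `trunk_height` must be >= 0", call. = FALSE)
  clipped <- !is.na(H) & H < trunk_height
  if (any(clipped))
    warning("H below trunk height for ", sum(clipped),
            " tree(s); volume clipped to 0", call. = FALSE)
  (2 / 3) * pmax(H - trunk_height, 0) * S_XOY
}

#' Morphometrics table for all segmented regions
#'
#' Computes `H`, `S_XOY` and `V` for every region of a segmentation with
#' assigned points. Regions with too few points keep `NA` height (and `NA`
#' volume) and are flagged rather than silently zeroed.
#'
#' Height uses every point in the region (with ground returns present the
#' Z minimum sits at the ground, as intended). The projected area, however,
#' is the hull of the *canopy*: points below `ground_z_max` are treated as
#' ground returns and excluded from the XOY hull, otherwise sparse ground
#' points would inflate the hull to the whole cell rectangle.
#'
#' @param seg a `grid_segmentation` with points assigned (see
#'   [assign_points()]).
#' @param trunk_height trunk height used in the volume formula, metres.
#' @param ground_z_max height below which points count as ground returns
#'   when building the hull, metres.
#' @return a data frame with one row per region: `region`, `row`, `col`,
#'   `P`, `H`, `S_XOY`, `V`, `flag_empty`, `flag_degenerate`.
#' @export
morph_table <- function(seg, trunk_height = 0.6, ground_z_max = 0.3) {
  stopifnot(inherits(seg, "grid_segmentation"))
  if (is.null(seg$point_region))
    stop("segmentation has no assigned points; call assign_points() first",
         call. = FALSE)
  cloud <- seg$cloud
  n_reg <- nrow(seg$regions)
  H <- S <- V <- rep(NA_real_, n_reg)
  f_empty <- f_degen <- logical(n_reg)
  pr <- seg$point_region
  ord <- order(pr, na.last = NA)
  split_idx <- split(ord, pr[ord])
  for (r in seq_len(n_reg)) {
    idx <- split_idx[[as.character(r)]]
    if (is.null(idx) || length(idx) < 2L) {
      f_empty[r] <- TRUE
      next
    }
    th <- tree_height(cloud[idx, "z"])
    H[r] <- th$H
    canopy <- idx[cloud[idx, "z"] >= ground_z_max]
    ha <- hull_area(cloud[canopy, c("x", "y"), drop = FALSE])
    S[r] <- ha$S
    f_degen[r] <- ha$degenerate
    V[r] <- suppressWarnings(ellipsoid_volume(H[r], S[r], trunk_height))
  }
  cbind(seg$regions[, c("region", "row", "col")],
        data.frame(P = seg$regions$P, H = H, S_XOY = S, V = V,
                   flag_empty = f_empty, flag_degenerate = f_degen))
}
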