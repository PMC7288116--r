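#' Define a gridded orchard layout
#'
#' Describes a rectangular orchard planted in parallel rows. Row 1 sits at the
#' maximum-Y (north) edge so that image row order matches orchard row order in
#' a north-up orthophoto. Defaults reproduce the 140 m x 25 m study block:
#' five rows of 30-34 apple trees at 5 m row spacing and 4 m plant spacing,
#' with 8/160 positions occupied by dead trees.
#'
#' @param n_rows number of tree rows (>= 1).
#' @param trees_per_row integer vector of trees in each row (recycled if
#'   length 1).
#' @param row_spacing distance between adjacent rows, metres.
#' @param plant_spacing distance between adjacent trees within a row, metres.
#' @param field_length field extent along the rows (X axis), metres.
#' @param field_width field extent across the rows (Y axis), metres.
#' @param dead_fraction probability in `[0, 1)` that a grid position holds a
#'   dead tree (trunk plus a few leaves).
#' @return an object of class `orchard_layout`.
#' @examples
#' layout <- orchard_layout()
#' sum(layout$trees_per_row)  # 160
#' @export
orchard_layout <- function(n_rows = 5L,
                           trees_per_row = c(30L, 31L, 32L, 33L, 34L),
                           row_spacing = 5,
                           plant_spacing = 4,
                           field_length = 140,
                           field_width = 25,
                           dead_fraction = 8 / 160) {
  if (!is.numeric(n_rows) || length(n_rows) != 1L || n_rows < 1)
    stop("invalid layout: `n_rows` must be a single count >= 1", call. = FALSE)
  n_rows <- as.integer(n_rows)
  if (length(trees_per_row) == 1L) trees_per_row <- rep(trees_per_row, n_rows)
  if (length(trees_per_row) != n_rows || any(trees_per_row < 1))
    stop("invalid layout: `trees_per_row` must give a count >= 1 per row",
         call. = FALSE)
  if (row_spacing <= 0 || plant_spacing <= 0)
    stop("invalid layout: `row_spacing` and `plant_spacing` must be > 0",
         call. = FALSE)
  if (field_width < n_rows * row_spacing)
    stop("invalid layout: `field_width` too small for n_rows rows plus a ",
         "half-spacing margin", call. = FALSE)
  if (field_length < max(trees_per_row) * plant_spacing)
    stop("invalid layout: `field_length` too small for the longest row plus ",
         "a half-spacing margin", call. = FALSE)
  if (dead_fraction < 0 || dead_fraction >= 1)
    stop("invalid layout: `dead_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(n_rows = n_rows,
                 trees_per_row = as.integer(trees_per_row),
                 row_spacing = row_spacing,
                 plant_spacing = plant_spacing,
                 field_length = field_length,
                 field_width = field_width,
                 dead_fraction = dead_fraction),
            class = "orchard_layout")
}

#' @export
print.orchard_layout <- function(x, ...) {
  cat("<orchard_layout> ", x$n_rows, " rows, ",
      sum(x$trees_per_row), " trees, field ",
      x$field_length, " m x ", x$field_width, " m\n", sep = "")
  invisible(x)
}

# nominal (unjittered) grid centres; row 1 at max-Y edge
layout_centers <- function(layout) {
  rows <- lapply(seq_len(layout$n_rows), function(i) {
    k <- layout$trees_per_row[i]
    x0 <- (layout$field_length - (k - 1) * layout$plant_spacing) / 2
    data.frame(row = i,
               col = seq_len(k),
               center_x = x0 + (seq_len(k) - 1) * layout$plant_spacing,
               center_y = layout$field_width - (i - 0.5) * layout$row_spacing)
  })
  do.call(rbind, rows)
}

#' Generate per-tree ground truth for a layout
#'
#' Draws one tree per grid position. Live canopies are spheroids sitting on a
#' 0.6 m trunk: total height and radius are drawn uniformly from the
#' configured ranges. Dead trees ("only a trunk or a few leaves") get a much
#' smaller residual canopy. Centres receive a small uniform jitter so that
#' segmentation is not trivially exact. A per-tree greenness factor (`vigor`)
#' modulates canopy reflectance and feeds the yield signal.
#'
#' @param layout an [orchard_layout()].
#' @param seed integer RNG seed; identical inputs give identical output.
#' @param height_range,radius_range live-tree total height / canopy radius
#'   ranges, metres.
#' @param dead_height_range,dead_radius_range the same for dead trees.
#' @param trunk_height trunk height below the canopy, metres.
#' @param center_jitter max absolute uniform jitter of each centre coordinate,
#'   metres.
#' @param vigor_range per-tree greenness factor range (1 = nominal canopy
#'   reflectance).
#' @return a data frame with one row per tree: `tree_id`, `row`, `col`,
#'   `center_x`, `center_y`, `trunk_height`, `height`, `radius`, `is_dead`,
#'   `vigor` (and `yield_kg` once [assign_yields()] has run).
#' @export
generate_trees <- function(layout, seed = 1L,
                           height_range = c(2.0, 3.5),
                           radius_range = c(0.8, 1.8),
                           dead_height_range = c(1.0, 2.0),
                           dead_radius_range = c(0.2, 0.5),
                           trunk_height = 0.6,
                           center_jitter = 0.3,
                           vigor_range = c(0.8, 1.2)) {
  stopifnot(inherits(layout, "orchard_layout"))
  grid <- layout_centers(layout)
  n <- nrow(grid)
  with_seed(seed, {
    dead <- stats::runif(n) < layout$dead_fraction
    jx <- stats::runif(n, -center_jitter, center_jitter)
    jy <- stats::runif(n, -center_jitter, center_jitter)
    h_live <- stats::runif(n, height_range[1], height_range[2])
    r_live <- stats::runif(n, radius_range[1], radius_range[2])
    h_dead <- stats::runif(n, dead_height_range[1], dead_height_range[2])
    r_dead <- stats::runif(n, dead_radius_range[1], dead_radius_range[2])
    vig <- stats::runif(n, vigor_range[1], vigor_range[2])
    data.frame(tree_id = seq_len(n),
               row = grid$row,
               col = grid$col,
               center_x = grid$center_x + jx,
               center_y = grid$center_y + jy,
               trunk_height = trunk_height,
               height = ifelse(dead, h_dead, h_live),
               radius = ifelse(dead, r_dead, r_live),
               is_dead = dead,
               vigor = vig)
  })
}

#' Ground-truth circumscribed-ellipsoid volume of a canopy
#'
#' The canopy is modelled as a spheroid with vertical semi-axis
#' `(height - trunk_height) / 2` and horizontal radius `radius`, so its volume
#' is `(4/3) * pi * radius^2 * (height - trunk_height) / 2`.
#'
#' @param height total tree height, metres.
#' @param radius canopy radius, metres.
#' @param trunk_height trunk height, metres.
#' @return volume in cubic metres.
#' @export
truth_volume <- function(height, radius, trunk_height = 0.6) {
  (2 / 3) * pi * radius^2 * pmax(height - trunk_height, 0)
}

#' Assign per-tree yields from a volume + greenness signal
#'
#' Live trees get `yield = b0 + b1 * V + b2 * vigor + N(0, noise_sd)` clipped
#' at zero, where `V` is the truth ellipsoid volume; dead trees yield 0 kg.
#' With `noise_sd = "auto"` the noise is calibrated so that the population
#' R-squared between the noise-free signal and the yield is `target_r2`
#' (`sd = sd(signal) * sqrt(1/target_r2 - 1)`). The defaults give a mean yield
#' of roughly 80 kg per live tree.
#'
#' @param trees data frame from [generate_trees()].
#' @param noise_sd Gaussian noise sd in kg, or `"auto"` to calibrate to
#'   `target_r2`.
#' @param seed integer RNG seed.
#' @param coefficients named vector `c(b0, b1, b2)` (kg, kg/m^3, kg per unit
#'   vigor).
#' @param target_r2 attainable R-squared used by the `"auto"` calibration.
#' @return `trees` with columns `yield_kg` and `yield_signal` added; the
#'   realized noise sd is attached as attribute `"noise_sd"`.
#' @export
assign_yields <- function(trees, noise_sd = "auto", seed = 1L,
                          coefficients = c(b0 = 10, b1 = 6, b2 = 30),
                          target_r2 = 0.90) {
  live <- !trees$is_dead
  v <- truth_volume(trees$height, trees$radius, trees$trunk_height)
  signal <- coefficients[["b0"]] + coefficients[["b1"]] * v +
    coefficients[["b2"]] * trees$vigor
  signal[!live] <- 0
  if (identical(noise_sd, "auto")) {
    noise_sd <- if (sum(live) > 1) stats::sd(signal[live]) *
        sqrt(1 / target_r2 - 1) else 0
  }
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be \"auto\" or a number >= 0", call. = FALSE)
  out <- with_seed(seed, {
    eps <- stats::rnorm(nrow(trees), 0, noise_sd)
    pmax(signal + eps, 0)
  })
  out[!live] <- 0
  trees$yield_signal <- signal
  trees$yield_kg <- out
  attr(trees, "noise_sd") <- noise_sd
  trees
}
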