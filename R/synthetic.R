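# Synthetic orchard scenes: band rasters, point clouds, truth.

# Volumetric canopy point density (points/m^3) observed at each flight GSD.
.gsd_density_table <- data.frame(
  gsd = c(2.13, 3.31, 4.39, 5.43, 6.69),
  density = c(364.77, 75.55, 32.01, 17.22, 8.65))

#' Canopy point density for a ground sampling distance
#'
#' Returns the calibrated volumetric point density (points/m^3) of
#' SfM-reconstructed canopies at the five calibrated GSDs
#' (2.13, 3.31, 4.39, 5.43, 6.69 cm/px); intermediate GSDs are interpolated
#' log-linearly (monotone and smooth in log-log space), and values outside the
#' calibrated range are clamped to the nearest endpoint.
#'
#' @param gsd ground sampling distance, cm/px (vectorized).
#' @return points per cubic metre.
#' @export
gsd_point_density <- function(gsd) {
  if (any(gsd <= 0)) stop("`gsd` must be > 0", call. = FALSE)
  exp(stats::approx(log(.gsd_density_table$gsd),
                    log(.gsd_density_table$density),
                    xout = log(gsd), rule = 2)$y)
}

# default reflectances (unitless, [0,1]); canopy NIR is modulated by vigor,
# canopy GRE inversely, so greener trees are darker in GRE and brighter in NIR
.soil_reflectance   <- c(gre = 0.18, red = 0.22, reg = 0.28, nir = 0.30)
.canopy_reflectance <- c(gre = 0.10, red = 0.06, reg = 0.35, nir = 0.55)

#' Render co-registered reflectance band rasters for an orchard scene
#'
#' Produces four single-band rasters (GRE, RED, REG, NIR) at the requested
#' GSD. Soil takes a constant baseline reflectance; each tree contributes a
#' disc of canopy reflectance, alpha-blended over one pixel at the rim.
#' Canopy NIR is scaled by the tree's `vigor` and GRE by `2 - vigor`.
#' Per-pixel Gaussian noise is added and values are clipped to `[0, 1]`.
#' With the default reflectances the NG index (GRE/(NIR+RED+GRE)) is brighter
#' over soil (~0.257) than over canopy (~0.141), which row/column detection
#' relies on.
#'
#' Pixel row 1 is the maximum-Y edge of the field (north-up orthophoto);
#' pixel `[i, j]` covers `x in [(j-1), j) * gsd/100` and the matching
#' from-the-top Y slab.
#'
#' @param trees data frame from [generate_trees()].
#' @param layout the [orchard_layout()] used to size the raster.
#' @param gsd ground sampling distance, cm/px.
#' @param noise_sd per-pixel reflectance noise sd.
#' @param seed integer RNG seed.
#' @param soil,canopy named reflectance vectors (`gre`, `red`, `reg`, `nir`).
#' @param max_pixels refuse rasters larger than this many pixels.
#' @return an object of class `band_stack`: matrices `gre`, `red`, `reg`,
#'   `nir`, plus `gsd` (cm/px), `origin` (metres) and `extent`
#'   (`c(length_m, width_m)`, the pixel-grid-rounded field size).
#' @export
render_bands <- function(trees, layout, gsd, noise_sd = 0.01, seed = 1L,
                         soil = .soil_reflectance,
                         canopy = .canopy_reflectance,
                         max_pixels = 2.5e8) {
  dims <- raster_dims(gsd, layout$field_length, layout$field_width)
  nr <- dims[["nrow"]]; nc <- dims[["ncol"]]
  if (as.double(nr) * nc > max_pixels)
    stop("raster of ", nr, " x ", nc, " px exceeds `max_pixels`",
         call. = FALSE)
  s <- gsd / 100                       # metres per pixel
  width_m <- nr * s
  xc <- (seq_len(nc) - 0.5) * s        # pixel-centre x
  yc <- width_m - (seq_len(nr) - 0.5) * s  # pixel-centre y (row 1 at top)

  alpha <- matrix(0, nr, nc)           # total canopy coverage
  acc <- list(gre = matrix(0, nr, nc), red = matrix(0, nr, nc),
              reg = matrix(0, nr, nc), nir = matrix(0, nr, nc))
  for (t in seq_len(nrow(trees))) {
    r <- trees$radius[t]
    if (r <= 0) next
    cx <- trees$center_x[t]; cy <- trees$center_y[t]
    ci <- which(abs(xc - cx) <= r + s)
    ri <- which(abs(yc - cy) <= r + s)
    if (!length(ci) || !length(ri)) next
    d <- sqrt(outer((yc[ri] - cy)^2, (xc[ci] - cx)^2, "+"))
    a <- pmin(1, pmax(0, (r - d) / s + 0.5))   # 1-px linear rim blend
    alpha[ri, ci] <- alpha[ri, ci] + a
    vig <- trees$vigor[t]
    vals <- c(gre = canopy[["gre"]] * (2 - vig), red = canopy[["red"]],
              reg = canopy[["reg"]], nir = canopy[["nir"]] * vig)
    for (b in names(acc)) acc[[b]][ri, ci] <- acc[[b]][ri, ci] + a * vals[[b]]
  }
  # where overlapping discs push total alpha above 1, renormalize the blend
  over <- alpha > 1
  if (any(over)) {
    sc <- alpha[over]
    for (b in names(acc)) acc[[b]][over] <- acc[[b]][over] / sc
    alpha[over] <- 1
  }
  bands <- with_seed(seed, {
    out <- list()
    for (b in names(acc)) {
      m <- soil[[b]] * (1 - alpha) + acc[[b]]
      if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
      out[[b]] <- matrix(pmin(1, pmax(0, m)), nr, nc)
    }
    out
  })
  structure(c(bands,
              list(gsd = gsd, origin = c(x = 0, y = 0),
                   extent = c(length_m = nc * s, width_m = width_m))),
            class = "band_stack")
}

#' @export
print.band_stack <- function(x, ...) {
  cat("<band_stack> ", nrow(x$gre), " x ", ncol(x$gre), " px, gsd ",
      x$gsd, " cm/px, extent ", round(x$extent[["length_m"]], 2), " m x ",
      round(x$extent[["width_m"]], 2), " m\n", sep = "")
  invisible(x)
}

# n uniform points in the unit ball (rejection-free: direction * u^(1/3))
.unit_ball <- function(n) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  g <- matrix(stats::rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2))
  g * stats::runif(n)^(1 / 3)
}

#' Render a synthetic orchard point cloud
#'
#' Samples canopy points inside each live tree's spheroid (between
#' `trunk_height` and `height`) at the volumetric density mapped from `gsd`
#' by [gsd_point_density()]; the per-tree count is `round(density * volume)`,
#' and a fraction `upper_fraction` of points is drawn from the upper
#' half-spheroid (SfM reconstructions see canopies from above). Dead trees
#' contribute `dead_points` trunk points. Sparse ground returns at z = 0 cover
#' the whole raster extent so that per-region Z minima reflect the ground.
#' All points finally receive isotropic Gaussian jitter.
#'
#' @param trees data frame from [generate_trees()].
#' @param layout the [orchard_layout()].
#' @param gsd ground sampling distance, cm/px (sets canopy point density).
#' @param xyz_noise_sd isotropic coordinate jitter sd, metres.
#' @param ground_density areal ground-point density, points/m^2 (0 disables).
#' @param upper_fraction fraction of canopy points drawn from the upper
#'   half-spheroid.
#' @param dead_points trunk points per dead tree.
#' @param seed integer RNG seed.
#' @return a numeric matrix with columns `x`, `y`, `z` (metres) and
#'   attributes `extent` (as in [render_bands()]), `gsd` and `density`.
#' @export
render_cloud <- function(trees, layout, gsd, xyz_noise_sd = 0.02,
                         ground_density = 4, upper_fraction = 0.65,
                         dead_points = 5L, seed = 1L) {
  if (xyz_noise_sd < 0)
    stop("`xyz_noise_sd` must be >= 0", call. = FALSE)
  dims <- raster_dims(gsd, layout$field_length, layout$field_width)
  s <- gsd / 100
  ext <- c(length_m = dims[["ncol"]] * s, width_m = dims[["nrow"]] * s)
  dens <- gsd_point_density(gsd)
  with_seed(seed, {
    parts <- vector("list", nrow(trees) + 1L)
    for (t in seq_len(nrow(trees))) {
      cx <- trees$center_x[t]; cy <- trees$center_y[t]
      if (trees$is_dead[t]) {
        # trunk-only returns
        z <- seq(0, trees$trunk_height[t], length.out = max(2L, dead_points))
        parts[[t]] <- cbind(rep(cx, length(z)), rep(cy, length(z)), z)
        next
      }
      r <- trees$radius[t]
      c_semi <- (trees$height[t] - trees$trunk_height[t]) / 2
      z0 <- (trees$height[t] + trees$trunk_height[t]) / 2
      vol <- (4 / 3) * pi * r^2 * c_semi
      n <- max(1L, as.integer(round(dens * vol)))
      n_up <- as.integer(round(n * upper_fraction))
      u <- .unit_ball(n)
      flip <- c(rep(1, n_up), rep(-1, n - n_up))
      u[, 3] <- abs(u[, 3]) * flip
      parts[[t]] <- cbind(cx + r * u[, 1], cy + r * u[, 2],
                          z0 + c_semi * u[, 3])
    }
    n_g <- as.integer(round(ext[["length_m"]] * ext[["width_m"]] *
                              ground_density))
    if (n_g > 0) {
      parts[[nrow(trees) + 1L]] <-
        cbind(stats::runif(n_g, 0, ext[["length_m"]]),
              stats::runif(n_g, 0, ext[["width_m"]]),
              rep(0, n_g))
    }
    pts <- do.call(rbind, parts)
    if (xyz_noise_sd > 0)
      pts <- pts + matrix(stats::rnorm(length(pts), 0, xyz_noise_sd),
                          nrow(pts), 3)
    colnames(pts) <- c("x", "y", "z")
    attr(pts, "extent") <- ext
    attr(pts, "gsd") <- gsd
    attr(pts, "density") <- dens
    pts
  })
}

#' Simulate a complete orchard scene
#'
#' Convenience wrapper chaining [generate_trees()], [assign_yields()],
#' [render_bands()] and [render_cloud()] with sub-seeds derived from `seed`
#' (seed, seed+1, seed+2, seed+3), so a `(parameters, seed)` pair fully
#' determines the scene.
#'
#' @param layout an [orchard_layout()].
#' @param gsd ground sampling distance, cm/px.
#' @param seed integer RNG seed.
#' @param bands,cloud set `FALSE` to skip rendering that modality.
#' @param ... passed on to [generate_trees()].
#' @param yield_noise_sd,band_noise_sd,xyz_noise_sd,ground_density noise and
#'   density settings forwarded to the respective stages.
#' @return a list of class `orchard_scene` with elements `layout`, `trees`,
#'   `bands`, `cloud`, `gsd`, `seed`.
#' @export
simulate_scene <- function(layout = orchard_layout(), gsd = 2.13, seed = 1L,
                           bands = TRUE, cloud = TRUE,
                           yield_noise_sd = "auto", band_noise_sd = 0.01,
                           xyz_noise_sd = 0.02, ground_density = 4, ...) {
  trees <- generate_trees(layout, seed = seed, ...)
  trees <- assign_yields(trees, noise_sd = yield_noise_sd, seed = seed + 1)
  bs <- if (bands) render_bands(trees, layout, gsd,
                                noise_sd = band_noise_sd, seed = seed + 2)
  cl <- if (cloud) render_cloud(trees, layout, gsd,
                                xyz_noise_sd = xyz_noise_sd,
                                ground_density = ground_density,
                                seed = seed + 3)
  structure(list(layout = layout, trees = trees, bands = bs, cloud = cl,
                 gsd = gsd, seed = seed),
            class = "orchard_scene")
}

#' @export
print.orchard_scene <- function(x, ...) {
  cat("<orchard_scene> ", nrow(x$trees), " trees (",
      sum(x$trees$is_dead), " dead), gsd ", x$gsd, " cm/px",
      if (!is.null(x$cloud)) paste0(", ", nrow(x$cloud), " cloud points"),
      "\n", sep = "")
  invisible(x)
}
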