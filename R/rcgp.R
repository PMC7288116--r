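# RCGP: row/column detection by cumulative grayscale projection with
# kernel-smoothed peak search, plus 2D <-> 3D boundary conversion.

#' Cumulative grayscale projection of an index image
#'
#' `axis = "row"` sums each image row across all columns (`G_L(i)`), giving a
#' profile along Y; `axis = "column"` sums each column across all rows
#' (`G_C(j)`), a profile along X.
#'
#' @param gray numeric matrix (grayscale index image or a sub-image).
#' @param axis `"row"` or `"column"`.
#' @return an object of class `gray_profile` with fields `axis`, `raw`,
#'   `smoothed` (unset until [smooth_profile()]), `bandwidth`.
#' @export
project_profile <- function(gray, axis = c("row", "column")) {
  axis <- match.arg(axis)
  if (!length(gray)) stop("empty image", call. = FALSE)
  raw <- if (axis == "row") rowSums(gray) else colSums(gray)
  structure(list(axis = axis, raw = as.numeric(raw),
                 smoothed = NULL, bandwidth = NULL, kernel = "gaussian"),
            class = "gray_profile")
}

# reflect-padded (edge repeated) index, scipy-style 'reflect'; period 2n
.reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# normalized Gaussian convolution along the position axis, bandwidth = sd in
# samples, kernel truncated at 4 sd; reflect padding preserves total mass
gaussian_smooth <- function(x, h) {
  n <- length(x)
  r <- max(1L, as.integer(ceiling(4 * h)))
  k <- stats::dnorm(seq(-r, r), sd = h)
  k <- k / sum(k)
  xp <- x[.reflect_index(seq(1 - r, n + r), n)]
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y)[(r + 1):(r + n)]
}

#' Kernel-smooth a projection profile
#'
#' Gaussian-kernel smoothing of the cumulative grayscale profile along the
#' position axis with bandwidth `h` (pixels, the kernel sd). Reflection
#' padding at the edges preserves the profile's total mass.
#'
#' @param profile a `gray_profile` from [project_profile()].
#' @param h bandwidth in pixels (> 0).
#' @return the profile with `smoothed` and `bandwidth` filled in.
#' @export
smooth_profile <- function(profile, h) {
  stopifnot(inherits(profile, "gray_profile"))
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("bandwidth `h` must be > 0", call. = FALSE)
  profile$smoothed <- gaussian_smooth(profile$raw, h)
  profile$bandwidth <- h
  profile
}

# plateau-aware interior local maxima of a numeric vector (1-based indices,
# plateau midpoint reported)
.local_maxima <- function(x) {
  r <- rle(x)
  v <- r$values
  K <- length(v)
  if (K < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- 2:(K - 1)
  peak <- k[v[k] > v[k - 1] & v[k] > v[k + 1]]
  as.integer(starts[peak] + (r$lengths[peak] - 1L) %/% 2L)
}

# topographic prominence of each peak: height above the higher of the two
# key saddles toward the nearest higher ground (or the range minimum walking
# off an edge)
.prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    lmin <- x[p]; j <- p - 1L
    while (j >= 1L && x[j] <= x[p]) { lmin <- min(lmin, x[j]); j <- j - 1L }
    rmin <- x[p]; j <- p + 1L
    n <- length(x)
    while (j <= n && x[j] <= x[p]) { rmin <- min(rmin, x[j]); j <- j + 1L }
    x[p] - max(lmin, rmin)
  }, numeric(1))
}

# dominant spatial period of a profile via the peak of its FFT power spectrum
.estimate_spacing <- function(x) {
  n <- length(x)
  if (n < 8) return(n / 2)
  z <- stats::fft(x - mean(x))
  kmax <- max(2L, n %/% 2L)
  p <- Mod(z[2:kmax])^2
  n / which.max(p)
}

#' Detect segmentation boundaries in a smoothed projection profile
#'
#' Interior boundaries are the local maxima of the smoothed profile (for a
#' soil-bright index such as NG the grayscale maxima are the soil strips
#' between tree rows/trees). Candidate peaks must clear a topographic
#' prominence threshold; the surviving peaks are then thinned greedily by
#' descending height so that no two accepted boundaries (including the image
#' edges) are closer than `min_separation`. The image edges `0` and
#' `length - 1` are always appended. For a canopy-bright index (NDVI family)
#' use `mode = "invert"` to take minima instead.
#'
#' @param profile a smoothed `gray_profile`.
#' @param min_prominence absolute prominence threshold; default 5% of the
#'   smoothed profile's dynamic range.
#' @param min_separation minimum distance between boundaries, pixels; default
#'   half of `expected_spacing`.
#' @param expected_spacing expected peak spacing in pixels; if `NULL` it is
#'   estimated from the profile's dominant spatial period.
#' @param mode `"peaks"` (soil-bright index) or `"invert"` (canopy-bright).
#' @return sorted integer vector of 0-based boundary positions, first and
#'   last entries being the image edges.
#' @export
detect_boundaries <- function(profile, min_prominence = NULL,
                              min_separation = NULL,
                              expected_spacing = NULL,
                              mode = c("peaks", "invert")) {
  stopifnot(inherits(profile, "gray_profile"))
  mode <- match.arg(mode)
  sm <- profile$smoothed
  if (is.null(sm)) stop("profile must be smoothed first", call. = FALSE)
  if (mode == "invert") sm <- -sm
  n <- length(sm)
  edges <- c(0L, n - 1L)
  rng <- diff(range(sm))
  if (rng == 0) return(edges)
  if (is.null(min_separation)) {
    if (is.null(expected_spacing)) expected_spacing <- .estimate_spacing(sm)
    min_separation <- 0.5 * expected_spacing
  }
  if (is.null(min_prominence)) min_prominence <- 0.05 * rng

  peaks <- .local_maxima(sm)
  peaks <- peaks[.prominence(sm, peaks) >= min_prominence]
  # greedy separation filter; edges are accepted first so that interior
  # peaks closer than min_separation to an edge are suppressed
  accepted <- edges
  for (p in peaks[order(sm[peaks], decreasing = TRUE)] - 1L) {
    if (all(abs(accepted - p) >= min_separation)) accepted <- c(accepted, p)
  }
  out <- sort(unique(as.integer(accepted)))
  if (length(out) == 2L)
    warning("no interior boundaries detected; returning image edges only",
            call. = FALSE)
  out
}

#' Convert pixel boundaries to point-cloud metres (and back)
#'
#' Proportional rescaling of 0-based pixel boundary positions onto the cloud
#' extent: `b_m = |b_px| * extent_m / n_px`. `boundaries_to_px` is the exact
#' inverse (up to one-pixel rounding when re-quantized).
#'
#' @param b_px,b_m boundary positions (0-based pixels / metres).
#' @param n_px image size along the axis, pixels.
#' @param extent_m point-cloud extent along the same axis, metres.
#' @return numeric vector of converted positions.
#' @export
boundaries_to_m <- function(b_px, n_px, extent_m) {
  if (n_px <= 0 || extent_m <= 0)
    stop("image and cloud extents must be > 0", call. = FALSE)
  abs(b_px) * extent_m / n_px
}

#' @rdname boundaries_to_m
#' @export
boundaries_to_px <- function(b_m, n_px, extent_m) {
  if (n_px <= 0 || extent_m <= 0)
    stop("image and cloud extents must be > 0", call. = FALSE)
  abs(b_m) * n_px / extent_m
}

# region id bookkeeping for a ragged grid: row band i has K_i cells
.region_offsets <- function(cells_per_row) {
  c(0L, cumsum(cells_per_row))
}

#' Segment an orchard scene into per-tree regions
#'
#' Runs row detection on the Y projection of the whole grayscale index image,
#' then column detection independently within each detected row band, and
#' converts all boundaries to cloud coordinates. Each rectangular cell
#' between consecutive boundaries becomes one tree region. If a point cloud
#' is supplied its points are assigned to regions (`P` = per-cell point
#' count).
#'
#' Geometry conventions: pixel row 0 is the maximum-Y edge of the cloud
#' extent; boundary positions are 0-based pixels; cells are half-open
#' `[lo, hi)` except that the last cell along each axis is closed to the
#' raster edge, so the cells tile the extent and point counts sum to the
#' total in-extent cloud size.
#'
#' @param index_image an `index_image` (a soil-bright index such as NG for
#'   the default `mode = "peaks"`).
#' @param cloud optional point matrix from [render_cloud()] / [read_ply()].
#' @param row_spacing_m,plant_spacing_m expected row / plant spacing, metres;
#'   they set the smoothing bandwidth (`bandwidth_frac` x spacing) and the
#'   minimum peak separation (`separation_frac` x spacing).
#' @param bandwidth_frac,separation_frac,prominence_frac detection parameters
#'   as fractions of the expected spacing / profile dynamic range.
#' @param mode passed to [detect_boundaries()].
#' @return an object of class `grid_segmentation`: boundary vectors `L_2D`,
#'   `L_3D`, boundary lists `C_2D`, `C_3D` (one per row band), image and
#'   cloud dimensions `m_2D`, `n_2D`, `m_3D`, `n_3D`, a `regions` data frame
#'   (`region`, `row`, `col`, pixel window `r0,r1,c0,c1`, metre window
#'   `t0,t1,x0,x1` with `t` measured from the max-Y edge, and `P`), and, when
#'   a cloud was given, `point_region` (region index per point, NA outside
#'   the extent).
#' @export
segment_scene <- function(index_image, cloud = NULL,
                          row_spacing_m = 5, plant_spacing_m = 4,
                          bandwidth_frac = 0.10, separation_frac = 0.25,
                          prominence_frac = 0.05,
                          mode = c("peaks", "invert")) {
  stopifnot(inherits(index_image, "index_image"))
  mode <- match.arg(mode)
  gray <- index_image$gray
  s <- index_image$gsd / 100
  m2 <- nrow(gray); n2 <- ncol(gray)
  m3 <- m2 * s; n3 <- n2 * s
  if (!is.null(cloud)) {
    ext <- attr(cloud, "extent")
    if (!is.null(ext)) {
      if (abs(ext[["width_m"]] - m3) > 0.05 * m3 ||
          abs(ext[["length_m"]] - n3) > 0.05 * n3)
        stop("cloud extent differs from image extent by more than 5%",
             call. = FALSE)
    }
  }
  sp_row_px <- row_spacing_m / s
  sp_col_px <- plant_spacing_m / s

  pr <- smooth_profile(project_profile(gray, "row"),
                       bandwidth_frac * sp_row_px)
  L2 <- detect_boundaries(pr,
                          min_prominence = prominence_frac *
                            diff(range(pr$smoothed)),
                          min_separation = separation_frac * sp_row_px,
                          mode = mode)
  nb <- length(L2) - 1L              # number of row bands
  C2 <- vector("list", nb)
  for (i in seq_len(nb)) {
    r_lo <- L2[i] + 1L               # R row index of px row L2[i]
    r_hi <- if (i < nb) L2[i + 1L] else m2   # last band closed to edge
    sub <- gray[r_lo:r_hi, , drop = FALSE]
    pc <- smooth_profile(project_profile(sub, "column"),
                         bandwidth_frac * sp_col_px)
    C2[[i]] <- suppressWarnings(
      detect_boundaries(pc,
                        min_prominence = prominence_frac *
                          diff(range(pc$smoothed)),
                        min_separation = separation_frac * sp_col_px,
                        mode = mode))
  }
  L3 <- boundaries_to_m(L2, m2, m3)
  C3 <- lapply(C2, boundaries_to_m, n_px = n2, extent_m = n3)

  cells_per_row <- vapply(C2, function(b) length(b) - 1L, integer(1))
  off <- .region_offsets(cells_per_row)
  regions <- do.call(rbind, lapply(seq_len(nb), function(i) {
    K <- cells_per_row[i]
    j <- seq_len(K)
    data.frame(region = off[i] + j, row = i, col = j,
               r0 = L2[i], r1 = ifelse(j > 0, NA, NA),  # filled below
               c0 = C2[[i]][j], c1 = c(C2[[i]][j[-K] + 1L], n2),
               t0 = L3[i], t1 = if (i < nb) L3[i + 1L] else m3,
               x0 = C3[[i]][j], x1 = c(C3[[i]][j[-K] + 1L], n3))
  }))
  regions$r1 <- ifelse(regions$row < nb, L2[regions$row + 1L], m2)
  regions$r0 <- L2[regions$row]

  seg <- structure(list(L_2D = L2, C_2D = C2, L_3D = L3, C_3D = C3,
                        m_2D = m2, n_2D = n2, m_3D = m3, n_3D = n3,
                        regions = regions,
                        params = list(row_spacing_m = row_spacing_m,
                                      plant_spacing_m = plant_spacing_m,
                                      bandwidth_frac = bandwidth_frac,
                                      separation_frac = separation_frac,
                                      prominence_frac = prominence_frac,
                                      mode = mode)),
                   class = "grid_segmentation")
  if (!is.null(cloud)) seg <- assign_points(seg, cloud)
  seg
}

#' @export
print.grid_segmentation <- function(x, ...) {
  cat("<grid_segmentation> ", length(x$L_2D) - 1L, " row bands, ",
      nrow(x$regions), " regions\n", sep = "")
  invisible(x)
}

# assign arbitrary (x, y[, t]) locations to region ids; y is the cloud Y
# coordinate, internally flipped to the from-the-top axis t = m3 - y
.locate_regions <- function(seg, x, y) {
  t <- seg$m_3D - y
  nb <- length(seg$L_3D) - 1L
  ri <- findInterval(t, seg$L_3D)
  ri[ri >= nb + 1L] <- nb           # last band closed at the raster edge
  ri[t == seg$m_3D] <- nb           # numeric guard
  valid <- ri >= 1L & t >= 0 & t <= seg$m_3D & x >= 0 & x <= seg$n_3D
  ri[!valid] <- NA_integer_
  cells_per_row <- vapply(seg$C_3D, function(b) length(b) - 1L, integer(1))
  off <- .region_offsets(cells_per_row)
  out <- rep(NA_integer_, length(x))
  for (i in seq_len(nb)) {
    sel <- which(!is.na(ri) & ri == i)
    if (!length(sel)) next
    ci <- findInterval(x[sel], seg$C_3D[[i]])
    ci[ci >= cells_per_row[i] + 1L] <- cells_per_row[i]
    ci[ci < 1L] <- 1L
    out[sel] <- off[i] + ci
  }
  out
}

#' Assign cloud points to segmentation regions
#'
#' Computes the per-cell point count `P` (the number of cloud points whose
#' (x, y) falls inside each cell) and stores the per-point region index.
#' Points outside the raster extent are left unassigned.
#'
#' @param seg a `grid_segmentation`.
#' @param cloud a point matrix with columns `x`, `y`, `z`.
#' @return `seg` with `regions$P` and `point_region` filled in, and the
#'   cloud attached as `cloud`.
#' @export
assign_points <- function(seg, cloud) {
  stopifnot(inherits(seg, "grid_segmentation"))
  pr <- .locate_regions(seg, cloud[, "x"], cloud[, "y"])
  tab <- tabulate(pr, nbins = nrow(seg$regions))
  seg$regions$P <- tab
  seg$point_region <- pr
  seg$cloud <- cloud
  seg
}

#' Score detected regions against ground truth (correct / erroneous rates)
#'
#' A region is correct when it contains exactly one truth tree centre (dead
#' or live); regions with zero or multiple centres count as erroneously
#' recognized. `C = NC/N * 100` and `E = NE/N * 100` with `N` the total
#' number of regions.
#'
#' @param seg a `grid_segmentation`.
#' @param trees truth data frame with `center_x`, `center_y`.
#' @return a list with `NC`, `NE`, `N`, `C`, `E` (percent).
#' @export
score_detection <- function(seg, trees) {
  reg <- .locate_regions(seg, trees$center_x, trees$center_y)
  counts <- tabulate(reg[!is.na(reg)], nbins = nrow(seg$regions))
  NC <- sum(counts == 1L)
  N <- nrow(seg$regions)
  NE <- N - NC
  list(NC = NC, NE = NE, N = N, C = 100 * NC / N, E = 100 * NE / N)
}

#' Score detected row bands against ground truth
#'
#' A row band is correct when the truth centres falling inside it belong to
#' exactly one orchard row.
#'
#' @param seg a `grid_segmentation`.
#' @param trees truth data frame with `center_x`, `center_y`, `row`.
#' @return a list with `NC`, `NE`, `N` (bands), `C`, `E` (percent).
#' @export
score_rows <- function(seg, trees) {
  t <- seg$m_3D - trees$center_y
  nb <- length(seg$L_3D) - 1L
  ri <- findInterval(t, seg$L_3D)
  ri[ri >= nb + 1L] <- nb
  ri[ri < 1L] <- NA_integer_
  n_rows_in_band <- vapply(seq_len(nb), function(i)
    length(unique(trees$row[!is.na(ri) & ri == i])), integer(1))
  NC <- sum(n_rows_in_band == 1L)
  list(NC = NC, NE = nb - NC, N = nb,
       C = 100 * NC / nb, E = 100 * (nb - NC) / nb)
}
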