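# Vegetation indices and 0-255 grayscale index images.

#' Names of the supported vegetation indices
#' @return character vector of the ten index names, in canonical order.
#' @export
vegetation_indices <- function() {
  c("NG", "NR", "NDVI", "GNDVI", "DVI", "CIG", "OSAVI", "RDVI", "NLI",
    "WDRVI")
}

# ratio with zero-denominator pixels forced to 0; count of such pixels is
# returned via attribute so callers can log them
.safe_ratio <- function(num, den) {
  bad <- den == 0
  den[bad] <- 1
  out <- num / den
  out[bad] <- 0
  attr(out, "n_invalid") <- sum(bad)
  out
}

# pixel-wise index formulas (reflectance in, unitless index out)
.index_fun <- function(name) {
  switch(name,
    NG    = function(g, r, e, n) .safe_ratio(g, n + r + g),
    NR    = function(g, r, e, n) .safe_ratio(r, n + r + g),
    NDVI  = function(g, r, e, n) .safe_ratio(n - r, n + r),
    GNDVI = function(g, r, e, n) .safe_ratio(n - g, n + g),
    DVI   = function(g, r, e, n) structure(n - r, n_invalid = 0L),
    CIG   = function(g, r, e, n) {
      out <- .safe_ratio(n, g)
      nb <- attr(out, "n_invalid")
      out <- out - 1
      out[g == 0] <- 0
      structure(out, n_invalid = nb)
    },
    OSAVI = function(g, r, e, n) .safe_ratio(1.16 * (n - r), n + r + 0.16),
    RDVI  = function(g, r, e, n) .safe_ratio(n - r, sqrt(n + r)),
    NLI   = function(g, r, e, n) .safe_ratio(n^2 - r, n^2 + r),
    WDRVI = function(g, r, e, n) .safe_ratio(0.2 * n - r, 0.2 * n + r),
    stop("unknown vegetation index: ", name, call. = FALSE))
}

#' Rescale an index raster to 0-255 grayscale
#'
#' Linear min-max rescale: `gray = round(255 * (v - min) / (max - min))`,
#' with rounding half-away-from-zero. A constant raster maps to all zeros.
#'
#' @param values numeric matrix (finite values).
#' @return integer matrix in `[0, 255]` with the same dimensions.
#' @export
to_grayscale <- function(values) {
  rng <- range(values)
  if (!all(is.finite(rng)))
    stop("`values` must be finite", call. = FALSE)
  if (rng[1] == rng[2]) {
    g <- array(0L, dim(values))
  } else {
    g <- round_half_up(255 * (values - rng[1]) / (rng[2] - rng[1]))
    storage.mode(g) <- "integer"
  }
  g
}

#' Compute a vegetation index image from a band stack
#'
#' Applies the pixel-wise index formula (see [vegetation_indices()] for the
#' supported set, e.g. `NDVI = (NIR - RED)/(NIR + RED)`,
#' `NG = GRE/(NIR + RED + GRE)`) and converts the result to a 0-255 grayscale
#' raster by per-image min-max scaling. Pixels with a zero denominator get
#' index value 0 and are counted in the `n_invalid` field. The REG band is
#' accepted for completeness; no formula in the supported set uses it.
#'
#' @param bands a `band_stack` from [render_bands()] or [read_scene()].
#' @param name one of [vegetation_indices()].
#' @return an object of class `index_image`: `name`, `values` (float raster),
#'   `gray` (integer raster in 0-255), `gsd`, `extent`, `n_invalid`.
#' @examples
#' b <- structure(list(gre = matrix(0.2), red = matrix(0.2),
#'                     reg = matrix(0.3), nir = matrix(0.6),
#'                     gsd = 2.13, extent = c(length_m = 1, width_m = 1)),
#'                class = "band_stack")
#' compute_index(b, "NDVI")$values  # 0.5
#' @export
compute_index <- function(bands, name) {
  name <- match.arg(name, vegetation_indices())
  if (!all(dim(bands$gre) == dim(bands$red)) ||
      !all(dim(bands$gre) == dim(bands$reg)) ||
      !all(dim(bands$gre) == dim(bands$nir)))
    stop("all four bands must share identical dimensions", call. = FALSE)
  v <- .index_fun(name)(bands$gre, bands$red, bands$reg, bands$nir)
  n_invalid <- attr(v, "n_invalid") %||% 0L
  attr(v, "n_invalid") <- NULL
  v <- matrix(v, nrow(bands$gre), ncol(bands$gre))
  structure(list(name = name, values = v, gray = to_grayscale(v),
                 gsd = bands$gsd, extent = bands$extent,
                 n_invalid = n_invalid),
            class = "index_image")
}

#' @export
print.index_image <- function(x, ...) {
  cat("<index_image> ", x$name, ", ", nrow(x$gray), " x ", ncol(x$gray),
      " px, gsd ", x$gsd, " cm/px\n", sep = "")
  invisible(x)
}
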