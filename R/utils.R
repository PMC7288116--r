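#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(abs(seed) %% 2147483647))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Raster dimensions for a field at a given ground sampling distance
#'
#' One pixel covers `gsd` cm on the ground, so a `field_length` x `field_width`
#' metre field maps to `ceiling(length*100/gsd)` columns by
#' `ceiling(width*100/gsd)` rows.
#'
#' @param gsd ground sampling distance, cm/px.
#' @param field_length field extent along X (image columns), metres.
#' @param field_width field extent along Y (image rows), metres.
#' @return integer vector `c(nrow, ncol)`.
#' @export
raster_dims <- function(gsd, field_length, field_width) {
  if (gsd <= 0) stop("`gsd` must be > 0", call. = FALSE)
  c(nrow = as.integer(ceiling(field_width * 100 / gsd)),
    ncol = as.integer(ceiling(field_length * 100 / gsd)))
}

# round-half-away-from-zero (values here are always >= 0)
round_half_up <- function(x) floor(x + 0.5)
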