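# Per-tree color moments and GLCM texture features of index images.

#' Color moments of a grayscale patch
#'
#' First-, second- and third-order moments: `mu` is the patch mean, `sigma`
#' the root mean squared deviation, and `s` the signed cube root of the mean
#' cubed deviation (sign preserved, so negative skew stays real).
#'
#' @param patch numeric matrix (or vector) of pixel values.
#' @return a list with `mu`, `sigma`, `s` (grayscale units).
#' @export
color_moments <- function(patch) {
  if (!length(patch)) stop("empty patch", call. = FALSE)
  p <- as.numeric(patch)
  mu <- mean(p)
  sigma <- sqrt(mean((p - mu)^2))
  m3 <- mean((p - mu)^3)
  list(mu = mu, sigma = sigma, s = sign(m3) * abs(m3)^(1 / 3))
}

# default GLCM offsets: distance 1 at 0, 45, 90, 135 degrees, as (dy, dx)
.glcm_offsets <- function() list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
                                 c(-1L, -1L))

#' Gray-level co-occurrence matrix of a patch
#'
#' Quantizes the patch to `levels` bins (uniform binning of `[0, 255]` unless
#' `quantize = FALSE`, in which case the patch must already hold integer
#' levels in `0:(levels-1)`), counts ordered neighbour pairs for each offset
#' `(dy, dx)`, averages over the offsets and normalizes to sum 1.
#'
#' @param patch numeric matrix of pixel values.
#' @param levels number of gray levels `N` (>= 2).
#' @param offsets list of integer `(dy, dx)` offsets; default distance 1 at
#'   0/45/90/135 degrees.
#' @param quantize quantize from `[0, 255]` (default) or use values as-is.
#' @return an `levels x levels` matrix `p` with `sum(p) == 1`; rows index the
#'   reference pixel's level, columns the neighbour's.
#' @export
glcm <- function(patch, levels = 16L, offsets = .glcm_offsets(),
                 quantize = TRUE) {
  if (levels < 2L) stop("`levels` must be >= 2", call. = FALSE)
  q <- if (quantize) {
    matrix(pmin(as.integer(levels) - 1L,
                as.integer(floor(patch * levels / 256))),
           nrow(patch), ncol(patch))
  } else {
    storage.mode(patch) <- "integer"
    patch
  }
  nr <- nrow(q); nc <- ncol(q)
  counts <- numeric(levels * levels)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    if (abs(dy) >= nr || abs(dx) >= nc)
      stop("patch smaller than offset reach", call. = FALSE)
    r1 <- max(1L, 1L - dy):min(nr, nr - dy)
    c1 <- max(1L, 1L - dx):min(nc, nc - dx)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dy, c1 + dx, drop = FALSE]
    counts <- counts + tabulate(a * levels + b + 1L,
                                nbins = levels * levels)
  }
  p <- matrix(counts, levels, levels, byrow = TRUE)
  p / sum(p)
}

#' Haralick texture features of a normalized co-occurrence matrix
#'
#' Contrast `CON = sum |i-j|^2 p(i,j)`, correlation
#' `COR = (sum i*j*p - mu_i*mu_j) / (sd_i*sd_j)` with marginal means and
#' standard deviations, angular second moment `ASM = sum p^2`, and inverse
#' difference moment `INM = sum p / (1 + |i-j|)`; levels are indexed
#' `0..N-1`. For a constant patch the marginal variance is zero and `COR` is
#' undefined: it is reported as 0 with `cor_defined = FALSE` so batch
#' extraction never aborts.
#'
#' @param p normalized co-occurrence matrix from [glcm()].
#' @return a list with `CON`, `COR`, `ASM`, `INM`, `cor_defined`.
#' @export
texture_features <- function(p) {
  N <- nrow(p)
  i <- matrix(0:(N - 1), N, N)
  j <- t(i)
  CON <- sum((i - j)^2 * p)
  ASM <- sum(p^2)
  INM <- sum(p / (1 + abs(i - j)))
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  var_i <- sum((i - mu_i)^2 * p); var_j <- sum((j - mu_j)^2 * p)
  if (var_i <= 0 || var_j <= 0) {
    COR <- 0; defined <- FALSE
  } else {
    COR <- (sum(i * j * p) - mu_i * mu_j) / sqrt(var_i * var_j)
    defined <- TRUE
  }
  list(CON = CON, COR = COR, ASM = ASM, INM = INM, cor_defined = defined)
}

# per-index feature names, in block order
.index_feature_names <- function(index) {
  paste0(index, "_", c("mu", "sigma", "s", "CON", "COR", "ASM", "INM"))
}

.morph_feature_names <- c("H", "S_XOY", "V", "P")

#' Extract the full per-tree feature table
#'
#' For every segmented region and every supplied index image, computes the
#' three color moments and four texture features of the region's rectangular
#' pixel window, and appends the morphometrics block (`H`, `S_XOY`, `V`,
#' `P`). Column order is fixed: per-index blocks
#' `{mu, sigma, s, CON, COR, ASM, INM}` in the order of `grays`, then the
#' morphometrics.
#'
#' @param grays named list of grayscale index rasters (integer matrices from
#'   [compute_index()]`$gray`), e.g. all ten of [vegetation_indices()].
#' @param seg a `grid_segmentation`.
#' @param morph morphometrics table from [morph_table()] (same region order).
#' @param levels,offsets GLCM parameters, see [glcm()].
#' @return a data frame: `region`, `row`, `col`, then `7 * length(grays)`
#'   spectral features, then `H`, `S_XOY`, `V`, `P`.
#' @export
extract_features <- function(grays, seg, morph, levels = 16L,
                             offsets = .glcm_offsets()) {
  stopifnot(inherits(seg, "grid_segmentation"), is.list(grays),
            !is.null(names(grays)))
  reg <- seg$regions
  n_reg <- nrow(reg)
  cols <- unlist(lapply(names(grays), .index_feature_names))
  out <- matrix(NA_real_, n_reg, length(cols),
                dimnames = list(NULL, cols))
  for (r in seq_len(n_reg)) {
    ri <- (reg$r0[r] + 1L):reg$r1[r]
    ci <- (reg$c0[r] + 1L):reg$c1[r]
    for (nm in names(grays)) {
      patch <- grays[[nm]][ri, ci, drop = FALSE]
      cm <- color_moments(patch)
      tx <- texture_features(glcm(patch, levels = levels, offsets = offsets))
      out[r, .index_feature_names(nm)] <-
        c(cm$mu, cm$sigma, cm$s, tx$CON, tx$COR, tx$ASM, tx$INM)
    }
  }
  stopifnot(nrow(morph) == n_reg)
  cbind(reg[, c("region", "row", "col")], as.data.frame(out),
        morph[, c("H", "S_XOY", "V", "P")])
}

#' Select the model input mode from a feature table
#'
#' The six input modes of the yield model:
#' * `"input1:<INDEX>"` - moments + texture of one index plus `H`, `S_XOY`,
#'   `V` (10 features);
#' * `"input2"` - morphometrics only: `H`, `S_XOY`, `V`, `P` (4);
#' * `"input3"` - color moments of all indices (30 for ten indices);
#' * `"input4"` - texture features of all indices (40);
#' * `"input5"` - moments + texture of all indices (70);
#' * `"input6"` - everything: input5 plus the four morphometrics (74).
#'
#' @param features feature table from [extract_features()].
#' @param mode one of the modes above.
#' @return numeric matrix of selected feature columns (rownames = region
#'   ids).
#' @export
select_input_mode <- function(features, mode = "input6") {
  idx_cols <- setdiff(colnames(features),
                      c("region", "row", "col", .morph_feature_names))
  indices <- unique(sub("_[^_]+$", "", idx_cols))
  moment_cols <- unlist(lapply(indices, function(i)
    paste0(i, "_", c("mu", "sigma", "s"))))
  texture_cols <- unlist(lapply(indices, function(i)
    paste0(i, "_", c("CON", "COR", "ASM", "INM"))))
  cols <- if (grepl("^input1:", mode)) {
    one <- sub("^input1:", "", mode)
    if (!one %in% indices)
      stop("unknown index in mode: ", one, call. = FALSE)
    c(.index_feature_names(one), "H", "S_XOY", "V")
  } else switch(mode,
    input2 = .morph_feature_names,
    input3 = moment_cols,
    input4 = texture_cols,
    input5 = unlist(lapply(indices, .index_feature_names)),
    input6 = c(unlist(lapply(indices, .index_feature_names)),
               .morph_feature_names),
    stop("unknown input mode: ", mode, call. = FALSE))
  m <- as.matrix(features[, cols, drop = FALSE])
  rownames(m) <- features$region
  m
}
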