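# File interchange: ASCII PLY point clouds, 16-bit TIFF band rasters with a
# JSON sidecar, truth/feature CSV tables.

#' Write / read an ASCII PLY 1.0 point cloud
#'
#' Minimal PLY support for clouds of `float x y z` vertices — the format the
#' photogrammetry software exports. Coordinates survive a write/read
#' round-trip at float32 precision.
#'
#' @param points numeric matrix with columns `x`, `y`, `z`, metres.
#' @param path file path.
#' @return `read_ply` returns the point matrix (with any `extent` comment
#'   restored as an attribute); `write_ply` returns `path` invisibly.
#' @export
write_ply <- function(points, path) {
  ext <- attr(points, "extent")
  header <- c("ply", "format ascii 1.0",
              if (!is.null(ext))
                paste("comment extent", ext[["length_m"]], ext[["width_m"]]),
              paste("element vertex", nrow(points)),
              "property float x", "property float y", "property float z",
              "end_header")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.8g %.8g %.8g",
                     points[, 1], points[, 2], points[, 3]), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "ply") ||
      !identical(lines[2], "format ascii 1.0"))
    stop("not an ASCII PLY 1.0 file: ", path, call. = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated", call. = FALSE)
  nv_line <- grep("^element vertex ", lines[seq_len(end)], value = TRUE)
  nv <- as.integer(sub("^element vertex ", "", nv_line[1]))
  ext_line <- grep("^comment extent ", lines[seq_len(end)], value = TRUE)
  body <- lines[(end + 1):(end + nv)]
  pts <- matrix(scan(text = body, quiet = TRUE), nv, 3, byrow = TRUE)
  colnames(pts) <- c("x", "y", "z")
  if (length(ext_line)) {
    v <- as.numeric(strsplit(ext_line[1], " ")[[1]][3:4])
    attr(pts, "extent") <- c(length_m = v[1], width_m = v[2])
  }
  pts
}

.band_scale <- 10000L  # reflectance file-encoding divisor

write_band_tiff <- function(mat, path, scale = .band_scale) {
  # 16-bit grayscale; stored integer = round(reflectance * scale)
  tiff::writeTIFF(round(mat * scale) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

read_band_tiff <- function(path, scale = .band_scale) {
  round(tiff::readTIFF(path) * 65535) / scale
}

#' Write / read a synthetic scene directory
#'
#' Lays a scene out the way the pipeline's consumers expect it: one 16-bit
#' grayscale TIFF per band (`GRE.tif`, `RED.tif`, `REG.tif`, `NIR.tif`,
#' reflectance scaled by 10000), the point cloud as `cloud.ply` (ASCII PLY),
#' a `scene.json` sidecar (gsd, extent, origin, band scale, seed) and the
#' ground truth as `truth.csv`.
#'
#' @param scene an `orchard_scene` from [simulate_scene()].
#' @param dir output directory (created if needed).
#' @return `read_scene` returns a list with `bands` (a `band_stack`),
#'   `cloud` (or `NULL`), `trees` (or `NULL`) and `meta`; `write_scene`
#'   returns `dir` invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- scene$bands
  for (nm in c("gre", "red", "reg", "nir"))
    write_band_tiff(b[[nm]], file.path(dir, paste0(toupper(nm), ".tif")))
  if (!is.null(scene$cloud)) write_ply(scene$cloud,
                                       file.path(dir, "cloud.ply"))
  meta <- list(gsd_cm_px = b$gsd,
               extent_m = as.list(b$extent),
               origin_m = as.list(b$origin),
               band_scale = .band_scale,
               seed = scene$seed,
               field_length_m = scene$layout$field_length,
               field_width_m = scene$layout$field_width)
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(scene$trees, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  bands <- lapply(c(gre = "GRE", red = "RED", reg = "REG", nir = "NIR"),
                  function(nm) read_band_tiff(file.path(dir,
                                                        paste0(nm, ".tif")),
                                              scale = meta$band_scale))
  bs <- structure(c(bands,
                    list(gsd = meta$gsd_cm_px,
                         origin = unlist(meta$origin_m),
                         extent = c(length_m = meta$extent_m$length_m,
                                    width_m = meta$extent_m$width_m))),
                  class = "band_stack")
  ply <- file.path(dir, "cloud.ply")
  cloud <- if (file.exists(ply)) read_ply(ply)
  tr <- file.path(dir, "truth.csv")
  trees <- if (file.exists(tr)) utils::read.csv(tr)
  list(bands = bs, cloud = cloud, trees = trees, meta = meta)
}

#' Write a segmentation result to JSON
#'
#' Serializes the 2-D and 3-D boundary arrays, per-cell point counts and,
#' when truth is supplied, the detection scores.
#'
#' @param seg a `grid_segmentation`.
#' @param path output path.
#' @param trees optional truth table; adds `scores` to the file.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path, trees = NULL) {
  out <- list(L_2D = seg$L_2D, C_2D = seg$C_2D,
              L_3D = seg$L_3D, C_3D = seg$C_3D,
              m_2D = seg$m_2D, n_2D = seg$n_2D,
              m_3D = seg$m_3D, n_3D = seg$n_3D,
              regions = seg$regions, params = seg$params)
  if (!is.null(trees))
    out$scores <- list(rows = score_rows(seg, trees),
                       columns = score_detection(seg, trees))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
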