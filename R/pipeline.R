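# End-to-end orchestration and the evaluation harness that reproduces the
# detection / morphometry / yield statistics on synthetic scenes.

#' Truth-aligned segmentation of a scene
#'
#' Builds the segmentation a perfect detector would produce: row boundaries
#' at the midlines between adjacent orchard rows and, within each row,
#' column boundaries at the midpoints between adjacent trees (plus the field
#' edges). Useful to measure morphometric error in isolation from detection
#' error.
#'
#' @param trees truth table from [generate_trees()].
#' @param layout the matching [orchard_layout()].
#' @param gsd ground sampling distance, cm/px (fixes the raster-aligned
#'   extent and the pixel quantization of the boundaries).
#' @return a `grid_segmentation` (no points assigned yet).
#' @export
truth_segmentation <- function(trees, layout, gsd) {
  dims <- raster_dims(gsd, layout$field_length, layout$field_width)
  s <- gsd / 100
  m2 <- dims[["nrow"]]; n2 <- dims[["ncol"]]
  m3 <- m2 * s; n3 <- n2 * s
  rows <- sort(unique(trees$row))
  # from-the-top coordinate of each row's mean centreline
  t_row <- vapply(rows, function(i) m3 - mean(trees$center_y[trees$row == i]),
                  numeric(1))
  mid <- (t_row[-1] + t_row[-length(t_row)]) / 2
  L2 <- sort(unique(as.integer(c(0L, round(mid / s), m2 - 1L))))
  nb <- length(L2) - 1L
  L3 <- boundaries_to_m(L2, m2, m3)
  C2 <- vector("list", nb)
  for (i in seq_len(nb)) {
    xs <- sort(trees$center_x[trees$row == rows[min(i, length(rows))]])
    midx <- (xs[-1] + xs[-length(xs)]) / 2
    C2[[i]] <- sort(unique(as.integer(c(0L, round(midx / s), n2 - 1L))))
  }
  C3 <- lapply(C2, boundaries_to_m, n_px = n2, extent_m = n3)
  cells_per_row <- vapply(C2, function(b) length(b) - 1L, integer(1))
  off <- .region_offsets(cells_per_row)
  regions <- do.call(rbind, lapply(seq_len(nb), function(i) {
    K <- cells_per_row[i]
    j <- seq_len(K)
    data.frame(region = off[i] + j, row = i, col = j,
               r0 = L2[i],
               r1 = if (i < nb) L2[i + 1L] else m2,
               c0 = C2[[i]][j], c1 = c(C2[[i]][j[-K] + 1L], n2),
               t0 = L3[i], t1 = if (i < nb) L3[i + 1L] else m3,
               x0 = C3[[i]][j], x1 = c(C3[[i]][j[-K] + 1L], n3))
  }))
  structure(list(L_2D = L2, C_2D = C2, L_3D = L3, C_3D = C3,
                 m_2D = m2, n_2D = n2, m_3D = m3, n_3D = n3,
                 regions = regions,
                 params = list(mode = "truth-aligned")),
            class = "grid_segmentation")
}

# match segmented regions to truth trees: returns per-region tree_id
# (NA when the region holds zero or multiple centres)
match_regions <- function(seg, trees) {
  reg <- .locate_regions(seg, trees$center_x, trees$center_y)
  n_reg <- nrow(seg$regions)
  out <- rep(NA_integer_, n_reg)
  counts <- tabulate(reg[!is.na(reg)], nbins = n_reg)
  one <- which(counts == 1L)
  for (r in one) out[r] <- trees$tree_id[which(reg == r)[1]]
  out
}

#' Run the full measurement pipeline on one scene
#'
#' Chains index computation, RCGP segmentation, point assignment,
#' morphometrics, feature extraction and (when yields are present) yield
#' model training/evaluation. Deterministic given the scene and
#' `train_seed`.
#'
#' @param scene an `orchard_scene` (bands required; cloud required for
#'   morphometrics).
#' @param index_names indices to compute (default all ten).
#' @param segment_index index used for row/column detection (NG by default:
#'   it is soil-bright, which the peak semantics require).
#' @param mode input mode for the yield model, see [select_input_mode()].
#' @param train_seed seed for the yield model split/initialization.
#' @param train whether to fit the yield model (needs `yield_kg` truth).
#' @param trunk_height trunk height for the volume formula, metres.
#' @return a list of class `pipeline_report`: `indices` (grayscale rasters),
#'   `segmentation`, `scores` (row and column detection vs truth), `morph`,
#'   `features`, `matched` (region-to-tree map), and `model`/`metrics` when
#'   trained.
#' @export
run_pipeline <- function(scene, index_names = vegetation_indices(),
                         segment_index = "NG", mode = "input6",
                         train_seed = 1L, train = TRUE, trunk_height = 0.6) {
  stopifnot(inherits(scene, "orchard_scene"), !is.null(scene$bands))
  imgs <- lapply(index_names, function(nm) compute_index(scene$bands, nm))
  names(imgs) <- index_names
  grays <- lapply(imgs, `[[`, "gray")
  seg <- segment_scene(imgs[[segment_index]], cloud = scene$cloud,
                       row_spacing_m = scene$layout$row_spacing,
                       plant_spacing_m = scene$layout$plant_spacing)
  scores <- list(rows = score_rows(seg, scene$trees),
                 columns = score_detection(seg, scene$trees))
  morph <- if (!is.null(scene$cloud)) morph_table(seg, trunk_height)
  report <- list(indices = grays, segmentation = seg, scores = scores,
                 morph = morph)
  if (!is.null(morph)) {
    feats <- extract_features(grays, seg, morph)
    matched <- match_regions(seg, scene$trees)
    report$features <- feats
    report$matched <- matched
    if (train && !is.null(scene$trees$yield_kg)) {
      x <- select_input_mode(feats, mode)
      keep <- which(!is.na(matched) &
                      !scene$trees$is_dead[matched] &
                      stats::complete.cases(x))
      if (length(keep) >= 8) {
        model <- bpann_train(x[keep, , drop = FALSE],
                             scene$trees$yield_kg[matched[keep]],
                             seed = train_seed)
        yhat <- predict(model, x[keep, , drop = FALSE])
        ytru <- scene$trees$yield_kg[matched[keep]]
        report$model <- model
        report$metrics <- list(
          test = regression_metrics(ytru[model$split$test],
                                    yhat[model$split$test]),
          all = regression_metrics(ytru, yhat))
      } else {
        warning("too few matched live trees to train the yield model",
                call. = FALSE)
      }
    } else if (train) {
      warning("no yields in truth; skipping the yield model", call. = FALSE)
    }
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat("  rows:    C = ", round(x$scores$rows$C, 2), "%\n", sep = "")
  cat("  columns: C = ", round(x$scores$columns$C, 2), "%, E = ",
      round(x$scores$columns$E, 2), "%\n", sep = "")
  if (!is.null(x$metrics))
    cat("  yield (test split): R2 = ", round(x$metrics$test$R2, 3),
        ", RMSE = ", round(x$metrics$test$RMSE, 2), " kg, RAD_avg = ",
        round(x$metrics$test$RAD_avg, 2), "%\n", sep = "")
  invisible(x)
}

#' Replicate the row/column detection study on synthetic scenes
#'
#' For each GSD and seed: simulates a scene (bands only), runs RCGP on the
#' NG grayscale image and scores row bands and column cells against the
#' generated truth.
#'
#' @param seeds integer vector of scene seeds.
#' @param gsds GSDs in cm/px (default: the five calibrated flight GSDs).
#' @param layout an [orchard_layout()].
#' @return data frame with one row per (gsd, seed): `row_C`, `col_C`,
#'   `col_E`, `n_regions`, `n_trees`.
#' @export
replicate_detection <- function(seeds = 1:10,
                                gsds = c(2.13, 3.31, 4.39, 5.43, 6.69),
                                layout = orchard_layout()) {
  res <- expand.grid(gsd = gsds, seed = seeds)
  res$row_C <- res$col_C <- res$col_E <- NA_real_
  res$n_regions <- res$n_trees <- NA_integer_
  for (k in seq_len(nrow(res))) {
    scene <- simulate_scene(layout, gsd = res$gsd[k], seed = res$seed[k],
                            cloud = FALSE)
    ng <- compute_index(scene$bands, "NG")
    seg <- segment_scene(ng, row_spacing_m = layout$row_spacing,
                         plant_spacing_m = layout$plant_spacing)
    rs <- score_rows(seg, scene$trees)
    cs <- score_detection(seg, scene$trees)
    res$row_C[k] <- rs$C
    res$col_C[k] <- cs$C
    res$col_E[k] <- cs$E
    res$n_regions[k] <- cs$N
    res$n_trees[k] <- nrow(scene$trees)
  }
  res
}

#' Replicate the morphometric recovery study
#'
#' For each seed: simulates a point cloud at the canopy density implied by
#' `gsd`, segments it with truth-aligned boundaries, measures `H`, `S_XOY`
#' and `V` per live tree and compares them with the generator truth
#' (`H` truth = total height, `S` truth = `pi r^2`, `V` truth =
#' [truth_volume()]).
#'
#' @param seeds integer vector of scene seeds.
#' @param gsd GSD in cm/px (2.13 gives the highest density, 364.77 pts/m^3).
#' @param layout an [orchard_layout()].
#' @return a list with `per_tree` (one row per live tree and seed, absolute
#'   relative deviations in percent) and `summary` (RAD_avg/max/min and R2
#'   per quantity).
#' @export
replicate_morphometrics <- function(seeds = 1:10, gsd = 2.13,
                                    layout = orchard_layout()) {
  rows <- list()
  for (sd in seeds) {
    scene <- simulate_scene(layout, gsd = gsd, seed = sd, bands = FALSE)
    seg <- truth_segmentation(scene$trees, layout, gsd)
    seg <- assign_points(seg, scene$cloud)
    morph <- morph_table(seg)
    matched <- match_regions(seg, scene$trees)
    ok <- which(!is.na(matched) & !scene$trees$is_dead[matched] &
                  !is.na(morph$H))
    tr <- scene$trees[matched[ok], ]
    est <- morph[ok, ]
    rows[[length(rows) + 1L]] <- data.frame(
      seed = sd, tree_id = tr$tree_id,
      H_est = est$H, H_tru = tr$height,
      S_est = est$S_XOY, S_tru = pi * tr$radius^2,
      V_est = est$V, V_tru = truth_volume(tr$height, tr$radius,
                                          tr$trunk_height))
  }
  per_tree <- do.call(rbind, rows)
  rad <- function(est, tru) abs(est - tru) / tru * 100
  per_tree$rad_H <- rad(per_tree$H_est, per_tree$H_tru)
  per_tree$rad_S <- rad(per_tree$S_est, per_tree$S_tru)
  per_tree$rad_V <- rad(per_tree$V_est, per_tree$V_tru)
  r2 <- function(est, tru) 1 - sum((tru - est)^2) / sum((tru - mean(tru))^2)
  summ <- data.frame(
    quantity = c("H", "S_XOY", "V"),
    RAD_avg = c(mean(per_tree$rad_H), mean(per_tree$rad_S),
                mean(per_tree$rad_V)),
    RAD_max = c(max(per_tree$rad_H), max(per_tree$rad_S),
                max(per_tree$rad_V)),
    RAD_min = c(min(per_tree$rad_H), min(per_tree$rad_S),
                min(per_tree$rad_V)),
    R2 = c(r2(per_tree$H_est, per_tree$H_tru),
           r2(per_tree$S_est, per_tree$S_tru),
           r2(per_tree$V_est, per_tree$V_tru)))
  list(per_tree = per_tree, summary = summ)
}

#' Replicate the yield prediction study
#'
#' Simulates one full scene, runs the pipeline up to feature extraction,
#' then trains the yield network once per training seed and collects the
#' held-out test metrics.
#'
#' @param scene_seed seed of the simulated scene.
#' @param train_seeds seeds for the model split/initialization.
#' @param gsd GSD in cm/px.
#' @param mode input mode, see [select_input_mode()].
#' @param layout an [orchard_layout()].
#' @return a list with `per_seed` (test metrics per training seed),
#'   `median_R2`, `median_RAD`, `n_train_samples` and the scene's attainable
#'   `target_r2` calibration.
#' @export
replicate_yield <- function(scene_seed = 7L, train_seeds = 1:10, gsd = 2.13,
                            mode = "input6", layout = orchard_layout()) {
  scene <- simulate_scene(layout, gsd = gsd, seed = scene_seed)
  imgs <- lapply(vegetation_indices(),
                 function(nm) compute_index(scene$bands, nm))
  names(imgs) <- vegetation_indices()
  grays <- lapply(imgs, `[[`, "gray")
  seg <- segment_scene(imgs$NG, cloud = scene$cloud,
                       row_spacing_m = layout$row_spacing,
                       plant_spacing_m = layout$plant_spacing)
  morph <- morph_table(seg)
  feats <- extract_features(grays, seg, morph)
  matched <- match_regions(seg, scene$trees)
  x_all <- select_input_mode(feats, mode)
  keep <- which(!is.na(matched) & !scene$trees$is_dead[matched] &
                  stats::complete.cases(x_all))
  x <- x_all[keep, , drop = FALSE]
  y <- scene$trees$yield_kg[matched[keep]]
  per_seed <- lapply(train_seeds, function(sd) {
    model <- bpann_train(x, y, seed = sd)
    yhat <- predict(model, x[model$split$test, , drop = FALSE])
    m <- regression_metrics(y[model$split$test], yhat)
    data.frame(train_seed = sd, a = model$a, h = model$h, R2 = m$R2,
               RMSE = m$RMSE, RAD_avg = m$RAD_avg)
  })
  per_seed <- do.call(rbind, per_seed)
  list(per_seed = per_seed,
       median_R2 = stats::median(per_seed$R2),
       median_RAD = stats::median(per_seed$RAD_avg),
       n_train_samples = length(keep),
       scene_noise_sd = attr(scene$trees, "noise_sd"))
}
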