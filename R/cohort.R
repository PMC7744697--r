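# Synthetic cohort generation. Emulates the study design the pipeline
# expects -- 28 subjects, 23 ROIs of 25 voxels inside a whole-brain map, 32
# videos of Likert ratings with missingness -- with a controllable latent
# coupling between one designated driver variable per ROI and that ROI's
# activity pattern, so parameter recovery and null calibration are testable
# with known ground truth.

#' Configuration of a synthetic cohort
#'
#' Each individual-difference variable (three intrinsic traits, six rating
#' measures) gets a standardized latent score per subject. An ROI listed in
#' `drivers` couples to its driver's latent t via
#' `pattern = template + gamma * t * direction + noise` with `direction` a
#' unit vector, so the expected squared pair distance is
#' `gamma^2 (t_i - t_j)^2 + 2 sigma^2 V` (see [expected_pair_distance()]).
#' Whole-brain contrast maps embed the ROI patterns at their peak locations
#' inside a background noise field, so whole-brain similarity is genuinely
#' correlated with ROI similarity.
#'
#' @param n_subjects cohort size (default 28).
#' @param n_videos rated videos per subject (default 32).
#' @param roi_table ROI peak table (default: the packaged 23-ROI table).
#' @param mask_radius Manhattan mask radius in voxels (default 2, 25 voxels).
#' @param voxel_size isotropic voxel size in mm (default 5).
#' @param wholebrain_min_voxels minimum whole-brain grid size; the grid is a
#'   bounding box of the ROI masks, padded to at least this many voxels
#'   (default 4000).
#' @param trait_effects named gammas (>= 0) for `MJrisk`, `SSscore`,
#'   `Compliance` (defaults 0 = null cohort).
#' @param rating_effects named gammas for `pMSV`, `pAS`, `AdLike`, `pos`,
#'   `neg`, `ThVal` (defaults 0).
#' @param drivers named character vector mapping ROI id (as character) to the
#'   variable whose latent drives that ROI's pattern; `NULL` = no coupling.
#' @param noise_sd voxel noise sd sigma (> 0, default 1).
#' @param missing_rate completely-at-random missingness rate for ratings, in
#'   [0, 0.2] (default 0.05).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 28L, n_videos = 32L,
                             roi_table = NULL, mask_radius = 2L,
                             voxel_size = 5, wholebrain_min_voxels = 4000L,
                             trait_effects = c(MJrisk = 0, SSscore = 0,
                                               Compliance = 0),
                             rating_effects = c(pMSV = 0, pAS = 0,
                                                AdLike = 0, pos = 0, neg = 0,
                                                ThVal = 0),
                             drivers = NULL, noise_sd = 1,
                             missing_rate = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 2, n_videos >= 3, mask_radius >= 0, noise_sd > 0,
            missing_rate >= 0, missing_rate <= 0.2)
  te <- c(MJrisk = 0, SSscore = 0, Compliance = 0)
  te[names(trait_effects)] <- trait_effects
  re <- c(pMSV = 0, pAS = 0, AdLike = 0, pos = 0, neg = 0, ThVal = 0)
  re[names(rating_effects)] <- rating_effects
  if (any(c(te, re) < 0)) stop("effect sizes must be >= 0")
  if (!is.null(drivers)) {
    bad <- setdiff(drivers, c(names(te), names(re)))
    if (length(bad))
      stop("unknown driver variable(s): ", paste(bad, collapse = ", "))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_videos = as.integer(n_videos), roi_table = roi_table,
                 mask_radius = as.integer(mask_radius),
                 voxel_size = voxel_size,
                 wholebrain_min_voxels = as.integer(wholebrain_min_voxels),
                 trait_effects = te, rating_effects = re, drivers = drivers,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Expected pairwise pattern distance under the generative model
#'
#' Closed-form oracle for generator validation: with a unit signal direction,
#' the expected squared Euclidean distance between two subjects' V-voxel
#' patterns is `gamma^2 (t_i - t_j)^2 + 2 sigma^2 V`; this returns its square
#' root.
#'
#' @param gamma effect size (>= 0).
#' @param t_i,t_j the two subjects' latent scores.
#' @param sigma voxel noise sd (>= 0).
#' @param V voxels per pattern (>= 1).
#' @return expected root squared distance.
#' @export
expected_pair_distance <- function(gamma, t_i, t_j, sigma, V) {
  stopifnot(sigma >= 0, V >= 1)
  sqrt(gamma^2 * (t_i - t_j)^2 + 2 * sigma^2 * V)
}

# clip-and-round to a Likert range
likert <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# exact standardization (mean 0, sd 1)
standardize <- function(x) as.numeric(scale(x))

#' Generate a synthetic cohort
#'
#' Draws latent scores, voxel maps (contrast, two control conditions,
#' structural segmentation), item-level intrinsic responses and long-format
#' video ratings according to a [synthetic_config()]. Deterministic given the
#' config seed. Ground truth (latents, effects, drivers) is stored alongside.
#'
#' @param config a [synthetic_config()].
#' @return object of class `idsim_cohort`: list with `config`, `grid`,
#'   `roi_table`, `masks`, `maps` (named list of subjects x voxels matrices),
#'   `intrinsic_items`, `ratings`, `subjects`, `ground_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  subjects <- sprintf("s%02d", seq_len(n))
  roi_table <- config$roi_table
  if (is.null(roi_table)) roi_table <- idsim_roi_table()
  r <- config$mask_radius
  s <- config$voxel_size

  # grid: bounding box of the ROI masks, padded along x to the minimum size
  centers <- as.matrix(roi_table[, c("x", "y", "z")])
  origin <- apply(centers, 2, min) - s * (r + 1)
  dims <- floor((apply(centers, 2, max) - origin) / s) + r + 2
  while (prod(dims) < config$wholebrain_min_voxels) dims[1] <- dims[1] + 1L
  grid <- grid_spec(dims, s, origin_mm = origin)

  masks <- lapply(seq_len(nrow(roi_table)), function(k)
    build_roi_mask(mm_to_voxel(centers[k, ], grid), r))
  names(masks) <- as.character(roi_table$id)
  V <- nrow(masks[[1]])
  nvox <- prod(grid$dims)

  # standardized latent score per variable
  vars <- c(names(config$trait_effects), names(config$rating_effects))
  latents <- vapply(vars, function(v) standardize(rnorm(n)), numeric(n))
  rownames(latents) <- subjects
  effects <- c(config$trait_effects, config$rating_effects)

  # whole-brain maps: template + subject noise
  mk_map <- function() {
    template <- rnorm(nvox)
    t(template + matrix(0, nvox, n)) +
      matrix(rnorm(n * nvox, sd = config$noise_sd), n, nvox)
  }
  maps <- list(contrast_msvxas = mk_map(),
               control_scrambled = mk_map(),
               control_blank = mk_map())
  struct_template <- runif(nvox, 0.2, 0.8)
  maps$structural_seg <- pmin(pmax(
    t(struct_template + matrix(0, nvox, n)) +
      matrix(rnorm(n * nvox, sd = 0.05), n, nvox), 0), 1)
  for (m in names(maps)) rownames(maps[[m]]) <- subjects

  # plant driver couplings into the contrast map at the ROI voxels
  for (id in names(masks)) {
    lin <- mask_linear_index(masks[[id]], grid)
    patt <- t(rnorm(V) + matrix(0, V, n)) +                       # template
      matrix(rnorm(n * V, sd = config$noise_sd), n, V)            # noise
    v <- if (!is.null(config$drivers)) config$drivers[id] else NA
    if (!is.na(v)) {
      dir <- rnorm(V)
      dir <- dir / sqrt(sum(dir^2))
      patt <- patt + effects[[v]] * latents[, v] %o% dir
    }
    maps$contrast_msvxas[, lin] <- patt
  }

  # intrinsic item responses recovering the latent trait under scale scoring
  scales <- default_scales()
  intrinsic_items <- data.frame(subject_id = subjects,
                                stringsAsFactors = FALSE)
  for (sc in scales) {
    t_v <- latents[, sc$name]
    for (it in sc$item_ids)
      intrinsic_items[[it]] <- likert(3 + 0.8 * t_v + rnorm(n, sd = 0.6),
                                      sc$response_range[1],
                                      sc$response_range[2])
  }

  # per-video ratings from subject latents + video effects + item noise
  nv <- config$n_videos
  rate_block <- function(measure, item, center, slope, latent, lo, hi) {
    video_fx <- rnorm(nv, sd = 0.6)
    val <- likert(rep(center + slope * latent, each = nv) +
                    rep(video_fx, times = n) + rnorm(n * nv, sd = 0.6),
                  lo, hi)
    # no subject may have a constant profile (degenerate for correlation)
    val <- matrix(val, nv, n)
    flat <- apply(val, 2, function(x) all(x == x[1]))
    if (any(flat))
      val[1, flat] <- ifelse(val[1, flat] < hi, val[1, flat] + 1,
                             val[1, flat] - 1)
    data.frame(subject_id = rep(subjects, each = nv),
               video_id = rep(seq_len(nv), times = n),
               measure = measure, item = item, value = as.numeric(val),
               stringsAsFactors = FALSE)
  }
  blocks <- list(
    rate_block("pMSV", NA, 4, 0.8, latents[, "pMSV"], 1, 7),
    rate_block("pAS", NA, 4, 0.8, latents[, "pAS"], 1, 7),
    rate_block("AdLike", NA, 4, 0.8, latents[, "AdLike"], 1, 7),
    rate_block("valence", "stay", 4, 0.7, latents[, "ThVal"], 1, 7),
    rate_block("valence", "try", 4, -0.7, latents[, "ThVal"], 1, 7))
  for (it in emotion_items_pos)
    blocks[[length(blocks) + 1L]] <-
      rate_block("emotion", it, 2.5, 0.5, latents[, "pos"], 1, 4)
  for (it in emotion_items_neg)
    blocks[[length(blocks) + 1L]] <-
      rate_block("emotion", it, 2.5, 0.5, latents[, "neg"], 1, 4)
  for (it in emotion_items_other)
    blocks[[length(blocks) + 1L]] <-
      rate_block("emotion", it, 2.5, 0, rep(0, n), 1, 4)
  ratings <- do.call(rbind, blocks)

  # completely-at-random missingness; keep >= 1 response per question column
  if (config$missing_rate > 0) {
    miss <- runif(nrow(ratings)) < config$missing_rate
    key <- interaction(ratings$measure, ratings$item, ratings$video_id,
                       drop = TRUE)
    for (lv in levels(key)) {
      idx <- which(key == lv)
      if (all(miss[idx])) miss[idx[1]] <- FALSE
    }
    ratings$value[miss] <- NA_real_
  }

  structure(list(
    config = config, grid = grid, roi_table = roi_table, masks = masks,
    maps = maps, subjects = subjects, intrinsic_items = intrinsic_items,
    ratings = ratings,
    ground_truth = list(latents = latents, effects = as.list(effects),
                        drivers = as.list(config$drivers),
                        noise_sd = config$noise_sd,
                        voxels_per_roi = V, seed = config$seed)
  ), class = "idsim_cohort")
}

#' @export
print.idsim_cohort <- function(x, ...) {
  cat("<idsim_cohort> ", length(x$subjects), " subjects, ",
      nrow(x$roi_table), " ROIs (", nrow(x$masks[[1]]),
      " voxels each), grid ", paste(x$grid$dims, collapse = "x"),
      ", ", x$config$n_videos, " videos\n", sep = "")
  drv <- x$ground_truth$drivers
  if (length(drv))
    cat("  planted drivers:",
        paste(sprintf("ROI %s <- %s", names(drv), unlist(drv)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write and read a cohort fixture
#'
#' `write_fixture()` emits a directory of plain-text files (grid and ground
#' truth as JSON, maps as one TSV per map kind with subjects in rows, ROI
#' table as TSV, measures and ratings as CSV with empty cells for missing).
#' `read_fixture()` reconstructs the cohort; with full-precision values the
#' round trip is exact.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param digits significant digits for map values (default 15, i.e.
#'   lossless; the packaged miniature fixture uses 4).
#' @return `write_fixture()` returns `dir` invisibly; `read_fixture()`
#'   returns an `idsim_cohort`.
#' @export
write_fixture <- function(cohort, dir, digits = 15) {
  stopifnot(inherits(cohort, "idsim_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  cfg <- cohort$config
  jsonlite::write_json(
    list(dims = cohort$grid$dims, voxel_size = cohort$grid$voxel_size,
         affine = as.numeric(t(cohort$grid$affine)),
         mask_radius = cfg$mask_radius, n_videos = cfg$n_videos,
         seed = cfg$seed, noise_sd = cfg$noise_sd,
         missing_rate = cfg$missing_rate),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  write.table(cohort$roi_table, file.path(dir, "roi_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (kind in names(cohort$maps)) {
    m <- signif(cohort$maps[[kind]], digits)
    df <- data.frame(subject_id = rownames(cohort$maps[[kind]]), m,
                     check.names = FALSE)
    colnames(df) <- c("subject_id", paste0("v", seq_len(ncol(m))))
    write.table(df, file.path(dir, paste0("maps_", kind, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.csv(cohort$intrinsic_items, file.path(dir, "intrinsic_items.csv"),
            row.names = FALSE, na = "")
  write.csv(cohort$ratings, file.path(dir, "ratings.csv"),
            row.names = FALSE, na = "")
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(latents = as.data.frame(gt$latents), effects = gt$effects,
         drivers = gt$drivers, noise_sd = gt$noise_sd,
         voxels_per_roi = gt$voxels_per_roi, seed = gt$seed,
         subjects = cohort$subjects),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "grid.json"),
                              simplifyVector = TRUE)
  grid <- grid_spec(meta$dims, meta$voxel_size,
                    affine = matrix(meta$affine, 3L, 4L, byrow = TRUE))
  roi_table <- idsim_roi_table(file.path(dir, "roi_table.tsv"))
  kinds <- c("contrast_msvxas", "control_scrambled", "control_blank",
             "structural_seg")
  maps <- lapply(kinds, function(kind) {
    df <- read.delim(file.path(dir, paste0("maps_", kind, ".tsv")))
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    dimnames(m)[[2]] <- NULL
    m
  })
  names(maps) <- kinds
  subjects <- rownames(maps[[1]])
  masks <- lapply(seq_len(nrow(roi_table)), function(k)
    build_roi_mask(mm_to_voxel(as.numeric(roi_table[k, c("x", "y", "z")]),
                               grid), meta$mask_radius))
  names(masks) <- as.character(roi_table$id)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  latents <- as.matrix(gt$latents)
  rownames(latents) <- gt$subjects
  ratings <- read.csv(file.path(dir, "ratings.csv"),
                      colClasses = c(subject_id = "character",
                                     item = "character"))
  ratings$item[ratings$item == ""] <- NA_character_
  cfg <- synthetic_config(
    n_subjects = length(subjects), n_videos = meta$n_videos,
    roi_table = roi_table, mask_radius = meta$mask_radius,
    voxel_size = grid$voxel_size[1],
    wholebrain_min_voxels = prod(grid$dims),
    trait_effects = unlist(gt$effects[c("MJrisk", "SSscore", "Compliance")]),
    rating_effects = unlist(gt$effects[c("pMSV", "pAS", "AdLike", "pos",
                                         "neg", "ThVal")]),
    drivers = if (length(gt$drivers)) unlist(gt$drivers) else NULL,
    noise_sd = meta$noise_sd, missing_rate = meta$missing_rate,
    seed = meta$seed)
  structure(list(
    config = cfg, grid = grid, roi_table = roi_table, masks = masks,
    maps = maps, subjects = subjects,
    intrinsic_items = read.csv(file.path(dir, "intrinsic_items.csv"),
                               colClasses = c(subject_id = "character")),
    ratings = ratings,
    ground_truth = list(latents = latents, effects = gt$effects,
                        drivers = gt$drivers, noise_sd = gt$noise_sd,
                        voxels_per_roi = gt$voxels_per_roi, seed = gt$seed)
  ), class = "idsim_cohort")
}

#' The packaged miniature cohort fixture
#'
#' An 8-subject, 4-ROI, 12-video synthetic cohort (one planted driver:
#' SSscore in ROI 6) stored as plain text under `inst/extdata/mini_cohort`,
#' small enough for fast smoke tests of the full pipeline.
#'
#' @return an `idsim_cohort`.
#' @export
mini_cohort <- function() {
  read_fixture(system.file("extdata", "mini_cohort", package = "idsim",
                           mustWork = TRUE))
}
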