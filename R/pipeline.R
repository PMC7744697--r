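# Full-pipeline orchestration: measures -> similarities -> per-ROI
# round-robin regression -> permutation p* -> clustering and profiling, with
# CSV/JSON outputs. Operates on an `idsim_cohort` (synthetic or read from a
# fixture directory laid out as by write_fixture()).

# shared (non-ROI-specific) regressor groups: whole-brain neural controls,
# intrinsic |difference| measures, and three-way rating-profile measures
build_shared_groups <- function(cohort, measures, index) {
  wb_names <- c(wb_msvxas = "contrast_msvxas", wb_struct = "structural_seg",
                wb_scrambled = "control_scrambled", wb_blank = "control_blank")
  wb_builder <- function(data, idx)
    lapply(names(data), function(nm) pattern_similarity(data[[nm]], idx, nm))
  wb_data <- lapply(wb_names, function(kind) cohort$maps[[kind]])
  names(wb_data) <- names(wb_names)
  groups <- list(regressor_group(
    "wbFxnSim", wb_builder(wb_data, index), category = "neural",
    data = wb_data, builder = wb_builder))

  # builder factories: each closure must capture its own measure name (a
  # bare loop variable would be shared across iterations)
  make_uni_builder <- function(nm) {
    force(nm)
    function(data, idx) list(univariate_similarity(data, idx, nm))
  }
  for (tr in c("MJrisk", "SSscore", "Compliance")) {
    b <- make_uni_builder(tr)
    scores <- measures$traits[[tr]]
    groups[[length(groups) + 1L]] <- regressor_group(
      tr, b(scores, index), category = "intrinsic",
      data = scores, builder = b)
  }

  make_profile_builder <- function(nm) {
    force(nm)
    function(data, idx)
      lapply(rating_profile_similarity(data, idx, nm), orient)
  }
  for (ms in c("pMSV", "pAS", "AdLike", "pos", "neg", "ThVal")) {
    b <- make_profile_builder(ms)
    prof <- measures$profiles[[ms]]
    groups[[length(groups) + 1L]] <- regressor_group(
      ms, b(prof, index), category = "psa",
      data = prof, builder = b)
  }
  groups
}

# ROI-level neural control group: structural and control-condition patterns
# restricted to this ROI's mask
build_roineur_group <- function(cohort, roi_id, index) {
  lin <- mask_linear_index(cohort$masks[[as.character(roi_id)]], cohort$grid)
  data <- list(roi_struct = cohort$maps$structural_seg[, lin, drop = FALSE],
               roi_scrambled = cohort$maps$control_scrambled[, lin,
                                                             drop = FALSE],
               roi_blank = cohort$maps$control_blank[, lin, drop = FALSE])
  builder <- function(d, idx)
    lapply(names(d), function(nm) pattern_similarity(d[[nm]], idx, nm))
  regressor_group("ROIneur", builder(data, index), category = "neural",
                  data = data, builder = builder)
}

#' Validate a cohort's inputs
#'
#' Machine-readable consistency checks: ROI table schema, one shared grid
#' across all maps, subject-id alignment across maps, intrinsic items and
#' ratings, Likert bounds, and ROI masks lying inside the grid. Findings are
#' returned, not raised.
#'
#' @param cohort an `idsim_cohort` (from [generate_cohort()] or
#'   [read_fixture()]).
#' @return data.frame `check, pass, detail`.
#' @export
validate_inputs <- function(cohort) {
  checks <- list()
  note <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)

  sch <- tryCatch({
    stopifnot(all(c("id", "source", "x", "y", "z", "label") %in%
                    names(cohort$roi_table)))
    TRUE
  }, error = function(e) FALSE)
  note("roi_table_schema", sch,
       if (!sch) paste("missing column(s):",
                       paste(setdiff(c("id", "source", "x", "y", "z",
                                       "label"), names(cohort$roi_table)),
                             collapse = ", ")) else "")

  nvox <- prod(cohort$grid$dims)
  gridok <- all(vapply(cohort$maps, ncol, integer(1)) == nvox)
  note("grid_consistency", gridok,
       if (!gridok) "map voxel count differs from grid" else "")

  subj <- cohort$subjects
  map_subj <- lapply(cohort$maps, rownames)
  align <- all(vapply(map_subj, identical, logical(1), y = subj)) &&
    identical(as.character(cohort$intrinsic_items$subject_id), subj) &&
    all(unique(cohort$ratings$subject_id) %in% subj)
  note("subject_alignment", align,
       if (!align) "subject ids differ across inputs" else "")

  bounds_ok <- TRUE
  bad_measure <- character()
  for (m in unique(cohort$ratings$measure)) {
    b <- rating_bounds[[m]]
    v <- cohort$ratings$value[cohort$ratings$measure == m]
    if (is.null(b) || any(!is.na(v) & (v < b[1] | v > b[2]))) {
      bounds_ok <- FALSE
      bad_measure <- c(bad_measure, m)
    }
  }
  note("likert_bounds", bounds_ok,
       if (!bounds_ok) paste("out-of-bounds or unknown measure:",
                             paste(bad_measure, collapse = ", ")) else "")

  mask_ok <- tryCatch({
    for (mk in cohort$masks) mask_linear_index(mk, cohort$grid)
    TRUE
  }, error = function(e) FALSE)
  note("masks_in_grid", mask_ok,
       if (!mask_ok) "at least one ROI mask exceeds the grid" else "")

  do.call(rbind, checks)
}

#' Run the full similarity analysis
#'
#' Executes measure preparation, similarity construction, per-ROI round-robin
#' regression, subject-level permutation p*, Ward clustering of z(p*)
#' profiles, MAP cluster profiles, the category summary, and the
#' strength-of-evidence table. Deterministic given `seed`.
#'
#' @param cohort an `idsim_cohort`.
#' @param B permutations per p* test (default 199).
#' @param seed integer seed driving all resampling.
#' @param K clusters for Ward profiling (`"auto"` = silhouette-maximising
#'   K in 2..10).
#' @param method resampling method, see [pstar_test()].
#' @param outdir optional directory; when given, all result tables are
#'   written as CSV plus a JSON provenance block.
#' @return object of class `idsim_report`: list with `fits` (per-ROI
#'   [round_robin()] objects), `pstar` (long table), `clusters`,
#'   `cluster_profiles`, `category_summary`, `strength`, `settings`.
#' @export
run_analysis <- function(cohort, B = 199L, seed = 1L, K = "auto",
                         method = "subject_permutation", outdir = NULL) {
  stopifnot(inherits(cohort, "idsim_cohort"))
  val <- validate_inputs(cohort)
  if (!all(val$pass))
    stop("input validation failed: ",
         paste(val$check[!val$pass], collapse = ", "))
  set.seed(seed)

  measures <- prepare_measures(cohort$intrinsic_items, cohort$ratings)
  index <- build_pair_index(length(cohort$subjects))
  shared <- build_shared_groups(cohort, measures, index)

  roi_ids <- as.character(cohort$roi_table$id)
  fits <- lapply(roi_ids, function(id) {
    lin <- mask_linear_index(cohort$masks[[id]], cohort$grid)
    response <- pattern_similarity(
      cohort$maps$contrast_msvxas[, lin, drop = FALSE], index,
      paste0("roi", id, "_msvxas"))
    groups <- c(list(build_roineur_group(cohort, id, index)), shared)
    round_robin(response, groups, index, roi_id = id)
  })
  names(fits) <- roi_ids

  ptab <- pstar_all(fits, B = B, method = method, seed = seed)

  # ROI x group matrices of z(p*) and delta R^2 for profiling
  gset <- unique(ptab$group)
  zmat <- matrix(NA_real_, length(roi_ids), length(gset),
                 dimnames = list(roi_ids, gset))
  dmat <- zmat
  zmat[cbind(ptab$roi_id, ptab$group)] <- ptab$z
  dmat[cbind(ptab$roi_id, ptab$group)] <- ptab$delta_r2

  clusters <- ward_cluster(zmat, K = K)
  profiles <- cluster_profiles(clusters, dmat)
  categ <- category_summary(fits, cohort$roi_table)
  strength <- strength_table(ptab)

  report <- structure(list(
    fits = fits, pstar = ptab, clusters = clusters,
    cluster_profiles = profiles, category_summary = categ,
    strength = strength,
    settings = list(B = B, seed = seed, K = clusters$K, method = method,
                    n_subjects = length(cohort$subjects),
                    n_rois = length(roi_ids),
                    package_version =
                      as.character(utils::packageVersion("idsim")))
  ), class = "idsim_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.idsim_report <- function(x, ...) {
  cat("idsim analysis report\n")
  cat(sprintf("  %d ROIs x %d subjects, B = %d (%s), K = %d clusters\n",
              x$settings$n_rois, x$settings$n_subjects, x$settings$B,
              x$settings$method, x$settings$K))
  r2 <- vapply(x$fits, function(f) f$r2_full, numeric(1))
  cat(sprintf("  full-model R^2: %.3f - %.3f (median %.3f)\n",
              min(r2), max(r2), median(r2)))
  cat("  high strength-of-evidence hits (p* < 0.05):",
      nrow(x$strength), "\n")
  cat("  category summary (mean proportion of variance):\n")
  print(x$category_summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.idsim_report <- function(x, ...) {
  pr <- x$cluster_profiles
  clusters <- sort(unique(pr$cluster))
  groups <- unique(pr$group)
  m <- matrix(0, length(groups), length(clusters),
              dimnames = list(groups, paste0("cluster ", clusters)))
  m[cbind(pr$group, paste0("cluster ", pr$cluster))] <- 100 * pr$map_mean
  graphics::barplot(m, beside = TRUE, las = 1,
                    legend.text = groups,
                    args.legend = list(cex = 0.6, x = "topright"),
                    ylab = "MAP unique variance (%)", ...)
  invisible(x)
}

#' Write all report tables to a directory
#'
#' @param report an `idsim_report`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  rr <- do.call(rbind, lapply(report$fits, function(f)
    data.frame(roi_id = f$roi_id, group = names(f$delta_r2),
               delta_r2_pct = 100 * unname(f$delta_r2),
               stringsAsFactors = FALSE)))
  write.csv(rr, file.path(outdir, "roundrobin.csv"), row.names = FALSE)
  fitdf <- do.call(rbind, lapply(report$fits, function(f)
    data.frame(roi_id = f$roi_id, r2_full = f$r2_full, shared = f$shared,
               residual = f$residual, stringsAsFactors = FALSE)))
  write.csv(fitdf, file.path(outdir, "model_fit.csv"), row.names = FALSE)
  write.csv(report$pstar, file.path(outdir, "pstar.csv"), row.names = FALSE)
  write.csv(data.frame(roi_id = names(report$clusters$assignment),
                       cluster = unname(report$clusters$assignment)),
            file.path(outdir, "clusters.csv"), row.names = FALSE)
  write.csv(report$cluster_profiles,
            file.path(outdir, "cluster_profiles.csv"), row.names = FALSE)
  write.csv(report$category_summary,
            file.path(outdir, "category_summary.csv"), row.names = FALSE)
  write.csv(report$strength, file.path(outdir, "strength_table.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$settings, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
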