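# shared fixtures and independent oracles, built in code

# compact synthetic ROI table: small bounding box -> fast map generation
compact_roi_table <- function(n_rois = 2L) {
  data.frame(id = seq_len(n_rois),
             source = rep(c("a_priori", "exploratory", "confirmatory"),
                          length.out = n_rois),
             x = seq(-8, by = 16, length.out = n_rois), y = 0, z = 0,
             label = paste0("synth_", seq_len(n_rois)))
}

# small cohort for fast pipeline-level tests
make_test_cohort <- function(n_subjects = 12L, n_videos = 10L, n_rois = 2L,
                             drivers = NULL, trait_effects = c(SSscore = 0),
                             rating_effects = c(pMSV = 0), seed = 1L,
                             missing_rate = 0.05) {
  generate_cohort(synthetic_config(
    n_subjects = n_subjects, n_videos = n_videos,
    roi_table = compact_roi_table(n_rois), wholebrain_min_voxels = 200L,
    drivers = drivers, trait_effects = trait_effects,
    rating_effects = rating_effects, missing_rate = missing_rate,
    seed = seed))
}

# independent R^2 oracle: normal equations solved with a pseudo-inverse,
# no shared code with the package's QR/SVD path
r2_normal_equations <- function(X, y) {
  b <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
  1 - sum((y - X %*% b)^2) / sum((y - mean(y))^2)
}

# brute-force Manhattan ball by triple loop, independent of build_roi_mask
manhattan_ball_bruteforce <- function(center, radius) {
  out <- NULL
  for (dx in -radius:radius)
    for (dy in -radius:radius)
      for (dz in -radius:radius)
        if (abs(dx) + abs(dy) + abs(dz) <= radius)
          out <- rbind(out, center + c(dx, dy, dz))
  out
}

# random design + response on a pair structure, for regression properties
random_instance <- function(n_pairs, n_cols, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n_pairs * n_cols), n_pairs))
  y <- rnorm(n_pairs)
  list(X = X, y = y)
}
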