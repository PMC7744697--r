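test_that("cohort generation is deterministic and shape-correct", {
  cfg <- synthetic_config(n_subjects = 9, n_videos = 8,
                          roi_table = compact_roi_table(3),
                          wholebrain_min_voxels = 200, seed = 81)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$maps, b$maps)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$intrinsic_items, b$intrinsic_items)

  expect_equal(length(a$subjects), 9)
  expect_equal(length(a$masks), 3)
  expect_true(all(vapply(a$masks, nrow, integer(1)) == 25))
  expect_gte(prod(a$grid$dims), 200)
  expect_equal(dim(a$maps$contrast_msvxas), c(9, prod(a$grid$dims)))
  expect_equal(sort(unique(a$ratings$video_id)), 1:8)
})

test_that("generated ratings respect Likert bounds before missingness", {
  co <- make_test_cohort(n_subjects = 10, seed = 82, missing_rate = 0)
  for (m in unique(co$ratings$measure)) {
    b <- idsim:::rating_bounds[[m]]
    v <- co$ratings$value[co$ratings$measure == m]
    expect_true(all(v >= b[1] & v <= b[2]))
    expect_true(all(v == round(v)))
  }
  items <- co$intrinsic_items[, -1]
  expect_true(all(items >= 1 & items <= 5))
})

test_that("missingness is injected at about the configured rate, never whole columns", {
  co <- make_test_cohort(n_subjects = 20, seed = 83, missing_rate = 0.1)
  rate <- mean(is.na(co$ratings$value))
  expect_gt(rate, 0.06); expect_lt(rate, 0.14)
  key <- interaction(co$ratings$measure, co$ratings$item,
                     co$ratings$video_id, drop = TRUE)
  all_missing <- tapply(co$ratings$value, key, function(v) all(is.na(v)))
  expect_false(any(all_missing))
})

test_that("expected pair distance matches its closed form and simulation", {
  expect_equal(expected_pair_distance(0, 0, 0, 1, 25), sqrt(50))
  expect_equal(expected_pair_distance(2, 1.3, 1.3, 1.7, 40),
               sqrt(2 * 1.7^2 * 40))   # no signal term when t_i = t_j
  expect_equal(expected_pair_distance(2, 1, -1, 1, 25),
               sqrt(4 * 4 + 50))

  # Monte-Carlo check: mean squared distance over simulated pairs
  set.seed(84)
  gamma <- 2; t_i <- 0.8; t_j <- -0.5; sigma <- 1; V <- 25
  nrep <- 10000
  dir <- rnorm(V); dir <- dir / sqrt(sum(dir^2))
  d2 <- replicate(nrep, {
    pi_ <- gamma * t_i * dir + rnorm(V, sd = sigma)
    pj <- gamma * t_j * dir + rnorm(V, sd = sigma)
    sum((pi_ - pj)^2)
  })
  expected <- expected_pair_distance(gamma, t_i, t_j, sigma, V)^2
  mc_se <- sd(d2) / sqrt(nrep)
  expect_lt(abs(mean(d2) - expected), 3 * mc_se)
})

test_that("planted couplings raise the driver's pattern-trait association", {
  co <- make_test_cohort(n_subjects = 16, seed = 85,
                         drivers = c("1" = "SSscore"),
                         trait_effects = c(SSscore = 5))
  idx <- build_pair_index(16)
  lin <- idsim:::mask_linear_index(co$masks[["1"]], co$grid)
  d_pat <- pattern_similarity(co$maps$contrast_msvxas[, lin], idx)$values
  t_lat <- co$ground_truth$latents[, "SSscore"]
  d_tr <- abs(t_lat[idx$i] - t_lat[idx$j])
  expect_gt(cor(d_pat, d_tr), 0.5)
  # an undriven ROI shows no such association
  lin2 <- idsim:::mask_linear_index(co$masks[["2"]], co$grid)
  d_pat2 <- pattern_similarity(co$maps$contrast_msvxas[, lin2], idx)$values
  expect_lt(abs(cor(d_pat2, d_tr)), 0.3)
})

test_that("driver mean delta R^2 is non-decreasing in effect size", {
  # common random numbers: same seed, increasing gamma
  d_at <- vapply(c(0, 0.5, 1, 2, 5), function(g) {
    co <- make_test_cohort(n_subjects = 12, seed = 86,
                           drivers = c("1" = "SSscore"),
                           trait_effects = c(SSscore = g))
    m <- prepare_measures(co$intrinsic_items, co$ratings)
    idx <- build_pair_index(12)
    lin <- idsim:::mask_linear_index(co$masks[["1"]], co$grid)
    resp <- pattern_similarity(co$maps$contrast_msvxas[, lin], idx, "y")
    fit <- round_robin(resp, idsim:::build_shared_groups(co, m, idx), idx)
    unname(fit$delta_r2["SSscore"])
  }, numeric(1))
  expect_gt(d_at[5], d_at[1])
  expect_gt(d_at[4], d_at[1])
})

test_that("fixtures round-trip exactly at full precision", {
  co <- make_test_cohort(n_subjects = 6, n_videos = 6, seed = 87)
  dir <- file.path(tempdir(), "fixture_rt")
  write_fixture(co, dir)
  back <- read_fixture(dir)
  expect_equal(back$maps, co$maps)
  expect_equal(back$grid$dims, co$grid$dims)
  expect_equal(back$grid$affine, co$grid$affine)
  expect_equal(back$intrinsic_items, co$intrinsic_items)
  expect_equal(back$ratings$value, co$ratings$value)
  expect_equal(back$masks, co$masks)
  expect_equal(back$ground_truth$latents, co$ground_truth$latents)
  unlink(dir, recursive = TRUE)
})

test_that("ground truth records exactly the configured nonzero effects", {
  co <- make_test_cohort(n_subjects = 6, seed = 88,
                         drivers = c("1" = "SSscore"),
                         trait_effects = c(SSscore = 3),
                         rating_effects = c(pMSV = 1))
  eff <- unlist(co$ground_truth$effects)
  expect_setequal(names(eff[eff > 0]), c("pMSV", "SSscore"))
  expect_equal(unname(eff["SSscore"]), 3)
  expect_equal(co$ground_truth$drivers, list(`1` = "SSscore"))
  expect_error(synthetic_config(drivers = c("1" = "nosuch")),
               "unknown driver")
})

test_that("the packaged miniature fixture loads and validates", {
  co <- mini_cohort()
  expect_s3_class(co, "idsim_cohort")
  expect_equal(length(co$subjects), 8)
  expect_equal(nrow(co$roi_table), 4)
  expect_true(all(validate_inputs(co)$pass))
  expect_equal(unlist(co$ground_truth$drivers), c(`6` = "SSscore"))
})
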