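test_that("p* follows the add-one permutation formula", {
  expect_equal(pstar(0.5, rep(0.1, 99)), 0.01)     # (0+1)/100
  expect_equal(pstar(0.5, rep(0.9, 99)), 1)        # all null >= observed
  expect_equal(pstar(0.5, c(rep(0.9, 4), rep(0.1, 15))), 0.25)  # 5/20
  expect_error(pstar(0.5, rep(0.1, 5)), "19")
})

test_that("the probit transform is finite, anchored and monotone", {
  expect_equal(z_transform(0.5, 199), 0)
  expect_equal(z_transform(0.025, 999), qnorm(0.975))
  expect_equal(z_transform(0.025, 999), 1.95996, tolerance = 1e-5)
  # clipping keeps extreme p* finite
  expect_true(is.finite(z_transform(1, 199)))
  expect_true(is.finite(z_transform(1 / 200, 199)))
  p <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(z_transform(p, 199)) < 0))
})

test_that("null resampling recomputes similarity from permuted subject data", {
  idx <- build_pair_index(9)
  set.seed(61)
  scores <- rnorm(9)
  builder <- function(data, i) list(univariate_similarity(data, i, "m"))
  g <- regressor_group("m", builder(scores, idx), category = "intrinsic",
                       data = scores, builder = builder)
  # identity permutation reproduces the observed column
  expect_equal(null_resample(g, 1:9, idx)[[1]]$values, g$members[[1]]$values)
  # permuted column equals |d| of the permuted score vector (direct oracle)
  perm <- sample(9)
  out <- null_resample(g, perm, idx)[[1]]$values
  oracle <- mapply(function(i, j) abs(scores[perm[i]] - scores[perm[j]]),
                   idx$i, idx$j)
  expect_equal(out, unname(oracle))
  # the multiset of pair values is preserved under permutation
  expect_equal(sort(out), sort(g$members[[1]]$values))
  g_nodata <- regressor_group("m", builder(scores, idx))
  expect_error(null_resample(g_nodata, perm, idx), "no underlying")
})

test_that("indexing at induced pairs equals recomputation from permuted data", {
  # the equivalence pstar_test relies on, checked for a multivariate
  # pattern group and a rating-profile group
  n <- 8
  idx <- build_pair_index(n)
  set.seed(66)
  pat <- matrix(rnorm(n * 30), n)
  pb <- function(d, i) list(pattern_similarity(d, i, "p"))
  gp <- regressor_group("p", pb(pat, idx), category = "neural",
                        data = pat, builder = pb)
  prof <- matrix(sample(1:7, n * 6, replace = TRUE) + rnorm(n * 6, sd = 0.1),
                 n)
  rb <- function(d, i) lapply(rating_profile_similarity(d, i, "q"), orient)
  gq <- regressor_group("q", rb(prof, idx), category = "psa",
                        data = prof, builder = rb)
  pos <- matrix(0L, n, n)
  pos[cbind(idx$i, idx$j)] <- seq_len(nrow(idx))
  pos[cbind(idx$j, idx$i)] <- seq_len(nrow(idx))
  for (rep_i in 1:5) {
    perm <- sample(n)
    map <- pos[cbind(perm[idx$i], perm[idx$j])]
    rebuilt_p <- null_resample(gp, perm, idx)[[1]]$values
    expect_equal(gp$members[[1]]$values[map], rebuilt_p)
    rebuilt_q <- null_resample(gq, perm, idx)
    for (m in seq_along(gq$members))
      expect_equal(gq$members[[m]]$values[map], rebuilt_q[[m]]$values)
  }
})

test_that("identity permutation gives delta R^2 equal to the observed value", {
  co <- make_test_cohort(n_subjects = 10, seed = 62)
  rep0 <- run_analysis(co, B = 29, seed = 5, K = 2)
  fit <- rep0$fits[["1"]]
  gnames <- vapply(fit$groups, function(g) g$name, character(1))
  g <- fit$groups[[match("SSscore", gnames)]]
  members <- null_resample(g, seq_along(co$subjects), fit$index)
  expect_equal(members[[1]]$values, g$members[[1]]$values)
})

test_that("p* is reproducible under a fixed seed and varies without one", {
  co <- make_test_cohort(n_subjects = 10, seed = 63)
  rep1 <- run_analysis(co, B = 49, seed = 9, K = 2)
  rep2 <- run_analysis(co, B = 49, seed = 9, K = 2)
  expect_identical(rep1$pstar, rep2$pstar)
  fit <- rep1$fits[["1"]]
  a <- pstar_test(fit, "MJrisk", B = 49, seed = 123)
  b <- pstar_test(fit, "MJrisk", B = 49, seed = 123)
  expect_identical(a$null_draws, b$null_draws)
  expect_equal(a$pstar, b$pstar)
  expect_gte(a$pstar, 1 / 50)
  expect_true(is.finite(a$z))
})

test_that("a strong planted effect is detected while inert groups are not", {
  ps_focal <- ps_inert <- numeric(5)
  for (k in 1:5) {
    co <- make_test_cohort(n_subjects = 14, seed = 640 + k,
                           drivers = c("1" = "SSscore"),
                           trait_effects = c(SSscore = 5))
    m <- prepare_measures(co$intrinsic_items, co$ratings)
    idx <- build_pair_index(14)
    lin <- idsim:::mask_linear_index(co$masks[["1"]], co$grid)
    resp <- pattern_similarity(co$maps$contrast_msvxas[, lin], idx, "y")
    groups <- c(list(idsim:::build_roineur_group(co, "1", idx)),
                idsim:::build_shared_groups(co, m, idx))
    fit <- round_robin(resp, groups, idx, roi_id = "1")
    ps_focal[k] <- pstar_test(fit, "SSscore", B = 99, seed = k)$pstar
    ps_inert[k] <- pstar_test(fit, "MJrisk", B = 99, seed = k)$pstar
  }
  expect_lt(median(ps_focal), 0.05)
  expect_gt(median(ps_inert), 0.2)
})

test_that("the bootstrap sensitivity mode runs and drops self-pairs", {
  co <- make_test_cohort(n_subjects = 12, seed = 65)
  m <- prepare_measures(co$intrinsic_items, co$ratings)
  idx <- build_pair_index(12)
  lin <- idsim:::mask_linear_index(co$masks[["1"]], co$grid)
  resp <- pattern_similarity(co$maps$contrast_msvxas[, lin], idx, "y")
  groups <- idsim:::build_shared_groups(co, m, idx)
  fit <- round_robin(resp, groups, idx, roi_id = "1")
  res <- pstar_test(fit, "MJrisk", B = 39, method = "subject_bootstrap",
                    seed = 7)
  expect_s3_class(res, "pstar_result")
  expect_gte(res$pstar, 1 / 40)
  expect_lte(res$pstar, 1)
})
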