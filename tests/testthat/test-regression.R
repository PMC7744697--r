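make_groups <- function(vectors_by_group, idx, category = "intrinsic") {
  lapply(names(vectors_by_group), function(g)
    regressor_group(g, vectors_by_group[[g]], category = category))
}

test_that("the design matrix codes pairs, z-scores columns, maps groups", {
  idx <- build_pair_index(3)
  set.seed(51)
  v <- univariate_similarity(rnorm(3), idx, "m1")
  d <- assemble_design(make_groups(list(g1 = list(v)), idx), idx)
  # subject-intercept coding: pair (1,2) row has ones in columns 1 and 2
  sub <- d$X[, d$col_group == "subints"]
  expect_equal(unname(sub[1, ]), c(1, 1, 0))
  expect_equal(ncol(d$X), 1 + 1 + 3)
  # each subject belongs to n-1 pairs
  expect_true(all(colSums(sub) == 2))
  expect_equal(mean(d$X[, "m1"]), 0)
  expect_equal(sd(d$X[, "m1"]), 1)

  idx8 <- build_pair_index(8)
  d8 <- assemble_design(make_groups(list(
    g1 = list(univariate_similarity(rnorm(8), idx8, "a")),
    g2 = list(univariate_similarity(rnorm(8), idx8, "b"),
              univariate_similarity(rnorm(8), idx8, "c"))), idx8), idx8)
  expect_equal(ncol(d8$X), 1 + 3 + 8)
  expect_true(all(colSums(d8$X[, d8$col_group == "subints"]) == 7))

  cv <- similarity_vector("const", rep(2, nrow(idx)), idx)
  expect_error(assemble_design(make_groups(list(g = list(cv)), idx), idx),
               "constant.*const")
})

test_that("R^2 matches a hand normal-equations oracle and handles rank deficiency", {
  # 6-pair toy instance
  idx <- build_pair_index(4)
  set.seed(52)
  x <- rnorm(4)
  v <- univariate_similarity(x, idx, "x")
  y <- 0.5 + 2 * v$values + rnorm(6, sd = 0.1)
  d <- assemble_design(make_groups(list(g = list(v)), idx), idx,
                       subject_intercepts = FALSE)
  f <- fit_r2(d, y)
  expect_equal(f$r2, r2_normal_equations(d$X, y), tolerance = 1e-10)

  # response equal to a regressor column -> R^2 = 1
  expect_equal(fit_r2(d, d$X[, "x"])$r2, 1, tolerance = 1e-12)
  # response orthogonal to the centered column space -> R^2 = 0
  y_orth <- residuals(lm(rnorm(6) ~ d$X))
  expect_equal(fit_r2(matrix(d$X[, "x"]), y_orth)$r2, 0, tolerance = 1e-10)

  # global intercept + subint block is rank deficient; R^2 still well defined
  dfull <- assemble_design(make_groups(list(g = list(v)), idx), idx)
  expect_equal(fit_r2(dfull, y)$r2, r2_normal_equations(dfull$X, y),
               tolerance = 1e-10)
  expect_error(fit_r2(d, y[1:3]), "match")
})

test_that("round-robin delta R^2 satisfies nesting, identity, and orthogonality", {
  # two exactly orthogonal centered regressors
  idx <- build_pair_index(5)
  set.seed(53)
  a <- rnorm(10); a <- a - mean(a)
  b <- residuals(lm(rnorm(10) ~ a)); b <- b / sd(b)
  va <- similarity_vector("a", a, idx)
  vb <- similarity_vector("b", b, idx)
  y <- rnorm(10)
  fit <- round_robin(similarity_vector("y", y, idx),
                     make_groups(list(A = list(va), B = list(vb)), idx),
                     idx, subject_intercepts = FALSE)
  r2_a_alone <- fit_r2(cbind(1, scale(a)), y)$r2
  expect_equal(unname(fit$delta_r2["A"]), r2_a_alone, tolerance = 1e-10)
  expect_equal(fit$shared, 0, tolerance = 1e-10)

  # the same vector in two groups: all credit moves to shared
  fit2 <- round_robin(similarity_vector("y", y, idx),
                      list(regressor_group("G1", list(va)),
                           regressor_group("G2", list(
                             similarity_vector("a2", a, idx)))),
                      idx, subject_intercepts = FALSE)
  expect_equal(unname(fit2$delta_r2[c("G1", "G2")]), c(0, 0),
               tolerance = 1e-10)
  expect_equal(fit2$shared, r2_a_alone, tolerance = 1e-10)

  # single group without intercepts: delta R^2 = R^2_full, shared = 0
  fit3 <- round_robin(similarity_vector("y", y, idx),
                      make_groups(list(A = list(va)), idx), idx,
                      subject_intercepts = FALSE)
  expect_equal(unname(fit3$delta_r2["A"]), fit3$r2_full, tolerance = 1e-10)
  expect_equal(fit3$shared, 0, tolerance = 1e-10)
})

test_that("random instances agree with the normal-equations oracle", {
  for (k in 1:20) {
    inst <- random_instance(n_pairs = sample(6:10, 1),
                            n_cols = sample(1:3, 1), seed = 530 + k)
    expect_equal(fit_r2(inst$X, inst$y)$r2,
                 r2_normal_equations(inst$X, inst$y), tolerance = 1e-10)
  }
})

test_that("delta R^2 is invariant to affine transforms of any single regressor", {
  idx <- build_pair_index(7)
  set.seed(54)
  mk <- function(x, nm) similarity_vector(nm, x, idx)
  x1 <- rnorm(21); x2 <- rnorm(21); y <- mk(abs(rnorm(21)), "y")
  # suppressWarnings: random instances may legitimately show suppression
  base <- suppressWarnings(
    round_robin(y, make_groups(list(A = list(mk(x1, "a")),
                                    B = list(mk(x2, "b"))), idx), idx))
  shifted <- suppressWarnings(
    round_robin(y, make_groups(list(A = list(mk(5 - 2.5 * x1, "a")),
                                    B = list(mk(x2, "b"))), idx), idx))
  expect_equal(base$delta_r2, shifted$delta_r2, tolerance = 1e-10)
  expect_equal(base$r2_full, shifted$r2_full, tolerance = 1e-10)
  # orientation flip (1 - r) is such an affine map
  vsim <- similarity_vector("r", runif(21, -1, 1), idx,
                            orientation = "similarity")
  f1 <- suppressWarnings(
    round_robin(y, make_groups(list(A = list(vsim),
                                    B = list(mk(x2, "b"))), idx), idx))
  f2 <- suppressWarnings(
    round_robin(y, make_groups(list(A = list(orient(vsim)),
                                    B = list(mk(x2, "b"))), idx), idx))
  expect_equal(f1$delta_r2, f2$delta_r2, tolerance = 1e-10)
})

test_that("partition identity and non-negativity hold on fitted cohorts", {
  co <- make_test_cohort(n_subjects = 10, seed = 55)
  rep <- run_analysis(co, B = 29, seed = 2, K = 2)
  for (f in rep$fits) {
    expect_true(all(f$delta_r2 >= 0))
    expect_equal(sum(f$delta_r2) + f$shared, f$r2_full, tolerance = 1e-10)
    expect_equal(sum(f$delta_r2) + f$shared + f$residual, 1,
                 tolerance = 1e-10)
  }
})

test_that("category summary averages summed unique variance by ROI source", {
  idx <- build_pair_index(6)
  set.seed(56)
  mk <- function(nm) similarity_vector(nm, abs(rnorm(15)), idx)
  fits <- lapply(c("1", "2"), function(id)
    suppressWarnings(round_robin(mk("y"), list(
      regressor_group("neuralA", list(mk("na")), category = "neural"),
      regressor_group("intrA", list(mk("ia")), category = "intrinsic"),
      regressor_group("psaA", list(mk("pa")), category = "psa")),
      idx, roi_id = id)))
  names(fits) <- c("1", "2")
  rt <- data.frame(id = 1:2, source = c("a_priori", "confirmatory"),
                   x = 0, y = 0, z = 0, label = c("r1", "r2"))
  cs <- category_summary(fits, rt)
  # one ROI per source: the summary equals that ROI's own sums
  f1 <- fits[["1"]]
  expect_equal(cs$neural[cs$source == "a_priori"],
               unname(f1$delta_r2["neuralA"]))
  expect_equal(cs$intrinsic[cs$source == "a_priori"],
               unname(f1$delta_r2["intrA"]))
  expect_equal(cs$shared[cs$source == "a_priori"], f1$shared)
  expect_error(category_summary(fits["1"], rt), "missing round-robin")
})
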