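# Round-robin distance-matrix regression. Each ROI's pairwise pattern
# distance is regressed on every explanatory similarity vector plus
# participant-specific intercepts; each named group of regressors is credited
# with the drop in R^2 when its columns are removed (its unique variance),
# and whatever the full model explains beyond the sum of unique contributions
# is reported as shared variance.

#' Group similarity vectors into a credited regressor block
#'
#' A group is the unit of credit assignment in the round-robin: a
#' single-measure group owns one |difference| column, a rating measure owns
#' its three profile-similarity columns, the whole-brain control owns all
#' whole-brain distance columns, and so on.
#'
#' `data` and `builder` (optional) describe how the group's columns derive
#' from per-subject data, which is what the permutation null resamples:
#' `builder(data, index)` must return the member vectors, and `data` must be
#' indexable by subject (a vector, a subjects-in-rows matrix, or a list of
#' such matrices).
#'
#' @param name unique group name.
#' @param members list of [similarity_vector()]s (at least one).
#' @param category one of `"neural"`, `"intrinsic"`, `"psa"`, `"control"`,
#'   `"unexplained"`.
#' @param data per-subject underlying data for resampling (optional).
#' @param builder function(data, index) -> list of similarity vectors
#'   (optional, required for permutation inference on this group).
#' @return object of class `regressor_group`.
#' @export
regressor_group <- function(name, members,
                            category = c("neural", "intrinsic", "psa",
                                         "control", "unexplained"),
                            data = NULL, builder = NULL) {
  category <- match.arg(category)
  if (inherits(members, "similarity_vector")) members <- list(members)
  if (!length(members)) stop("group '", name, "' must have >= 1 member")
  ok <- vapply(members, inherits, logical(1), what = "similarity_vector")
  if (!all(ok)) stop("all members must be similarity_vector objects")
  ns <- vapply(members, function(m) m$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("members of group '", name, "' disagree on subject count")
  structure(list(name = name, members = members, category = category,
                 data = data, builder = builder),
            class = "regressor_group")
}

# subject-permuted copy of a group's underlying data
permute_subject_data <- function(data, perm) {
  if (is.list(data) && !is.data.frame(data))
    lapply(data, permute_subject_data, perm = perm)
  else if (is.matrix(data)) data[perm, , drop = FALSE]
  else data[perm]
}

#' Assemble the design matrix for one ROI model
#'
#' Columns are: a global intercept, all group member columns (z-scored), and
#' optionally one 0/1 intercept column per participant with exactly two ones
#' per row (the two members of the pair). The participant block's row sums
#' are constant (= 2), so it is collinear with the global intercept; R^2
#' depends only on the column space and the fitter tolerates the rank
#' deficiency.
#'
#' @param groups list of [regressor_group()]s with unique names.
#' @param index a [build_pair_index()].
#' @param subject_intercepts add the participant-intercept block as a group
#'   named `"subints"` (default `TRUE`).
#' @return list with `X` (matrix), `col_group` (character per column;
#'   `"(intercept)"` for the global intercept), and `groups` (names incl.
#'   `"subints"` when present).
#' @export
assemble_design <- function(groups, index, subject_intercepts = TRUE) {
  nm <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("group names must be unique")
  n <- n_subjects(index)
  np <- nrow(index)

  cols <- list(`(intercept)` = rep(1, np))
  col_group <- "(intercept)"
  for (g in groups) {
    for (m in g$members) {
      if (length(m$values) != np)
        stop("member '", m$name, "' is not on the model's pair index")
      s <- sd(m$values)
      if (s == 0)
        stop("constant (zero-variance) regressor: ", m$name)
      cols[[m$name]] <- (m$values - mean(m$values)) / s
      col_group <- c(col_group, g$name)
    }
  }
  if (subject_intercepts) {
    sub <- matrix(0, np, n, dimnames = list(NULL, paste0("subint_",
                                                         seq_len(n))))
    sub[cbind(seq_len(np), index$i)] <- 1
    sub[cbind(seq_len(np), index$j)] <- 1
    for (k in seq_len(n)) cols[[colnames(sub)[k]]] <- sub[, k]
    col_group <- c(col_group, rep("subints", n))
  }
  X <- do.call(cbind, cols)
  list(X = X, col_group = col_group,
       groups = c(nm, if (subject_intercepts) "subints"))
}

# R^2 of a least-squares fit; rank deficiency handled by pivoted QR (R^2
# depends only on the column space, so any solution from the span works)
r2_qr <- function(X, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("response has zero variance")
  qf <- qr(X)
  1 - sum(qr.resid(qf, y)^2) / sst
}

#' Least-squares fit of a pairwise-similarity design
#'
#' @param design as returned by [assemble_design()] (or a plain numeric
#'   matrix).
#' @param response a [similarity_vector()] or numeric vector.
#' @return list with `r2` (R^2 about the response mean) and `coefficients`
#'   (minimum-norm least-squares solution, so rank deficiency from the
#'   intercept/participant-block collinearity is resolved deterministically).
#' @export
fit_r2 <- function(design, response) {
  X <- if (is.list(design)) design$X else as.matrix(design)
  y <- if (inherits(response, "similarity_vector")) response$values
       else as.numeric(response)
  if (nrow(X) != length(y)) stop("design rows must match response length")
  if (nrow(X) < 2L) stop("need at least 2 rows to fit")
  # minimum-norm solution via SVD
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  beta <- drop(beta)
  names(beta) <- colnames(X)
  list(r2 = r2_qr(X, y), coefficients = beta)
}

#' Round-robin unique-variance regression
#'
#' Fits the full model of a pairwise distance response on all regressor
#' groups (plus participant intercepts), then refits once per group with that
#' group's columns removed. Each group's unique variance is
#' `delta R^2 = R^2_full - R^2_without_group` (non-negative by model
#' nesting); `shared = R^2_full - sum(delta R^2)` is the variance explained
#' only jointly (it can be negative under suppression, which is reported with
#' a warning, never clamped).
#'
#' @param response a [similarity_vector()] (the ROI's pattern distances).
#' @param groups list of [regressor_group()]s.
#' @param index a [build_pair_index()].
#' @param subject_intercepts include the participant-intercept block
#'   (default `TRUE`).
#' @param roi_id optional ROI identifier carried into reports.
#' @return object of class `round_robin` with elements `r2_full`,
#'   `delta_r2` (named, proportions), `shared`, `residual`, `coefficients`,
#'   `roi_id`, plus the design internals used by [pstar_test()].
#' @seealso [pstar_test()], [category_summary()]
#' @export
round_robin <- function(response, groups, index, subject_intercepts = TRUE,
                        roi_id = NULL) {
  if (inherits(groups, "regressor_group")) groups <- list(groups)
  design <- assemble_design(groups, index, subject_intercepts)
  y <- if (inherits(response, "similarity_vector")) response$values
       else as.numeric(response)
  full <- fit_r2(design, y)

  credited <- design$groups
  delta <- vapply(credited, function(g) {
    keep <- design$col_group != g
    full$r2 - r2_qr(design$X[, keep, drop = FALSE], y)
  }, numeric(1))
  # nesting guarantees non-negativity; clip numerical dust
  if (any(delta < -1e-8))
    warning("delta R^2 below numerical tolerance: ",
            paste(credited[delta < -1e-8], collapse = ", "))
  delta <- pmax(delta, 0)
  shared <- full$r2 - sum(delta)
  if (shared < -1e-8)
    warning(sprintf("negative shared variance (%.4g): suppression present",
                    shared))
  structure(list(
    roi_id = roi_id,
    r2_full = full$r2,
    delta_r2 = delta,
    shared = shared,
    residual = 1 - full$r2,
    coefficients = full$coefficients,
    groups = groups,
    index = index,
    response = y,
    design = design,
    subject_intercepts = subject_intercepts
  ), class = "round_robin")
}

#' @export
print.round_robin <- function(x, digits = 3, ...) {
  cat("Round-robin distance regression",
      if (!is.null(x$roi_id)) paste0(" (ROI ", x$roi_id, ")"), "\n", sep = "")
  cat(sprintf("  full-model R^2: %.*f   shared: %.*f   residual: %.*f\n",
              digits, x$r2_full, digits, x$shared, digits, x$residual))
  cat("  unique variance (% of total):\n")
  d <- sort(100 * x$delta_r2, decreasing = TRUE)
  for (g in names(d)) cat(sprintf("    %-12s %6.2f%%\n", g, d[g]))
  invisible(x)
}

#' @export
summary.round_robin <- function(object, ...) {
  df <- data.frame(group = names(object$delta_r2),
                   category = vapply(object$groups, function(g) g$category,
                                     character(1))[
                     match(names(object$delta_r2),
                           vapply(object$groups, function(g) g$name,
                                  character(1)))],
                   delta_r2 = unname(object$delta_r2),
                   delta_r2_pct = unname(100 * object$delta_r2),
                   stringsAsFactors = FALSE)
  df$category[df$group == "subints"] <- "unexplained"
  structure(list(roi_id = object$roi_id, table = df,
                 r2_full = object$r2_full, shared = object$shared,
                 residual = object$residual),
            class = "summary.round_robin")
}

#' @export
print.summary.round_robin <- function(x, ...) {
  cat("Round-robin variance partition",
      if (!is.null(x$roi_id)) paste0(" (ROI ", x$roi_id, ")"), "\n", sep = "")
  print(x$table, row.names = FALSE)
  cat(sprintf("R^2 full = %.4f, shared = %.4f, residual = %.4f\n",
              x$r2_full, x$shared, x$residual))
  invisible(x)
}

#' @export
coef.round_robin <- function(object, ...) object$coefficients

#' @export
plot.round_robin <- function(x, ...) {
  d <- sort(100 * x$delta_r2)
  graphics::barplot(d, horiz = TRUE, las = 1,
                    xlab = "unique variance (% of total)",
                    main = if (!is.null(x$roi_id))
                      paste("ROI", x$roi_id) else "round-robin fit", ...)
  invisible(x)
}

#' Average unique variance by measure category and ROI source
#'
#' For each ROI, sums unshrunken delta R^2 over the groups of each measure
#' category (neural, intrinsic, psa; shared, participant-intercept and
#' residual variance reported as-is), then averages over the ROIs of each
#' source partition (a priori / exploratory / confirmatory).
#'
#' @param fits named list of [round_robin()] fits, names = ROI ids.
#' @param roi_table data.frame with `id` and `source` columns.
#' @return data.frame, one row per ROI source, columns per category (as
#'   proportions of variance).
#' @export
category_summary <- function(fits, roi_table) {
  ids <- as.character(roi_table$id)
  absent <- setdiff(ids, names(fits))
  if (length(absent))
    stop("missing round-robin result for ROI(s): ",
         paste(absent, collapse = ", "))
  per_roi <- do.call(rbind, lapply(ids, function(id) {
    f <- fits[[id]]
    cat_of <- vapply(f$groups, function(g) g$category, character(1))
    names(cat_of) <- vapply(f$groups, function(g) g$name, character(1))
    d <- f$delta_r2
    data.frame(
      id = id,
      neural = sum(d[names(d) %in% names(cat_of)[cat_of == "neural"]]),
      intrinsic = sum(d[names(d) %in% names(cat_of)[cat_of == "intrinsic"]]),
      psa = sum(d[names(d) %in% names(cat_of)[cat_of == "psa"]]),
      unexplained = if ("subints" %in% names(d)) d[["subints"]] else 0,
      shared = f$shared,
      residual = f$residual,
      stringsAsFactors = FALSE)
  }))
  per_roi$source <- roi_table$source[match(per_roi$id, ids)]
  agg <- aggregate(per_roi[c("neural", "intrinsic", "psa", "unexplained",
                             "shared", "residual")],
                   by = list(source = per_roi$source), FUN = mean)
  agg[order(match(agg$source, c("a_priori", "exploratory", "confirmatory"))), ]
}
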