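# Strength-of-evidence inference for unique variance. Pairwise similarities
# are not independent observations: each of the n subjects contributes n-1
# pairs to every similarity vector, so row-level permutation of the design
# would be anti-conservative. The null here operates at the subject level:
# the focal group's underlying per-subject data are permuted (or resampled)
# and its similarity columns are re-computed from the permuted data, keeping
# the dyadic dependence structure of the regressor intact (Mantel-style).

#' Resample a regressor group's similarity columns under the null
#'
#' Applies a subject-level permutation to the group's underlying data and
#' rebuilds the group's similarity vectors from the permuted data. Pair
#' values are never shuffled independently.
#'
#' @param group a [regressor_group()] carrying `data` and `builder`.
#' @param perm integer permutation of `1:n` (subject labels).
#' @param index the model's [build_pair_index()].
#' @return list of [similarity_vector()]s (same shape as `group$members`).
#' @export
null_resample <- function(group, perm, index) {
  stopifnot(inherits(group, "regressor_group"))
  if (is.null(group$data) || is.null(group$builder))
    stop("group '", group$name,
         "' has no underlying subject data/builder for resampling")
  group$builder(permute_subject_data(group$data, perm), index)
}

#' Pseudo p-value of an observed statistic against null draws
#'
#' One-tailed, with the add-one correction that keeps p* in
#' `[1/(B+1), 1]`: `p* = (1 + #(null >= observed)) / (B + 1)`.
#'
#' @param observed observed delta R^2.
#' @param null_draws numeric vector of B null statistics.
#' @return p* in (0, 1].
#' @export
pstar <- function(observed, null_draws) {
  B <- length(null_draws)
  if (B < 19L) stop("need at least 19 null draws")
  (1 + sum(null_draws >= observed)) / (B + 1)
}

#' Probit transform of a p*-value
#'
#' `z = qnorm(1 - p*)` after clipping p* into `[1/(B+1), 1 - 1/(B+1)]` so the
#' result is always finite. Strictly decreasing in p*.
#'
#' @param pstar p*-value in (0, 1].
#' @param B number of resamples that produced it.
#' @return finite z score.
#' @export
z_transform <- function(pstar, B) {
  eps <- 1 / (B + 1)
  qnorm(1 - pmin(pmax(pstar, eps), 1 - eps))
}

#' Permutation p* for one group's unique variance
#'
#' Recomputes the focal group's delta R^2 under B subject-level permutations
#' of that group's underlying data. Because every similarity value is a
#' function of the unordered subject pair alone, the permuted columns are
#' obtained exactly by indexing the observed columns at the induced pairs
#' (equivalent to rebuilding them from permuted subject data; see
#' [null_resample()], which tests verify against this path). Only the focal
#' columns change between permutations, so the reduced model (full minus
#' focal) is fitted once; the full model is refitted per permutation.
#'
#' @param fit a [round_robin()] fit.
#' @param focal name of the focal group (the participant-intercept group is
#'   not testable this way, since permuting subject labels only permutes its
#'   columns; bootstrap mode additionally requires the group to carry
#'   data + builder).
#' @param B number of permutations (default 999, minimum 19).
#' @param method `"subject_permutation"` (default) or `"subject_bootstrap"`
#'   (resample subjects with replacement; a sensitivity mode).
#' @param seed optional integer seed for reproducibility.
#' @return object of class `pstar_result`: list with `roi_id`, `group`,
#'   `observed_delta_r2`, `pstar`, `z`, `B`, `method`, `seed`,
#'   `null_draws`.
#' @export
pstar_test <- function(fit, focal, B = 999L,
                       method = c("subject_permutation", "subject_bootstrap"),
                       seed = NULL) {
  stopifnot(inherits(fit, "round_robin"))
  method <- match.arg(method)
  B <- as.integer(B)
  if (B < 19L) stop("B must be >= 19")
  gnames <- vapply(fit$groups, function(g) g$name, character(1))
  if (!focal %in% gnames)
    stop("unknown focal group: ", focal)
  group <- fit$groups[[match(focal, gnames)]]
  if (!is.null(seed)) set.seed(seed)

  X <- fit$design$X
  y <- fit$response
  focal_cols <- fit$design$col_group == focal
  if (!any(focal_cols)) stop("focal group has no columns in the design")
  r2_reduced <- r2_qr(X[, !focal_cols, drop = FALSE], y)
  observed <- fit$r2_full - r2_reduced

  n <- n_subjects(fit$index)
  # pair-position lookup: a similarity value depends only on the unordered
  # subject pair, so under a label permutation the focal column equals the
  # observed column indexed at the induced pairs -- identical to rebuilding
  # it from the permuted subject data, without recomputing any distances
  np <- nrow(fit$index)
  pos <- matrix(0L, n, n)
  pos[cbind(fit$index$i, fit$index$j)] <- seq_len(np)
  pos[cbind(fit$index$j, fit$index$i)] <- seq_len(np)
  draws <- vapply(seq_len(B), function(b) {
    if (method == "subject_permutation") {
      perm <- sample.int(n)
      map <- pos[cbind(perm[fit$index$i], perm[fit$index$j])]
      Xb <- X
      for (m in group$members) {
        v <- m$values[map]
        s <- sd(v)
        Xb[, m$name] <- if (s == 0) 0 else (v - mean(v)) / s
      }
      r2_qr(Xb, y) - r2_reduced
    } else {
      # bootstrap: rebuild the columns from the resampled subject data and
      # drop self-pairs (same subject on both sides of the dyad)
      perm <- sample.int(n, replace = TRUE)
      members <- null_resample(group, perm, fit$index)
      Xb <- X
      for (m in members) {
        v <- m$values
        s <- sd(v)
        # a resampling-degenerate constant column carries no information
        Xb[, m$name] <- if (s == 0) 0 else (v - mean(v)) / s
      }
      keep <- perm[fit$index$i] != perm[fit$index$j]
      r2_qr(Xb[keep, , drop = FALSE], y[keep]) -
        r2_qr(Xb[keep, !focal_cols, drop = FALSE], y[keep])
    }
  }, numeric(1))

  p <- pstar(observed, draws)
  structure(list(roi_id = fit$roi_id, group = focal,
                 observed_delta_r2 = max(observed, 0),
                 pstar = p, z = z_transform(p, B), B = B, method = method,
                 seed = seed, null_draws = draws),
            class = "pstar_result")
}

#' @export
print.pstar_result <- function(x, ...) {
  cat(sprintf(
    "p* for group '%s'%s: delta R^2 = %.4f, p* = %.4f (z = %.3f, B = %d, %s)\n",
    x$group, if (!is.null(x$roi_id)) paste0(" in ROI ", x$roi_id) else "",
    x$observed_delta_r2, x$pstar, x$z, x$B, x$method))
  invisible(x)
}

#' Permutation p* for every resamplable group of every fit
#'
#' @param fits named list of [round_robin()] fits (names = ROI ids).
#' @param B permutations per test.
#' @param method see [pstar_test()].
#' @param seed integer; per-test seeds are derived deterministically from it.
#' @return data.frame `roi_id, group, delta_r2, delta_r2_pct, pstar, z, B,
#'   method`.
#' @export
pstar_all <- function(fits, B = 999L,
                      method = c("subject_permutation", "subject_bootstrap"),
                      seed = 1L) {
  method <- match.arg(method)
  rows <- list()
  k <- 0L
  for (id in names(fits)) {
    fit <- fits[[id]]
    for (g in fit$groups) {
      if (is.null(g$data) || is.null(g$builder)) next
      k <- k + 1L
      res <- pstar_test(fit, g$name, B = B, method = method,
                        seed = as.integer((as.double(seed) + 7919 * k) %%
                                            2147483647))
      rows[[k]] <- data.frame(
        roi_id = id, group = g$name, delta_r2 = res$observed_delta_r2,
        delta_r2_pct = 100 * res$observed_delta_r2, pstar = res$pstar,
        z = res$z, B = B, method = method, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
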