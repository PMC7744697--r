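# ROI profiling: regions are grouped by the similarity of their
# strength-of-evidence profiles (probit-transformed p* across variables,
# Ward's minimum-variance clustering), and each cluster's per-variable mean
# unique variance is summarised with a zero-centred normal-normal MAP
# estimate, so small or heterogeneous clusters are shrunk toward zero.

#' Ward clustering of ROI evidence profiles
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between ROI rows (z-transformed p* profiles).
#' Deterministic given the input. With `K = "auto"`, K is chosen to maximise
#' the mean silhouette width over K = 2..10.
#'
#' @param z_matrix numeric matrix, ROIs x variables, finite; rownames are
#'   ROI ids.
#' @param K fixed number of clusters (2..nrow) or `"auto"`.
#' @return object of class `cluster_solution`: list with `K`, `assignment`
#'   (named integer vector of labels 1..K), `hclust` (the linkage record),
#'   and `silhouette` (mean widths per candidate K when auto-selected).
#' @export
ward_cluster <- function(z_matrix, K = "auto") {
  z_matrix <- as.matrix(z_matrix)
  if (!all(is.finite(z_matrix))) stop("z matrix must be finite")
  n <- nrow(z_matrix)
  if (n < 2L) stop("need at least 2 ROIs to cluster")
  d <- dist(z_matrix, method = "euclidean")
  hc <- hclust(d, method = "ward.D2")
  sil <- NULL
  if (identical(K, "auto")) {
    ks <- 2:min(10L, n - 1L)
    sil <- vapply(ks, function(k) {
      a <- cutree(hc, k = k)
      mean(cluster::silhouette(a, d)[, "sil_width"])
    }, numeric(1))
    names(sil) <- ks
    K <- ks[which.max(sil)]
  } else {
    K <- as.integer(K)
    if (is.na(K) || K < 2L || K > n)
      stop("K must be in 2..", n, " or \"auto\"")
  }
  assignment <- cutree(hc, k = K)
  names(assignment) <- rownames(z_matrix)
  structure(list(K = K, assignment = assignment, hclust = hc,
                 silhouette = sil),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> K =", x$K, "\n")
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

#' Normal-normal MAP shrinkage of a cluster mean
#'
#' Observations x_1..x_n ~ N(mu, sigma2) with prior mu ~ N(0, tau2) give the
#' posterior mode `xbar * n * tau2 / (n * tau2 + sigma2)`. The estimate never
#' exceeds the raw mean in magnitude, keeps its sign, and shrinks less for
#' larger n or larger prior variance.
#'
#' @param values delta R^2 of one variable across a cluster's ROIs (n >= 1).
#' @param tau2 prior variance of cluster means (>= 0).
#' @param sigma2 within-cluster observation variance (>= 0; not both 0).
#' @return shrunken mean.
#' @export
map_shrink <- function(values, tau2, sigma2) {
  n <- length(values)
  if (n < 1L) stop("need at least one value")
  if (tau2 < 0 || sigma2 < 0 || (tau2 == 0 && sigma2 == 0))
    stop("tau2 and sigma2 must be >= 0 and not both 0")
  mean(values) * (n * tau2) / (n * tau2 + sigma2)
}

# method-of-moments hyperparameters for one variable across clusters:
# sigma2 = pooled within-cluster variance; tau2 = variance of raw cluster
# means minus its sampling contribution, floored at 0
shrinkage_params <- function(values_by_cluster) {
  ns <- lengths(values_by_cluster)
  ss <- sum(vapply(values_by_cluster, function(v)
    if (length(v) > 1L) sum((v - mean(v))^2) else 0, numeric(1)))
  df <- sum(pmax(ns - 1L, 0L))
  sigma2 <- if (df > 0) ss / df else 0
  means <- vapply(values_by_cluster, mean, numeric(1))
  tau2 <- if (length(means) > 1L)
    max(0, var(means) - sigma2 * mean(1 / ns)) else var(means)
  if (is.na(tau2)) tau2 <- 0
  if (tau2 == 0 && sigma2 == 0) tau2 <- .Machine$double.eps
  list(tau2 = tau2, sigma2 = sigma2)
}

#' Per-cluster variable profiles with MAP shrinkage
#'
#' For every variable group, computes each cluster's raw mean delta R^2 and
#' its MAP-shrunken counterpart. Unless overridden, sigma2 is the pooled
#' within-cluster variance of that variable across all clusters and tau2 is
#' the method-of-moments between-cluster variance (floored at 0).
#'
#' @param solution a [ward_cluster()] solution.
#' @param delta_matrix numeric matrix, ROIs x variables, of delta R^2
#'   (proportions); rownames must match the clustered ROIs.
#' @param tau2,sigma2 optional scalar overrides applied to every variable.
#' @return data.frame `cluster, group, n_rois, raw_mean, map_mean` (all
#'   delta R^2 columns as proportions).
#' @export
cluster_profiles <- function(solution, delta_matrix, tau2 = NULL,
                             sigma2 = NULL) {
  stopifnot(inherits(solution, "cluster_solution"))
  delta_matrix <- as.matrix(delta_matrix)
  a <- solution$assignment[rownames(delta_matrix)]
  if (anyNA(a)) stop("delta matrix rows must match clustered ROI ids")
  out <- list()
  for (v in colnames(delta_matrix)) {
    by_cl <- split(delta_matrix[, v], a)
    par <- shrinkage_params(by_cl)
    t2 <- if (is.null(tau2)) par$tau2 else tau2
    s2 <- if (is.null(sigma2)) par$sigma2 else sigma2
    out[[v]] <- data.frame(
      cluster = as.integer(names(by_cl)),
      group = v,
      n_rois = lengths(by_cl),
      raw_mean = vapply(by_cl, mean, numeric(1)),
      map_mean = vapply(by_cl, map_shrink, numeric(1), tau2 = t2,
                        sigma2 = s2),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$cluster, res$group), ]
}

#' High strength-of-evidence variables per ROI
#'
#' Lists, for each ROI, the variable groups whose p* falls below the
#' threshold (one-tailed, uncorrected), ordered by p* ascending. Intended for
#' dimensionality reduction, not confirmatory inference.
#'
#' @param pstar_table data.frame as returned by [pstar_all()].
#' @param threshold p* cutoff (default 0.05).
#' @return data.frame `roi_id, group, delta_r2_pct, pstar` (possibly
#'   zero-row).
#' @export
strength_table <- function(pstar_table, threshold = 0.05) {
  hits <- pstar_table[pstar_table$pstar < threshold,
                      c("roi_id", "group", "delta_r2_pct", "pstar")]
  hits <- hits[order(match(hits$roi_id, unique(pstar_table$roi_id)),
                     hits$pstar), ]
  rownames(hits) <- NULL
  hits
}
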