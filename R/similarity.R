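# Pairwise (dis)similarity construction. Every subject-level quantity is
# reduced to one value per unordered subject pair, in a fixed lexicographic
# pair order, with explicit orientation metadata (distance vs similarity).

#' Lexicographic index of unordered subject pairs
#'
#' @param n number of subjects (>= 2).
#' @return object of class `pair_index`: data.frame with columns `i`, `j`
#'   (1-based, i < j, lexicographic) and attribute `n`.
#' @export
build_pair_index <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) stop("`n` must be an integer >= 2")
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  structure(data.frame(i = i, j = j), n = n, class = c("pair_index",
                                                       "data.frame"))
}

n_subjects <- function(index) attr(index, "n")

#' Construct a similarity vector
#'
#' A named per-pair vector with orientation metadata. `orientation`
#' `"distance"` means larger values = more dissimilar; `"similarity"` the
#' reverse (e.g. a Pearson correlation).
#'
#' @param name regressor name.
#' @param values numeric, one finite value per pair of `index`.
#' @param index a [build_pair_index()].
#' @param orientation `"distance"` or `"similarity"`.
#' @param provenance free-text note on which measure/map produced the vector.
#' @return object of class `similarity_vector`.
#' @export
similarity_vector <- function(name, values, index,
                              orientation = c("distance", "similarity"),
                              provenance = name) {
  orientation <- match.arg(orientation)
  values <- as.numeric(values)
  if (length(values) != nrow(index))
    stop("`values` length must match the pair index (", nrow(index), ")")
  if (!all(is.finite(values)))
    stop("similarity vector '", name, "' has non-finite values")
  structure(list(name = name, orientation = orientation, values = values,
                 provenance = provenance, n = n_subjects(index)),
            class = "similarity_vector")
}

#' @export
print.similarity_vector <- function(x, ...) {
  cat("<similarity_vector> ", x$name, " (", x$orientation, "), ",
      length(x$values), " pairs, ", x$n, " subjects\n", sep = "")
  invisible(x)
}

#' Euclidean distance between two activity patterns
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
pattern_distance <- function(a, b) {
  if (length(a) != length(b)) stop("pattern length mismatch")
  sqrt(sum((a - b)^2))
}

#' Absolute-difference similarity of a univariate measure
#'
#' For each pair (i, j), `|score_i - score_j|`; orientation is distance.
#'
#' @param scores one value per subject, no missing values.
#' @param index a [build_pair_index()].
#' @param name regressor name.
#' @return a [similarity_vector()].
#' @export
univariate_similarity <- function(scores, index, name = "measure") {
  if (length(scores) != n_subjects(index))
    stop("`scores` must have one value per subject")
  if (anyNA(scores))
    stop("missing score in '", name, "': imputation must precede similarity")
  similarity_vector(name, abs(scores[index$i] - scores[index$j]), index,
                    orientation = "distance",
                    provenance = paste0("|d| of ", name))
}

#' Pairwise Euclidean distances between subject patterns
#'
#' @param patterns subjects x features numeric matrix (an ROI pattern or a
#'   vectorized whole-brain map per row).
#' @param index a [build_pair_index()].
#' @param name regressor name.
#' @return a [similarity_vector()] with distance orientation.
#' @export
pattern_similarity <- function(patterns, index, name = "pattern") {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != n_subjects(index))
    stop("`patterns` must have one row per subject")
  d <- as.matrix(dist(patterns, method = "euclidean"))
  similarity_vector(name, d[cbind(index$i, index$j)], index,
                    orientation = "distance",
                    provenance = paste0("euclidean distance of ", name))
}

#' Three-way similarity of a per-video rating profile
#'
#' A subject's evaluations over all videos form a profile; each pair of
#' subjects is compared three ways: Pearson correlation of the two profiles
#' (similarity orientation), absolute difference of the profile means, and
#' absolute difference of the profile standard deviations (n-1 denominator;
#' both distance orientation).
#'
#' @param ratings subjects x videos numeric matrix, complete (imputed).
#' @param index a [build_pair_index()].
#' @param name base name; components are suffixed `_r`, `_dmean`, `_dsd`.
#' @return named list of three [similarity_vector()]s.
#' @export
rating_profile_similarity <- function(ratings, index, name = "rating") {
  ratings <- as.matrix(ratings)
  n <- n_subjects(index)
  if (nrow(ratings) != n) stop("`ratings` must have one row per subject")
  if (ncol(ratings) < 3L) stop("need at least 3 videos per profile")
  if (anyNA(ratings)) stop("`ratings` must be complete (impute first)")
  sds <- apply(ratings, 1, sd)
  if (any(sds == 0)) {
    who <- rownames(ratings)[which(sds == 0)]
    if (is.null(who)) who <- which(sds == 0)
    stop("zero-variance profile in '", name, "' for subject(s): ",
         paste(who, collapse = ", "))
  }
  cm <- cor(t(ratings))
  means <- rowMeans(ratings)
  list(
    r = similarity_vector(paste0(name, "_r"), cm[cbind(index$i, index$j)],
                          index, orientation = "similarity",
                          provenance = paste0("pearson r of ", name,
                                              " profiles")),
    dmean = univariate_similarity(means, index, paste0(name, "_dmean")),
    dsd = univariate_similarity(sds, index, paste0(name, "_dsd"))
  )
}

#' Orient a similarity vector as a distance
#'
#' Correlation-type (similarity-oriented) vectors are mapped through
#' `x -> 1 - x`; distance-oriented vectors pass through unchanged. Delta
#' R-squared downstream is invariant to this affine transform; orientation is
#' normalised purely so signs of reported coefficients read consistently.
#'
#' @param vec a [similarity_vector()].
#' @return a distance-oriented [similarity_vector()].
#' @export
orient <- function(vec) {
  stopifnot(inherits(vec, "similarity_vector"))
  if (vec$orientation == "distance") return(vec)
  vec$values <- 1 - vec$values
  vec$orientation <- "distance"
  vec$provenance <- paste0("1 - (", vec$provenance, ")")
  vec
}

#' Serialize similarity vectors to a data frame
#'
#' @param vectors list of [similarity_vector()]s sharing one pair index.
#' @param index the shared [build_pair_index()].
#' @return long data.frame `pair_i, pair_j, name, value, orientation`.
#' @export
similarity_to_df <- function(vectors, index) {
  do.call(rbind, lapply(vectors, function(v)
    data.frame(pair_i = index$i, pair_j = index$j, name = v$name,
               value = v$values, orientation = v$orientation,
               stringsAsFactors = FALSE)))
}
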