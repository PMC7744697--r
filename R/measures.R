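# Scoring of intrinsic scales and per-video message evaluations.
#
# Three intrinsic self-report scales (marijuana-use risk, sensation seeking,
# task compliance) are summarised as item means. Per-video evaluations cover
# perceived message sensation value (pMSV), perceived argument strength (pAS),
# ad liking, 14 emotion items collapsed into positive/negative means, and a
# two-item thought-valence difference score. Missing responses are
# mean-imputed per question column across subjects before any similarity is
# computed.

#' Item names of the packaged measures
#'
#' @format Lists of character vectors naming emotion items. Three items enter
#'   the positive mean, seven the negative mean; the remaining four are
#'   carried through unused.
#' @name measure_items
#' @export
emotion_items_pos <- c("good", "happy", "inspired")

#' @rdname measure_items
#' @export
emotion_items_neg <- c("sad", "afraid", "bad", "guilty", "angry",
                       "disgusted", "sympathetic")

#' @rdname measure_items
#' @export
emotion_items_other <- c("surprised", "confused", "bored", "calm")

# Likert bounds per rating measure (item-level, before aggregation)
rating_bounds <- list(
  pMSV    = c(1, 7),
  pAS     = c(1, 7),
  AdLike  = c(1, 7),
  emotion = c(1, 4),
  valence = c(1, 7)
)

#' Define a multi-item scale
#'
#' @param name scale name.
#' @param item_ids character vector of item column names (non-empty).
#' @param response_range numeric(2), inclusive Likert bounds, min < max.
#' @return An object of class `scale_def`. Scales are summarised as the
#'   arithmetic mean of their items.
#' @export
scale_def <- function(name, item_ids, response_range) {
  if (!length(item_ids)) stop("`item_ids` must be non-empty")
  response_range <- as.numeric(response_range)
  if (length(response_range) != 2L || response_range[1] >= response_range[2])
    stop("`response_range` must be [min, max] with min < max")
  structure(list(name = name, item_ids = as.character(item_ids),
                 response_range = response_range),
            class = "scale_def")
}

#' Default intrinsic scale definitions
#'
#' Sensation seeking and compliance are four-item 1-5 scales with fixed item
#' sets; the marijuana-risk instrument is not reproduced in the package, so
#' its item count is configurable (default 5 items on 1-5).
#'
#' @param mjrisk_items number of marijuana-risk items.
#' @return named list of [scale_def()] objects.
#' @export
default_scales <- function(mjrisk_items = 5L) {
  list(
    MJrisk = scale_def("MJrisk", paste0("mj_", seq_len(mjrisk_items)), c(1, 5)),
    SSscore = scale_def("SSscore", paste0("ss_", 1:4), c(1, 5)),
    Compliance = scale_def("Compliance", paste0("comp_", 1:4), c(1, 5))
  )
}

#' Mean-impute a response column
#'
#' Missing entries are replaced by the mean of the non-missing entries of the
#' same scale/question column; non-missing entries are untouched, so the
#' column mean is preserved exactly.
#'
#' @param column numeric vector, `NA` = missing.
#' @param name column name used in error messages.
#' @return completed numeric vector.
#' @export
impute_missing <- function(column, name = deparse(substitute(column))) {
  ok <- !is.na(column)
  if (!any(ok)) stop("cannot impute: column '", name, "' is all-missing")
  column[!ok] <- mean(column[ok])
  column
}

#' Score a multi-item scale
#'
#' @param item_responses numeric vector of responses, one per item, already
#'   imputed (no `NA`).
#' @param scale a [scale_def()].
#' @return arithmetic mean of the items.
#' @export
score_scale <- function(item_responses, scale) {
  stopifnot(inherits(scale, "scale_def"))
  if (length(item_responses) != length(scale$item_ids))
    stop("expected ", length(scale$item_ids), " responses for scale ",
         scale$name)
  r <- scale$response_range
  if (any(is.na(item_responses)))
    stop("missing response in scale ", scale$name, " (impute first)")
  if (any(item_responses < r[1] | item_responses > r[2]))
    stop("response out of range [", r[1], ", ", r[2], "] for scale ",
         scale$name)
  mean(item_responses)
}

#' Collapse the 14 emotion items into positive and negative means
#'
#' @param ratings named numeric vector of the emotion items for one
#'   subject-video cell (names from [emotion_items_pos] etc.).
#' @return named numeric(2): `pos` (mean of the 3 positive items) and `neg`
#'   (mean of the 7 negative items). The four remaining items are unused.
#' @export
aggregate_emotions <- function(ratings) {
  need <- c(emotion_items_pos, emotion_items_neg)
  absent <- setdiff(need, names(ratings))
  if (length(absent))
    stop("missing emotion item(s): ", paste(absent, collapse = ", "))
  if (any(is.na(ratings[need])))
    stop("missing emotion response after imputation")
  c(pos = mean(ratings[emotion_items_pos]),
    neg = mean(ratings[emotion_items_neg]))
}

#' Thought-valence difference score
#'
#' Difference between two 7-point items: thoughts about staying away from
#' marijuana minus thoughts about wanting to try it, so higher values mean
#' message-consistent thoughts. Pairwise absolute-difference similarity is
#' invariant to flipping this sign convention.
#'
#' @param stay_item,try_item responses on 1-7.
#' @return `stay_item - try_item`.
#' @export
thought_valence <- function(stay_item, try_item) {
  if (any(c(stay_item, try_item) < 1) || any(c(stay_item, try_item) > 7) ||
      any(is.na(c(stay_item, try_item))))
    stop("thought-valence items must be in 1-7")
  stay_item - try_item
}

#' Score all subject measures
#'
#' Takes item-level intrinsic responses and a long rating table, applies
#' per-column mean imputation, and returns trait scores plus per-subject-by-
#' video matrices for the six evaluation measures. Imputation columns are
#' (scale, item) across subjects for intrinsic items and (measure, item,
#' video) across subjects for ratings.
#'
#' @param intrinsic_items data.frame with `subject_id` plus one column per
#'   scale item (see [default_scales()]); `NA` = missing.
#' @param ratings long data.frame with columns
#'   `subject_id, video_id, measure, item, value`; measure is one of
#'   `pMSV`, `pAS`, `AdLike`, `emotion`, `valence`; `item` is the emotion item
#'   name, `"stay"`/`"try"` for valence, and `NA` for single-item measures.
#' @param scales named list of [scale_def()]s (default [default_scales()]).
#' @return list with `traits` (data.frame subject_id, MJrisk, SSscore,
#'   Compliance) and `profiles` (named list of subject x video matrices for
#'   pMSV, pAS, AdLike, pos, neg, ThVal).
#' @export
prepare_measures <- function(intrinsic_items, ratings,
                             scales = default_scales()) {
  subjects <- as.character(intrinsic_items$subject_id)
  if (anyDuplicated(subjects)) stop("duplicate subject_id in intrinsic items")

  # intrinsic: impute per item column, then score
  traits <- data.frame(subject_id = subjects, stringsAsFactors = FALSE)
  for (sc in scales) {
    absent <- setdiff(sc$item_ids, names(intrinsic_items))
    if (length(absent))
      stop("intrinsic items missing column(s): ",
           paste(absent, collapse = ", "))
    block <- matrix(
      unlist(lapply(sc$item_ids, function(it)
        impute_missing(intrinsic_items[[it]], name = it))),
      nrow = length(subjects))
    traits[[sc$name]] <- apply(block, 1, score_scale, scale = sc)
  }

  # ratings: impute per (measure, item, video) column across subjects
  ratings$subject_id <- as.character(ratings$subject_id)
  bad_subj <- setdiff(unique(ratings$subject_id), subjects)
  if (length(bad_subj))
    stop("rating table has unknown subject(s): ",
         paste(bad_subj, collapse = ", "))
  ratings$item[is.na(ratings$item) | ratings$item == ""] <- "."
  for (m in unique(ratings$measure)) {
    b <- rating_bounds[[m]]
    if (is.null(b)) stop("unknown rating measure: ", m)
    v <- ratings$value[ratings$measure == m]
    if (any(!is.na(v) & (v < b[1] | v > b[2])))
      stop("rating values out of bounds [", b[1], ", ", b[2],
           "] for measure ", m)
  }
  key <- interaction(ratings$measure, ratings$item, ratings$video_id,
                     drop = TRUE)
  ratings$value <- as.numeric(
    unsplit(lapply(split(ratings$value, key), function(v) {
      if (all(is.na(v))) stop("cannot impute: all-missing rating column")
      impute_missing(v, name = "rating column")
    }), key))

  videos <- sort(unique(ratings$video_id))
  cell <- function(measure, item = ".") {
    sub <- ratings[ratings$measure == measure & ratings$item == item, ]
    m <- matrix(NA_real_, length(subjects), length(videos),
                dimnames = list(subjects, videos))
    m[cbind(match(sub$subject_id, subjects), match(sub$video_id, videos))] <-
      sub$value
    if (anyNA(m))
      stop("incomplete rating grid for measure ", measure,
           if (item != ".") paste0(" item ", item))
    m
  }

  profiles <- list(
    pMSV = cell("pMSV"), pAS = cell("pAS"), AdLike = cell("AdLike"))
  emo <- lapply(c(emotion_items_pos, emotion_items_neg), cell,
                measure = "emotion")
  names(emo) <- c(emotion_items_pos, emotion_items_neg)
  profiles$pos <- Reduce(`+`, emo[emotion_items_pos]) /
    length(emotion_items_pos)
  profiles$neg <- Reduce(`+`, emo[emotion_items_neg]) /
    length(emotion_items_neg)
  profiles$ThVal <- cell("valence", "stay") - cell("valence", "try")

  list(traits = traits, profiles = profiles)
}
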