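# Entity relevance weighting: logarithmic term frequency with pivoted
# unique document-length normalization. "Length" here is the number of
# DISTINCT entities detected in a document, and the pivot is the
# collection-wide average of that count, so documents of average entity
# richness are neither penalized nor rewarded:
#
#   relevance(tf, dl) = (1 + log tf) / ((1 - slope) * pivot + slope * dl)
#
# At dl = pivot the denominator reduces to the pivot exactly; dl > pivot is
# penalized, dl < pivot rewarded. slope = 0.2 follows the classical
# pivoted-normalization recommendation.

#' Relevance parameters
#'
#' @param slope penalty slope in (0, 1); default 0.2.
#' @param pivot positive pivot (collection average of distinct entities per
#'   document); usually from [compute_pivot()].
#' @param log_base `"natural"` or `"ten"`.
#' @return list of class `ndkg_relparams`.
#' @export
relevance_params <- function(slope = 0.2, pivot, log_base = c("natural", "ten")) {
  log_base <- match.arg(log_base)
  stopifnot(is.numeric(slope), slope >= 0, slope < 1,
            is.numeric(pivot), pivot > 0)
  structure(list(slope = slope, pivot = pivot, log_base = log_base),
            class = "ndkg_relparams")
}

#' Compute the pivot of a collection
#'
#' Arithmetic mean of the number of distinct named entities per document
#' over the entire collection, including documents in which no entity was
#' detected.
#'
#' @param freq an `ndkg_freq` table from [count_frequencies()].
#' @return positive scalar.
#' @export
compute_pivot <- function(freq) {
  d <- freq$distinct_entities
  if (!length(d) || sum(d) == 0) {
    stop_ndkg("cannot compute pivot: no entity mentions in the collection")
  }
  mean(d)
}

#' Entity relevance weight (pivoted unique normalization)
#'
#' Vectorized over `tf` and `dl`.
#'
#' @param tf term frequency of the entity in the document (>= 1; an absent
#'   entity yields no edge rather than a zero weight).
#' @param dl number of distinct entities in the document (>= 1).
#' @param params an `ndkg_relparams` object.
#' @return positive numeric weight(s).
#' @examples
#' p <- relevance_params(slope = 0.2, pivot = 5)
#' entity_relevance(10, 10, p)  # (1 + ln 10) / 6
#' @export
entity_relevance <- function(tf, dl, params) {
  stopifnot(inherits(params, "ndkg_relparams"))
  if (any(tf < 1)) stop_ndkg("tf must be >= 1 (absent entities get no edge)")
  if (any(dl < 1)) stop_ndkg("dl must be >= 1")
  lg <- if (params$log_base == "natural") log(tf) else log10(tf)
  # (1-slope)*pivot + slope*dl, factored so that dl = pivot yields the
  # pivot exactly in floating point
  (1 + lg) / (params$pivot + params$slope * (dl - params$pivot))
}

#' Relevance weights for every (document, entity) pair
#'
#' @param freq an `ndkg_freq` table.
#' @param params an `ndkg_relparams` object (pivot typically from
#'   [compute_pivot()] on the same table).
#' @return data frame `doc_id`, `canonical`, `vocab`, `tf`, `dl`, `weight`.
#' @export
relevance_scores <- function(freq, params) {
  tf <- freq$tf
  if (!nrow(tf)) {
    return(data.frame(doc_id = character(), canonical = character(),
                      vocab = character(), tf = integer(), dl = integer(),
                      weight = numeric()))
  }
  tf$dl <- as.integer(freq$distinct_entities[tf$doc_id])
  tf$weight <- entity_relevance(tf$tf, tf$dl, params)
  tf
}
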