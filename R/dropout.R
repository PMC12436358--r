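# Attribute drop-out: decide which attributes to hide from the annotator for
# a queried instance, based on the pairwise worst-case mislabeling model.

#' Rank attributes as drop candidates for a queried instance
#'
#' Evaluates every unordered pair of attributes of a queried instance. For a
#' pair, the worst-case mislabeling probability is computed from the absolute
#' deviations of the two values from their population medians; if it exceeds
#' `threshold`, the pair's smaller-deviation attribute (the one closer to its
#' median, hence the riskier cue) becomes a candidate for removal.
#'
#' @param instance Numeric vector: the attribute values of the queried
#'   instance (length d >= 2).
#' @param medians Numeric vector of the same length: per-attribute population
#'   medians, on the raw attribute scale.
#' @param threshold Drop threshold on the worst-case probability, in
#'   (0, 0.5); candidates must exceed it strictly. Default 0.3, the value at
#'   which a point is inclined within 18 degrees of an attribute axis.
#' @param rescale If `TRUE`, deviations are divided by each attribute's
#'   median absolute deviation (`mad_scale`, which must then be supplied)
#'   before the pairwise ratios are formed. Off by default: the model is
#'   stated on raw deviations, but cross-attribute ratios are unit-sensitive,
#'   so a robust rescaling is offered for heterogeneous units.
#' @param mad_scale Optional numeric vector of per-attribute scale factors
#'   used when `rescale = TRUE`.
#' @return A tibble of candidates sorted by `probability` descending (ties in
#'   the order pairs are enumerated), with columns `attribute` (index of the
#'   smaller-deviation member; ties go to the lower index), `probability`,
#'   and the source pair `pair_i`, `pair_j`.
#' @examples
#' rank_drop_candidates(c(0.1, 0.2, 5), medians = c(0, 0, 0))
#' @export
rank_drop_candidates <- function(instance, medians, threshold = 0.3,
                                 rescale = FALSE, mad_scale = NULL) {
  check_finite(instance, "instance")
  check_finite(medians, "medians")
  d <- length(instance)
  if (d < 2) abort("The pairwise drop-out mechanism needs at least 2 attributes.")
  if (length(medians) != d) abort("`instance` and `medians` must have the same length.")
  if (threshold <= 0 || threshold >= 0.5) abort("`threshold` must lie in (0, 0.5).")
  dev <- abs(instance - medians)
  if (rescale) {
    if (is.null(mad_scale)) abort("`rescale = TRUE` requires `mad_scale`.")
    check_finite(mad_scale, "mad_scale")
    dev <- dev / ifelse(mad_scale > 0, mad_scale, 1)
  }

  pairs <- utils::combn(d, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- p_worst_scalar(dev[i], dev[j])
    if (p > threshold) {
      cand <- if (dev[i] <= dev[j]) i else j  # tie -> lower index
      tibble::tibble(attribute = cand, probability = p, pair_i = i, pair_j = j)
    } else {
      NULL
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(attribute = integer(), probability = double(),
                          pair_i = integer(), pair_j = integer()))
  }
  # stable sort: descending probability, ties keep pair enumeration order
  out[order(-out$probability), , drop = FALSE]
}

#' Select the attributes to drop from a ranked candidate list
#'
#' Deduplicates a descending-sorted candidate list (keeping each attribute's
#' highest-probability occurrence) and keeps at most `max_drop` attributes,
#' never reducing the instance below one visible attribute: the cap is
#' `min(max_drop, d - 1)`, since an annotator cannot label a query with every
#' attribute hidden.
#'
#' @param candidates A tibble from [rank_drop_candidates()] (sorted by
#'   probability descending).
#' @param d Number of attributes of the instance.
#' @param max_drop Maximum number of attributes to hide (default 2).
#' @return Integer vector of attribute indices to hide, ordered by descending
#'   probability; possibly empty.
#' @export
select_drop_attributes <- function(candidates, d, max_drop = 2) {
  if (d < 2) abort("`d` must be at least 2.")
  if (nrow(candidates) == 0) return(integer())
  keep <- !duplicated(candidates$attribute)
  attrs <- candidates$attribute[keep]
  as.integer(head(attrs, min(max_drop, d - 1)))
}

#' Apply a drop list to an instance, producing a masked query
#'
#' @param instance Numeric vector of attribute values.
#' @param droplist Integer vector of attribute indices to hide (may be
#'   empty); must leave at least one attribute visible.
#' @return A `masked_query` object: a list with `values` (unchanged) and
#'   `visible` (logical mask, `FALSE` exactly on `droplist`).
#' @examples
#' apply_dropout(c(0.1, 5, 5), 1L)
#' @export
apply_dropout <- function(instance, droplist = integer()) {
  check_finite(instance, "instance")
  d <- length(instance)
  droplist <- as.integer(droplist)
  if (length(droplist) > 0 && (any(droplist < 1) || any(droplist > d))) {
    abort("`droplist` contains indices outside the instance.")
  }
  visible <- rep(TRUE, d)
  visible[droplist] <- FALSE
  if (!any(visible)) abort("A masked query must keep at least one attribute visible.")
  structure(list(values = instance, visible = visible), class = "masked_query")
}

#' @export
print.masked_query <- function(x, ...) {
  shown <- ifelse(x$visible, format(x$values), "<hidden>")
  cat("<masked_query> ", paste(shown, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mask a queried instance with the drop-out mechanism
#'
#' Convenience wrapper chaining [rank_drop_candidates()],
#' [select_drop_attributes()] and [apply_dropout()]: the full drop-out
#' mechanism for one query.
#'
#' @inheritParams rank_drop_candidates
#' @inheritParams select_drop_attributes
#' @return A `masked_query` object.
#' @examples
#' mask_query(c(0.1, 0.2, 5), medians = c(0, 0, 0))
#' @export
mask_query <- function(instance, medians, threshold = 0.3, max_drop = 2,
                       rescale = FALSE, mad_scale = NULL) {
  cand <- rank_drop_candidates(instance, medians, threshold = threshold,
                               rescale = rescale, mad_scale = mad_scale)
  drop <- select_drop_attributes(cand, d = length(instance), max_drop = max_drop)
  apply_dropout(instance, drop)
}
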