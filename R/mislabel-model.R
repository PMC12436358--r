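# Closed-form model of the chance that a one-attribute annotator mislabels a
# query, as a function of the query's absolute deviations (a, b) from the two
# attributes' population medians.

atan_deg <- function(x) atan(x) * 180 / pi

clip01 <- function(x) pmin(1, pmax(0, x))

check_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(paste0("`", what, "` must be finite numeric, with no missing values."))
  }
  invisible(x)
}

#' Absolute deviations of a pair of attribute values from their medians
#'
#' The drop-out model works on the absolute deviation of each attribute value
#' from that attribute's population median. This helper computes the deviation
#' pair (a, b) for a pair of attributes, vectorised over instances.
#'
#' @param value_a,value_b Attribute values (numeric, recycled to a common
#'   length).
#' @param median_a,median_b Population medians of the two attributes, on the
#'   raw attribute scale.
#' @return A tibble with columns `a` and `b`, the nonnegative absolute
#'   deviations `|value - median|` for each attribute.
#' @examples
#' deviation_pair(7, 4, 1, 6)
#' @export
deviation_pair <- function(value_a, median_a, value_b, median_b) {
  check_finite(value_a, "value_a"); check_finite(median_a, "median_a")
  check_finite(value_b, "value_b"); check_finite(median_b, "median_b")
  tibble::tibble(a = abs(value_a - median_a), b = abs(value_b - median_b))
}

check_pair <- function(pair) {
  if (is.data.frame(pair)) {
    if (!all(c("a", "b") %in% names(pair))) {
      abort("`pair` must have columns `a` and `b`.")
    }
    a <- pair$a
    b <- pair$b
  } else {
    abort("`pair` must be a data frame with columns `a` and `b` (see `deviation_pair()`).")
  }
  check_finite(a, "a"); check_finite(b, "b")
  if (any(a < 0) || any(b < 0)) abort("Deviations `a` and `b` must be nonnegative.")
  list(a = a, b = b)
}

#' Worst-case probability of mislabeling a query
#'
#' Probability that a query with attribute deviations (a, b) from the medians
#' receives a wrong label when the annotator decides on a single attribute and
#' the true decision boundary passes through the medians at an angle between
#' 45 and 90 degrees. Because the attribute the annotator actually uses is
#' unknown, the worst case over the two choices is taken:
#'
#' \deqn{P(a, b) = 0.5 - \frac{1}{90}\arctan^{\circ}\frac{\min(a,b)}{\max(a,b)}}
#'
#' with a degree-valued arctangent (equivalently
#' \eqn{0.5 - (2/\pi)\arctan(\min/\max)} in radians). The probability is 0.5
#' when either deviation is 0 (the value sits exactly at its median, the most
#' ambiguous case) and falls to 0 on the 45-degree line a = b, where no
#' heuristic/true-boundary combination can flip the label. When both
#' deviations are 0 the probability is defined as 0.5, the supremum.
#'
#' @param pair A data frame with nonnegative columns `a` and `b` (for example
#'   from [deviation_pair()]); vectorised over rows.
#' @return A tibble with columns `a`, `b`, `probability` (in \[0, 0.5\]),
#'   `point_angle_deg` (the angle \eqn{\arctan^{\circ}(b/a)} the point makes
#'   with the first attribute's axis, `NA` when a = b = 0) and `variant`
#'   (`"worst_case"`).
#' @seealso [p_mislabel_directed()] for the single-attribute variants,
#'   [rank_drop_candidates()] for its use in the drop-out mechanism.
#' @examples
#' p_mislabel_worst(deviation_pair(7, 4, 1, 6))
#' # the zero locus: equal deviations
#' p_mislabel_worst(data.frame(a = 3, b = 3))
#' @export
p_mislabel_worst <- function(pair) {
  p <- check_pair(pair)
  both_zero <- p$a == 0 & p$b == 0
  ratio <- ifelse(both_zero, 0, pmin(p$a, p$b) / pmax(p$a, p$b))
  prob <- clip01(0.5 - atan_deg(ratio) / 90)
  angle <- ifelse(both_zero, NA_real_, atan_deg(ifelse(p$a == 0, Inf, p$b / p$a)))
  tibble::tibble(a = p$a, b = p$b, probability = prob,
                 point_angle_deg = angle, variant = "worst_case")
}

#' Mislabeling probability when the attribute used is known
#'
#' Directed variant of [p_mislabel_worst()] for the case where the annotator's
#' attribute is known. When attribute A is used, the probability is
#' \eqn{0.5 - \arctan^{\circ}(b/a)/90} clipped to \[0, 1\]: it is 0 whenever
#' b > a (the point leans toward the B axis, where a decision on A is safe)
#' and rises toward 1 as the point approaches the A axis. The roles of a and
#' b swap when attribute B is used. The maximum of the two directed variants
#' equals the worst case.
#'
#' @inheritParams p_mislabel_worst
#' @param used Which attribute the annotator decides on: `"A"` or `"B"`.
#' @return A tibble like [p_mislabel_worst()]'s, with `variant` `"used_A"` or
#'   `"used_B"` and `probability` in \[0, 1\].
#' @examples
#' p_mislabel_directed(deviation_pair(7, 4, 1, 6), used = "A")
#' @export
p_mislabel_directed <- function(pair, used = c("A", "B")) {
  used <- match.arg(used)
  p <- check_pair(pair)
  if (any(p$a == 0 & p$b == 0)) {
    abort("Directed probability is undefined at a = b = 0; use `p_mislabel_worst()`.")
  }
  ratio <- if (used == "A") p$b / p$a else p$a / p$b
  prob <- clip01(0.5 - atan_deg(ratio) / 90)
  tibble::tibble(a = p$a, b = p$b, probability = prob,
                 point_angle_deg = atan_deg(ifelse(p$a == 0, Inf, p$b / p$a)),
                 variant = paste0("used_", used))
}

# Scalar fast path used by the dropout loop.
p_worst_scalar <- function(a, b) {
  if (a == 0 && b == 0) return(0.5)
  max(0, min(1, 0.5 - atan_deg(min(a, b) / max(a, b)) / 90))
}
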