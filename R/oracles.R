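# Synthetic annotators that label (possibly masked) queries with
# fast-and-frugal heuristics: Take-the-Best and fast-and-frugal trees.

label_col_check <- function(data, label) {
  if (!label %in% names(data)) abort(paste0("Label column `", label, "` not found."))
  y <- data[[label]]
  uy <- sort(unique(y))
  if (length(uy) != 2) abort("The label column must contain exactly two classes.")
  as.integer(y == uy[2])  # positive class = higher/second level
}

attribute_matrix <- function(data, label) {
  X <- data[setdiff(names(data), label)]
  bad <- names(X)[!vapply(X, is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric attribute column(s): ", paste(bad, collapse = ", ")))
  }
  as.matrix(X)
}

# Single-cue classifiers "positive iff value > median" (direction +1) or
# "positive iff value < median" (direction -1); values exactly at the median
# do not exceed it and predict the negative class under either direction.
cue_stats <- function(X, y) {
  d <- ncol(X)
  med <- apply(X, 2, median)
  purrr::map_dfr(seq_len(d), function(j) {
    v <- X[, j]
    if (all(v == v[1])) {  # zero spread: an uninformative cue
      return(tibble::tibble(index = j, attribute = colnames(X)[j],
                            threshold = med[j], direction = 1, accuracy = 0.5))
    }
    acc_pos <- mean((v > med[j]) == (y == 1))
    acc_neg <- mean((v < med[j]) == (y == 1))
    if (acc_neg > acc_pos) {
      tibble::tibble(index = j, attribute = colnames(X)[j], threshold = med[j],
                     direction = -1, accuracy = acc_neg)
    } else {
      tibble::tibble(index = j, attribute = colnames(X)[j], threshold = med[j],
                     direction = 1, accuracy = acc_pos)
    }
  })
}

majority_class <- function(y) as.integer(mean(y) >= 0.5)

#' Fit a Take-the-Best oracle
#'
#' Take-the-Best (TTB) decides with a single cue: the instance is labeled
#' positive when the most valid visible attribute exceeds its population
#' median (or falls below it, for a cue whose direction is inverted). Fitting
#' measures, for every attribute, the accuracy of the one-cue median-split
#' classifier against the ground-truth labels, flips the cue's direction when
#' accuracy is below one half, and ranks cues by the direction-adjusted
#' accuracy (ties go to the earlier column).
#'
#' @param data A data frame of numeric attribute columns plus one binary
#'   label column.
#' @param label Name of the label column (default `"label"`). The positive
#'   class is the higher of the two sorted unique values.
#' @return A `ttb_oracle` object with a `cues` tibble (index, attribute,
#'   threshold = median, direction, accuracy; sorted by accuracy descending)
#'   and the majority class of the fitting data, used as a fallback when no
#'   visible cue can decide.
#' @seealso [predict.ttb_oracle()], [fit_fft()]
#' @export
fit_ttb <- function(data, label = "label") {
  y <- label_col_check(data, label)
  X <- attribute_matrix(data, label)
  cues <- cue_stats(X, y)
  cues <- cues[order(-cues$accuracy, cues$index), , drop = FALSE]
  structure(list(cues = cues, majority = majority_class(y),
                 attributes = colnames(X)),
            class = "ttb_oracle")
}

#' @export
print.ttb_oracle <- function(x, ...) {
  cat("Take-the-Best oracle with", nrow(x$cues), "ranked cues\n")
  print(x$cues, n = 5)
  invisible(x)
}

#' @rdname tidy-oracles
#' @export
tidy.ttb_oracle <- function(x, ...) x$cues

#' @rdname tidy-oracles
#' @export
glance.ttb_oracle <- function(x, ...) {
  tibble::tibble(n_cues = nrow(x$cues),
                 best_accuracy = x$cues$accuracy[1],
                 majority_class = x$majority)
}

label_one_ttb <- function(object, values, visible) {
  for (k in seq_len(nrow(object$cues))) {
    j <- object$cues$index[k]
    if (!visible[j]) next
    s <- object$cues$direction[k] * (values[j] - object$cues$threshold[k])
    if (s > 0) return(1L)
    if (s < 0) return(0L)
    # exactly at the median: this cue cannot decide, fall through
  }
  object$majority
}

#' Label queries with a fitted Take-the-Best oracle
#'
#' The highest-ranked visible cue decides. A masked cue is skipped (TTB
#' "uses the next best alternative"); a value exactly at its median does not
#' exceed it in either direction and also falls through to the next visible
#' cue. When no visible cue can decide, the majority class of the fitting
#' data is returned: an annotator always answers.
#'
#' @param object A fitted `ttb_oracle`.
#' @param newdata Either a `masked_query` (see [mask_query()]), a numeric
#'   vector of attribute values (all visible), or a data frame / matrix of
#'   instances (one per row).
#' @param visible Optional logical mask: a vector for a single instance, or
#'   a matrix matching `newdata` row-for-row. Default: everything visible.
#' @param ... Unused.
#' @return Integer label(s) in \{0, 1\}.
#' @export
predict.ttb_oracle <- function(object, newdata, visible = NULL, ...) {
  q <- normalize_queries(newdata, visible, object$attributes)
  vapply(seq_len(nrow(q$values)),
         function(i) label_one_ttb(object, q$values[i, ], q$visible[i, ]),
         integer(1))
}

# Common query normalization: returns values/visible matrices.
normalize_queries <- function(newdata, visible, attributes) {
  d <- length(attributes)
  if (inherits(newdata, "masked_query")) {
    values <- matrix(newdata$values, nrow = 1)
    vis <- matrix(newdata$visible, nrow = 1)
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    values <- matrix(newdata, nrow = 1)
    vis <- if (is.null(visible)) matrix(TRUE, 1, d) else matrix(visible, nrow = 1)
  } else {
    if (is.data.frame(newdata)) newdata <- as.matrix(newdata[, attributes, drop = FALSE])
    values <- newdata
    vis <- if (is.null(visible)) matrix(TRUE, nrow(values), d) else visible
  }
  if (ncol(values) != d) abort("Query has the wrong number of attributes.")
  if (any(rowSums(vis) == 0)) abort("Cannot label a query with no visible attribute.")
  list(values = values, visible = vis)
}

#' Fit a fast-and-frugal tree oracle
#'
#' A fast-and-frugal tree (FFT) is a shallow decision list: each node
#' median-splits one attribute; every non-terminal node exits with a label on
#' one side and passes the other side to the next node; the last node exits
#' on both sides. Construction here follows the standard recipe: the top
#' `depth` attributes by direction-adjusted single-cue accuracy (as in
#' [fit_ttb()]) become the nodes in rank order; each non-terminal node exits
#' on the side (above/below its median) with the higher class purity among
#' the fitting rows that reach it, labeling with that side's majority class;
#' the terminal node labels both sides with their majority classes.
#'
#' @inheritParams fit_ttb
#' @param depth Number of nodes (default 3; must not exceed the number of
#'   attributes).
#' @return An `fft_oracle` with a `nodes` tibble (`index`, `attribute`,
#'   `threshold`, `exit_side` in above/below/both, `label_above`,
#'   `label_below`; `NA` for the side that continues) and the fitting data's
#'   majority class, used when every node of a masked query is skipped.
#' @seealso [predict.fft_oracle()], [new_fft_oracle()] to build a tree by hand
#' @export
fit_fft <- function(data, label = "label", depth = 3) {
  y <- label_col_check(data, label)
  X <- attribute_matrix(data, label)
  if (depth < 1) abort("`depth` must be at least 1.")
  if (depth > ncol(X)) abort("`depth` cannot exceed the number of attributes.")
  cues <- cue_stats(X, y)
  cues <- cues[order(-cues$accuracy, cues$index), , drop = FALSE]
  picked <- cues[seq_len(depth), , drop = FALSE]

  reach <- rep(TRUE, length(y))
  nodes <- vector("list", depth)
  for (k in seq_len(depth)) {
    j <- picked$index[k]; m <- picked$threshold[k]
    above <- X[, j] > m
    ya <- y[reach & above]; yb <- y[reach & !above]
    maj <- function(v, fallback) if (length(v) == 0) fallback else majority_class(v)
    overall <- majority_class(if (any(reach)) y[reach] else y)
    if (k < depth) {
      purity <- function(v) if (length(v) == 0) 0 else max(mean(v), 1 - mean(v))
      side <- if (purity(ya) >= purity(yb)) "above" else "below"
      nodes[[k]] <- tibble::tibble(
        index = j, attribute = picked$attribute[k], threshold = m,
        exit_side = side,
        label_above = if (side == "above") maj(ya, overall) else NA_integer_,
        label_below = if (side == "below") maj(yb, overall) else NA_integer_)
      reach <- reach & (if (side == "above") !above else above)
    } else {
      nodes[[k]] <- tibble::tibble(
        index = j, attribute = picked$attribute[k], threshold = m,
        exit_side = "both",
        label_above = maj(ya, overall), label_below = maj(yb, overall))
    }
  }
  structure(list(nodes = dplyr::bind_rows(nodes), majority = majority_class(y),
                 attributes = colnames(X)),
            class = "fft_oracle")
}

#' Construct a fast-and-frugal tree oracle by hand
#'
#' Builds an `fft_oracle` from an explicit node table instead of fitting one
#' with [fit_fft()] — useful to encode a published tree (for instance a
#' clinical Insulin/BMI/Age screening tree) or a fixture for testing.
#'
#' @param nodes A data frame with columns `index` (attribute position),
#'   `threshold`, `exit_side` (`"above"`/`"below"` for non-terminal nodes,
#'   `"both"` for the last), and `label_above` / `label_below` (0/1, `NA` on
#'   the continuing side).
#' @param attributes Character vector of attribute names, positions matching
#'   `index`.
#' @param majority Fallback label when every node is masked (default 1).
#' @return An `fft_oracle`.
#' @export
new_fft_oracle <- function(nodes, attributes, majority = 1L) {
  nodes <- tibble::as_tibble(nodes)
  needed <- c("index", "threshold", "exit_side", "label_above", "label_below")
  if (!all(needed %in% names(nodes))) {
    abort(paste0("`nodes` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (nodes$exit_side[nrow(nodes)] != "both" ||
      any(nodes$exit_side[-nrow(nodes)] == "both")) {
    abort("Exactly the last node must have exit_side = \"both\".")
  }
  if (!"attribute" %in% names(nodes)) nodes$attribute <- attributes[nodes$index]
  structure(list(nodes = nodes, majority = as.integer(majority),
                 attributes = attributes),
            class = "fft_oracle")
}

#' @export
print.fft_oracle <- function(x, ...) {
  cat("Fast-and-frugal tree oracle with", nrow(x$nodes), "nodes\n")
  print(x$nodes)
  invisible(x)
}

#' Tidy summaries of fitted heuristic oracles
#'
#' `tidy()` returns the cue ranking (TTB) or the node table (FFT) as a
#' tibble; `glance()` returns a one-row summary.
#'
#' @param x A fitted `ttb_oracle` or `fft_oracle`.
#' @param ... Unused.
#' @name tidy-oracles
#' @export
tidy.fft_oracle <- function(x, ...) x$nodes

#' @rdname tidy-oracles
#' @export
glance.fft_oracle <- function(x, ...) {
  tibble::tibble(depth = nrow(x$nodes), majority_class = x$majority)
}

label_one_fft <- function(object, values, visible) {
  n <- object$nodes
  for (k in seq_len(nrow(n))) {
    j <- n$index[k]
    if (!visible[j]) next  # masked node: the tree skips this cue
    above <- values[j] > n$threshold[k]
    if (n$exit_side[k] == "both") {
      return(as.integer(if (above) n$label_above[k] else n$label_below[k]))
    }
    if (above && n$exit_side[k] == "above") return(as.integer(n$label_above[k]))
    if (!above && n$exit_side[k] == "below") return(as.integer(n$label_below[k]))
  }
  object$majority
}

#' Label queries with a fitted fast-and-frugal tree
#'
#' Nodes are traversed in order; a node whose attribute is masked is skipped,
#' so the decision falls to the remaining cues. The first exit reached yields
#' the label; if every node is skipped, the majority class of the fitting
#' data is returned.
#'
#' @inheritParams predict.ttb_oracle
#' @param object A fitted `fft_oracle`.
#' @return Integer label(s) in \{0, 1\}.
#' @export
predict.fft_oracle <- function(object, newdata, visible = NULL, ...) {
  q <- normalize_queries(newdata, visible, object$attributes)
  vapply(seq_len(nrow(q$values)),
         function(i) label_one_fft(object, q$values[i, ], q$visible[i, ]),
         integer(1))
}
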