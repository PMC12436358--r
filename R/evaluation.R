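# Learning-curve summarization, the effectiveness metric, paired comparisons
# and the full experiment harness.

#' Area under a learning curve
#'
#' Sum of the post-query accuracies, one unit of width per query; the
#' pre-query point (query_index 0) is excluded. A constant curve at accuracy
#' 1 over 100 queries therefore has AULC 100, and AULC divided by the number
#' of queries is the mean post-query accuracy.
#'
#' @param curve An `al_curve` from [run_al_cycle()], or any data frame with
#'   columns `query_index` and `accuracy`.
#' @return A single number in \[0, n_queries\].
#' @examples
#' aulc(data.frame(query_index = 0:3, accuracy = c(0.5, 0.6, 0.7, 0.8)))
#' @export
aulc <- function(curve) {
  if (!is.data.frame(curve) || !all(c("query_index", "accuracy") %in% names(curve))) {
    abort("`curve` must have columns `query_index` and `accuracy`.")
  }
  if (nrow(curve) == 0) abort("`curve` is empty.")
  sum(curve$accuracy[curve$query_index > 0])
}

#' Increase in active-learning effectiveness due to drop-out
#'
#' The effectiveness of an active-learning strategy is its AULC gain over
#' random sampling; the drop-out mechanism's relative improvement is
#'
#' \deqn{\frac{\mathrm{AULC}_{with} - \mathrm{AULC}_{without}}
#'            {\mathrm{AULC}_{without} - \mathrm{AULC}_{random}}}
#'
#' Undefined (returned as `NA` with a warning) when the strategy is no
#' better than random sampling, i.e. the denominator vanishes.
#'
#' @param auc_with,auc_without Mean AULC with and without the drop-out
#'   mechanism.
#' @param auc_random Mean AULC of random sampling (no drop-out).
#' @return The improvement ratio (multiply by 100 for percent); vectorised.
#' @examples
#' effectiveness_increase(366.21, 362.91, 359.16)
#' @export
effectiveness_increase <- function(auc_with, auc_without, auc_random) {
  denom <- auc_without - auc_random
  bad <- abs(denom) < sqrt(.Machine$double.eps)
  if (any(bad)) {
    warn("Effectiveness undefined where the strategy matches random sampling; returning NA.")
  }
  ifelse(bad, NA_real_, (auc_with - auc_without) / denom)
}

#' One-sided paired t-test for a drop-out improvement
#'
#' Standard paired t statistic on the differences `with - without`, with
#' df = n - 1 and a one-sided p-value for the alternative "with > without".
#' When the differences have zero variance the statistic is undefined unless
#' they are all exactly zero, in which case t = 0 and p = 0.5.
#'
#' @param with_values,without_values Equal-length numeric vectors of paired
#'   AULC values (pairs matched by experiment cell).
#' @return A one-row tibble with `estimate` (mean difference), `statistic`,
#'   `df` and `p_value`; `statistic` and `p_value` are `NA` in the
#'   degenerate nonzero-constant case.
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 2, 2))
#' @export
paired_t_test <- function(with_values, without_values) {
  check_finite(with_values, "with_values")
  check_finite(without_values, "without_values")
  n <- length(with_values)
  if (length(without_values) != n) abort("Paired vectors must have equal length.")
  if (n < 2) abort("At least 2 pairs are required.")
  d <- with_values - without_values
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(tibble::tibble(estimate = 0, statistic = 0, df = n - 1, p_value = 0.5))
    }
    warn("Zero-variance nonzero differences: t statistic undefined.")
    return(tibble::tibble(estimate = m, statistic = NA_real_, df = n - 1,
                          p_value = NA_real_))
  }
  t_stat <- m / (s / sqrt(n))
  tibble::tibble(estimate = m, statistic = t_stat, df = n - 1,
                 p_value = pt(t_stat, df = n - 1, lower.tail = FALSE))
}

#' Run the full drop-out evaluation experiment
#'
#' For every combination of dataset, heuristic oracle and query strategy,
#' runs `iterations` independent active-learning cycles with and without the
#' drop-out mechanism (plus a random-sampling baseline per dataset and
#' heuristic), records the AULC of each run, and summarizes the cells. The
#' run seed for iteration i is `base_seed + i - 1` in every cell, so cells
#' are matched: the same initial labeled sets and random streams face each
#' condition.
#'
#' @param datasets A named list of data frames (numeric attributes plus a
#'   binary label column).
#' @param label Name of the label column (default `"label"`).
#' @param heuristics Character subset of `c("ttb", "fft")`.
#' @param strategies Character subset of `c("entropy", "density")`.
#' @param iterations Independent repetitions per cell (default 10).
#' @param base_seed Integer; iteration i uses seed `base_seed + i - 1`.
#' @param n_init,threshold,max_drop,fft_depth Passed to [run_al_cycle()].
#' @param include_random Also run the random-sampling baseline (no
#'   drop-out) for each dataset and heuristic (default `TRUE`; needed for
#'   [effectiveness_summary()]).
#' @return An `al_experiment` object: a list with `runs` (a tibble with one
#'   row per run: dataset, heuristic, strategy, dropout, iteration, seed,
#'   aulc, n_queries) and the experiment configuration.
#' @seealso [tidy.al_experiment()], [glance.al_experiment()],
#'   [dropout_t_tests()], [effectiveness_summary()]
#' @export
run_experiment <- function(datasets, label = "label",
                           heuristics = c("ttb", "fft"),
                           strategies = c("entropy", "density"),
                           iterations = 10, base_seed = 1, n_init = 5,
                           threshold = 0.3, max_drop = 2, fft_depth = 3,
                           include_random = TRUE) {
  if (is.data.frame(datasets)) datasets <- list(dataset = datasets)
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  heuristics <- match.arg(heuristics, c("ttb", "fft"), several.ok = TRUE)
  strategies <- match.arg(strategies, c("entropy", "density"), several.ok = TRUE)

  grid <- tidyr::expand_grid(
    dataset = names(datasets), heuristic = heuristics,
    strategy = strategies, dropout = c(FALSE, TRUE))
  if (include_random) {
    grid <- dplyr::bind_rows(
      tidyr::expand_grid(dataset = names(datasets), heuristic = heuristics,
                         strategy = "random", dropout = FALSE),
      grid)
  }
  grid <- tidyr::expand_grid(grid, iteration = seq_len(iterations))

  runs <- purrr::pmap_dfr(grid, function(dataset, heuristic, strategy, dropout, iteration) {
    seed <- base_seed + iteration - 1
    curve <- run_al_cycle(datasets[[dataset]], label = label,
                          strategy = strategy, oracle = heuristic,
                          dropout = dropout, n_init = n_init,
                          threshold = threshold, max_drop = max_drop,
                          fft_depth = fft_depth, seed = seed)
    tibble::tibble(dataset = dataset, heuristic = heuristic,
                   strategy = strategy, dropout = dropout,
                   iteration = iteration, seed = seed,
                   aulc = aulc(curve), n_queries = max(curve$query_index))
  })
  structure(list(runs = runs,
                 config = list(label = label, iterations = iterations,
                               base_seed = base_seed, n_init = n_init,
                               threshold = threshold, max_drop = max_drop,
                               fft_depth = fft_depth)),
            class = "al_experiment")
}

#' @export
print.al_experiment <- function(x, ...) {
  cat("Active-learning drop-out experiment:", nrow(x$runs), "runs\n")
  print(tidy(x))
  invisible(x)
}

#' Summaries of a drop-out experiment
#'
#' `tidy()` returns the cell means: one row per (dataset, heuristic,
#' strategy, dropout) with the mean AULC over iterations — the shape of a
#' per-dataset results table. `glance()` returns the paired one-sided
#' t-tests of [dropout_t_tests()].
#'
#' @param x An `al_experiment` from [run_experiment()].
#' @param ... Unused.
#' @export
tidy.al_experiment <- function(x, ...) {
  x$runs |>
    dplyr::group_by(.data$dataset, .data$heuristic, .data$strategy, .data$dropout) |>
    dplyr::summarise(mean_aulc = mean(.data$aulc), n_iterations = dplyr::n(),
                     .groups = "drop")
}

#' @rdname tidy.al_experiment
#' @export
glance.al_experiment <- function(x, ...) dropout_t_tests(x)

#' Paired t-tests of the drop-out effect per strategy
#'
#' For each query strategy, pairs the per-cell mean AULCs (cells = dataset
#' x heuristic) with and without drop-out and applies the one-sided paired
#' t-test of [paired_t_test()] for the alternative "with > without".
#'
#' @param experiment An `al_experiment`.
#' @return A tibble with one row per strategy: `strategy`, `n_pairs`,
#'   `mean_with`, `mean_without`, `estimate`, `statistic`, `df`, `p_value`.
#' @export
dropout_t_tests <- function(experiment) {
  cells <- tidy(experiment) |> dplyr::filter(.data$strategy != "random")
  wide <- tidyr::pivot_wider(cells, names_from = "dropout",
                             values_from = "mean_aulc",
                             names_prefix = "dropout_")
  wide |>
    dplyr::group_by(.data$strategy) |>
    dplyr::group_modify(function(g, key) {
      res <- paired_t_test(g$dropout_TRUE, g$dropout_FALSE)
      dplyr::bind_cols(
        tibble::tibble(n_pairs = nrow(g),
                       mean_with = mean(g$dropout_TRUE),
                       mean_without = mean(g$dropout_FALSE)),
        res)
    }) |>
    dplyr::ungroup()
}

#' Effectiveness increase of the drop-out mechanism per heuristic/strategy
#'
#' Averages AULC across datasets (and iterations) for each heuristic and
#' strategy — the aggregate-table view — then applies
#' [effectiveness_increase()] against the matching random-sampling baseline.
#' Requires the experiment to include the random baseline.
#'
#' @param experiment An `al_experiment` run with `include_random = TRUE`.
#' @return A tibble with one row per (heuristic, strategy):
#'   `aulc_random`, `aulc_without`, `aulc_with`, `effectiveness_increase`
#'   (a ratio; multiply by 100 for percent).
#' @export
effectiveness_summary <- function(experiment) {
  agg <- experiment$runs |>
    dplyr::group_by(.data$heuristic, .data$strategy, .data$dropout) |>
    dplyr::summarise(mean_aulc = mean(.data$aulc), .groups = "drop")
  rand <- agg |> dplyr::filter(.data$strategy == "random") |>
    dplyr::select("heuristic", aulc_random = "mean_aulc")
  if (nrow(rand) == 0) abort("Experiment has no random-sampling baseline.")
  agg |>
    dplyr::filter(.data$strategy != "random") |>
    tidyr::pivot_wider(names_from = "dropout", values_from = "mean_aulc") |>
    dplyr::rename(aulc_without = "FALSE", aulc_with = "TRUE") |>
    dplyr::left_join(rand, by = "heuristic") |>
    dplyr::mutate(effectiveness_increase = effectiveness_increase(
      .data$aulc_with, .data$aulc_without, .data$aulc_random))
}

#' Plot the AULC distribution of an experiment
#'
#' @param object An `al_experiment`.
#' @param ... Unused.
#' @return A ggplot: AULC by strategy and drop-out condition, faceted by
#'   dataset and heuristic.
#' @export
autoplot.al_experiment <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$strategy, y = .data$aulc,
                               fill = .data$dropout)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_grid(heuristic ~ dataset, scales = "free_y") +
    ggplot2::labs(x = "Query strategy", y = "Area under learning curve",
                  fill = "Drop-out") +
    ggplot2::theme_minimal()
}
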