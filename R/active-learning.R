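# Pool-based active learning: query scoring, selection, and the full
# query-label-retrain loop with optional attribute drop-out.

#' Shannon entropy of a class-probability vector
#'
#' \eqn{E(x) = -\sum_i p_i \log p_i} with the natural logarithm; zero
#' probabilities contribute nothing. Used by the entropy (uncertainty)
#' sampling strategy, which queries the pool point with the largest entropy.
#'
#' @param class_probabilities Numeric vector on the probability simplex
#'   (nonnegative, summing to 1 within 1e-9).
#' @return A single nonnegative number.
#' @examples
#' entropy_score(c(0.5, 0.5))  # log(2)
#' @export
entropy_score <- function(class_probabilities) {
  p <- class_probabilities
  check_finite(p, "class_probabilities")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`class_probabilities` must be nonnegative and sum to 1.")
  }
  -sum(ifelse(p > 0, p * log(p), 0))
}

# Row-wise binary entropy, vectorised for the pool scores.
binary_entropy <- function(p1) {
  p1 <- pmin(1, pmax(0, p1))
  term <- function(p) ifelse(p > 0, p * log(p), 0)
  -(term(p1) + term(1 - p1))
}

#' Information-density score of a candidate query
#'
#' Weights a candidate's uncertainty by how representative it is of the
#' unlabeled pool: the entropy is multiplied by the average similarity
#' \eqn{\mathrm{sim}(x, x_u) = 1 / (1 + \lVert x - x_u \rVert)} over all pool
#' points (the candidate's own pool entry counts, contributing similarity 1).
#' The reciprocal-distance similarity is bounded in (0, 1\] and monotone in
#' Euclidean distance; a Gaussian kernel is available as an alternative.
#'
#' @param x Numeric attribute vector of the candidate.
#' @param pool A matrix or data frame of pool attribute vectors (one per
#'   row), including the candidate itself.
#' @param entropy The candidate's entropy score (>= 0).
#' @param kernel Similarity kernel: `"reciprocal"` (default) or
#'   `"gaussian"` (\eqn{\exp(-\lVert x - x_u\rVert^2 / 2)}).
#' @return A single nonnegative number: entropy times mean similarity.
#' @export
information_density_score <- function(x, pool, entropy,
                                      kernel = c("reciprocal", "gaussian")) {
  kernel <- match.arg(kernel)
  if (is.data.frame(pool)) pool <- as.matrix(pool)
  if (is.null(dim(pool))) pool <- matrix(pool, ncol = length(x))
  if (nrow(pool) == 0) abort("`pool` must be non-empty.")
  if (entropy < 0) abort("`entropy` must be nonnegative.")
  dist <- sqrt(rowSums(sweep(pool, 2, x)^2))
  sim <- if (kernel == "reciprocal") 1 / (1 + dist) else exp(-dist^2 / 2)
  entropy * mean(sim)
}

# Logistic-regression learner used inside the loop. Falls back to a
# single-class model when L holds one class only: it predicts that class,
# and exposes uniform class probabilities so uncertainty scoring stays
# defined until both classes appear.
fit_learner <- function(X, y) {
  if (length(unique(y)) < 2) {
    return(list(kind = "single", class = y[1]))
  }
  Xd <- cbind(1, X)
  fit <- suppressWarnings(stats::glm.fit(Xd, y, family = binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(kind = "logistic", beta = beta)
}

predict_learner <- function(model, X) {
  if (model$kind == "single") {
    p1 <- rep(0.5, nrow(X))            # uniform scores: maximal uncertainty
    pred <- rep(model$class, nrow(X))  # but predictions follow the only class
  } else {
    eta <- drop(cbind(1, X) %*% model$beta)
    p1 <- plogis(eta)
    pred <- as.integer(p1 > 0.5)
  }
  list(p1 = p1, pred = pred)
}

#' Select the next pool index to query
#'
#' Computes the strategy score for every pool member and returns the argmax,
#' breaking ties toward the smallest dataset index; the random strategy draws
#' uniformly from the pool using the run's RNG stream.
#'
#' @param scores Numeric vector: `p1` class-1 probabilities for the pool
#'   rows (entropy/density strategies); ignored for random.
#' @param pool_idx Integer vector of dataset indices currently in the pool.
#' @param strategy One of `"random"`, `"entropy"`, `"density"`.
#' @param sim_pool For `"density"`: precomputed mean similarity of each pool
#'   row to the whole pool.
#' @return A single dataset index from `pool_idx`.
#' @export
select_query_index <- function(scores, pool_idx, strategy, sim_pool = NULL) {
  if (length(pool_idx) == 0) abort("The pool is empty.")
  if (strategy == "random") {
    return(pool_idx[sample.int(length(pool_idx), 1)])
  }
  ent <- binary_entropy(scores)
  s <- switch(strategy, entropy = ent, density = ent * sim_pool,
              abort("Unknown strategy."))
  pool_idx[which.max(s)]  # ties -> first, i.e. smallest dataset index
}

#' Run one active-learning cycle with a heuristic annotator
#'
#' Implements the full pool-based loop: a small random initial set is labeled
#' by the heuristic oracle on unmasked instances; then, until the pool is
#' exhausted, a logistic-regression learner is (re)trained on the labeled set
#' using all attributes, a query is chosen by the strategy, the query is
#' optionally masked by the drop-out mechanism (medians taken over the full
#' dataset), the oracle labels the masked query, and the full attribute
#' vector with the oracle's label joins the labeled set. After every
#' retraining, accuracy is scored on the entire dataset against the ground
#' truth, which serves as the test set.
#'
#' Attributes are z-score standardized (over the full dataset) for learner
#' fitting and similarity computation; medians and deviations for the
#' drop-out mechanism and the oracles stay on the raw attribute scale.
#'
#' @param data Data frame of numeric attributes plus a binary label column
#'   (the ground truth: used to fit the oracle and to score accuracy, never
#'   shown to the learner).
#' @param label Name of the label column (default `"label"`).
#' @param strategy Query strategy: `"entropy"`, `"density"` or `"random"`.
#' @param oracle `"ttb"`, `"fft"`, or an already fitted oracle object; a
#'   string is fitted on the full data. `"truth"` gives an omniscient oracle
#'   that returns the ground-truth label (useful for calibration).
#' @param dropout Logical: mask queries with the drop-out mechanism?
#' @param n_init Size of the initial random labeled set (default 5).
#' @param threshold,max_drop Drop-out configuration (defaults 0.3 and 2).
#' @param fft_depth Depth used when `oracle = "fft"` (default 3).
#' @param seed Integer seed controlling the initial set and the random
#'   strategy.
#' @return An `al_curve`: a tibble with columns `query_index` (0 = model
#'   trained on the initial set only, before any query) and `accuracy`, of
#'   length pool size + 1, with the run configuration and the query history
#'   stored in attributes `config` and `query_history`.
#' @examples
#' d <- generate_linear_dataset(n = 40, seed = 7)
#' curve <- run_al_cycle(d, strategy = "entropy", oracle = "ttb",
#'                       dropout = TRUE, seed = 7)
#' aulc(curve)
#' @export
run_al_cycle <- function(data, label = "label",
                         strategy = c("entropy", "density", "random"),
                         oracle = "ttb", dropout = TRUE, n_init = 5,
                         threshold = 0.3, max_drop = 2, fft_depth = 3,
                         seed = 1) {
  strategy <- match.arg(strategy)
  y <- label_col_check(data, label)
  X <- attribute_matrix(data, label)
  n <- nrow(X); d <- ncol(X)
  if (n_init < 2) abort("`n_init` must be at least 2.")
  if (n_init >= n) abort("`n_init` must leave a non-empty pool.")

  medians <- apply(X, 2, median)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd); sdev[sdev == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdev, `/`)

  orc <- if (is.character(oracle)) {
    switch(oracle,
           ttb = fit_ttb(data, label),
           fft = fit_fft(data, label, depth = fft_depth),
           truth = structure(list(), class = "truth_oracle"),
           abort("Unknown oracle."))
  } else oracle
  ask_oracle <- function(i, visible) {
    if (inherits(orc, "truth_oracle")) return(y[i])
    q <- normalize_queries(X[i, ], visible, colnames(X))
    if (inherits(orc, "ttb_oracle")) label_one_ttb(orc, q$values[1, ], q$visible[1, ])
    else label_one_fft(orc, q$values[1, ], q$visible[1, ])
  }

  sim_all <- NULL
  if (strategy == "density") {
    dm <- as.matrix(stats::dist(Xs))
    sim_all <- 1 / (1 + dm)
  }

  local_seed(seed)
  labeled <- sort(sample.int(n, n_init))
  pool <- setdiff(seq_len(n), labeled)
  oracle_labels <- integer(n)
  oracle_labels[labeled] <- vapply(labeled, function(i) ask_oracle(i, rep(TRUE, d)), integer(1))

  history <- integer(length(pool))
  acc <- numeric(length(pool) + 1)
  step <- 0L
  repeat {
    model <- fit_learner(Xs[labeled, , drop = FALSE], oracle_labels[labeled])
    pr <- predict_learner(model, Xs)
    acc[step + 1L] <- mean(pr$pred == y)
    if (length(pool) == 0) break
    sim_pool <- if (strategy == "density") rowMeans(sim_all[pool, pool, drop = FALSE]) else NULL
    qi <- select_query_index(pr$p1[pool], pool, strategy, sim_pool)
    visible <- rep(TRUE, d)
    if (dropout) {
      cand <- rank_drop_candidates(X[qi, ], medians, threshold = threshold)
      drop <- select_drop_attributes(cand, d = d, max_drop = max_drop)
      visible[drop] <- FALSE
    }
    oracle_labels[qi] <- ask_oracle(qi, visible)
    step <- step + 1L
    history[step] <- qi
    labeled <- c(labeled, qi)
    pool <- setdiff(pool, qi)
  }

  out <- tibble::tibble(query_index = 0:(length(history)), accuracy = acc)
  class(out) <- c("al_curve", class(out))
  attr(out, "config") <- list(strategy = strategy,
                              oracle = class(orc)[1], dropout = dropout,
                              n_init = n_init, threshold = threshold,
                              max_drop = max_drop, seed = seed)
  attr(out, "query_history") <- history
  out
}

#' Plot a learning curve
#'
#' @param object An `al_curve` from [run_al_cycle()].
#' @param ... Unused.
#' @return A ggplot of accuracy against number of queries.
#' @export
autoplot.al_curve <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$query_index, y = .data$accuracy)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "Data points queried", y = "Accuracy on full dataset",
                  title = paste0(cfg$strategy, " sampling, ", cfg$oracle,
                                 if (cfg$dropout) ", with drop-out" else ", no drop-out")) +
    ggplot2::theme_minimal()
}
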