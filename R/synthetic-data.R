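# Generators realizing the model's assumptions: linearly separable two-class
# data whose true decision boundary passes through the attribute medians, a
# bias fixture with a salient weakly-predictive attribute, and a Monte-Carlo
# simulator of the boundary-wedge mislabeling geometry.

#' Generate a linearly separable two-class dataset
#'
#' Attributes are drawn independently and uniformly on symmetric intervals
#' around per-attribute centers, so the population medians coincide with the
#' centers. Labels come from a linear boundary through the center point:
#' positive iff \eqn{\sum_j w_j (x_j - c_j) > 0} with nonnegative weights.
#' For two attributes the boundary is parameterized by its angle to the
#' first attribute's axis, drawn uniformly on \[45, 90\] degrees when not
#' supplied (weights \eqn{(\sin\theta, \cos\theta)}, so the first attribute
#' is at least as important as the second). At 90 degrees the boundary is the
#' second attribute's axis and the label is the sign of the first attribute's
#' deviation.
#'
#' @param n Number of rows (>= 10).
#' @param d Number of attributes (>= 2).
#' @param theta_deg Boundary angle in degrees for `d = 2`, in \[45, 90\];
#'   `NULL` (default) draws it uniformly from that range.
#' @param weights Optional nonnegative weight vector of length `d` for
#'   `d > 2` (or to override the angle parameterization); `NULL` draws
#'   weights uniformly on \[0.2, 1\].
#' @param centers Per-attribute centers (= medians); scalar or length-`d`
#'   vector, default 0.
#' @param halfwidth Half-width of the uniform attribute range, default 10.
#' @param label_noise Probability in \[0, 0.5) of flipping each label
#'   (default 0).
#' @param seed Integer seed; every draw is deterministic given it.
#' @return A tibble with `d` attribute columns `x1..xd` and an integer
#'   `label` column in \{0, 1\}, carrying the boundary parameters in
#'   attributes `theta_deg` (d = 2) / `weights` and `centers`.
#' @examples
#' d <- generate_linear_dataset(n = 50, d = 2, theta_deg = 90, seed = 1)
#' table(d$label)
#' @export
generate_linear_dataset <- function(n, d = 2, theta_deg = NULL, weights = NULL,
                                    centers = 0, halfwidth = 10,
                                    label_noise = 0, seed = 1) {
  if (n < 10) abort("`n` must be at least 10.")
  if (d < 2) abort("`d` must be at least 2.")
  if (label_noise < 0 || label_noise >= 0.5) abort("`label_noise` must lie in [0, 0.5).")
  centers <- rep_len(centers, d)
  attempt <- 0L
  repeat {
    local_seed(seed + attempt)
    if (is.null(weights)) {
      if (d == 2) {
        th <- theta_deg %||% runif(1, 45, 90)
        if (th < 45 || th > 90) abort("`theta_deg` must lie in [45, 90].")
        w <- c(sin(th * pi / 180), cos(th * pi / 180))
      } else {
        th <- NA_real_
        w <- runif(d, 0.2, 1)
      }
    } else {
      if (length(weights) != d || any(weights < 0)) {
        abort("`weights` must be a nonnegative vector of length `d`.")
      }
      th <- NA_real_
      w <- weights
    }
    X <- matrix(runif(n * d, -halfwidth, halfwidth), n, d)
    X <- sweep(X, 2, centers, `+`)
    y <- as.integer(sweep(X, 2, centers) %*% w > 0)
    if (label_noise > 0) {
      flip <- runif(n) < label_noise
      y[flip] <- 1L - y[flip]
    }
    if (length(unique(y)) == 2) break
    attempt <- attempt + 1L
    inform(paste0("Degenerate single-class draw; resampling with seed ", seed + attempt, "."))
  }
  out <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(d))
  out$label <- y
  attr(out, "theta_deg") <- th
  attr(out, "weights") <- w
  attr(out, "centers") <- centers
  out
}

# All randomness flows through an explicit integer seed.
local_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  set.seed(as.integer(seed))
}

#' Generate the annotator-bias fixture
#'
#' A four-attribute, linearly separable dataset built so that a heuristic
#' annotator is accurate away from the medians but error-prone near them —
#' the situation the drop-out mechanism targets. The true label is set by a
#' linear boundary through the medians of attributes 2-4 with weights
#' (1, 0.45, 0.45). Attribute 1 (the salient cue) has deviation magnitude
#' uniform on \[0, 10\]; when the magnitude exceeds 3, its sign agrees with
#' the label, otherwise the sign is a fair coin. A single-cue classifier on
#' attribute 1 is therefore right about 85% of the time overall (so
#' Take-the-Best ranks it first) but only 50% within the near-median band —
#' exactly the queries the mislabeling model flags, making the salient cue
#' the drop candidate whenever its deviation is small relative to another
#' attribute's.
#'
#' @param n Number of rows (>= 100).
#' @param seed Integer seed.
#' @return A tibble with attributes `x1..x4` (centers 120, 30, 25, 60),
#'   integer `label`, and the construction parameters in attributes.
#' @export
generate_bias_fixture <- function(n, seed = 1) {
  if (n < 100) abort("`n` must be at least 100.")
  local_seed(seed)
  centers <- c(120, 30, 25, 60)
  w <- c(1, 0.45, 0.45)
  half <- 10
  band <- 3
  dev234 <- matrix(runif(n * 3, -half, half), n, 3)
  y <- as.integer(dev234 %*% w > 0)
  m1 <- runif(n, 0, half)
  sign1 <- ifelse(m1 > band, ifelse(y == 1, 1, -1),
                  ifelse(runif(n) < 0.5, 1, -1))
  X <- cbind(m1 * sign1, dev234)
  X <- sweep(X, 2, centers, `+`)
  out <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(out) <- paste0("x", 1:4)
  out$label <- y
  attr(out, "weights") <- c(0, w)
  attr(out, "centers") <- centers
  attr(out, "salient_band") <- band
  out
}

#' Simulate the wedge geometry behind the mislabeling formula
#'
#' Monte-Carlo check of the geometric argument underlying the closed-form
#' mislabeling probability. For a point with deviations (a, b), each
#' single-attribute heuristic implies an axis-aligned decision boundary; the
#' true boundary passes through the medians at an angle drawn uniformly on
#' \[45, 90\] degrees from the axis of the attribute the heuristic uses. The
#' point is mislabeled on a draw exactly when it lies in the wedge between
#' the true boundary and the heuristic's boundary — for the heuristic using
#' attribute A, when the point's angle from the A axis exceeds the drawn
#' boundary angle, and symmetrically for B. The reported frequency is the
#' worst case over the two heuristic choices.
#'
#' The simulated worst-case frequency reproduces the *ordering* of
#' [p_mislabel_worst()] exactly (it is a monotone transform of it: zero on
#' the 45-degree line, maximal on the axes, scale-invariant and symmetric in
#' a and b); its absolute level differs by the closed form's normalization,
#' which is why the formula — not the simulation — is the normative score in
#' the drop-out mechanism.
#'
#' @param pair A one-row data frame with columns `a`, `b` (not both 0).
#' @param n_draws Number of boundary draws (>= 1000).
#' @param seed Integer seed.
#' @return A tibble with `freq_used_A`, `freq_used_B` (per-heuristic wedge
#'   frequencies) and `freq_worst`, their maximum.
#' @export
simulate_mislabel_frequency <- function(pair, n_draws = 10000, seed = 1) {
  p <- check_pair(pair)
  if (length(p$a) != 1) abort("`pair` must be a single deviation pair.")
  if (p$a == 0 && p$b == 0) abort("Both deviations are 0: the point angle is undefined.")
  if (n_draws < 1000) abort("`n_draws` must be at least 1000.")
  local_seed(seed)
  theta <- runif(n_draws, 45, 90)
  angle_from_A <- atan_deg(ifelse(p$a == 0, Inf, p$b / p$a))
  angle_from_B <- 90 - angle_from_A
  fa <- mean(angle_from_A > theta)
  fb <- mean(angle_from_B > theta)
  tibble::tibble(freq_used_A = fa, freq_used_B = fb, freq_worst = max(fa, fb))
}

#' Load a labeled tabular dataset from a CSV file
#'
#' Reads a headered CSV with numeric attribute columns and one binary label
#' column, drops rows with missing values (with a message), and maps the
#' labels to \{0, 1\}.
#'
#' @param path Path to the CSV file.
#' @param label Name of the label column (default `"label"`).
#' @param positive Value of the label column to map to 1; default: the
#'   higher/later of the two sorted unique values.
#' @return A tibble of numeric attributes plus an integer `label` column.
#' @export
load_csv_dataset <- function(path, label = "label", positive = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (!label %in% names(data)) abort(paste0("Label column `", label, "` not found."))
  n0 <- nrow(data)
  data <- data[stats::complete.cases(data), , drop = FALSE]
  if (nrow(data) < n0) {
    inform(paste0("Dropped ", n0 - nrow(data), " row(s) with missing values."))
  }
  attrs <- setdiff(names(data), label)
  bad <- attrs[!vapply(data[attrs], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("Non-numeric attribute column(s): ", paste(bad, collapse = ", ")))
  }
  vals <- data[[label]]
  uv <- sort(unique(vals))
  if (length(uv) != 2) abort("Label column must contain exactly two distinct values.")
  positive <- positive %||% uv[2]
  if (!positive %in% uv) abort("`positive` is not a value of the label column.")
  y <- as.integer(vals == positive)
  out <- data[attrs]
  out[[label]] <- y
  out
}

#' Per-attribute population medians of a labeled dataset
#'
#' @param data A data frame of numeric attributes plus a label column.
#' @param label Name of the label column excluded from the computation.
#' @return A named numeric vector of medians over all rows.
#' @export
dataset_medians <- function(data, label = "label") {
  X <- attribute_matrix(data, label)
  apply(X, 2, median)
}
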