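test_that("entropy score follows -sum(p log p) with natural log", {
  expect_equal(entropy_score(c(0.5, 0.5)), log(2))
  expect_equal(entropy_score(c(1, 0)), 0)
  expect_equal(entropy_score(c(0.9, 0.1)), -(0.9 * log(0.9) + 0.1 * log(0.1)))
  expect_equal(entropy_score(c(0.2, 0.3, 0.5)), entropy_score(c(0.5, 0.2, 0.3)))
  expect_error(entropy_score(c(0.7, 0.4)), "sum to 1")
  expect_error(entropy_score(c(-0.1, 1.1)), "nonnegative")
})

test_that("information density multiplies entropy by mean pool similarity", {
  x <- c(1, 2)
  pool_same <- rbind(x, x, x)
  expect_equal(information_density_score(x, pool_same, 0.6931), 0.6931)
  expect_equal(information_density_score(x, pool_same, 0), 0)
  # hand evaluation: own entry (sim 1) plus one point at distance 1 (sim 0.5)
  pool <- rbind(x, x + c(1, 0))
  expect_equal(information_density_score(x, pool, log(2)), log(2) * 0.75)
  expect_error(information_density_score(x, pool[0, , drop = FALSE], 0.5), "non-empty")
})

test_that("query selection takes the argmax with ties to the smallest index", {
  # p1 of 0.5 gives maximal entropy; 0.98 is nearly certain
  expect_equal(select_query_index(c(0.5, 0.98), c(4L, 9L), "entropy"), 4L)
  expect_equal(select_query_index(c(0.98, 0.5), c(4L, 9L), "entropy"), 9L)
  expect_equal(select_query_index(c(0.7, 0.7, 0.7), c(3L, 7L, 9L), "entropy"), 3L)
  # density weighting can overturn the entropy ranking
  expect_equal(select_query_index(c(0.6, 0.6), c(1L, 2L), "density",
                                  sim_pool = c(0.2, 0.9)), 2L)
  set.seed(1); a <- select_query_index(NULL, c(3L, 7L, 9L), "random")
  set.seed(1); b <- select_query_index(NULL, c(3L, 7L, 9L), "random")
  expect_identical(a, b)
  expect_true(a %in% c(3L, 7L, 9L))
  expect_error(select_query_index(numeric(), integer(), "entropy"), "empty")
})

test_that("the AL cycle accounts for every pool point exactly once", {
  d <- generate_linear_dataset(n = 40, d = 2, seed = 2)
  curve <- run_al_cycle(d, strategy = "entropy", oracle = "ttb", dropout = TRUE,
                        n_init = 5, seed = 2)
  expect_s3_class(curve, "al_curve")
  expect_equal(nrow(curve), 35 + 1)           # pool size + pre-query point
  expect_equal(curve$query_index, 0:35)
  hist <- attr(curve, "query_history")
  expect_equal(length(hist), 35)
  expect_equal(length(unique(hist)), 35)      # no index queried twice
  expect_true(all(curve$accuracy >= 0 & curve$accuracy <= 1))
})

test_that("an omniscient oracle ends at the full-data training accuracy", {
  d <- generate_linear_dataset(n = 60, d = 2, seed = 6, label_noise = 0.1)
  X <- as.matrix(d[1:2]); y <- d$label
  Xs <- scale(X)
  fit <- suppressWarnings(glm.fit(cbind(1, Xs), y, family = binomial()))
  full_acc <- mean((plogis(drop(cbind(1, Xs) %*% fit$coefficients)) > 0.5) == y)
  for (dropout in c(TRUE, FALSE)) {
    curve <- run_al_cycle(d, strategy = "entropy", oracle = "truth",
                          dropout = dropout, seed = 6)
    expect_equal(curve$accuracy[nrow(curve)], full_acc, tolerance = 1e-9)
  }
})

test_that("runs are bitwise reproducible under a fixed seed", {
  d <- generate_bias_fixture(120, seed = 19)
  for (strategy in c("entropy", "density", "random")) {
    c1 <- run_al_cycle(d, strategy = strategy, oracle = "fft", dropout = TRUE,
                       seed = 123)
    c2 <- run_al_cycle(d, strategy = strategy, oracle = "fft", dropout = TRUE,
                       seed = 123)
    expect_identical(attr(c1, "query_history"), attr(c2, "query_history"))
    expect_identical(c1$accuracy, c2$accuracy)
  }
})

test_that("enabling drop-out changes at least one oracle label on biased data", {
  d <- generate_bias_fixture(120, seed = 23)
  with_do <- run_al_cycle(d, strategy = "entropy", oracle = "ttb",
                          dropout = TRUE, seed = 5)
  without <- run_al_cycle(d, strategy = "entropy", oracle = "ttb",
                          dropout = FALSE, seed = 5)
  # same seed, same initial set: any divergence comes from masked queries
  expect_false(identical(with_do$accuracy, without$accuracy) &&
                 identical(attr(with_do, "query_history"),
                           attr(without, "query_history")))
})

test_that("degenerate single-class labeled sets fall back gracefully", {
  # an oracle that always answers 1 keeps L single-class throughout
  d <- generate_linear_dataset(n = 20, d = 2, seed = 4)
  one_sided <- new_fft_oracle(
    nodes = tibble::tibble(index = 1L, threshold = -1e9, exit_side = "both",
                           label_above = 1L, label_below = 1L),
    attributes = c("x1", "x2"))
  curve <- run_al_cycle(d, strategy = "entropy", oracle = one_sided,
                        dropout = FALSE, seed = 4)
  expect_equal(nrow(curve), 16)
  # the constant-class model predicts that class everywhere
  expect_equal(curve$accuracy[1], mean(d$label == 1))
})
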