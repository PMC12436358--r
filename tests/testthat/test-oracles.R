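test_that("TTB ranks cues by single-cue accuracy and flips poor directions", {
  d <- generate_linear_dataset(n = 200, d = 2, theta_deg = 75, seed = 5)
  ttb <- fit_ttb(d)
  # brute-force accuracy count as the independent oracle
  med <- dataset_medians(d)
  acc <- vapply(1:2, function(j) {
    v <- d[[j]]
    max(mean((v > med[j]) == (d$label == 1)), mean((v < med[j]) == (d$label == 1)))
  }, numeric(1))
  expect_equal(ttb$cues$index, order(-acc))
  expect_equal(sort(ttb$cues$accuracy, decreasing = TRUE), sort(acc, decreasing = TRUE))
  # theta 75 degrees: attribute 1 carries more weight and must rank first
  expect_equal(ttb$cues$index[1], 1L)

  anti <- fit_ttb(anti_correlated_table())
  row <- anti$cues[anti$cues$attribute == "anti", ]
  expect_equal(row$direction, -1)
  expect_gt(row$accuracy, 0.5)
  # a perfectly separating cue reaches accuracy 1
  expect_equal(anti$cues$accuracy[1], 1)
})

test_that("constant attributes are uninformative cues ranked last", {
  d <- anti_correlated_table()
  d$flat <- 5
  ttb <- fit_ttb(d)
  row <- ttb$cues[ttb$cues$attribute == "flat", ]
  expect_equal(row$accuracy, 0.5)
  expect_equal(row$direction, 1)
  expect_equal(ttb$cues$attribute[nrow(ttb$cues)], "flat")
})

test_that("TTB decides with the best visible cue and falls through at the median", {
  d <- anti_correlated_table()
  ttb <- fit_ttb(d)
  best <- ttb$cues$index[1]
  q <- c(good = 9, anti = 1)
  expect_equal(predict(ttb, q), 1L)
  expect_equal(predict(ttb, c(good = 1, anti = 9)), 0L)
  # best cue masked: second-ranked cue decides (anti, inverted direction)
  vis <- c(TRUE, TRUE); vis[best] <- FALSE
  expect_equal(predict(ttb, c(good = 1, anti = 1), visible = vis), 1L)
  # value exactly at the median falls through to the next visible cue
  med <- dataset_medians(d)
  expect_equal(predict(ttb, c(good = med[["good"]], anti = 1)), 1L)
  # no cue can decide: majority class
  expect_equal(predict(ttb, med), ttb$majority)
  expect_error(predict(ttb, c(1, 1), visible = c(FALSE, FALSE)), "visible")
})

test_that("fitted FFT matches a hand-rolled two-level rule", {
  d <- generate_linear_dataset(n = 200, d = 3, weights = c(1, 0.6, 0.2), seed = 8)
  fft <- fit_fft(d, depth = 2)
  expect_equal(nrow(fft$nodes), 2)
  expect_equal(fft$nodes$exit_side[2], "both")
  expect_false(any(fft$nodes$exit_side[1] == "both"))
  # trace equality: hand-rolled traversal of the same node table
  hand <- function(x) {
    n <- fft$nodes
    above1 <- x[n$index[1]] > n$threshold[1]
    if (above1 && n$exit_side[1] == "above") return(n$label_above[1])
    if (!above1 && n$exit_side[1] == "below") return(n$label_below[1])
    if (x[n$index[2]] > n$threshold[2]) n$label_above[2] else n$label_below[2]
  }
  X <- as.matrix(d[1:3])
  expect_equal(predict(fft, d[1:3]),
               vapply(seq_len(nrow(X)), function(i) as.integer(hand(X[i, ])), integer(1)))
})

test_that("depth-1 FFT agrees with TTB off the median and with the best single cue", {
  d <- generate_linear_dataset(n = 150, d = 2, theta_deg = 80, seed = 12)
  fft1 <- fit_fft(d, depth = 1)
  ttb <- fit_ttb(d)
  expect_equal(fft1$nodes$index[1], ttb$cues$index[1])
  off <- d[abs(d[[fft1$nodes$index[1]]] - fft1$nodes$threshold[1]) > 1e-9, ]
  expect_equal(predict(fft1, off[1:2]), predict(ttb, off[1:2]))
  expect_error(fit_fft(d, depth = 3), "exceed")
})

test_that("FFT skips masked nodes: the diabetes-style screening tree", {
  tree <- diabetes_tree()
  # full traversal: low insulin exits immediately regardless of the rest
  expect_equal(predict(tree, c(insulin = 50, bmi = 35, age = 60)), 0L)
  expect_equal(predict(tree, c(insulin = 150, bmi = 35, age = 20)), 1L)
  expect_equal(predict(tree, c(insulin = 150, bmi = 25, age = 60)), 1L)
  expect_equal(predict(tree, c(insulin = 150, bmi = 25, age = 30)), 0L)
  # BMI masked: the decision comes from insulin and age alone
  vis <- c(TRUE, FALSE, TRUE)
  expect_equal(predict(tree, c(insulin = 150, bmi = 35, age = 30), visible = vis), 0L)
  expect_equal(predict(tree, c(insulin = 150, bmi = 35, age = 60), visible = vis), 1L)
  expect_error(predict(tree, c(1, 1, 1), visible = rep(FALSE, 3)), "visible")
})

test_that("an FFT whose nodes are all masked falls back to the majority class", {
  d <- generate_bias_fixture(200, seed = 17)
  fft <- fit_fft(d, depth = 3)
  vis <- rep(TRUE, 4)
  vis[fft$nodes$index] <- FALSE
  expect_true(any(vis))  # one non-node attribute stays visible
  expect_equal(predict(fft, as.numeric(d[1, 1:4]), visible = vis), fft$majority)
})

test_that("masking an attribute the traversal never uses leaves labels unchanged", {
  d <- generate_bias_fixture(200, seed = 31)
  ttb <- fit_ttb(d)
  fft <- fit_fft(d, depth = 3)
  X <- as.matrix(d[1:4])
  worst_ttb <- ttb$cues$index[4]  # lowest-ranked cue: used only if others tie
  set.seed(77)
  rows <- sample(nrow(X), 40)
  for (i in rows) {
    vis <- rep(TRUE, 4); vis[worst_ttb] <- FALSE
    expect_equal(predict(ttb, X[i, ], visible = vis), predict(ttb, X[i, ]))
  }
  # FFT: an attribute outside the tree's nodes can never change the label
  outside <- setdiff(1:4, fft$nodes$index)
  if (length(outside) > 0) {
    for (i in rows) {
      vis <- rep(TRUE, 4); vis[outside[1]] <- FALSE
      expect_equal(predict(fft, X[i, ], visible = vis), predict(fft, X[i, ]))
    }
  }
})

test_that("oracle accuracy degrades when the best cue is masked", {
  d <- generate_bias_fixture(400, seed = 13)
  X <- as.matrix(d[1:4])
  for (fit in list(fit_ttb(d), fit_fft(d, depth = 3))) {
    best <- if (inherits(fit, "ttb_oracle")) fit$cues$index[1] else fit$nodes$index[1]
    vis <- matrix(TRUE, nrow(X), 4); vis[, best] <- FALSE
    acc_full <- mean(predict(fit, d[1:4]) == d$label)
    acc_masked <- mean(predict(fit, d[1:4], visible = vis) == d$label)
    expect_lte(acc_masked, acc_full)
  }
})

test_that("oracle labels are deterministic and tidy methods expose the fit", {
  d <- generate_bias_fixture(150, seed = 3)
  ttb <- fit_ttb(d); fft <- fit_fft(d)
  expect_identical(predict(ttb, d[1:4]), predict(ttb, d[1:4]))
  expect_identical(predict(fft, d[1:4]), predict(fft, d[1:4]))
  expect_s3_class(tidy(ttb), "tbl_df")
  expect_named(glance(fft), c("depth", "majority_class"))
  expect_equal(glance(ttb)$n_cues, 4)
})
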