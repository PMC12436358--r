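# Fixtures built in code for the oracle and evaluation tests.

# Eight-row table whose second attribute is anti-correlated with the label.
anti_correlated_table <- function() {
  tibble::tibble(
    good = c(1, 2, 3, 4, 6, 7, 8, 9),   # above-median -> label 1
    anti = c(9, 8, 7, 6, 4, 3, 2, 1),   # above-median -> label 0
    label = c(0, 0, 0, 0, 1, 1, 1, 1))
}

# A depth-3 screening tree in the shape of a published diabetes example:
# low insulin exits negative, high BMI exits positive, age decides the rest.
diabetes_tree <- function() {
  new_fft_oracle(
    nodes = tibble::tibble(
      index = 1:3,
      threshold = c(100, 30, 40),
      exit_side = c("below", "above", "both"),
      label_above = c(NA, 1L, 1L),
      label_below = c(0L, NA, 0L)),
    attributes = c("insulin", "bmi", "age"),
    majority = 1L)
}

# The study conditions for the scaled-down directional experiment.
bias_fixture_suite <- function(n = 400) {
  list(bias1 = generate_bias_fixture(n, seed = 101),
       bias2 = generate_bias_fixture(n, seed = 202),
       bias3 = generate_bias_fixture(n, seed = 303))
}
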