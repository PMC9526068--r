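# Shared helpers: exact-equality expectation, hand-built genealogies, and
# the canonical pair list.

expect_rat_equal <- function(x, y) {
  x <- rational(x); y <- rational(y)
  expect_true(x == y,
              label = paste0(as.character(x), " == ", as.character(y)))
}

canonical_pairs <- function() {
  list(ratio_pair("H", "L"), ratio_pair("E", "H"), ratio_pair("H", "I"),
       ratio_pair("B", "H"), ratio_pair("E", "L"), ratio_pair("L", "I"),
       ratio_pair("B", "L"), ratio_pair("E", "I"), ratio_pair("B", "E"),
       ratio_pair("B", "I"))
}

# Build a coal_tree by hand from waiting times (T_n..T_2) and merge rows.
# Node ids follow the simulator convention: leaves 1..n, internal nodes
# n+1..2n-1 in merge order.
hand_tree <- function(n, times, merges) {
  stopifnot(length(times) == n - 1, nrow(merges) == n - 1)
  age <- numeric(2 * n - 1)
  t <- 0
  for (j in seq_len(n - 1)) {
    t <- t + times[j]
    age[n + j] <- t
  }
  structure(list(n = n, times = times, merges = merges, node_age = age),
            class = "coal_tree")
}

# Monte-Carlo z-scores of empirical means/variances against exact values.
mc_mean_z <- function(sims, col, exact_val) {
  v <- sims[[col]]
  (mean(v) - exact_val) / (stats::sd(v) / sqrt(length(v)))
}

mc_var_z <- function(sims, col, exact_val) {
  v <- sims[[col]]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  m4 <- mean((v - m)^4)
  se <- sqrt(max(m4 - m2^2, 0) / length(v))
  (stats::var(v) - exact_val) / se
}

mc_cov_z <- function(sims, cx, cy, exact_val) {
  x <- sims[[cx]]; y <- sims[[cy]]
  prod_c <- (x - mean(x)) * (y - mean(y))
  se <- stats::sd(prod_c) / sqrt(length(x))
  (stats::cov(x, y) - exact_val) / se
}

# smallest n at which both members of a ratio pair are defined
pair_min_n <- function(p) max(stat_min_n(p$num), stat_min_n(p$den))

pair_label <- function(p) {
  lab <- function(s) if (s$kind == "T") paste0("T", s$k) else s$kind
  paste0(lab(p$num), "/", lab(p$den))
}

# Compare a computed double against a constant printed to `places` decimals:
# absolute error bounded by rounding of the printed value plus a small
# finite-n evaluation allowance.
expect_decimal <- function(x, printed, places = 5) {
  expect_lt(abs(x - printed), 10^(-places) * 1.0)
}
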