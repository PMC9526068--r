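test_that("delta-method mean formula on hand-evaluated inputs", {
  # degenerate denominator: plain ratio of means
  expect_rat_equal(
    taylor_mean_ratio(rational(3), rational(4), rational(0), rational(0)),
    rational("3/4"))
  # fully correlated pair X = H2, Y = L2 = 2 H2: exact deterministic ratio
  expect_rat_equal(
    taylor_mean_ratio(rational(1), rational(2), rational(4), rational(2)),
    rational("1/2"))
  expect_rat_equal(
    taylor_mean_ratio(rational(2), rational(2), rational(1), rational(0)),
    rational("5/4"))
  # doubles in, doubles out
  expect_decimal(taylor_mean_ratio(2, 2, 1, 0), 1.25)
})

test_that("delta-method variance formula on hand-evaluated inputs", {
  expect_rat_equal(
    taylor_var_ratio(rational(1), rational(2), rational(1), rational(4),
                     rational(2)),
    rational(0))
  expect_rat_equal(
    taylor_var_ratio(rational(5), rational(7), rational(0), rational(0),
                     rational(0)),
    rational(0))
  expect_rat_equal(
    taylor_var_ratio(rational(1), rational(1), rational(1), rational(1),
                     rational(0)),
    rational(2))
})

test_that("zero means in denominator positions fail loudly", {
  expect_error(taylor_mean_ratio(rational(1), rational(0), rational(1),
                                 rational(0)), "denominator mean")
  expect_error(taylor_var_ratio(rational(0), rational(1), rational(1),
                                rational(1), rational(0)), "numerator mean")
  expect_error(ratio_mean_approx(ratio_pair("H", "I"), 2))
})

test_that("ratio approximations reproduce hand-composed values", {
  expect_rat_equal(ratio_mean_approx(ratio_pair("H", "L"), 2)$value,
                   rational("1/2"))
  expect_rat_equal(ratio_var_approx(ratio_pair("H", "L"), 2)$value,
                   rational(0))
  # E[E_3]=2, E[T_2]=1, Var[T_2]=1, Cov[E_3,T_2]=1 -> 2 - 1 + 2 = 3
  expect_rat_equal(ratio_mean_approx(ratio_pair("E", "T2"), 3)$value,
                   rational(3))
  expect_rat_equal(ratio_mean_approx(ratio_pair("H", "T2"), 2)$value,
                   rational(1))
  expect_rat_equal(ratio_var_approx(ratio_pair("H", "T2"), 2)$value,
                   rational(0))
  expect_rat_equal(ratio_var_approx(ratio_pair("E", "L"), 2)$value,
                   rational(0))
  expect_rat_equal(ratio_var_approx(ratio_pair("E", "T2"), 2)$value,
                   rational(0))
})

test_that("variance approximations are nonnegative across pairs and n", {
  zero <- rational(0)
  for (p in canonical_pairs()) {
    lo <- max(pair_min_n(p), 3)
    for (n in c(lo, lo + 1, 10, 25, 80)) {
      expect_true(ratio_var_approx(p, n)$value >= zero)
    }
  }
  for (k in 2:6) {
    for (x in c("H", "L", "E", "I", "B")) {
      p <- ratio_pair(x, tree_stat("T", k))
      expect_true(ratio_var_approx(p, 12)$value >= zero)
    }
  }
})

test_that("the approximate-covariance flag propagates to ratios", {
  expect_true(ratio_mean_approx(ratio_pair("B", "E"), 8)$approximate)
  expect_true(ratio_var_approx(ratio_pair("B", "I"), 8)$approximate)
  expect_false(ratio_mean_approx(ratio_pair("B", "H"), 8)$approximate)
})

test_that("reciprocal orientations run through the generic machinery", {
  # H/E is the reciprocal of the canonical E/H: both defined, different values
  a <- ratio_mean_approx(ratio_pair("H", "E"), 10)$value
  b <- ratio_mean_approx(ratio_pair("E", "H"), 10)$value
  expect_false(a == b)
  expect_error(ratio_mean_limit(ratio_pair("H", "E")), "canonical")
})

test_that("mean approximation of L over a fixed coalescence time grows in n", {
  for (k in c(2, 4)) {
    p <- ratio_pair("L", tree_stat("T", k))
    vals <- sapply(c(5, 10, 20, 40, 80), function(n)
      as.numeric(ratio_mean_approx(p, n)$value))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("ratio limits match printed constants and diverge where expected", {
  expect_decimal(as.numeric(ratio_mean_limit(ratio_pair("E", "H"))$value), 1.28987)
  expect_decimal(as.numeric(ratio_mean_limit(ratio_pair("B", "H"))$value), 0.56463)
  expect_decimal(as.numeric(ratio_mean_limit(ratio_pair("B", "E"))$value), 0.64493)
  expect_rat_equal(ratio_mean_limit(ratio_pair("L", "I"))$value, rational(1))
  expect_decimal(as.numeric(ratio_var_limit(ratio_pair("B", "H"))$value), 0.03744)
  expect_decimal(as.numeric(ratio_var_limit(ratio_pair("B", "E"))$value), 0.26159)
  expect_decimal(as.numeric(ratio_var_limit(ratio_pair("E", "H"))$value), 0.28987)
  expect_rat_equal(ratio_var_limit(ratio_pair("H", "L"))$value, rational(0))
  expect_true(is_divergent(ratio_mean_limit(ratio_pair("L", "T2"))$value))
  expect_true(is_divergent(ratio_var_limit(ratio_pair("I", "T4"))$value))
})

test_that("T-pair limits match the k-dependent closed expressions", {
  for (k in c(2, 3, 7)) {
    tk <- tree_stat("T", k)
    expect_rat_equal(ratio_mean_limit(ratio_pair("H", tk))$value,
                     rational(2 * k^2 - 2 * k - 1))
    expect_rat_equal(ratio_mean_limit(ratio_pair("E", tk))$value,
                     rational(2 * k * (k - 1)))
    expect_rat_equal(ratio_var_limit(ratio_pair("E", tk))$value,
                     rational(k^2 * (k - 1)^2))
    # numeric agreement with the finite-n composition at large n
    for (f in list(c(ratio_mean_limit, ratio_mean_approx),
                   c(ratio_var_limit, ratio_var_approx))) {
      p <- ratio_pair("B", tk)
      expect_equal(as.numeric(f[[1]](p)$value),
                   f[[2]](p, 1e6, exact = FALSE)$value, tolerance = 1e-3)
    }
  }
})
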