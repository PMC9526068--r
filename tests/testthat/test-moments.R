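test_that("tabulated mean examples hold exactly", {
  for (n in c(2, 5, 17)) expect_rat_equal(stat_mean("T2", n), rational(1))
  expect_rat_equal(stat_mean("E", 17), rational(2))
  expect_rat_equal(stat_mean("B", 4), rational("11/9"))
  expect_rat_equal(stat_mean("H", 2), rational(1))
  expect_rat_equal(stat_mean("L", 4), 2 * rational("11/6"))
})

test_that("tabulated variance examples hold exactly", {
  expect_rat_equal(stat_variance("T2", 5), rational(1))
  expect_rat_equal(stat_variance("E", 2), rational(4))
  expect_rat_equal(stat_variance("H", 2), rational(1))
})

test_that("height moments decompose over independent coalescence times", {
  # H = sum T_k with independent T_k, so its mean and variance are the sums
  for (n in c(2:12, 50, 120, 200)) {
    ks <- 2:n
    expect_rat_equal(stat_mean("H", n),
                     sum(c(rational(0),
                           sapply(ks, function(k)
                             unclass(stat_mean(tree_stat("T", k), n))))))
    expect_rat_equal(stat_variance("H", n),
                     sum(c(rational(0),
                           sapply(ks, function(k)
                             unclass(stat_variance(tree_stat("T", k), n))))))
  }
})

test_that("branch-length accounting: E[L] = E[E] + E[I] exactly", {
  for (n in c(3:40, 100, 200)) {
    expect_rat_equal(stat_mean("L", n),
                     stat_mean("E", n) + stat_mean("I", n))
  }
})

test_that("basal-branch mean equals its coalescence-time representation", {
  # E[B_n] = sum_k 2/(k(k-1)^2): the simplification holds in expectation
  for (n in c(4, 7, 30)) {
    s <- sum(c(rational(0), sapply(2:n, function(k)
      unclass(rational(2) / (rational(k) * rational(k - 1)^2)))))
    expect_rat_equal(stat_mean("B", n), s)
  }
})

test_that("mean height increases in n and stays below 2; mean length unbounded", {
  prev <- rational(0)
  for (n in 2:60) {
    m <- stat_mean("H", n)
    expect_true(m > prev)
    expect_true(m < rational(2))
    prev <- m
  }
  expect_true(stat_mean("L", 200) > stat_mean("L", 100))
  expect_gt(stat_mean("L", 1e6, exact = FALSE), 14)  # ~ 2 log n, unbounded
})

test_that("finite-n values approach the exact limits", {
  finite_mean <- c("H", "E", "B")
  for (kd in finite_mean) {
    expect_equal(stat_mean(kd, 1e6, exact = FALSE),
                 as.numeric(stat_mean_limit(kd)), tolerance = 1e-3)
  }
  for (kd in c("H", "L", "E", "I", "B")) {
    expect_equal(stat_variance(kd, 1e6, exact = FALSE),
                 as.numeric(stat_variance_limit(kd)), tolerance = 1e-3)
  }
  expect_true(is_divergent(stat_mean_limit("L")))
  expect_true(is_divergent(stat_mean_limit("I")))
})

test_that("limit constants match their printed 5-decimal renderings", {
  expect_decimal(as.numeric(stat_mean_limit("B")), 1.28987)
  expect_decimal(as.numeric(stat_variance_limit("H")), 1.15947)
  expect_decimal(as.numeric(stat_variance_limit("L")), 6.57974)
  expect_decimal(as.numeric(stat_variance_limit("B")), 1.04637)
})

test_that("validity domains are enforced", {
  expect_error(stat_mean("B", 3), "n >= 4")
  expect_error(stat_mean("I", 2), "n >= 3")
  expect_error(stat_mean(tree_stat("T", 5), 4), "n >= 5")
  expect_error(stat_mean("H", 1), "n")
  expect_error(tree_stat("H", k = 3), "only meaningful")
  expect_error(tree_stat("T", k = 1), "k")
})

test_that("exact and numeric moment paths agree at moderate n", {
  for (kd in c("H", "L", "E", "I", "B")) {
    expect_equal(stat_mean(kd, 37, exact = FALSE),
                 as.numeric(stat_mean(kd, 37)), tolerance = 1e-12)
    expect_equal(stat_variance(kd, 37, exact = FALSE),
                 as.numeric(stat_variance(kd, 37)), tolerance = 1e-12)
  }
})
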