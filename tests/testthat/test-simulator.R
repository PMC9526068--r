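test_that("identical seed and replicate give identical trees", {
  a <- simulate_tree(10, seed = 123, replicate = 5)
  b <- simulate_tree(10, seed = 123, replicate = 5)
  expect_identical(a$times, b$times)
  expect_identical(a$merges, b$merges)
  d <- simulate_tree(10, seed = 124, replicate = 5)
  expect_false(identical(a$times, d$times))
})

test_that("two leaves force the only possible topology", {
  tr <- simulate_tree(2, seed = 99)
  st <- tree_statistics(tr, basal_always = TRUE)
  t2 <- tr$times[1]
  expect_equal(st$H, t2)
  expect_equal(st$L, 2 * t2)
  expect_equal(st$E, 2 * t2)
  expect_equal(st$I, 0)
  expect_equal(st$B, t2)      # both basal branches are the leaf branches
  expect_true(is.na(tree_statistics(tr)$B))  # undefined by default at n = 2
})

test_that("statistics of hand-built genealogies match hand computation", {
  # n = 3: leaves a=1,b=2 merge first (node 4), then 4 with 3 (root 5)
  tr3 <- hand_tree(3, times = c(0.2, 0.5),
                   merges = rbind(c(1L, 2L), c(4L, 3L)))
  st <- tree_statistics(tr3, basal_always = TRUE)
  expect_equal(st$H, 0.7)
  expect_equal(st$L, 1.6)
  expect_equal(st$E, 1.1)
  expect_equal(st$I, 0.5)
  expect_equal(unname(st$T), c(0.5, 0.2))
  expect_equal(st$B, mean(c(0.5, 0.7)))  # basal: node 4 at 0.2, leaf 3 at 0

  # n = 4: (1,2) -> 5, (3,4) -> 6, (5,6) -> root 7
  tr4 <- hand_tree(4, times = c(0.1, 0.2, 0.3),
                   merges = rbind(c(1L, 2L), c(3L, 4L), c(5L, 6L)))
  st4 <- tree_statistics(tr4)
  expect_equal(st4$H, 0.6)
  expect_equal(st4$L, 1.6)
  expect_equal(st4$E, 0.8)
  expect_equal(st4$I, 0.8)
  expect_equal(st4$B, mean(c(0.6 - 0.1, 0.6 - 0.3)))  # 0.5 and 0.3
})

test_that("per-tree identities hold on simulated genealogies", {
  for (i in 1:40) {
    n <- sample(c(2:8, 20), 1)
    tr <- simulate_tree(n, seed = 7, replicate = i)
    st <- tree_statistics(tr, basal_always = TRUE)
    k <- seq(n, 2)
    expect_equal(st$H, sum(tr$times), tolerance = 1e-12)
    expect_equal(st$L, sum(k * tr$times), tolerance = 1e-12)
    expect_equal(st$I, st$L - st$E, tolerance = 1e-12)
    expect_true(st$E >= 0 && st$I >= -1e-12 && st$B >= 0)
    # root has exactly two children, recorded by the final merge
    expect_identical(length(tr$merges[n - 1, ]), 2L)
    # node ages are nondecreasing along the event order
    expect_true(all(diff(tr$node_age[(n + 1):(2 * n - 1)]) >= 0))
  }
})

test_that("batch statistics agree with single-tree statistics", {
  n <- 12
  sims <- simulate_tree_statistics(n, reps = 20, seed = 31)
  for (r in c(1, 7, 20)) {
    st <- tree_statistics(simulate_tree(n, seed = 31, replicate = r))
    expect_equal(sims$H[r], st$H, tolerance = 1e-12)
    expect_equal(sims$E[r], st$E, tolerance = 1e-12)
    expect_equal(sims$B[r], st$B, tolerance = 1e-12)
    expect_equal(unname(unlist(sims[r, paste0("T", 2:n)])), unname(st$T),
                 tolerance = 1e-12)
  }
})

test_that("coalescence-time marginals recover their exponential moments", {
  n <- 10
  sims <- simulate_tree_statistics(n, reps = 2e4, seed = 5)
  for (k in 2:n) {
    exact <- 2 / (k * (k - 1))
    z <- mc_mean_z(sims, paste0("T", k), exact)
    expect_lt(abs(z), 4)
  }
  # E has expectation 2 at every n
  expect_lt(abs(mc_mean_z(sims, "E", 2)), 4)
})

test_that("empirical ratio moments are deterministic and exact for H/L at n=2", {
  em <- empirical_ratio_moments("H", "L", n = 2, reps = 1000, seed = 7)
  expect_equal(em$mean, 0.5, tolerance = 1e-15)
  expect_equal(em$variance, 0, tolerance = 1e-15)
  a <- empirical_ratio_moments("E", "H", n = 20, reps = 500, seed = 42)
  b <- empirical_ratio_moments("E", "H", n = 20, reps = 500, seed = 42)
  expect_identical(a$mean, b$mean)
  expect_identical(a$variance, b$variance)
  expect_equal(a$se_mean, sqrt(a$variance / a$reps))
  expect_error(empirical_ratio_moments("B", "H", n = 3, reps = 100, seed = 1))
})

test_that("newick output is well formed and round-trips through ape", {
  tr <- hand_tree(2, times = 0.5, merges = rbind(c(1L, 2L)))
  expect_identical(write_newick(tr), "(1:0.5,2:0.5);")
  skip_if_not_installed("ape")
  for (n in c(4, 9)) {
    tr <- simulate_tree(n, seed = 77, replicate = n)
    ph <- ape::read.tree(text = write_newick(tr))
    expect_identical(ape::Ntip(ph), as.integer(n))
    st <- tree_statistics(tr)
    expect_equal(sum(ph$edge.length), st$L, tolerance = 1e-9)
    expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  }
})
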