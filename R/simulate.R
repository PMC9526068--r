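#' Simulate a Kingman coalescent genealogy
#'
#' Draws one random genealogy of `n` leaves under the standard constant-size
#' coalescent: while `k` lineages are active the waiting time to the next
#' coalescence is exponential with rate \eqn{k(k-1)/2} (time in units of `N`
#' generations) and the merging pair is uniform over the unordered pairs.
#'
#' Randomness is fully determined by `(n, seed, replicate)`: each replicate
#' draws from its own counter-derived stream, so replicate `r` of a large
#' run can be regenerated in isolation and runs can be chunked without
#' changing results.
#'
#' @param n Number of leaves, `n >= 2`.
#' @param seed Integer seed.
#' @param replicate Replicate index within the seed's stream (default 1).
#' @return An object of class `"coal_tree"`: list with `n`, `times` (the
#'   waiting times `T_n, ..., T_2`, in that order), `merges` (an
#'   `(n-1) x 2` matrix of child node ids; leaves are `1..n`, internal
#'   nodes `n+1 .. 2n-1` in coalescence order, the root is `2n-1`), and
#'   `node_age` (ages of all `2n-1` nodes, leaves at 0).
#' @examples
#' tr <- simulate_tree(5, seed = 42)
#' tree_statistics(tr)
#' @export
simulate_tree <- function(n, seed, replicate = 1) {
  check_count(n, "n", min = 2)
  check_count(seed, "seed", min = -2^31 + 1)
  check_count(replicate, "replicate", min = 1)
  out <- .sim_tree(as.integer(n), as.integer(seed), as.integer(replicate))
  structure(out, class = "coal_tree")
}

#' @export
print.coal_tree <- function(x, ...) {
  cat("<coalescent genealogy> n = ", x$n,
      ", height = ", format(sum(x$times), digits = 6),
      " (coalescent units)\n", sep = "")
  invisible(x)
}

#' Summary statistics of one genealogy
#'
#' Computes the per-tree values of the six summaries from the topology and
#' waiting times of a [simulate_tree()] genealogy (or any object with the
#' same structure): height `H`, total length `L`, external length `E`
#' (each leaf's branch up to its first coalescence), internal length
#' `I = L - E`, mean basal branch length `B` (the two branches incident to
#' the root), and the waiting times `T_k`.
#'
#' `B` is reported only for `n >= 4` by default, matching its moment
#' theory; `basal_always = TRUE` computes it for smaller trees anyway.
#'
#' @param tree A `"coal_tree"`.
#' @param basal_always Compute `B` even for `n < 4` (default `FALSE`,
#'   reporting `NA`).
#' @return A list with elements `H`, `L`, `E`, `I`, `B`, and `T` (named
#'   vector `T2..Tn`).
#' @export
tree_statistics <- function(tree, basal_always = FALSE) {
  if (!all(c("n", "times", "merges", "node_age") %in% names(tree))) {
    stop("malformed tree: expected fields n, times, merges, node_age")
  }
  n <- tree$n
  times <- tree$times
  if (length(times) != n - 1 || nrow(tree$merges) != n - 1) {
    stop("malformed tree: expected n - 1 waiting times and merge events")
  }
  if (any(times < 0)) stop("malformed tree: negative waiting time")
  k <- seq(n, 2)
  H <- sum(times)
  L <- sum(k * times)

  # parent of each node, from the merge record
  parent <- rep(NA_integer_, 2 * n - 1)
  for (j in seq_len(n - 1)) {
    parent[tree$merges[j, ]] <- n + j
  }
  if (any(is.na(parent[seq_len(2 * n - 2)]))) {
    stop("malformed tree: some non-root node has no parent")
  }
  E <- sum(tree$node_age[parent[seq_len(n)]])
  root <- 2 * n - 1
  root_children <- tree$merges[n - 1, ]
  B <- if (n >= 4 || basal_always) {
    mean(tree$node_age[root] - tree$node_age[root_children])
  } else {
    NA_real_
  }
  Tk <- rev(times)
  names(Tk) <- paste0("T", 2:n)
  list(H = H, L = L, E = E, I = L - E, B = B, T = Tk)
}

#' Batch simulation of tree summary statistics
#'
#' Simulates `reps` independent genealogies of `n` leaves and returns the
#' per-tree summaries as a data frame with columns `H`, `L`, `E`, `I`, `B`
#' and `T2 ... Tn`. This is the workhorse for Monte-Carlo validation of the
#' moment and ratio formulas; one batch serves every pair of summaries.
#'
#' @inheritParams simulate_tree
#' @param reps Number of replicate genealogies, `>= 1`.
#' @param basal_always Compute `B` even for `n < 4`.
#' @return A data frame with `reps` rows.
#' @examples
#' s <- simulate_tree_statistics(5, reps = 100, seed = 1)
#' colMeans(s[, c("H", "L", "E", "I", "B")])
#' @export
simulate_tree_statistics <- function(n, reps, seed, basal_always = FALSE) {
  check_count(n, "n", min = 2)
  check_count(reps, "reps", min = 1)
  check_count(seed, "seed", min = -2^31 + 1)
  m <- .sim_stats(as.integer(n), as.integer(reps), as.integer(seed),
                  isTRUE(basal_always))
  as.data.frame(m)
}

#' Monte-Carlo moments of a ratio of tree summaries
#'
#' Simulates `reps` genealogies, forms the per-tree ratio of the two
#' summaries, and returns its sample mean and variance with standard
#' errors. Reproducible: the same `(n, reps, seed)` always returns the
#' same estimates.
#'
#' @param x,y [tree_stat()] objects or labels; the ratio is `x / y`
#'   per tree.
#' @param n Sample size within the joint validity domain.
#' @param reps Number of replicates, `>= 2`.
#' @param seed Integer seed.
#' @return An object of class `"empirical_moments"`: list with `mean`,
#'   `variance`, `se_mean`, `se_variance`, `reps`, `seed`, `n`, and the
#'   pair labels. `se_variance` is the large-sample standard error of the
#'   sample variance, \eqn{\sqrt{(m_4 - m_2^2)/reps}}.
#' @examples
#' empirical_ratio_moments("H", "L", n = 2, reps = 500, seed = 7)$mean  # 0.5
#' @export
empirical_ratio_moments <- function(x, y, n, reps, seed) {
  x <- as_tree_stat(x); y <- as_tree_stat(y)
  n <- check_stat_n(x, n)
  n <- check_stat_n(y, n)
  check_count(reps, "reps", min = 2)
  sims <- simulate_tree_statistics(n, reps, seed)
  r <- stat_column(sims, x) / stat_column(sims, y)
  empirical_summary(r, reps, seed, n,
                    paste0(stat_label(x), "/", stat_label(y)))
}

stat_column <- function(sims, stat) {
  sims[[stat_label(stat)]]
}

empirical_summary <- function(v, reps, seed, n, label) {
  m <- mean(v)
  s2 <- stats::var(v)
  m4 <- mean((v - m)^4)
  m2 <- mean((v - m)^2)
  structure(list(mean = m, variance = s2,
                 se_mean = sqrt(s2 / reps),
                 se_variance = sqrt(max(m4 - m2^2, 0) / reps),
                 reps = reps, seed = seed, n = n, label = label),
            class = "empirical_moments")
}

#' @export
print.empirical_moments <- function(x, ...) {
  cat("<Monte-Carlo moments> ", x$label, " at n = ", x$n,
      " (", x$reps, " replicates, seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  mean     %.5f  (se %.2g)\n", x$mean, x$se_mean))
  cat(sprintf("  variance %.5f  (se %.2g)\n", x$variance, x$se_variance))
  invisible(x)
}

#' Write a genealogy in Newick format
#'
#' Serialises a [simulate_tree()] genealogy to a one-line Newick string
#' with branch lengths in coalescent units, leaves labelled `1..n`, no
#' internal-node labels, terminated by `";"`.
#'
#' @param tree A `"coal_tree"`.
#' @param file Optional path; when given the string is written there.
#' @param digits Significant digits for branch lengths (default 12).
#' @return The Newick string, invisibly when `file` is given.
#' @examples
#' write_newick(simulate_tree(4, seed = 1))
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  n <- tree$n
  children <- vector("list", 2 * n - 1)
  for (j in seq_len(n - 1)) {
    children[[n + j]] <- tree$merges[j, ]
  }
  age <- tree$node_age
  render <- function(node, parent_age) {
    bl <- sprintf("%.*g", digits, parent_age - age[node])
    if (node <= n) return(paste0(node, ":", bl))
    kids <- vapply(children[[node]], render, character(1),
                   parent_age = age[node])
    paste0("(", paste(kids, collapse = ","), "):", bl)
  }
  root <- 2 * n - 1
  kids <- vapply(children[[root]], render, character(1),
                 parent_age = age[root])
  s <- paste0("(", paste(kids, collapse = ","), ");")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}
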