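#' Tree summary statistics of a coalescent genealogy
#'
#' Identifies one of the six summaries of a genealogy with `n` leaves:
#'
#' * `"H"` -- tree height (time to the most recent common ancestor),
#'   \eqn{H_n = \sum_{k=2}^n T_k}; defined for `n >= 2`.
#' * `"L"` -- total branch length, \eqn{L_n = \sum_{k=2}^n k T_k};
#'   `n >= 2`.
#' * `"E"` -- total length of external branches (leaf to first
#'   coalescence); `n >= 2`.
#' * `"I"` -- total length of internal branches, \eqn{I_n = L_n - E_n};
#'   `n >= 3`.
#' * `"B"` -- mean length of the two basal branches (those incident to
#'   the root); `n >= 4`.
#' * `"T"` -- the coalescence time \eqn{T_k} while `k` lineages are
#'   active, `2 <= k <= n`; requires the `k` argument.
#'
#' @param kind One of `"H"`, `"L"`, `"E"`, `"I"`, `"B"`, `"T"`.
#' @param k Level for `kind = "T"`; must be `NULL` otherwise.
#' @return An object of class `"tree_stat"`.
#' @examples
#' tree_stat("H")
#' tree_stat("T", k = 3)
#' @export
tree_stat <- function(kind, k = NULL) {
  kind <- match.arg(kind, c("H", "L", "E", "I", "B", "T"))
  if (kind == "T") {
    # a bare T (k = NULL) is allowed as a placeholder; the reporting
    # functions fill in concrete levels from their k_choices argument
    if (!is.null(k)) {
      check_count(k, "k", min = 2)
      k <- as.integer(k)
    }
  } else if (!is.null(k)) {
    stop("'k' is only meaningful for the coalescence-time statistic T")
  }
  structure(list(kind = kind, k = k), class = "tree_stat")
}

as_tree_stat <- function(x) {
  if (inherits(x, "tree_stat")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (grepl("^T[0-9]+$", x)) {
      return(tree_stat("T", k = as.integer(sub("^T", "", x))))
    }
    return(tree_stat(x))
  }
  stop("expected a tree_stat or a label like \"H\" or \"T3\"")
}

stat_label <- function(stat) {
  if (stat$kind == "T") paste0("T", stat$k) else stat$kind
}

#' @export
print.tree_stat <- function(x, ...) {
  desc <- c(H = "tree height", L = "total branch length",
            E = "total external branch length",
            I = "total internal branch length",
            B = "mean basal branch length", T = "coalescence time")
  cat("<tree statistic> ", stat_label(x), ": ", desc[[x$kind]], "\n", sep = "")
  invisible(x)
}

#' Smallest sample size for which a statistic is defined
#'
#' H, L and E are defined for `n >= 2`, I for `n >= 3`, B for `n >= 4`,
#' and T(k) for `n >= k`.
#'
#' @param stat A [tree_stat()] (or label).
#' @return An integer.
#' @export
stat_min_n <- function(stat) {
  stat <- as_tree_stat(stat)
  if (stat$kind == "T" && is.null(stat$k)) {
    stop("the coalescence-time statistic needs a concrete level k")
  }
  switch(stat$kind, H = 2L, L = 2L, E = 2L, I = 3L, B = 4L, T = stat$k)
}

check_stat_n <- function(stat, n) {
  check_count(n, "n", min = 2)
  lo <- stat_min_n(stat)
  if (n < lo) {
    stop(stat_label(stat), " is not defined for n = ", n,
         " (needs n >= ", lo, ")", call. = FALSE)
  }
  invisible(as.integer(n))
}
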