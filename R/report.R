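#' Tabulate moments of the tree summaries over a range of sample sizes
#'
#' Builds a data frame with one row per sample size and columns for the
#' mean and variance of each of H, L, E, I, B (cells outside a statistic's
#' validity domain are `NA`), followed by a limit row (`n = Inf`) holding
#' the exact large-sample limits rendered as doubles (`Inf` where the
#' limit diverges).
#'
#' @param n_range Integer vector of sample sizes (each `>= 2`).
#' @param exact Use exact rational arithmetic internally (values are
#'   rendered to doubles either way). `exact = FALSE` is faster for large
#'   `n`.
#' @return A data frame.
#' @examples
#' build_moment_table(2:5)
#' @export
build_moment_table <- function(n_range, exact = TRUE) {
  n_range <- check_n_range(n_range)
  kinds <- c("H", "L", "E", "I", "B")
  rows <- lapply(n_range, function(n) {
    vals <- lapply(kinds, function(kd) {
      if (n < stat_min_n(kd)) {
        c(NA_real_, NA_real_)
      } else {
        c(exact_value(stat_mean(kd, n, exact = exact)),
          exact_value(stat_variance(kd, n, exact = exact)))
      }
    })
    c(n = n, unlist(vals))
  })
  lim <- c(n = Inf, unlist(lapply(kinds, function(kd) {
    c(exact_value(stat_mean_limit(kd)), exact_value(stat_variance_limit(kd)))
  })))
  out <- as.data.frame(do.call(rbind, c(rows, list(lim))))
  names(out) <- c("n", as.vector(t(outer(kinds, c("mean", "var"), paste,
                                         sep = "_"))))
  out
}

#' Tabulate the delta-method ratio approximations
#'
#' One row per combination of pair, sample size (and `k` for pairs with a
#' coalescence time), with the approximate mean and variance of the ratio
#' and the approximate-covariance flag; rows outside a pair's validity
#' domain are dropped. A final limit row (`n = Inf`) is added per pair
#' (and per `k`) for canonical orientations, with divergent limits
#' rendered as `Inf`.
#'
#' @param pairs A list of [ratio_pair()] objects, or character labels like
#'   `"E/H"` (use `"T"` with `k_choices`, e.g. `"L/T"`).
#' @param n_range Integer vector of sample sizes.
#' @param k_choices Levels `k` to use for pairs involving `T` (default 2).
#' @param exact Use exact rational arithmetic internally.
#' @return A data frame with columns `pair`, `n`, `k`, `approx_mean`,
#'   `approx_var`, `approx_cov_flag`.
#' @examples
#' build_ratio_table(list(ratio_pair("E", "H")), n_range = c(5, 10))
#' @export
build_ratio_table <- function(pairs, n_range, k_choices = 2, exact = TRUE) {
  n_range <- check_n_range(n_range)
  pairs <- lapply(pairs, as_ratio_pair)
  rows <- list()
  for (p0 in pairs) {
    for (pp in expand_t(p0, k_choices)) {
      lab <- paste0(stat_label(pp$num), "/", stat_label(pp$den))
      kv <- if (is.null(t_level(pp))) NA_integer_ else t_level(pp)
      any_valid <- FALSE
      for (n in n_range) {
        if (n < ratio_min_n(pp)) next
        if (mean_vanishes(pp$den, n)) next
        m <- ratio_mean_approx(pp, n, exact = exact)
        v <- ratio_var_approx(pp, n, exact = exact)
        any_valid <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          pair = lab, n = n, k = kv,
          approx_mean = exact_value(m$value),
          approx_var = exact_value(v$value),
          approx_cov_flag = m$approximate)
      }
      if (!any_valid) {
        stop("pair ", lab, " is not valid anywhere in the requested n range")
      }
      if (ratio_is_canonical(pp)) {
        ml <- ratio_mean_limit(pp); vl <- ratio_var_limit(pp)
        rows[[length(rows) + 1]] <- data.frame(
          pair = lab, n = Inf, k = kv,
          approx_mean = exact_value(ml$value),
          approx_var = exact_value(vl$value),
          approx_cov_flag = ml$approximate)
      }
    }
  }
  do.call(rbind, rows)
}

#' Compare delta-method approximations with coalescent simulations
#'
#' For each pair and sample size, computes the approximate mean and
#' variance of the ratio and the Monte-Carlo estimates from `reps`
#' simulated genealogies (one simulation batch per sample size serves all
#' pairs). Every record carries the seed and replicate count needed to
#' regenerate it bit-identically.
#'
#' @inheritParams build_ratio_table
#' @param reps Replicates per sample size (`>= 2`). The study-scale choice
#'   is 100,000 replicates per tree size.
#' @param seed Integer seed.
#' @return A data frame with approximate and empirical moments, standard
#'   errors, and metadata.
#' @examples
#' compare_simulation(list(ratio_pair("H", "L")), n_range = c(5, 10),
#'                    reps = 200, seed = 1)
#' @export
compare_simulation <- function(pairs, n_range, reps = 1e5, seed = 1,
                               k_choices = 2, exact = FALSE) {
  n_range <- check_n_range(n_range)
  check_count(reps, "reps", min = 2)
  pairs <- lapply(pairs, as_ratio_pair)
  rows <- list()
  for (n in n_range) {
    sims <- simulate_tree_statistics(n, reps, seed)
    for (p0 in pairs) {
      for (pp in expand_t(p0, k_choices)) {
        if (n < ratio_min_n(pp) || mean_vanishes(pp$den, n)) next
        m <- ratio_mean_approx(pp, n, exact = exact)
        v <- ratio_var_approx(pp, n, exact = exact)
        r <- stat_column(sims, pp$num) / stat_column(sims, pp$den)
        emp <- empirical_summary(r, reps, seed, n, "")
        rows[[length(rows) + 1]] <- data.frame(
          pair = paste0(stat_label(pp$num), "/", stat_label(pp$den)),
          n = n, k = if (is.null(t_level(pp))) NA_integer_ else t_level(pp),
          approx_mean = exact_value(m$value),
          approx_var = exact_value(v$value),
          empirical_mean = emp$mean, empirical_var = emp$variance,
          se_mean = emp$se_mean, se_var = emp$se_variance,
          reps = reps, seed = seed,
          approx_cov_flag = m$approximate)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write records as delimited text
#'
#' Writes a data frame to UTF-8 delimited text with a header row. Floats
#' are rounded to `digits` decimals by default; `exact` columns of
#' rational strings (`"p/q"`) pass through untouched. A `#`-prefixed
#' comment header recording metadata (e.g. seed and replicates) can be
#' included for reproducibility.
#'
#' @param records A nonempty data frame.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param digits Decimal places for numeric columns (default 5);
#'   `NULL` writes full precision.
#' @param comments Character vector of metadata lines to prepend, each
#'   written as `# line`.
#' @return `path`, invisibly.
#' @export
write_delimited <- function(records, path, delim = ",", digits = 5,
                            comments = NULL) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("'records' must be a nonempty data frame")
  }
  out <- records
  if (!is.null(digits)) {
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], round, digits = digits)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(paste("#", comments), con)
  }
  utils::write.table(out, con, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read records written by [write_delimited()]
#'
#' @param path Input path.
#' @param delim Field delimiter.
#' @return A data frame (comment lines are skipped).
#' @export
read_delimited <- function(path, delim = ",") {
  utils::read.table(path, header = TRUE, sep = delim, comment.char = "#",
                    stringsAsFactors = FALSE)
}

check_n_range <- function(n_range) {
  if (length(n_range) == 0) stop("empty sample-size range")
  if (!is.numeric(n_range) || any(n_range != floor(n_range) | n_range < 2)) {
    stop("sample sizes must be integers >= 2")
  }
  as.integer(n_range)
}

as_ratio_pair <- function(p) {
  if (inherits(p, "ratio_pair")) return(p)
  if (is.character(p) && length(p) == 1 && grepl("/", p, fixed = TRUE)) {
    parts <- strsplit(p, "/", fixed = TRUE)[[1]]
    return(ratio_pair(parts[1], parts[2]))
  }
  stop("expected a ratio_pair or a label like \"E/H\"")
}

# replace a bare "T" (no k) in a pair by concrete levels
expand_t <- function(pair, k_choices) {
  fill <- function(stat, k) {
    if (stat$kind == "T" && is.null(stat$k)) tree_stat("T", k) else stat
  }
  has_bare_t <- (pair$num$kind == "T" && is.null(pair$num$k)) ||
                (pair$den$kind == "T" && is.null(pair$den$k))
  if (!has_bare_t) return(list(pair))
  lapply(k_choices, function(k) {
    ratio_pair(fill(pair$num, k), fill(pair$den, k))
  })
}

# denominator means that vanish: only I at n = 2 among the supported stats
mean_vanishes <- function(stat, n) {
  stat$kind == "I" && n == 2
}
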