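# log multivariate-hypergeometric probability of a table given fixed margins:
# log P = sum lgamma(r_i + 1) + sum lgamma(c_j + 1) - lgamma(N + 1) - sum lgamma(n_ij + 1)
log_table_prob <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1) - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, calling visit(tab) on
# each; aborts (returning FALSE) if more than max_tables are visited
enumerate_tables <- function(row_margins, col_margins, visit, max_tables = 2e5) {
  r <- length(row_margins); c <- length(col_margins)
  tab <- matrix(0L, r, c)
  count <- 0L
  fill_row <- function(i, col_left) {
    if (count > max_tables) return(FALSE)
    if (i == r) {
      # last row forced by remaining column margins
      if (any(col_left < 0)) return(TRUE)
      tab[r, ] <<- col_left
      count <<- count + 1L
      if (count > max_tables) return(FALSE)
      visit(tab)
      return(TRUE)
    }
    fill_cell <- function(j, row_left, col_left) {
      if (j == c) {
        if (row_left > col_left[c]) return(TRUE)
        tab[i, c] <<- row_left
        col_left[c] <- col_left[c] - row_left
        return(fill_row(i + 1L, col_left))
      }
      hi <- min(row_left, col_left[j])
      for (v in 0:hi) {
        tab[i, j] <<- v
        col_left2 <- col_left; col_left2[j] <- col_left2[j] - v
        if (!fill_cell(j + 1L, row_left - v, col_left2)) return(FALSE)
      }
      TRUE
    }
    fill_cell(1L, row_margins[i], col_left)
  }
  fill_row(1L, col_margins)
}

# crude upper bound on the number of tables: product over free cells of
# (min(row, col) + 1); used only to pick exact vs Monte Carlo under "auto"
enumeration_bound <- function(row_margins, col_margins) {
  r <- length(row_margins); c <- length(col_margins)
  b <- 1
  for (i in seq_len(r - 1)) for (j in seq_len(c - 1)) {
    b <- b * (min(row_margins[i], col_margins[j]) + 1)
    if (b > 1e15) return(b)
  }
  b
}

#' Fisher's exact test for r x c contingency tables
#'
#' Tests independence of the two classifications of a contingency table by
#' summing multivariate-hypergeometric probabilities, conditional on the
#' observed margins, over all tables whose probability does not exceed that
#' of the observed table (within relative tolerance 1e-7). Small problems are
#' fully enumerated; larger ones fall back to Monte-Carlo sampling of
#' margin-conditioned tables (Patefield's algorithm via [stats::r2dtable()]),
#' with `n_reps` and `seed` recorded in the result. Rows and columns whose
#' margin is zero are dropped with a warning before testing.
#'
#' @param table Matrix of non-negative integer counts, at least 2 x 2 after
#'   dropping empty margins.
#' @param method `"auto"` (enumerate when the total count is <= 200 and the
#'   free-cell bound on the number of tables is small, else Monte Carlo),
#'   `"exact"`, or `"monte_carlo"`.
#' @param n_reps Monte-Carlo replicates.
#' @param seed Integer seed for the Monte-Carlo path (required there for
#'   reproducibility; ignored by the exact path).
#' @return A `"gr_test"` with `statistic_name = "p"` and `method` recording
#'   which route ran.
#' @examples
#' fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, 2))
#' @export
fisher_exact_rxc <- function(table, method = c("auto", "exact", "monte_carlo"),
                             n_reps = 100000, seed = NULL) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != floor(tab))) stop("counts must be non-negative integers")
  dropped_margin <- FALSE
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns")
    dropped_margin <- TRUE
    tab <- tab[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need at least 2 x 2 after dropping empty margins")
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  lp_obs <- log_table_prob(tab)
  tol <- log1p(1e-7)

  if (method == "auto") {
    method <- if (N <= 200 && enumeration_bound(rs, cs) <= 2e5) "exact" else "monte_carlo"
  }
  if (method == "exact") {
    acc <- 0
    ok <- enumerate_tables(rs, cs, function(t) {
      lp <- log_table_prob(t)
      if (lp <= lp_obs + tol) acc <<- acc + exp(lp)
    })
    if (!isTRUE(ok)) stop("enumeration bound exceeded; use method = \"monte_carlo\"")
    p <- min(1, acc)
    res <- new_test_result("Fisher's exact test (r x c)", "p", p, p_value = p,
                           method = "exact",
                           sample_sizes = N,
                           extra = list(table = tab, dropped_margin = dropped_margin))
  } else {
    if (is.null(seed)) stop("seed is required for the Monte-Carlo method")
    hits <- local_seed(seed, {
      sims <- stats::r2dtable(n_reps, rs, cs)
      sum(vapply(sims, function(t) log_table_prob(t) <= lp_obs + tol, logical(1)))
    })
    p <- (hits + 1) / (n_reps + 1)
    res <- new_test_result("Fisher's exact test (r x c)", "p", p, p_value = p,
                           method = "monte_carlo", n_reps = n_reps, seed = seed,
                           sample_sizes = N,
                           extra = list(table = tab, dropped_margin = dropped_margin))
  }
  res
}

# evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
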