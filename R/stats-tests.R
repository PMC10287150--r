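as_group_list <- function(samples) {
  if (!is.list(samples)) stop("samples must be a list of numeric vectors")
  if (is.null(names(samples))) names(samples) <- paste0("group", seq_along(samples))
  if (length(samples) < 2) stop("need at least 2 groups")
  if (any(vapply(samples, length, 1L) == 0)) stop("every group must be non-empty")
  lapply(samples, function(v) {
    if (any(!is.finite(v))) stop("values must be finite")
    as.numeric(v)
  })
}

#' Kruskal-Wallis rank-sum test with tie correction
#'
#' Tests whether k independent groups come from the same distribution, using
#' the rank-sum statistic
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_j R_j^2/n_j - 3(N+1)}
#'            {1 - \sum (t^3 - t) / (N^3 - N)}}
#' where \eqn{R_j} are pooled mid-rank sums and the denominator corrects for
#' tie groups of size \eqn{t}. The p-value uses the upper chi-square tail at
#' \eqn{k - 1} degrees of freedom for all k and n (the convention of the
#' survey's statistics environment; no exact small-sample tables).
#'
#' @param samples List of k >= 2 non-empty numeric vectors (names become
#'   group labels).
#' @return A `"gr_test"` with `statistic_name = "H"`, `df = k - 1`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
kruskal_wallis <- function(samples) {
  samples <- as_group_list(samples)
  pooled <- unlist(samples, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    stop("degenerate input: all values identical (tie correction denominator is 0)")
  }
  rk <- midranks(pooled)
  N <- rk$N
  sizes <- vapply(samples, length, 1L)
  grp <- rep(seq_along(samples), sizes)
  R <- vapply(split(rk$midranks, grp), sum, numeric(1))
  H_raw <- 12 / (N * (N + 1)) * sum(R^2 / sizes) - 3 * (N + 1)
  correction <- 1 - tie_term(rk$tie_groups) / (N^3 - N)
  H <- H_raw / correction
  df <- length(samples) - 1L
  new_test_result("Kruskal-Wallis rank sum test", "H", H,
                  p_value = chi_square_upper_tail(max(H, 0), df),
                  df = df, method = "chi2_approx",
                  group_labels = names(samples), sample_sizes = sizes,
                  tie_correction_applied = length(rk$tie_groups) > 0)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z-tests on pooled mean mid-ranks after a significant
#' Kruskal-Wallis test, with the tie-corrected variance
#' \eqn{[N(N+1)/12 - \sum(t^3 - t) / (12(N-1))](1/n_i + 1/n_j)}.
#' The sign convention is first group minus second group mean rank, so
#' `z(a, b) = -z(b, a)`. Unadjusted p-values are two-sided normal tails;
#' Bonferroni multiplies by `m = k(k-1)/2` and caps at 1.
#'
#' @param samples List of k >= 2 non-empty numeric vectors; the pooled
#'   ranking is shared by every comparison.
#' @param adjustment Only `"bonferroni"` is implemented.
#' @return Data frame of class `"gr_dunn"` with columns `group_a`, `group_b`,
#'   `z`, `p_unadjusted`, `p_adjusted`, `m`.
#' @examples
#' dunn_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
dunn_posthoc <- function(samples, adjustment = c("bonferroni")) {
  adjustment <- match.arg(adjustment)
  samples <- as_group_list(samples)
  pooled <- unlist(samples, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    stop("degenerate input: all values identical")
  }
  rk <- midranks(pooled)
  N <- rk$N
  sizes <- vapply(samples, length, 1L)
  grp <- rep(seq_along(samples), sizes)
  mean_ranks <- vapply(split(rk$midranks, grp), mean, numeric(1))
  var_unit <- N * (N + 1) / 12 - tie_term(rk$tie_groups) / (12 * (N - 1))
  k <- length(samples)
  m <- k * (k - 1L) / 2L
  pairs <- utils::combn(k, 2)
  z <- vapply(seq_len(ncol(pairs)), function(c) {
    i <- pairs[1, c]; j <- pairs[2, c]
    (mean_ranks[i] - mean_ranks[j]) / sqrt(var_unit * (1 / sizes[i] + 1 / sizes[j]))
  }, numeric(1))
  p <- normal_two_sided_p(z)
  out <- data.frame(group_a = names(samples)[pairs[1, ]],
                    group_b = names(samples)[pairs[2, ]],
                    z = z, p_unadjusted = p,
                    p_adjusted = pmin(1, m * p), m = m,
                    stringsAsFactors = FALSE)
  class(out) <- c("gr_dunn", "data.frame")
  out
}

#' Mann-Whitney U test
#'
#' Two-sample rank test for a difference in distribution. Reports both names
#' of the same statistic: `U`, the number of (x, y) pairs with x > y (ties
#' counting 1/2), and `W`, the mid-rank sum of the first sample minus
#' `n1(n1+1)/2` (identical by construction; the value depends on which sample
#' comes first, and the two orientations are linked by `W + W' = n1*n2`).
#' The p-value is exact (full enumeration of the permutation null) when both
#' samples have at most 20 observations and there are no ties, otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction 0.5. The exact two-sided p doubles the smaller tail and caps
#' at 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact path;
#'   default `NULL` applies the rule above. Forcing `TRUE` with ties is an
#'   error.
#' @return A `"gr_test"` with `statistic_name = "W"` and extra fields `U`,
#'   `W` and `W_other` (the opposite orientation).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- midranks(c(x, y))
  has_ties <- length(rk$tie_groups) > 0
  R1 <- sum(rk$midranks[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) !has_ties && n1 <= 20 && n2 <= 20 else isTRUE(exact)
  if (use_exact && has_ties) stop("exact p-value is unavailable with ties")
  if (use_exact) {
    counts <- mw_count_distribution(n1, n2)
    total <- sum(counts)
    lower <- sum(counts[seq_len(U + 1)]) / total        # P(U <= u)
    upper <- sum(counts[(U + 1):(n1 * n2 + 1)]) / total # P(U >= u)
    p <- min(1, 2 * if (U > n1 * n2 / 2) upper else lower)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term(rk$tie_groups) / (N * (N - 1)))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- normal_two_sided_p(z)
    method <- "normal_approx"
  }
  new_test_result("Mann-Whitney U test", "W", U, p_value = p, method = method,
                  group_labels = c("x", "y"), sample_sizes = c(n1, n2),
                  tie_correction_applied = has_ties && method == "normal_approx",
                  extra = list(U = U, W = U, W_other = n1 * n2 - U))
}

# frequency of U = 0..n1*n2 over all labelings, two-sample DP:
# c(m, n, u) = c(m-1, n, u-n) + c(m, n-1, u)
mw_count_distribution <- function(n1, n2) {
  U <- n1 * n2
  # iterate over m (size of first sample); for each m, build counts over n
  prev_m <- matrix(0, nrow = n2 + 1, ncol = U + 1)
  prev_m[, 1] <- 1                       # m = 0: U = 0 for any n
  for (m in seq_len(n1)) {
    cur <- matrix(0, nrow = n2 + 1, ncol = U + 1)
    cur[1, 1] <- 1                       # n = 0: U = 0
    for (n in seq_len(n2)) {
      shifted <- c(rep(0, n), prev_m[n + 1, seq_len(U + 1 - n)])
      cur[n + 1, ] <- shifted + cur[n, ]
    }
    prev_m <- cur
  }
  prev_m[n2 + 1, ]
}

#' Kendall's tau-b rank correlation
#'
#' Rank correlation for paired samples with the tie-aware tau-b
#' normalization:
#' \deqn{\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}}}
#' with \eqn{n_0 = n(n-1)/2} and \eqn{n_1, n_2} the within-variable tie pair
#' counts, so perfectly monotone tied data still reach +/-1. The two-sided
#' p-value uses the normal approximation of `S = C - D` with the standard
#' tie-adjusted variance.
#'
#' @param x,y Paired numeric vectors, equal length n >= 2, each with at
#'   least two distinct values.
#' @return A `"gr_test"` with `statistic_name = "tau_b"` and extra fields
#'   `S`, `concordant`, `discordant`, `z`.
#' @examples
#' kendall_tau_b(c(1, 2, 3), c(3, 2, 1))
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be the same length")
  n <- length(x)
  if (n < 2) stop("need n >= 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("undefined correlation: constant variable")
  }
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  prod <- sx * sy
  up <- upper.tri(prod)
  S <- sum(prod[up])
  C <- sum(prod[up] > 0); D <- sum(prod[up] < 0)
  tx <- table(x); ty <- table(y)
  tx <- as.numeric(tx[tx >= 2]); ty <- as.numeric(ty[ty >= 2])
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau_b <- S / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2) {
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
  } else 0
  var_S <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(var_S)
  new_test_result("Kendall's tau-b rank correlation", "tau_b", tau_b,
                  p_value = normal_two_sided_p(z), method = "normal_approx",
                  sample_sizes = n,
                  tie_correction_applied = length(tx) > 0 || length(ty) > 0,
                  extra = list(S = S, concordant = C, discordant = D, z = z))
}
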