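# Independent oracles: first-principles implementations kept deliberately
# separate from the package's formulas. Everything here is brute force.

# ranks by explicit counting: rank_i = #{j: v_j < v_i} + (#{j: v_j == v_i} + 1)/2
oracle_ranks <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

# tie-corrected Kruskal-Wallis H via the variance-ratio identity
# H = (N - 1) * sum n_j (Rbar_j - Rbar)^2 / sum (r_i - Rbar)^2
oracle_kruskal_H <- function(groups) {
  v <- unlist(groups, use.names = FALSE)
  r <- oracle_ranks(v)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(v)
  rbar <- mean(r)
  num <- sum(vapply(seq_along(groups), function(j) {
    length(groups[[j]]) * (mean(r[g == j]) - rbar)^2
  }, numeric(1)))
  den <- sum((r - rbar)^2)
  (N - 1) * num / den
}

# Mann-Whitney U by pair counting (ties count 1/2)
oracle_U <- function(x, y) {
  sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
}

# exact two-sided Mann-Whitney p by enumerating all choose(n1+n2, n1)
# labelings; two-sided = double the smaller tail, capped at 1
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  us <- apply(idx, 2, function(sel) oracle_U(pooled[sel], pooled[-sel]))
  u_obs <- oracle_U(x, y)
  lower <- mean(us <= u_obs); upper <- mean(us >= u_obs)
  min(1, 2 * (if (u_obs > n1 * n2 / 2) upper else lower))
}

# Kendall tau-b by O(n^2) pair counting
oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx * dy > 0) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Fisher 2x2 p by direct enumeration of the hypergeometric support
oracle_fisher_2x2_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  prob_a <- function(a) {
    b <- rs[1] - a; c <- cs[1] - a; d <- rs[2] - c
    if (b < 0 || c < 0 || d < 0) return(0)
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(N) -
          sum(lfactorial(c(a, b, c, d))))
  }
  support <- 0:min(rs[1], cs[1])
  probs <- vapply(support, prob_a, numeric(1))
  p_obs <- prob_a(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random valid response block under the code book, uniform over each
# question's states (NA included where allowed)
random_responses <- function(n) {
  codes <- question_codes()
  out <- lapply(codes, function(q) {
    states <- c(q$allowed, if (q$na_ok) NA_integer_)
    states[sample.int(length(states), n, replace = TRUE)]
  })
  as.data.frame(out)
}

fixture_expected_gr <- c(5L, 2L, 0L, 4L, 3L, 3L, -2L, 0L, 0L, -1L, 2L, 1L)
fixture_expected_nmiss <- c(1L, 2L, 6L, 2L, 1L, 2L, 5L, 2L, 3L, 4L, 4L, 5L)
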