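test_that("midranks assigns mean occupied ranks and records tie groups", {
  expect_equal(midranks(c(10, 20, 30))$midranks, c(1, 2, 3))
  expect_length(midranks(c(10, 20, 30))$tie_groups, 0)
  r <- midranks(c(5, 5, 7))
  expect_equal(r$midranks, c(1.5, 1.5, 3))
  expect_equal(r$tie_groups, 2L)
  expect_equal(midranks(c(4, 4, 4, 4))$midranks, rep(2.5, 4))
  expect_equal(midranks(c(4, 4, 4, 4))$tie_groups, 4L)
  expect_error(midranks(numeric(0)), "empty")
  expect_error(midranks(c(1, NA)), "finite")
  # rank-sum invariant on random tied data
  set.seed(11)
  for (i in 1:20) {
    v <- sample(1:4, sample(2:30, 1), replace = TRUE)
    rk <- midranks(v)
    expect_equal(sum(rk$midranks), rk$N * (rk$N + 1) / 2)
    expect_true(sum(rk$tie_groups) <= rk$N)
  }
})

test_that("kruskal_wallis reproduces hand and reference values", {
  r <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(r$statistic, 27 / 7, tolerance = 1e-12)  # hand rank-sum evaluation
  expect_equal(r$df, 1)
  expect_false(r$tie_correction_applied)
  expect_equal(kruskal_wallis(list(c(1, 2), c(1, 2)))$statistic, 0)
  # equal rank sums across three groups of distinct pooled values
  r3 <- kruskal_wallis(list(c(1, 6, 8), c(2, 4, 9), c(3, 5, 7)))
  expect_equal(r3$statistic, 0, tolerance = 1e-12)
  expect_error(kruskal_wallis(list(c(1, 2))), "2 groups")
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "degenerate")
  # independent reference implementation, heavy ties
  set.seed(12)
  for (i in 1:25) {
    x <- sample(0:4, 40, replace = TRUE)
    g <- sample(1:3, 40, replace = TRUE)
    if (min(table(g)) == 0 || length(unique(x)) == 1) next
    mine <- kruskal_wallis(split(x, g))
    ref <- stats::kruskal.test(x, g)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_true(mine$tie_correction_applied)
  }
})

test_that("dunn_posthoc follows the pooled-rank z formula and Bonferroni", {
  d <- dunn_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # mean ranks 2 and 5; variance term 3.5 * (2/3)
  expect_equal(d$z, (2 - 5) / sqrt(3.5 * 2 / 3), tolerance = 1e-12)
  expect_equal(d$m, 1)
  d0 <- dunn_posthoc(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_adjusted, 1)
  # antisymmetry and p invariance under swapped group order
  set.seed(13)
  x <- sample(0:3, 30, TRUE); y <- sample(0:3, 25, TRUE); z <- sample(0:3, 20, TRUE)
  fwd <- dunn_posthoc(list(A = x, B = y, C = z))
  rev <- dunn_posthoc(list(B = y, A = x, C = z))
  ab_fwd <- fwd[fwd$group_a == "A" & fwd$group_b == "B", ]
  ba_rev <- rev[rev$group_a == "B" & rev$group_b == "A", ]
  expect_equal(ab_fwd$z, -ba_rev$z)
  expect_equal(ab_fwd$p_adjusted, ba_rev$p_adjusted)
  expect_equal(fwd$m, rep(3, 3))
  expect_true(all(fwd$p_adjusted >= fwd$p_unadjusted - 1e-15))
  expect_true(all(fwd$p_adjusted <= 1))
  expect_equal(pmin(1, 3 * fwd$p_unadjusted), fwd$p_adjusted)
})

test_that("with two untied groups H equals the squared Dunn z", {
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    H <- kruskal_wallis(list(x, y))$statistic
    z <- dunn_posthoc(list(x, y))$z
    expect_equal(H, z^2, tolerance = 1e-12)
  }
})

test_that("mann_whitney reports U/W and matches enumeration and reference", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(5, 1)$U, 1)
  m <- mann_whitney(c(1, 3), c(2, 4))
  expect_equal(m$U, 1)
  expect_equal(m$method, "exact")
  expect_equal(m$p_value, oracle_mw_exact_p(c(1, 3), c(2, 4)))
  expect_equal(m$p_value, 2 / 3)
  # W orientation bookkeeping: W + W_other = n1 * n2
  expect_equal(m$W + m$W_other, 4)
  # ties force the approximation; matches the reference with continuity correction
  set.seed(15)
  for (i in 1:20) {
    x <- sample(0:3, sample(5:25, 1), TRUE)
    y <- sample(0:3, sample(5:25, 1), TRUE)
    mine <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
    expect_equal(mine$W, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$method, "normal_approx")
  }
  # untied but large samples also take the approximation
  expect_equal(mann_whitney(rnorm(21), rnorm(5))$method, "normal_approx")
  expect_error(mann_whitney(c(1, 1, 2), c(2, 3), exact = TRUE), "ties")
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("kendall_tau_b matches pair-counting oracle and reference", {
  expect_equal(kendall_tau_b(c(1, 2, 3), c(1, 2, 3))$statistic, 1)
  expect_equal(kendall_tau_b(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  # perfectly monotone tied data still reaches 1 under tau-b
  expect_equal(kendall_tau_b(c(1, 1, 2, 3), c(2, 2, 5, 9))$statistic, 1)
  k <- kendall_tau_b(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_equal(k$statistic, oracle_tau_b(c(1, 1, 2, 3), c(1, 2, 2, 3)))
  expect_error(kendall_tau_b(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(kendall_tau_b(1, 2), "n >= 2")
  set.seed(16)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- sample(0:4, n, TRUE); y <- sample(0:4, n, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    mine <- kendall_tau_b(x, y)
    expect_equal(mine$statistic, oracle_tau_b(x, y), tolerance = 1e-12)
    expect_true(abs(mine$statistic) <= 1)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  # equals tau-a (and the exact reference) when no ties exist
  x <- c(3, 1, 4, 9, 2); y <- c(5, 8, 6, 10, 7)
  expect_equal(kendall_tau_b(x, y)$statistic,
               unname(stats::cor.test(x, y, method = "kendall")$estimate))
})

test_that("fisher_exact_rxc enumerates, falls back to Monte Carlo, drops empty margins", {
  t22 <- matrix(c(3, 1, 1, 3), 2, 2)
  f <- fisher_exact_rxc(t22)
  expect_equal(f$method, "exact")
  expect_equal(f$p_value, oracle_fisher_2x2_p(t22), tolerance = 1e-10)
  expect_equal(f$p_value, 0.4857143, tolerance = 1e-6)
  expect_equal(fisher_exact_rxc(matrix(c(2, 0, 0, 2), 2, 2))$p_value, 1 / 3,
               tolerance = 1e-12)
  # agreement with the reference implementation on an r x c toy
  t33 <- matrix(c(5, 2, 3, 1, 4, 2, 2, 2, 6), 3, 3)
  expect_equal(fisher_exact_rxc(t33)$p_value,
               stats::fisher.test(t33)$p.value, tolerance = 1e-9)
  # a zero row changes nothing once dropped
  t_aug <- rbind(t33, c(0, 0, 0))
  expect_warning(f_aug <- fisher_exact_rxc(t_aug), "zero-margin")
  expect_equal(f_aug$p_value, fisher_exact_rxc(t33)$p_value)
  # Monte-Carlo route is seeded, reproducible, and close to the exact value
  m1 <- fisher_exact_rxc(t33, method = "monte_carlo", n_reps = 20000, seed = 9)
  m2 <- fisher_exact_rxc(t33, method = "monte_carlo", n_reps = 20000, seed = 9)
  expect_equal(m1$p_value, m2$p_value)
  expect_equal(m1$method, "monte_carlo")
  expect_equal(m1$n_reps, 20000)
  expect_error(fisher_exact_rxc(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
  expect_error(fisher_exact_rxc(t33, method = "monte_carlo"), "seed")
})

test_that("tail distribution helpers satisfy their contracts", {
  expect_equal(chi_square_upper_tail(0, df = 3), 1)
  expect_equal(chi_square_upper_tail(2 * log(20), df = 2), 0.05, tolerance = 1e-12)
  expect_equal(chi_square_upper_tail(1.959964^2, df = 1), 0.05, tolerance = 1e-6)
  x <- seq(0, 20, by = 0.5)
  expect_true(all(diff(chi_square_upper_tail(x, df = 4)) < 0))
  expect_error(chi_square_upper_tail(1, df = 0), "df")
  expect_error(chi_square_upper_tail(-1, df = 1), "non-negative")

  expect_equal(normal_two_sided_p(0), 1)
  expect_equal(normal_two_sided_p(1.959964), 0.05, tolerance = 1e-6)
  expect_equal(normal_two_sided_p(-2.5), normal_two_sided_p(2.5))
  expect_error(normal_two_sided_p(Inf), "finite")
})
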