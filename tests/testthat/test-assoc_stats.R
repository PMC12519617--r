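test_that("spearman_test matches a brute-force mid-rank computation", {
  expect_equal(spearman_test(1:3, c(10, 20, 30))$r, 1)
  expect_equal(spearman_test(1:3, c(3, 2, 1))$r, -1)
  expect_equal(spearman_test(1:3, c(10, 20, 30))$p, 0)

  # 6-point vectors with ties; oracle does the ranking by hand
  x <- c(1, 2, 2, 4, 5, 6)
  y <- c(3, 3, 1, 6, 5, 4)
  midrank <- function(v) {
    vapply(v, function(a) sum(v < a) + (1 + sum(v == a)) / 2, numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  r_oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  res <- spearman_test(x, y)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_oracle <- r_oracle * sqrt(4 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)

  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
})

test_that("correlation_matrix is symmetric, self-correlated, and null-calibrated", {
  set.seed(31)
  vals <- matrix(rnorm(2000 * 8), 2000, 8,
                 dimnames = list(NULL, paste0("V", 1:8)))
  cm <- correlation_matrix(vals)
  expect_equal(unname(diag(cm$r)), rep(1, 8))
  expect_true(all(diag(cm$highlight)))
  expect_equal(cm$r, t(cm$r))
  # independent columns at n = 2000: very few highlighted off-diagonal pairs
  off <- cm$highlight[upper.tri(cm$highlight)]
  expect_lt(mean(off), 0.15)
})

test_that("kruskal_wallis reproduces the rank-sum hand computation", {
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(rep(4, 3), rep(4, 5)))$p, 1)

  # ranks 1..6: H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$H, 27 / 7, tolerance = 1e-12)
  expect_equal(res$df, 1L)

  # rank invariance: the statistic depends on data only through ranks
  set.seed(4)
  g <- list(rnorm(8), rnorm(6), rnorm(7))
  pooled_ranks <- rank(unlist(g))
  g_ranked <- split(pooled_ranks, rep(seq_along(g), lengths(g)))
  expect_equal(kruskal_wallis(g)$H, kruskal_wallis(g_ranked)$H, tolerance = 1e-12)
})

test_that("dunn_posthoc agrees with an exhaustive permutation oracle at tiny n", {
  groups <- list(a = c(1.2, 3.4, 2.2), b = c(5.1, 6.3, 4.4), c = c(2.8, 3.9, 7.5))
  res <- dunn_posthoc(groups)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$adjusted_p >= res$raw_p - 1e-12))

  # enumerate all 9!/(3!3!3!) = 1680 relabelings; statistic = |mean-rank diff|
  pooled <- unlist(groups)
  rk <- rank(pooled)
  obs <- abs(outer(tapply(rk, rep(1:3, each = 3), mean),
                   tapply(rk, rep(1:3, each = 3), mean), `-`))
  idx <- seq_len(9)
  count_ge <- c(0, 0, 0); total <- 0
  for (g1 in combn(9, 3, simplify = FALSE)) {
    rest <- setdiff(idx, g1)
    for (g2 in combn(rest, 3, simplify = FALSE)) {
      g3 <- setdiff(rest, g2)
      m <- c(mean(rk[g1]), mean(rk[g2]), mean(rk[g3]))
      total <- total + 1
      count_ge <- count_ge + (abs(c(m[1] - m[2], m[1] - m[3], m[2] - m[3])) >=
                                c(obs[1, 2], obs[1, 3], obs[2, 3]) - 1e-12)
    }
  }
  p_perm <- count_ge / total
  # pair ordering by evidence strength must agree with the normal approximation
  expect_equal(order(res$raw_p), order(p_perm))

  # identical groups cap at 1; fully tied data gives all-1 adjusted p
  expect_equal(dunn_posthoc(list(1:4, 1:4))$adjusted_p, 1)
  expect_equal(dunn_posthoc(list(rep(2, 3), rep(2, 3), rep(2, 3)))$adjusted_p,
               rep(1, 3))
})

test_that("chi_square reproduces published statistics and the zero case", {
  tabs <- fixture_tables()
  res <- suppressWarnings(chi_square(tabs$epilepsy_status))
  expect_equal(res$statistic, 13.47, tolerance = 0.005 / 13.47)
  expect_equal(res$df, 6L)
  expect_equal(res$p, 0.036, tolerance = 0.02)

  flat <- matrix(c(10, 10, 10, 10), 2, dimnames = list(c("a", "b"), c("x", "y")))
  res0 <- chi_square(flat)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)

  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2,
                                 dimnames = list(c("a", "b"), c("x", "y")))),
               "zero row or column")
  expect_warning(chi_square(matrix(c(1, 2, 3, 4), 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
                 "below 5")
})

test_that("chi_square is invariant to permutation and transposition", {
  tab <- fixture_tables()$seizure_status
  base <- suppressWarnings(chi_square(tab))
  perm <- suppressWarnings(chi_square(tab[c(3, 1, 4, 2), c(2, 3, 1)]))
  trans <- suppressWarnings(chi_square(t(tab)))
  expect_equal(base$statistic, perm$statistic, tolerance = 1e-12)
  expect_equal(base$statistic, trans$statistic, tolerance = 1e-12)
  # residual identity: observed minus expected sums to zero
  expect_lt(abs(sum(base$observed - base$expected)), 1e-9)
})

test_that("pairwise chi-square with BH reproduces the published post hoc pattern", {
  tab <- fixture_tables()$epilepsy_status
  ph <- suppressWarnings(pairwise_chi_square(tab))
  expect_equal(nrow(ph), 6L)
  key <- paste(ph$group1, ph$group2)
  hh_nl <- ph$raw_p[key == "High-High Normal-Low"]
  hh_nh <- ph$raw_p[key == "High-High Normal-High"]
  expect_equal(round(hh_nl, 3), 0.005)
  expect_equal(round(hh_nh, 3), 0.009)  # 0.0085 at full precision
  adj <- ph$adjusted_p
  expect_equal(round(adj[key == "High-High Normal-Low"], 2), 0.03)
  expect_equal(round(adj[key == "High-High Normal-High"], 2), 0.03)
  expect_equal(round(max(adj), 2), 0.76)

  # identical rows give raw p of 1
  same <- matrix(c(3, 3, 3, 5, 5, 5), 3,
                 dimnames = list(c("a", "b", "c"), c("x", "y")))
  ph2 <- suppressWarnings(pairwise_chi_square(same))
  expect_equal(ph2$raw_p, rep(1, 3), tolerance = 1e-12)

  # zero-margin columns within a pair are dropped with a message
  zc <- matrix(c(5, 2, 0, 0, 0, 4, 3, 1, 6), 3,
               dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  expect_message(suppressWarnings(pairwise_chi_square(zc)), "zero-margin")
})

test_that("bh_adjust performs the step-up procedure", {
  expect_equal(bh_adjust(0.01), 0.01)
  expect_equal(bh_adjust(c(0.005, 0.008, 0.16, 0.63, 0.74, 0.76)),
               c(0.024, 0.024, 0.32, 0.76, 0.76, 0.76))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # order is preserved relative to input
  p <- c(0.63, 0.005, 0.76, 0.16, 0.008, 0.74)
  expect_equal(bh_adjust(p), c(0.76, 0.024, 0.76, 0.32, 0.024, 0.76))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("bonferroni_adjust caps at 1 and dominates BH", {
  expect_equal(bonferroni_adjust(c(0.01, 0.5)), c(0.02, 1.0))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  set.seed(99)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    bh <- bh_adjust(p); bf <- bonferroni_adjust(p)
    expect_true(all(bf >= p - 1e-12) && all(bf >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12) && all(bh <= 1) && all(bf <= 1))
    # BH preserves the ordering of the raw p-values
    expect_true(all(diff(bh[order(p)]) >= -1e-12))
  }
})
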