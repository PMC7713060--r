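# Nonparametric tests: enumeration-derived expected values, agreement with
# the reference implementations, and type-I error calibration.

test_that("Mann-Whitney U matches enumeration on separated samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 20)   # 2 extreme of C(6,3) = 20 arrangements
  # symmetry under sample swap
  r2 <- mann_whitney_u(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r2$statistic, 9)     # U' = n1 n2 - U
  expect_equal(r2$p_value, r$p_value)
})

test_that("identical samples give the central U and p near 1", {
  x <- c(3, 1, 4, 1, 5)
  r <- mann_whitney_u(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)
  expect_gte(r$p_value, 0.99)
})

test_that("exact enumeration agrees with the reference exact test", {
  set.seed(71)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    ours <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("approximate route deviates boundedly from the exact p", {
  set.seed(72)
  x <- rnorm(9); y <- rnorm(9)         # n = 18 > enumeration limit
  approx_p <- mann_whitney_u(x, y)$p_value
  exact_p <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p) / exact_p, 0.25)
})

test_that("enumeration handles ties via midranks", {
  r <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4))
  expect_true(is.finite(r$p_value))
  expect_match(r$method, "exact")
  # midrank U: ranks of (1,2,2,2,3,4) are (1,3,3,3,5,6)
  expect_equal(r$statistic, (1 + 3 + 3) - 6)
})

test_that("Kruskal-Wallis H matches hand rank arithmetic", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  # ranks 1..6: H = 12/(6*7) * sum n_i Rbar_i^2 - 3*7 = 32/7
  expect_equal(r$statistic, 12 / 42 * (2 * 1.5^2 + 2 * 3.5^2 + 2 * 5.5^2) - 21)
  expect_equal(r$statistic, 4.5714286, tolerance = 1e-6)
  # three identical groups: degenerate contract
  g <- list(rep(2, 3), rep(2, 3), rep(2, 3))
  rd <- kruskal_wallis(g)
  expect_equal(rd$statistic, 0)
  expect_equal(rd$p_value, 1)
})

test_that("two-group Kruskal-Wallis agrees in direction with Mann-Whitney", {
  set.seed(33)
  x <- rnorm(12); y <- rnorm(12) + 2
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney_u(x, y)
  expect_lt(kw$p_value, 0.05)
  expect_lt(mw$p_value, 0.05)
})

test_that("post-hoc variants return a full adjusted pairwise table", {
  set.seed(90)
  groups <- list(a = rnorm(8), b = rnorm(8) + 3, c = rnorm(8))
  for (m in c("dunn", "tukey_on_ranks")) {
    ph <- posthoc_pairwise(groups, method = m)
    expect_equal(nrow(ph), 3L)
    expect_true(all(ph$p_value >= 0 & ph$p_value <= 1))
    sep <- ph$p_value[(ph$group1 == "a" & ph$group2 == "b") |
                        (ph$group1 == "b" & ph$group2 == "a")]
    same <- ph$p_value[(ph$group1 == "a" & ph$group2 == "c") |
                         (ph$group1 == "c" & ph$group2 == "a")]
    expect_lt(sep, same)
  }
})

test_that("Mann-Whitney holds its nominal type-I error under the null", {
  set.seed(2024)
  n_sim <- 2000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    if (mann_whitney_u(rnorm(20), rnorm(20))$p_value < 0.05)
      rejections <- rejections + 1L
  }
  rate <- rejections / n_sim
  # 0.05 within Monte-Carlo error (~3.5 SD) plus approximation slack
  expect_lt(abs(rate - 0.05), 0.02)
})
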