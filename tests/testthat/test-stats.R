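test_that("Mann-Whitney U, Z and exact p match full enumeration on a worked example", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u1, 0)
  expect_equal(mw$z, -4.5 / sqrt(3 * 3 * 7 / 12), tolerance = 1e-12)
  expect_equal(round(mw$z, 3), -1.964)
  # exact: 2 of the 20 assignments are as extreme as U = 0
  expect_equal(mw$p_exact, 0.1)
  expect_equal(mw$n1, 3L); expect_equal(mw$n2, 3L)
})

test_that("identical groups give Z = 0 and swapping groups flips the sign", {
  x <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney(x, x)$z, 0)
  set.seed(10)
  for (k in 1:20) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    m1 <- mann_whitney(a, b); m2 <- mann_whitney(b, a)
    expect_equal(m1$z, -m2$z, tolerance = 1e-12)
    expect_equal(m1$u1 + m2$u1, m1$n1 * m1$n2)
  }
})

test_that("U statistic agrees with wilcox.test and ties shrink sigma", {
  set.seed(2)
  for (k in 1:20) {
    a <- sample(1:6, sample(4:10, 1), replace = TRUE)   # heavy ties
    b <- sample(1:6, sample(4:10, 1), replace = TRUE)
    mw <- mann_whitney(a, b)
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    expect_equal(mw$u1, unname(wt$statistic))
    expect_equal(mw$p_two_sided, wt$p.value, tolerance = 1e-9)
  }
  # tie-free sigma vs tied sigma on the same ranks
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  at <- c(1, 1, 3, 3); bt <- c(5, 5, 7, 7)
  z_free <- abs(mann_whitney(a, b)$z)
  z_tied <- abs(mann_whitney(at, bt)$z)
  expect_gt(z_tied, z_free)   # same U, smaller sigma under ties
})

test_that("normal approximation tracks the exact permutation p for small n", {
  # with the continuity correction the gap stays below 0.05 for every
  # tie-free configuration at these sizes (without it, U = 3 at n1 = n2 = 3
  # alone gives exact p = 0.7 vs normal p = 0.51 — no approximation on the
  # plain z can close that)
  set.seed(14)
  worst <- 0
  for (k in 1:100) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    a <- rnorm(n1); b <- rnorm(n2)     # continuous: tie-free
    mw <- mann_whitney(a, b, continuity = TRUE)
    expect_false(is.na(mw$p_exact))
    worst <- max(worst, abs(mw$p_two_sided - mw$p_exact))
  }
  expect_lt(worst, 0.05)
})

test_that("two-sided z test holds its type-I error near the nominal level", {
  set.seed(2024)
  rejections <- vapply(1:2000, function(k) {
    abs(mann_whitney(rnorm(20), rnorm(20))$z) > qnorm(0.975)
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("Kruskal-Wallis matches the hand-ranked example and the z^2 identity", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, 12 / (6 * 7) * (9 / 2 + 49 / 2 + 121 / 2) - 3 * 7,
               tolerance = 1e-12)
  expect_equal(round(kw$H, 3), 4.571)
  expect_equal(kw$df, 2)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  # two tie-free groups: H equals z^2
  set.seed(6)
  a <- rnorm(8); b <- rnorm(11)
  expect_equal(kruskal_wallis(list(a, b))$H, mann_whitney(a, b)$z^2,
               tolerance = 1e-9)
})

test_that("Pearson r handles the canonical cases and rejects degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  set.seed(31)
  for (k in 1:10) {
    x <- rnorm(50)
    expect_lt(pearson_r(x, -x + rnorm(50, 0, 0.5)), 0)
  }
})

test_that("group comparisons use the fixed sphere-first orientation", {
  rec <- data.frame(observed = rep(c("sphere", "network"), c(4, 4)),
                    ned = c(0.20, 0.22, 0.24, 0.25, 0.30, 0.31, 0.33, 0.35),
                    length_nt = c(800, 900, 1000, 1100, 2000, 2200, 2500, 2600))
  mw <- compare_groups(rec, "ned")
  expect_lt(mw$z, 0)      # sphere group is smaller -> negative Z
  expect_equal(mw$u1, 0)
  mw2 <- compare_groups(rec, "length_nt", subset = rec$length_nt < 2500)
  expect_equal(mw2$n2, 2L)
  expect_error(compare_groups(rec, "ned", subset = rec$ned > 0.29), "nonempty")
})

test_that("null cohorts rarely reject; separated cohorts almost always do", {
  null_rej <- vapply(1:100, function(s) {
    spec <- cohort_spec(n_sphere = 50L, n_network = 50L,
                        ned_mean_sphere = 0.27, ned_mean_network = 0.27,
                        ned_sd = 0.03, seed = s)
    abs(compare_groups(gen_cohort(spec), "ned")$z) >= qnorm(0.975)
  }, logical(1))
  expect_gte(mean(!null_rej), 0.9)
  power <- vapply(1:200, function(s) {
    spec <- cohort_spec(n_sphere = 14L, n_network = 14L,
                        ned_mean_sphere = 0.24, ned_mean_network = 0.31,
                        ned_sd = 0.03, seed = 10000 + s)
    abs(compare_groups(gen_cohort(spec), "ned")$z) >= qnorm(0.975)
  }, logical(1))
  expect_gte(mean(power), 0.8)
})
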