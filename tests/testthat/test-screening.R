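test_that("likelihood-ratio test reproduces the cohort distribution p-values", {
  # homozygosity / sex split 11 vs 13 in 24 patients
  x <- rep(c("Y", "N"), c(11, 13))
  r <- test_distribution(x, name = "homozygous")
  expect_equal(r$p, 0.6829, tolerance = 1e-4)
  # hypogonadism split 4 vs 20
  r2 <- test_distribution(rep(c("Y", "N"), c(4, 20)))
  expect_lt(abs(r2$p - 0.0006), 5e-5)
  # perfectly even split satisfies the null exactly
  r3 <- test_distribution(rep(c("A", "B"), each = 12))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p, 1)
})

test_that("continuous distribution testing uses Shapiro-Wilk", {
  x <- c(12, 15, 11, 19, 14, 13, 16, 18, 12, 15)
  r <- test_distribution(x, name = "aoo")
  sw <- shapiro.test(x)
  expect_equal(r$statistic, unname(sw$statistic))
  expect_equal(r$p, sw$p.value)
  expect_error(test_distribution(rep(3, 10)), "identical")
  expect_error(test_distribution(c(1, 2)), "at least 3")
})

test_that("Fisher's exact test matches exhaustive enumeration", {
  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  tab <- matrix(c(8, 1, 2, 9), 2)
  expect_equal(fisher_exact(tab)$p, fisher_oracle_2x2(tab), tolerance = 1e-12)
  # every nondegenerate 2x2 table with total count <= 12
  for (n in 2:12) for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    tab <- matrix(c(a, b, cc, n - a - b - cc), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, fisher_oracle_2x2(tab),
                 tolerance = 1e-10)
  }
})

test_that("2x3 Fisher matches the conditional-distribution enumeration", {
  tabs <- list(matrix(c(5, 1, 2, 6, 1, 4), 2),
               matrix(c(9, 2, 1, 7, 4, 4), 2),
               matrix(c(2, 5, 3, 3, 6, 1), 2))
  for (tab in tabs) {
    expect_equal(fisher_exact(tab)$p, fisher_oracle_2xk(tab),
                 tolerance = 1e-10)
  }
})

test_that("a zero margin yields p = 1 flagged degenerate, not an error", {
  r <- fisher_exact(matrix(c(0, 0, 3, 5), 2, byrow = TRUE))
  expect_equal(r$p, 1)
  expect_true(r$degenerate)
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("pooled t test matches the textbook formula", {
  r <- two_group_t(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 2 * pt(-3.6742346, df = 4), tolerance = 1e-6)
  expect_equal(r$estimate, -3)

  same <- two_group_t(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("one-way ANOVA matches a direct sum-of-squares decomposition", {
  y <- c(0, 0, 1, 5, 5, 6, 9, 10, 11)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  r <- anova_tukey(y, g)
  gm <- tapply(y, g, mean)
  ssb <- sum(3 * (gm - mean(y))^2)
  ssw <- sum((y - gm[g])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(r$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(r$p, pf(f_oracle, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(nrow(r$posthoc[[1]]), 3)

  flat <- anova_tukey(rep(c(1, 2), 6), rep(c("a", "b", "c"), each = 4))
  expect_lt(flat$statistic, 1e-20)

  # singleton level excluded and reported
  r2 <- anova_tukey(c(y, 100), c(g, "g4"))
  expect_equal(r2$excluded, "g4")
  expect_equal(r2$n_used, 9)
})

test_that("simple regression recovers exact linear relationships", {
  x <- 1:10
  r <- suppressWarnings(simple_regression(2 * x, x))  # exact fit warns in lm
  expect_equal(r$estimate, 2)
  expect_equal(r$r_squared, 1)
  expect_error(simple_regression(1:5, rep(2, 5)), "constant")
})

test_that("regression p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(300, simple_regression(rnorm(24), rnorm(24))$p)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(1)
  for (i in 1:10) {
    p <- runif(sample(2:30, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone in p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # constant families are fixed points of the step-up transform
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 3)), rep(1, 3))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("screen dispatches on variable types and adjusts as one family", {
  set.seed(5)
  d <- tibble::tibble(
    y = rnorm(30), xc = rnorm(30),
    x2 = sample(c("A", "B"), 30, TRUE),
    x3 = sample(c("A", "B", "C"), 30, TRUE),
    yk = sample(c("Y", "N"), 30, TRUE)
  )
  res <- screen(d, "y", c("xc", "x2", "x3"))
  expect_equal(res$test_name, c("regression", "pooled_t", "anova"))
  expect_equal(res$q, bh_adjust(res$p))

  res2 <- screen(d, "yk", c("x2"))
  expect_equal(res2$test_name, "fisher_exact")
  expect_equal(res2$q, res2$p)  # single-test family

  # row order invariance
  perm <- sample(30)
  res3 <- screen(d[perm, ], "y", c("xc", "x2", "x3"))
  expect_equal(res3$p, res$p, tolerance = 1e-12)

  # group relabeling flips the sign of t but not the p-value
  d2 <- d; d2$x2 <- ifelse(d$x2 == "A", "B", "A")
  ra <- screen(d, "y", "x2"); rb <- screen(d2, "y", "x2")
  expect_equal(ra$p, rb$p, tolerance = 1e-12)
  expect_equal(ra$statistic, -rb$statistic, tolerance = 1e-12)
})

test_that("screening holds its type-I error on null synthetic cohorts", {
  set.seed(99)
  ps <- unlist(lapply(1:170, function(i) {
    d <- tibble::tibble(y = rnorm(24), xc = rnorm(24),
                        x2 = rep(c("A", "B"), 12),
                        x3 = rep(c("A", "B", "C"), 8))
    screen(d, "y", c("xc", "x2", "x3"))$p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)))
})

test_that("screen results export as a tidy table", {
  d <- tibble::tibble(y = rnorm(20), x = rnorm(20))
  res <- screen(d, "y", "x")
  path <- withr::local_tempfile(fileext = ".csv")
  write_screen(res, path)
  back <- read.csv(path)
  expect_equal(back$p, res$p, tolerance = 1e-12)
  expect_true(all(c("test_name", "y_var", "x_var", "q", "flagged") %in%
                    names(back)))
})
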