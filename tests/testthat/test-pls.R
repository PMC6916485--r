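test_that("design encoding standardizes and effect-codes predictors", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), f = c("Y", "N", "Y", "N"),
                      g = c("a", "b", "c", "a"))
  des <- encode_design(d, c("x", "f", "g"))
  expect_equal(colnames(des$x), c("x", "f:N", "f:Y", "g:a", "g:b", "g:c"))
  expect_equal(unname(colMeans(des$x)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(des$x, 2, sd)), rep(1, 6), tolerance = 1e-12)

  # sum coding: a binary factor becomes a single +1/-1 column
  des2 <- encode_design(d, "f", coding = "sum")
  expect_equal(ncol(des2$x), 1)
  raw <- des2$contrasts$f[d$f, 1]
  expect_equal(unname(raw), c(-1, 1, -1, 1))

  expect_error(encode_design(tibble::tibble(x = rep(1, 5)), "x"), "zero scale")
  expect_error(encode_design(tibble::tibble(f = rep("Y", 5)), "f"), "single level")
})

test_that("one-factor PLS on a single predictor equals simple OLS", {
  set.seed(2)
  d <- tibble::tibble(x = rnorm(25))
  d$y <- 3 + 2 * d$x + rnorm(25, sd = 0.5)
  m <- fit_pls(encode_design(d, "x"), d$y, 1)
  expect_equal(unname(m$fitted[, 1]), unname(fitted(lm(y ~ x, d))),
               tolerance = 1e-10)
})

test_that("full-factor PLS predictions equal OLS on full-rank designs", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(15:50, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("x", 1:p)))
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- rnorm(n, sd = 2) + X %*% rnorm(p)
    m <- fit_pls(encode_design(d, paste0("x", 1:p)), d$y, p)
    ols <- fitted(lm(y ~ ., d))
    expect_equal(unname(m$fitted[, 1]), unname(ols), tolerance = 1e-8)
  }
})

test_that("multi-response fit agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  eqs <- scar16_reference_equations()
  d <- generate_from_equation(list(eqs$aoo_biochem, eqs$sara_biochem),
                              n = 60, noise_sd = 4, seed = 31)
  preds <- c("pct_hsp70_ub", "pct_chain", "kd", "bmax")
  m <- fit_pls(encode_design(d, preds), d[c("aoo", "sara")], 2)
  ref <- mixOmics::pls(as.matrix(d[preds]), as.matrix(d[c("aoo", "sara")]),
                       ncomp = 2, mode = "regression", scale = TRUE)
  ref_pred <- predict(ref, as.matrix(d[preds]))$predict[, , 2]
  mine <- predict(m, d)
  expect_equal(unname(mine), unname(ref_pred), tolerance = 1e-6)
})

test_that("VIP normalization identities hold", {
  set.seed(7)
  d <- tibble::tibble(x = rnorm(20)); d$y <- d$x + rnorm(20)
  m1 <- fit_pls(encode_design(d, "x"), d$y, 1)
  expect_equal(unname(vip(m1)), 1)

  # orthonormal two-predictor design with equal loadings: both VIP = 1
  d2 <- tibble::tibble(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  d2$y <- d2$a + d2$b
  m2 <- fit_pls(encode_design(d2, c("a", "b")), d2$y, 1)
  expect_equal(unname(vip(m2)), c(1, 1), tolerance = 1e-10)

  for (seed in 1:3) {  # mean VIP^2 = 1 for any fit
    set.seed(seed)
    n <- 30; p <- 5
    d3 <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * p), n)))
    names(d3) <- paste0("x", 1:p)
    d3$y <- rnorm(n)
    m3 <- fit_pls(encode_design(d3, paste0("x", 1:p)), d3$y, 2)
    expect_equal(mean(vip(m3)^2), 1, tolerance = 1e-10)
  }
})

test_that("LOO PRESS selects one factor for noiseless single-factor data", {
  set.seed(14)
  t_ <- rnorm(30)
  d <- tibble::tibble(x1 = t_, x2 = t_ + rnorm(30, sd = 1e-3), y = 2 * t_)
  cv <- loo_select(encode_design(d, c("x1", "x2")), d$y)
  expect_equal(cv$a_selected, 1)
  expect_lt(cv$press["A1"], 0.01 * cv$press["A0"])
})

test_that("LOO PRESS refuses to model pure noise", {
  picks <- vapply(1:10, function(seed) {
    set.seed(seed)
    d <- tibble::as_tibble(as.data.frame(matrix(rnorm(24 * 4), 24)))
    names(d) <- paste0("x", 1:4)
    d$y <- rnorm(24)
    cv <- loo_select(encode_design(d, paste0("x", 1:4)), d$y)
    cv$a_selected
  }, numeric(1))
  expect_gte(mean(picks <= 1), 0.8)
})

test_that("raw-scale equations reproduce the model and its intercept", {
  set.seed(3)
  d <- tibble::tibble(x = rnorm(30, 50, 10),
                      f = sample(c("lo", "mid", "hi"), 30, TRUE))
  d$y <- 5 + 0.3 * d$x + c(lo = -2, mid = 0, hi = 2)[d$f] + rnorm(30)
  m <- fit_pls(encode_design(d, c("x", "f")), d$y, 3)
  eq <- export_equation(m, "y")
  expect_equal(evaluate_equation(eq, d), unname(m$fitted[, 1]),
               tolerance = 1e-8)
  # per-factor offsets sum to zero exactly
  expect_equal(sum(eq$categorical$f), 0, tolerance = 1e-10)
  # at all-center inputs, the mean over levels is the intercept
  centers <- list(x = eq$continuous$center[1])
  preds <- vapply(names(eq$categorical$f), function(l) {
    evaluate_equation(eq, c(centers, list(f = l)))
  }, numeric(1))
  expect_equal(mean(preds), eq$intercept, tolerance = 1e-10)
})

test_that("equations serialize to YAML and back", {
  eqs <- scar16_reference_equations()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_equation(eqs$aoo_biochem, path)
  back <- read_equation(path)
  probe <- list(pct_hsp70_ub = 30, pct_chain = 80, kd = 4, bmax = 200)
  expect_equal(evaluate_equation(back, probe),
               evaluate_equation(eqs$aoo_biochem, probe), tolerance = 1e-12)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_equation(eqs$sara_clinical, path2)
  back2 <- read_equation(path2)
  expect_equal(back2$categorical$ancestry, eqs$sara_clinical$categorical$ancestry)
})

test_that("reference equation evaluation matches hand arithmetic", {
  eqs <- scar16_reference_equations()
  # clinical model at CD = Y, EUR ancestry, TR = Y: 17.2 + 5.6 + 4.7 + 2.7
  expect_equal(evaluate_equation(eqs$sara_clinical,
                                 list(cd = "Y", ancestry = "EUR", tr = "Y")),
               30.2, tolerance = 1e-10)
  opt <- list(pct_hsp70_ub = 7.2, pct_chain = 15, kd = 17, bmax = 217)
  expect_equal(evaluate_equation(eqs$aoo_biochem, opt), 27.6979, tolerance = 1e-4)
  expect_equal(evaluate_equation(eqs$sara_biochem, opt), 10.6080, tolerance = 1e-4)
  expect_error(evaluate_equation(eqs$sara_clinical,
                                 list(cd = "maybe", ancestry = "EUR", tr = "Y")),
               "unknown level")
})

test_that("raw-scale coefficients are recovered from generated data", {
  eqs <- scar16_reference_equations()
  truth <- eqs$aoo_biochem$continuous$coefficient
  hits <- vapply(1:20, function(seed) {
    d <- generate_from_equation(eqs$aoo_biochem, n = 500, noise_sd = 5,
                                seed = seed)
    m <- fit_pls(encode_design(d, eqs$aoo_biochem$continuous$name), d$aoo, 4)
    eq <- export_equation(m, "y")
    est <- eq$continuous$coefficient *
      eqs$aoo_biochem$continuous$scale / eq$continuous$scale
    all(abs(est - truth) / abs(truth) < 0.15)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("VIP reduction keeps the clinical drivers of SARA", {
  params <- generator_params(n_patients = 200, seed = 17,
                             noise_sd = c(sara = 5, aoo = 5))
  gen <- generate_cohort(params)
  d <- gen$cohort
  d$homozygous <- ifelse(d$homozygous, "Y", "N")
  red <- reduce_and_refit(d, c("cd", "ancestry", "tr", "homozygous", "sex"),
                          "sara", cutoff = 0.8)
  expect_true(all(c("cd", "tr") %in% red$retained))
  expect_false("sex" %in% red$retained)
  # CD carries the largest effect, close to its generating +/- 5.6 offset
  cd_off <- red$equations$sara$categorical$cd
  expect_equal(unname(cd_off["Y"]), 5.6, tolerance = 0.35)
  expect_gt(red$r_squared[["sara"]], 0.3)
})

test_that("reduction with no predictor below the cutoff refits unchanged", {
  set.seed(23)
  d <- tibble::tibble(a = rnorm(40), b = rnorm(40))
  d$y <- d$a + d$b + rnorm(40, sd = 0.3)
  red <- reduce_and_refit(d, c("a", "b"), "y")
  expect_equal(red$dropped, character(0))
  expect_equal(red$reduced$fitted, red$initial$fitted, tolerance = 1e-10)
  # factor count never grows during reduction
  expect_lte(red$reduced$n_factors, red$initial$n_factors)
})
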