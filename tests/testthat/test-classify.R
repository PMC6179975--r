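# Multinomial logistic regression, selection, tests, fit statistics and
# random-forest importance.

test_that("mlr_score is the inner product with intercept and softmax normalises", {
  expect_equal(mlr_score(c(1, 0.5), 2), 2)
  p <- softmax_probs(matrix(0, 1, 2))
  expect_equal(unname(p[1, ]), rep(1 / 3, 3))
  set.seed(2)
  sc <- matrix(rnorm(10), 5, 2)
  expect_equal(unname(rowSums(softmax_probs(sc))), rep(1, 5))
  expect_rt_error(mlr_score(c(1, 0.5), c(1, 2)), "dimension")
})

test_that("intercept-only deviance matches the closed form and the fitted model", {
  expect_equal(intercept_only_deviance(c(114, 70, 27)),
               -2 * (114 * log(114 / 211) + 70 * log(70 / 211) +
                       27 * log(27 / 211)))
  y <- rep(1:3, c(20, 12, 8))
  m <- fit_mlr(matrix(numeric(0), 40, 0), y)
  expect_equal(m$deviance, intercept_only_deviance(c(20, 12, 8)),
               tolerance = 1e-8)
  # fitted probabilities are the class proportions
  expect_equal(unname(m$fitted[1, ]), c(20, 12, 8) / 40, tolerance = 1e-6)
})

test_that("the Newton fit agrees with the independent multinomial fitter", {
  skip_if_not_installed("nnet")
  d <- simulate_mlr(400, B = cbind(c(1, 2, 0), c(-1, 0, 2)), seed = 1)
  m <- fit_mlr(d$x, d$y)
  ref <- nnet::multinom(factor(d$y) ~ d$x, trace = FALSE, reltol = 1e-12)
  expect_equal(m$deviance, ref$deviance, tolerance = 1e-6)
  expect_equal(unname(m$coefficients), unname(t(coef(ref))), tolerance = 1e-4)
  expect_equal(unname(m$se),
               unname(t(summary(ref)$standard.errors)), tolerance = 1e-3)
  expect_equal(m$aic, ref$deviance + 2 * 6, tolerance = 1e-6)
})

test_that("log-likelihood is non-decreasing and probabilities sum to one", {
  d <- simulate_mlr(200, B = cbind(c(0.5, 1, -1), c(-0.5, -1, 1)), seed = 3)
  m <- fit_mlr(d$x, d$y)
  expect_true(m$converged)
  expect_equal(unname(rowSums(m$fitted)), rep(1, 200), tolerance = 1e-12)
  expect_lte(m$deviance, m$null_deviance + 1e-9)
})

test_that("coefficient recovery is within 2 SE for simulated data", {
  B <- cbind(c(0.5, 1.2, -0.8, 0.4), c(-0.3, -0.6, 0.9, 0))
  hits <- 0; total <- 0
  for (s in 1:20) {
    d <- simulate_mlr(2000, B, seed = s)
    m <- fit_mlr(d$x, d$y)
    cover <- abs(m$coefficients - B) <= 2 * m$se
    hits <- hits + sum(cover); total <- total + length(cover)
  }
  expect_gte(hits / total, 0.90)
})

test_that("perfect separation raises a dedicated warning", {
  x <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1,
              dimnames = list(NULL, "b"))
  y <- rep(1:2, each = 20)
  expect_warning(fit_mlr(x, y, max_iter = 100),
                 class = "ricotype_separation")
})

test_that("rank-deficient designs fail naming the collinear column", {
  set.seed(4)
  x <- cbind(a = rnorm(60), b = rnorm(60))
  x <- cbind(x, c = x[, "a"] + x[, "b"])
  y <- rep(1:3, each = 20)
  err <- tryCatch(fit_mlr(x, y), error = function(e) e)
  expect_s3_class(err, "ricotype_rank_deficient")
  expect_match(conditionMessage(err), "c")
})

test_that("forward AIC selection finds a strong predictor among noise", {
  found <- logical(20)
  for (s in 1:20) {
    set.seed(s + 100)
    n <- 500
    x <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("v", 1:10)))
    eta2 <- 2 * x[, "v1"]
    eta3 <- -2 * x[, "v1"]
    pr <- cbind(1, exp(eta2), exp(eta3)); pr <- pr / rowSums(pr)
    y <- apply(pr, 1, function(q) sample.int(3, 1, prob = q))
    m <- forward_aic_select(x, y)
    found[s] <- "v1" %in% m$variables
  }
  expect_gte(mean(found), 0.95)
})

test_that("selection AIC matches an independent fit and never exceeds the null model", {
  skip_if_not_installed("nnet")
  d <- simulate_mlr(300, B = cbind(c(0, 1.5, 0.3), c(0.2, -1, 0.5)), seed = 9)
  colnames(d$x) <- c("x1", "x2")
  x <- cbind(d$x, x3 = rnorm(300))
  m <- forward_aic_select(x, d$y)
  ref <- nnet::multinom(factor(d$y) ~ x[, m$variables, drop = FALSE],
                        trace = FALSE, reltol = 1e-12)
  expect_equal(m$aic, ref$deviance + 2 * 2 * (length(m$variables) + 1),
               tolerance = 1e-5)
  null_aic <- intercept_only_deviance(table(d$y)) + 2 * 2
  expect_lte(m$aic, null_aic)
  expect_equal(m$selection$aic[nrow(m$selection)], m$aic)
})

test_that("the LR test equals the deviance difference of two direct fits", {
  skip_if_not_installed("nnet")
  d <- simulate_mlr(250, B = cbind(c(0, 1, 0.5), c(0, -0.5, 1)), seed = 5)
  m <- fit_mlr(d$x, d$y)
  lrt <- lr_test(m, "x1")
  f_full <- nnet::multinom(factor(d$y) ~ d$x, trace = FALSE, reltol = 1e-12)
  f_red <- nnet::multinom(factor(d$y) ~ d$x[, 2], trace = FALSE, reltol = 1e-12)
  expect_equal(lrt$chisq, f_red$deviance - f_full$deviance, tolerance = 1e-5)
  expect_equal(lrt$df, 2)
  expect_gte(lrt$chisq, 0)
})

test_that("LR-test p-values are approximately uniform under the null", {
  pvals <- numeric(200)
  for (s in 1:200) {
    set.seed(s)
    n <- 150
    x <- cbind(sig = rnorm(n), nul = rnorm(n))
    eta2 <- 0.8 * x[, "sig"]; eta3 <- -0.8 * x[, "sig"]
    pr <- cbind(1, exp(eta2), exp(eta3)); pr <- pr / rowSums(pr)
    y <- apply(pr, 1, function(q) sample.int(3, 1, prob = q))
    m <- suppressWarnings(fit_mlr(x, y))
    pvals[s] <- lr_test(m, "nul")$p
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals > 0.05), 0.85)
})

test_that("pseudo-R2 statistics: null model zero, identities, counting accuracy", {
  y <- rep(1:3, c(30, 20, 10))
  m0 <- fit_mlr(matrix(numeric(0), 60, 0), y)
  g0 <- goodness_of_fit(m0)
  expect_equal(g0$mcfadden, 0, tolerance = 1e-8)
  expect_equal(g0$cox_snell, 0, tolerance = 1e-8)
  expect_equal(g0$cragg_uhler, 0, tolerance = 1e-8)

  d <- simulate_mlr(300, B = cbind(c(0, 2, 0), c(0, 0, 2)), seed = 7)
  m <- fit_mlr(d$x, d$y)
  g <- goodness_of_fit(m)
  expect_equal(g$chisq, g$null_deviance - g$deviance, tolerance = 1e-12)
  expect_equal(g$mcfadden, 1 - g$deviance / g$null_deviance, tolerance = 1e-12)
  pred <- predict(m)
  expect_equal(g$accuracy, 100 * mean(as.integer(as.character(pred)) == d$y))
  # accuracy is pure counting: 47 of 50 correct is 94%
  expect_equal(100 * 47 / 50, 94)
})

test_that("random-forest importance is seed-reproducible and flags the planted predictor", {
  set.seed(20)
  n <- 240
  x <- data.frame(planted = c(rnorm(n / 3, 0), rnorm(n / 3, 3), rnorm(n / 3, 6)),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  y <- rep(1:3, each = n / 3)
  i1 <- rf_importance(x, y, seed = 77)
  i2 <- rf_importance(x, y, seed = 77)
  expect_identical(i1$importance, i2$importance)
  expect_equal(i1$rankings[["1"]][1], "planted")
  expect_equal(i1$rankings[["3"]][1], "planted")
  expect_lt(i1$oob_error, 15)
})

test_that("pure-noise predictors have importance centred near zero", {
  set.seed(21)
  x <- data.frame(matrix(rnorm(200 * 5), 200, 5))
  y <- rep(1:2, each = 100)
  imp <- rf_importance(x, y, n_trees = 300, seed = 5)
  # standardised scores: individually z-scale noise, collectively near 0
  expect_lt(max(abs(imp$importance)), 5)
  expect_lt(abs(mean(imp$importance)), 1)
})

test_that("degenerate single-class input is rejected", {
  x <- data.frame(a = rnorm(10))
  expect_rt_error(rf_importance(x, rep(1, 10)), "degenerate")
})
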