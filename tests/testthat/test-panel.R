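# Panel assembly: conversions, class bins, replicates, correlations,
# pruning.

test_that("protein conversion applies the rice nitrogen factor", {
  expect_equal(protein_from_nitrogen(0), 0)
  expect_equal(protein_from_nitrogen(1.400), 8.33)
  # the cluster-1 mean protein (8.66%) corresponds to 1.456% N
  expect_equal(protein_from_nitrogen(1.456), 8.66, tolerance = 0.005)
  expect_rt_error(protein_from_nitrogen(-0.1), "domain")
})

test_that("amylose classes follow the conventional bins with gap-resolving cuts", {
  expect_equal(as.character(assign_ac_class(c(0, 1.9, 2.5, 9.4, 9.5, 19.4,
                                              19.5, 21.22, 25, 25.07, 25.51))),
               c("waxy", "waxy", "very_low", "very_low", "low", "low",
                 "intermediate", "intermediate", "intermediate",
                 "high", "high"))
  # totality: every non-negative value maps to exactly one class
  set.seed(1)
  cls <- assign_ac_class(runif(500, 0, 45))
  expect_false(anyNA(cls))
  expect_rt_error(assign_ac_class(-1), "domain")
})

test_that("GT classes use the low < 67 and high >= 74 edges with a contiguous middle", {
  expect_equal(as.character(assign_gt_class(c(66, 66.99, 67, 67.5, 73.5,
                                              74, 77.94))),
               c("low", "low", "intermediate", "intermediate",
                 "intermediate", "high", "high"))
  expect_rt_error(assign_gt_class(0), "domain")
})

test_that("replicate averaging takes arithmetic means and records counts", {
  rows <- data.frame(sample_id = c("a", "a", "a", "b"),
                     HRD = c(1.9, 2.0, 1.98, 2.49),
                     COH = c(0.4, 0.5, NA, 0.44))
  p <- average_replicates(rows)
  expect_equal(unname(p$x["a", "HRD"]), 1.96)
  expect_equal(unname(p$x["b", "HRD"]), 2.49)
  expect_equal(unname(p$x["a", "COH"]), 0.45)
  expect_equal(unname(p$n_reps["a", "COH"]), 2L)
  expect_equal(unname(p$n_reps["a", "HRD"]), 3L)
})

test_that("replicate averaging is invariant to replicate order and fails on empty cells", {
  rows <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                     v = c(1, 2, 3, 4, 5, 6))
  p1 <- average_replicates(rows)
  p2 <- average_replicates(rows[sample(6), ])
  expect_equal(p1$x[sort(rownames(p1$x)), , drop = FALSE],
               p2$x[sort(rownames(p2$x)), , drop = FALSE])

  rows$v[4:6] <- NA
  err <- tryCatch(average_replicates(rows), error = function(e) e)
  expect_s3_class(err, "ricotype_missing_data")
  expect_match(conditionMessage(err), "b")
  expect_match(conditionMessage(err), "v")
  # mean imputation as the opt-in alternative
  p3 <- average_replicates(rows, impute = TRUE)
  expect_equal(unname(p3$x["b", "v"]), 2)
})

test_that("pearson matrix has unit diagonal, symmetry and exact linear pairs", {
  set.seed(3)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  x <- cbind(x, c = 2 * x[, "a"])
  rep <- pearson_matrix(x)
  expect_equal(unname(diag(rep$r)), rep(1, 3))
  expect_equal(rep$r, t(rep$r))
  expect_equal(unname(rep$r["a", "c"]), 1)
  expect_true(all(abs(rep$r) <= 1 + 1e-12))
  expect_equal(unname(rep$stars["a", "c"]), "***")
})

test_that("zero-variance variables are flagged with absent correlations", {
  x <- cbind(a = rnorm(20), z = rep(5, 20))
  rep <- pearson_matrix(x)
  expect_equal(rep$zero_variance, "z")
  expect_true(all(is.na(rep$r["z", ])))
})

test_that("pruning drops nothing when variables are independent", {
  set.seed(9)
  x <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, letters[1:5]))
  out <- prune_correlated(x, drop_policy = "greedy")
  expect_equal(out$report$dropped, character(0))
  expect_equal(out$report$retained, letters[1:5])
})

test_that("greedy pruning drops exactly one of a duplicated pair", {
  set.seed(4)
  X <- rnorm(100)
  Z <- rnorm(100)
  x <- cbind(X = X, Y = X, Z = Z)
  # oracle: the full 3x3 correlation matrix flags only the X-Y pair
  r <- cor(x)
  expect_equal(sum(abs(r) > 0.75 & upper.tri(r)), 1)
  out <- prune_correlated(x, drop_policy = "greedy")
  expect_length(out$report$dropped, 1)
  expect_true(out$report$dropped %in% c("X", "Y"))
  expect_true("Z" %in% out$report$retained)
})

test_that("pruning at threshold 1 is the identity without exact collinearity", {
  set.seed(5)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, letters[1:4]))
  out <- prune_correlated(x, threshold = 1, drop_policy = "greedy")
  expect_equal(out$panel$x, as_panel_matrix(x))
})

test_that("the pinned drop policy errors when a pinned variable is absent", {
  x <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  expect_rt_error(prune_correlated(x, drop_policy = "paper"), "config")
})

test_that("paper drop policy on a full generated panel retains the 19 reporting variables", {
  gp <- gen_feature_panel(full = TRUE, seed = 2)
  expect_equal(ncol(gp$panel$x), 25)
  out <- prune_correlated(gp$panel, drop_policy = "paper")
  expect_setequal(out$report$retained, panel_variables()$retained)
  expect_setequal(out$report$dropped, panel_variables()$dropped)
  expect_equal(ncol(out$panel$x), 19)
})
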