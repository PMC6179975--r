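# Synthetic data generators.

test_that("generators are pure functions of spec and seed", {
  g1 <- gen_rheometry_curve(rheo_spec(noise_sd = 0.2), seed = 3)
  g2 <- gen_rheometry_curve(rheo_spec(noise_sd = 0.2), seed = 3)
  expect_identical(g1$curve, g2$curve)
  p1 <- gen_feature_panel(seed = 4)
  p2 <- gen_feature_panel(seed = 4)
  expect_identical(p1$panel$x, p2$panel$x)
  expect_identical(p1$labels, p2$labels)
  s1 <- gen_sensory_scores(seed = 5)
  s2 <- gen_sensory_scores(seed = 5)
  expect_identical(s1$scores, s2$scores)
})

test_that("inconsistent curve specs are rejected", {
  expect_rt_error(rheo_spec(Gmax = 20, Gtrough = 20), "spec")
  expect_rt_error(rheo_spec(gel_temp = 92, temp_at_Gmax = 90), "spec")
  expect_rt_error(rva_spec(PV = 2, TV = 2.5), "spec")
  expect_rt_error(tpa_spec(area1 = 0.5, peak1 = 2, T1 = 1.6), "spec")
})

test_that("planted pasting landmarks round-trip through extraction", {
  g <- gen_pasting_curve(rva_spec(PV = 2.49, TV = 1.39, FV = 2.64))
  f <- extract_pasting_features(g$curve)
  expect_equal(f$BD, 1.10, tolerance = 1e-9)
  expect_equal(f$SB, 0.15, tolerance = 1e-9)
  expect_equal(f$LO, 1.25, tolerance = 1e-9)
  expect_gte(f$PTemp, g$truth$onset_temp)
  expect_lt(f$PTemp, g$truth$onset_temp + 3)
})

test_that("planted TPA areas give the planted cohesiveness ratio", {
  g <- gen_tpa_curve(tpa_spec(area1 = 2.0, area2 = 0.88))
  f <- extract_tpa_features(g$curve)
  expect_equal(f$COH, 0.44, tolerance = 1e-2)
})

test_that("doubling the sampling rate leaves extracted features unchanged within tolerance", {
  f1 <- extract_pasting_features(gen_pasting_curve(rva_spec(dt = 0.01))$curve)
  f2 <- extract_pasting_features(gen_pasting_curve(rva_spec(dt = 0.005))$curve)
  for (v in c("PV", "TV", "FV", "BD", "SB", "LO")) {
    expect_equal(f1[[v]], f2[[v]], tolerance = 1e-6)
  }
  expect_lt(abs(f1$PT - f2$PT), 0.011)

  t1 <- extract_tpa_features(gen_tpa_curve(tpa_spec(dt = 0.002))$curve)
  t2 <- extract_tpa_features(gen_tpa_curve(tpa_spec(dt = 0.001))$curve)
  expect_equal(t1$COH, t2$COH, tolerance = 1e-2)
  expect_equal(t1$HRD, t2$HRD, tolerance = 1e-6)
})

test_that("zero-SD panels collapse onto the cluster mean vectors", {
  arch <- quality_archetypes()
  gp <- gen_feature_panel(sizes = c(4, 3, 2), sds = arch$sds * 0, seed = 6)
  for (k in 1:3) {
    rows <- gp$panel$x[gp$labels == k, , drop = FALSE]
    expect_equal(unname(t(rows)),
                 matrix(arch$means[, k], ncol(gp$panel$x), nrow(rows)),
                 tolerance = 1e-10)
  }
})

test_that("large panels recover the archetype means within the CLT bound", {
  arch <- quality_archetypes()
  n <- 4000
  gp <- gen_feature_panel(sizes = rep(n, 3), seed = 7)
  for (k in 1:3) {
    mu <- colMeans(gp$panel$x[gp$labels == k, ])
    expect_true(all(abs(mu - arch$means[, k]) <=
                      3 * arch$sds[, k] / sqrt(n) + 1e-9))
  }
})

test_that("the default correlation structure is a valid correlation matrix", {
  R <- default_panel_correlation()
  expect_equal(unname(diag(R)), rep(1, 19))
  expect_equal(R, t(R))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_lt(attr(R, "psd_repair"), 0.05)
})

test_that("generated panels carry the planted redundancy structure", {
  gp <- gen_feature_panel(full = TRUE, seed = 8)
  x <- gp$panel$x
  expect_equal(unname(x[, "TV"]), unname(x[, "PV"] - x[, "BD"]))
  expect_equal(unname(x[, "FV"]), unname(x[, "PV"] + x[, "SB"]))
  expect_equal(unname(x[, "GppGmax"]),
               unname(x[, "TandGmax"] * x[, "Gmax"]))
  r <- pearson_matrix(x)$r
  expect_gt(r["PTemp", "GT"], 0.75)
  expect_gt(r["TV", "PV"], 0.75)
  expect_lt(r["TempGmax", "Gmax"], -0.70)
})

test_that("sensory generation respects the line scale and truncation", {
  g <- gen_sensory_scores(n_samples = 10, n_panelists = 8,
                          panelist_sd = 40, seed = 9)
  expect_true(all(g$scores$intensity_mm >= 0 & g$scores$intensity_mm <= 150))
  expect_rt_error(gen_sensory_scores(means = sensory_archetypes()$means + 200),
                  "spec")
})

test_that("best-permutation label matching behaves as an accuracy", {
  truth <- rep(1:3, each = 5)
  relab <- c(3, 1, 2)[truth]
  expect_equal(label_match_accuracy(relab, truth), 100)
  flipped <- truth
  flipped[1] <- 2
  expect_equal(label_match_accuracy(flipped, truth), 100 * 14 / 15)
})

test_that("the Bayes ceiling of the default generator is a high but bounded accuracy", {
  acc <- bayes_accuracy(n_mc = 4000, seed = 2)
  expect_gt(acc, 80)
  expect_lte(acc, 100)
})
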