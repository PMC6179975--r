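# Landmark extraction from instrument traces.

test_that("rheometry extraction recovers planted landmarks on a noiseless curve", {
  spec <- rheo_spec(gel_temp = 75, Gmax = 40, temp_at_Gmax = 90, Gtrough = 15)
  g <- gen_rheometry_curve(spec)
  f <- extract_rheometry_features(g$curve)
  dt <- spec$dt
  expect_lt(abs(f$gel_temp - 75), spec$rate * dt + 1e-9)
  expect_lt(abs(f$gel_time - g$truth$gel_time), dt + 1e-9)
  expect_equal(f$Gmax, 40, tolerance = 1e-6)
  expect_lt(abs(f$temp_at_Gmax - 90), spec$rate * dt + 1e-9)
  expect_equal(f$Gtrough, 15, tolerance = 1e-6)
  expect_equal(f$S1, g$truth$S1, tolerance = 0.02)
  expect_equal(f$S2, g$truth$S2, tolerance = 0.02)
  expect_lt(f$S2, 0)             # decline is signed
  expect_equal(f$tand_at_Gmax, g$truth$tand_at_Gmax, tolerance = 1e-3)
})

test_that("tan-delta ratio identity holds exactly and matches the reported-means arithmetic", {
  f <- extract_rheometry_features(gen_rheometry_curve(rheo_spec())$curve)
  expect_identical(f$tand_at_Gmax * f$Gmax, f$Gpp_at_Gmax)
  # the cluster-1 reporting: G'max 40.64 kPa at tan delta 0.11 implies
  # G'' about 4.47 kPa by the same identity
  expect_equal(40.64 * 0.11, 4.47, tolerance = 0.01)
})

test_that("a curve with identical moduli has no gel point", {
  t <- seq(0, 30, by = 0.1)
  temp <- ifelse(t <= 15, 35 + 4 * t, 95 - 4 * (t - 15))
  g <- 2 + t
  expect_rt_error(extract_rheometry_features(rheo_curve(t, temp, g, g)),
                  "no_gel_point")
})

test_that("monotonically rising G' yields a no-trough flag with absent G'trough", {
  f <- extract_rheometry_features(rising_rheo_curve())
  expect_true("no_trough" %in% f$flags)
  expect_true(is.na(f$Gtrough))
  expect_true(is.na(f$S2))
})

test_that("rheometry landmarks are stable under denser resampling", {
  f1 <- extract_rheometry_features(gen_rheometry_curve(rheo_spec(dt = 0.05))$curve)
  f2 <- extract_rheometry_features(gen_rheometry_curve(rheo_spec(dt = 0.025))$curve)
  expect_lt(abs(f1$gel_time - f2$gel_time), 0.05)
  expect_lt(abs(f1$time_at_Gmax - f2$time_at_Gmax), 0.05)
  expect_lt(abs(f1$Gmax - f2$Gmax), 1e-3)
  expect_lt(abs(f1$Gtrough - f2$Gtrough), 1e-3)
})

test_that("noisy rheometry traces are recoverable with smoothing", {
  spec <- rheo_spec(noise_sd = 0.3)
  g <- gen_rheometry_curve(spec, seed = 11)
  f <- extract_rheometry_features(g$curve, curve_config(smooth_window = 5))
  expect_lt(abs(f$gel_temp - spec$gel_temp), 1.5)
  expect_lt(abs(f$Gmax - spec$Gmax), 1)
  expect_lt(abs(f$Gtrough - spec$Gtrough), 1)
})

test_that("pasting extraction matches the brute-force scan oracle", {
  g <- gen_pasting_curve(rva_spec(PV = 2.49, TV = 1.39, FV = 2.64, PT = 5.89))
  cv <- g$curve
  f <- extract_pasting_features(cv)
  stage_end <- max(which(cv$temperature > 94.5))
  o <- oracle_pasting(cv$time, cv$viscosity, stage_end)
  expect_equal(f$PV, o$PV)
  expect_equal(f$PT, o$PT)
  expect_equal(f$TV, o$TV)
  expect_equal(f$FV, o$FV)
  expect_equal(f$PV, 2.49, tolerance = 1e-9)
  expect_equal(f$PT, 5.89, tolerance = 1e-9)
  expect_equal(f$BD, 1.10, tolerance = 1e-9)
  expect_equal(f$SB, 0.15, tolerance = 1e-9)
  expect_equal(f$LO, 1.25, tolerance = 1e-9)
  # the reference cluster-3 means round the same identity to 1.24
  expect_lt(abs((1.10 + 0.15) - 1.24), 0.011)
})

test_that("pasting identities hold to machine precision on arbitrary curves", {
  for (s in 1:10) {
    set.seed(s)
    pv <- runif(1, 1.5, 3.5)
    tv <- pv - runif(1, 0.2, 1)
    fv <- tv + runif(1, 0.2, 1.5)
    f <- extract_pasting_features(
      gen_pasting_curve(rva_spec(PV = pv, TV = tv, FV = fv,
                                 noise_sd = 0.01), seed = s)$curve)
    expect_identical(f$BD, f$PV - f$TV)
    expect_identical(f$SB, f$FV - f$PV)
    expect_identical(f$LO, f$FV - f$TV)
    expect_equal(f$LO, f$BD + f$SB, tolerance = 1e-12)
    expect_lte(f$TV, f$PV)
  }
})

test_that("a flat viscosity trace gives zero derived parameters and no pasting onset", {
  t <- seq(0, 12.5, by = 0.05)
  temp <- ifelse(t <= 4.8, 50 + 45 * t / 4.8,
          ifelse(t <= 7.3, 95, pmax(95 - 45 * (t - 7.3) / 4.5, 50)))
  f <- extract_pasting_features(rva_curve(t, temp, rep(1, length(t))))
  expect_equal(f$PV, 1)
  expect_equal(f$TV, 1)
  expect_equal(f$FV, 1)
  expect_equal(f$BD, 0)
  expect_equal(f$SB, 0)
  expect_equal(f$LO, 0)
  expect_true(is.na(f$PTemp))
  expect_true("no_pasting_onset" %in% f$flags)
})

test_that("a monotone declining curve flags the missing trough and sets TV = FV", {
  t <- seq(0, 12.5, by = 0.05)
  temp <- ifelse(t <= 4.8, 50 + 45 * t / 4.8,
          ifelse(t <= 7.3, 95, pmax(95 - 45 * (t - 7.3) / 4.5, 50)))
  v <- 3 - 0.1 * t
  f <- extract_pasting_features(rva_curve(t, temp, v))
  expect_true("no_trough" %in% f$flags)
  expect_equal(f$TV, f$FV)
})

test_that("TPA extraction matches hand trapezoidal integration", {
  g <- gen_tpa_curve(tpa_spec(area1 = 2.0, area2 = 0.88, peak1 = 1.96,
                              area_neg = 0.02))
  f <- extract_tpa_features(g$curve)
  expect_equal(f$HRD, 1.96, tolerance = 1e-6)
  expect_equal(f$COH, 0.44, tolerance = 1e-2)
  expect_equal(f$ADH, 0.02, tolerance = 1e-3)
  # oracle: integrate the positive and negative parts of the trace directly
  cv <- g$curve
  pos_area <- oracle_trapz(cv$time, pmax(cv$force, 0))
  neg_area <- abs(oracle_trapz(cv$time, pmin(cv$force, 0)))
  expect_equal(f$area1 + f$area2, pos_area, tolerance = 1e-6)
  expect_equal(f$ADH, neg_area, tolerance = 1e-6)
})

test_that("two identical lobes give unit cohesiveness and zero adhesiveness", {
  dt <- 0.002
  tri <- c(seq(0, 1, by = dt), seq(1 - dt, 0, by = -dt))
  f0 <- rep(0, 100)
  force <- c(f0, tri, f0, tri, f0)
  t <- seq_along(force) * dt
  f <- extract_tpa_features(tpa_curve(t, force))
  expect_equal(f$COH, 1, tolerance = 1e-6)
  expect_equal(f$ADH, 0)
  expect_equal(f$HRD, 1)
  expect_equal(f$SPR, 1, tolerance = 1e-6)
})

test_that("an all-zero force trace has no compression peaks", {
  expect_rt_error(
    extract_tpa_features(tpa_curve(seq(0, 5, 0.01), rep(0, 501))),
    "no_compression_peaks")
})

test_that("a single-lobe trace has no second compression", {
  t <- seq(0, 3, by = 0.005)
  force <- pmax(1 - abs(t - 1), 0)
  expect_rt_error(extract_tpa_features(tpa_curve(t, force)),
                  "no_compression_peaks")
})

test_that("curve constructors validate their invariants", {
  expect_rt_error(rheo_curve(c(1, 1, 2), c(35, 40, 45), 1:3, 1:3), "curve")
  expect_rt_error(rva_curve(1:3, c(50, 60, 70), c(-1, 1, 1)), "curve")
  expect_rt_error(tpa_curve(1:3, c(0, NA, 1)), "curve")
})
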