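# Independent oracles and small fixtures shared across tests.

# brute-force scan of a sampled pasting curve: max over the heat+hold
# window, min after it, last value
oracle_pasting <- function(time, visc, stage_end) {
  i_pv <- which.max(visc[seq_len(stage_end)])
  i_tv <- if (i_pv < length(visc)) i_pv + which.min(visc[(i_pv + 1):length(visc)]) else i_pv
  list(PV = visc[i_pv], PT = time[i_pv], TV = visc[i_tv],
       FV = visc[length(visc)])
}

# hand trapezoidal integration (independent of the package's trapz)
oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + (y[i] + y[i + 1]) * (x[i + 1] - x[i]) / 2
  }
  s
}

# a handcrafted rheometry curve with a tan-delta crossing but a G' that
# keeps rising to the final sample (no trough)
rising_rheo_curve <- function() {
  t <- seq(0, 30, by = 0.1)
  temp <- ifelse(t <= 15, 35 + 4 * t, 95 - 4 * (t - 15))
  gp <- 2 + 38 * (t / 30)^2
  tand <- 0.1 + 2.4 / (1 + exp((t - 8) / 1.2))
  rheo_curve(t, temp, gp, gp * tand)
}

# three-cluster toy panel with obvious separation for exact-recovery
# clustering tests
toy_separated_panel <- function(n_per = 10, gap = 100, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = gap), n_per, 2))
  colnames(x) <- c("v1", "v2")
  rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
  x
}

# draw one multinomial data set from known coefficients (reference
# class 1, scores 0 / b2.x / b3.x with intercepts)
simulate_mlr <- function(n, B, seed) {
  # B: (p+1) x 2 matrix, columns are classes 2 and 3
  set.seed(seed)
  p <- nrow(B) - 1
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  eta <- cbind(0, cbind(1, x) %*% B)
  pr <- exp(eta) / rowSums(exp(eta))
  y <- apply(pr, 1, function(q) sample.int(3, 1, prob = q))
  list(x = x, y = y)
}

expect_rt_error <- function(expr, code) {
  expect_error(expr, class = paste0("ricotype_", code))
}
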