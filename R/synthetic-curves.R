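# Synthetic instrument traces with planted, recoverable landmarks.
#
# Each generator builds a smooth piecewise curve through the requested
# landmark geometry, optionally adds Gaussian noise, and returns the
# curve together with the ground-truth record. Generators are pure
# functions of (spec, seed).

#' Specification for a synthetic rheometry curve
#'
#' @param gel_temp Planted gel-point temperature (degC, on the heating
#'   ramp): where tan(delta) crosses 1.
#' @param Gmax,temp_at_Gmax Planted storage-modulus maximum (kPa) and its
#'   temperature (degC); must be reached after the gel point.
#' @param Gtrough Planted storage-modulus trough after the peak (kPa),
#'   strictly below `Gmax`.
#' @param g0 Baseline storage modulus before gelation (kPa).
#' @param r0,r_end,r_width Tan-delta profile: starting value (> 1), final
#'   plateau (< 1) and logistic transition width (min). The profile is
#'   monotone decreasing, so tan(delta) crosses 1 exactly once.
#' @param trough_lag Minutes from the G' peak to the trough.
#' @param rebound Small G' rise after the trough (kPa), keeping the
#'   trough unique; must satisfy `Gtrough + rebound < Gmax`.
#' @param ramp Temperature range degC (start, peak) of the symmetric
#'   heat/cool program.
#' @param rate Ramp rate degC/min.
#' @param dt Sampling interval (min).
#' @param noise_sd SD of additive Gaussian noise on both moduli (kPa).
#' @return A list of class `rheo_spec`.
#' @export
rheo_spec <- function(gel_temp = 75, Gmax = 40, temp_at_Gmax = 90,
                      Gtrough = 15, g0 = 2, r0 = 2.5, r_end = 0.08,
                      r_width = 1.5, trough_lag = 6, rebound = 2,
                      ramp = c(35, 95), rate = 4, dt = 0.05,
                      noise_sd = 0) {
  rt_assert(gel_temp > ramp[1] && gel_temp < ramp[2], "spec",
            "gel_temp must lie inside the heating ramp")
  rt_assert(temp_at_Gmax > gel_temp && temp_at_Gmax <= ramp[2], "spec",
            "temp_at_Gmax must be after the gel point and within the ramp")
  rt_assert(Gtrough < Gmax, "spec", "Gtrough must be strictly below Gmax")
  rt_assert(g0 > 0 && g0 < Gmax, "spec", "need 0 < g0 < Gmax")
  rt_assert(r0 > 1 && r_end > 0 && r_end < 1, "spec",
            "tan-delta profile needs r0 > 1 and 0 < r_end < 1")
  rt_assert(Gtrough + rebound < Gmax, "spec",
            "post-trough rebound would exceed Gmax")
  rt_assert(trough_lag > 0 && dt > 0 && noise_sd >= 0, "spec",
            "trough_lag and dt must be positive; noise_sd non-negative")
  structure(as.list(environment()), class = "rheo_spec")
}

half_cos <- function(u) (1 - cos(pi * pmin(pmax(u, 0), 1))) / 2

#' Generate a synthetic rheometry curve
#'
#' Builds G'(t) as baseline -> cosine rise to the planted maximum ->
#' cosine fall to the planted trough -> slight rebound, and
#' G''(t) = G'(t) * tan_delta(t) with a monotone-decreasing logistic
#' tan-delta profile crossing 1 exactly at the planted gel temperature.
#'
#' @param spec A [rheo_spec()].
#' @param seed RNG seed for the additive noise.
#' @param sample_id Carried into the curve.
#' @return A list with `curve` (a [rheo_curve()]) and `truth` (planted
#'   landmark record including closed-form S1 and S2).
#' @export
gen_rheometry_curve <- function(spec = rheo_spec(), seed = NULL,
                                sample_id = NA_character_) {
  stopifnot(inherits(spec, "rheo_spec"))
  s <- spec
  t_total <- 2 * (s$ramp[2] - s$ramp[1]) / s$rate
  t <- seq(0, t_total, by = s$dt)
  t_half <- t_total / 2
  temp <- ifelse(t <= t_half, s$ramp[1] + s$rate * t,
                 s$ramp[2] - s$rate * (t - t_half))

  t_gel <- (s$gel_temp - s$ramp[1]) / s$rate
  t_peak <- (s$temp_at_Gmax - s$ramp[1]) / s$rate
  t_rise0 <- max(0, t_gel - 3)
  t_trough <- t_peak + s$trough_lag
  rt_assert(t_trough < t_total, "spec", "trough would fall beyond the trace")

  gp <- numeric(length(t))
  gp[t < t_rise0] <- s$g0
  up <- t >= t_rise0 & t <= t_peak
  gp[up] <- s$g0 + (s$Gmax - s$g0) * half_cos((t[up] - t_rise0) / (t_peak - t_rise0))
  dn <- t > t_peak & t <= t_trough
  gp[dn] <- s$Gmax - (s$Gmax - s$Gtrough) * half_cos((t[dn] - t_peak) / s$trough_lag)
  tail_ <- t > t_trough
  gp[tail_] <- s$Gtrough + s$rebound *
    half_cos((t[tail_] - t_trough) / (t_total - t_trough))

  t0 <- t_gel - s$r_width * log((s$r0 - 1) / (1 - s$r_end))
  tand <- s$r_end + (s$r0 - s$r_end) / (1 + exp((t - t0) / s$r_width))
  gpp <- gp * tand

  if (s$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    gp <- pmax(gp + rnorm(length(t), 0, s$noise_sd), 0)
    gpp <- pmax(gpp + rnorm(length(t), 0, s$noise_sd), 0)
  }

  gp_gel <- s$g0 + (s$Gmax - s$g0) * half_cos((t_gel - t_rise0) / (t_peak - t_rise0))
  truth <- list(gel_temp = s$gel_temp, gel_time = t_gel,
                Gmax = s$Gmax, temp_at_Gmax = s$temp_at_Gmax,
                time_at_Gmax = t_peak,
                Gtrough = s$Gtrough, time_at_trough = t_trough,
                S1 = (s$Gmax - gp_gel) / (t_peak - t_gel),
                S2 = (s$Gtrough - s$Gmax) / s$trough_lag,
                tand_at_Gmax = s$r_end + (s$r0 - s$r_end) /
                  (1 + exp((t_peak - t0) / s$r_width)))
  list(curve = rheo_curve(t, temp, gp, gpp, sample_id = sample_id),
       truth = truth, spec = spec)
}

#' Specification for a synthetic RVA pasting curve
#'
#' @param PV,TV,FV Planted peak, trough and final viscosities
#'   (instrument units); `TV < PV`, `TV <= FV`.
#' @param PT Planted peak time (min), within the heating/holding stages
#'   and after the pasting onset.
#' @param onset_temp Temperature (degC) at which viscosity starts rising
#'   on the heating ramp.
#' @param v0 Baseline viscosity before pasting.
#' @param t_trough Time of the trough (min), between `PT` and the end.
#' @param heat_end,hold_end,cool_end,t_total Stage boundaries (min) of
#'   the heat (50-95 degC) - hold (95) - cool (95-50) program.
#' @param temp_range degC range of the program.
#' @param dt Sampling interval (min).
#' @param noise_sd Additive Gaussian noise SD.
#' @param units Viscosity unit string carried through.
#' @return A list of class `rva_spec`.
#' @export
rva_spec <- function(PV = 2.49, TV = 1.39, FV = 2.64, PT = 5.89,
                     onset_temp = 75, v0 = 0.05, t_trough = 8.5,
                     heat_end = 4.8, hold_end = 7.3, cool_end = 11.8,
                     t_total = 12.5, temp_range = c(50, 95), dt = 0.01,
                     noise_sd = 0, units = "instrument") {
  rt_assert(TV < PV, "spec", "need TV < PV")
  rt_assert(FV >= TV, "spec", "need FV >= TV")
  rt_assert(v0 < PV, "spec", "baseline must be below PV")
  rt_assert(onset_temp > temp_range[1] && onset_temp < temp_range[2],
            "spec", "onset_temp must lie inside the heating range")
  t_onset <- heat_end * (onset_temp - temp_range[1]) / diff(temp_range)
  rt_assert(PT > t_onset && PT <= hold_end, "spec",
            "PT must fall after pasting onset and within heat+hold")
  rt_assert(t_trough > PT && t_trough < t_total, "spec",
            "t_trough must lie between PT and the end")
  rt_assert(heat_end < hold_end && hold_end < cool_end && cool_end <= t_total,
            "spec", "stage boundaries must be increasing")
  structure(c(as.list(environment())), class = "rva_spec")
}

#' Generate a synthetic RVA pasting curve
#'
#' @param spec An [rva_spec()].
#' @param seed RNG seed for the additive noise.
#' @param sample_id Carried into the curve.
#' @return A list with `curve` (an [rva_curve()]) and `truth` (planted
#'   PV/TV/FV/PT, the derived BD/SB/LO identities and the onset
#'   temperature).
#' @export
gen_pasting_curve <- function(spec = rva_spec(), seed = NULL,
                              sample_id = NA_character_) {
  stopifnot(inherits(spec, "rva_spec"))
  s <- spec
  t <- seq(0, s$t_total, by = s$dt)
  temp <- ifelse(t <= s$heat_end,
                 s$temp_range[1] + diff(s$temp_range) * t / s$heat_end,
          ifelse(t <= s$hold_end, s$temp_range[2],
          ifelse(t <= s$cool_end,
                 s$temp_range[2] - diff(s$temp_range) *
                   (t - s$hold_end) / (s$cool_end - s$hold_end),
                 s$temp_range[1])))
  v <- numeric(length(t))
  v[t <= s$t_onset] <- s$v0
  up <- t > s$t_onset & t <= s$PT
  v[up] <- s$v0 + (s$PV - s$v0) * half_cos((t[up] - s$t_onset) / (s$PT - s$t_onset))
  dn <- t > s$PT & t <= s$t_trough
  v[dn] <- s$PV - (s$PV - s$TV) * half_cos((t[dn] - s$PT) / (s$t_trough - s$PT))
  fin <- t > s$t_trough
  v[fin] <- s$TV + (s$FV - s$TV) * half_cos((t[fin] - s$t_trough) / (s$t_total - s$t_trough))
  if (s$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- pmax(v + rnorm(length(t), 0, s$noise_sd), 0)
  }
  truth <- list(PV = s$PV, TV = s$TV, FV = s$FV, PT = s$PT,
                BD = s$PV - s$TV, SB = s$FV - s$PV, LO = s$FV - s$TV,
                onset_temp = s$onset_temp, t_trough = s$t_trough)
  list(curve = rva_curve(t, temp, v, units = s$units, sample_id = sample_id),
       truth = truth, spec = spec)
}

#' Specification for a synthetic two-compression TPA curve
#'
#' Two triangular compression lobes with planted areas, first-lobe peak
#' force and downstroke times, plus an optional triangular pull-off
#' (negative) lobe after the first compression.
#'
#' @param area1,area2 Planted trapezoidal areas of the two positive
#'   lobes (kg.s); their ratio is the planted cohesiveness.
#' @param peak1 Planted peak force of lobe 1 (kg): the hardness.
#' @param peak2 Peak force of lobe 2 (kg).
#' @param T1,T2 Downstroke (rise) durations of the two lobes (s); their
#'   ratio T2/T1 is the planted springiness.
#' @param area_neg Planted negative-lobe area magnitude (kg.s): the
#'   adhesiveness.
#' @param neg_dur Negative-lobe duration (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Additive Gaussian force noise SD (kg).
#' @return A list of class `tpa_spec`.
#' @export
tpa_spec <- function(area1 = 2.0, area2 = 0.88, peak1 = 1.96, peak2 = 0.8,
                     T1 = 1.6, T2 = 0.18, area_neg = 0.02, neg_dur = 0.6,
                     dt = 0.002, noise_sd = 0) {
  rt_assert(area1 > 0 && peak1 > 0 && T1 > 0 && T2 > 0, "spec",
            "lobe-1 area, peak and downstroke times must be positive")
  rt_assert(area2 >= 0 && area_neg >= 0, "spec", "areas must be non-negative")
  fall1 <- 2 * area1 / peak1 - T1
  fall2 <- 2 * area2 / peak2 - T2
  rt_assert(fall1 > 0, "spec",
            "inconsistent lobe 1: area too small for the peak/downstroke")
  rt_assert(area2 == 0 || fall2 > 0, "spec",
            "inconsistent lobe 2: area too small for the peak/downstroke")
  structure(c(as.list(environment())), class = "tpa_spec")
}

#' Generate a synthetic two-compression TPA curve
#'
#' @param spec A [tpa_spec()].
#' @param seed RNG seed for the additive noise.
#' @param sample_id Carried into the curve.
#' @return A list with `curve` (a [tpa_curve()]) and `truth` (planted
#'   HRD, ADH, COH, SPR, T1, T2 and lobe areas).
#' @export
gen_tpa_curve <- function(spec = tpa_spec(), seed = NULL,
                          sample_id = NA_character_) {
  stopifnot(inherits(spec, "tpa_spec"))
  s <- spec
  tri <- function(t, t0, rise, fall, peak) {
    u <- t - t0
    ifelse(u >= 0 & u <= rise, peak * u / rise,
    ifelse(u > rise & u <= rise + fall, peak * (1 - (u - rise) / fall), 0))
  }
  pre <- 0.2; gap1 <- 0.05; gap2 <- 0.3; post <- 0.2
  t1s <- pre
  t1e <- t1s + s$T1 + s$fall1
  tns <- t1e + gap1
  tne <- tns + s$neg_dur
  t2s <- tne + gap2
  t2e <- t2s + s$T2 + s$fall2
  t <- seq(0, t2e + post, by = s$dt)

  f <- tri(t, t1s, s$T1, s$fall1, s$peak1) + tri(t, t2s, s$T2, s$fall2, s$peak2)
  if (s$area_neg > 0) {
    depth <- 2 * s$area_neg / s$neg_dur
    f <- f - tri(t, tns, s$neg_dur / 2, s$neg_dur / 2, depth)
  }
  if (s$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + rnorm(length(t), 0, s$noise_sd)
  }
  truth <- list(HRD = s$peak1, ADH = s$area_neg,
                COH = if (s$area1 > 0) s$area2 / s$area1 else NA_real_,
                SPR = s$T2 / s$T1, T1 = s$T1, T2 = s$T2,
                area1 = s$area1, area2 = s$area2)
  list(curve = tpa_curve(t, f, sample_id = sample_id),
       truth = truth, spec = spec)
}
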