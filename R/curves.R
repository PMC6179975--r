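# Instrument-curve containers and landmark extraction.
#
# Three trace types are supported: oscillatory rheometry (storage/loss
# moduli over a 35-95-35 degC temperature program), RVA pasting
# (viscosity over a heat-hold-cool program), and two-compression TPA
# (force over time). Extraction works on the sampled trace only; no
# parametric model is fitted.

#' Rheometry trace
#'
#' @param time Time in minutes, strictly increasing.
#' @param temperature Temperature in degC; one heating ramp followed by
#'   one cooling ramp.
#' @param g_prime Storage modulus G' (kPa), non-negative.
#' @param g_double_prime Loss modulus G'' (kPa), non-negative.
#' @param sample_id Optional sample identifier carried as metadata.
#' @return An object of class `rheo_curve`.
#' @export
rheo_curve <- function(time, temperature, g_prime, g_double_prime,
                       sample_id = NA_character_) {
  validate_trace(time, temperature)
  rt_assert(length(g_prime) == length(time) &&
            length(g_double_prime) == length(time),
            "curve", "moduli must have one value per time point")
  rt_assert(all(is.finite(g_prime)) && all(is.finite(g_double_prime)),
            "curve", "moduli must be finite")
  rt_assert(all(g_prime >= 0) && all(g_double_prime >= 0),
            "curve", "moduli must be non-negative")
  structure(list(time = as.numeric(time),
                 temperature = as.numeric(temperature),
                 g_prime = as.numeric(g_prime),
                 g_double_prime = as.numeric(g_double_prime),
                 sample_id = sample_id),
            class = "rheo_curve")
}

#' RVA pasting trace
#'
#' @param time Time in minutes, strictly increasing.
#' @param temperature Temperature in degC following a heat-hold-cool
#'   program.
#' @param viscosity Non-negative viscosity in instrument units.
#' @param units Unit string carried through to the features (the package
#'   performs no viscosity unit conversion).
#' @param sample_id Optional sample identifier.
#' @return An object of class `rva_curve`.
#' @export
rva_curve <- function(time, temperature, viscosity, units = "instrument",
                      sample_id = NA_character_) {
  validate_trace(time, temperature)
  rt_assert(length(viscosity) == length(time), "curve",
            "viscosity must have one value per time point")
  rt_assert(all(is.finite(viscosity)) && all(viscosity >= 0), "curve",
            "viscosity must be finite and non-negative")
  structure(list(time = as.numeric(time),
                 temperature = as.numeric(temperature),
                 viscosity = as.numeric(viscosity),
                 units = units, sample_id = sample_id),
            class = "rva_curve")
}

#' Two-compression TPA trace
#'
#' @param time Time in seconds, strictly increasing.
#' @param force Force in kg; positive during compression, negative during
#'   probe pull-off.
#' @param sample_id Optional sample identifier.
#' @return An object of class `tpa_curve`.
#' @export
tpa_curve <- function(time, force, sample_id = NA_character_) {
  rt_assert(length(time) >= 2 && all(diff(time) > 0), "curve",
            "time must be strictly increasing")
  rt_assert(length(force) == length(time) && all(is.finite(force)),
            "curve", "force must be finite with one value per time point")
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 sample_id = sample_id),
            class = "tpa_curve")
}

validate_trace <- function(time, temperature) {
  rt_assert(length(time) >= 2 && all(diff(time) > 0), "curve",
            "time must be strictly increasing")
  rt_assert(length(temperature) == length(time) && all(is.finite(temperature)),
            "curve", "temperature must be finite with one value per time point")
  invisible(TRUE)
}

# Centred moving average; window w must be odd (rounded up if even).
smooth_ma <- function(y, w) {
  if (w < 3) return(y)
  w <- as.integer(w); if (w %% 2L == 0L) w <- w + 1L
  k <- rep(1 / w, w)
  n <- length(y)
  pad <- (w - 1L) %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[n], pad))
  as.numeric(stats::filter(yp, k, sides = 2))[(pad + 1L):(pad + n)]
}

interp_at <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, ties = "ordered")$y
}

#' Extract rheometry landmark features
#'
#' Finds the gel point (first tan-delta = 1 crossing on the heating ramp,
#' by linear interpolation between the bracketing samples), the storage
#' modulus maximum G'max and the subsequent trough G'trough, the loss
#' modulus maximum G''max, and the four slope features: S1 (G' from gel
#' point to G'max), S2 (G' from G'max to G'trough), S3 (G'' from gel
#' point to G''max) and S4 (G'' from G''max to the level-off point, the
#' first subsequent sample where |dG''/dt| falls below
#' `config$level_off_eps`). Ties at maxima resolve to the earliest time.
#'
#' Slopes are returned signed (S2 and S4 are negative on a typical
#' trace); panel assembly stores their magnitudes, the field convention.
#' The ratio identity `tand_at_Gmax * Gmax == Gpp_at_Gmax` holds exactly
#' by construction.
#'
#' @param curve A [rheo_curve()] with at least 20 samples spanning both
#'   ramps.
#' @param config A [curve_config()].
#' @return An object of class `rheometry_features`: a list with elements
#'   `gel_temp`, `gel_time`, `Gmax`, `Gpp_at_Gmax`, `tand_at_Gmax`,
#'   `temp_at_Gmax`, `time_at_Gmax`, `Gtrough`, `S1`, `S2`, `S3`, `S4`
#'   and a character vector `flags`.
#' @export
extract_rheometry_features <- function(curve, config = curve_config()) {
  stopifnot(inherits(curve, "rheo_curve"))
  n <- length(curve$time)
  rt_assert(n >= 20, "curve", "rheometry trace needs at least 20 samples")
  t <- curve$time
  gp <- smooth_ma(curve$g_prime, config$smooth_window)
  gpp <- smooth_ma(curve$g_double_prime, config$smooth_window)
  temp <- curve$temperature
  flags <- character()

  i_heat_end <- which.max(temp)
  heat <- seq_len(i_heat_end)

  # gel point: first tan(delta) = 1 crossing on the heating ramp
  d <- ifelse(gp > 0, gpp / gp, Inf) - 1
  dh <- d[heat]
  if (all(abs(dh) < 1e-12)) {
    rt_stop("no_gel_point", "no gel point: tan(delta) identically 1 on the heating ramp")
  }
  cross <- which(dh[-length(dh)] * dh[-1] < 0 |
                   (abs(dh[-length(dh)]) < 1e-12 & abs(dh[-1]) > 1e-12))
  if (length(cross) == 0) {
    rt_stop("no_gel_point", "no gel point: tan(delta) does not cross 1 on the heating ramp")
  }
  i <- cross[1]
  if (abs(dh[i]) < 1e-12) {
    frac <- 0
  } else {
    frac <- dh[i] / (dh[i] - dh[i + 1])
  }
  gel_time <- t[i] + frac * (t[i + 1] - t[i])
  gel_temp <- temp[i] + frac * (temp[i + 1] - temp[i])
  gp_gel <- gp[i] + frac * (gp[i + 1] - gp[i])
  gpp_gel <- gpp[i] + frac * (gpp[i + 1] - gpp[i])

  # storage-modulus maximum and trough
  i_max <- which.max(gp)
  Gmax <- gp[i_max]
  Gpp_at_Gmax <- gpp[i_max]
  tand_at_Gmax <- Gpp_at_Gmax / Gmax
  if (i_max < n) {
    i_tr <- i_max + which.min(gp[(i_max + 1):n])
    Gtrough <- gp[i_tr]
    S2 <- (Gtrough - Gmax) / (t[i_tr] - t[i_max])
  } else {
    flags <- c(flags, "no_trough")
    i_tr <- NA_integer_
    Gtrough <- NA_real_
    S2 <- NA_real_
  }

  # loss-modulus maximum and level-off
  scope <- if (config$gpp_max_scope == "heating") heat else seq_len(n)
  i_gppmax <- scope[which.max(gpp[scope])]
  Gpp_max <- gpp[i_gppmax]
  S1 <- (Gmax - gp_gel) / (t[i_max] - gel_time)
  S3 <- (Gpp_max - gpp_gel) / (t[i_gppmax] - gel_time)
  # S4 endpoint: the G'' decline after its maximum must first get under
  # way (rate <= -eps) before the first |rate| < eps sample counts as
  # the level-off point; otherwise the flat top of the peak itself would
  # qualify.
  S4 <- NA_real_
  if (i_gppmax < n) {
    rate <- diff(gpp) / diff(t)          # rate[j] is the step into sample j+1
    idx <- seq_len(n - 1)
    dec <- which(rate <= -config$level_off_eps & idx >= i_gppmax)
    if (length(dec) == 0) {
      flags <- c(flags, "no_level_off")
    } else {
      lev <- which(abs(rate) < config$level_off_eps & idx > dec[1])
      if (length(lev) > 0) {
        j <- lev[1] + 1L
      } else {
        j <- n
        flags <- c(flags, "no_level_off")
      }
      S4 <- (gpp[j] - Gpp_max) / (t[j] - t[i_gppmax])
    }
  } else {
    flags <- c(flags, "no_level_off")
  }

  structure(list(gel_temp = gel_temp, gel_time = gel_time,
                 Gmax = Gmax, Gpp_at_Gmax = Gpp_at_Gmax,
                 tand_at_Gmax = tand_at_Gmax,
                 temp_at_Gmax = temp[i_max], time_at_Gmax = t[i_max],
                 Gtrough = Gtrough, Gpp_max = Gpp_max,
                 temp_at_Gpp_max = temp[i_gppmax],
                 S1 = S1, S2 = S2, S3 = S3, S4 = S4,
                 sample_id = curve$sample_id, flags = flags),
            class = "rheometry_features")
}

#' Extract RVA pasting features
#'
#' Peak viscosity (PV) is the maximum viscosity over the heating and
#' holding stages (earliest sample on ties), with peak time PT; trough
#' viscosity (TV) is the minimum after the peak; final viscosity (FV) is
#' the last sample. Breakdown, setback and lift-off are the exact
#' identities `BD = PV - TV`, `SB = FV - PV`, `LO = FV - TV` (so
#' `LO = BD + SB` always). The pasting temperature PTemp is the
#' temperature at the first sample whose forward-difference viscosity
#' rate exceeds `config$ptemp_rate`; if the rate is never exceeded PTemp
#' is `NA` and the result is flagged.
#'
#' @param curve An [rva_curve()] covering the heat-hold-cool program.
#' @param config A [curve_config()].
#' @return An object of class `pasting_features` with elements `PV`,
#'   `TV`, `FV`, `BD`, `SB`, `LO`, `PT`, `PTemp`, `units` and `flags`.
#' @export
extract_pasting_features <- function(curve, config = curve_config()) {
  stopifnot(inherits(curve, "rva_curve"))
  t <- curve$time
  v <- smooth_ma(curve$viscosity, config$smooth_window)
  temp <- curve$temperature
  n <- length(t)
  flags <- character()

  # heating + holding stage: everything before the temperature starts
  # its descent from the hold plateau (0.5 degC tolerance)
  i_tmax <- which.max(temp)
  after <- if (i_tmax < n) which(temp < temp[i_tmax] - 0.5 & seq_len(n) > i_tmax) else integer()
  stage_end <- if (length(after) > 0) after[1] - 1L else n

  i_pv <- which.max(v[seq_len(stage_end)])
  PV <- v[i_pv]
  PT <- t[i_pv]
  if (i_pv < n) {
    i_tv <- i_pv + which.min(v[(i_pv + 1):n])
  } else {
    i_tv <- n
  }
  if (i_tv == n) flags <- c(flags, "no_trough")
  TV <- v[i_tv]
  FV <- v[n]

  rate <- diff(v) / diff(t)
  onset <- which(rate > config$ptemp_rate)
  if (length(onset) > 0) {
    PTemp <- temp[onset[1]]
  } else {
    PTemp <- NA_real_
    flags <- c(flags, "no_pasting_onset")
  }

  structure(list(PV = PV, TV = TV, FV = FV,
                 BD = PV - TV, SB = FV - PV, LO = FV - TV,
                 PT = PT, PTemp = PTemp,
                 units = curve$units, sample_id = curve$sample_id,
                 flags = flags),
            class = "pasting_features")
}

#' Extract TPA features from a two-compression trace
#'
#' The trace must contain two positive force lobes separated by a
#' zero-force gap, with an optional negative (pull-off) lobe after the
#' first compression. Hardness (HRD) is the peak force of the first lobe;
#' cohesiveness (COH) is the ratio of the second lobe's trapezoidal area
#' to the first's; adhesiveness (ADH) is the magnitude of the negative
#' lobe area (the sign only encodes direction and is recorded in the
#' `adh_sign` field); springiness (SPR) is the downstroke-duration ratio
#' T2/T1, where Tk is the time from first sample contact of lobe k to its
#' peak.
#'
#' @param curve A [tpa_curve()].
#' @param config A [curve_config()]; `force_eps` separates lobes from
#'   baseline.
#' @return An object of class `tpa_features` with elements `HRD`, `ADH`,
#'   `COH`, `SPR`, `T1`, `T2`, `area1`, `area2`, `adh_sign` and `flags`.
#' @export
extract_tpa_features <- function(curve, config = curve_config()) {
  stopifnot(inherits(curve, "tpa_curve"))
  t <- curve$time
  f <- smooth_ma(curve$force, config$smooth_window)
  eps <- config$force_eps

  pos <- f > eps
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  lobe_idx <- which(runs$values)
  # discard low-prominence runs (baseline noise crossings): a real
  # compression lobe reaches a sizeable fraction of the trace maximum
  if (length(lobe_idx) > 0) {
    peak_of <- vapply(lobe_idx, function(i) max(f[starts[i]:ends[i]]),
                      numeric(1))
    lobe_idx <- lobe_idx[peak_of >= 0.05 * max(f)]
  }
  if (length(lobe_idx) < 2) {
    rt_stop("no_compression_peaks",
            "fewer than two positive compression lobes detected")
  }
  l1 <- c(starts[lobe_idx[1]], ends[lobe_idx[1]])
  l2 <- c(starts[lobe_idx[2]], ends[lobe_idx[2]])

  # integrate including one flanking baseline sample on each side so the
  # zero crossings contribute
  lobe_area <- function(lim) {
    i0 <- max(1L, lim[1] - 1L); i1 <- min(length(t), lim[2] + 1L)
    trapz(t[i0:i1], pmax(f[i0:i1], 0))
  }
  area1 <- lobe_area(l1)
  area2 <- lobe_area(l2)
  if (area1 <= eps) {
    rt_stop("zero_first_lobe", "first compression lobe has zero area; COH undefined")
  }

  i_pk1 <- l1[1] - 1L + which.max(f[l1[1]:l1[2]])
  i_pk2 <- l2[1] - 1L + which.max(f[l2[1]:l2[2]])
  HRD <- f[i_pk1]
  T1 <- t[i_pk1] - t[l1[1]]
  T2 <- t[i_pk2] - t[l2[1]]
  rt_assert(T1 > 0, "curve", "degenerate first lobe: peak at first contact sample")

  # negative lobe between the two compressions
  gap <- seq(l1[2], l2[1])
  ADH <- abs(trapz(t[gap], pmin(f[gap], 0)))

  structure(list(HRD = HRD, ADH = ADH, COH = area2 / area1,
                 SPR = T2 / T1, T1 = T1, T2 = T2,
                 area1 = area1, area2 = area2,
                 adh_sign = "magnitude (negative lobe, sign encodes direction only)",
                 sample_id = curve$sample_id, flags = character()),
            class = "tpa_features")
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @export
print.rheometry_features <- function(x, ...) {
  cat("Rheometry features", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"), "\n")
  cat(sprintf("  gel point: %.2f degC (t = %.2f min)\n", x$gel_temp, x$gel_time))
  cat(sprintf("  G'max %.2f kPa at %.1f degC; G'' there %.2f kPa (tan delta %.3f)\n",
              x$Gmax, x$temp_at_Gmax, x$Gpp_at_Gmax, x$tand_at_Gmax))
  cat(sprintf("  G'trough %.2f kPa; slopes S1 %.2f S2 %.2f S3 %.2f S4 %.2f kPa/min\n",
              x$Gtrough, x$S1, x$S2, x$S3, x$S4))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pasting_features <- function(x, ...) {
  cat("Pasting features", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"), "\n")
  cat(sprintf("  PV %.3f TV %.3f FV %.3f (%s); BD %.3f SB %.3f LO %.3f\n",
              x$PV, x$TV, x$FV, x$units, x$BD, x$SB, x$LO))
  cat(sprintf("  peak time %.2f min; pasting temp %s\n", x$PT,
              if (is.na(x$PTemp)) "not detected" else sprintf("%.1f degC", x$PTemp)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.tpa_features <- function(x, ...) {
  cat("TPA features", if (!is.na(x$sample_id)) paste0("[", x$sample_id, "]"), "\n")
  cat(sprintf("  HRD %.3f kg; ADH %.4f kg.s (%s)\n", x$HRD, x$ADH, x$adh_sign))
  cat(sprintf("  COH %.3f; SPR %.3f (T1 %.2f s, T2 %.2f s)\n",
              x$COH, x$SPR, x$T1, x$T2))
  invisible(x)
}
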