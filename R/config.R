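#' Curve-extraction configuration
#'
#' Thresholds used by the landmark extractors. All defaults are applied
#' uniformly across samples; none are instrument-specific.
#'
#' @param smooth_window Centred moving-average window (samples) applied to
#'   the measured channel before landmark detection; `0` disables
#'   smoothing. Noiseless fixtures should use `0`; for noisy traces a
#'   window of 5 is a reasonable starting point.
#' @param level_off_eps Rate threshold (kPa/min) below which the loss
#'   modulus is considered to have levelled off after its maximum; defines
#'   the S4 endpoint.
#' @param ptemp_rate Viscosity rate-of-change threshold (viscosity
#'   units/min); the pasting temperature is the temperature at the first
#'   sample whose forward-difference dV/dt exceeds it.
#' @param gpp_max_scope Where the loss-modulus maximum is searched:
#'   `"global"` (whole trace, the default) or `"heating"` (heating ramp
#'   only).
#' @param force_eps Force threshold (kg) separating a TPA compression lobe
#'   from baseline noise.
#'
#' @return A list of class `curve_config`.
#' @export
curve_config <- function(smooth_window = 0,
                         level_off_eps = 0.05,
                         ptemp_rate = 0.1,
                         gpp_max_scope = c("global", "heating"),
                         force_eps = 1e-4) {
  gpp_max_scope <- match.arg(gpp_max_scope)
  rt_assert(smooth_window == 0 || smooth_window >= 3, "config",
            "smooth_window must be 0 (off) or >= 3")
  rt_assert(level_off_eps > 0, "config", "level_off_eps must be positive")
  rt_assert(ptemp_rate > 0, "config", "ptemp_rate must be positive")
  rt_assert(force_eps > 0, "config", "force_eps must be positive")
  structure(list(smooth_window = as.integer(smooth_window),
                 level_off_eps = level_off_eps,
                 ptemp_rate = ptemp_rate,
                 gpp_max_scope = gpp_max_scope,
                 force_eps = force_eps),
            class = "curve_config")
}

#' Pipeline configuration
#'
#' Bundles the tunable settings of [run_pipeline()]. Every run snapshot
#' includes the resolved configuration so results can be reproduced.
#'
#' @param curve A [curve_config()].
#' @param cor_threshold Absolute Pearson correlation above which a
#'   variable pair is flagged as redundant (default 0.75).
#' @param drop_policy Redundancy drop policy, `"paper"` (pinned drop set,
#'   see [prune_correlated()]) or `"greedy"`.
#' @param k Number of clusters cut from the Ward tree.
#' @param standardize Z-score variables before clustering.
#' @param reference_cluster Reference category for the multinomial model.
#' @param tol,max_iter Newton convergence tolerance (relative
#'   log-likelihood change) and iteration cap for the multinomial fit.
#' @param rf_trees,rf_vars_per_split,rf_seed Random-forest settings:
#'   number of trees, variables tried at each split, and RNG seed.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(curve = curve_config(),
                            cor_threshold = 0.75,
                            drop_policy = c("paper", "greedy"),
                            k = 3,
                            standardize = TRUE,
                            reference_cluster = 1,
                            tol = 1e-8,
                            max_iter = 500,
                            rf_trees = 500,
                            rf_vars_per_split = 3,
                            rf_seed = 20180245) {
  drop_policy <- match.arg(drop_policy)
  rt_assert(cor_threshold > 0, "config", "cor_threshold must be positive")
  rt_assert(k >= 2, "config", "k must be at least 2")
  rt_assert(tol > 0 && max_iter > 0, "config", "tol and max_iter must be positive")
  rt_assert(rf_trees > 0 && rf_vars_per_split > 0, "config",
            "random-forest settings must be positive")
  structure(list(curve = curve, cor_threshold = cor_threshold,
                 drop_policy = drop_policy, k = as.integer(k),
                 standardize = isTRUE(standardize),
                 reference_cluster = reference_cluster,
                 tol = tol, max_iter = as.integer(max_iter),
                 rf_trees = as.integer(rf_trees),
                 rf_vars_per_split = as.integer(rf_vars_per_split),
                 rf_seed = as.integer(rf_seed)),
            class = "pipeline_config")
}
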