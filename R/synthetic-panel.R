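# Synthetic feature panels, sensory score sets and full study loops.

#' Generate a multivariate-normal cluster feature panel
#'
#' Draws each cluster from a multivariate normal with the given
#' per-cluster means and SDs and a shared inter-variable correlation
#' structure, concatenates and shuffles the samples, and returns the
#' truth labels separately. Defaults reproduce the study conditions:
#' cluster sizes 114/70/27 with the [quality_archetypes()] moments and
#' the [default_panel_correlation()] structure.
#'
#' With `full = TRUE` the six redundant variables removed by the
#' correlation pruning are added back: trough and final viscosity via the
#' exact pasting identities (`TV = PV - BD`, `FV = PV + SB`), the loss
#' modulus at G'max via the ratio identity (`GppGmax = TandGmax * Gmax`),
#' and pasting temperature, gel-point temperature and temperature at
#' G'max as linear responses to their retained partner (GT, GT and Gmax)
#' with within-cluster correlations 0.82, 0.80 and -0.80, so the
#' 25-variable panel carries the redundancy structure the pruning stage
#' is meant to find.
#'
#' @param sizes Per-cluster sample counts.
#' @param means,sds Variables x clusters matrices (default
#'   [quality_archetypes()]).
#' @param correlation Inter-variable correlation matrix (default
#'   [default_panel_correlation()]); repaired to the nearest correlation
#'   matrix if not positive semi-definite.
#' @param full Also derive the six redundant variables (25-variable
#'   panel).
#' @param seed RNG seed.
#' @return A list with `panel` (a [feature_panel()]), `labels` (named
#'   integer truth vector, in panel row order) and `psd_repair` (the
#'   nearest-PSD repair distance, 0 if none).
#' @export
gen_feature_panel <- function(sizes = NULL, means = NULL, sds = NULL,
                              correlation = NULL, full = FALSE,
                              seed = NULL) {
  arch <- quality_archetypes()
  if (is.null(sizes)) sizes <- arch$sizes
  if (is.null(means)) means <- arch$means
  if (is.null(sds)) sds <- arch$sds
  if (is.null(correlation)) correlation <- default_panel_correlation()
  K <- length(sizes)
  rt_assert(all(sizes >= 1), "spec", "cluster sizes must be >= 1")
  rt_assert(is.matrix(means) && is.matrix(sds) &&
              all(dim(means) == dim(sds)) && ncol(means) == K,
            "spec", "means and sds must be variables x clusters matrices")
  rt_assert(all(sds >= 0), "spec", "SDs must be non-negative")
  vars <- rownames(means)
  rt_assert(!is.null(vars), "spec", "means must carry variable row names")
  rt_assert(all(dim(correlation) == length(vars)), "spec",
            "correlation must match the number of variables")
  correlation <- repair_psd(correlation)

  if (!is.null(seed)) set.seed(seed)
  X <- NULL
  labels <- integer()
  for (k in seq_len(K)) {
    Sig <- diag(sds[, k], nrow = length(vars)) %*% correlation %*%
      diag(sds[, k], nrow = length(vars))
    Xk <- MASS::mvrnorm(sizes[k], means[, k], Sig, tol = 1e-6)
    if (sizes[k] == 1) Xk <- matrix(Xk, nrow = 1)
    X <- rbind(X, Xk)
    labels <- c(labels, rep(k, sizes[k]))
  }
  colnames(X) <- vars

  if (full) X <- add_redundant_vars(X, labels, means, sds)

  perm <- sample.int(nrow(X))
  X <- X[perm, , drop = FALSE]
  labels <- labels[perm]
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  names(labels) <- rownames(X)
  list(panel = feature_panel(X), labels = labels,
       psd_repair = attr(correlation, "psd_repair"))
}

# Derive the six pruning-target variables from their retained partners.
# TV, FV and the loss modulus at G'max follow exact identities; the
# three temperatures are linear responses to their partner calibrated so
# the PANEL-WIDE Pearson correlation (the quantity the redundancy filter
# sees) hits the study's printed value in expectation, using the mixture
# moments implied by the cluster sizes.
add_redundant_vars <- function(X, labels, means, sds) {
  need <- c("PV", "BD", "SB", "GT", "Gmax", "TandGmax")
  rt_assert(all(need %in% colnames(X)), "spec",
            "full panel derivation needs the retained RVA/rheometry variables")
  n <- nrow(X)
  w <- as.vector(table(factor(labels, levels = seq_len(ncol(means))))) / n
  mix_sd <- function(var) {
    mu <- means[var, ]; s <- sds[var, ]
    mbar <- sum(w * mu)
    sqrt(sum(w * (s^2 + (mu - mbar)^2)))
  }
  linked <- function(parent_var, target_mean, slope, r) {
    rt_assert(abs(r) > 0 && abs(r) < 1, "spec", "link correlation must be in (0, 1)")
    b <- sign(r) * slope
    sd_e <- abs(b) * mix_sd(parent_var) * sqrt(1 / r^2 - 1)
    v <- X[, parent_var]
    target_mean + b * (v - mean(v)) + sd_e * rnorm(n)
  }
  X2 <- cbind(
    X,
    TV = X[, "PV"] - X[, "BD"],
    FV = X[, "PV"] + X[, "SB"],
    GppGmax = X[, "TandGmax"] * X[, "Gmax"],
    PTemp = linked("GT", 80.5, 0.50, 0.82),
    TempGel = linked("GT", 68.0, 0.45, 0.75),
    TempGmax = linked("Gmax", 89.0, 0.15, -0.79))
  X2[, intersect(PANEL_VARS_25, colnames(X2)), drop = FALSE]
}

# multivariate-normal log density via Cholesky
mvn_logdens <- function(X, mu, Sigma) {
  L <- chol(Sigma)
  z <- forwardsolve(t(L), t(X) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 0.5 * ncol(X) * log(2 * pi)
}

#' Bayes-optimal accuracy of the generating mixture
#'
#' Monte-Carlo estimate of the accuracy of the Bayes classifier (true
#' class-conditional Gaussian densities and mixing weights) under the
#' panel generator's mixture: the ceiling no classifier trained on
#' generated panels can beat in expectation.
#'
#' @param sizes,means,sds,correlation As in [gen_feature_panel()];
#'   all SDs must be positive.
#' @param n_mc Monte-Carlo draws.
#' @param seed RNG seed.
#' @return Accuracy in percent.
#' @export
bayes_accuracy <- function(sizes = NULL, means = NULL, sds = NULL,
                           correlation = NULL, n_mc = 20000, seed = 1) {
  arch <- quality_archetypes()
  if (is.null(sizes)) sizes <- arch$sizes
  if (is.null(means)) means <- arch$means
  if (is.null(sds)) sds <- arch$sds
  if (is.null(correlation)) correlation <- default_panel_correlation()
  rt_assert(all(sds > 0), "spec", "Bayes accuracy needs positive SDs")
  correlation <- repair_psd(correlation)
  K <- length(sizes)
  w <- sizes / sum(sizes)
  Sigs <- lapply(seq_len(K), function(k)
    diag(sds[, k]) %*% correlation %*% diag(sds[, k]))
  set.seed(seed)
  nk <- pmax(1, round(n_mc * w))
  X <- NULL; lab <- integer()
  for (k in seq_len(K)) {
    X <- rbind(X, MASS::mvrnorm(nk[k], means[, k], Sigs[[k]], tol = 1e-6))
    lab <- c(lab, rep(k, nk[k]))
  }
  ld <- sapply(seq_len(K), function(k)
    mvn_logdens(X, means[, k], Sigs[[k]]) + log(w[k]))
  100 * mean(max.col(ld) == lab)
}

# truncated-normal draws on [lo, hi] by inverse-CDF resampling
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 150) {
  if (all(sd == 0)) return(rep_len(mean, n))
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  qnorm(runif(n, a, b), mean, sd)
}

#' Generate descriptive sensory panel scores
#'
#' For each cluster, draws per-sample true attribute intensities from a
#' normal truncated to the 150-mm line scale (per-cluster means/SDs,
#' default [sensory_archetypes()]), then per-panelist scores around each
#' sample's truth with SD `panelist_sd`, also truncated.
#'
#' @param means,sds Attribute x cluster matrices on the 0-150 mm scale.
#' @param n_samples Samples profiled per cluster (default 5).
#' @param n_panelists Panelists scoring every sample.
#' @param panelist_sd Panelist-to-panelist score SD (mm).
#' @param seed RNG seed.
#' @return A list with `scores` (long data frame: sample_id,
#'   panelist_id, session, attribute, intensity_mm), `cluster_map`
#'   (named vector) and `truth` (per-sample true attribute means).
#' @export
gen_sensory_scores <- function(means = NULL, sds = NULL, n_samples = 5,
                               n_panelists = 10, panelist_sd = 8,
                               seed = NULL) {
  arch <- sensory_archetypes()
  if (is.null(means)) means <- arch$means
  if (is.null(sds)) sds <- arch$sds
  rt_assert(all(means >= 0) && all(means <= 150), "spec",
            "attribute means must lie on the 0-150 mm scale")
  rt_assert(all(sds >= 0) && panelist_sd >= 0, "spec",
            "SDs must be non-negative")
  attrs <- rownames(means)
  K <- ncol(means)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  truth <- list()
  cluster_map <- integer()
  for (k in seq_len(K)) {
    for (s in seq_len(n_samples)) {
      sid <- sprintf("C%dS%d", k, s)
      cluster_map[sid] <- k
      tm <- vapply(attrs, function(a)
        rtrunc_norm(1, means[a, k], sds[a, k]), numeric(1))
      truth[[sid]] <- tm
      for (a in attrs) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid,
          panelist_id = sprintf("P%02d", seq_len(n_panelists)),
          session = 1L, attribute = a,
          intensity_mm = pmin(pmax(
            rtrunc_norm(n_panelists, tm[[a]], panelist_sd), 0), 150),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(scores = do.call(rbind, rows), cluster_map = cluster_map,
       truth = truth)
}

#' Curve-level cluster archetypes for the synthetic study loop
#'
#' Per-cluster means (and common SDs) for the curve landmarks and scalar
#' assays consumed by [gen_study_curves()]. The three archetypes follow
#' the quality-cluster pattern (high-AC/low-GT/high-modulus;
#' high-AC/high-GT/low-modulus; intermediate-AC/high-breakdown) but with
#' deliberately well-separated means relative to the landmark SDs, so
#' that the full generate-extract-cluster-classify loop is
#' demonstrably recoverable.
#'
#' @return A list of parameter tables used by [gen_study_curves()].
#' @export
curve_archetypes <- function() {
  list(
    scalars = list(
      AC = list(mean = c(25.1, 25.5, 21.2), sd = 0.7),
      GT = list(mean = c(74.8, 77.1, 77.9), sd = 0.6),
      PC = list(mean = c(8.7, 8.3, 8.3), sd = 0.5)),
    rheo = list(
      gel_temp = list(mean = c(70, 74, 76), sd = 0.8),
      Gmax = list(mean = c(40.6, 28.3, 29.8), sd = 1.5),
      temp_at_Gmax = list(mean = c(90, 86, 87), sd = 0.8),
      Gtrough = list(mean = c(15.5, 11.9, 11.7), sd = 0.8)),
    rva = list(
      PV = list(mean = c(2.23, 2.28, 2.49), sd = 0.05),
      BD = list(mean = c(0.67, 0.78, 1.10), sd = 0.05),
      SB = list(mean = c(0.69, 0.61, 0.15), sd = 0.05),
      PT = list(mean = c(5.96, 5.84, 5.89), sd = 0.04),
      onset_temp = list(mean = c(76, 79, 80), sd = 0.5)),
    tpa = list(
      peak1 = list(mean = c(1.96, 1.94, 1.73), sd = 0.05),
      area1 = list(mean = c(2.0, 2.0, 2.0), sd = 0.05),
      coh = list(mean = c(0.44, 0.42, 0.43), sd = 0.01),
      area_neg = list(mean = c(0.02, 0.02, 0.04), sd = 0.003),
      spr = list(mean = c(0.11, 0.11, 0.10), sd = 0.004)))
}

#' Generate a full synthetic study: curves and scalars per sample
#'
#' Draws per-sample landmark parameters from the per-cluster
#' [curve_archetypes()] distributions, generates the three instrument
#' traces per sample (optionally in replicate), and returns the curve
#' set with truth labels. Feed the result to
#' [build_panel_from_curves()] to obtain the 25-variable panel.
#'
#' @param n_per_cluster Samples per cluster.
#' @param arch Archetype parameter tables ([curve_archetypes()]).
#' @param noise_sd Named noise SDs for the three trace types.
#' @param n_reps Replicates per sample per instrument.
#' @param seed RNG seed.
#' @return A list with `samples` (per sample: `rheo`, `rva`, `tpa`
#'   replicate curve lists and a `scalars` vector), `labels` (named
#'   integer truth vector) and `seed`.
#' @export
gen_study_curves <- function(n_per_cluster = c(30, 20, 10),
                             arch = curve_archetypes(),
                             noise_sd = c(rheo = 0.15, rva = 0.01,
                                          tpa = 0.003),
                             n_reps = 1, seed = 1) {
  set.seed(seed)
  draw <- function(p, k) rnorm(1, p$mean[k], p$sd)
  samples <- list()
  labels <- integer()
  i <- 0
  for (k in seq_along(n_per_cluster)) {
    for (j in seq_len(n_per_cluster[k])) {
      i <- i + 1
      sid <- sprintf("S%03d", i)
      labels[sid] <- k
      scalars <- c(AC = max(draw(arch$scalars$AC, k), 0),
                   GT = draw(arch$scalars$GT, k),
                   PC = max(draw(arch$scalars$PC, k), 0))
      gel <- draw(arch$rheo$gel_temp, k)
      rs <- rheo_spec(
        gel_temp = gel,
        Gmax = draw(arch$rheo$Gmax, k),
        temp_at_Gmax = max(draw(arch$rheo$temp_at_Gmax, k), gel + 4),
        Gtrough = draw(arch$rheo$Gtrough, k),
        noise_sd = noise_sd[["rheo"]])
      pv <- draw(arch$rva$PV, k)
      bd <- max(draw(arch$rva$BD, k), 0.05)
      sb <- draw(arch$rva$SB, k)
      vs <- rva_spec(PV = pv, TV = pv - bd, FV = pv + sb,
                     PT = min(max(draw(arch$rva$PT, k), 5.2), 7.3),
                     onset_temp = draw(arch$rva$onset_temp, k),
                     noise_sd = noise_sd[["rva"]])
      a1 <- draw(arch$tpa$area1, k)
      ts <- tpa_spec(area1 = a1,
                     area2 = max(draw(arch$tpa$coh, k), 0.05) * a1,
                     peak1 = draw(arch$tpa$peak1, k),
                     T2 = 1.6 * max(draw(arch$tpa$spr, k), 0.02),
                     area_neg = max(draw(arch$tpa$area_neg, k), 0.001),
                     noise_sd = noise_sd[["tpa"]])
      samples[[sid]] <- list(
        scalars = scalars,
        rheo = lapply(seq_len(n_reps), function(r)
          gen_rheometry_curve(rs, sample_id = sid)$curve),
        rva = lapply(seq_len(n_reps), function(r)
          gen_pasting_curve(vs, sample_id = sid)$curve),
        tpa = lapply(seq_len(n_reps), function(r)
          gen_tpa_curve(ts, sample_id = sid)$curve))
    }
  }
  list(samples = samples, labels = labels, seed = seed)
}

#' Assemble the 25-variable panel from extracted curve features
#'
#' Runs the three extractors on every replicate trace of every sample,
#' maps the features onto the canonical 25 panel variables (S2, S4 and
#' ADH stored as magnitudes, the reporting convention), and averages
#' replicates.
#'
#' @param study A [gen_study_curves()] result (or any list with the same
#'   shape).
#' @param config A [curve_config()].
#' @return A [feature_panel()] with the 25 canonical variables.
#' @export
build_panel_from_curves <- function(study, config = curve_config()) {
  rows <- list()
  for (sid in names(study$samples)) {
    smp <- study$samples[[sid]]
    nr <- max(length(smp$rheo), length(smp$rva), length(smp$tpa))
    for (r in seq_len(nr)) {
      rh <- extract_rheometry_features(
        smp$rheo[[min(r, length(smp$rheo))]], config)
      pa <- extract_pasting_features(
        smp$rva[[min(r, length(smp$rva))]], config)
      tp <- extract_tpa_features(
        smp$tpa[[min(r, length(smp$tpa))]], config)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid,
        GT = smp$scalars[["GT"]], AC = smp$scalars[["AC"]],
        PC = smp$scalars[["PC"]],
        PV = pa$PV, TV = pa$TV, BD = pa$BD, FV = pa$FV, SB = pa$SB,
        LO = pa$LO, PT = pa$PT, PTemp = pa$PTemp,
        HRD = tp$HRD, ADH = abs(tp$ADH), COH = tp$COH, SPR = tp$SPR,
        Gmax = rh$Gmax, GppGmax = rh$Gpp_at_Gmax,
        TandGmax = rh$tand_at_Gmax, TempGel = rh$gel_temp,
        TempGmax = rh$temp_at_Gmax, Gtrough = rh$Gtrough,
        S1 = rh$S1, S2 = abs(rh$S2), S3 = rh$S3, S4 = abs(rh$S4),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df <- df[, c("sample_id", PANEL_VARS_25)]
  average_replicates(df)
}

#' Best-permutation agreement between two labelings
#'
#' Accuracy of labeling `pred` against `truth` maximised over all
#' relabelings of `pred` (cluster numbers are arbitrary).
#'
#' @param pred,truth Equal-length label vectors with the same number of
#'   distinct values (at most 6 clusters).
#' @return Agreement in percent.
#' @export
label_match_accuracy <- function(pred, truth) {
  pred <- as.integer(factor(pred))
  truth <- as.integer(factor(truth))
  ks <- sort(unique(c(pred, truth)))
  rt_assert(length(ks) <= 6, "domain", "too many clusters for permutation matching")
  perms <- perm_all(length(ks))
  best <- 0
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[i, pred] == truth))
  }
  100 * best
}

perm_all <- function(k) {
  if (k == 1) return(matrix(1))
  sub <- perm_all(k - 1)
  out <- NULL
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub, k)[, append(seq_len(k - 1), k, after = pos - 1),
                                    drop = FALSE])
  }
  out
}
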