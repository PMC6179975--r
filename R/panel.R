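# Panel assembly: replicate averaging, class binning, protein
# conversion, Pearson correlation reporting and redundancy pruning.

#' Feature panel container
#'
#' A samples-by-variables numeric matrix with sample ids as row names,
#' plus per-cell replicate counts when the panel came from replicate
#' averaging.
#'
#' @param x Numeric matrix or data frame (samples x variables) with
#'   sample ids as row names (or in a `sample_id` column).
#' @param n_reps Optional integer matrix of the same shape with the
#'   number of replicates behind each cell.
#' @return An object of class `feature_panel`.
#' @export
feature_panel <- function(x, n_reps = NULL) {
  if (is.data.frame(x)) {
    if ("sample_id" %in% names(x)) {
      rn <- as.character(x$sample_id)
      x <- x[, setdiff(names(x), "sample_id"), drop = FALSE]
      rownames(x) <- rn
    }
    x <- as.matrix(x)
  }
  rt_assert(is.numeric(x), "panel", "panel values must be numeric")
  rt_assert(!anyDuplicated(colnames(x)), "panel", "duplicated variable names")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  structure(list(x = x, variables = colnames(x),
                 samples = rownames(x), n_reps = n_reps),
            class = "feature_panel")
}

as_panel_matrix <- function(panel) {
  if (inherits(panel, "feature_panel")) return(panel$x)
  if (is.data.frame(panel)) return(feature_panel(panel)$x)
  rt_assert(is.matrix(panel) && is.numeric(panel), "panel",
            "expected a feature_panel, data frame or numeric matrix")
  if (is.null(rownames(panel))) rownames(panel) <- paste0("S", seq_len(nrow(panel)))
  panel
}

#' @export
print.feature_panel <- function(x, ...) {
  cat(sprintf("Feature panel: %d samples x %d variables\n",
              nrow(x$x), ncol(x$x)))
  cat("  variables:", paste(head(x$variables, 8), collapse = ", "),
      if (length(x$variables) > 8) "...", "\n")
  invisible(x)
}

#' @export
as.data.frame.feature_panel <- function(x, ...) {
  data.frame(sample_id = x$samples, x$x, check.names = FALSE,
             row.names = NULL)
}

#' Convert Kjeldahl nitrogen to crude protein
#'
#' Crude protein content is the Kjeldahl nitrogen value multiplied by the
#' rice-specific factor 5.95.
#'
#' @param kjeldahl_n Percent nitrogen, non-negative (vectorised).
#' @return Percent crude protein.
#' @export
protein_from_nitrogen <- function(kjeldahl_n) {
  rt_assert(all(is.finite(kjeldahl_n)) && all(kjeldahl_n >= 0),
            "domain", "Kjeldahl N must be non-negative")
  5.95 * kjeldahl_n
}

#' Assign amylose-content class
#'
#' Bins apparent amylose content (%) into the five conventional classes:
#' waxy (0-2), very low (3-9), low (10-19), intermediate (20-25) and
#' high (> 25). The printed class ranges leave gaps; bins are implemented
#' half-open with midpoint cuts at 2.5, 9.5 and 19.5, and 25.0 is
#' assigned to intermediate (the 20-25 range is inclusive), so every
#' non-negative value maps to exactly one class.
#'
#' @param ac Amylose content in percent, non-negative (vectorised).
#' @return Factor with levels waxy, very_low, low, intermediate, high.
#' @export
assign_ac_class <- function(ac) {
  rt_assert(all(is.finite(ac)) && all(ac >= 0), "domain",
            "amylose content must be non-negative")
  lev <- c("waxy", "very_low", "low", "intermediate", "high")
  cls <- ifelse(ac < 2.5, "waxy",
         ifelse(ac < 9.5, "very_low",
         ifelse(ac < 19.5, "low",
         ifelse(ac <= 25, "intermediate", "high"))))
  factor(cls, levels = lev)
}

#' Assign gelatinisation-temperature class
#'
#' Low GT is below 67 degC and high GT is 74 degC or above; the
#' intermediate class covers the remainder (the nominal 68-73 range plus
#' the printed gaps 67-68 and 73-74, resolved into intermediate for
#' contiguity).
#'
#' @param gt Gelatinisation temperature in degC, positive (vectorised).
#' @param low_edge,high_edge Configurable class edges (degC).
#' @return Factor with levels low, intermediate, high.
#' @export
assign_gt_class <- function(gt, low_edge = 67, high_edge = 74) {
  rt_assert(all(is.finite(gt)) && all(gt > 0), "domain",
            "gelatinisation temperature must be positive")
  cls <- ifelse(gt < low_edge, "low",
         ifelse(gt < high_edge, "intermediate", "high"))
  factor(cls, levels = c("low", "intermediate", "high"))
}

#' Average replicate feature rows into a panel
#'
#' Takes one row per sample per replicate and returns the arithmetic mean
#' per sample per variable, recording replicate counts. `NA` cells are
#' excluded from the mean; a cell with no non-missing replicate is an
#' error naming the sample and variable (fail-fast), unless
#' `impute = TRUE`, in which case the variable's grand mean is
#' substituted.
#'
#' @param rows Data frame with a `sample_id` column and numeric feature
#'   columns; multiple rows per sample are replicates.
#' @param impute Substitute the variable grand mean for empty cells
#'   instead of failing.
#' @return A [feature_panel()] with `n_reps` filled in.
#' @export
average_replicates <- function(rows, impute = FALSE) {
  rt_assert(is.data.frame(rows) && "sample_id" %in% names(rows), "panel",
            "rows must be a data frame with a sample_id column")
  vars <- setdiff(names(rows), "sample_id")
  rt_assert(length(vars) > 0, "panel", "no feature columns")
  rt_assert(all(vapply(rows[vars], is.numeric, logical(1))), "panel",
            "all feature columns must be numeric")
  sid <- factor(as.character(rows$sample_id),
                levels = unique(as.character(rows$sample_id)))
  m <- matrix(NA_real_, nlevels(sid), length(vars),
              dimnames = list(levels(sid), vars))
  nrep <- matrix(0L, nlevels(sid), length(vars),
                 dimnames = dimnames(m))
  for (v in vars) {
    vals <- rows[[v]]
    nrep[, v] <- as.integer(tapply(!is.na(vals), sid, sum))
    m[, v] <- as.numeric(tapply(vals, sid, function(z) mean(z, na.rm = TRUE)))
  }
  empty <- which(nrep == 0L, arr.ind = TRUE)
  if (nrow(empty) > 0) {
    if (!impute) {
      rt_stop("missing_data", sprintf(
        "no replicates for sample '%s', variable '%s'",
        rownames(nrep)[empty[1, 1]], colnames(nrep)[empty[1, 2]]))
    }
    for (i in seq_len(nrow(empty))) {
      m[empty[i, 1], empty[i, 2]] <- mean(m[, empty[i, 2]], na.rm = TRUE)
    }
  }
  feature_panel(m, n_reps = nrep)
}

#' Pearson correlation report for a panel
#'
#' All pairwise Pearson correlations with two-sided significance from the
#' t approximation, starred at p < 0.1 (*), p < 0.05 (**) and
#' p < 0.01 (***). Zero-variance variables are flagged and their
#' correlations set to `NA`.
#'
#' @param panel A [feature_panel()], data frame or numeric matrix with at
#'   least 3 samples.
#' @return An object of class `correlation_report` with elements `r`,
#'   `p`, `stars`, `n` and `zero_variance`.
#' @export
pearson_matrix <- function(panel) {
  x <- as_panel_matrix(panel)
  n <- nrow(x)
  rt_assert(n >= 3, "panel", "need at least 3 samples for correlations")
  rt_assert(all(is.finite(x)), "non_finite",
            "panel contains non-finite values")
  sds <- apply(x, 2, sd)
  zv <- colnames(x)[sds == 0]
  r <- suppressWarnings(cor(x))
  r[zv, ] <- NA_real_
  r[, zv] <- NA_real_
  diag(r) <- ifelse(colnames(x) %in% zv, NA_real_, 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.1] <- "*"
  stars[!is.na(p) & p < 0.05] <- "**"
  stars[!is.na(p) & p < 0.01] <- "***"
  structure(list(r = r, p = p, stars = stars, n = n, zero_variance = zv),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 2, ...) {
  cat(sprintf("Pearson correlation report (%d samples, %d variables)\n",
              x$n, ncol(x$r)))
  if (length(x$zero_variance))
    cat("  zero-variance:", paste(x$zero_variance, collapse = ", "), "\n")
  if (!is.null(x$flagged) && nrow(x$flagged) > 0) {
    cat(sprintf("  %d pairs flagged at |r| > %.2f; dropped: %s\n",
                nrow(x$flagged), x$threshold,
                paste(x$dropped, collapse = ", ")))
  }
  invisible(x)
}

flagged_pairs <- function(r, threshold) {
  idx <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  out <- data.frame(var1 = rownames(r)[idx[, 1]],
                    var2 = colnames(r)[idx[, 2]],
                    r = r[idx], stringsAsFactors = FALSE)
  out[order(-abs(out$r), out$var1, out$var2), , drop = FALSE]
}

#' Prune correlation-redundant variables
#'
#' Flags every variable pair with `|r| > threshold` and removes
#' redundant members. Policy `"paper"` removes the pinned drop set of the
#' reference analysis (pasting temperature, temperature at gel point,
#' trough and final viscosity, loss modulus at G'max and temperature at
#' G'max); it errors if a pinned variable is absent from the panel.
#' Policy `"greedy"` iterates over flagged pairs in decreasing `|r|` and
#' drops the member with the larger mean absolute correlation to all
#' other remaining variables.
#'
#' @param panel A [feature_panel()], data frame or matrix.
#' @param threshold Absolute correlation threshold (default 0.75).
#' @param drop_policy `"paper"` or `"greedy"`.
#' @param drop_set Override for the pinned drop set under the `"paper"`
#'   policy.
#' @return A list with `panel` (the pruned [feature_panel()]) and
#'   `report` (a `correlation_report` extended with `threshold`,
#'   `flagged`, `dropped` and `retained`).
#' @export
prune_correlated <- function(panel, threshold = 0.75,
                             drop_policy = c("paper", "greedy"),
                             drop_set = PAPER_DROP_SET) {
  drop_policy <- match.arg(drop_policy)
  x <- as_panel_matrix(panel)
  rep <- pearson_matrix(x)
  fl <- flagged_pairs(rep$r, threshold)

  if (drop_policy == "paper") {
    missing <- setdiff(drop_set, colnames(x))
    rt_assert(length(missing) == 0, "config", paste0(
      "pinned drop set names absent variable(s): ",
      paste(missing, collapse = ", ")))
    dropped <- drop_set
  } else {
    remaining <- colnames(x)
    dropped <- character()
    meanabs <- function(v, vs) mean(abs(rep$r[v, setdiff(vs, v)]), na.rm = TRUE)
    repeat {
      live <- fl[fl$var1 %in% remaining & fl$var2 %in% remaining, , drop = FALSE]
      if (nrow(live) == 0) break
      a <- live$var1[1]; b <- live$var2[1]
      out <- if (meanabs(a, remaining) >= meanabs(b, remaining)) a else b
      dropped <- c(dropped, out)
      remaining <- setdiff(remaining, out)
    }
  }
  retained <- setdiff(colnames(x), dropped)
  rep$threshold <- threshold
  rep$flagged <- fl
  rep$dropped <- dropped
  rep$retained <- retained
  nr <- if (inherits(panel, "feature_panel")) panel$n_reps else NULL
  if (!is.null(nr)) nr <- nr[, retained, drop = FALSE]
  list(panel = feature_panel(x[, retained, drop = FALSE], n_reps = nr),
       report = rep)
}
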