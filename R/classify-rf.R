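# Per-cluster variable importance by random-forest OOB permutation.

#' Random-forest permutation importance per cluster
#'
#' Grows a classification forest (default 500 trees, 3 variables tried
#' at each split) and reports, for every cluster and variable, the
#' standardised mean increase in out-of-bag classification error when
#' that variable's OOB values are permuted (permutation importance;
#' mean-decrease-in-impurity is deliberately not used). Results are
#' bit-for-bit reproducible under a fixed seed.
#'
#' @param x Predictors ([feature_panel()], data frame or matrix),
#'   typically restricted to the variables retained by the multinomial
#'   model.
#' @param labels Cluster labels; at least two distinct clusters.
#' @param n_trees Number of trees (default 500).
#' @param vars_per_split Variables sampled at each split (default 3).
#' @param seed RNG seed, recorded in the result.
#' @param scale Divide importances by their permutation standard errors
#'   (standardised scores, the default).
#' @return An object of class `importance_result`: `importance`
#'   (variables x clusters), `mean_decrease_accuracy`, per-cluster
#'   `rankings`, `oob_error` (percent) and the forest `settings`.
#' @export
rf_importance <- function(x, labels, n_trees = 500, vars_per_split = 3,
                          seed = 20180245, scale = TRUE) {
  if (inherits(x, "feature_panel")) x <- x$x
  x <- as.data.frame(x)
  y <- factor(labels)
  rt_assert(nlevels(droplevels(y)) >= 2, "degenerate",
            "labels contain a single class")
  rt_assert(nrow(x) == length(y), "dimension", "labels must match rows")
  vars_per_split <- min(vars_per_split, ncol(x))
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = n_trees, mtry = vars_per_split,
    importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = scale)
  # class-specific permutation importance columns precede the aggregates
  impc <- rf$importance[, levels(y), drop = FALSE]
  if (scale) {
    sdc <- rf$importanceSD[, levels(y), drop = FALSE]
    impc <- impc / ifelse(sdc > 0, sdc, 1)
  }
  rankings <- lapply(levels(y), function(k) {
    rownames(impc)[order(-impc[, k])]
  })
  names(rankings) <- levels(y)
  structure(list(importance = impc,
                 mean_decrease_accuracy = drop(imp),
                 rankings = rankings,
                 oob_error = 100 * rf$err.rate[n_trees, "OOB"],
                 confusion = rf$confusion,
                 settings = list(n_trees = n_trees,
                                 vars_per_split = vars_per_split,
                                 seed = seed, scaled = scale)),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Random-forest permutation importance (%d trees, %d vars/split, seed %d)\n",
    s$n_trees, s$vars_per_split, s$seed))
  cat(sprintf("  OOB error %.2f%%\n", x$oob_error))
  for (k in names(x$rankings)) {
    cat(sprintf("  cluster %s top: %s\n", k,
                paste(head(x$rankings[[k]], 3), collapse = " > ")))
  }
  invisible(x)
}
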