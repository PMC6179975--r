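# Ward clustering of the quality panel and per-cluster profiling.

#' Ward hierarchical clustering of a feature panel
#'
#' Agglomerative clustering with the Ward minimum-variance criterion on
#' Euclidean distances, using the squared-distance update convention
#' (`hclust` method `"ward.D2"`). With `standardize = TRUE` (the
#' default) variables are centred and scaled to unit standard deviation
#' first, so that kilopascal-scale moduli do not dominate ratio-scale
#' variables. The tree is cut at `k` clusters and clusters are renumbered
#' by decreasing size (ties broken by the original cut label).
#'
#' @param panel A [feature_panel()], data frame or numeric matrix; all
#'   values must be finite.
#' @param k Number of clusters (default 3).
#' @param standardize Z-score the variables before computing distances.
#' @return An object of class `cluster_result`: a list with the `hclust`
#'   tree (`linkage`), `k`, the renumbered `labels` (named integer
#'   vector) and `sizes`.
#' @export
ward_cluster <- function(panel, k = 3, standardize = TRUE) {
  x <- as_panel_matrix(panel)
  rt_assert(all(is.finite(x)), "non_finite", "panel contains non-finite values")
  rt_assert(nrow(x) > k, "cluster", "need more samples than clusters")
  if (standardize) {
    sds <- apply(x, 2, sd)
    rt_assert(all(sds > 0), "cluster", paste0(
      "constant variable(s) cannot be standardized: ",
      paste(colnames(x)[sds == 0], collapse = ", ")))
    x <- scale(x)
  }
  hc <- hclust(dist(x), method = "ward.D2")
  raw <- cutree(hc, k = k)
  tab <- table(raw)
  ord <- as.integer(names(tab))[order(-as.integer(tab), as.integer(names(tab)))]
  labels <- match(raw, ord)
  names(labels) <- rownames(x)
  structure(list(linkage = hc, k = as.integer(k), labels = labels,
                 sizes = as.integer(table(labels)),
                 standardize = isTRUE(standardize)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Ward clustering (ward.D2%s), k = %d\n",
              if (x$standardize) ", z-scored" else "", x$k))
  cat("  cluster sizes:", paste(x$sizes, collapse = " / "), "\n")
  invisible(x)
}

#' Per-cluster mean and standard deviation profile
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' every panel variable within each cluster. Clusters of size 1 report
#' `NA` standard deviations.
#'
#' @param panel A [feature_panel()], data frame or matrix.
#' @param clusters A [ward_cluster()] result, or an integer vector of
#'   cluster labels covering every panel row.
#' @return An object of class `cluster_profile` with `mean` and `sd`
#'   matrices (variables x clusters) and cluster `sizes`.
#' @export
cluster_profile <- function(panel, clusters) {
  x <- as_panel_matrix(panel)
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels else clusters
  rt_assert(length(labels) == nrow(x), "cluster",
            "labels must cover every panel sample")
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  mu <- sapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]))
  sdev <- sapply(ks, function(k) {
    xi <- x[labels == k, , drop = FALSE]
    if (nrow(xi) < 2) rep(NA_real_, ncol(x)) else apply(xi, 2, sd)
  })
  dimnames(mu) <- dimnames(sdev) <- list(colnames(x), paste0("cluster", ks))
  structure(list(mean = mu, sd = sdev,
                 sizes = as.integer(table(factor(labels, levels = ks)))),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, digits = 2, ...) {
  cat("Cluster profile (mean, SD in parentheses); sizes:",
      paste(x$sizes, collapse = " / "), "\n")
  fm <- matrix(sprintf(paste0("%.", digits, "f (%.", digits, "f)"),
                       x$mean, x$sd),
               nrow(x$mean), ncol(x$mean), dimnames = dimnames(x$mean))
  print(fm, quote = FALSE)
  invisible(x)
}
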