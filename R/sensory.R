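# Descriptive sensory profile summaries.

#' Summarise sensory panel scores per cluster
#'
#' Panelist scores are first averaged per sample per attribute, then each
#' cluster's mean and sample standard deviation are computed over those
#' sample-level means (the per-cluster dispersion therefore reflects
#' sample-to-sample, not panelist-to-panelist, variation). Intensities
#' must lie on the 150-mm line scale and attributes must come from the
#' closed 13-term texture lexicon. A designated reference (standard)
#' sample can be excluded from the cluster summaries.
#'
#' @param scores Data frame with columns `sample_id`, `panelist_id`,
#'   `attribute`, `intensity_mm` (a `session` column is allowed and
#'   ignored by the aggregation).
#' @param cluster_map Named vector mapping every scored sample id to its
#'   cluster.
#' @param reference_sample Optional sample id excluded from summaries.
#' @return An object of class `sensory_summary` with `mean` and `sd`
#'   matrices (attributes x clusters) and per-cluster sample counts.
#' @export
summarize_sensory <- function(scores, cluster_map, reference_sample = NULL) {
  need <- c("sample_id", "panelist_id", "attribute", "intensity_mm")
  rt_assert(is.data.frame(scores) && all(need %in% names(scores)),
            "sensory", paste("scores needs columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(scores$attribute), SENSORY_ATTRIBUTES)
  if (length(bad) > 0) {
    rt_stop("sensory", paste0("unknown attribute(s): ", paste(bad, collapse = ", ")))
  }
  rt_assert(all(is.finite(scores$intensity_mm)) &&
              all(scores$intensity_mm >= 0) &&
              all(scores$intensity_mm <= 150),
            "sensory", "intensities must lie on the 0-150 mm scale")
  if (!is.null(reference_sample)) {
    scores <- scores[!(scores$sample_id %in% reference_sample), , drop = FALSE]
  }
  ids <- unique(as.character(scores$sample_id))
  unmapped <- setdiff(ids, names(cluster_map))
  rt_assert(length(unmapped) == 0, "sensory", paste0(
    "sample(s) without cluster assignment: ", paste(unmapped, collapse = ", ")))

  # panelists -> sample means -> cluster summaries
  smean <- aggregate(intensity_mm ~ sample_id + attribute, data = scores, FUN = mean)
  smean$cluster <- as.integer(cluster_map[as.character(smean$sample_id)])
  ks <- sort(unique(smean$cluster))
  attrs <- SENSORY_ATTRIBUTES[SENSORY_ATTRIBUTES %in% unique(smean$attribute)]
  mu <- sdv <- matrix(NA_real_, length(attrs), length(ks),
                      dimnames = list(attrs, paste0("cluster", ks)))
  cnt <- integer(length(ks))
  for (j in seq_along(ks)) {
    sub <- smean[smean$cluster == ks[j], , drop = FALSE]
    cnt[j] <- length(unique(sub$sample_id))
    for (a in attrs) {
      v <- sub$intensity_mm[sub$attribute == a]
      mu[a, j] <- mean(v)
      sdv[a, j] <- if (length(v) > 1) sd(v) else NA_real_
    }
  }
  structure(list(mean = mu, sd = sdv, n_samples = cnt,
                 clusters = ks, attributes = attrs),
            class = "sensory_summary")
}

#' @export
print.sensory_summary <- function(x, digits = 1, ...) {
  cat("Sensory summary (mean +/- SD per cluster); samples:",
      paste(x$n_samples, collapse = " / "), "\n")
  fm <- matrix(sprintf(paste0("%.", digits, "f+/-%.", digits, "f"), x$mean, x$sd),
               nrow(x$mean), ncol(x$mean), dimnames = dimnames(x$mean))
  print(fm, quote = FALSE)
  invisible(x)
}

#' Compare clusters on one sensory attribute
#'
#' Orders the clusters by mean intensity and reports all pairwise mean
#' differences, descriptively (no inferential test is attached).
#'
#' @param summary A [summarize_sensory()] result.
#' @param attribute One of the lexicon attributes present in the summary.
#' @return A list with `order` (a data frame of clusters sorted by
#'   decreasing mean) and `differences` (pairwise mean-difference
#'   matrix, row minus column).
#' @export
compare_clusters <- function(summary, attribute) {
  stopifnot(inherits(summary, "sensory_summary"))
  rt_assert(attribute %in% rownames(summary$mean), "sensory",
            paste0("attribute not in summary: ", attribute))
  m <- summary$mean[attribute, ]
  ord <- order(-m)
  diffs <- outer(m, m, "-")
  list(order = data.frame(cluster = names(m)[ord], mean = unname(m[ord]),
                          stringsAsFactors = FALSE),
       differences = diffs)
}
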