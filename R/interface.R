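# File input/output and the end-to-end pipeline driver.

#' Read a quality panel from CSV or XLSX
#'
#' Expects one row per accession with named variable columns. Header
#' variants are reconciled through `name_map`, a named character vector
#' (`canonical = file_header`) or a YAML file of the same mapping. The
#' 19 core quality variables must resolve; further canonical variables
#' are included when present and the remainder reported with a warning.
#'
#' @param path CSV or XLSX file (XLSX requires the readxl package).
#' @param name_map Named character vector or YAML path mapping canonical
#'   variable names to file headers.
#' @param id_col Sample-id column in the file (default `sample_id`, with
#'   the first column as fallback).
#' @param required Canonical variables that must be present (default the
#'   19 retained quality variables).
#' @return A [feature_panel()].
#' @export
read_panel <- function(path, name_map = NULL, id_col = "sample_id",
                       required = PANEL_VARS_19) {
  rt_assert(file.exists(path), "io", paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    rt_assert(requireNamespace("readxl", quietly = TRUE), "io",
              "reading XLSX requires the readxl package")
    df <- as.data.frame(readxl::read_excel(path))
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (is.character(name_map) && length(name_map) == 1 && file.exists(name_map)) {
    rt_assert(requireNamespace("yaml", quietly = TRUE), "io",
              "YAML name maps require the yaml package")
    name_map <- unlist(yaml::read_yaml(name_map))
  }
  if (!is.null(name_map)) {
    hit <- match(name_map, names(df))
    names(df)[hit[!is.na(hit)]] <- names(name_map)[!is.na(hit)]
  }
  if (!id_col %in% names(df)) {
    names(df)[1] <- "sample_id"
  } else if (id_col != "sample_id") {
    names(df)[names(df) == id_col] <- "sample_id"
  }
  missing <- setdiff(required, names(df))
  rt_assert(length(missing) == 0, "missing_column", paste0(
    "panel is missing required variable(s): ", paste(missing, collapse = ", ")))
  vars <- intersect(PANEL_VARS_25, names(df))
  absent <- setdiff(PANEL_VARS_25, vars)
  if (length(absent) > 0) {
    warning(sprintf("panel has %d of 25 canonical variables (absent: %s)",
                    length(vars), paste(absent, collapse = ", ")))
  }
  for (v in vars) {
    val <- df[[v]]
    if (!is.numeric(val)) {
      conv <- suppressWarnings(as.numeric(val))
      bad <- which(is.na(conv) & !is.na(val))
      rt_assert(length(bad) == 0, "io", sprintf(
        "non-numeric value in column '%s', row %d", v, bad[1]))
      df[[v]] <- conv
    }
  }
  feature_panel(df[, c("sample_id", vars)])
}

#' Write a feature panel to CSV
#'
#' @param panel A [feature_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Read instrument traces from a long-format CSV
#'
#' One trace per sample id. Column layouts: rheometry `sample_id,
#' time_min, temp_C, g_prime_kPa, g_double_prime_kPa`; RVA `sample_id,
#' time_min, temp_C, viscosity`; TPA `sample_id, time_s, force_kg`.
#'
#' @param path CSV path.
#' @param type `"rheo"`, `"rva"` or `"tpa"`.
#' @return Named list of curve objects, one per sample id.
#' @export
read_curves_csv <- function(path, type = c("rheo", "rva", "tpa")) {
  type <- match.arg(type)
  rt_assert(file.exists(path), "io", paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- switch(type,
    rheo = c("sample_id", "time_min", "temp_C", "g_prime_kPa", "g_double_prime_kPa"),
    rva = c("sample_id", "time_min", "temp_C", "viscosity"),
    tpa = c("sample_id", "time_s", "force_kg"))
  missing <- setdiff(need, names(df))
  rt_assert(length(missing) == 0, "missing_column", paste0(
    "curve file missing column(s): ", paste(missing, collapse = ", ")))
  by_id <- split(df, df$sample_id)
  lapply(by_id, function(d) {
    switch(type,
      rheo = rheo_curve(d$time_min, d$temp_C, d$g_prime_kPa,
                        d$g_double_prime_kPa, sample_id = d$sample_id[1]),
      rva = rva_curve(d$time_min, d$temp_C, d$viscosity,
                      sample_id = d$sample_id[1]),
      tpa = tpa_curve(d$time_s, d$force_kg, sample_id = d$sample_id[1]))
  })
}

#' Write instrument curves to a long-format CSV
#'
#' @param curves A curve object or list of curve objects of one type.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves_csv <- function(curves, path) {
  if (inherits(curves, c("rheo_curve", "rva_curve", "tpa_curve"))) {
    curves <- list(curves)
  }
  rows <- lapply(curves, function(cv) {
    if (inherits(cv, "rheo_curve")) {
      data.frame(sample_id = cv$sample_id, time_min = cv$time,
                 temp_C = cv$temperature, g_prime_kPa = cv$g_prime,
                 g_double_prime_kPa = cv$g_double_prime)
    } else if (inherits(cv, "rva_curve")) {
      data.frame(sample_id = cv$sample_id, time_min = cv$time,
                 temp_C = cv$temperature, viscosity = cv$viscosity)
    } else {
      data.frame(sample_id = cv$sample_id, time_s = cv$time,
                 force_kg = cv$force)
    }
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# stable short checksum of the resolved configuration
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(js))
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

#' Run the full ideotype pipeline on a feature panel
#'
#' Executes, in order: correlation pruning, Ward clustering, cluster
#' profiling, forward-AIC multinomial model selection, per-variable
#' likelihood-ratio tests, goodness of fit, and per-cluster
#' random-forest permutation importance on the selected variables. The
#' run is deterministic given the panel, configuration and seed.
#'
#' @param panel A [feature_panel()] (typically the full 25-variable
#'   panel; already-pruned panels are pruned to no effect under the
#'   greedy policy).
#' @param config A [pipeline_config()].
#' @param out_dir If given, tables and a JSON summary (with the resolved
#'   configuration snapshot) are written there.
#' @return An object of class `pipeline_result` with elements `pruning`,
#'   `clusters`, `profile`, `model`, `lr_tests`, `fit`, `importance` and
#'   a flat `summary` list.
#' @export
run_pipeline <- function(panel, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- as_panel_matrix(panel)
  stage <- "prune"
  result <- tryCatch({
    drop_set <- intersect(PAPER_DROP_SET, colnames(x))
    pr <- prune_correlated(x, threshold = config$cor_threshold,
                           drop_policy = if (length(drop_set) > 0)
                             config$drop_policy else "greedy",
                           drop_set = drop_set)
    stage <- "cluster"
    cl <- ward_cluster(pr$panel, k = config$k,
                       standardize = config$standardize)
    stage <- "profile"
    prof <- cluster_profile(pr$panel, cl)
    stage <- "select"
    model <- forward_aic_select(pr$panel, cl$labels,
                                reference = config$reference_cluster,
                                tol = config$tol,
                                max_iter = config$max_iter)
    stage <- "lr_test"
    lrt <- lr_test(model)
    stage <- "goodness_of_fit"
    fit <- goodness_of_fit(model)
    stage <- "rf_importance"
    imp <- rf_importance(pr$panel$x[, model$variables, drop = FALSE],
                         cl$labels,
                         n_trees = config$rf_trees,
                         vars_per_split = config$rf_vars_per_split,
                         seed = config$rf_seed)
    list(pruning = pr$report, panel_pruned = pr$panel, clusters = cl,
         profile = prof, model = model, lr_tests = lrt, fit = fit,
         importance = imp)
  }, ricotype_error = function(e) {
    rt_stop("stage_failure", sprintf("pipeline stage '%s' failed: %s",
                                     stage, conditionMessage(e)))
  })

  summary <- list(
    n_samples = nrow(x),
    n_variables_input = ncol(x),
    n_variables_pruned = length(result$pruning$retained),
    n_variables_selected = length(result$model$variables),
    cluster_sizes = result$clusters$sizes,
    selected_variables = result$model$variables,
    aic = result$model$aic,
    null_deviance = result$fit$null_deviance,
    deviance = result$fit$deviance,
    mcfadden = result$fit$mcfadden,
    cox_snell = result$fit$cox_snell,
    cragg_uhler = result$fit$cragg_uhler,
    accuracy = result$fit$accuracy,
    rf_oob_error = result$importance$oob_error,
    rf_rankings = result$importance$rankings,
    config_hash = config_hash(config))
  result$summary <- summary
  result$config <- config
  class(result) <- "pipeline_result"

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- result$summary$config_hash
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste0("# config_hash: ", h), con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  r <- result$pruning$r
  wcsv(data.frame(variable = rownames(r), round(r, 4), check.names = FALSE),
       "correlation_matrix.csv")
  wcsv(data.frame(sample_id = names(result$clusters$labels),
                  cluster = unname(result$clusters$labels)),
       "cluster_labels.csv")
  prof <- result$profile
  wcsv(data.frame(variable = rownames(prof$mean),
                  matrix(sprintf("%.2f (%.2f)", prof$mean, prof$sd),
                         nrow(prof$mean),
                         dimnames = list(NULL, colnames(prof$mean))),
                  check.names = FALSE),
       "cluster_profile.csv")
  B <- result$model$coefficients; SE <- result$model$se
  wcsv(data.frame(term = rownames(B),
                  matrix(sprintf("%.2f (%.2f)", B, SE), nrow(B),
                         dimnames = list(NULL, paste0("cluster", colnames(B)))),
                  check.names = FALSE),
       "mlr_coefficients.csv")
  wcsv(result$lr_tests, "lr_tests.csv")
  imp <- result$importance$importance
  wcsv(data.frame(variable = rownames(imp), round(imp, 4), check.names = FALSE),
       "rf_importance.csv")
  snapshot <- list(summary = result$summary,
                   config = unclass_deep(result$config))
  jsonlite::write_json(snapshot, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("Ideotype pipeline result\n")
  cat(sprintf("  %d samples; variables %d -> %d (pruned) -> %d (selected)\n",
              s$n_samples, s$n_variables_input, s$n_variables_pruned,
              s$n_variables_selected))
  cat("  cluster sizes:", paste(s$cluster_sizes, collapse = " / "), "\n")
  cat(sprintf("  AIC %.2f; accuracy %.2f%%; McFadden %.2f\n",
              s$aic, s$accuracy, s$mcfadden))
  invisible(x)
}
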