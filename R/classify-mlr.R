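# Multinomial logistic regression for cluster membership.
#
# The model scores sample i for cluster k with a linear predictor
# f(x_i, k) = beta_k . x_i (intercept prepended), the reference cluster
# fixed at score 0, and class probabilities given by the softmax over
# scores. Fitting is full-Newton maximum likelihood with step-halving;
# standard errors come from the observed information at the optimum.

#' Linear score of the multinomial model
#'
#' @param beta Coefficient vector for one cluster, intercept first.
#' @param x Predictor vector (without intercept) or matrix with one row
#'   per sample.
#' @return The inner product(s) `beta[1] + x %*% beta[-1]`.
#' @export
mlr_score <- function(beta, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  rt_assert(ncol(x) == length(beta) - 1, "dimension",
            "predictor length must match coefficients minus intercept")
  drop(beta[1] + x %*% beta[-1])
}

#' Class probabilities from per-cluster scores
#'
#' Softmax over the cluster scores with the reference cluster's score
#' fixed at zero.
#'
#' @param scores Matrix of non-reference scores (samples x clusters) or a
#'   vector for one sample.
#' @return Probability matrix over all clusters, reference first;
#'   rows sum to 1.
#' @export
softmax_probs <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  eta <- cbind(0, scores)
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  p <- e / rowSums(e)
  if (!is.null(colnames(scores))) {
    colnames(p) <- c("reference", colnames(scores))
  }
  p
}

# internal: deviance of the intercept-only multinomial model, closed form
null_deviance_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  -2 * sum(counts * log(counts / n))
}

#' Intercept-only multinomial deviance from class counts
#'
#' The maximum-likelihood intercept-only multinomial model fits the class
#' proportions, so its -2 log-likelihood has the closed form
#' `-2 * sum(n_k * log(n_k / n))`.
#'
#' @param counts Vector of class counts.
#' @return The null deviance (-2 log-likelihood).
#' @export
intercept_only_deviance <- function(counts) {
  rt_assert(all(counts >= 0) && sum(counts) > 0, "domain",
            "counts must be non-negative with a positive total")
  null_deviance_counts(counts)
}

prep_design <- function(x, labels, reference) {
  if (inherits(x, "feature_panel")) x <- x$x
  if (is.data.frame(x)) x <- as.matrix(x)
  rt_assert(is.numeric(x) && all(is.finite(x)), "non_finite",
            "predictors must be finite numeric")
  y <- factor(labels)
  rt_assert(nlevels(y) >= 2, "domain", "need at least 2 clusters")
  rt_assert(as.character(reference) %in% levels(y), "domain",
            "reference cluster not among the labels")
  y <- stats::relevel(y, ref = as.character(reference))
  rt_assert(length(y) == nrow(x), "dimension",
            "labels must match panel rows")
  list(x = x, y = y)
}

#' Fit a multinomial logistic regression
#'
#' Maximum-likelihood fit of the softmax model with one linear score per
#' non-reference cluster, by full Newton iteration with step-halving
#' (the log-likelihood never decreases across iterations). Convergence
#' is declared when the relative log-likelihood change falls below
#' `tol`. Standard errors are the square roots of the inverse observed
#' information. The design must be full rank; collinear columns are named
#' in the error. Suspected perfect separation (iteration cap hit with
#' diverging coefficients, a vanishing deviance, or a singular
#' information matrix) raises a warning of class `ricotype_separation`
#' and returns the capped fit.
#'
#' @param x Predictors: [feature_panel()], data frame or numeric matrix
#'   (no intercept column; one is prepended). Raw, unstandardised
#'   predictors are used unless `standardize = TRUE`.
#' @param labels Cluster labels (factor or coercible).
#' @param reference Reference cluster level (default `1`).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @param standardize Z-score predictors before fitting (coefficients are
#'   then per-SD).
#' @return An object of class `mlr_model`: coefficients and standard
#'   errors (`(p+1) x (K-1)` matrices, non-reference clusters in
#'   columns), `deviance`, `null_deviance`, `aic`, `fitted` class
#'   probabilities, convergence metadata, and the training data (for
#'   refits in [lr_test()] and [goodness_of_fit()]).
#' @export
fit_mlr <- function(x, labels, reference = 1, tol = 1e-8, max_iter = 500,
                    standardize = FALSE) {
  d <- prep_design(x, labels, reference)
  xm <- d$x; y <- d$y
  if (standardize && ncol(xm) > 0) xm <- scale(xm)
  n <- nrow(xm)
  X <- cbind("(Intercept)" = 1, xm)
  p <- ncol(X)
  K <- nlevels(y)
  rt_assert(n > p * (K - 1), "domain",
            "need more samples than free parameters")

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    rt_stop("rank_deficient", paste0(
      "design is rank deficient; collinear column(s): ",
      paste(bad, collapse = ", ")))
  }

  Y <- matrix(0, n, K - 1)
  yi <- as.integer(y)
  for (k in 2:K) Y[yi == k, k - 1] <- 1

  loglik <- function(B) {
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    sum(eta[cbind(seq_len(n), yi)] - m - log(rowSums(exp(eta - m))))
  }
  probs <- function(B) {
    eta <- cbind(0, X %*% B)
    m <- apply(eta, 1, max)
    e <- exp(eta - m)
    e / rowSums(e)
  }

  B <- matrix(0, p, K - 1)
  ll <- loglik(B)
  converged <- FALSE
  separation <- FALSE
  iter <- 0
  H <- NULL
  while (iter < max_iter) {
    iter <- iter + 1
    P <- probs(B)
    Pn <- P[, -1, drop = FALSE]
    grad <- as.vector(crossprod(X, Y - Pn))
    # observed information: (K-1)p x (K-1)p block matrix
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (a in seq_len(K - 1)) {
      for (b in seq_len(K - 1)) {
        w <- if (a == b) Pn[, a] * (1 - Pn[, a]) else -Pn[, a] * Pn[, b]
        blk <- crossprod(X * w, X)
        H[(a - 1) * p + 1:p, (b - 1) * p + 1:p] <- blk
      }
    }
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) { separation <- TRUE; break }
    step <- 1
    repeat {
      Bnew <- B + matrix(step * delta, p, K - 1)
      llnew <- loglik(Bnew)
      if (is.finite(llnew) && llnew >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { Bnew <- B; llnew <- ll; break }
    }
    moved <- abs(llnew - ll) / (abs(llnew) + 0.1)
    B <- Bnew
    ll <- llnew
    if (moved < tol) { converged <- TRUE; break }
  }
  dev <- -2 * ll
  if (separation || (!converged && max(abs(B)) > 15) || dev < 1e-6) {
    warning(warningCondition(
      "possible perfect separation: coefficients diverging or deviance ~ 0",
      class = c("ricotype_separation", "warning")))
  }

  se <- matrix(NA_real_, p, K - 1)
  if (!is.null(H)) {
    vc <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vc)) se <- matrix(sqrt(pmax(diag(vc), 0)), p, K - 1)
  }
  dimnames(B) <- dimnames(se) <- list(colnames(X), levels(y)[-1])

  counts <- table(y)
  structure(list(coefficients = B, se = se,
                 levels = levels(y), reference = levels(y)[1],
                 variables = colnames(xm),
                 deviance = dev,
                 null_deviance = null_deviance_counts(as.integer(counts)),
                 aic = dev + 2 * p * (K - 1),
                 npar = p * (K - 1),
                 n = n, counts = as.integer(counts),
                 fitted = {
                   P <- probs(B); colnames(P) <- levels(y); P
                 },
                 converged = converged, iterations = iter,
                 tol = tol, max_iter = max_iter,
                 standardize = standardize,
                 x = xm, y = y),
            class = "mlr_model")
}

#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf(
    "Multinomial logistic model: %d samples, %d clusters (reference %s)\n",
    x$n, length(x$levels), x$reference))
  cat(sprintf("  predictors: %s\n",
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(intercept only)"))
  cat(sprintf("  deviance %.2f (null %.2f), AIC %.2f, %s in %d iterations\n",
              x$deviance, x$null_deviance, x$aic,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' @export
predict.mlr_model <- function(object, newdata = NULL,
                              type = c("class", "probs"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    P <- object$fitted
  } else {
    if (inherits(newdata, "feature_panel")) newdata <- newdata$x
    newdata <- as.matrix(newdata)[, object$variables, drop = FALSE]
    eta <- cbind(1, newdata) %*% object$coefficients
    P <- softmax_probs(eta)
    colnames(P) <- object$levels
  }
  if (type == "probs") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' Forward variable selection by AIC
#'
#' Starts from the intercept-only multinomial model and at each step adds
#' the candidate variable whose inclusion gives the lowest AIC
#' (`deviance + 2 * free parameters`), stopping when no addition lowers
#' the AIC. Ties resolve to the earlier column. The returned model is the
#' final refit and never has a higher AIC than the intercept-only model.
#'
#' @param x Candidate predictors ([feature_panel()], data frame or
#'   matrix); column order is the tie-break order.
#' @param labels Cluster labels.
#' @param reference,tol,max_iter As in [fit_mlr()].
#' @param verbose Print one line per accepted step.
#' @return The selected `mlr_model`, with a `selection` data frame
#'   (step, variable, AIC) attached.
#' @export
forward_aic_select <- function(x, labels, reference = 1, tol = 1e-8,
                               max_iter = 500, verbose = FALSE) {
  if (inherits(x, "feature_panel")) x <- x$x
  if (is.data.frame(x)) x <- as.matrix(x)
  cand <- colnames(x)
  rt_assert(length(cand) > 0, "panel", "no candidate variables")
  fit0 <- suppressWarnings(
    fit_mlr(x[, character(0), drop = FALSE], labels,
            reference = reference, tol = tol, max_iter = max_iter))
  selected <- character()
  best <- fit0
  history <- data.frame(step = 0L, variable = "(intercept)",
                        aic = fit0$aic, stringsAsFactors = FALSE)
  repeat {
    remaining <- setdiff(cand, selected)
    if (length(remaining) == 0) break
    # a candidate collinear with the current set (e.g. the exact
    # lift-off = breakdown + setback identity) adds no information:
    # treat it as AIC infinity and move on
    aics <- vapply(remaining, function(v) {
      tryCatch(
        suppressWarnings(
          fit_mlr(x[, c(selected, v), drop = FALSE], labels,
                  reference = reference, tol = tol,
                  max_iter = max_iter))$aic,
        ricotype_rank_deficient = function(e) Inf)
    }, numeric(1))
    i <- which.min(aics)
    if (aics[i] >= best$aic) break
    selected <- c(selected, remaining[i])
    best <- suppressWarnings(
      fit_mlr(x[, selected, drop = FALSE], labels,
              reference = reference, tol = tol, max_iter = max_iter))
    history <- rbind(history, data.frame(
      step = nrow(history), variable = remaining[i], aic = best$aic,
      stringsAsFactors = FALSE))
    if (verbose) message(sprintf("+ %s (AIC %.2f)", remaining[i], best$aic))
  }
  best$selection <- history
  best
}

#' Likelihood-ratio test for model terms
#'
#' For each requested variable, refits the model without it and reports
#' the deviance difference as a chi-square statistic with one degree of
#' freedom per non-reference cluster.
#'
#' @param model A fitted `mlr_model` (training data is stored inside).
#' @param variables Variables to test; default all model predictors.
#' @return Data frame with columns `variable`, `chisq`, `df`, `p` and
#'   `converged` (of the reduced refit).
#' @export
lr_test <- function(model, variables = NULL) {
  stopifnot(inherits(model, "mlr_model"))
  if (is.null(variables)) variables <- model$variables
  rt_assert(all(variables %in% model$variables), "domain",
            "variable not in model")
  K1 <- length(model$levels) - 1
  rows <- lapply(variables, function(v) {
    keep <- setdiff(model$variables, v)
    f <- suppressWarnings(
      fit_mlr(model$x[, keep, drop = FALSE], model$y,
              reference = model$reference,
              tol = model$tol, max_iter = model$max_iter))
    chisq <- max(f$deviance - model$deviance, 0)
    data.frame(variable = v, chisq = chisq, df = K1,
               p = pchisq(chisq, df = K1, lower.tail = FALSE),
               converged = f$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pseudo-R-squared statistics from deviances
#'
#' McFadden: `1 - Df/D0`. Cox & Snell: `1 - exp(-(D0 - Df)/n)`.
#' Cragg & Uhler (Nagelkerke): Cox & Snell divided by its maximum
#' `1 - exp(-D0/n)`.
#'
#' @param null_deviance,deviance -2 log-likelihood of the intercept-only
#'   and fitted models.
#' @param n Number of samples.
#' @return Named list with `mcfadden`, `cox_snell`, `cragg_uhler`.
#' @export
pseudo_r2 <- function(null_deviance, deviance, n) {
  rt_assert(null_deviance > 0, "domain",
            "null deviance must be positive for pseudo-R2")
  chisq <- null_deviance - deviance
  cs <- 1 - exp(-chisq / n)
  list(mcfadden = 1 - deviance / null_deviance,
       cox_snell = cs,
       cragg_uhler = cs / (1 - exp(-null_deviance / n)))
}

#' Goodness-of-fit report for a multinomial model
#'
#' Reports the null and residual -2 log-likelihoods, the model
#' chi-square (their difference) with degrees of freedom, the three
#' pseudo-R-squared statistics, and the resubstitution classification
#' accuracy (percent of samples whose highest fitted probability matches
#' the observed label).
#'
#' @param model A fitted `mlr_model`.
#' @return An object of class `fit_report`.
#' @export
goodness_of_fit <- function(model) {
  stopifnot(inherits(model, "mlr_model"))
  D0 <- model$null_deviance
  Df <- model$deviance
  chisq <- D0 - Df
  df <- model$npar - (length(model$levels) - 1)
  pr2 <- pseudo_r2(D0, Df, model$n)
  pred <- model$levels[max.col(model$fitted, ties.method = "first")]
  acc <- 100 * mean(pred == as.character(model$y))
  structure(list(null_deviance = D0, deviance = Df,
                 chisq = chisq, df = df,
                 p = pchisq(chisq, df = max(df, 1), lower.tail = FALSE),
                 mcfadden = pr2$mcfadden, cox_snell = pr2$cox_snell,
                 cragg_uhler = pr2$cragg_uhler,
                 accuracy = acc, aic = model$aic, n = model$n),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Multinomial goodness of fit\n")
  cat(sprintf("  -2LL: intercept-only %.2f, final %.2f; chi2 %.2f (df %d, p %s)\n",
              x$null_deviance, x$deviance, x$chisq, x$df,
              format.pval(x$p, digits = 3)))
  cat(sprintf("  pseudo-R2: McFadden %.2f, Cox & Snell %.2f, Cragg & Uhler %.2f\n",
              x$mcfadden, x$cox_snell, x$cragg_uhler))
  cat(sprintf("  AIC %.2f; classification accuracy %.2f%%\n", x$aic, x$accuracy))
  invisible(x)
}
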