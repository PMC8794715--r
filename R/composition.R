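# Multivariate diet-composition analysis: binary Jaccard distances, NMDS
# ordination, and per-taxon binomial GLMs combined into a sum-of-Wald
# multivariate statistic with Monte Carlo resampling inference and AIC
# model selection.

#' Pairwise Jaccard distance between samples
#'
#' `d(a, b) = 1 - |A intersect B| / |A union B|` over detected taxa.
#'
#' @param matrix logical presence-absence matrix (taxa x samples); every
#'   sample must have at least one detection.
#' @return symmetric distance matrix with zero diagonal.
#' @export
jaccard_matrix <- function(matrix) {
  stopifnot(is.matrix(matrix), is.logical(matrix))
  empty <- colSums(matrix) == 0
  .stop_if(any(empty), "samples without detections (drop upstream): ",
           paste(colnames(matrix)[empty], collapse = ", "))
  as.matrix(vegan::vegdist(t(matrix * 1), method = "jaccard", binary = TRUE))
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal stress-1 by iterative monotone regression from random
#' starts, keeping the best of `restarts` configurations. Deterministic for
#' a fixed seed.
#'
#' @param dist distance matrix (or `dist` object).
#' @param k number of ordination dimensions.
#' @param restarts random starts.
#' @param max_iter iteration cap per start.
#' @param seed RNG seed.
#' @return list with `points` (samples x k), `stress` (in `[0, 1]`),
#'   `converged`, `restarts`, `seed`.
#' @export
nmds <- function(dist, k = 3, restarts = 20, max_iter = 200, seed = 42) {
  .stop_if(k < 2, "`k` must be at least 2")
  d <- stats::as.dist(dist)
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = restarts, trymax = restarts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  if (!isTRUE(fit$converged) && !identical(fit$converged, 1L))
    warning("NMDS did not converge within the allotted restarts; ",
            "best configuration returned", call. = FALSE)
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || identical(fit$converged, 1L),
       restarts = restarts, seed = seed)
}

# ---- penalized per-taxon logistic fits --------------------------------

# Newton/IRLS for a Bernoulli GLM with a small L2 penalty on all
# coefficients; the penalty tames complete separation (taxa seen in only
# one season), which would otherwise send coefficients to infinity.
.fit_ridge_logistic <- function(X, y, ridge = 0.05, max_iter = 100,
                                tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  eta <- drop(X %*% beta)
  escalations <- 0L
  repeat {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      grad <- drop(crossprod(X, y - mu)) - ridge * beta
      info <- crossprod(X, X * w) + diag(ridge, p)
      step <- solve(info, grad)
      beta <- beta + step
      eta <- drop(X %*% beta)
      if (max(abs(grad)) < tol || max(abs(step)) < 1e-10) {
        converged <- TRUE
        break
      }
    }
    if (converged || escalations >= 4L) break
    escalations <- escalations + 1L # never fail silently: stiffen and retry
    ridge <- ridge * 10
    beta <- numeric(p)
    eta <- drop(X %*% beta)
  }
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(X, X * w) + diag(ridge, p)
  list(beta = beta, vcov = solve(info), mu = mu, ridge = ridge,
       converged = converged, escalations = escalations,
       loglik = sum(y * log(pmax(mu, 1e-12)) +
                      (1 - y) * log(pmax(1 - mu, 1e-12))))
}

.design_matrix <- function(formula, metadata) {
  vars <- all.vars(formula)
  md <- metadata
  for (v in vars) {
    .stop_if(!v %in% colnames(md), "metadata lacks variable ", sQuote(v))
    md[[v]] <- as.character(md[[v]])
  }
  known <- rep(TRUE, nrow(md))
  for (v in vars) known <- known & md[[v]] != "unknown" & !is.na(md[[v]])
  md <- md[known, , drop = FALSE]
  # documented reference levels: dry season, female sex; other variables
  # alphabetical
  if ("season" %in% vars)
    md$season <- factor(md$season, levels = intersect(c("dry", "wet"),
                                                      unique(md$season)))
  if ("sex" %in% vars)
    md$sex <- factor(md$sex, levels = intersect(c("female", "male"),
                                                unique(md$sex)))
  X <- stats::model.matrix(formula, data = md)
  .stop_if(qr(X)$rank < ncol(X), "design matrix is rank deficient")
  list(X = X, keep = md$sample_id, metadata = md)
}

#' Fit per-taxon binomial GLMs (a multivariate GLM by stacking)
#'
#' One logistic regression per taxon on the shared design, fitted by
#' penalized IRLS with a small L2 ridge so that taxa
#' completely separated by a factor (e.g. detected in one season only)
#' still yield finite coefficients and Wald statistics. Samples with an
#' unknown level of any model variable are excluded and listed in the
#' result. Reference levels: dry season, female sex (treatment contrasts).
#'
#' @param matrix logical presence-absence matrix (taxa x samples).
#' @param metadata sample metadata (see [read_metadata()]) covering the
#'   matrix columns.
#' @param formula right-hand-side model formula over metadata columns,
#'   e.g. `~ season * sex`.
#' @param ridge L2 penalty; escalated tenfold (at most four times, flagged)
#'   for any taxon whose fit fails to converge. The default (0.05) is
#'   large enough that a separated taxon's Wald statistic still reflects
#'   its effect (at very small ridges the penalized information vanishes
#'   faster than the coefficient grows, silencing exactly the strongest
#'   effects) yet shrinks ordinary coefficients by well under 5%.
#' @return object of class `mglm_fit`: coefficient matrix (taxa x terms),
#'   per-taxon covariance array, fitted probabilities, design information.
#' @export
fit_binomial_mglm <- function(matrix, metadata, formula = ~ season * sex,
                              ridge = 0.05) {
  stopifnot(is.matrix(matrix), is.logical(matrix))
  des <- .design_matrix(formula, metadata)
  .stop_if(!all(des$keep %in% colnames(matrix)),
           "metadata samples missing from the matrix")
  Y <- t(matrix[, des$keep, drop = FALSE]) * 1 # samples x taxa
  X <- des$X
  fits <- apply(Y, 2, function(y) .fit_ridge_logistic(X, y, ridge),
                simplify = FALSE)
  coefs <- do.call(rbind, lapply(fits, `[[`, "beta"))
  dimnames(coefs) <- list(colnames(Y), colnames(X))
  vcovs <- array(unlist(lapply(fits, `[[`, "vcov")),
                 dim = c(ncol(X), ncol(X), ncol(Y)),
                 dimnames = list(colnames(X), colnames(X), colnames(Y)))
  structure(list(formula = formula, X = X, Y = Y,
                 coefficients = coefs, vcov = vcovs,
                 fitted = vapply(fits, `[[`, numeric(nrow(X)), "mu"),
                 loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                 converged = vapply(fits, `[[`, logical(1), "converged"),
                 ridge_used = vapply(fits, `[[`, numeric(1), "ridge"),
                 excluded = setdiff(colnames(matrix), des$keep),
                 metadata = des$metadata, ridge = ridge),
            class = "mglm_fit")
}

#' @export
print.mglm_fit <- function(x, ...) {
  cat(sprintf("<mglm_fit> %d taxa x %d samples, formula %s\n",
              ncol(x$Y), nrow(x$Y), deparse(x$formula)))
  if (length(x$excluded) > 0)
    cat(sprintf("excluded %d sample(s) with unknown factor levels\n",
                length(x$excluded)))
  invisible(x)
}

.term_columns <- function(fit, term) {
  labels <- attr(stats::terms(fit$formula), "term.labels")
  .stop_if(!term %in% labels,
           sprintf("term %s not in model (available: %s)", sQuote(term),
                   paste(labels, collapse = ", ")))
  which(attr(fit$X, "assign") == match(term, labels))
}

# per-taxon Wald statistic for the coefficients of one model term
.wald_stats <- function(fit, term) {
  j <- .term_columns(fit, term)
  vapply(seq_len(ncol(fit$Y)), function(t) {
    b <- fit$coefficients[t, j]
    V <- fit$vcov[j, j, t]
    drop(t(b) %*% solve(V, b))
  }, numeric(1))
}

.reduced_formula <- function(formula, term) {
  labels <- setdiff(attr(stats::terms(formula), "term.labels"), term)
  if (length(labels) == 0) ~1 else stats::reformulate(labels)
}

.simulate_response <- function(fitted) {
  matrix(stats::rbinom(length(fitted), 1, fitted), nrow = nrow(fitted),
         dimnames = dimnames(fitted))
}

#' Resampling-based multivariate test of one model term
#'
#' The observed statistic is the sum over taxa of the per-taxon Wald
#' statistics for `term`. Its null distribution is built by Monte Carlo
#' resampling: responses are simulated from the reduced model (the fit
#' without `term`), the full model is refitted, and the statistic
#' recomputed; `p = (1 + #\{null >= observed\}) / (1 + n_resamples)`. Row
#' permutation of the response matrix (valid under a global null) is
#' available as an alternative scheme.
#'
#' @param fit an [fit_binomial_mglm()] result.
#' @param term model term label, e.g. `"season"` or `"season:sex"`.
#' @param n_resamples Monte Carlo resamples (>= 99).
#' @param seed RNG seed.
#' @param method `"parametric"` simulation from the reduced model, or
#'   `"permutation"` of sample rows.
#' @return list with `term`, `statistic` (sum of Wald), `wald` (per
#'   taxon), `p`, `n_resamples`, `seed`, `null_stats`.
#' @export
multivariate_test <- function(fit, term, n_resamples = 999, seed = 1,
                              method = c("parametric", "permutation")) {
  stopifnot(inherits(fit, "mglm_fit"), n_resamples >= 99)
  method <- match.arg(method)
  null_fit <- .null_refits(fit, term, n_resamples, seed, method)
  obs <- sum(.wald_stats(fit, term))
  null_stats <- vapply(null_fit, function(w) sum(w), numeric(1))
  list(term = term, statistic = obs, wald = .wald_stats(fit, term),
       p = (1 + sum(null_stats >= obs)) / (1 + n_resamples),
       n_resamples = n_resamples, seed = seed, null_stats = null_stats)
}

# shared resampling engine: returns a list of per-taxon Wald vectors under
# the null for `term`
.null_refits <- function(fit, term, n_resamples, seed, method) {
  reduced <- fit_binomial_mglm(t(fit$Y > 0), fit$metadata,
                               .reduced_formula(fit$formula, term),
                               ridge = fit$ridge)
  set.seed(seed)
  X <- fit$X
  j_fun <- function(f) .wald_stats(f, term)
  lapply(seq_len(n_resamples), function(r) {
    Yr <- if (method == "parametric") .simulate_response(reduced$fitted)
          else fit$Y[sample(nrow(fit$Y)), , drop = FALSE]
    fr <- fit
    refits <- apply(Yr, 2, function(y) .fit_ridge_logistic(X, y, fit$ridge),
                    simplify = FALSE)
    fr$coefficients <- do.call(rbind, lapply(refits, `[[`, "beta"))
    fr$vcov <- array(unlist(lapply(refits, `[[`, "vcov")),
                     dim = dim(fit$vcov))
    fr$Y <- Yr
    j_fun(fr)
  })
}

#' Per-taxon resampling tests with step-down multiplicity adjustment
#'
#' Per-taxon Wald statistics for `term` with Monte Carlo p-values from the
#' same null-resampling scheme as [multivariate_test()]. Adjustment across
#' taxa is free step-down resampling (successive-maxima), which controls
#' the family-wise error rate while exploiting the correlation among taxa;
#' `"none"` and `"holm"` are also available.
#'
#' @inheritParams multivariate_test
#' @param adjust multiplicity adjustment.
#' @return data frame with columns `taxon`, `wald`, `p_raw`, `p_adj`.
#' @export
per_taxon_tests <- function(fit, term, n_resamples = 999, seed = 1,
                            method = c("parametric", "permutation"),
                            adjust = c("free_stepdown", "none", "holm")) {
  stopifnot(inherits(fit, "mglm_fit"), n_resamples >= 99)
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  obs <- .wald_stats(fit, term)
  W0 <- do.call(rbind, .null_refits(fit, term, n_resamples, seed, method))
  p_raw <- vapply(seq_along(obs), function(t)
    (1 + sum(W0[, t] >= obs[t])) / (1 + n_resamples), numeric(1))
  p_adj <- switch(adjust,
    none = p_raw,
    holm = stats::p.adjust(p_raw, "holm"),
    free_stepdown = {
      ord <- order(obs, decreasing = TRUE)
      K <- length(ord)
      # successive maxima over the null draws, from least significant up:
      # column t of cummax_null is the max over the t least significant taxa
      cummax_null <- t(apply(W0[, rev(ord), drop = FALSE], 1, cummax))
      if (K == 1) cummax_null <- t(cummax_null)
      q <- vapply(seq_len(K), function(i)
        (1 + sum(cummax_null[, K - i + 1] >= obs[ord[i]])) /
          (1 + n_resamples), numeric(1))
      q <- cummax(q) # enforce monotonicity down the ordered list
      out <- numeric(length(obs))
      out[ord] <- q
      out
    })
  data.frame(taxon = colnames(fit$Y), wald = obs, p_raw = p_raw,
             p_adj = p_adj, row.names = NULL)
}

#' AIC-based model selection across candidate formulas
#'
#' The AIC of a multivariate fit is the sum over taxa of the per-taxon
#' binomial AIC (`2k - 2 logLik`). All candidates are fitted on the same
#' samples (those with known levels for every variable appearing in any
#' candidate) so their AICs are comparable.
#'
#' @param matrix logical presence-absence matrix (taxa x samples).
#' @param metadata sample metadata.
#' @param formulas list of right-hand-side formulas.
#' @param ridge L2 penalty passed to the fits.
#' @return list with `table` (formula, n_terms, aic, converged, sorted by
#'   AIC), `best` (lowest-AIC formula) and `fits`.
#' @export
aic_model_selection <- function(matrix, metadata,
                                formulas = list(~1, ~season, ~sex,
                                                ~ season + sex,
                                                ~ season * sex),
                                ridge = 0.05) {
  .stop_if(length(formulas) == 0, "no candidate formulas")
  all_vars <- unique(unlist(lapply(formulas, all.vars)))
  common <- metadata
  for (v in all_vars) common <- common[common[[v]] != "unknown", , drop = FALSE]
  fits <- lapply(formulas, function(f)
    tryCatch(fit_binomial_mglm(matrix[, colnames(matrix) %in%
                                        common$sample_id, drop = FALSE],
                               common, f, ridge),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (any(!ok))
    warning("candidate(s) failed to fit and were excluded: ",
            paste(vapply(formulas[!ok], deparse, character(1)),
                  collapse = "; "), call. = FALSE)
  aic <- vapply(fits[ok], function(f)
    sum(2 * ncol(f$X) - 2 * f$loglik), numeric(1))
  tab <- data.frame(formula = vapply(formulas[ok], function(f)
                      paste(deparse(f), collapse = ""), character(1)),
                    n_coef = vapply(fits[ok], function(f) ncol(f$X),
                                    numeric(1)),
                    aic = aic,
                    converged = vapply(fits[ok], function(f)
                      all(f$converged), logical(1)),
                    row.names = NULL)
  ord <- order(tab$aic)
  list(table = tab[ord, , drop = FALSE],
       best = formulas[ok][[which.min(aic)]],
       fits = fits[ok])
}
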