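## L1-logistic stability selection of diagnosis from metabolite intensities.

#' Stability-selection configuration
#'
#' @param C inverse regularization strength of the L1 logistic model
#'   (default 100); mapped to a lasso penalty `lambda = 1 / (C * n_train)`.
#' @param n_subsamples number of stratified train/test subsamples
#'   (default 500).
#' @param test_fraction fraction of each class held out per subsample
#'   (default 0.25).
#' @param top_k number of top-ranked predictors retained by
#'   [rankPredictors()] (default 200).
#' @param seed RNG seed (mandatory).
#' @return a list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(C = 100, n_subsamples = 500,
                             test_fraction = 0.25, top_k = 200, seed) {
  mcAssert(!missing(seed), "argumentError", "seed is mandatory")
  mcAssert(C > 0 && n_subsamples >= 1, "argumentError",
           "C and n_subsamples must be positive")
  mcAssert(test_fraction > 0 && test_fraction < 1, "argumentError",
           "test_fraction must be in (0,1)")
  structure(list(C = C, n_subsamples = n_subsamples,
                 test_fraction = test_fraction, top_k = top_k,
                 seed = as.integer(seed)),
            class = "ClassifierConfig")
}

## Mann-Whitney formulation of the ROC AUC; ties contribute 1/2, so a
## constant score gives 0.5.
rocAuc <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stability selection with L1-regularized logistic regression
#'
#' Draws `n_subsamples` seeded stratified train/test splits; on each, peaks
#' are standardized within the training fold (the same transform applied to
#' the test fold), an L1 logistic model with fixed penalty (`C` of
#' [classifierConfig()]) is fitted on the training fold, the set of
#' nonzero-coefficient peaks is recorded, and the ROC AUC is evaluated on
#' the test fold. A peak's inclusion probability is the fraction of
#' subsamples in which its coefficient was nonzero.
#'
#' @param x a [PeakExperiment-class] or a peaks x samples matrix;
#'   linear-scale intensities are log2-transformed first.
#' @param labels two-level vector (e.g. `"control"`/`"ASD"`) aligned with the
#'   samples; the second level sorted alphabetically last is the positive
#'   class unless `labels` is a factor, whose second level is used.
#' @param config a [classifierConfig()].
#' @return a list of class `StabilityResult`: `inclusion_probability` (named,
#'   in `[0,1]`), `mean_abs_coef`, `auc` (per subsample), `mean_auc`,
#'   `ranking` (peak ids by the documented tie-break chain),
#'   `n_nonconverged`.
#' @export
stabilitySelection <- function(x, labels, config) {
  mcAssert(is(config, "ClassifierConfig"), "argumentError",
           "config must come from classifierConfig()")
  if (is(x, "PeakExperiment")) {
    m <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  } else m <- as.matrix(x)
  labels <- as.factor(labels)
  mcAssert(nlevels(labels) == 2, "argumentError", "labels must have 2 levels")
  y <- as.integer(labels == levels(labels)[2])
  mcAssert(min(table(y)) >= 4, "argumentError",
           "both classes need at least 4 samples")
  feat <- t(m)                        # samples x peaks
  n <- nrow(feat); p <- ncol(feat)
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  ntr1 <- max(2L, round((1 - config$test_fraction) * length(idx1)))
  ntr0 <- max(2L, round((1 - config$test_fraction) * length(idx0)))
  ntr1 <- min(ntr1, length(idx1) - 1L)
  ntr0 <- min(ntr0, length(idx0) - 1L)
  set.seed(config$seed)
  incl <- numeric(p)
  coef_abs <- numeric(p)
  aucs <- numeric(config$n_subsamples)
  n_nc <- 0L
  for (b in seq_len(config$n_subsamples)) {
    tr <- c(sample(idx1, ntr1), sample(idx0, ntr0))
    te <- setdiff(seq_len(n), tr)
    mu <- colMeans(feat[tr, , drop = FALSE])
    s <- apply(feat[tr, , drop = FALSE], 2L, sd)
    s[!is.finite(s) | s == 0] <- 1
    xtr <- sweep(sweep(feat[tr, , drop = FALSE], 2L, mu), 2L, s, "/")
    xte <- sweep(sweep(feat[te, , drop = FALSE], 2L, mu), 2L, s, "/")
    informative <- apply(xtr, 2L, function(v) any(v != v[1]))
    if (!any(informative)) {          # intercept-only degenerate case
      aucs[b] <- rocAuc(rep(0, length(te)), y[te] == 1)
      next
    }
    lam <- 1 / (config$C * length(tr))
    lam_path <- exp(seq(log(lam * 200), log(lam), length.out = 20))
    fit <- tryCatch(
      glmnet::glmnet(xtr[, informative, drop = FALSE], y[tr],
                     family = "binomial", alpha = 1, lambda = lam_path,
                     standardize = FALSE),
      warning = function(w) {
        n_nc <<- n_nc + 1L
        suppressWarnings(
          glmnet::glmnet(xtr[, informative, drop = FALSE], y[tr],
                         family = "binomial", alpha = 1, lambda = lam_path,
                         standardize = FALSE))
      })
    beta <- as.numeric(coef(fit, s = lam, exact = FALSE))[-1]
    nz <- which(beta != 0)
    full <- which(informative)
    incl[full[nz]] <- incl[full[nz]] + 1
    coef_abs[full] <- coef_abs[full] + abs(beta)
    eta <- as.numeric(xte[, informative, drop = FALSE] %*% beta)
    aucs[b] <- rocAuc(eta, y[te] == 1)
  }
  incl <- incl / config$n_subsamples
  coef_abs <- coef_abs / config$n_subsamples
  names(incl) <- names(coef_abs) <- colnames(feat)
  ranking <- colnames(feat)[order(-incl, -coef_abs, colnames(feat))]
  structure(list(inclusion_probability = incl, mean_abs_coef = coef_abs,
                 auc = aucs, mean_auc = mean(aucs, na.rm = TRUE),
                 ranking = ranking, n_nonconverged = n_nc),
            class = "StabilityResult")
}

#' Top-k stability-selected predictors
#'
#' Deterministic ranking by inclusion probability, ties broken by mean
#' absolute coefficient, then peak id. Only peaks with inclusion probability
#' `> 0` are returned; if fewer than `top_k` remain, the shorter list is
#' returned with a warning.
#'
#' @param result a `StabilityResult` from [stabilitySelection()].
#' @param top_k number of predictors requested (default 200).
#' @return character vector of peak ids.
#' @export
rankPredictors <- function(result, top_k = 200) {
  mcAssert(is.numeric(top_k) && top_k > 0, "argumentError",
           "top_k must be a positive integer")
  nonzero <- result$ranking[result$inclusion_probability[result$ranking] > 0]
  if (length(nonzero) < top_k)
    warning(sprintf("only %d predictors have nonzero inclusion probability",
                    length(nonzero)))
  utils::head(nonzero, top_k)
}
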