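## Two-reference polynomial-age ANCOVA, BH adjustment and temporal-module
## clustering of significant peaks.

#' Differential-analysis configuration
#'
#' @param max_degree largest polynomial degree of the age trend considered
#'   (default 3).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param n_modules number of temporal modules the significant peaks are cut
#'   into (default 4).
#' @param degree_tie_epsilon adjusted-R2 ties within this epsilon resolve to
#'   the smaller degree (default 1e-8).
#' @return a list of class `DifferentialConfig`.
#' @export
differentialConfig <- function(max_degree = 3, alpha = 0.05, n_modules = 4,
                               degree_tie_epsilon = 1e-8) {
  mcAssert(alpha > 0 && alpha < 1, "argumentError", "alpha must be in (0,1)")
  mcAssert(max_degree >= 1, "argumentError", "max_degree must be >= 1")
  structure(list(max_degree = max_degree, alpha = alpha,
                 n_modules = n_modules,
                 degree_tie_epsilon = degree_tie_epsilon),
            class = "DifferentialConfig")
}

## Power basis on standardized age (centering/scaling before powers keeps the
## design well conditioned at degree <= 4).
.polyBasis <- function(age, degree, center, scale) {
  a <- (age - center) / scale
  X <- matrix(1, length(age), 1L)
  if (degree >= 1)
    X <- cbind(X, outer(a, seq_len(degree), `^`))
  X
}

#' Choose the polynomial degree of an age trend by adjusted R-squared
#'
#' Fits OLS polynomials of degree 0..`max_degree` in standardized age and
#' returns the degree maximizing adjusted R2; ties within
#' `tie_epsilon` resolve to the smallest degree. The degree is capped at
#' what the data can support (`n - 2` observations, number of distinct
#' ages minus one), with a warning when the cap binds.
#'
#' @param age numeric vector of ages (years).
#' @param y numeric response (log2 intensities).
#' @param max_degree largest degree considered (default 3).
#' @param tie_epsilon adjusted-R2 tie tolerance (default 1e-8).
#' @return the selected degree (integer) with attribute `"adj_r2"`.
#' @export
selectPolyDegree <- function(age, y, max_degree = 3, tie_epsilon = 1e-8) {
  n <- length(y)
  mcAssert(n == length(age) && n >= 2, "argumentError",
           "need matching age/y vectors with >= 2 observations")
  mcAssert(sd(age) > 0, "argumentError", "ages must not all be identical")
  cap <- min(max_degree, n - 2L, length(unique(age)) - 1L)
  if (cap < max_degree)
    warning(sprintf("polynomial degree capped at %d (n=%d, %d distinct ages)",
                    cap, n, length(unique(age))))
  ctr <- mean(age); scl <- sd(age)
  tss <- sum((y - mean(y))^2)
  adj <- numeric(cap + 1L)
  for (d in 0:cap) {
    X <- .polyBasis(age, d, ctr, scl)
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    p <- fit$rank - 1L            # slope terms actually estimated
    adj[d + 1L] <- if (tss == 0) 0 else
      1 - (rss / (n - p - 1L)) / (tss / (n - 1L))
  }
  best <- which(adj >= max(adj) - tie_epsilon)[1L] - 1L
  structure(as.integer(best), adj_r2 = adj)
}

#' Group-offset ANCOVA on a polynomial age trend
#'
#' The polynomial degree is chosen on the reference group's samples only
#' ([selectPolyDegree()]); the null model is that polynomial fitted to all
#' samples, the full model adds an additive group-offset term, and the
#' improvement is assessed with a 1-df F-test:
#' `F = (RSS0 - RSS1) / (RSS1 / (n - k - 2))` with `k` the chosen degree.
#'
#' @param y numeric response (log2 intensities).
#' @param age numeric ages (years); standardized internally before powers.
#' @param group two-level factor/character vector.
#' @param reference the group used for degree selection.
#' @param max_degree largest degree considered (default 3).
#' @return a list: `degree`, `F`, `p`, `coef_group` (offset of the
#'   non-reference group relative to the reference), `df2`.
#' @export
groupAncova <- function(y, age, group, reference, max_degree = 3) {
  group <- as.character(group)
  lev <- unique(group)
  mcAssert(length(lev) == 2, "argumentError", "group must have two levels")
  mcAssert(reference %in% lev, "argumentError",
           "reference must be one of the group levels")
  mcAssert(all(table(group) >= 2), "argumentError",
           "both groups need at least 2 samples")
  ref_idx <- which(group == reference)
  d <- suppressWarnings(
    selectPolyDegree(age[ref_idx], y[ref_idx], max_degree))
  n <- length(y)
  ctr <- mean(age); scl <- sd(age)
  X0 <- .polyBasis(age, d, ctr, scl)
  ind <- as.numeric(group != reference)
  X1 <- cbind(X0, ind)
  f0 <- lm.fit(X0, y)
  f1 <- lm.fit(X1, y)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df2 <- n - d - 2L
  if (rss1 <= 1e-12 * max(1, sum(y^2))) {
    ## perfect full-model fit: constant response (null fits too -> no effect)
    ## or a pure group offset (null cannot fit -> overwhelming effect)
    perfect_null <- rss0 <= 1e-12 * max(1, sum(y^2))
    return(list(degree = d, F = if (perfect_null) 0 else Inf,
                p = if (perfect_null) 1 else 0,
                coef_group = unname(f1$coefficients[ncol(X1)]), df2 = df2))
  }
  Fstat <- max(rss0 - rss1, 0) / (rss1 / df2)
  list(degree = d, F = Fstat, p = pf(Fstat, 1, df2, lower.tail = FALSE),
       coef_group = unname(f1$coefficients[ncol(X1)]), df2 = df2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false-discovery-rate adjustment (`q(i) = min over j >= i of
#' p(j) * m / j`, clipped at 1). Non-finite p-values propagate as `NA` with
#' a warning.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return the vector of q-values.
#' @export
bhAdjust <- function(p) {
  nan <- !is.finite(p)
  if (any(nan)) {
    warning(sprintf("%d non-finite p-value(s) propagated as NA", sum(nan)))
    p[nan] <- NA_real_
  }
  mcAssert(all(p >= 0 & p <= 1, na.rm = TRUE), "argumentError",
           "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call ASD-related metabolites with a two-reference age-ANCOVA
#'
#' Each peak is tested with [groupAncova()] twice, once choosing the age
#' polynomial on the control samples and once on the ASD samples. BH
#' adjustment is applied separately within each reference run across all
#' peaks, and a peak is significant when both adjusted values pass `alpha`.
#' The effect direction is read off the ASD offset coefficient of the
#' control-reference fit.
#'
#' @param x a [PeakExperiment-class]; intensities are log2-transformed here
#'   unless already flagged log2.
#' @param meta sample metadata (defaults to `sampleData(x)`); only human
#'   control/ASD samples enter the test.
#' @param config a [differentialConfig()].
#' @return a `data.frame` sorted by `max(q)` with columns `peak_id`,
#'   `degree_ref_control`, `degree_ref_asd`, `F_ref_control`, `F_ref_asd`,
#'   `p_ref_control`, `p_ref_asd`, `q_ref_control`, `q_ref_asd`,
#'   `significant`, `effect_sign`; the largest nominal p among significant
#'   peaks per run is attached as attribute `"nominal_cutoff"`.
#' @export
callAsdMetabolites <- function(x, meta = sampleData(x),
                               config = differentialConfig()) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  mcAssert(!anyNA(idx), "linkageError", "samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  human <- which(meta$species == "human" & meta$group %in% c("control", "ASD"))
  mcAssert(length(human) >= 2 * (config$max_degree + 2), "argumentError",
           "too few human samples for the ANCOVA")
  grp <- meta$group[human]
  age <- meta$age[human]
  L <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  L <- L[, human, drop = FALSE]
  n <- nrow(L)
  res <- data.frame(peak_id = rownames(L),
                    degree_ref_control = NA_integer_,
                    degree_ref_asd = NA_integer_,
                    F_ref_control = NA_real_, F_ref_asd = NA_real_,
                    p_ref_control = NA_real_, p_ref_asd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rc <- groupAncova(L[i, ], age, grp, "control", config$max_degree)
    ra <- groupAncova(L[i, ], age, grp, "ASD", config$max_degree)
    res$degree_ref_control[i] <- rc$degree
    res$degree_ref_asd[i] <- ra$degree
    res$F_ref_control[i] <- rc$F
    res$F_ref_asd[i] <- ra$F
    res$p_ref_control[i] <- rc$p
    res$p_ref_asd[i] <- ra$p
    if (i == 1L) coefs <- numeric(n)
    coefs[i] <- rc$coef_group
  }
  res$q_ref_control <- bhAdjust(res$p_ref_control)
  res$q_ref_asd <- bhAdjust(res$p_ref_asd)
  res$significant <- res$q_ref_control <= config$alpha &
    res$q_ref_asd <= config$alpha
  res$effect_sign <- ifelse(coefs > 0, "up_in_ASD", "down_in_ASD")
  res <- res[order(pmax(res$q_ref_control, res$q_ref_asd)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nominal_cutoff") <- c(
    ref_control = suppressWarnings(max(res$p_ref_control[res$significant])),
    ref_asd = suppressWarnings(max(res$p_ref_asd[res$significant])))
  res
}

#' Cluster significant peaks into temporal modules
#'
#' Feature vector per significant peak = standardized log2 intensities over
#' all human (control + ASD) samples; distance = 1 - Pearson correlation;
#' complete-linkage hierarchical clustering cut at `n_modules`. Peaks are
#' sorted by id before clustering so the assignment is invariant to input
#' order; zero-variance peaks are dropped with a warning. Per-module summary
#' trajectories (mean standardized intensity per sample, smoothed with a
#' cubic smoothing spline on an age grid) are returned per group.
#'
#' @param x a [PeakExperiment-class].
#' @param results output of [callAsdMetabolites()].
#' @param meta sample metadata.
#' @param config a [differentialConfig()].
#' @return a list: `assignment` (named integer vector peak -> module),
#'   `trajectories` (`data.frame`: module, group, age, mean, sd),
#'   `hclust` (the tree).
#' @export
clusterModules <- function(x, results, meta = sampleData(x),
                           config = differentialConfig()) {
  sig <- sort(results$peak_id[results$significant])
  mcAssert(length(sig) >= config$n_modules, "argumentError",
           sprintf("need at least %d significant peaks to form modules",
                   config$n_modules))
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  meta <- meta[idx, , drop = FALSE]
  human <- which(meta$species == "human" & meta$group %in% c("control", "ASD"))
  L <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  L <- L[sig, human, drop = FALSE]
  z <- rowStandardize(L)
  degen <- attr(z, "degenerate")
  if (length(degen)) {
    warning(sprintf("%d zero-variance peak(s) dropped from module clustering",
                    length(degen)))
    z <- z[-degen, , drop = FALSE]
  }
  d <- stats::as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "complete")
  assignment <- cutree(hc, k = config$n_modules)
  age <- meta$age[human]
  grp <- meta$group[human]
  grid <- seq(min(age), max(age), length.out = 50)
  traj <- list()
  for (m in sort(unique(assignment))) {
    zm <- z[names(assignment)[assignment == m], , drop = FALSE]
    for (g in unique(grp)) {
      cols <- which(grp == g)
      mean_per_sample <- colMeans(zm[, cols, drop = FALSE])
      fit <- tryCatch(smooth.spline(age[cols], mean_per_sample),
                      error = function(e) NULL)
      traj[[length(traj) + 1L]] <- data.frame(
        module = m, group = g, age = grid,
        mean = if (is.null(fit)) NA_real_ else predict(fit, grid)$y,
        sd = sd(mean_per_sample), stringsAsFactors = FALSE)
    }
  }
  list(assignment = assignment,
       trajectories = do.call(rbind, traj), hclust = hc)
}
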