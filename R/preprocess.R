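## Measurement-order drift correction, PMD-sensitivity filter and
## upper-quartile normalization.

#' Drift-correction configuration
#'
#' One shared SVR hyperparameter set is applied to every metabolite. Because
#' injection-order drift is a run-scale phenomenon, the default RBF kernel
#' width ties the length scale to the run length
#' (`gamma = 1 / range(order)^2`). Curve estimation and cluster flagging use
#' disjoint sample halves (split by order-rank parity): clusters are formed
#' from curves fitted on one half, and a cluster is flagged as
#' drift-affected only when its members' raw mean profile on the held-out
#' half shows |Spearman rho| vs order at or above `discard_rho_threshold`
#' AND a smoothed peak-to-trough amplitude of at least
#' `discard_amplitude_threshold` standardized units. The held-out
#' evaluation removes the selection bias that makes clusters of coherent
#' noise curves look order-associated on the data they were selected from.
#'
#' @param svr_c,svr_epsilon SVR cost and epsilon-tube width (defaults 1, 0.1).
#' @param svr_gamma RBF kernel width; `NULL` (default) uses
#'   `1 / range(injection order)^2`.
#' @param kmeans_k number of curve clusters (default 10).
#' @param kmeans_seed RNG seed for k-means (mandatory determinism).
#' @param discard_rho_threshold Spearman threshold (default 0.3).
#' @param discard_amplitude_threshold amplitude threshold in SD units
#'   (default 0.5).
#' @param action `"correct"` (subtract the cluster-average profile, default)
#'   or `"discard"` (drop members of flagged clusters).
#' @return a list of class `DriftConfig`.
#' @export
driftConfig <- function(svr_c = 1, svr_epsilon = 0.1, svr_gamma = NULL,
                        kmeans_k = 10, kmeans_seed = 1,
                        discard_rho_threshold = 0.3,
                        discard_amplitude_threshold = 0.5,
                        action = c("correct", "discard")) {
  mcAssert(kmeans_k >= 2, "argumentError", "kmeans_k must be >= 2")
  mcAssert(discard_rho_threshold > 0 && discard_rho_threshold < 1,
           "argumentError", "discard_rho_threshold must be in (0,1)")
  structure(list(svr_c = svr_c, svr_epsilon = svr_epsilon,
                 svr_gamma = svr_gamma, kmeans_k = kmeans_k,
                 kmeans_seed = kmeans_seed,
                 discard_rho_threshold = discard_rho_threshold,
                 discard_amplitude_threshold = discard_amplitude_threshold,
                 action = match.arg(action)),
            class = "DriftConfig")
}

## Fit one RBF-SVR of standardized intensity on injection order and return
## its predictions at the requested orders.
.svrCurve <- function(ord, y, at, config, gamma) {
  fit <- e1071::svm(x = matrix(ord, ncol = 1), y = y,
                    type = "eps-regression", kernel = "radial",
                    cost = config$svr_c, epsilon = config$svr_epsilon,
                    gamma = gamma, scale = FALSE)
  as.numeric(predict(fit, matrix(at, ncol = 1)))
}

#' Remove injection-order drift
#'
#' Per metabolite, intensities are log2-transformed, centered to mean 0 and
#' scaled to SD 1. The samples are split into two halves by injection-order
#' rank parity: on the estimation half, an RBF-kernel support vector
#' regression of standardized intensity on injection order gives each
#' metabolite an order-effect curve, and the curves (evaluated on the full
#' sorted-order grid) are clustered with k-means. Each cluster is then
#' judged on the held-out half: its members' raw mean profile vs order is
#' tested against the Spearman and amplitude thresholds of [driftConfig()]
#' (both must be met). Members of flagged clusters are corrected by
#' subtracting the cluster-average standardized profile (computed on all
#' samples), or dropped when `action = "discard"`; intensities are then
#' recalculated back to the original linear magnitude scale. Zero-variance
#' metabolites are passed through unchanged with a warning. When no cluster
#' is flagged the output equals the input (up to floating-point round-trip).
#'
#' @param x a linear-scale [PeakExperiment-class] with at least 10 samples.
#' @param meta sample metadata with `sample_id` and `injection_order`
#'   (defaults to `sampleData(x)`).
#' @param config a [driftConfig()].
#' @return a list with `table` (the corrected [PeakExperiment-class]) and
#'   `report`, a per-peak `data.frame` (`peak_id`, `cluster`, `flagged`,
#'   `corrected`, `discarded`) carrying the estimation-half fitted curves in
#'   `attr(report, "curves")` (peaks x order grid), the grid in
#'   `attr(report, "order_grid")` and per-cluster flag statistics in
#'   `attr(report, "cluster_stats")`.
#' @export
correctOrderEffect <- function(x, meta = sampleData(x),
                               config = driftConfig()) {
  mcAssert(!isLog2(x), "argumentError",
           "correctOrderEffect expects linear-scale intensities")
  mcAssert(ncol(x) >= 10, "argumentError",
           "drift curve fitting needs at least 10 samples")
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  mcAssert(!anyNA(idx), "linkageError", "samples missing from metadata")
  ord <- as.numeric(meta$injection_order[idx])
  mcAssert(all(is.finite(ord)) && !anyDuplicated(ord), "validationError",
           "injection_order must be defined and unique")
  L <- log2Matrix(intensities(x))
  z <- rowStandardize(L)
  degen <- attr(z, "degenerate")
  if (length(degen))
    warning(sprintf("%d constant-intensity peak(s) excluded from drift fitting",
                    length(degen)))
  active <- setdiff(seq_len(nrow(z)), degen)
  grid <- sort(ord)
  gamma <- if (is.null(config$svr_gamma)) 1 / diff(range(ord))^2 else
    config$svr_gamma
  ## estimation half (odd order ranks) / evaluation half (even order ranks)
  rk <- rank(ord)
  est <- which(rk %% 2 == 1L)
  ev <- which(rk %% 2 == 0L)
  curves <- matrix(0, nrow(z), ncol(z), dimnames = list(rownames(z), NULL))
  for (i in active)
    curves[i, ] <- .svrCurve(ord[est], z[i, est], grid, config, gamma)
  set.seed(config$kmeans_seed)
  k <- min(config$kmeans_k, length(active))
  km <- kmeans(curves[active, , drop = FALSE], centers = k,
               nstart = 5, iter.max = 100)
  cluster <- rep(NA_integer_, nrow(z))
  cluster[active] <- km$cluster
  ev_ord <- ord[ev]
  stats <- data.frame(cluster = seq_len(k), n = NA_integer_,
                      heldout_rho = NA_real_, heldout_amplitude = NA_real_,
                      flagged = FALSE)
  flagged_clusters <- integer()
  for (cl in seq_len(k)) {
    members <- active[km$cluster == cl]
    prof <- colMeans(z[members, ev, drop = FALSE])
    rho <- suppressWarnings(cor(prof, ev_ord, method = "spearman"))
    sm <- .svrCurve(ev_ord, prof, sort(ev_ord), config, gamma)
    amp <- max(sm) - min(sm)
    hit <- is.finite(rho) && abs(rho) >= config$discard_rho_threshold &&
      amp >= config$discard_amplitude_threshold
    stats[cl, c("n", "heldout_rho", "heldout_amplitude", "flagged")] <-
      list(length(members), rho, amp, hit)
    if (hit) flagged_clusters <- c(flagged_clusters, cl)
  }
  flagged <- !is.na(cluster) & cluster %in% flagged_clusters
  corrected <- discarded <- rep(FALSE, nrow(z))
  z_new <- z
  if (any(flagged)) {
    if (config$action == "correct") {
      for (cl in flagged_clusters) {
        members <- which(!is.na(cluster) & cluster == cl)
        prof <- colMeans(z[members, , drop = FALSE])  # cluster average
        z_new[members, ] <- sweep(z[members, , drop = FALSE], 2L, prof)
        corrected[members] <- TRUE
      }
    } else {
      discarded[flagged] <- TRUE
    }
  }
  back <- 2^(z_new * attr(z, "scale") + attr(z, "center"))
  back[degen, ] <- intensities(x)[degen, , drop = FALSE]
  keep <- which(!discarded)
  out <- PeakExperiment(back[keep, , drop = FALSE], mz = peakMz(x)[keep],
                        mode = peakMode(x)[keep], rt = peakRt(x)[keep],
                        sampleData = meta[idx, , drop = FALSE])
  report <- data.frame(peak_id = rownames(z), cluster = cluster,
                       flagged = flagged, corrected = corrected,
                       discarded = discarded, stringsAsFactors = FALSE)
  attr(report, "curves") <- curves
  attr(report, "order_grid") <- grid
  attr(report, "cluster_stats") <- stats
  list(table = out, report = report)
}

#' PMD-filter configuration
#'
#' @param spline_df degrees of freedom of the natural cubic reference spline
#'   (default 4).
#' @param ci_level interval level (default 0.95).
#' @param short_pmd_max_hours postmortem delays at or below this bound count
#'   as short-PMD reference samples (default 1/3 h, i.e. 20 minutes).
#' @param species species providing reference and probe samples (default
#'   `"macaque"`).
#' @return a list of class `PmdConfig`.
#' @export
pmdConfig <- function(spline_df = 4, ci_level = 0.95,
                      short_pmd_max_hours = 1 / 3, species = "macaque") {
  mcAssert(ci_level > 0 && ci_level < 1, "argumentError",
           "ci_level must be in (0,1)")
  structure(list(spline_df = spline_df, ci_level = ci_level,
                 short_pmd_max_hours = short_pmd_max_hours,
                 species = species),
            class = "PmdConfig")
}

#' Exclude metabolites sensitive to postmortem delay
#'
#' For each metabolite a natural cubic regression spline (default 4 df) of
#' log2 intensity on age is fitted to the short-PMD reference samples; each
#' prolonged-PMD probe sample is compared against a prediction-style interval
#' (point prediction +/- z(ci_level) x sqrt(residual variance x (1 +
#' leverage))). A metabolite is excluded if any probe falls strictly outside
#' its interval; a probe exactly on a bound is retained. Probes whose age
#' lies outside the reference age range are skipped with a warning (no
#' extrapolation).
#'
#' @param x a [PeakExperiment-class] (linear or log2 scale).
#' @param meta sample metadata with `species`, `age`, `pmd_hours`.
#' @param config a [pmdConfig()].
#' @return a list with `table` (retained peaks), `excluded` (peak ids) and
#'   `details`, a `data.frame` of per-peak, per-probe predictions and bounds
#'   (log2 scale).
#' @export
pmdFilter <- function(x, meta = sampleData(x), config = pmdConfig()) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  mcAssert(!anyNA(idx), "linkageError", "samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  mcAssert(all(c("species", "age", "pmd_hours") %in% colnames(meta)),
           "formatError", "pmdFilter needs species, age and pmd_hours")
  in_sp <- meta$species == config$species
  ref <- which(in_sp & meta$pmd_hours <= config$short_pmd_max_hours)
  probe <- which(in_sp & meta$pmd_hours > config$short_pmd_max_hours)
  mcAssert(length(ref) >= 8, "argumentError",
           "need at least 8 short-PMD reference samples")
  if (length(probe) == 0) {
    warning("no prolonged-PMD probe samples present; nothing excluded")
    return(list(table = x, excluded = character(),
                details = data.frame()))
  }
  age_ref <- meta$age[ref]
  age_probe <- meta$age[probe]
  rng <- range(age_ref)
  usable <- age_probe >= rng[1] & age_probe <= rng[2]
  if (any(!usable))
    warning(sprintf("%d probe sample(s) outside the reference age range skipped",
                    sum(!usable)))
  probe <- probe[usable]
  if (length(probe) == 0)
    return(list(table = x, excluded = character(), details = data.frame()))
  L <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  zq <- qnorm(1 - (1 - config$ci_level) / 2)
  basis <- splines::ns(age_ref, df = config$spline_df)
  newb <- predict(basis, meta$age[probe])
  X <- cbind(1, basis)
  Xp <- cbind(1, newb)
  qrX <- qr(X)
  ## leverage of new points: x' (X'X)^-1 x
  XtXi <- chol2inv(qr.R(qrX))
  lev <- rowSums((Xp %*% XtXi) * Xp)
  det_list <- vector("list", nrow(L))
  excluded <- logical(nrow(L))
  for (i in seq_len(nrow(L))) {
    y <- L[i, ref]
    cf <- qr.coef(qrX, y)
    res <- y - as.vector(X %*% cf)
    s2 <- sum(res^2) / (length(ref) - ncol(X))
    pred <- as.vector(Xp %*% cf)
    half <- zq * sqrt(s2 * (1 + lev))
    lo <- pred - half
    hi <- pred + half
    obs <- L[i, probe]
    out <- obs < lo | obs > hi        # strictly outside
    excluded[i] <- any(out)
    det_list[[i]] <- data.frame(peak_id = rownames(L)[i],
                                probe = colnames(L)[probe],
                                observed = obs, predicted = pred,
                                lower = lo, upper = hi, outside = out,
                                stringsAsFactors = FALSE)
  }
  details <- do.call(rbind, det_list)
  rownames(details) <- NULL
  keep <- which(!excluded)
  list(table = x[keep, ], excluded = rownames(L)[excluded],
       details = details)
}

#' Upper-quartile normalization
#'
#' Within each ionization mode independently: each sample's intensities are
#' divided by the 75th percentile of its nonzero intensities and multiplied
#' by the geometric mean of the per-sample 75th percentiles, so output stays
#' near the input magnitude and per-sample upper quartiles become equal.
#'
#' @param x a linear-scale [PeakExperiment-class].
#' @return the normalized [PeakExperiment-class].
#' @export
upperQuartileNormalize <- function(x) {
  mcAssert(!isLog2(x), "argumentError",
           "upper-quartile normalization expects linear-scale intensities")
  m <- intensities(x)
  for (md in unique(peakMode(x))) {
    rows <- which(peakMode(x) == md)
    sub <- m[rows, , drop = FALSE]
    uq <- apply(sub, 2L, function(v) {
      v <- v[v > 0]
      if (length(v) == 0) return(NA_real_)
      quantile(v, 0.75, names = FALSE)
    })
    bad <- which(is.na(uq))
    mcAssert(length(bad) == 0, "normalizationError",
             sprintf("sample '%s' has all-zero intensities in %s mode",
                     colnames(m)[bad[1]], md))
    g <- exp(mean(log(uq)))
    m[rows, ] <- sweep(sub, 2L, uq / g, "/")
  }
  y <- x
  SummarizedExperiment::assay(y, "intensity") <- m
  y
}
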