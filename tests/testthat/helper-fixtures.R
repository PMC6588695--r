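## Shared fixtures and independent oracles used across the test files.

## Small PeakExperiment built directly in code.
toyPeaks <- function(p = 3, n = 2, seed = 1, mode = "positive",
                     log2 = FALSE) {
  set.seed(seed)
  m <- matrix(round(runif(p * n, 10, 1000), 3), p, n,
              dimnames = list(sprintf("pk%02d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  PeakExperiment(m, mz = round(runif(p, 100, 900), 4), mode = mode,
                 rt = round(runif(p, 0.5, 14), 2), log2 = log2)
}

## Human-only two-group table with chosen per-peak offsets (log2 scale).
twoGroupTable <- function(n_peaks, offsets = numeric(n_peaks),
                          n_control = 36, n_asd = 36, seed = 1,
                          noise_sd = 1) {
  set.seed(seed)
  n <- n_control + n_asd
  grp <- rep(c("control", "ASD"), c(n_control, n_asd))
  age <- runif(n, 1, 60)
  L <- matrix(rnorm(n_peaks * n, 20, noise_sd), n_peaks, n,
              dimnames = list(sprintf("pk%03d", seq_len(n_peaks)),
                              sprintf("s%03d", seq_len(n))))
  L <- L + outer(offsets, as.numeric(grp == "ASD"))
  meta <- data.frame(sample_id = colnames(L), species = "human",
                     group = grp, age = age,
                     injection_order = sample(n),
                     stringsAsFactors = FALSE)
  pe <- PeakExperiment(L, mz = runif(n_peaks, 100, 900), mode = "positive",
                       sampleData = meta, log2 = TRUE)
  list(table = pe, meta = meta)
}

## Brute-force BH step-up oracle: q(i) = min_{j >= i} p_(j) * m / j.
bhBrute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

## Exhaustive hypergeometric upper tail by enumeration of the pmf.
hyperBrute <- function(overlap, n_pathway, n_background, n_selected) {
  kmax <- min(n_pathway, n_selected)
  total <- choose(n_background, n_selected)
  sum(vapply(overlap:kmax, function(k)
    choose(n_pathway, k) * choose(n_background - n_pathway, n_selected - k),
    numeric(1))) / total
}

## Brute-force adduct annotation by exhaustive scan.
annotateBrute <- function(x, compounds, tol = 10,
                          config = annotationConfig(ppm_tolerance = tol)) {
  tab <- adductTable()
  recs <- list()
  for (i in seq_len(nrow(x))) {
    md <- peakMode(x)[i]
    adds <- if (md == "positive") config$adducts_positive else
      config$adducts_negative
    for (ad in adds) {
      for (j in seq_len(nrow(compounds))) {
        theo <- compounds$monoisotopic_mass[j] +
          tab$delta[tab$adduct == ad]
        pe <- (peakMz(x)[i] - theo) / theo * 1e6
        if (abs(pe) <= config$ppm_tolerance)
          recs[[length(recs) + 1L]] <- data.frame(
            peak_id = rownames(x)[i],
            compound_id = compounds$compound_id[j], adduct = ad,
            theoretical_mz = theo, ppm_error = pe,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(recs) == 0)
    return(data.frame(peak_id = character(), compound_id = character(),
                      adduct = character(), theoretical_mz = numeric(),
                      ppm_error = numeric()))
  out <- do.call(rbind, recs)
  out <- out[order(out$peak_id, out$compound_id, out$adduct), ]
  rownames(out) <- NULL
  out
}

## Mean silhouette width of a labelled 2-D embedding.
meanSilhouette <- function(xy, lab) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  s <- numeric(n)
  for (i in seq_len(n)) {
    a <- mean(d[i, lab == lab[i] & seq_len(n) != i])
    b <- min(tapply(d[i, lab != lab[i]], lab[lab != lab[i]], mean))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

## Adjusted Rand index between two labellings (independent of the
## package's code path; e1071 is already a package dependency).
ari <- function(a, b) e1071::classAgreement(table(a, b))$crand

## One shared default synthetic cohort run through the full preprocessing
## chain; computed lazily and cached for the acceptance tests.
.pipelineCache <- new.env()
defaultPipeline <- function() {
  if (!is.null(.pipelineCache$out)) return(.pipelineCache$out)
  coh <- generateCohort(cohortConfig(seed = 7))
  merged <- mergeModes(coh$pos, coh$neg)
  dr <- suppressWarnings(correctOrderEffect(merged))
  uq <- upperQuartileNormalize(dr$table)
  pf <- pmdFilter(uq)
  .pipelineCache$out <- list(cohort = coh, merged = merged, drift = dr,
                             normalized = uq, pmd = pf, clean = pf$table)
  .pipelineCache$out
}
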