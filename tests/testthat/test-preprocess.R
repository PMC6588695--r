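test_that("a driftless table is a fixed point of order correction", {
  set.seed(1)
  n <- 60; p <- 150
  m <- matrix(2^rnorm(n * p, 20, 1), p, n,
              dimnames = list(sprintf("pk%03d", 1:p), sprintf("s%02d", 1:n)))
  meta <- data.frame(sample_id = colnames(m), injection_order = sample(n))
  pe <- PeakExperiment(m, mz = runif(p, 100, 900), mode = "positive",
                       sampleData = meta)
  dr <- correctOrderEffect(pe)
  expect_equal(sum(dr$report$flagged), 0L)
  expect_equal(intensities(dr$table), m, tolerance = 1e-6)
})

test_that("seeded linear drift is detected, corrected and reported", {
  set.seed(2)
  n <- 150; p <- 200; nd <- 50   # a study-sized run length
  ord <- sample(n)
  drift <- 2 * ((ord - 1) / (n - 1) - 0.5)      # 2 SD across the run
  L <- matrix(rnorm(p * n, 20, 1), p, n,
              dimnames = list(sprintf("pk%03d", 1:p), sprintf("s%02d", 1:n)))
  L[1:nd, ] <- L[1:nd, ] + matrix(drift, nd, n, byrow = TRUE)
  meta <- data.frame(sample_id = colnames(L), injection_order = ord)
  pe <- PeakExperiment(2^L, mz = runif(p, 100, 900), mode = "positive",
                       sampleData = meta)
  dr <- correctOrderEffect(pe)
  drifted_ids <- sprintf("pk%03d", 1:nd)
  in_flagged <- dr$report$flagged[match(drifted_ids, dr$report$peak_id)]
  expect_gte(sum(in_flagged), 45)
  after <- log2(intensities(dr$table)[drifted_ids, ])
  rho <- apply(after, 1L, function(v) cor(v, ord, method = "spearman"))
  expect_lt(median(abs(rho)), 0.1)
  ## flagged members were corrected, none discarded under the default action
  expect_true(all(dr$report$corrected[dr$report$flagged]))
  expect_false(any(dr$report$discarded))
  ## discard action drops flagged peaks instead
  drd <- correctOrderEffect(pe, config = driftConfig(action = "discard"))
  expect_equal(nrow(drd$table), p - sum(drd$report$flagged))
})

test_that("order correction is idempotent and guards degenerate input", {
  set.seed(3)
  n <- 40; p <- 60
  ord <- sample(n)
  L <- matrix(rnorm(p * n, 18, 1), p, n,
              dimnames = list(sprintf("pk%03d", 1:p), sprintf("s%02d", 1:n)))
  L[1:15, ] <- L[1:15, ] + matrix(2 * ((ord - 1) / (n - 1) - 0.5), 15, n,
                                  byrow = TRUE)
  L[60, ] <- 12                                  # constant-intensity peak
  meta <- data.frame(sample_id = colnames(L), injection_order = ord)
  pe <- PeakExperiment(2^L, mz = runif(p, 100, 900), mode = "positive",
                       sampleData = meta)
  expect_warning(dr <- correctOrderEffect(pe), "constant")
  expect_equal(unname(intensities(dr$table)["pk060", ]),
               rep(2^12, n))                     # passed through unchanged
  dr2 <- suppressWarnings(correctOrderEffect(dr$table))
  expect_equal(sum(dr2$report$flagged), 0L)

  expect_error(correctOrderEffect(pe[, 1:8]), class = "argumentError")
  meta_bad <- meta; meta_bad$injection_order[2] <- meta_bad$injection_order[1]
  expect_error(correctOrderEffect(pe, meta_bad), class = "validationError")
})

## --- PMD filter -----------------------------------------------------------

pmdFixture <- function(p = 40, shift = numeric(p), seed = 4,
                       on_curve = FALSE) {
  set.seed(seed)
  n_ref <- 30; n_probe <- 2
  age <- c(runif(n_ref, 0, 20), 6, 14)
  pmd <- c(runif(n_ref, 0.05, 0.3), 5.5, 5.8)
  ids <- c(sprintf("r%02d", 1:n_ref), "probe1", "probe2")
  L <- matrix(rnorm(p * (n_ref + n_probe), 20, 1), p, n_ref + n_probe,
              dimnames = list(sprintf("pk%03d", 1:p), ids))
  trend <- outer(runif(p, -0.05, 0.05), age)     # smooth age trend
  L <- L + trend
  if (on_curve) {
    ## probe intensities exactly on the per-peak reference spline
    for (i in seq_len(p)) {
      df_ref <- data.frame(y = L[i, 1:n_ref], a = age[1:n_ref])
      fit <- lm(y ~ splines::ns(a, df = 4), df_ref)
      L[i, n_ref + 1:2] <- predict(fit, data.frame(a = age[n_ref + 1:2]))
    }
  }
  L[, n_ref + 1:2] <- L[, n_ref + 1:2] + shift
  meta <- data.frame(sample_id = ids, species = "macaque",
                     group = NA_character_, age = age, pmd_hours = pmd,
                     injection_order = seq_along(ids),
                     stringsAsFactors = FALSE)
  PeakExperiment(2^L, mz = runif(p, 100, 900), mode = "positive",
                 sampleData = meta)
}

test_that("probes on the reference spline are never excluded", {
  pe <- pmdFixture(p = 25, on_curve = TRUE)
  pf <- pmdFilter(pe)
  expect_length(pf$excluded, 0L)
  expect_equal(nrow(pf$table), 25L)
})

test_that("PMD-shifted peaks are excluded and the null rate matches theory", {
  p <- 500; nshift <- 20
  pe <- pmdFixture(p = p, shift = c(rep(10, nshift), rep(0, p - nshift)) *
                     0)  # shift applied per-peak below
  ## apply a +10 SD probe shift to the first 20 peaks only
  m <- log2(intensities(pe))
  m[1:nshift, c("probe1", "probe2")] <- m[1:nshift, c("probe1", "probe2")] + 10
  pe <- PeakExperiment(2^m, mz = peakMz(pe), mode = "positive",
                       sampleData = sampleData(pe))
  pf <- pmdFilter(pe)
  shifted <- sprintf("pk%03d", 1:nshift)
  expect_true(all(shifted %in% pf$excluded))
  ## false-exclusion rate among nulls ~ 1 - ci^2 per two probes (within 3 SD)
  fp <- length(setdiff(pf$excluded, shifted))
  p0 <- 1 - 0.95^2
  expect_lt(abs(fp / (p - nshift) - p0), 3 * sqrt(p0 * (1 - p0) / (p - nshift)) + 0.02)
})

test_that("a probe exactly on the interval boundary is retained", {
  pe <- pmdFixture(p = 10, on_curve = TRUE)
  pf0 <- pmdFilter(pe)
  d <- pf0$details
  ## move one probe of one retained peak exactly onto its upper bound
  row <- d[d$peak_id == "pk001" & d$probe == "probe1", ]
  m <- log2(intensities(pe))
  m["pk001", "probe1"] <- row$upper      # log2-scale table avoids round-trip
  pe2 <- PeakExperiment(m, mz = peakMz(pe), mode = "positive",
                        sampleData = sampleData(pe), log2 = TRUE)
  pf2 <- pmdFilter(pe2)
  expect_false("pk001" %in% pf2$excluded)
  ## nudged strictly outside, it is excluded
  m["pk001", "probe1"] <- row$upper + 1e-6
  pe3 <- PeakExperiment(m, mz = peakMz(pe), mode = "positive",
                        sampleData = sampleData(pe), log2 = TRUE)
  expect_true("pk001" %in% pmdFilter(pe3)$excluded)
})

test_that("PMD exclusions ignore sample order and peak relabeling", {
  pe <- pmdFixture(p = 60, seed = 8)
  m <- log2(intensities(pe))
  m[1:5, c("probe1", "probe2")] <- m[1:5, c("probe1", "probe2")] + 8
  pe <- PeakExperiment(2^m, mz = peakMz(pe), mode = "positive",
                       sampleData = sampleData(pe))
  base <- pmdFilter(pe)$excluded
  perm <- sample(ncol(pe))
  expect_setequal(pmdFilter(pe[, perm])$excluded, base)
  relab <- pe
  rownames(relab) <- sprintf("zz%03d", seq_len(nrow(pe)))
  expect_setequal(pmdFilter(relab)$excluded,
                  sprintf("zz%03d", match(base, rownames(pe))))
})

## --- upper-quartile normalization ----------------------------------------

test_that("upper-quartile normalization follows the hand-worked example", {
  ## two samples with upper quartiles 2 and 8; restoration factor 4, so
  ## sample 1 is scaled x2 and sample 2 x0.5
  a <- c(0.5, 1, 1.5, 2, 3)             # 75th percentile exactly 2
  m <- cbind(a = a, b = 4 * a)          # 75th percentile exactly 8
  rownames(m) <- paste0("p", 1:5)
  pe <- PeakExperiment(m, mz = 100 + 1:5, mode = "positive")
  out <- intensities(upperQuartileNormalize(pe))
  expect_equal(unname(out[, "a"]), unname(m[, "a"]) * 2, tolerance = 1e-12)
  expect_equal(unname(out[, "b"]), unname(m[, "b"]) * 0.5, tolerance = 1e-12)
  q <- apply(out, 2, function(v) quantile(v[v > 0], 0.75))
  expect_equal(q[[1]], q[[2]], tolerance = 1e-12)
})

test_that("upper-quartile normalization is identity on homogeneous data and scale-equivariant", {
  v <- c(3, 9, 27, 81, 1)
  m <- matrix(rep(v, 3), 5, 3,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:3)))
  pe <- PeakExperiment(m, mz = 100 + 1:5, mode = "positive")
  expect_equal(intensities(upperQuartileNormalize(pe)), m, tolerance = 1e-12)

  ## rescaling one sample changes the output only by one global factor
  ## (the geometric-mean restoration constant); between-sample structure
  ## and quartile equalization are exactly invariant
  pe2 <- toyPeaks(p = 12, n = 5, seed = 6)
  scaled <- intensities(pe2)
  scaled[, 2] <- scaled[, 2] * 10
  pe2s <- PeakExperiment(scaled, mz = peakMz(pe2), mode = "positive")
  o1 <- intensities(upperQuartileNormalize(pe2))
  o2 <- intensities(upperQuartileNormalize(pe2s))
  ratio <- o2 / o1
  expect_lt(diff(range(ratio)), 1e-9)
  expect_equal(unname(ratio[1, 1]), 10^(1 / 5), tolerance = 1e-9)
})

test_that("modes are normalized independently and all-zero samples are refused", {
  set.seed(10)
  m <- matrix(runif(40, 1, 100), 10, 4,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:4)))
  mode <- rep(c("positive", "negative"), each = 5)
  pe <- PeakExperiment(m, mz = 100 + 1:10, mode = mode)
  out <- intensities(upperQuartileNormalize(pe))
  for (md in unique(mode)) {
    q <- apply(out[mode == md, ], 2, function(v) quantile(v[v > 0], 0.75))
    expect_lt(diff(range(q)), 1e-10)
  }
  m2 <- m; m2[1:5, 2] <- 0
  pe2 <- PeakExperiment(m2, mz = 100 + 1:10, mode = mode)
  expect_error(upperQuartileNormalize(pe2), "s2",
               class = "normalizationError")
})
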