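## Lineage-specific (human vs chimpanzee) intensity-difference calls and
## their distribution over ASD modules.

#' Evolution-analysis configuration
#'
#' @param alpha BH threshold for the stringent (ANCOVA) calls (default 0.05).
#' @param age_scale named multiplicative factors mapping each species' ages
#'   onto human-equivalent years. The defaults align species lifespans onto
#'   the human range (human 1, chimpanzee 61/42, macaque 61/21) and are meant
#'   to be overridden when calibrated factors are available.
#' @param n_module_subsamples number of subsamplings for
#'   [moduleSpecificityRatio()] (default 1000).
#' @param subsample_n samples drawn per species per subsampling (default 30).
#' @param seed RNG seed.
#' @param max_degree polynomial degree bound of the stringent ANCOVA
#'   (default 3).
#' @param humans_included `"control"` (default) restricts human samples to
#'   controls; `"all"` keeps ASD samples too.
#' @return a list of class `EvolutionConfig`.
#' @export
evolutionConfig <- function(alpha = 0.05,
                            age_scale = c(human = 1, chimpanzee = 61 / 42,
                                          macaque = 61 / 21),
                            n_module_subsamples = 1000, subsample_n = 30,
                            seed = 1, max_degree = 3,
                            humans_included = c("control", "all")) {
  mcAssert(alpha > 0 && alpha < 1, "argumentError", "alpha must be in (0,1)")
  structure(list(alpha = alpha, age_scale = age_scale,
                 n_module_subsamples = n_module_subsamples,
                 subsample_n = subsample_n, seed = as.integer(seed),
                 max_degree = max_degree,
                 humans_included = match.arg(humans_included)),
            class = "EvolutionConfig")
}

#' Map ages onto human-equivalent years
#'
#' Multiplies each sample's age by its species' scaling factor; human ages
#' are unchanged under the default factor 1 and prenatal (negative) ages
#' scale identically.
#'
#' @param meta sample metadata with `species` and `age`.
#' @param config an [evolutionConfig()] carrying the `age_scale` factors.
#' @return `meta` with an added `age_scaled` column.
#' @export
scaleAges <- function(meta, config = evolutionConfig()) {
  meta <- as.data.frame(meta)
  missing <- setdiff(unique(meta$species), names(config$age_scale))
  mcAssert(length(missing) == 0, "configError",
           paste0("no age-scaling factor for species: ",
                  paste(missing, collapse = ", ")))
  meta$age_scaled <- meta$age * unname(config$age_scale[meta$species])
  meta
}

## Samples entering the cross-species comparison: humans restricted per
## config, nonhumans restricted to short-PMD animals when pmd_hours exists.
.evoSamples <- function(meta, config) {
  keep <- rep(TRUE, nrow(meta))
  if (config$humans_included == "control")
    keep <- keep & (meta$species != "human" |
                      (!is.na(meta$group) & meta$group == "control"))
  if ("pmd_hours" %in% colnames(meta))
    keep <- keep & (meta$species != "macaque" | meta$pmd_hours <= 1 / 3)
  which(keep)
}

#' Stringent lineage-specificity calls (two-reference species ANCOVA)
#'
#' For each species pair (human/chimpanzee, human/macaque,
#' chimpanzee/macaque) every peak is tested with the two-reference
#' polynomial ANCOVA ([groupAncova()]) on human-equivalent age, BH-adjusted
#' within the pair across peaks; the pair is significant when both
#' reference runs pass `alpha`. A peak is `human_specific` when both human
#' pairs are significant and the chimpanzee/macaque pair is not, and
#' `chimp_specific` under the mirrored rule.
#'
#' @param x a [PeakExperiment-class].
#' @param meta sample metadata with `species`, `age` (and optionally
#'   `group`, `pmd_hours`, see Details).
#' @param config an [evolutionConfig()].
#' @return a `data.frame`: `peak_id`, `stringent`, per-pair q-values
#'   `q_hc`, `q_hm`, `q_cm` (each the max over the two reference runs) and
#'   per-species mean z-scored intensities.
#' @export
stringentLineageCalls <- function(x, meta = sampleData(x),
                                  config = evolutionConfig()) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  mcAssert(!anyNA(idx), "linkageError", "samples missing from metadata")
  meta <- scaleAges(meta[idx, , drop = FALSE], config)
  use <- .evoSamples(meta, config)
  sp <- meta$species[use]
  mcAssert(all(c("human", "chimpanzee", "macaque") %in% sp), "argumentError",
           "all three species must be present")
  mcAssert(all(table(sp) >= 8), "argumentError",
           "each species needs at least 8 samples")
  L <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  L <- L[, use, drop = FALSE]
  age <- meta$age_scaled[use]
  pairs <- list(hc = c("human", "chimpanzee"),
                hm = c("human", "macaque"),
                cm = c("chimpanzee", "macaque"))
  qmat <- matrix(NA_real_, nrow(L), 3,
                 dimnames = list(rownames(L), names(pairs)))
  for (pr in names(pairs)) {
    cols <- which(sp %in% pairs[[pr]])
    g <- sp[cols]
    p1 <- p2 <- numeric(nrow(L))
    for (i in seq_len(nrow(L))) {
      p1[i] <- groupAncova(L[i, cols], age[cols], g, pairs[[pr]][1],
                           config$max_degree)$p
      p2[i] <- groupAncova(L[i, cols], age[cols], g, pairs[[pr]][2],
                           config$max_degree)$p
    }
    qmat[, pr] <- pmax(bhAdjust(p1), bhAdjust(p2))
  }
  sig <- qmat <= config$alpha
  call <- rep("none", nrow(L))
  call[sig[, "hc"] & sig[, "hm"] & !sig[, "cm"]] <- "human_specific"
  call[sig[, "hc"] & sig[, "cm"] & !sig[, "hm"]] <- "chimp_specific"
  z <- rowStandardize(L)
  out <- data.frame(peak_id = rownames(L), stringent = call,
                    q_hc = qmat[, "hc"], q_hm = qmat[, "hm"],
                    q_cm = qmat[, "cm"],
                    m_human = rowMeans(z[, sp == "human", drop = FALSE]),
                    m_chimp = rowMeans(z[, sp == "chimpanzee", drop = FALSE]),
                    m_macaque = rowMeans(z[, sp == "macaque", drop = FALSE]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Vectorized relaxed rule on a log2 matrix and species vector.
.relaxedCalls <- function(L, sp) {
  z <- rowStandardize(L)
  degen <- attr(z, "degenerate")
  mH <- rowMeans(z[, sp == "human", drop = FALSE])
  mC <- rowMeans(z[, sp == "chimpanzee", drop = FALSE])
  mM <- rowMeans(z[, sp == "macaque", drop = FALSE])
  dH <- mH - mM
  dC <- mC - mM
  same_sign <- sign(dH) == sign(dC) & dH != 0 & dC != 0
  call <- rep("none", nrow(L))
  call[same_sign & abs(dH) > abs(dC)] <- "human_specific"
  call[same_sign & abs(dC) > abs(dH)] <- "chimp_specific"
  call[degen] <- "none"
  list(call = call, m_human = mH, m_chimp = mC, m_macaque = mM,
       degenerate = degen)
}

#' Relaxed lineage-specificity calls (z-distance rule)
#'
#' Intensities are z-transformed per peak across all included samples
#' pooled; with species means `m_H`, `m_C`, `m_M`, a peak is
#' `human_specific` when `|m_H - m_M| > |m_C - m_M|` and the human and
#' chimpanzee deviations from macaque share their sign, `chimp_specific`
#' under the mirrored rule, otherwise `none`. Zero-variance peaks are
#' `none` with a warning. The call is invariant to any affine transform of
#' a peak's intensities.
#'
#' @param x a [PeakExperiment-class].
#' @param meta sample metadata.
#' @param config an [evolutionConfig()] (controls which samples enter).
#' @return a `data.frame`: `peak_id`, `relaxed`, `m_human`, `m_chimp`,
#'   `m_macaque`.
#' @export
relaxedLineageCalls <- function(x, meta = sampleData(x),
                                config = evolutionConfig()) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  mcAssert(!anyNA(idx), "linkageError", "samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  use <- .evoSamples(meta, config)
  sp <- meta$species[use]
  mcAssert(all(c("human", "chimpanzee", "macaque") %in% sp), "argumentError",
           "all three species must be present")
  L <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  rc <- .relaxedCalls(L[, use, drop = FALSE], sp)
  if (length(rc$degenerate))
    warning(sprintf("%d zero-variance peak(s) called 'none'",
                    length(rc$degenerate)))
  data.frame(peak_id = rownames(L), relaxed = rc$call,
             m_human = rc$m_human, m_chimp = rc$m_chimp,
             m_macaque = rc$m_macaque, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Human/chimpanzee specificity ratio per module under subsampling
#'
#' Repeatedly draws `subsample_n` samples per species without replacement,
#' recomputes the relaxed lineage calls on the subsample, and records the
#' ratio of human-specific to chimpanzee-specific call counts for the whole
#' metabolome, for all module peaks pooled, and within each module. Zero
#' denominators yield `Inf`; summaries use median and quartiles, which stay
#' finite while fewer than a quarter of draws are degenerate.
#'
#' @param modules module assignment (named integer vector peak -> module,
#'   as from [clusterModules()]`$assignment`), or `NULL` for whole-metabolome
#'   ratios only.
#' @param x a [PeakExperiment-class].
#' @param meta sample metadata.
#' @param config an [evolutionConfig()] (`n_module_subsamples`,
#'   `subsample_n`, `seed`).
#' @return a list: `ratios` (`data.frame`: category, subsample, ratio,
#'   n_human, n_chimp) and `summary` (`data.frame`: category, median, q1,
#'   q3, prop_degenerate).
#' @export
moduleSpecificityRatio <- function(modules, x, meta = sampleData(x),
                                   config = evolutionConfig()) {
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% colnames(meta)) meta$sample_id <- rownames(meta)
  idx <- match(colnames(x), meta$sample_id)
  mcAssert(!anyNA(idx), "linkageError", "samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  use <- .evoSamples(meta, config)
  sp_all <- meta$species[use]
  by_sp <- split(use, sp_all)
  mcAssert(all(c("human", "chimpanzee", "macaque") %in% names(by_sp)),
           "argumentError", "all three species must be present")
  short <- vapply(by_sp, length, 1L) < config$subsample_n
  mcAssert(!any(short), "argumentError",
           sprintf("subsample_n = %d exceeds the sample count of: %s",
                   config$subsample_n,
                   paste(names(by_sp)[short], collapse = ", ")))
  L <- if (isLog2(x)) intensities(x) else log2Matrix(intensities(x))
  cats <- list(whole_metabolome = rownames(L))
  if (!is.null(modules)) {
    cats$all_modules <- names(modules)
    for (m in sort(unique(modules)))
      cats[[paste0("module_", m)]] <- names(modules)[modules == m]
  }
  set.seed(config$seed)
  rows <- vector("list", config$n_module_subsamples)
  for (b in seq_len(config$n_module_subsamples)) {
    cols <- unlist(lapply(by_sp, sample, size = config$subsample_n),
                   use.names = FALSE)
    rc <- .relaxedCalls(L[, cols, drop = FALSE], meta$species[cols])
    call <- setNames(rc$call, rownames(L))
    rows[[b]] <- do.call(rbind, lapply(names(cats), function(cn) {
      h <- sum(call[cats[[cn]]] == "human_specific")
      cc <- sum(call[cats[[cn]]] == "chimp_specific")
      data.frame(category = cn, subsample = b,
                 ratio = if (cc == 0) Inf else h / cc,
                 n_human = h, n_chimp = cc, stringsAsFactors = FALSE)
    }))
  }
  ratios <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(cats), function(cn) {
    r <- ratios$ratio[ratios$category == cn]
    data.frame(category = cn, median = median(r),
               q1 = quantile(r, 0.25, names = FALSE),
               q3 = quantile(r, 0.75, names = FALSE),
               prop_degenerate = mean(!is.finite(r)),
               stringsAsFactors = FALSE)
  }))
  list(ratios = ratios, summary = summ)
}

#' Fold-change concordance with an external dataset
#'
#' Matches peaks by id, computes the Pearson correlation of log2 fold
#' changes, the 2x2 sign-quadrant table, and a one-sided Fisher exact test
#' on that table.
#'
#' @param fc_self,fc_published named numeric vectors (peak -> log2 fold
#'   change); at least 3 shared names required.
#' @return a list: `r`, `n`, `table`, `p`.
#' @export
datasetConcordance <- function(fc_self, fc_published) {
  shared <- intersect(names(fc_self), names(fc_published))
  mcAssert(length(shared) >= 3, "testError",
           "need at least 3 matched peaks")
  a <- fc_self[shared]; b <- fc_published[shared]
  nz <- a != 0 & b != 0
  if (any(!nz)) warning("zero fold changes dropped from the quadrant table")
  tab <- matrix(c(sum(a > 0 & b > 0), sum(a > 0 & b < 0),
                  sum(a < 0 & b > 0), sum(a < 0 & b < 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(self = c("up", "down"),
                                published = c("up", "down")))
  list(r = cor(a, b), n = length(shared), table = tab,
       p = fisher.test(tab, alternative = "greater")$p.value)
}

#' @importFrom stats median
NULL
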