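## Three-species fixture with controllable per-species mean shifts
## (log2 scale); humans are controls.
threeSpeciesTable <- function(n_peaks, shift_h = numeric(n_peaks),
                              shift_c = numeric(n_peaks), n_per = 30,
                              seed = 1, noise_sd = 1) {
  set.seed(seed)
  sp <- rep(c("human", "chimpanzee", "macaque"), each = n_per)
  ids <- sprintf("%s%02d", rep(c("H", "C", "M"), each = n_per), 1:n_per)
  age <- c(runif(n_per, 0, 60), runif(n_per, 0, 40), runif(n_per, 0, 20))
  L <- matrix(rnorm(n_peaks * length(ids), 20, noise_sd), n_peaks,
              dimnames = list(sprintf("pk%03d", seq_len(n_peaks)), ids))
  L <- L + outer(shift_h, as.numeric(sp == "human")) +
    outer(shift_c, as.numeric(sp == "chimpanzee"))
  meta <- data.frame(sample_id = ids, species = sp,
                     group = ifelse(sp == "human", "control", NA),
                     age = age, injection_order = seq_along(ids),
                     stringsAsFactors = FALSE)
  PeakExperiment(L, mz = runif(n_peaks, 100, 900), mode = "positive",
                 sampleData = meta, log2 = TRUE)
}

test_that("age scaling multiplies nonhuman ages and preserves sign", {
  meta <- data.frame(species = c("human", "chimpanzee", "macaque"),
                     age = c(10, 10, -0.10))
  cfg <- evolutionConfig(age_scale = c(human = 1, chimpanzee = 1.5,
                                       macaque = 3))
  out <- scaleAges(meta, cfg)
  expect_equal(out$age_scaled, c(10, 15, -0.30))
  id <- scaleAges(meta, evolutionConfig(age_scale = c(human = 1,
                                                      chimpanzee = 1,
                                                      macaque = 1)))
  expect_equal(id$age_scaled, meta$age)
  expect_error(scaleAges(meta, evolutionConfig(age_scale = c(human = 1))),
               class = "configError")
})

test_that("relaxed calls follow the z-distance and sign-concordance rule", {
  ## engineered species shifts mirroring means (1.0, 0.2, -0.6) around the
  ## macaque baseline -> human-specific, and its mirror -> chimp-specific
  pe <- threeSpeciesTable(2, seed = 2, noise_sd = 0.05,
                          shift_h = c(1.6, 0.8),
                          shift_c = c(0.8, 1.6))
  rel <- relaxedLineageCalls(pe)
  expect_equal(rel$relaxed, c("human_specific", "chimp_specific"))
  expect_gt(rel$m_human[1], rel$m_chimp[1])
  ## equal species means: zero distances, no call
  pe0 <- threeSpeciesTable(1, seed = 2, noise_sd = 0.05)
  m <- intensities(pe0); m[1, ] <- 20    # constant peak -> degenerate
  pe0 <- PeakExperiment(m, mz = peakMz(pe0), mode = "positive",
                        sampleData = sampleData(pe0), log2 = TRUE)
  expect_warning(rel0 <- relaxedLineageCalls(pe0), "zero-variance")
  expect_equal(rel0$relaxed, "none")
})

test_that("relaxed calls are invariant to affine transforms of a peak", {
  pe <- threeSpeciesTable(20, seed = 3,
                          shift_h = c(rep(2, 8), rep(0, 12)),
                          shift_c = c(rep(0.4, 8), rep(0, 12)))
  base <- relaxedLineageCalls(pe)
  m <- intensities(pe)
  m[5, ] <- 3 * m[5, ] - 17              # affine transform of one peak
  m[12, ] <- -0.5 * m[12, ] + 40         # including a reflection
  pe2 <- PeakExperiment(m, mz = peakMz(pe), mode = "positive",
                        sampleData = sampleData(pe), log2 = TRUE)
  rel2 <- relaxedLineageCalls(pe2)
  expect_identical(base$relaxed[5], rel2$relaxed[5])
  ## a reflection flips the deviation signs but the winner side is unchanged
  expect_identical(rel2$relaxed[12], base$relaxed[12])
})

test_that("swapping human and chimpanzee labels swaps the calls exactly", {
  pe <- threeSpeciesTable(60, seed = 4,
                          shift_h = rep(c(2, 0.4, 0), c(15, 10, 35)),
                          shift_c = rep(c(0.4, 2, 0), c(15, 10, 35)))
  meta <- sampleData(pe)
  swapped <- meta
  swapped$species[meta$species == "human"] <- "chimpanzee"
  swapped$species[meta$species == "chimpanzee"] <- "human"
  swapped$group <- ifelse(swapped$species == "human", "control", NA)
  base <- relaxedLineageCalls(pe, meta)
  swp <- relaxedLineageCalls(pe, swapped)
  flip <- c(human_specific = "chimp_specific",
            chimp_specific = "human_specific", none = "none")
  expect_identical(swp$relaxed, unname(flip[base$relaxed]))
})

test_that("stringent calls place strong shifts on the correct lineage", {
  ## pure one-lineage shifts: the sister lineage stays at the macaque level
  nh <- 15; nc <- 10; n0 <- 75
  pe <- threeSpeciesTable(nh + nc + n0, seed = 5,
                          shift_h = c(rep(2.5, nh), rep(0, nc), rep(0, n0)),
                          shift_c = c(rep(0, nh), rep(2.5, nc), rep(0, n0)))
  st <- stringentLineageCalls(pe)
  expect_gte(mean(st$stringent[1:nh] == "human_specific"), 0.8)
  expect_gte(mean(st$stringent[nh + 1:nc] == "chimp_specific"), 0.8)
  ## nulls essentially never called
  expect_lte(sum(st$stringent[nh + nc + 1:n0] != "none"), 2)
  expect_error(stringentLineageCalls(pe[, 1:50]), class = "argumentError")
})

test_that("stringent and relaxed criteria agree on strongly shifted peaks", {
  ## 2.5 SD human shifts with a small (0.4 SD) same-direction chimpanzee
  ## shift: large enough to fix the relaxed sign, small enough that the
  ## chimpanzee/macaque ANCOVA stays below the BH threshold when such
  ## peaks are rare; agreement pooled over three replicate tables
  agree <- logical(0)
  for (s in 1:3) {
    nh <- 10; n0 <- 290
    pe <- threeSpeciesTable(nh + n0, seed = 50 + s, n_per = 40,
                            shift_h = c(rep(2.5, nh), rep(0, n0)),
                            shift_c = c(rep(0.4, nh), rep(0, n0)))
    st <- stringentLineageCalls(pe)
    rel <- relaxedLineageCalls(pe)
    agree <- c(agree, (st$stringent[1:nh] == "human_specific") ==
                 (rel$relaxed[1:nh] == "human_specific"))
  }
  expect_gte(mean(agree), 0.9)
})

test_that("module specificity ratios summarize subsampled relaxed calls", {
  ## a lineage-balanced module: equal human and chimp shifts
  nh <- 20; nc <- 20; n0 <- 60
  pe <- threeSpeciesTable(nh + nc + n0, seed = 7, n_per = 35,
                          shift_h = c(rep(2, nh), rep(0.4, nc), rep(0, n0)),
                          shift_c = c(rep(0.4, nh), rep(2, nc), rep(0, n0)))
  modules <- setNames(rep(1L, nh + nc), rownames(pe)[seq_len(nh + nc)])
  cfg <- evolutionConfig(n_module_subsamples = 300, subsample_n = 30,
                         seed = 11)
  out <- moduleSpecificityRatio(modules, pe, config = cfg)
  bal <- out$summary[out$summary$category == "module_1", ]
  expect_gte(bal$median, 0.5)
  expect_lte(bal$median, 2)

  ## a module carrying only human-specific shifts: zero chimp calls show up
  ## as +Inf ratios, counted but not breaking the quartile summary
  modH <- setNames(rep(1L, nh), rownames(pe)[seq_len(nh)])
  outH <- moduleSpecificityRatio(modH, pe, config = cfg)
  mh <- outH$summary[outH$summary$category == "module_1", ]
  expect_gte(mh$median, 5)
  expect_true(is.finite(mh$q1) || mh$prop_degenerate >= 0.25)

  expect_error(
    moduleSpecificityRatio(modules, pe,
                           config = evolutionConfig(subsample_n = 200)),
    class = "argumentError")
})

test_that("fold-change concordance reports r, quadrants and Fisher p", {
  set.seed(8)
  fc <- setNames(rnorm(31), sprintf("pk%02d", 1:31))
  same <- datasetConcordance(fc, fc)
  expect_equal(same$r, 1)
  expect_equal(same$table[1, 2] + same$table[2, 1], 0)
  expect_equal(datasetConcordance(fc, -fc)$r, -1)

  ## seeded bivariate-normal pair at rho = 0.7, n = 31
  rho <- 0.7
  x <- rnorm(31); y <- rho * x + sqrt(1 - rho^2) * rnorm(31)
  names(x) <- names(y) <- sprintf("m%02d", 1:31)
  bv <- datasetConcordance(x, y)
  expect_lt(abs(bv$r - rho), 0.25)
  expect_lt(bv$p, 0.05)
  expect_error(datasetConcordance(fc[1:2], fc[1:2]), class = "testError")
})
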