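test_that("degree selection prefers the smallest adequate polynomial", {
  set.seed(1)
  age <- runif(40, 0, 60)
  ## exactly quadratic, zero noise: adjusted R2 = 1 for d >= 2, tie -> 2
  y <- 3 + 0.1 * age - 0.01 * age^2
  expect_identical(as.integer(selectPolyDegree(age, y, 3)), 2L)
  ## exactly linear -> 1
  expect_identical(as.integer(selectPolyDegree(age, 2 - 0.3 * age, 3)), 1L)
  ## n = 3 observations cap the degree at 1, with a warning
  expect_warning(d <- selectPolyDegree(c(1, 5, 9), c(2, 3, 9), 3), "capped")
  expect_lte(as.integer(d), 1L)
  expect_error(selectPolyDegree(rep(4, 10), rnorm(10), 3),
               class = "argumentError")
})

test_that("degree selection matches lm-computed adjusted R2 exactly", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(20:80, 1)
    age <- runif(n, 0, 60)
    a <- (age - mean(age)) / sd(age)
    y <- rnorm(n) + sample(c(0, 0.3), 1) * a + sample(c(0, 0.3), 1) * a^2
    adj <- c(0, vapply(1:3, function(d)
      summary(lm(y ~ poly(a, d, raw = TRUE)))$adj.r.squared, numeric(1)))
    expect_identical(as.integer(selectPolyDegree(age, y, 3)),
                     which.max(adj) - 1L)
  }
})

test_that("adjusted R2 shifts degree choice heavily toward parsimony under noise", {
  ## the unpenalized criterion would select the maximum degree every time;
  ## adjusted R2 accepts a spurious term with probability ~ P(F > 1) ~ 1/3,
  ## making degree 0 the modal choice on pure noise
  degs <- integer(200)
  for (s in 1:200) {
    set.seed(s)
    age <- runif(72, 0, 60)
    degs[s] <- as.integer(selectPolyDegree(age, 5 + rnorm(72), 3))
  }
  tab <- tabulate(degs + 1L, 4)
  expect_identical(which.max(tab), 1L)   # degree 0 modal
  expect_gt(tab[1] / 200, 0.35)
  expect_lt(tab[4] / 200, 0.35)          # max degree chosen in a minority
})

test_that("group ANCOVA recovers a known offset and is null on identical groups", {
  set.seed(2)
  n <- 72
  age <- runif(n, 1, 60)
  grp <- rep(c("control", "ASD"), each = 36)
  ## byte-identical groups: zero group coefficient, F ~ 0, p ~ 1
  y0 <- rep(1 + 0.2 * age[1:36] + rnorm(36, 0, 0.5), 2)
  r0 <- groupAncova(y0, rep(age[1:36], 2), grp, "control")
  expect_lt(abs(r0$coef_group), 1e-10)
  expect_lt(r0$F, 1e-10)
  expect_gt(r0$p, 0.999)

  ## planted additive offset of 2: p tiny, offset recovered
  y <- 1 + 0.5 * age + 2 * (grp == "ASD") + rnorm(n, 0, 0.1)
  r <- groupAncova(y, age, grp, "control")
  expect_lt(r$p, 1e-10)
  expect_lt(abs(r$coef_group - 2), 0.1)
  ## direct least-squares oracle for the offset at the selected degree
  a <- (age - mean(age)) / sd(age)
  X <- cbind(1, outer(a, seq_len(r$degree), `^`), grp == "ASD")
  expect_equal(r$coef_group, unname(qr.solve(X, y)[ncol(X)]),
               tolerance = 1e-10)

  expect_error(groupAncova(y, age, rep("control", n), "control"),
               class = "argumentError")
})

test_that("permuting group labels yields a uniform p-value distribution", {
  set.seed(3)
  n <- 72
  age <- runif(n, 1, 60)
  y <- 1 + 0.5 * age + 2 * rep(c(0, 1), each = 36) + rnorm(n, 0, 0.1)
  hits <- 0L
  for (b in 1:500) {
    grp <- sample(rep(c("control", "ASD"), each = 36))
    hits <- hits + (groupAncova(y, age, grp, "control")$p < 0.05)
  }
  expect_lt(abs(hits / 500 - 0.05), 0.03)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(0.037), 0.037)
  for (s in 1:1000) {
    set.seed(s)
    p <- switch(1 + s %% 3,
                runif(sample(1:40, 1)),
                round(runif(20), 2),             # heavy ties
                rbeta(30, 0.3, 1))
    expect_equal(bhAdjust(p), bhBrute(p), tolerance = 1e-12)
  }
  expect_warning(q <- bhAdjust(c(0.1, NaN, 0.5)), "non-finite")
  expect_true(is.na(q[2]))
})

test_that("callAsdMetabolites recovers planted group effects with controlled FDR", {
  fx <- twoGroupTable(n_peaks = 300, offsets = c(rep(1, 30), rep(0, 270)),
                      seed = 11)
  res <- callAsdMetabolites(fx$table)
  truth <- sprintf("pk%03d", 1:30)
  sens <- mean(truth %in% res$peak_id[res$significant])
  called <- res$peak_id[res$significant]
  expect_gte(sens, 0.8)
  expect_lte(mean(!called %in% truth), 0.1)
  ## signs follow the planted direction
  up <- res$effect_sign[match(truth, res$peak_id)]
  expect_true(mean(up == "up_in_ASD") > 0.9)
  ## significance flag is exactly the two-sided q rule
  expect_identical(res$significant,
                   pmax(res$q_ref_control, res$q_ref_asd) <= 0.05)

  ## a pure-null table yields no significant calls
  fx0 <- twoGroupTable(n_peaks = 150, seed = 12)
  res0 <- callAsdMetabolites(fx0$table)
  expect_equal(sum(res0$significant), 0L)
})

test_that("differential results are invariant to peak and sample ordering", {
  fx <- twoGroupTable(n_peaks = 60, offsets = c(rep(1.2, 10), rep(0, 50)),
                      n_control = 20, n_asd = 20, seed = 13)
  res <- callAsdMetabolites(fx$table)
  pp <- sample(nrow(fx$table)); sp <- sample(ncol(fx$table))
  res2 <- callAsdMetabolites(fx$table[pp, sp])
  res2 <- res2[match(res$peak_id, res2$peak_id), ]
  expect_equal(res$p_ref_control, res2$p_ref_control, tolerance = 1e-9)
  expect_identical(res$significant, res2$significant)
})

test_that("module clustering separates anticorrelated archetypes and is deterministic", {
  set.seed(4)
  n <- 50
  age <- runif(n, 0, 60)
  profile <- scale(sin(age / 20))[, 1]
  L <- rbind(t(replicate(10, 20 + profile + rnorm(n, 0, 0.05))),
             t(replicate(10, 20 - profile + rnorm(n, 0, 0.05))))
  dimnames(L) <- list(sprintf("pk%02d", 1:20), sprintf("s%02d", 1:n))
  meta <- data.frame(sample_id = colnames(L), species = "human",
                     group = rep(c("control", "ASD"), length.out = n),
                     age = age, injection_order = 1:n,
                     stringsAsFactors = FALSE)
  pe <- PeakExperiment(L, mz = runif(20, 100, 900), mode = "positive",
                       sampleData = meta, log2 = TRUE)
  res <- data.frame(peak_id = rownames(L), significant = TRUE)
  mod <- clusterModules(pe, res, config = differentialConfig(n_modules = 2))
  split1 <- mod$assignment[sprintf("pk%02d", 1:10)]
  split2 <- mod$assignment[sprintf("pk%02d", 11:20)]
  expect_equal(length(unique(split1)), 1L)
  expect_equal(length(unique(split2)), 1L)
  expect_false(unique(split1) == unique(split2))

  ## permuting peak input order leaves the partition unchanged
  mod2 <- clusterModules(pe[sample(20), ], res,
                         config = differentialConfig(n_modules = 2))
  expect_equal(ari(mod$assignment[names(mod2$assignment)], mod2$assignment), 1)
})

test_that("module clustering recovers the four planted archetypes", {
  coh <- generateCohort(cohortConfig(seed = 31, n_peaks = 250,
                                     fraction_drifted = 0,
                                     fraction_pmd_sensitive = 0))
  merged <- mergeModes(coh$pos, coh$neg)
  res <- callAsdMetabolites(merged)
  mod <- clusterModules(merged, res)
  truemod <- coh$truth$module[match(names(mod$assignment),
                                    coh$truth$peak_id)]
  keep <- !is.na(truemod)
  expect_gte(ari(mod$assignment[keep], truemod[keep]), 0.8)
  expect_equal(length(unique(mod$assignment)), 4L)
  expect_true(all(c("module", "group", "age", "mean") %in%
                    colnames(mod$trajectories)))
})
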