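## Synthetic cohort generator: peak tables, metadata, compound/pathway
## fixtures and ground-truth labels emulating the statistical structure of a
## cross-species brain LC-MS study, so every pipeline stage is testable
## without measured data.

## Monoisotopic atomic masses (Da) for the formula arithmetic used by the
## built-in compound library.
.ATOMIC_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                  O = 15.9949146221, P = 30.97376151, S = 31.97207069,
                  Na = 22.98976928, K = 38.9637064864, Cl = 34.96885268)

#' Monoisotopic mass of a molecular formula
#'
#' @param formula e.g. `"C6H12O6"`; supported elements: C, H, N, O, P, S,
#'   Na, K, Cl.
#' @return monoisotopic mass in Da.
#' @examples
#' formulaMass("C6H12O6")  # glucose, 180.063388
#' @export
formulaMass <- function(formula) {
  vapply(formula, function(f) {
    m <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    mcAssert(sum(nchar(m)) == nchar(f), "argumentError",
             paste0("cannot parse formula: ", f))
    tot <- 0
    for (tok in m) {
      el <- gsub("[0-9]", "", tok)
      n <- gsub("[^0-9]", "", tok)
      mcAssert(el %in% names(.ATOMIC_MASS), "argumentError",
               paste0("unsupported element '", el, "' in ", f))
      tot <- tot + .ATOMIC_MASS[[el]] * if (nchar(n)) as.integer(n) else 1L
    }
    tot
  }, numeric(1), USE.NAMES = FALSE)
}

## Built-in compound library: a small HMDB-style table spanning glutathione,
## purine, pyrimidine, TCA and amino-acid chemistry plus assorted polar
## metabolites. Masses derive from the formulas at load time.
.compoundLibrary <- function() {
  def <- rbind(
    c("glutathione", "C10H17N3O6S", "glutathione"),
    c("glutathione disulfide", "C20H32N6O12S2", "glutathione"),
    c("5-oxoproline", "C5H7NO3", "glutathione"),
    c("L-gamma-glutamylcysteine", "C8H14N2O5S", "glutathione"),
    c("L-cysteinylglycine", "C5H10N2O3S", "glutathione"),
    c("L-cysteine", "C3H7NO2S", "glutathione"),
    c("glycine", "C2H5NO2", "glutathione"),
    c("L-glutamate", "C5H9NO4", "glutathione"),
    c("adenine", "C5H5N5", "purine"),
    c("adenosine", "C10H13N5O4", "purine"),
    c("AMP", "C10H14N5O7P", "purine"),
    c("ADP", "C10H15N5O10P2", "purine"),
    c("ATP", "C10H16N5O13P3", "purine"),
    c("guanine", "C5H5N5O", "purine"),
    c("guanosine", "C10H13N5O5", "purine"),
    c("hypoxanthine", "C5H4N4O", "purine"),
    c("inosine", "C10H12N4O5", "purine"),
    c("xanthine", "C5H4N4O2", "purine"),
    c("urate", "C5H4N4O3", "purine"),
    c("uracil", "C4H4N2O2", "pyrimidine"),
    c("uridine", "C9H12N2O6", "pyrimidine"),
    c("cytosine", "C4H5N3O", "pyrimidine"),
    c("cytidine", "C9H13N3O5", "pyrimidine"),
    c("thymine", "C5H6N2O2", "pyrimidine"),
    c("dihydrouracil", "C4H6N2O2", "pyrimidine"),
    c("beta-alanine", "C3H7NO2", "pyrimidine"),
    c("citrate", "C6H8O7", "tca"),
    c("succinate", "C4H6O4", "tca"),
    c("fumarate", "C4H4O4", "tca"),
    c("malate", "C4H6O5", "tca"),
    c("alpha-ketoglutarate", "C5H6O5", "tca"),
    c("pyruvate", "C3H4O3", "tca"),
    c("lactate", "C3H6O3", "tca"),
    c("L-alanine", "C3H7NO2", "amino_acid"),
    c("L-serine", "C3H7NO3", "amino_acid"),
    c("L-threonine", "C4H9NO3", "amino_acid"),
    c("L-valine", "C5H11NO2", "amino_acid"),
    c("L-leucine", "C6H13NO2", "amino_acid"),
    c("L-proline", "C5H9NO2", "amino_acid"),
    c("L-phenylalanine", "C9H11NO2", "amino_acid"),
    c("L-tyrosine", "C9H11NO3", "amino_acid"),
    c("L-tryptophan", "C11H12N2O2", "amino_acid"),
    c("L-methionine", "C5H11NO2S", "amino_acid"),
    c("L-lysine", "C6H14N2O2", "amino_acid"),
    c("L-arginine", "C6H14N4O2", "amino_acid"),
    c("L-histidine", "C6H9N3O2", "amino_acid"),
    c("L-aspartate", "C4H7NO4", "amino_acid"),
    c("L-asparagine", "C4H8N2O3", "amino_acid"),
    c("L-glutamine", "C5H10N2O3", "amino_acid"),
    c("glucose", "C6H12O6", "other"),
    c("myo-inositol", "C6H12O6", "other"),
    c("sucrose", "C12H22O11", "other"),
    c("taurine", "C2H7NO3S", "other"),
    c("creatine", "C4H9N3O2", "other"),
    c("creatinine", "C4H7N3O", "other"),
    c("carnitine", "C7H15NO3", "other"),
    c("acetylcarnitine", "C9H17NO4", "other"),
    c("choline", "C5H13NO", "other"),
    c("nicotinamide", "C6H6N2O", "other"),
    c("GABA", "C4H9NO2", "other"),
    c("dopamine", "C8H11NO2", "other"),
    c("serotonin", "C10H12N2O", "other"))
  data.frame(compound_id = sprintf("cpd%03d", seq_len(nrow(def))),
             name = def[, 1], formula = def[, 2],
             monoisotopic_mass = formulaMass(def[, 2]),
             source = "synthetic", class = def[, 3],
             stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the study design the generator emulates: 40 human
#' controls (ages 0-61 y), 32 ASD cases (2-60 y), 40 chimpanzees (0-42 y)
#' and 40 short-PMD macaques (14 weeks post-conception, i.e. -0.27 y, to
#' 21 y) plus 2 extra prolonged-PMD (5-6 h) macaque probe animals; 500
#' peaks; 10% ASD-affected with 1 pooled-SD offsets shaped by four module
#' archetypes; 10% drifting 2 SD across the injection run; 4% PMD-sensitive
#' (10 SD probe shift); human:chimpanzee lineage-shift fractions 3:1
#' (0.45/0.15) with 2 SD shifts. See the methods vignette for the rationale
#' behind each default.
#'
#' @param seed RNG seed (mandatory).
#' @param n_control,n_asd,n_chimp,n_macaque cohort sizes.
#' @param n_pmd_probes extra prolonged-PMD macaque samples (default 2).
#' @param n_peaks total peak count across both ionization modes.
#' @param frac_positive_mode fraction of peaks in positive mode.
#' @param age_range_control,age_range_asd,age_range_chimp,age_range_macaque
#'   uniform age ranges (years; negative = prenatal).
#' @param fraction_asd_affected fraction of peaks with an ASD group effect.
#' @param effect_size_sd ASD group offset, in units of the residual log2 SD.
#' @param archetype_amplitude SD of the shared module age trajectory.
#' @param trajectory_sd scale of the smooth random age trend of null peaks.
#' @param fraction_drifted,drift_amplitude fraction of peaks with a linear
#'   injection-order drift and its full span (SD units).
#' @param fraction_pmd_sensitive,pmd_shift_sd fraction of PMD-sensitive
#'   peaks and their probe-sample shift (SD units).
#' @param lineage_fraction_human,lineage_fraction_chimp fractions of peaks
#'   with human- / chimpanzee-specific mean shifts.
#' @param lineage_shift_sd lineage shift magnitude (SD units).
#' @param lineage_partial_fraction same-direction fractional shift of the
#'   sister lineage (default 0.2), modelling gradual shared change with
#'   lineage-specific acceleration.
#' @param fraction_annotated fraction of peaks placed at a library
#'   compound's adduct m/z (within a few ppm).
#' @param noise_sd residual log2 SD.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-peak
#'   baseline log2 abundances.
#' @param age_scale species -> human-equivalent-age factors (see
#'   [evolutionConfig()]).
#' @return a list of class `CohortConfig`.
#' @export
cohortConfig <- function(seed,
                         n_control = 40, n_asd = 32, n_chimp = 40,
                         n_macaque = 40, n_pmd_probes = 2,
                         n_peaks = 500, frac_positive_mode = 0.6,
                         age_range_control = c(0, 61),
                         age_range_asd = c(2, 60),
                         age_range_chimp = c(0, 42),
                         age_range_macaque = c(-0.27, 21),
                         fraction_asd_affected = 0.10,
                         effect_size_sd = 1.0,
                         archetype_amplitude = 1.5,
                         trajectory_sd = 0.8,
                         fraction_drifted = 0.10,
                         drift_amplitude = 2.0,
                         fraction_pmd_sensitive = 0.04,
                         pmd_shift_sd = 10,
                         lineage_fraction_human = 0.45,
                         lineage_fraction_chimp = 0.15,
                         lineage_shift_sd = 2.0,
                         lineage_partial_fraction = 0.2,
                         fraction_annotated = 0.7,
                         noise_sd = 1.0,
                         baseline_log2_mean = 20,
                         baseline_log2_sd = 2,
                         age_scale = c(human = 1, chimpanzee = 61 / 42,
                                       macaque = 61 / 21)) {
  mcAssert(!missing(seed), "configError", "seed is mandatory")
  fr <- c(fraction_asd_affected, fraction_drifted, fraction_pmd_sensitive,
          lineage_fraction_human, lineage_fraction_chimp)
  mcAssert(all(fr >= 0 & fr <= 1), "configError", "fractions must be in [0,1]")
  mcAssert(sum(round(fr * n_peaks)) <= n_peaks, "configError",
           "peak-category fractions exceed the peak count")
  mcAssert(all(c(n_control, n_asd, n_chimp, n_macaque, n_peaks) > 0),
           "configError", "all counts must be positive")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "CohortConfig")
}

## Module archetypes: shared temporal profiles of the four ASD modules.
## The four shapes are tetrahedral-simplex combinations of the first three
## Legendre polynomials in scaled age (standardized over a uniform human
## age grid), giving smooth distinct trajectories with pairwise correlation
## exactly -1/3 - mutually separable by correlation-distance clustering.
.archetypeBasis <- function(age_h) {
  leg3 <- function(a) {
    s <- a / 30.5 - 1
    cbind(s, (3 * s^2 - 1) / 2, (5 * s^3 - 3 * s) / 2)
  }
  g <- seq(0, 61, length.out = 400)     # standardization reference grid
  Fg <- leg3(g)
  ctr <- colMeans(Fg)
  scl <- apply(Fg, 2L, sd)
  std <- function(Fm) sweep(sweep(Fm, 2L, ctr), 2L, scl, "/")
  V <- matrix(c(1, 1, 1,  1, -1, -1,  -1, 1, -1,  -1, -1, 1) / sqrt(3),
              nrow = 3)                 # tetrahedron vertices, unit columns
  Ag <- std(Fg) %*% V
  arch <- std(leg3(age_h)) %*% V
  sweep(sweep(arch, 2L, colMeans(Ag)), 2L, apply(Ag, 2L, sd), "/")
}

.moduleSign <- c(1, 1, -1, -1)

## ASD-offset modulation: module 3's offset is larger early in life (linear
## 1.5 -> 0.5 decline across the human age range, mean ~1), the others are
## constant; the mean-1 normalization keeps the average offset at
## effect_size_sd for every module.
.moduleWeight <- function(module, age_h) {
  if (module == 3) {
    w <- 1.5 - age_h / 60
    g <- seq(2, 60, length.out = 200)
    w / mean(1.5 - g / 60)
  } else rep(1, length(age_h))
}

#' Generate a synthetic cross-species cohort with ground truth
#'
#' Draws ages uniformly per cohort, builds per-peak log2 signals (baseline +
#' smooth age trend + planted ASD, lineage, injection-order-drift and
#' PMD effects + Gaussian residuals), exponentiates to linear scale and
#' splits the peaks into positive- and negative-mode tables. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [cohortConfig()].
#' @return a list: `pos` and `neg` ([PeakExperiment-class] per mode), `meta`
#'   (sample metadata `data.frame`), `truth` (per-peak `data.frame` with
#'   columns `peak_id` (mode-prefixed id as produced by [mergeModes()]),
#'   `mode`, `asd_affected`, `module`, `effect_sign`, `drifted`,
#'   `pmd_sensitive`, `lineage`, `compound_id`, `adduct`).
#' @export
generateCohort <- function(config) {
  mcAssert(inherits(config, "CohortConfig"), "configError",
           "config must come from cohortConfig()")
  set.seed(config$seed)
  ## ---- samples -----------------------------------------------------------
  n_h <- config$n_control + config$n_asd
  ids <- c(sprintf("HC%02d", seq_len(config$n_control)),
           sprintf("HA%02d", seq_len(config$n_asd)),
           sprintf("CH%02d", seq_len(config$n_chimp)),
           sprintf("MA%02d", seq_len(config$n_macaque)),
           if (config$n_pmd_probes > 0)
             sprintf("MP%02d", seq_len(config$n_pmd_probes)))
  species <- c(rep("human", n_h), rep("chimpanzee", config$n_chimp),
               rep("macaque", config$n_macaque + config$n_pmd_probes))
  group <- c(rep("control", config$n_control), rep("ASD", config$n_asd),
             rep(NA_character_, length(ids) - n_h))
  r <- function(n, rng) runif(n, rng[1], rng[2])
  mac_rng <- config$age_range_macaque
  probe_age <- mac_rng[1] + c(0.3, 0.7) * diff(mac_rng)
  age <- c(r(config$n_control, config$age_range_control),
           r(config$n_asd, config$age_range_asd),
           r(config$n_chimp, config$age_range_chimp),
           r(config$n_macaque, mac_rng),
           if (config$n_pmd_probes > 0)
             rep_len(probe_age, config$n_pmd_probes))
  pmd <- c(runif(n_h, 5, 30), runif(config$n_chimp, 1, 20),
           runif(config$n_macaque, 2 / 60, 19 / 60),
           if (config$n_pmd_probes > 0) runif(config$n_pmd_probes, 5, 6))
  n_s <- length(ids)
  meta <- data.frame(sample_id = ids, species = species, group = group,
                     age = age, sex = sample(c("M", "F"), n_s, TRUE),
                     pmd_hours = pmd, rin = round(runif(n_s, 6, 9.5), 1),
                     injection_order = sample(n_s),
                     stringsAsFactors = FALSE)
  meta$batch <- paste0("b", ceiling(meta$injection_order / 48))
  age_h <- age * unname(config$age_scale[species])  # human-equivalent years
  is_asd <- !is.na(group) & group == "ASD"
  ## ---- peak categories ---------------------------------------------------
  np <- config$n_peaks
  n_pos <- round(config$frac_positive_mode * np)
  mode <- rep(c("positive", "negative"), c(n_pos, np - n_pos))
  raw_id <- c(sprintf("P%04d", seq_len(n_pos)),
              sprintf("N%04d", seq_len(np - n_pos)))
  peak_id <- paste0(ifelse(mode == "positive", "pos:", "neg:"), raw_id)
  counts <- round(np * c(config$fraction_asd_affected,
                         config$fraction_drifted,
                         config$fraction_pmd_sensitive,
                         config$lineage_fraction_human,
                         config$lineage_fraction_chimp))
  perm <- sample(np)
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- perm[seq_len(k)]
    perm <<- perm[-seq_len(k)]
    out
  }
  asd_peaks <- take(counts[1])
  drift_peaks <- take(counts[2])
  pmd_peaks <- take(counts[3])
  lin_h <- take(counts[4])
  lin_c <- take(counts[5])
  module <- rep(NA_integer_, np)
  module[asd_peaks] <- rep_len(1:4, length(asd_peaks))
  lineage <- rep("none", np)
  lineage[lin_h] <- "human"
  lineage[lin_c] <- "chimp"
  ## ---- signal assembly (log2 scale) --------------------------------------
  base_mu <- rnorm(np, config$baseline_log2_mean, config$baseline_log2_sd)
  s <- age_h / 30.5 - 1                       # scaled age in ~[-1, 1]
  leg <- cbind(s, (3 * s^2 - 1) / 2, (5 * s^3 - 3 * s) / 2)
  coefs <- cbind(rnorm(np, 0, config$trajectory_sd),
                 rnorm(np, 0, config$trajectory_sd * 0.5),
                 rnorm(np, 0, config$trajectory_sd * 0.25))
  arch <- .archetypeBasis(age_h)              # samples x 4
  L <- matrix(rnorm(np * n_s, 0, config$noise_sd), np, n_s,
              dimnames = list(raw_id, ids))
  L <- L + base_mu
  traj <- coefs %*% t(leg)                    # peaks x samples
  has_mod <- !is.na(module)
  traj[has_mod, ] <- config$archetype_amplitude *
    t(arch[, module[has_mod], drop = FALSE])
  L <- L + traj
  effect_sign <- rep(NA_character_, np)
  for (i in asd_peaks) {
    m <- module[i]
    off <- .moduleSign[m] * config$effect_size_sd *
      .moduleWeight(m, age_h[is_asd])
    L[i, is_asd] <- L[i, is_asd] + off
    effect_sign[i] <- if (.moduleSign[m] > 0) "up_in_ASD" else "down_in_ASD"
  }
  lin_sign <- rep(0, np)
  lin_sign[c(lin_h, lin_c)] <- sample(c(-1, 1), counts[4] + counts[5], TRUE)
  hum <- species == "human"; chi <- species == "chimpanzee"
  for (i in lin_h) {
    d <- lin_sign[i] * config$lineage_shift_sd
    L[i, hum] <- L[i, hum] + d
    L[i, chi] <- L[i, chi] + config$lineage_partial_fraction * d
  }
  for (i in lin_c) {
    d <- lin_sign[i] * config$lineage_shift_sd
    L[i, chi] <- L[i, chi] + d
    L[i, hum] <- L[i, hum] + config$lineage_partial_fraction * d
  }
  if (length(drift_peaks)) {
    drift <- config$drift_amplitude *
      ((meta$injection_order - 1) / (n_s - 1) - 0.5)
    L[drift_peaks, ] <- L[drift_peaks, , drop = FALSE] +
      matrix(drift, length(drift_peaks), n_s, byrow = TRUE)
  }
  if (length(pmd_peaks) && config$n_pmd_probes > 0) {
    probes <- grepl("^MP", ids)
    L[pmd_peaks, probes] <- L[pmd_peaks, probes, drop = FALSE] +
      config$pmd_shift_sd * config$noise_sd
  }
  ## ---- m/z assignment ----------------------------------------------------
  lib <- .compoundLibrary()
  n_ann <- round(config$fraction_annotated * np)
  annotated <- sort(sample(np, n_ann))
  compound_id <- rep(NA_character_, np)
  adduct <- rep(NA_character_, np)
  mz <- runif(np, 100, 1000)
  ## module-3 peaks draw glutathione-pathway compounds, module-4 purines,
  ## modules 1-2 pyrimidine/amino-acid compounds; unaffected peaks cycle
  ## the classes no affected peak uses, so that the genes linked to
  ## affected and unaffected peaks stay disjoint (the planted pathway and
  ## expression-shift contrasts are then well defined)
  module_class <- c("pyrimidine", "amino_acid", "glutathione", "purine")
  classFor <- function(i) {
    if (is.na(module[i])) return(NA_character_)
    module_class[module[i]]
  }
  used_classes <- if (length(asd_peaks)) unique(module_class[
    module[asd_peaks]]) else character()
  cls_pool <- split(seq_len(nrow(lib)), lib$class)
  cls_pool$free <- which(!lib$class %in% used_classes)
  cursor <- setNames(rep(1L, length(cls_pool)), names(cls_pool))
  nextFrom <- function(pool_name) {
    pool <- cls_pool[[pool_name]]
    j <- pool[(cursor[[pool_name]] - 1L) %% length(pool) + 1L]
    cursor[[pool_name]] <<- cursor[[pool_name]] + 1L
    j
  }
  pos_adducts <- .ADDUCTS$adduct[.ADDUCTS$mode == "positive"]
  neg_adducts <- .ADDUCTS$adduct[.ADDUCTS$mode == "negative"]
  annotated <- sort(union(asd_peaks, annotated))  # affected peaks always get
                                                  # a compound, so enrichment
                                                  # planting is well defined
  for (i in annotated) {
    cl <- classFor(i)
    j <- nextFrom(if (is.na(cl)) "free" else cl)
    ad <- if (mode[i] == "positive")
      pos_adducts[(i %% length(pos_adducts)) + 1L]
    else neg_adducts[(i %% length(neg_adducts)) + 1L]
    compound_id[i] <- lib$compound_id[j]
    adduct[i] <- ad
    mz[i] <- adductMz(lib$monoisotopic_mass[j], ad) *
      (1 + runif(1, -3, 3) * 1e-6)
  }
  ## ---- assemble outputs --------------------------------------------------
  lin_mat <- 2^L
  rt <- runif(np, 0.5, 14)
  truth <- data.frame(peak_id = peak_id, raw_id = raw_id, mode = mode,
                      asd_affected = seq_len(np) %in% asd_peaks,
                      module = module, effect_sign = effect_sign,
                      drifted = seq_len(np) %in% drift_peaks,
                      pmd_sensitive = seq_len(np) %in% pmd_peaks,
                      lineage = lineage, lineage_sign = lin_sign,
                      compound_id = compound_id, adduct = adduct,
                      stringsAsFactors = FALSE)
  pos_rows <- mode == "positive"
  list(pos = PeakExperiment(lin_mat[pos_rows, , drop = FALSE],
                            mz = mz[pos_rows], mode = "positive",
                            rt = rt[pos_rows], sampleData = meta),
       neg = PeakExperiment(lin_mat[!pos_rows, , drop = FALSE],
                            mz = mz[!pos_rows], mode = "negative",
                            rt = rt[!pos_rows], sampleData = meta),
       meta = meta, truth = truth)
}

#' Generate compound, pathway and expression reference tables
#'
#' Produces the built-in compound library, a toy pathway annotation in which
#' each compound class maps to a pathway (so the glutathione-like pathway is
#' enriched by construction whenever module-3 peaks drive a selection), and a
#' gene-level log2 fold-change table in which genes linked to ASD-affected
#' peaks carry inflated fold changes.
#'
#' @param config a [cohortConfig()].
#' @param truth optional `truth` table from [generateCohort()]; when given,
#'   the expression fold changes are inflated for genes linked to the
#'   compounds of ASD-affected peaks.
#' @return a list: `compounds` (compound table usable with
#'   [annotatePeaks()]), `pathway_annotation` (a [pathwayAnnotation()]),
#'   `gene_log2fc` (named numeric vector).
#' @export
generateReferenceTables <- function(config, truth = NULL) {
  mcAssert(inherits(config, "CohortConfig"), "configError",
           "config must come from cohortConfig()")
  lib <- .compoundLibrary()
  gene_pool <- list(
    glutathione = c("GSS", "GPX1", "GSTM1", "GGT1", "GCLC", "GCLM",
                    "ANPEP", "OPLAH"),
    purine = c("ADA", "PNP", "XDH", "HPRT1", "AMPD2", "NT5E", "ADSL",
               "IMPDH1"),
    pyrimidine = c("UMPS", "DPYD", "DPYS", "UPB1", "CDA", "TYMS"),
    tca = c("CS", "ACO2", "IDH1", "SDHA", "FH", "MDH2", "OGDH"),
    amino_acid = c("GOT1", "GPT", "TAT", "BCAT1", "ASNS", "GLUD1",
                   "AARS1", "GLS"),
    other = sprintf("ENZ%03d", 1:24))
  rows <- list()
  cnt <- setNames(rep(0L, length(gene_pool)), names(gene_pool))
  for (i in seq_len(nrow(lib))) {
    cl <- lib$class[i]
    pool <- gene_pool[[cl]]
    g1 <- pool[(cnt[[cl]] %% length(pool)) + 1L]
    g2 <- pool[((cnt[[cl]] + 1L) %% length(pool)) + 1L]
    cnt[[cl]] <- cnt[[cl]] + 2L
    rows[[i]] <- data.frame(compound_id = lib$compound_id[i],
                            gene_id = unique(c(g1, g2)),
                            stringsAsFactors = FALSE)
  }
  compound_gene <- do.call(rbind, rows)
  pw_name <- c(glutathione = "Glutathione metabolism",
               purine = "Purine metabolism",
               pyrimidine = "Pyrimidine metabolism",
               tca = "Citrate cycle (TCA cycle)",
               amino_acid = "Amino acid metabolism",
               other = "Miscellaneous polar metabolism")
  gene_pathway <- do.call(rbind, lapply(names(gene_pool), function(cl)
    data.frame(gene_id = gene_pool[[cl]],
               pathway_id = paste0("pw_", cl),
               pathway_name = pw_name[[cl]], stringsAsFactors = FALSE)))
  pa <- pathwayAnnotation(compound_gene, gene_pathway)
  set.seed(config$seed + 1L)
  genes <- unique(compound_gene$gene_id)
  fc <- setNames(rnorm(length(genes), 0, 0.08), genes)
  if (!is.null(truth)) {
    aff_cpd <- unique(truth$compound_id[truth$asd_affected &
                                          !is.na(truth$compound_id)])
    aff_genes <- unique(compound_gene$gene_id[
      compound_gene$compound_id %in% aff_cpd])
    fc[aff_genes] <- sample(c(-1, 1), length(aff_genes), TRUE) *
      (0.3 + abs(rnorm(length(aff_genes), 0, 0.1)))
  }
  list(compounds = lib[, c("compound_id", "name", "monoisotopic_mass",
                           "source", "class")],
       pathway_annotation = pa, gene_log2fc = fc)
}
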