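## Peak table and sample metadata IO, mode merging, MDS embedding.

.readTable <- function(path) {
  mcAssert(file.exists(path), "formatError", paste0("file not found: ", path))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, na.strings = "NA",
           stringsAsFactors = FALSE)
}

#' Read an aligned peak table
#'
#' Reads a CSV/TSV peak table (one row per peak; columns `peak_id`, `mz`,
#' optional `rt`, then one intensity column per sample) into a
#' [PeakExperiment-class]. The dialect is chosen by extension (`.tsv`/`.txt`
#' are tab-separated), missing values are written `NA`, and intensities are
#' assumed linear-scale.
#'
#' @param path path to the peak table.
#' @param mode ionization mode of this run, `"positive"` or `"negative"`.
#' @param metadata optional sample metadata `data.frame` (from
#'   [readSampleMetadata()]); when supplied, every intensity column must be a
#'   known `sample_id` and the matching rows are attached as `colData`.
#' @return a [PeakExperiment-class].
#' @seealso [writePeakTable()], [mergeModes()]
#' @export
readPeakTable <- function(path, mode = c("positive", "negative"),
                          metadata = NULL) {
  mode <- match.arg(mode)
  df <- .readTable(path)
  mcAssert(all(c("peak_id", "mz") %in% colnames(df)), "formatError",
           "peak table must contain 'peak_id' and 'mz' columns")
  dup <- unique(df$peak_id[duplicated(df$peak_id)])
  mcAssert(length(dup) == 0, "formatError",
           paste0("duplicate peak id(s): ", paste(dup, collapse = ", ")))
  has_rt <- "rt" %in% colnames(df)
  samp_cols <- setdiff(colnames(df), c("peak_id", "mz", "rt"))
  mcAssert(length(samp_cols) >= 1, "formatError", "no sample columns found")
  m <- matrix(NA_real_, nrow(df), length(samp_cols),
              dimnames = list(df$peak_id, samp_cols))
  for (j in seq_along(samp_cols)) {
    raw <- df[[samp_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    mcAssert(length(bad) == 0, "formatError",
             sprintf("non-numeric intensity at peak '%s', sample '%s'",
                     df$peak_id[bad[1]], samp_cols[j]))
    m[, j] <- num
  }
  neg <- which(m < 0, arr.ind = TRUE)
  mcAssert(nrow(neg) == 0, "validationError",
           sprintf("negative intensity at peak '%s', sample '%s'",
                   rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  PeakExperiment(m, mz = df$mz, mode = mode,
                 rt = if (has_rt) df$rt else NULL, sampleData = metadata)
}

#' Write a peak table to CSV/TSV
#'
#' Inverse of [readPeakTable()]: `readPeakTable(writePeakTable(x, f))`
#' reproduces `x`'s ids, m/z, retention times and intensities.
#'
#' @param x a [PeakExperiment-class].
#' @param path output path; `.tsv`/`.txt` write tab-separated.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(x, path) {
  df <- data.frame(peak_id = rownames(x), mz = peakMz(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(peakRt(x))) df$rt <- peakRt(x)
  df <- cbind(df, as.data.frame(intensities(x), check.names = FALSE))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @importFrom utils write.table
NULL

#' Read sample metadata
#'
#' Reads per-sample covariates from CSV/TSV. Required columns: `sample_id`,
#' `species`, `group`, `age`, `injection_order`. Optional columns (`sex`,
#' `pmd_hours`, `rin`, `batch`, ...) are carried through. Species labels are
#' parsed case-insensitively to `human`, `chimpanzee`, `macaque`. `group`
#' must be `control`/`ASD` for humans and `NA` for nonhuman species. Ages are
#' years relative to birth; negative (prenatal) values are allowed.
#'
#' @param path path to the metadata table.
#' @return a `data.frame`, one row per sample.
#' @export
readSampleMetadata <- function(path) {
  df <- .readTable(path)
  req <- c("sample_id", "species", "group", "age", "injection_order")
  missing <- setdiff(req, colnames(df))
  mcAssert(length(missing) == 0, "formatError",
           paste0("metadata is missing required column(s): ",
                  paste(missing, collapse = ", ")))
  validateSampleMetadata(df)
}

#' Validate a sample metadata data.frame
#'
#' Applies the same checks [readSampleMetadata()] performs: unique sample
#' ids, recognized species, group present for humans only, numeric ages and
#' unique positive injection orders.
#'
#' @param df a `data.frame` of per-sample covariates.
#' @return the validated (type-normalized) `data.frame`.
#' @export
validateSampleMetadata <- function(df) {
  df <- as.data.frame(df)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  mcAssert(length(dup) == 0, "validationError",
           paste0("duplicate sample_id(s): ", paste(dup, collapse = ", ")))
  sp <- tolower(as.character(df$species))
  known <- c(human = "human", chimpanzee = "chimpanzee", chimp = "chimpanzee",
             macaque = "macaque", `rhesus macaque` = "macaque")
  mcAssert(all(sp %in% names(known)), "validationError",
           paste0("unknown species: ",
                  paste(unique(sp[!sp %in% names(known)]), collapse = ", ")))
  df$species <- unname(known[sp])
  grp <- as.character(df$group)
  grp[!is.na(grp) & tolower(grp) == "control"] <- "control"
  grp[!is.na(grp) & toupper(grp) == "ASD"] <- "ASD"
  bad_nh <- df$species != "human" & !is.na(grp)
  mcAssert(!any(bad_nh), "validationError",
           paste0("group must be NA for nonhuman samples: ",
                  paste(df$sample_id[bad_nh], collapse = ", ")))
  bad_h <- df$species == "human" & (is.na(grp) | !grp %in% c("control", "ASD"))
  mcAssert(!any(bad_h), "validationError",
           paste0("human samples need group control/ASD: ",
                  paste(df$sample_id[bad_h], collapse = ", ")))
  df$group <- grp
  df$age <- as.numeric(df$age)
  mcAssert(all(is.finite(df$age)), "validationError", "non-numeric age")
  if ("injection_order" %in% colnames(df)) {
    df$injection_order <- as.integer(df$injection_order)
    mcAssert(all(df$injection_order >= 1) &&
               !anyDuplicated(df$injection_order), "validationError",
             "injection_order must be unique positive integers within a run")
  }
  df
}

#' Merge positive- and negative-mode peak tables
#'
#' Concatenates the peak axes of the two ionization-mode runs over a shared
#' sample set. Peak ids are prefixed `"pos:"` / `"neg:"` so ids can never
#' collide; sample columns are aligned by id; every intensity value is
#' preserved.
#'
#' @param pos,neg [PeakExperiment-class] objects for the two runs over the
#'   same samples (column order may differ).
#' @return a merged [PeakExperiment-class] with `nrow(pos) + nrow(neg)` peaks.
#' @export
mergeModes <- function(pos, neg) {
  only_pos <- setdiff(colnames(pos), colnames(neg))
  only_neg <- setdiff(colnames(neg), colnames(pos))
  mcAssert(length(only_pos) == 0 && length(only_neg) == 0, "mergeError",
           paste0("sample sets differ between modes",
                  if (length(only_pos)) paste0("; only in positive: ",
                                               paste(only_pos, collapse = ", ")),
                  if (length(only_neg)) paste0("; only in negative: ",
                                               paste(only_neg, collapse = ", "))))
  mcAssert(isLog2(pos) == isLog2(neg), "mergeError",
           "cannot merge tables on different intensity scales")
  neg <- neg[, colnames(pos)]
  m <- rbind(intensities(pos), intensities(neg))
  rownames(m) <- c(paste0("pos:", rownames(pos)), paste0("neg:", rownames(neg)))
  rt_p <- peakRt(pos); rt_n <- peakRt(neg)
  rt <- if (is.null(rt_p) && is.null(rt_n)) NULL else
    c(if (is.null(rt_p)) rep(NA_real_, nrow(pos)) else rt_p,
      if (is.null(rt_n)) rep(NA_real_, nrow(neg)) else rt_n)
  sd_ <- sampleData(pos)
  if (ncol(sd_) && !"sample_id" %in% colnames(sd_))
    sd_ <- cbind(sample_id = rownames(sd_), sd_)
  PeakExperiment(m, mz = c(peakMz(pos), peakMz(neg)),
                 mode = c(peakMode(pos), peakMode(neg)), rt = rt,
                 sampleData = if (ncol(sd_)) sd_ else NULL,
                 log2 = isLog2(pos))
}

#' Classical MDS embedding of samples
#'
#' Embeds samples by classical multidimensional scaling of Euclidean
#' distances computed on log2-transformed, per-peak standardized intensities
#' (zero-variance peaks are dropped). Dimensions are ordered by decreasing
#' eigenvalue.
#'
#' @param x a [PeakExperiment-class] with at least 3 samples.
#' @param n_dims number of dimensions to return (must be `< ncol(x)`).
#' @return a samples x `n_dims` coordinate matrix with an `"eigenvalues"`
#'   attribute.
#' @export
mdsEmbedding <- function(x, n_dims = 2) {
  mcAssert(ncol(x) >= 3, "argumentError", "MDS needs at least 3 samples")
  mcAssert(n_dims >= 1 && n_dims < ncol(x), "argumentError",
           "n_dims must be positive and smaller than the sample count")
  m <- intensities(x)
  if (!isLog2(x)) m <- log2Matrix(m)
  z <- rowStandardize(m)
  keep <- setdiff(seq_len(nrow(z)), attr(z, "degenerate"))
  d <- dist(t(z[keep, , drop = FALSE]))
  fit <- stats::cmdscale(d, k = n_dims, eig = TRUE)
  coords <- fit$points
  ## cmdscale drops trailing zero-eigenvalue axes; pad so the contract holds
  if (ncol(coords) < n_dims)
    coords <- cbind(coords, matrix(0, nrow(coords), n_dims - ncol(coords)))
  dimnames(coords) <- list(colnames(x), paste0("Dim", seq_len(n_dims)))
  attr(coords, "eigenvalues") <- fit$eig
  coords
}
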