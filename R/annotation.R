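## Putative metabolite annotation: adduct m/z arithmetic and ppm matching.

## Monoisotopic mass deltas (Da) for singly charged adducts. One auditable
## constant table; positive-mode ions gain the listed mass, as do
## negative-mode ions (deltas already carry their sign).
.ADDUCTS <- data.frame(
  adduct = c("[M+H]", "[M+NH4]", "[M+Na]",
             "[M-H]", "[M+FA-H]", "[M-H2O-H]", "[M+Na-2H]"),
  mode = c("positive", "positive", "positive",
           "negative", "negative", "negative", "negative"),
  delta = c(1.007276, 18.033823, 22.989218,
            -1.007276, 44.998201, -19.018390, 20.974666),
  stringsAsFactors = FALSE)

#' Supported adducts and their monoisotopic mass deltas
#'
#' @return a `data.frame` with columns `adduct`, `mode`, `delta` (Da). The
#'   seven singly charged forms are `[M+H]`, `[M+NH4]`, `[M+Na]` in positive
#'   mode and `[M-H]`, `[M+FA-H]` (formic acid adduct), `[M-H2O-H]`,
#'   `[M+Na-2H]` in negative mode.
#' @export
adductTable <- function() .ADDUCTS

#' Theoretical m/z of an adduct ion
#'
#' @param monoisotopic_mass neutral monoisotopic mass (Da), `> 0`; vectorized.
#' @param adduct one of the labels in [adductTable()].
#' @return theoretical m/z in Da (`mass + delta`, singly charged).
#' @examples
#' adductMz(180.063388, "[M+H]")   # glucose -> 181.070664
#' @export
adductMz <- function(monoisotopic_mass, adduct) {
  mcAssert(all(monoisotopic_mass > 0), "argumentError", "mass must be > 0")
  i <- match(adduct, .ADDUCTS$adduct)
  mcAssert(!is.na(i), "argumentError",
           paste0("unknown adduct label: ", adduct))
  monoisotopic_mass + .ADDUCTS$delta[i]
}

#' Signed relative mass error in parts per million
#'
#' @param observed_mz,theoretical_mz m/z values (Da), both `> 0`; vectorized.
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppmError <- function(observed_mz, theoretical_mz) {
  mcAssert(all(observed_mz > 0) && all(theoretical_mz > 0), "argumentError",
           "m/z values must be > 0")
  (observed_mz - theoretical_mz) / theoretical_mz * 1e6
}

#' Annotation configuration
#'
#' @param ppm_tolerance mass tolerance in ppm (default 10; comparison is
#'   inclusive, `|ppm error| <= tolerance`).
#' @param adducts_positive,adducts_negative adduct labels considered per mode
#'   (defaults: the full sets in [adductTable()]).
#' @return a list of class `AnnotationConfig`.
#' @export
annotationConfig <- function(ppm_tolerance = 10,
                             adducts_positive = c("[M+H]", "[M+NH4]", "[M+Na]"),
                             adducts_negative = c("[M-H]", "[M+FA-H]",
                                                  "[M-H2O-H]", "[M+Na-2H]")) {
  mcAssert(is.numeric(ppm_tolerance) && ppm_tolerance > 0, "argumentError",
           "ppm_tolerance must be > 0")
  bad <- setdiff(c(adducts_positive, adducts_negative), .ADDUCTS$adduct)
  mcAssert(length(bad) == 0, "argumentError",
           paste0("unknown adduct label(s): ", paste(bad, collapse = ", ")))
  structure(list(ppm_tolerance = ppm_tolerance,
                 adducts_positive = adducts_positive,
                 adducts_negative = adducts_negative),
            class = "AnnotationConfig")
}

#' Validate a compound mass table
#'
#' @param compounds `data.frame` with columns `compound_id`, `name`,
#'   `monoisotopic_mass` (Da, finite, `> 0`) and optionally `source`.
#' @return the validated table.
#' @export
validateCompoundTable <- function(compounds) {
  compounds <- as.data.frame(compounds)
  mcAssert(nrow(compounds) > 0, "argumentError", "empty compound table")
  mcAssert(all(c("compound_id", "monoisotopic_mass") %in% colnames(compounds)),
           "formatError",
           "compound table needs 'compound_id' and 'monoisotopic_mass'")
  mcAssert(!anyDuplicated(compounds$compound_id), "validationError",
           "compound_id values must be unique")
  mcAssert(all(is.finite(compounds$monoisotopic_mass)) &&
             all(compounds$monoisotopic_mass > 0), "validationError",
           "monoisotopic masses must be finite and > 0")
  compounds
}

#' Putatively annotate peaks by adduct mass matching
#'
#' For every peak, every (compound, mode-appropriate adduct) pair whose
#' theoretical m/z lies within the configured ppm tolerance of the observed
#' m/z is reported; peaks may receive zero or several records and no "best
#' match" collapse is applied. Candidate lookup uses an interval query over a
#' mass-sorted index and is record-for-record identical to an exhaustive
#' scan.
#'
#' @param x a [PeakExperiment-class] (each peak carries its ionization mode).
#' @param compounds a compound table (see [validateCompoundTable()]).
#' @param config an [annotationConfig()].
#' @return a `data.frame` with columns `peak_id`, `compound_id`, `adduct`,
#'   `theoretical_mz`, `ppm_error`, sorted by peak id, compound id, adduct.
#' @export
annotatePeaks <- function(x, compounds, config = annotationConfig()) {
  compounds <- validateCompoundTable(compounds)
  tol <- config$ppm_tolerance
  mz <- peakMz(x)
  mode <- peakMode(x)
  ids <- rownames(x)
  out <- vector("list", 2 * 4)
  k <- 0
  for (md in c("positive", "negative")) {
    sel <- which(mode == md)
    if (length(sel) == 0) next
    adds <- if (md == "positive") config$adducts_positive else
      config$adducts_negative
    for (ad in adds) {
      theo <- adductMz(compounds$monoisotopic_mass, ad)
      ord <- order(theo)
      theo_s <- theo[ord]
      ## |obs - theo|/theo <= tol*1e-6  <=>  theo in [obs/(1+t), obs/(1-t)];
      ## the window is widened by a sliver and the exact ppm test applied
      ## below so boundary hits are decided by the ppm rule, not by rounding.
      t_ <- tol * 1e-6
      lo <- mz[sel] / (1 + t_) * (1 - 1e-10)
      hi <- mz[sel] / (1 - t_) * (1 + 1e-10)
      i0 <- findInterval(lo, theo_s)  # last theo <= lo (lo already shrunk)
      i1 <- findInterval(hi, theo_s)  # last theo <= hi
      n_hit <- pmax(i1 - i0, 0L)
      if (sum(n_hit) == 0) next
      pk <- rep(sel, n_hit)
      ci <- unlist(lapply(which(n_hit > 0), function(j)
        ord[(i0[j] + 1L):i1[j]]), use.names = FALSE)
      pe <- ppmError(mz[pk], theo[ci])
      keep <- abs(pe) <= tol  # guard the interval endpoints exactly
      k <- k + 1
      out[[k]] <- data.frame(peak_id = ids[pk][keep],
                             compound_id = compounds$compound_id[ci][keep],
                             adduct = ad,
                             theoretical_mz = theo[ci][keep],
                             ppm_error = pe[keep],
                             stringsAsFactors = FALSE)
    }
  }
  res <- if (k == 0)
    data.frame(peak_id = character(), compound_id = character(),
               adduct = character(), theoretical_mz = numeric(),
               ppm_error = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, out[seq_len(k)])
  res <- res[order(res$peak_id, res$compound_id, res$adduct), , drop = FALSE]
  rownames(res) <- NULL
  res
}
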