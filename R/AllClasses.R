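#' PeakExperiment: an LC-MS peak table with per-peak metadata
#'
#' `PeakExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds a peaks x samples intensity matrix in the `"intensity"` assay.
#' Per-peak mass-to-charge (`mz`, Da), ionization mode (`mode`, `"positive"`
#' or `"negative"`) and optional retention time (`rt`, minutes) live in
#' `rowData`; per-sample covariates (species, diagnosis group, age, sex,
#' postmortem delay, RNA integrity, injection order, batch) live in
#' `colData`. Intensities are linear-scale unless the `log2` flag in the
#' object metadata is set.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass PeakExperiment
setClass("PeakExperiment", contains = "SummarizedExperiment")

.validPeakExperiment <- function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mz", "mode") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'mz' and 'mode'")
  } else {
    if (any(!is.finite(rd$mz)) || any(rd$mz <= 0))
      msg <- c(msg, "all m/z values must be finite and > 0")
    if (any(!rd$mode %in% c("positive", "negative")))
      msg <- c(msg, "mode must be 'positive' or 'negative' for every peak")
    if ("rt" %in% colnames(rd) && any(rd$rt < 0, na.rm = TRUE))
      msg <- c(msg, "retention times must be >= 0")
  }
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msg <- c(msg, paste0("peak ids must be present and unique",
                         if (length(dup)) paste0(" (duplicated: ",
                                                 paste(dup, collapse = ", "), ")")))
  }
  sids <- colnames(object)
  if (is.null(sids) || anyDuplicated(sids))
    msg <- c(msg, "sample ids must be present and unique")
  if (length(msg) == 0 && !isLog2(object)) {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (any(!is.finite(a)) || any(a < 0))
      msg <- c(msg, "linear-scale intensities must be finite and >= 0")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PeakExperiment", .validPeakExperiment)

#' Construct a PeakExperiment
#'
#' @param intensity numeric peaks x samples matrix with rownames (peak ids)
#'   and colnames (sample ids).
#' @param mz numeric vector of per-peak m/z values (Da).
#' @param mode ionization mode, either a single label recycled to all peaks or
#'   a per-peak vector of `"positive"` / `"negative"`.
#' @param rt optional numeric vector of retention times (minutes).
#' @param sampleData optional `data.frame` of per-sample covariates with a
#'   `sample_id` column (see [readSampleMetadata()]); rows are matched to the
#'   intensity columns by id.
#' @param log2 logical; `TRUE` if `intensity` is already on the log2 scale.
#' @return a validated [PeakExperiment-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' pe <- PeakExperiment(m, mz = c(181.07, 203.05, 150.1), mode = "positive")
#' peakMz(pe)
#' @export
PeakExperiment <- function(intensity, mz, mode, rt = NULL, sampleData = NULL,
                           log2 = FALSE) {
  intensity <- as.matrix(intensity)
  mode <- rep_len(as.character(mode), nrow(intensity))
  rd <- S4Vectors::DataFrame(mz = as.numeric(mz), mode = mode)
  if (!is.null(rt)) rd$rt <- as.numeric(rt)
  cd <- S4Vectors::DataFrame(row.names = colnames(intensity))
  if (!is.null(sampleData)) {
    sampleData <- as.data.frame(sampleData)
    missing <- setdiff(colnames(intensity), sampleData$sample_id)
    mcAssert(length(missing) == 0, "linkageError",
             paste0("samples absent from metadata: ",
                    paste(missing, collapse = ", ")))
    idx <- match(colnames(intensity), sampleData$sample_id)
    cd <- S4Vectors::DataFrame(sampleData[idx, , drop = FALSE],
                               row.names = colnames(intensity))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity), rowData = rd, colData = cd,
    metadata = list(log2 = isTRUE(log2)))
  tryCatch(new("PeakExperiment", se),
           error = function(e) mcStop("validationError", conditionMessage(e)))
}

#' @describeIn PeakExperiment per-peak m/z values (Da)
#' @param x,object a `PeakExperiment`
#' @export
peakMz <- function(x) SummarizedExperiment::rowData(x)$mz

#' @describeIn PeakExperiment per-peak ionization mode labels
#' @export
peakMode <- function(x) as.character(SummarizedExperiment::rowData(x)$mode)

#' @describeIn PeakExperiment per-peak retention times (or NULL)
#' @export
peakRt <- function(x) SummarizedExperiment::rowData(x)$rt

#' @describeIn PeakExperiment the intensity matrix
#' @export
intensities <- function(x) SummarizedExperiment::assay(x, "intensity")

#' @describeIn PeakExperiment TRUE if intensities are log2-scale
#' @export
isLog2 <- function(x) isTRUE(S4Vectors::metadata(x)$log2)

#' @describeIn PeakExperiment per-sample covariates as a data.frame
#' @export
sampleData <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "PeakExperiment", function(object) {
  cat(sprintf("PeakExperiment: %d peaks x %d samples (%s scale)\n",
              nrow(object), ncol(object),
              if (isLog2(object)) "log2" else "linear"))
  tab <- table(peakMode(object))
  cat("  modes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cd <- SummarizedExperiment::colData(object)
  if ("species" %in% colnames(cd)) {
    st <- table(cd$species)
    cat("  species:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  }
  invisible(object)
})
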