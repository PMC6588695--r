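## Metabolite -> gene linking, hypergeometric pathway enrichment, pathway-set
## overlap tests, and expression-shift comparison of linked genes.

#' Build a pathway annotation from mapping tables
#'
#' @param compound_gene `data.frame` with columns `compound_id`, `gene_id`
#'   (enzymes directly linked to each metabolite).
#' @param gene_pathway `data.frame` with columns `gene_id`, `pathway_id` and
#'   optionally `pathway_name`.
#' @return a list of class `PathwayAnnotation` with `metabolite_to_genes`
#'   (named list compound -> genes), `gene_to_pathways` (named list gene ->
#'   pathways) and `pathway_names` (named character).
#' @export
pathwayAnnotation <- function(compound_gene, gene_pathway) {
  mcAssert(all(c("compound_id", "gene_id") %in% colnames(compound_gene)),
           "formatError", "compound_gene needs compound_id and gene_id")
  mcAssert(all(c("gene_id", "pathway_id") %in% colnames(gene_pathway)),
           "formatError", "gene_pathway needs gene_id and pathway_id")
  m2g <- split(as.character(compound_gene$gene_id),
               as.character(compound_gene$compound_id))
  g2p <- split(as.character(gene_pathway$pathway_id),
               as.character(gene_pathway$gene_id))
  nm <- if ("pathway_name" %in% colnames(gene_pathway)) {
    u <- !duplicated(gene_pathway$pathway_id)
    setNames(as.character(gene_pathway$pathway_name[u]),
             gene_pathway$pathway_id[u])
  } else {
    ids <- unique(as.character(gene_pathway$pathway_id))
    setNames(ids, ids)
  }
  structure(list(metabolite_to_genes = lapply(m2g, unique),
                 gene_to_pathways = lapply(g2p, unique),
                 pathway_names = nm),
            class = "PathwayAnnotation")
}

#' Link peaks to genes through their putative compound annotations
#'
#' The selected gene set is the union of genes over all compounds putatively
#' matching the given peaks (multi-compound peaks contribute all their
#' compounds' genes); the background is the same union over all annotated
#' peaks in `annotations`.
#'
#' @param peak_ids character vector of peaks of interest.
#' @param annotations output of [annotatePeaks()].
#' @param pathway_annotation a [pathwayAnnotation()].
#' @return a list: `selected` and `background` gene id vectors, plus
#'   `n_unannotated`, the number of requested peaks without any annotation.
#' @export
linkGenes <- function(peak_ids, annotations, pathway_annotation) {
  m2g <- pathway_annotation$metabolite_to_genes
  genesOf <- function(peaks) {
    cpds <- unique(annotations$compound_id[annotations$peak_id %in% peaks])
    sort(unique(unlist(m2g[intersect(cpds, names(m2g))], use.names = FALSE)))
  }
  selected <- genesOf(peak_ids)
  n_un <- sum(!peak_ids %in% annotations$peak_id)
  if (length(selected) == 0)
    warning("no genes linked to the requested peaks")
  list(selected = selected,
       background = genesOf(unique(annotations$peak_id)),
       n_unannotated = n_un)
}

#' Hypergeometric pathway overrepresentation test
#'
#' For every pathway with at least one background gene, the upper-tail
#' hypergeometric probability of drawing the observed overlap (or more)
#' between the selected set and pathway-in-background genes from the
#' background is computed, followed by BH adjustment across tested pathways.
#'
#' @param selected,background gene id vectors, `selected` a subset of
#'   `background`.
#' @param pathway_annotation a [pathwayAnnotation()].
#' @param alpha BH threshold recorded in the `enriched` column (default 0.05).
#' @return a `data.frame` sorted by q: `pathway_id`, `pathway_name`,
#'   `overlap_count`, `selected_gene_count`, `background_gene_count`,
#'   `pathway_gene_count`, `p`, `q`, `enriched`.
#' @export
hypergeomEnrichment <- function(selected, background, pathway_annotation,
                                alpha = 0.05) {
  mcAssert(all(selected %in% background), "validationError",
           "selected genes must be a subset of the background")
  g2p <- pathway_annotation$gene_to_pathways
  bg <- unique(background)
  sel <- unique(selected)
  pw_genes <- list()
  for (g in intersect(bg, names(g2p)))
    for (pw in g2p[[g]]) pw_genes[[pw]] <- c(pw_genes[[pw]], g)
  mcAssert(length(pw_genes) >= 1, "argumentError",
           "no pathway intersects the background")
  rows <- lapply(names(pw_genes), function(pw) {
    pg <- pw_genes[[pw]]               # pathway genes within the background
    k <- length(intersect(sel, pg))
    p <- phyper(k - 1, length(pg), length(bg) - length(pg), length(sel),
                lower.tail = FALSE)
    data.frame(pathway_id = pw,
               pathway_name = unname(
                 pathway_annotation$pathway_names[pw] %||% pw),
               overlap_count = k, selected_gene_count = length(sel),
               background_gene_count = length(bg),
               pathway_gene_count = length(pg), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bhAdjust(res$p)
  res$enriched <- res$q <= alpha
  res <- res[order(res$q, res$p, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Fisher's exact test on the overlap of two pathway sets
#'
#' Builds the 2x2 membership table of `setA` x `setB` over `universe` and
#' tests one-sided (enrichment direction) with Fisher's exact test. The test
#' is symmetric in A and B.
#'
#' @param setA,setB pathway id vectors, subsets of `universe`.
#' @param universe the pathway universe.
#' @return a list: `table` (2x2 matrix), `odds_ratio`, `p`.
#' @export
fisherOverlap <- function(setA, setB, universe) {
  universe <- unique(universe)
  mcAssert(length(universe) > 0, "argumentError", "empty universe")
  mcAssert(all(setA %in% universe) && all(setB %in% universe),
           "validationError", "setA and setB must be subsets of the universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                  sum(!inA & inB), sum(!inA & !inB)),
                nrow = 2, byrow = TRUE,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  ft <- fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Expression-configuration
#'
#' @param log2fc_threshold absolute log2 fold-change above which a gene
#'   counts as differentially expressed (default 0.2).
#' @return a list of class `ExpressionConfig`.
#' @export
expressionConfig <- function(log2fc_threshold = 0.2) {
  mcAssert(log2fc_threshold > 0, "argumentError", "threshold must be > 0")
  structure(list(log2fc_threshold = log2fc_threshold),
            class = "ExpressionConfig")
}

#' Compare expression shifts of genes linked to two peak sets
#'
#' For each peak, the proportion of its linked genes with
#' `|log2FC| > threshold` is computed (peaks without linked genes covered by
#' the fold-change table are skipped); the two resulting proportion
#' distributions are compared with a two-sample Kolmogorov-Smirnov test.
#'
#' @param asd_peak_ids,other_peak_ids peak id vectors for the two categories.
#' @param annotations output of [annotatePeaks()].
#' @param pathway_annotation a [pathwayAnnotation()].
#' @param gene_log2fc named numeric vector, gene -> log2 fold change.
#' @param config an [expressionConfig()].
#' @return a list: `asd_proportions`, `other_proportions`, `statistic`
#'   (KS D), `p`.
#' @export
expressionShiftTest <- function(asd_peak_ids, other_peak_ids, annotations,
                                pathway_annotation, gene_log2fc,
                                config = expressionConfig()) {
  m2g <- pathway_annotation$metabolite_to_genes
  propOf <- function(peaks) {
    out <- numeric(0)
    for (pk in peaks) {
      cpds <- unique(annotations$compound_id[annotations$peak_id == pk])
      genes <- unique(unlist(m2g[intersect(cpds, names(m2g))],
                             use.names = FALSE))
      genes <- intersect(genes, names(gene_log2fc))
      if (length(genes) == 0) next
      out <- c(out, setNames(
        mean(abs(gene_log2fc[genes]) > config$log2fc_threshold), pk))
    }
    out
  }
  a <- propOf(asd_peak_ids)
  b <- propOf(other_peak_ids)
  mcAssert(length(a) > 0 && length(b) > 0, "testError",
           "both peak sets need at least one peak with linked genes")
  ks <- suppressWarnings(ks.test(a, b))
  list(asd_proportions = a, other_proportions = b,
       statistic = unname(ks$statistic), p = ks$p.value)
}
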