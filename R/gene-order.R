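# Numerical gene-order signatures and rearrangement comparison against
# the ancestral insect order.

#' Gene-order signature of a mitogenome
#'
#' Encodes the chromosomal gene order numerically: each of the 37 genes
#' carries the index of its position in the ancestral insect order
#' (*trnI* = 1, *trnQ* = 2, ...), listed in the order they occur on the
#' chromosome together with their +1/-1 orientation. The circular order
#' is rotated so that *trnI* leads when present; the control region is
#' excluded. Missing genes are simply absent from the signature.
#'
#' @param genome a [Mitogenome-class].
#' @return data.frame of class `GeneOrderSignature` with columns `gene`,
#'   `index`, `orientation`, in chromosomal order.
#' @export
geneOrderSignature <- function(genome) {
  ft <- featureTable(genome)
  ft <- ft[ft$geneClass != "CR", , drop = FALSE]
  ft <- ft[order(ft$start), , drop = FALSE]
  anc <- ancestralGeneOrder()
  sig <- data.frame(gene = ft$gene,
                    index = anc$index[match(ft$gene, anc$gene)],
                    orientation = ft$strand,
                    stringsAsFactors = FALSE)
  lead <- which(sig$gene == "trnI")
  if (length(lead) == 1L && lead > 1L)
    sig <- sig[c(lead:nrow(sig), 1L:(lead - 1L)), , drop = FALSE]
  rownames(sig) <- NULL
  class(sig) <- c("GeneOrderSignature", "data.frame")
  sig
}

# circular directed adjacency pairs "a>b" of a signature's index sequence
.adjacencyPairs <- function(idx) {
  if (length(idx) < 2L) return(character())
  nxt <- c(idx[-1], idx[1])
  paste(idx, nxt, sep = ">")
}

#' Compare a gene-order signature against a reference order
#'
#' Reports identity, missing genes, genes with flipped orientation, and
#' the breakpoint count: the number of circular directed adjacencies
#' (consecutive gene pairs) of the signature that do not occur in the
#' reference. Orientation enters only the inversion report, not the
#' adjacency count, so a pure in-place inversion contributes inverted
#' genes but no breakpoints. Genes out of ancestral adjacency are
#' reported as translocated.
#'
#' @param sig a `GeneOrderSignature` (see [geneOrderSignature()]).
#' @param reference the reference signature; default
#'   [ancestralGeneOrder()].
#' @return list of class `RearrangementReport`: `is_identical`,
#'   `missing_genes`, `breakpoint_count`, `inverted_genes`,
#'   `translocated_genes`.
#' @export
compareGeneOrder <- function(sig, reference = ancestralGeneOrder()) {
  missing <- setdiff(reference$gene, sig$gene)
  m <- match(sig$gene, reference$gene)
  inverted <- sig$gene[!is.na(m) & sig$orientation != reference$orientation[m]]
  sigPairs <- .adjacencyPairs(sig$index)
  refPairs <- .adjacencyPairs(reference$index)
  broken <- !(sigPairs %in% refPairs)
  breakpoints <- sum(broken)
  translocated <- character()
  if (breakpoints) {
    idx <- unique(unlist(strsplit(sigPairs[broken], ">", fixed = TRUE)))
    translocated <- sort(reference$gene[reference$index %in% as.integer(idx)])
  }
  out <- list(
    is_identical = length(missing) == 0L && breakpoints == 0L &&
      length(inverted) == 0L,
    missing_genes = missing,
    breakpoint_count = breakpoints,
    inverted_genes = inverted,
    translocated_genes = translocated)
  class(out) <- "RearrangementReport"
  out
}

#' @export
print.RearrangementReport <- function(x, ...) {
  cat("RearrangementReport:",
      if (x$is_identical) "identical to reference\n" else "rearranged\n")
  cat("  breakpoints:", x$breakpoint_count, "\n")
  if (length(x$missing_genes))
    cat("  missing:", paste(x$missing_genes, collapse = ", "), "\n")
  if (length(x$inverted_genes))
    cat("  inverted:", paste(x$inverted_genes, collapse = ", "), "\n")
  if (length(x$translocated_genes))
    cat("  translocated:", paste(x$translocated_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Tabulate gene-order signatures for a set of genomes
#'
#' @param genomes list of [Mitogenome-class] objects.
#' @return data.frame with columns `genome_id`, `gene`, `index`,
#'   `start`, `end`, `strand`.
#' @export
geneOrderTable <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    ft <- featureTable(g)
    ft <- ft[ft$geneClass != "CR", , drop = FALSE]
    ft <- ft[order(ft$start), , drop = FALSE]
    anc <- ancestralGeneOrder()
    data.frame(genome_id = identifier(g), gene = ft$gene,
               index = anc$index[match(ft$gene, anc$gene)],
               start = ft$start, end = ft$end, strand = ft$strand,
               stringsAsFactors = FALSE)
  }))
}
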