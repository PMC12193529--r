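# Oriented gene extraction and fixed-order concatenations.

# fixed plus/plus concatenation orders
.PCG_CONCAT_ORDER <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
                       "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5",
                       "nad6")
.TRNA_CONCAT_ORDER <- .ANCESTRAL_ORDER$gene[
  geneClassOf(.ANCESTRAL_ORDER$gene) == "tRNA"]
.RRNA_CONCAT_ORDER <- c("rrnL", "rrnS")

#' Fixed concatenation orders for the composition data sets
#'
#' The 13 protein-coding genes in the conventional alphabetical order
#' (atp6, atp8, cox1..3, cob, nad1..nad6 with nad4l after nad4), the 22
#' tRNAs in ancestral chromosomal order (trnI, trnQ, trnM, ...), and the
#' two rRNAs. All concatenations are built from coding-sense ("plus/
#' plus") oriented gene sequences.
#'
#' @param class one of `"PCG"`, `"tRNA"`, `"rRNA"`.
#' @return character vector of canonical gene names.
#' @export
concatOrder <- function(class = c("PCG", "tRNA", "rRNA")) {
  switch(match.arg(class),
         PCG = .PCG_CONCAT_ORDER,
         tRNA = .TRNA_CONCAT_ORDER,
         rRNA = .RRNA_CONCAT_ORDER)
}

.REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N",
              R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
              B = "V", V = "B", D = "H", H = "D")

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (IUPAC letters).
#' @return the reverse complement, as a character string.
#' @export
reverseComplement <- function(seq) {
  s <- strsplit(toupper(as.character(seq)), "")[[1]]
  out <- .REVCOMP[rev(s)]
  if (anyNA(out))
    stop(.err("mitocomp_invalid_sequence",
              paste("non-IUPAC letters in sequence:",
                    paste(unique(s[is.na(.REVCOMP[s])]), collapse = ", "))))
  paste(out, collapse = "")
}

#' Extract an oriented gene sequence from a mitogenome
#'
#' Returns the gene reading 5'->3' in coding sense: light(-)-strand
#' genes are reverse-complemented, and features that span the origin of
#' a circular genome are concatenated across it (modular indexing, so
#' `start > end` is permitted for such features).
#'
#' @param genome a [Mitogenome-class].
#' @param name canonical gene name (see [canonicalGeneNames()]).
#' @return nucleotide string (character).
#' @examples
#' \dontrun{extractGene(genome, "cox1")}
#' @export
extractGene <- function(genome, name) {
  ft <- featureTable(genome)
  i <- match(name, ft$gene)
  if (is.na(i))
    stop(.err("mitocomp_missing_gene",
              sprintf("gene '%s' absent from genome '%s'", name,
                      identifier(genome))))
  seq <- as.character(genomeSequence(genome))
  f <- ft[i, ]
  s <- if (f$wrapsOrigin)
    paste0(substr(seq, f$start + 1L, nchar(seq)), substr(seq, 1L, f$end))
  else substr(seq, f$start + 1L, f$end)
  if (f$strand == -1L) reverseComplement(s) else s
}

#' Concatenate the 13 protein-coding genes in a fixed order
#'
#' Concatenation of coding-sense gene sequences in exactly the given
#' order, independent of where the genes sit on the chromosome; the
#' default is the conventional plus/plus order of [concatOrder()].
#'
#' @param genome a [Mitogenome-class].
#' @param order character vector of the 13 PCG names.
#' @return nucleotide string.
#' @export
concatenatePCGs <- function(genome, order = concatOrder("PCG")) {
  paste(vapply(order, function(g) extractGene(genome, g), character(1)),
        collapse = "")
}
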