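# Nucleotide composition and strand-asymmetry (AT/GC skew) statistics.

.IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W",
                    "K", "M", "B", "D", "H", "V")

#' Base counts of a nucleotide sequence
#'
#' Case-insensitive counts of A, T, G, C; every other IUPAC letter
#' (ambiguity codes and N) is tallied as `other` and excluded from all
#' downstream ratios. U counts as T.
#'
#' @param seq nucleotide string (character or
#'   [Biostrings::DNAString]-like).
#' @return named integer vector `c(A, T, G, C, other)`.
#' @export
baseCounts <- function(seq) {
  s <- toupper(as.character(seq))
  if (!nzchar(s))
    stop(.err("mitocomp_invalid_sequence", "empty sequence"))
  ch <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(ch), .IUPAC_LETTERS)
  if (length(bad))
    stop(.err("mitocomp_invalid_sequence",
              paste("non-IUPAC letters in sequence:",
                    paste(bad, collapse = ", "))))
  tab <- table(factor(ch, levels = .IUPAC_LETTERS))
  c(A = unname(tab[["A"]]), T = unname(tab[["T"]]) + unname(tab[["U"]]),
    G = unname(tab[["G"]]), C = unname(tab[["C"]]),
    other = length(ch) - sum(tab[c("A", "T", "U", "G", "C")]))
}

#' AT and GC skew
#'
#' Strand compositional asymmetry: AT skew = (A - T)/(A + T) and
#' GC skew = (G - C)/(G + C), computed on the unambiguous base counts.
#' When the denominator is zero the skew is undefined and `NA` is
#' returned (reported as missing, never as zero).
#'
#' @param seq nucleotide string.
#' @return numeric skew in `[-1, 1]`, or `NA_real_`.
#' @examples
#' atSkew("AAAT")  # (3 - 1) / (3 + 1) = 0.5
#' gcSkew("ATAT")  # NA: no G or C
#' @export
atSkew <- function(seq) {
  n <- baseCounts(seq)
  if (n[["A"]] + n[["T"]] == 0L) return(NA_real_)
  (n[["A"]] - n[["T"]]) / (n[["A"]] + n[["T"]])
}

#' @rdname atSkew
#' @export
gcSkew <- function(seq) {
  n <- baseCounts(seq)
  if (n[["G"]] + n[["C"]] == 0L) return(NA_real_)
  (n[["G"]] - n[["C"]]) / (n[["G"]] + n[["C"]])
}

.skewRecord <- function(genomeId, label, seq) {
  n <- baseCounts(seq)
  unamb <- n[["A"]] + n[["T"]] + n[["G"]] + n[["C"]]
  data.frame(
    genome_id = genomeId, dataset_label = label,
    A = n[["A"]], T = n[["T"]], G = n[["G"]], C = n[["C"]],
    other = n[["other"]],
    at_percent = if (unamb > 0) 100 * (n[["A"]] + n[["T"]]) / unamb else NA_real_,
    at_skew = if (n[["A"]] + n[["T"]] > 0)
      (n[["A"]] - n[["T"]]) / (n[["A"]] + n[["T"]]) else NA_real_,
    gc_skew = if (n[["G"]] + n[["C"]] > 0)
      (n[["G"]] - n[["C"]]) / (n[["G"]] + n[["C"]]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Skew table over a set of genomes at a given data-set level
#'
#' Computes composition records for one of the analysis levels: the
#' whole deposited genome sequence, the 13 concatenated protein-coding
#' genes, the concatenated rRNAs, the concatenated tRNAs (all
#' concatenations coding-sense, fixed plus/plus order, see
#' [concatOrder()]), or per-gene records for each PCG or tRNA.
#'
#' @param genomes list of [Mitogenome-class] objects (a single genome is
#'   accepted).
#' @param level one of `"whole_genome"`, `"pcg_concat"`, `"pcg"`,
#'   `"trna_concat"`, `"trna"`, `"rrna_concat"`.
#' @return data.frame of skew records, one row per genome (concatenated
#'   levels) or per genome x gene (`"pcg"`, `"trna"`); `dataset_label`
#'   is the level, or `"pcg:<gene>"` / `"trna:<gene>"` for per-gene
#'   rows.
#' @export
skewTable <- function(genomes,
                      level = c("whole_genome", "pcg_concat", "pcg",
                                "trna_concat", "trna", "rrna_concat")) {
  level <- match.arg(level)
  if (methods::is(genomes, "Mitogenome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    id <- identifier(g)
    switch(level,
      whole_genome = .skewRecord(id, level, as.character(genomeSequence(g))),
      pcg_concat = .skewRecord(id, level, concatenatePCGs(g)),
      rrna_concat = .skewRecord(id, level, paste(
        vapply(concatOrder("rRNA"), function(x) extractGene(g, x),
               character(1)), collapse = "")),
      trna_concat = .skewRecord(id, level, paste(
        vapply(concatOrder("tRNA"), function(x) extractGene(g, x),
               character(1)), collapse = "")),
      pcg = do.call(rbind, lapply(concatOrder("PCG"), function(x)
        .skewRecord(id, paste0("pcg:", x), extractGene(g, x)))),
      trna = do.call(rbind, lapply(concatOrder("tRNA"), function(x)
        .skewRecord(id, paste0("trna:", x), extractGene(g, x)))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two skew vectors
#'
#' @param xs,ys numeric vectors of equal length >= 2.
#' @return list of class `CorrelationResult` with `n` (pairs used) and
#'   `r` (product-moment coefficient).
#' @export
pearsonCorrelation <- function(xs, ys) {
  if (length(xs) != length(ys))
    stop(.err("mitocomp_invalid_input", "xs and ys must have equal length"))
  keep <- stats::complete.cases(xs, ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) < 2L)
    stop(.err("mitocomp_invalid_input", "need at least 2 complete pairs"))
  if (stats::var(xs) == 0 || stats::var(ys) == 0)
    stop(.err("mitocomp_undefined_correlation",
              "zero variance: correlation undefined"))
  structure(list(n = length(xs), r = unname(stats::cor(xs, ys))),
            class = "CorrelationResult")
}
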