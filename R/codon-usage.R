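# Codon counting, RSCU, CAI (whole-gene and 300-bp sliding windows)
# and GC content by codon position.

.ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"), paste0),
                               c("T", "C", "A", "G"), paste0))

#' Count codons of a coding sequence
#'
#' The reading frame is fixed at 0. Complete codons containing only
#' A/C/G/T are counted in a 64-entry table (stop codons included in the
#' table but excluded from all downstream sense statistics); complete
#' codons containing an ambiguity letter are excluded and counted in
#' `excluded`; a trailing 1-2 nt remainder (the incomplete stop codon
#' completed by polyadenylation in mitochondrial mRNAs) is dropped and
#' reported in `trailing_nt`.
#'
#' @param cds coding sequence, 5'->3' coding sense.
#' @param code a [GeneticCode-class].
#' @param label optional label stored with the counts.
#' @return list of class `CodonCounts`: `label`, `counts` (named
#'   integer, all 64 codons), `excluded`, `trailing_nt`, `n_codons`
#'   (complete codons scanned).
#' @export
codonCounts <- function(cds, code = geneticCode(), label = NA_character_) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) < 3L)
    stop(.err("mitocomp_invalid_input", "CDS shorter than one codon"))
  cods <- splitCodons(cds)
  clean <- grepl("^[ACGT]{3}$", cods)
  counts <- table(factor(cods[clean], levels = .ALL_CODONS))
  counts <- stats::setNames(as.integer(counts), .ALL_CODONS)
  structure(list(label = label, counts = counts,
                 excluded = sum(!clean),
                 trailing_nt = nchar(cds) %% 3L,
                 n_codons = length(cods)),
            class = "CodonCounts")
}

# sense counts (stop codons removed), from CodonCounts or a named vector
.senseCounts <- function(counts, code) {
  v <- if (inherits(counts, "CodonCounts")) counts$counts else counts
  v[senseCodons(code)]
}

#' Relative synonymous codon usage (RSCU)
#'
#' For sense codon c in a synonymous family F,
#' `RSCU(c) = count(c) * |F| / sum(counts over F)`: the observed count
#' divided by the expectation under uniform use within the family.
#' Families with zero total count get `NA` entries.
#'
#' @param counts a `CodonCounts` object (see [codonCounts()]) or a named
#'   codon count vector.
#' @param code a [GeneticCode-class].
#' @return named numeric vector over the sense codons of the code, with
#'   attribute `amino_acid` giving each codon's amino acid.
#' @examples
#' cc <- codonCounts("TTATTGCTATTA")
#' rscu(cc)[["TTA"]]  # 2 * 6 / 4 = 3 under the mito code's 6-fold Leu
#' @export
rscu <- function(counts, code = geneticCode()) {
  v <- .senseCounts(counts, code)
  out <- rep(NA_real_, length(v))
  names(out) <- names(v)
  for (fam in codonFamilies(code)) {
    tot <- sum(v[fam])
    if (tot > 0) out[fam] <- v[fam] * length(fam) / tot
  }
  attr(out, "amino_acid") <- translateCodons(names(out), code)
  out
}

#' Read a reference codon-usage table
#'
#' Accepts the Kazusa-style layout (whitespace-separated triples
#' `codon frequency-per-thousand count`, parentheses around counts
#' tolerated, several triples per line allowed) or a two-column
#' `codon count` table. RNA alphabet (U) is accepted and mapped to T.
#' Values are normalized to relative frequencies over all 64 codons;
#' codons absent from the table are filled with zero and flagged in the
#' `missing_codons` attribute.
#'
#' @param file path to the table, or its content via `text`.
#' @param text table content (single string or lines).
#' @return named numeric vector of length 64 summing to 1, with
#'   attributes `missing_codons` and `provenance`.
#' @export
readCodonTable <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else readLines(file, warn = FALSE)
  prov <- if (is.null(text)) basename(file) else "inline"
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- unlist(strsplit(gsub("[()]", " ", paste(lines, collapse = " ")),
                          "\\s+"))
  toks <- toks[nzchar(toks)]
  isCodon <- grepl("^[ACGTUacgtu]{3}$", toks)
  isNum <- grepl("^-?[0-9.]+$", toks) & !isCodon
  if (any(!isCodon & !isNum))
    stop(.err("mitocomp_parse_error",
              paste("unparseable token in codon table:",
                    toks[which(!isCodon & !isNum)[1]])))
  starts <- which(isCodon)
  if (!length(starts))
    stop(.err("mitocomp_parse_error", "no codons found in table"))
  vals <- numeric(0); keys <- character(0)
  bounds <- c(starts, length(toks) + 1L)
  for (k in seq_along(starts)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L] - 1L
    span <- if (hi >= lo) toks[lo:hi] else character()
    nums <- as.numeric(span)
    if (length(nums) == 0L || anyNA(nums))
      stop(.err("mitocomp_parse_error",
                paste("no numeric value for codon", toks[starts[k]])))
    # triples carry (freq/1000, count): prefer the raw count; two-column
    # tables carry a single value
    keys <- c(keys, gsub("U", "T", toupper(toks[starts[k]])))
    vals <- c(vals, nums[length(nums)])
  }
  if (anyDuplicated(keys))
    stop(.err("mitocomp_parse_error", paste(
      "codon listed twice:", keys[duplicated(keys)][1])))
  out <- stats::setNames(rep(0, 64L), .ALL_CODONS)
  out[keys] <- vals
  missing <- setdiff(.ALL_CODONS, keys)
  tot <- sum(out)
  if (tot <= 0)
    stop(.err("mitocomp_parse_error", "codon table sums to zero"))
  raw <- out
  out <- out / tot
  attr(out, "raw") <- raw          # original count scale, for CAI weights
  attr(out, "missing_codons") <- missing
  attr(out, "provenance") <- prov
  out
}

#' Relative adaptiveness weights for the CAI
#'
#' Within each synonymous family of the code, `w(c) = f(c) / max f`
#' where f is the reference frequency. Zero-frequency codons receive a
#' pseudocount (default 0.5, standard Sharp-Li practice) before
#' normalization so that no weight is exactly zero; the pseudocount is
#' applied on the count scale, so tables parsed by [readCodonTable()]
#' (which carry their raw counts as an attribute) behave identically
#' however they were normalized.
#'
#' @param reference reference codon frequencies or counts (named vector
#'   as from [readCodonTable()]).
#' @param code a [GeneticCode-class].
#' @param pseudocount value substituted for zero reference entries.
#' @return list of class `CAIWeights`: `w` (named numeric over sense
#'   codons, max 1 within each family), `provenance`, `tableId`.
#' @export
caiWeights <- function(reference, code = geneticCode(), pseudocount = 0.5) {
  if (!is.null(attr(reference, "raw"))) {
    prov <- attr(reference, "provenance")
    reference <- attr(reference, "raw")
    attr(reference, "provenance") <- prov
  }
  w <- rep(NA_real_, length(senseCodons(code)))
  names(w) <- senseCodons(code)
  for (fam in codonFamilies(code)) {
    f <- reference[fam]
    f[is.na(f)] <- 0
    if (all(f == 0))
      stop(.err("mitocomp_degenerate_reference", paste(
        "reference covers no codon of the family:",
        paste(fam, collapse = ", "))))
    f[f == 0] <- pseudocount
    w[fam] <- f / max(f)
  }
  structure(list(w = w,
                 provenance = attr(reference, "provenance"),
                 tableId = code@tableId),
            class = "CAIWeights")
}

# per-codon weights of a gene (NA for stops/ambiguous/single-codon
# families), in gene order
.codonWeightSeq <- function(cods, weights, code) {
  fams <- codonFamilies(code)
  single <- unlist(fams[vapply(fams, length, integer(1)) == 1L])
  w <- unname(weights$w[cods])
  w[cods %in% c(stopCodons(code), single)] <- NA_real_
  w[!grepl("^[ACGT]{3}$", cods)] <- NA_real_
  w
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of the relative adaptiveness w over the counted sense
#' codons of the gene (computed in log domain). Stop codons, codons
#' containing ambiguity letters, and members of single-codon families
#' (none exist under the invertebrate mitochondrial code) are excluded.
#'
#' @param cds coding sequence, 5'->3'.
#' @param weights a `CAIWeights` object (see [caiWeights()]).
#' @param code a [GeneticCode-class].
#' @return CAI in (0, 1], or `NA` for genes with no countable codons.
#' @export
cai <- function(cds, weights, code = geneticCode()) {
  cods <- splitCodons(cds)
  if (!length(cods))
    stop(.err("mitocomp_invalid_input", "CDS shorter than one codon"))
  w <- .codonWeightSeq(cods, weights, code)
  w <- w[!is.na(w)]
  if (!length(w)) return(NA_real_)
  exp(mean(log(w)))
}

#' Sliding-window CAI profile of a gene
#'
#' CAI in windows of `windowCodons` codons (default 100, i.e. 300 bp)
#' advanced by `stepCodons`; a gene shorter than one window yields a
#' single window covering the whole gene. The whole-gene CAI and the
#' peak (maximum windowed) CAI are reported alongside the profile.
#'
#' @param cds coding sequence, 5'->3'.
#' @param weights a `CAIWeights` object.
#' @param code a [GeneticCode-class].
#' @param windowCodons window size in codons.
#' @param stepCodons step between window starts, in codons.
#' @param gene,genomeId optional labels carried into the result.
#' @return list of class `CAIProfile`: `genome_id`, `gene`,
#'   `window_starts` (1-based codon index), `window_cai`, `gene_cai`,
#'   `peak_cai`.
#' @export
slidingWindowCAI <- function(cds, weights, code = geneticCode(),
                             windowCodons = 100L, stepCodons = 1L,
                             gene = NA_character_,
                             genomeId = NA_character_) {
  cods <- splitCodons(cds)
  n <- length(cods)
  if (!n) stop(.err("mitocomp_invalid_input", "CDS shorter than one codon"))
  w <- .codonWeightSeq(cods, weights, code)
  lw <- log(w)
  geneCai <- if (all(is.na(w))) NA_real_ else exp(mean(lw, na.rm = TRUE))
  if (n <= windowCodons) {
    starts <- 1L
    winCai <- geneCai
  } else {
    starts <- seq.int(1L, n - windowCodons + 1L, by = stepCodons)
    winCai <- vapply(starts, function(s) {
      x <- lw[s:(s + windowCodons - 1L)]
      if (all(is.na(x))) NA_real_ else exp(mean(x, na.rm = TRUE))
    }, numeric(1))
  }
  structure(list(genome_id = genomeId, gene = gene,
                 window_starts = starts, window_cai = winCai,
                 gene_cai = geneCai,
                 peak_cai = if (all(is.na(winCai))) NA_real_
                            else max(winCai, na.rm = TRUE)),
            class = "CAIProfile")
}

#' GC content by codon position
#'
#' G+C fraction at codon positions 1, 2 and 3 over the complete
#' unambiguous codons of a CDS, plus `gc12`, the arithmetic mean of
#' positions 1 and 2 (the ordinate of the neutrality plot).
#'
#' @param cds coding sequence, 5'->3'.
#' @param excludeStops drop stop codons (of the invertebrate mito code)
#'   before tallying; defaults to FALSE (all unambiguous codons count).
#' @param code a [GeneticCode-class], used when `excludeStops = TRUE`.
#' @return list of class `PositionalGC`: `gc1`, `gc2`, `gc3`, `gc12`,
#'   `n_codons`.
#' @export
gcByPosition <- function(cds, excludeStops = FALSE, code = geneticCode()) {
  cods <- splitCodons(cds)
  cods <- cods[grepl("^[ACGT]{3}$", cods)]
  if (excludeStops) cods <- cods[!cods %in% stopCodons(code)]
  if (!length(cods))
    stop(.err("mitocomp_invalid_input", "no countable codons"))
  mat <- do.call(rbind, strsplit(cods, ""))
  gc <- apply(mat, 2, function(col) mean(col %in% c("G", "C")))
  structure(list(gc1 = gc[1], gc2 = gc[2], gc3 = gc[3],
                 gc12 = (gc[1] + gc[2]) / 2, n_codons = length(cods)),
            class = "PositionalGC")
}
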