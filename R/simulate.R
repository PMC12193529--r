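# Seeded synthetic annotated-mitogenome generator: the ground-truth
# source for every analysis stage.

# typical insect mitochondrial gene lengths (nt; PCGs multiples of 3)
.DEFAULT_GENE_LENGTHS <- local({
  pcg <- c(atp6 = 678L, atp8 = 162L, cox1 = 1536L, cox2 = 687L,
           cox3 = 786L, cob = 1137L, nad1 = 939L, nad2 = 1023L,
           nad3 = 354L, nad4 = 1338L, nad4l = 291L, nad5 = 1719L,
           nad6 = 525L)
  trna <- stats::setNames(rep(66L, 22L),
                          .ANCESTRAL_ORDER$gene[
                            geneClassOf(.ANCESTRAL_ORDER$gene) == "tRNA"])
  c(pcg, trna, rrnL = 1326L, rrnS = 789L)
})

#' Specification for a synthetic mitogenome
#'
#' Bundles the generator's controls. The defaults emulate a typical
#' tephritid mitogenome: ~15.9 kb circular genome in the ancestral
#' insect gene order, whole-genome AT ~74%, a mild adenine bias on the
#' heavy strand (AT skew 0.066) and a strong cytosine bias (GC skew
#' -0.227), and synonymous codon usage biased toward A/T-ending codons.
#'
#' @param seed integer seed; all randomness derives from it (per-gene
#'   substreams, so adding a gene does not perturb the others).
#' @param lengthTarget target genome length in nt (the control region
#'   absorbs the slack).
#' @param atPercent target whole-genome AT, in percent (0-100).
#' @param atSkewTarget,gcSkewTarget target heavy-strand skews in (-1,1).
#' @param geneOrder a `GeneOrderSignature` (default the ancestral
#'   order).
#' @param geneLengths named integer vector of per-gene lengths; PCG
#'   entries must be multiples of 3.
#' @param codonBias strength (>= 0) of the bias toward A/T-ending
#'   codons in PCGs; 0 removes it.
#' @param identifier,organism labels for the emitted record.
#' @return list of class `MitogenomeSpec`.
#' @export
mitogenomeSpec <- function(seed = 1L, lengthTarget = 15900L,
                           atPercent = 74, atSkewTarget = 0.066,
                           gcSkewTarget = -0.227,
                           geneOrder = ancestralGeneOrder(),
                           geneLengths = .DEFAULT_GENE_LENGTHS,
                           codonBias = 2,
                           identifier = sprintf("SYN%06d", seed),
                           organism = "Synthetica exempli") {
  if (atPercent <= 0 || atPercent >= 100)
    stop(.err("mitocomp_infeasible_spec", "atPercent must be in (0, 100)"))
  if (abs(atSkewTarget) >= 1 || abs(gcSkewTarget) >= 1)
    stop(.err("mitocomp_infeasible_spec", "skew targets must be in (-1, 1)"))
  pcg <- names(geneLengths)[geneClassOf(names(geneLengths)) == "PCG"]
  if (any(geneLengths[pcg] %% 3L != 0L))
    stop(.err("mitocomp_infeasible_spec", "PCG lengths must be multiples of 3"))
  if (sum(geneLengths) > lengthTarget)
    stop(.err("mitocomp_infeasible_spec",
              "gene lengths exceed the genome length target"))
  if (codonBias < 0)
    stop(.err("mitocomp_infeasible_spec", "codonBias must be >= 0"))
  structure(list(seed = as.integer(seed), lengthTarget = as.integer(lengthTarget),
                 atPercent = atPercent, atSkewTarget = atSkewTarget,
                 gcSkewTarget = gcSkewTarget, geneOrder = geneOrder,
                 geneLengths = geneLengths, codonBias = codonBias,
                 identifier = identifier, organism = organism),
            class = "MitogenomeSpec")
}

# heavy-strand base probabilities implied by the composition targets
.baseProbs <- function(atPercent, atSkew, gcSkew) {
  at <- atPercent / 100
  gc <- 1 - at
  c(A = at * (1 + atSkew) / 2, T = at * (1 - atSkew) / 2,
    G = gc * (1 + gcSkew) / 2, C = gc * (1 - gcSkew) / 2)
}

# counter-based substream: derive a per-component seed below 2^31
.subSeed <- function(seed, counter) {
  (as.numeric(seed) %% 83492791) * 25 + counter
}

# codon sampling weights over the sense codons: positional base
# probabilities times an A/T-third-position bias factor
.codonWeights <- function(p, bias, code) {
  sense <- senseCodons(code)
  mat <- do.call(rbind, strsplit(sense, ""))
  wt <- p[mat[, 1]] * p[mat[, 2]] * p[mat[, 3]]
  wt <- wt * ifelse(mat[, 3] %in% c("A", "T"), 1 + bias, 1)
  stats::setNames(wt / sum(wt), sense)
}

# the A/T-ending bias (and the exclusion of stops) shifts the AT content
# of sampled codons away from the per-base target; calibrate the AT%
# fed to the base probabilities so the sampled expectation hits the
# target
.calibrateCodonAt <- function(atPercent, atSkew, gcSkew, bias, code) {
  expectedAt <- function(theta) {
    wt <- .codonWeights(.baseProbs(theta, atSkew, gcSkew), bias, code)
    mat <- do.call(rbind, strsplit(names(wt), ""))
    sum(wt * rowSums(matrix(mat %in% c("A", "T"), nrow(mat)))) / 3
  }
  f <- function(theta) expectedAt(theta) - atPercent / 100
  if (f(0.5) > 0) return(0.5)
  if (f(99.5) < 0) return(99.5)
  stats::uniroot(f, c(0.5, 99.5), tol = 1e-6)$root
}

# sample a PCG as codons; starts with a start codon, ends with TAA, no
# internal stops by construction
.samplePcg <- function(nCodons, wt, code) {
  starts <- intersect(c("ATG", "ATA", "ATT"), code@startCodons)
  if (!length(starts)) starts <- "ATG"
  body <- sample(names(wt), max(nCodons - 2L, 0L), replace = TRUE, prob = wt)
  paste(c(sample(starts, 1L), body, "TAA"), collapse = "")
}

.complementProbs <- function(p) {
  c(A = p[["T"]], T = p[["A"]], G = p[["C"]], C = p[["G"]])
}

.sampleNoncoding <- function(n, p) {
  if (n <= 0L) return("")
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate an annotated mitogenome with known ground truth
#'
#' Emits a circular genome carrying the 37 genes of `spec$geneOrder`
#' plus a control region, laid out with short random spacers and the CR
#' closing the circle back to *trnI*. PCGs are generated codon-wise
#' (start codon, sense-codon body, TAA stop; no internal stops by
#' construction) with codon weights derived from the composition
#' targets and the A/T-third-position bias; tRNAs, rRNAs, spacers and
#' the CR are filled with skew-matched random nucleotides.
#' Light-strand genes are generated in coding sense and placed
#' reverse-complemented. Base composition hits the AT% target in
#' expectation; the same seed always yields a byte-identical genome.
#'
#' @param spec a `MitogenomeSpec` (see [mitogenomeSpec()]).
#' @return list with `genome` (a [Mitogenome-class]) and `truth`, a
#'   list holding the spec, the per-gene coding-sense sequences, the
#'   realized layout table and the realized whole-genome composition.
#' @export
simulateMitogenome <- function(spec = mitogenomeSpec()) {
  stopifnot(inherits(spec, "MitogenomeSpec"))
  code <- geneticCode(5)
  p <- .baseProbs(spec$atPercent, spec$atSkewTarget, spec$gcSkewTarget)
  order <- spec$geneOrder
  lens <- spec$geneLengths
  missing <- setdiff(order$gene, names(lens))
  if (length(missing))
    stop(.err("mitocomp_infeasible_spec", paste(
      "no length for gene(s):", paste(missing, collapse = ", "))))

  # calibrated codon-sampling AT so PCG regions hit the AT target in
  # expectation despite the A/T-ending bias; light-strand genes are
  # generated in coding sense from complemented probabilities so the
  # deposited (forward) strand carries the target composition
  theta <- .calibrateCodonAt(spec$atPercent, spec$atSkewTarget,
                             spec$gcSkewTarget, spec$codonBias, code)
  pCodon <- .baseProbs(theta, spec$atSkewTarget, spec$gcSkewTarget)
  wtPlus <- .codonWeights(pCodon, spec$codonBias, code)
  wtMinus <- .codonWeights(.complementProbs(pCodon), spec$codonBias, code)
  pMinus <- .complementProbs(p)

  geneSeqs <- stats::setNames(vector("list", nrow(order)), order$gene)
  for (i in seq_len(nrow(order))) {
    g <- order$gene[i]
    minus <- order$orientation[i] == -1L
    set.seed(.subSeed(spec$seed, i))
    geneSeqs[[g]] <- if (geneClassOf(g) == "PCG")
      .samplePcg(lens[[g]] %/% 3L, if (minus) wtMinus else wtPlus, code)
    else .sampleNoncoding(lens[[g]], if (minus) pMinus else p)
  }

  # layout: genes in order with 0-5 nt spacers, CR fills to the target
  set.seed(.subSeed(spec$seed, 1000L))
  spacers <- sample(0:5, nrow(order), replace = TRUE)
  coreLen <- sum(nchar(unlist(geneSeqs))) + sum(spacers)
  crLen <- max(spec$lengthTarget - coreLen, 50L)
  set.seed(.subSeed(spec$seed, 1001L))
  crSeq <- .sampleNoncoding(crLen, p)
  set.seed(.subSeed(spec$seed, 1002L))
  spacerSeqs <- vapply(spacers, .sampleNoncoding, character(1), p = p)

  chunks <- character(0)
  rows <- list()
  pos <- 0L
  for (i in seq_len(nrow(order))) {
    g <- order$gene[i]
    s <- geneSeqs[[g]]
    placed <- if (order$orientation[i] == -1L) reverseComplement(s) else s
    rows[[i]] <- data.frame(gene = g, start = pos,
                            end = pos + nchar(placed),
                            strand = order$orientation[i],
                            geneClass = geneClassOf(g), wrapsOrigin = FALSE,
                            stringsAsFactors = FALSE)
    chunks <- c(chunks, placed, spacerSeqs[i])
    pos <- pos + nchar(placed) + spacers[i]
  }
  rows[[length(rows) + 1L]] <- data.frame(
    gene = "CR", start = pos, end = pos + crLen, strand = 1L,
    geneClass = "CR", wrapsOrigin = FALSE, stringsAsFactors = FALSE)
  chunks <- c(chunks, crSeq)
  seq <- paste(chunks, collapse = "")
  features <- do.call(rbind, rows)
  genome <- Mitogenome(identifier = spec$identifier, sequence = seq,
                       features = features, organism = spec$organism,
                       circular = TRUE)
  truth <- list(spec = spec, genes = lapply(geneSeqs, identity),
                layout = features,
                composition = baseCounts(seq))
  list(genome = genome, truth = truth)
}

#' Simulate divergence of a coding sequence at a target Ka/Ks
#'
#' Proposes single-nucleotide substitutions at uniformly random coding
#' positions (the terminal stop codon is left untouched): proposals
#' creating a stop codon are always rejected; synonymous and
#' nonsynonymous proposals are accepted with relative rates 1 and
#' `omegaTarget` (acceptance probabilities `min(1, 1/omega)` and
#' `min(1, omega)`, so targets above 1 are representable), until
#' `round(divergence x codons)` substitutions have been accepted. The
#' realized synonymous/nonsynonymous substitution counts are returned
#' as ground truth.
#'
#' @param cds coding sequence (5'->3').
#' @param omegaTarget target Ka/Ks (>= 0).
#' @param divergence expected accepted substitutions per codon.
#' @param code a [GeneticCode-class].
#' @param seed integer seed.
#' @return list with `cds` (the mutated sequence), `syn_true` and
#'   `nonsyn_true` (accepted substitution counts by class).
#' @export
simulateDivergence <- function(cds, omegaTarget, divergence,
                               code = geneticCode(), seed = 1L) {
  cds <- toupper(as.character(cds))
  cods <- splitCodons(cds)
  mutable <- seq_along(cods)
  if (cods[length(cods)] %in% stopCodons(code))
    mutable <- mutable[-length(mutable)]
  target <- round(divergence * length(mutable))
  syn <- 0L; nonsyn <- 0L
  if (target > 0L) {
    set.seed(.subSeed(seed, 424243L))
    bases <- c("A", "C", "G", "T")
    pSyn <- min(1, 1 / omegaTarget)
    pNonsyn <- min(1, omegaTarget)
    accepted <- 0L
    guard <- 0L
    while (accepted < target) {
      guard <- guard + 1L
      if (guard > 1e6L)
        stop(.err("mitocomp_invalid_input",
                  "divergence target unreachable (acceptance stalled)"))
      ci <- sample(mutable, 1L)
      pos <- sample(3L, 1L)
      old <- cods[ci]
      cur <- substr(old, pos, pos)
      new <- sample(setdiff(bases, cur), 1L)
      mut <- old
      substr(mut, pos, pos) <- new
      if (!grepl("^[ACGT]{3}$", old)) next
      if (mut %in% stopCodons(code)) next
      isSyn <- code@codonMap[[mut]] == code@codonMap[[old]]
      if (stats::runif(1) < (if (isSyn) pSyn else pNonsyn)) {
        cods[ci] <- mut
        accepted <- accepted + 1L
        if (isSyn) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      }
    }
  }
  list(cds = paste(c(cods, if (nchar(cds) %% 3L)
    substr(cds, nchar(cds) - nchar(cds) %% 3L + 1L, nchar(cds))),
    collapse = ""),
    syn_true = syn, nonsyn_true = nonsyn)
}

#' Emit a synthetic reference codon-usage table
#'
#' Draws per-family codon frequencies from a Dirichlet whose
#' concentration favors A/T-ending codons in proportion to `bias`
#' (gamma draws with shape `1 + bias` for A/T-ending sense codons and 1
#' otherwise, normalized within each family), weights families by a
#' uniform Dirichlet over amino acids, and serializes the result in the
#' Kazusa dialect (`codon freq-per-thousand count` triples) that
#' [readCodonTable()] parses.
#'
#' @param bias >= 0; 0 gives near-uniform within-family usage.
#' @param code a [GeneticCode-class].
#' @param seed integer seed.
#' @param totalCount total codon count distributed over the table.
#' @return list with `text` (the serialized table), `frequencies` (the
#'   exact per-codon relative frequencies drawn) and `counts`.
#' @export
makeReferenceTable <- function(bias = 2, code = geneticCode(), seed = 1L,
                               totalCount = 1e6) {
  if (bias < 0)
    stop(.err("mitocomp_invalid_input", "bias must be >= 0"))
  set.seed(.subSeed(seed, 777777L))
  fams <- codonFamilies(code)
  aaW <- stats::rgamma(length(fams), shape = 1)
  aaW <- aaW / sum(aaW)
  freq <- stats::setNames(rep(0, length(senseCodons(code))),
                          senseCodons(code))
  for (k in seq_along(fams)) {
    fam <- fams[[k]]
    shape <- ifelse(substr(fam, 3, 3) %in% c("A", "T"), 1 + bias, 1)
    x <- stats::rgamma(length(fam), shape = shape)
    freq[fam] <- aaW[k] * x / sum(x)
  }
  counts <- round(freq * totalCount)
  perThousand <- round(1000 * counts / sum(counts), 2)
  lines <- sprintf("%s %6.2f %d", gsub("T", "U", names(freq)),
                   perThousand, counts)
  list(text = paste(lines, collapse = "\n"),
       frequencies = freq, counts = counts)
}
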