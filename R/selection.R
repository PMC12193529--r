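# Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method and the
# GC12-on-GC3 neutrality-plot regression.

# package-level cache of per-code lookup tables (site counts and
# pairwise pathway-averaged difference counts)
.ng86Cache <- new.env(parent = emptyenv())

#' Fractional synonymous / nonsynonymous site counts of a codon
#'
#' For each of the three positions, the fraction of the possible
#' single-nucleotide changes that are synonymous; mutations to stop
#' codons are disregarded (excluded from the denominator), so each codon
#' contributes exactly 3 sites partitioned between the two classes
#' (Nei and Gojobori 1986).
#'
#' @param codon a sense codon of the code.
#' @param code a [GeneticCode-class].
#' @return named numeric `c(syn, nonsyn)`, summing to 3.
#' @examples
#' ng86SiteCounts("TTT")  # syn = 1/3: only TTT->TTC is synonymous
#' @export
ng86SiteCounts <- function(codon, code = geneticCode()) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop(.err("mitocomp_invalid_codon",
              paste("ambiguous or malformed codon:", codon)))
  if (codon %in% stopCodons(code))
    stop(.err("mitocomp_invalid_codon", paste("stop codon:", codon)))
  aa <- code@codonMap[[codon]]
  syn <- 0
  bases <- c("A", "C", "G", "T")
  for (pos in 1:3) {
    nsyn <- 0L; nvalid <- 0L
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      maa <- code@codonMap[[mut]]
      if (maa == "*") next
      nvalid <- nvalid + 1L
      if (maa == aa) nsyn <- nsyn + 1L
    }
    if (nvalid > 0L) syn <- syn + nsyn / nvalid
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# site-count lookup for all sense codons of a code
.siteTable <- function(code) {
  key <- paste0("sites", code@tableId)
  if (!is.null(.ng86Cache[[key]])) return(.ng86Cache[[key]])
  sense <- senseCodons(code)
  tab <- t(vapply(sense, ng86SiteCounts, numeric(2), code = code))
  .ng86Cache[[key]] <- tab
  tab
}

# pathway-averaged (Sd, Nd) for one ordered codon pair: enumerate the
# k! orderings of the differing positions, drop pathways through stop
# codons, average synonymous/nonsynonymous step counts over the rest.
# If every pathway passes through a stop, average over all pathways,
# counting steps into or out of a stop as nonsynonymous.
.pathwayCounts <- function(a, b, code) {
  diffPos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diffPos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(k, list(diffPos),
                  list(diffPos, rev(diffPos)),
                  {
                    p <- list()
                    for (i in 1:3) for (j in setdiff(1:3, i))
                      p[[length(p) + 1L]] <- diffPos[c(i, j, setdiff(1:3, c(i, j)))]
                    p
                  })
  evalPath <- function(ord) {
    cur <- a; sd <- 0L; nd <- 0L; blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      aa1 <- code@codonMap[[cur]]; aa2 <- code@codonMap[[nxt]]
      if (aa1 == "*" || aa2 == "*") blocked <- TRUE
      if (aa1 != "*" && aa1 == aa2) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  paths <- lapply(perms, evalPath)
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, integer(1), "sd")),
    nd = mean(vapply(use, `[[`, integer(1), "nd")))
}

# 64x64 pathway tables, cached per code
.pathwayTables <- function(code) {
  key <- paste0("paths", code@tableId)
  if (!is.null(.ng86Cache[[key]])) return(.ng86Cache[[key]])
  n <- length(.ALL_CODONS)
  sd <- matrix(0, n, n, dimnames = list(.ALL_CODONS, .ALL_CODONS))
  nd <- sd
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    pc <- .pathwayCounts(.ALL_CODONS[i], .ALL_CODONS[j], code)
    sd[i, j] <- pc[["sd"]]; nd[i, j] <- pc[["nd"]]
  }
  out <- list(sd = sd, nd = nd)
  .ng86Cache[[key]] <- out
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -3/4 log(1 - 4p/3)`; `NA` when `p >= 3/4` (saturation).
#'
#' @param p proportion of differences per site.
#' @return corrected number of substitutions per site.
#' @export
jukesCantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Both sequences must be codon-aligned and of equal length (see
#' [codonAlignAndClean()] when they are not). Codon pairs containing
#' ambiguity letters or a stop codon in either sequence are skipped.
#' Sites are averaged over the two sequences; codon pairs differing at
#' more than one position are resolved by equal-weight averaging over
#' all minimal mutational pathways, skipping pathways through stop
#' codons; pS and pN receive the Jukes-Cantor correction. A proportion
#' at or beyond 3/4 is reported as saturated (`note` field) with `NA`
#' rates.
#'
#' @param cdsA,cdsB codon-aligned coding sequences of equal length.
#' @param code a [GeneticCode-class].
#' @param gene,queryId,referenceId optional labels carried into the row.
#' @return one-row data.frame of class `KaKsEstimate`: `gene`,
#'   `query_id`, `reference_id`, `codons_compared`, `S_sites`,
#'   `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `ratio`, `note`.
#' @export
ng86Pairwise <- function(cdsA, cdsB, code = geneticCode(),
                         gene = NA_character_, queryId = NA_character_,
                         referenceId = NA_character_) {
  a <- toupper(as.character(cdsA)); b <- toupper(as.character(cdsB))
  if (nchar(a) != nchar(b))
    stop(.err("mitocomp_alignment_error", sprintf(
      "sequences differ in length (%d vs %d); codon-align first",
      nchar(a), nchar(b))))
  ca <- splitCodons(a); cb <- splitCodons(b)
  if (!length(ca))
    stop(.err("mitocomp_invalid_input", "sequences shorter than one codon"))
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  stops <- stopCodons(code)
  clean <- clean & !(ca %in% stops) & !(cb %in% stops)
  ca <- ca[clean]; cb <- cb[clean]
  nc <- length(ca)
  if (nc == 0L)
    stop(.err("mitocomp_no_data", "no scoreable codon pairs"))
  st <- .siteTable(code)
  S <- (sum(st[ca, "syn"]) + sum(st[cb, "syn"])) / 2
  N <- (sum(st[ca, "nonsyn"]) + sum(st[cb, "nonsyn"])) / 2
  pt <- .pathwayTables(code)
  idx <- cbind(match(ca, .ALL_CODONS), match(cb, .ALL_CODONS))
  Sd <- sum(pt$sd[idx]); Nd <- sum(pt$nd[idx])
  pS <- Sd / S; pN <- Nd / N
  note <- NA_character_
  if (pS >= 0.75 || pN >= 0.75) note <- "saturated"
  Ks <- jukesCantor(pS); Ka <- jukesCantor(pN)
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  out <- data.frame(gene = gene, query_id = queryId,
                    reference_id = referenceId, codons_compared = nc,
                    S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
                    pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
                    note = note, stringsAsFactors = FALSE)
  class(out) <- c("KaKsEstimate", "data.frame")
  out
}

#' Protein-guided pairwise codon alignment
#'
#' Translates both coding sequences (terminal stop codons stripped),
#' aligns the proteins globally with a BLOSUM62 scheme, back-threads the
#' codons through the protein alignment, and removes every codon column
#' containing a gap, an ambiguity letter or an internal stop. The
#' result is a pair of equal-length codon-aligned sequences suitable
#' for [ng86Pairwise()].
#'
#' @param cdsA,cdsB coding sequences, possibly of different lengths.
#' @param code a [GeneticCode-class].
#' @param minIdentity minimum aligned protein identity below which the
#'   pair is rejected as dissimilar.
#' @return list with elements `a` and `b` (cleaned, equal length) and
#'   `identity` (aligned protein identity).
#' @export
codonAlignAndClean <- function(cdsA, cdsB, code = geneticCode(),
                               minIdentity = 0.2) {
  prep <- function(x) {
    cods <- splitCodons(x)
    if (!length(cods))
      stop(.err("mitocomp_invalid_input", "CDS shorter than one codon"))
    if (cods[length(cods)] %in% stopCodons(code))
      cods <- cods[-length(cods)]
    if (!length(cods))
      stop(.err("mitocomp_no_data", "CDS contains only a stop codon"))
    cods
  }
  ca <- prep(cdsA); cb <- prep(cdsB)
  pa <- paste(translateCodons(ca, code), collapse = "")
  pb <- paste(translateCodons(cb, code), collapse = "")
  # '*'/'X' are not BLOSUM62 rows; mask internal stops/ambiguity as X
  ali <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chartr("*", "X", pa)),
    Biostrings::AAString(chartr("*", "X", pb)),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  sa <- strsplit(as.character(Biostrings::alignedPattern(ali)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(ali)), "")[[1]]
  ia <- cumsum(sa != "-"); ib <- cumsum(sb != "-")
  keep <- sa != "-" & sb != "-"
  matched <- sum(sa[keep] == sb[keep])
  identity <- if (any(keep)) matched / sum(keep) else 0
  colsA <- ca[ia[keep]]; colsB <- cb[ib[keep]]
  ok <- grepl("^[ACGT]{3}$", colsA) & grepl("^[ACGT]{3}$", colsB) &
    !(colsA %in% stopCodons(code)) & !(colsB %in% stopCodons(code))
  if (!any(ok))
    stop(.err("mitocomp_no_data", "no aligned codon columns after cleaning"))
  if (identity < minIdentity)
    stop(.err("mitocomp_no_data", sprintf(
      "aligned protein identity %.2f below %.2f: no significant similarity",
      identity, minIdentity)))
  list(a = paste(colsA[ok], collapse = ""),
       b = paste(colsB[ok], collapse = ""),
       identity = identity)
}

#' Neutrality-plot regression (GC12 on GC3)
#'
#' Ordinary least squares of GC content at codon positions 1+2 on GC
#' content at position 3 across species. The slope decomposes the
#' forces shaping codon usage: mutation pressure percentage =
#' slope x 100, selection percentage = (1 - slope) x 100.
#'
#' @param gc3,gc12 numeric vectors (one point per species), or `gc12`
#'   omitted and `gc3` a list of `PositionalGC` objects.
#' @param gene optional gene label.
#' @return one-row data.frame of class `NeutralityFit`: `gene`,
#'   `n_species`, `slope`, `intercept`, `r_squared`,
#'   `mutation_pressure_pct`, `selection_pct`.
#' @export
neutralityFit <- function(gc3, gc12 = NULL, gene = NA_character_) {
  if (is.null(gc12)) {
    pts <- gc3
    gc3 <- vapply(pts, function(p) p$gc3, numeric(1))
    gc12 <- vapply(pts, function(p) p$gc12, numeric(1))
  }
  keep <- stats::complete.cases(gc3, gc12)
  gc3 <- gc3[keep]; gc12 <- gc12[keep]
  if (length(gc3) < 3L)
    stop(.err("mitocomp_invalid_input", "need at least 3 points"))
  if (stats::var(gc3) == 0)
    stop(.err("mitocomp_undefined_fit", "zero variance in GC3"))
  fit <- stats::lm(gc12 ~ gc3)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ssTot <- sum((gc12 - mean(gc12))^2)
  r2 <- if (ssTot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ssTot
  out <- data.frame(gene = gene, n_species = length(gc3), slope = slope,
                    intercept = intercept, r_squared = r2,
                    mutation_pressure_pct = 100 * slope,
                    selection_pct = 100 * (1 - slope),
                    stringsAsFactors = FALSE)
  class(out) <- c("NeutralityFit", "data.frame")
  out
}

#' Retain genes with high Ka/Ks
#'
#' Averages the Ka/Ks ratio per gene across species and retains genes
#' whose mean reaches the threshold (default 0.9, which keeps near-
#' neutral genes alongside those at or above 1).
#'
#' @param estimates data.frame of Ka/Ks rows (as from [ng86Pairwise()],
#'   row-bound across species and genes).
#' @param threshold minimum mean ratio for retention.
#' @return character vector of retained gene names.
#' @export
selectHighRateGenes <- function(estimates, threshold = 0.9) {
  means <- tapply(estimates$ratio, estimates$gene, mean, na.rm = TRUE)
  sort(names(means)[!is.na(means) & means >= threshold])
}
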