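# Shared fixture builders: everything is generated in code.

# assemble a Mitogenome from coding-sense gene sequences laid out in the
# given chromosomal order (no spacers); orientation -1 genes are placed
# reverse-complemented
buildGenomeFromGenes <- function(geneSeqs, order, id = "FIX001",
                                 circular = TRUE, crSeq = NULL) {
  stopifnot(all(order$gene %in% names(geneSeqs)))
  pos <- 0L
  chunks <- character()
  rows <- list()
  for (i in seq_len(nrow(order))) {
    g <- order$gene[i]
    s <- geneSeqs[[g]]
    placed <- if (order$orientation[i] == -1L) reverseComplement(s) else s
    rows[[i]] <- data.frame(gene = g, start = pos, end = pos + nchar(placed),
                            strand = order$orientation[i],
                            geneClass = geneClassOf(g), wrapsOrigin = FALSE,
                            stringsAsFactors = FALSE)
    chunks <- c(chunks, placed)
    pos <- pos + nchar(placed)
  }
  if (!is.null(crSeq)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = "CR", start = pos, end = pos + nchar(crSeq), strand = 1L,
      geneClass = "CR", wrapsOrigin = FALSE, stringsAsFactors = FALSE)
    chunks <- c(chunks, crSeq)
  }
  Mitogenome(identifier = id, sequence = paste(chunks, collapse = ""),
             features = do.call(rbind, rows), circular = circular)
}

# one cached default synthetic genome per session (generation is seeded,
# so this is reproducible)
.fixtureEnv <- new.env()
defaultSim <- function(seed = 11) {
  key <- paste0("sim", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- simulateMitogenome(mitogenomeSpec(seed = seed))
  .fixtureEnv[[key]]
}

# random DNA string
randomDna <- function(n, p = c(A = .25, C = .25, G = .25, T = .25)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random CDS of sense codons under a code (no stops), for CAI/RSCU tests
randomCds <- function(nCodons, code = geneticCode()) {
  paste(sample(senseCodons(code), nCodons, replace = TRUE), collapse = "")
}

# independent oracle: NG86 site counts of one codon by direct
# enumeration of its nine single-nucleotide mutants
oracleSiteCounts <- function(codon, code) {
  map <- code@codonMap
  syn <- 0
  for (pos in 1:3) {
    muts <- character()
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      m <- codon
      substr(m, pos, pos) <- b
      muts <- c(muts, m)
    }
    aas <- map[muts]
    valid <- aas != "*"
    if (any(valid)) syn <- syn + sum(aas[valid] == map[[codon]]) / sum(valid)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# independent oracle: pathway-averaged (Sd, Nd) between two codons by
# explicit recursive enumeration of orderings of the differing sites
oraclePathwayCounts <- function(a, b, code) {
  map <- code@codonMap
  diffPos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(diffPos)) return(c(sd = 0, nd = 0))
  results <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      results[[length(results) + 1L]] <<- list(sd = sd, nd = nd,
                                               blocked = blocked)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      stepBlocked <- map[[cur]] == "*" || map[[nxt]] == "*"
      stepSyn <- !stepBlocked && map[[cur]] == map[[nxt]]
      recurse(nxt, setdiff(remaining, pos),
              sd + as.integer(stepSyn),
              nd + as.integer(!stepSyn),
              blocked || stepBlocked)
    }
  }
  recurse(a, diffPos, 0L, 0L, FALSE)
  ok <- !vapply(results, `[[`, logical(1), "blocked")
  use <- if (any(ok)) results[ok] else results
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}
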