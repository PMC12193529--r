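code5 <- geneticCode(5)

test_that("codon counting handles stops, trailing bases and ambiguity", {
  cc <- codonCounts("TTATTATAA", code5)
  expect_equal(cc$counts[["TTA"]], 2L)
  expect_equal(cc$counts[["TAA"]], 1L)   # stop kept in the 64-map
  expect_equal(cc$excluded, 0L)
  expect_equal(cc$trailing_nt, 0L)

  cc2 <- codonCounts("TTATT", code5)
  expect_equal(cc2$counts[["TTA"]], 1L)
  expect_equal(cc2$trailing_nt, 2L)

  cc3 <- codonCounts("TTNTTA", code5)
  expect_equal(cc3$counts[["TTA"]], 1L)
  expect_equal(cc3$excluded, 1L)
  expect_equal(sum(cc3$counts) + cc3$excluded, cc3$n_codons)

  expect_error(codonCounts("TT", code5), class = "mitocomp_invalid_input")
})

test_that("RSCU follows the definition and its limits", {
  # only TTA used in the 6-fold Leu family
  cc <- codonCounts(strrep("TTA", 4), code5)
  r <- rscu(cc, code5)
  expect_equal(r[["TTA"]], 6)
  expect_equal(unname(r[c("TTG", "CTA", "CTT")]), c(0, 0, 0))
  # uniform use within a family gives RSCU 1 everywhere
  r2 <- rscu(codonCounts("TTATTGCTTCTCCTACTG", code5), code5)
  expect_equal(unname(r2[codonFamilies(code5)[["L"]]]), rep(1, 6))
  # direct formula on a mixed family
  counts <- setNames(rep(0L, 64), names(codonCounts("AAA", code5)$counts))
  counts[c("TTA", "TTG", "CTA")] <- c(3L, 1L, 2L)
  r3 <- rscu(counts, code5)
  expect_equal(r3[["TTA"]], 3 * 6 / 6)
  expect_equal(r3[["CTA"]], 2 * 6 / 6)
  # untouched families are undefined, not zero
  expect_true(is.na(r3[["GGA"]]))
})

test_that("RSCU family sums equal family size on random count tables", {
  set.seed(123)
  for (code in list(code5, geneticCode(1))) {
    fams <- codonFamilies(code)
    for (i in 1:40) {
      counts <- setNames(rpois(length(senseCodons(code)), 10),
                         senseCodons(code))
      r <- rscu(counts, code)
      for (fam in fams) {
        if (sum(counts[fam]) > 0)
          expect_equal(sum(r[fam]), length(fam), tolerance = 1e-9)
      }
    }
  }
})

test_that("reference tables parse in Kazusa and two-column dialects", {
  kaz <- "UUU 26.1 (123) UUC 20.0 (94)\nUUA 80.5 (380)"
  f <- readCodonTable(text = kaz)
  expect_equal(sum(f), 1)
  expect_equal(unname(f[["TTT"]]), 123 / (123 + 94 + 380))
  expect_true("GGG" %in% attr(f, "missing_codons"))

  twocol <- paste(sprintf("%s 10", names(f)), collapse = "\n")
  u <- readCodonTable(text = twocol)
  expect_equal(as.vector(u), rep(1 / 64, 64))
  expect_length(attr(u, "missing_codons"), 0L)

  expect_error(readCodonTable(text = "UUU abc"),
               class = "mitocomp_parse_error")
})

test_that("CAI weights normalize within families with the 0.5 pseudocount", {
  counts <- setNames(rep(10, 64), names(readCodonTable(text = "AAA 1")))
  ref <- counts / sum(counts)
  w <- caiWeights(ref, code5)
  expect_equal(unname(w$w[senseCodons(code5)]),
               rep(1, 62))  # equal frequencies: all weights 1
  # family (8, 2) -> w (1, 0.25); family (5, 0) with pseudocount -> (1, 0.1)
  counts2 <- counts
  counts2[codonFamilies(code5)[["F"]]] <- c(8, 2)       # TTT, TTC
  counts2[codonFamilies(code5)[["K"]]] <- c(5, 0)       # AAA, AAG
  w2 <- caiWeights(counts2, code5)
  fam <- codonFamilies(code5)[["F"]]
  expect_equal(unname(w2$w[fam]), c(1, 0.25))
  famK <- codonFamilies(code5)[["K"]]
  expect_equal(unname(w2$w[famK]), c(1, 0.1))
  # a family with no reference mass at all is degenerate
  counts3 <- counts
  counts3[codonFamilies(code5)[["W"]]] <- 0
  expect_error(caiWeights(counts3, code5),
               class = "mitocomp_degenerate_reference")
})

test_that("CAI is a geometric mean with the documented invariances", {
  set.seed(5)
  tab <- makeReferenceTable(bias = 1.5, code = code5, seed = 9)
  ref <- readCodonTable(text = tab$text)
  w <- caiWeights(ref, code5)
  # maximal-w gene has CAI exactly 1
  best <- vapply(codonFamilies(code5), function(fam)
    fam[which.max(w$w[fam])], character(1))
  gene <- paste(sample(best, 60, replace = TRUE), collapse = "")
  expect_equal(cai(gene, w, code5), 1)
  # two-codon gene with w = 1 and 0.25
  refF <- setNames(rep(10, 64), names(ref))
  refF[codonFamilies(code5)[["F"]]] <- c(8, 2)
  wF <- caiWeights(refF, code5)
  expect_equal(cai("TTTTTC", wF, code5), sqrt(1 * 0.25))
  # log-domain oracle on random genes
  for (i in 1:25) {
    cds <- randomCds(sample(30:120, 1), code5)
    cods <- splitCodons(cds)
    oracle <- exp(mean(log(w$w[cods])))
    expect_equal(cai(cds, w, code5), oracle, tolerance = 1e-12)
    # permutation invariance
    perm <- paste(sample(cods), collapse = "")
    expect_equal(cai(perm, w, code5), cai(cds, w, code5))
  }
  # scale invariance of the reference (zero-free table)
  countsA <- pmax(tab$counts, 1)
  wA <- caiWeights(countsA, code5)
  wB <- caiWeights(countsA * 1000, code5)
  cds <- randomCds(80, code5)
  expect_equal(wA$w, wB$w)
  expect_equal(cai(cds, wA, code5), cai(cds, wB, code5))
})

test_that("sliding windows reduce to the whole-gene CAI when they should", {
  tab <- makeReferenceTable(bias = 1, code = code5, seed = 21)
  w <- caiWeights(readCodonTable(text = tab$text), code5)
  # homogeneous gene: every window equals the gene value
  gene <- strrep("TTA", 150)
  pr <- slidingWindowCAI(gene, w, code5)
  expect_equal(unique(pr$window_cai), pr$gene_cai)
  expect_equal(pr$peak_cai, max(pr$window_cai))
  # gene of exactly one window
  g100 <- randomCds(100, code5)
  pr100 <- slidingWindowCAI(g100, w, code5)
  expect_length(pr100$window_cai, 1L)
  expect_equal(pr100$window_cai, pr100$gene_cai)
  # shorter than a window: one window covering the gene
  g30 <- randomCds(30, code5)
  pr30 <- slidingWindowCAI(g30, w, code5)
  expect_length(pr30$window_cai, 1L)
  expect_equal(pr30$window_cai, cai(g30, w, code5))
})

test_that("a high-adaptiveness block shows up as the window peak", {
  # weights: Phe family (8, 2) -> low codon TTC w 0.25, high TTT w 1
  refF <- setNames(rep(10, 64), names(readCodonTable(text = "AAA 1")))
  refF[c("TTT", "TTC")] <- c(8, 2)
  wF <- caiWeights(refF, code5)
  lowBlock <- strrep("TTC", 150)
  highBlock <- strrep("TTT", 100)
  gene <- paste0(lowBlock, highBlock, lowBlock)
  pr <- slidingWindowCAI(gene, wF, code5)
  expect_equal(pr$peak_cai, 1)              # the pure high-w block
  peakAt <- pr$window_starts[which.max(pr$window_cai)]
  expect_equal(peakAt, 151)
  expect_lt(pr$gene_cai, pr$peak_cai)
})

test_that("positional GC matches hand enumeration", {
  expect_equal(gcByPosition("GCGCGC")$gc1, 1)
  expect_equal(gcByPosition("GCGCGC")$gc3, 1)
  expect_equal(gcByPosition("ATATAT")$gc12, 0)
  cds <- "ATGGCTTTAGGCACCAATTGAGCCTAAGGGTTT"  # 11 codons
  cods <- splitCodons(cds)
  mat <- do.call(rbind, strsplit(cods, ""))
  want <- colMeans(matrix(mat %in% c("G", "C"), nrow(mat)))
  got <- gcByPosition(cds)
  expect_equal(c(got$gc1, got$gc2, got$gc3), unname(want))
  expect_equal(got$gc12, (want[1] + want[2]) / 2)
  expect_equal(got$n_codons, 11L)
})
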