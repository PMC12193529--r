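code5 <- geneticCode(5)

test_that("simulated genomes carry the full annotation in the stated order", {
  sim <- defaultSim()
  g <- sim$genome
  ft <- featureTable(g)
  expect_equal(nrow(ft), 38L)  # 37 genes + CR
  expect_setequal(ft$gene, c(canonicalGeneNames(), "CR"))
  sig <- geneOrderSignature(g)
  expect_equal(sig$index, ancestralGeneOrder()$index)
  # PCGs: start codon, terminal TAA, no internal stops
  for (gene in concatOrder("PCG")) {
    s <- extractGene(g, gene)
    cods <- splitCodons(s)
    expect_true(cods[1] %in% code5@startCodons)
    expect_identical(cods[length(cods)], "TAA")
    expect_false(any(cods[-length(cods)] %in% stopCodons(code5)))
  }
})

test_that("the same seed reproduces a byte-identical genome", {
  a <- simulateMitogenome(mitogenomeSpec(seed = 123))
  b <- simulateMitogenome(mitogenomeSpec(seed = 123))
  expect_identical(as.character(genomeSequence(a$genome)),
                   as.character(genomeSequence(b$genome)))
  expect_identical(featureTable(a$genome), featureTable(b$genome))
  c <- simulateMitogenome(mitogenomeSpec(seed = 124))
  expect_false(identical(as.character(genomeSequence(a$genome)),
                         as.character(genomeSequence(c$genome))))
})

test_that("truth records are self-consistent with the analysis modules", {
  sim <- defaultSim()
  g <- sim$genome
  for (gene in c("cox1", "nad5", "trnI", "rrnS"))
    expect_identical(extractGene(g, gene), sim$truth$genes[[gene]])
  expect_equal(sim$truth$composition,
               baseCounts(as.character(genomeSequence(g))))
  expect_identical(sim$truth$layout$gene,
                   featureTable(g)$gene)
})

test_that("generator output parses cleanly through the GenBank reader", {
  sim <- defaultSim()
  tmp <- tempfile(fileext = ".gb")
  expect_no_warning(writeGenBank(sim$genome, tmp))
  expect_no_warning(g2 <- readGenBank(tmp))
  expect_equal(genomeLength(g2), genomeLength(sim$genome))
})

test_that("infeasible specs are rejected", {
  expect_error(mitogenomeSpec(atPercent = 110),
               class = "mitocomp_infeasible_spec")
  expect_error(mitogenomeSpec(atSkewTarget = 1.2),
               class = "mitocomp_infeasible_spec")
  expect_error(mitogenomeSpec(lengthTarget = 1000L),
               class = "mitocomp_infeasible_spec")
  lens <- mitogenomeSpec()$geneLengths
  lens[["cox1"]] <- 100L  # not a multiple of 3
  expect_error(mitogenomeSpec(geneLengths = lens),
               class = "mitocomp_infeasible_spec")
})

test_that("divergence simulation honours its acceptance rules", {
  cds <- paste0("ATG", randomCds(150, code5), "TAA")
  none <- simulateDivergence(cds, 1, 0, code5, seed = 3)
  expect_identical(none$cds, cds)
  expect_equal(none$syn_true + none$nonsyn_true, 0L)

  onlySyn <- simulateDivergence(cds, 0, 0.2, code5, seed = 4)
  expect_equal(onlySyn$nonsyn_true, 0L)
  expect_gt(onlySyn$syn_true, 0L)
  # no stops ever created
  cods <- splitCodons(onlySyn$cds)
  expect_false(any(cods[-length(cods)] %in% stopCodons(code5)))
  # observed differences never exceed the recorded truth (multiple hits
  # at one site can coincide or revert)
  a <- splitCodons(cds); b <- splitCodons(onlySyn$cds)
  nDiff <- sum(mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b))
  expect_lte(nDiff, onlySyn$syn_true)
  expect_gt(nDiff, 0L)

  both <- simulateDivergence(cds, 0.5, 0.1, code5, seed = 5)
  expect_equal(both$syn_true + both$nonsyn_true,
               round(0.1 * 150))  # terminal stop is immutable
  expect_identical(simulateDivergence(cds, 0.5, 0.1, code5, seed = 5)$cds,
                   both$cds)
})

test_that("reference tables round-trip and respond to the AT bias", {
  tab <- makeReferenceTable(bias = 2, code = code5, seed = 6)
  ref <- readCodonTable(text = tab$text)
  sense <- senseCodons(code5)
  expect_equal(unname(ref[sense]),
               unname(tab$counts[sense] / sum(tab$counts)),
               tolerance = 1e-9)
  expect_equal(unname(ref[sense]), unname(tab$frequencies),
               tolerance = 2e-5)   # integer-count rounding only

  # extreme bias: an all-A/T-ending gene approaches CAI 1
  hot <- makeReferenceTable(bias = 500, code = code5, seed = 7)
  w <- caiWeights(readCodonTable(text = hot$text), code5)
  atEnding <- sense[substr(sense, 3, 3) %in% c("A", "T")]
  gene <- paste(sample(atEnding, 100, replace = TRUE), collapse = "")
  expect_gt(cai(gene, w, code5), 0.9)

  # bias 0: within-family frequencies near-uniform on average
  flat <- sapply(1:40, function(s)
    makeReferenceTable(bias = 0, code = code5, seed = s)$frequencies)
  fam <- codonFamilies(code5)[["L"]]
  shares <- rowMeans(apply(flat[fam, ], 2, function(x) x / sum(x)))
  expect_true(all(abs(shares - 1 / 6) < 0.08))
})

test_that("replicated genomes hit the AT% target in expectation", {
  ats <- vapply(1:60, function(s) {
    g <- simulateMitogenome(mitogenomeSpec(seed = 2000 + s,
                                           atPercent = 75))$genome
    skewTable(g, "whole_genome")$at_percent
  }, numeric(1))
  expect_lt(abs(mean(ats) - 75), 0.5)
})
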