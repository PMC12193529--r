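test_that("generator records round-trip through the GenBank writer/parser", {
  g <- defaultSim()$genome
  txt <- writeGenBank(g)
  g2 <- readGenBank(text = txt)
  expect_equal(nrow(featureTable(g2)), 38L)  # 37 genes + CR
  expect_identical(as.character(genomeSequence(g2)),
                   as.character(genomeSequence(g)))
  ft1 <- featureTable(g); ft1 <- ft1[order(ft1$gene), ]
  ft2 <- featureTable(g2); ft2 <- ft2[order(ft2$gene), ]
  rownames(ft1) <- rownames(ft2) <- NULL
  expect_identical(ft2, ft1)
  expect_true(isCircularGenome(g2))
  # parse -> serialize is a fixed point
  expect_identical(writeGenBank(g2), txt)
})

.gbRecord <- function(features, seq, circular = TRUE) {
  c(sprintf("LOCUS       TEST%17d bp    DNA     %s INV", nchar(seq),
            if (circular) "circular" else "linear"),
    "DEFINITION  synthetic test record.",
    "ACCESSION   TEST",
    "FEATURES             Location/Qualifiers",
    features,
    "ORIGIN",
    sprintf("%9d %s", 1L, tolower(seq)),
    "//")
}

test_that("coordinates, strands and dialect names parse from GenBank", {
  seq <- strrep("ACGT", 30)  # 120 bp
  rec <- .gbRecord(c(
    '     CDS             5..22',
    '                     /gene="COI"',
    '     tRNA            complement(31..52)',
    '                     /gene="trnQ"',
    '     rRNA            60..80',
    '                     /product="16S ribosomal RNA"'), seq)
  g <- readGenBank(text = rec)
  ft <- featureTable(g)
  expect_setequal(ft$gene, c("cox1", "trnQ", "rrnL"))
  # 1-based inclusive 5..22 becomes 0-based half-open [4, 22)
  expect_equal(ft$start[ft$gene == "cox1"], 4L)
  expect_equal(ft$end[ft$gene == "cox1"], 22L)
  expect_equal(ft$strand[ft$gene == "trnQ"], -1L)
  expect_equal(ft$geneClass[ft$gene == "rrnL"], "rRNA")
})

test_that("origin-spanning joins on circular records wrap", {
  seq <- strrep("ACGT", 30)
  rec <- .gbRecord(c(
    '     tRNA            join(110..120,1..11)',
    '                     /gene="trnI"'), seq)
  g <- readGenBank(text = rec)
  ft <- featureTable(g)
  expect_true(ft$wrapsOrigin)
  expect_equal(ft$start, 109L)
  expect_equal(ft$end, 11L)
  expect_equal(nchar(extractGene(g, "trnI")), (120L - 109L) + 11L)
})

test_that("annotation conflicts and malformed records raise typed errors", {
  seq <- strrep("ACGT", 30)
  dup <- .gbRecord(c(
    '     CDS             5..22',
    '                     /gene="COI"',
    '     CDS             30..60',
    '                     /gene="cox1"'), seq)
  err <- tryCatch(readGenBank(text = dup), error = identity)
  expect_s3_class(err, "mitocomp_annotation_conflict")
  expect_match(conditionMessage(err), "cox1")
  expect_match(conditionMessage(err), "5..22")

  bad <- .gbRecord('     CDS             5..twenty', seq)
  err2 <- tryCatch(readGenBank(text = bad), error = identity)
  expect_s3_class(err2, "mitocomp_parse_error")
  expect_match(conditionMessage(err2), "twenty")

  expect_error(readGenBank(text = "no locus here"),
               class = "mitocomp_parse_error")
})

test_that("tRNA copies resolve from anticodon qualifiers and position", {
  seq <- strrep("ACGT", 60)  # 240 bp
  rec <- .gbRecord(c(
    '     tRNA            1..22',
    '                     /product="tRNA-Ser"',
    '                     /anticodon=(pos:8..10,aa:Ser,seq:gct)',
    '     tRNA            30..52',
    '                     /product="tRNA-Ser"',
    '                     /anticodon=(pos:38..40,aa:Ser,seq:tga)'), seq)
  ft <- featureTable(readGenBank(text = rec))
  expect_identical(ft$gene[ft$start == 0L], "trnS1")
  expect_identical(ft$gene[ft$start == 29L], "trnS2")
})

test_that("a bare gene feature is superseded by its typed feature", {
  seq <- strrep("ACGT", 30)
  rec <- .gbRecord(c(
    '     gene            5..22',
    '                     /gene="COI"',
    '     CDS             5..22',
    '                     /gene="COI"'), seq)
  ft <- featureTable(readGenBank(text = rec))
  expect_equal(nrow(ft), 1L)
  expect_identical(ft$geneClass, "PCG")
})
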