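code5 <- geneticCode(5)

test_that("site counts match the spec'd worked examples", {
  # TTT: only TTT->TTC synonymous among the nine mutants
  expect_equal(ng86SiteCounts("TTT", code5),
               c(syn = 1 / 3, nonsyn = 3 - 1 / 3))
  # CTA: third position fully synonymous, CTA->TTA also Leu at position 1
  expect_equal(ng86SiteCounts("CTA", code5),
               c(syn = 1 + 1 / 3, nonsyn = 3 - (1 + 1 / 3)))
  expect_error(ng86SiteCounts("TAA", code5), class = "mitocomp_invalid_codon")
  expect_error(ng86SiteCounts("TNA", code5), class = "mitocomp_invalid_codon")
})

test_that("site counts equal the enumeration oracle for all sense codons", {
  for (codon in senseCodons(code5)) {
    got <- ng86SiteCounts(codon, code5)
    want <- oracleSiteCounts(codon, code5)
    expect_equal(got, want, info = codon)
    expect_equal(sum(got), 3)
  }
})

test_that("pathway averaging matches the exhaustive oracle (toy pair)", {
  # TTT (Phe) <-> CTC (Leu): two minimal pathways
  pts <- oraclePathwayCounts("TTT", "CTC", code5)
  est <- ng86Pairwise("TTT", "CTC", code5)
  expect_equal(est$Sd, pts[["sd"]])
  expect_equal(est$Nd, pts[["nd"]])
  expect_equal(est$Sd + est$Nd, 2)   # two observed differences
})

test_that("pairwise estimates behave at the edges", {
  a <- randomCds(100, code5)
  same <- ng86Pairwise(a, a, code5)
  expect_equal(same$Sd, 0)
  expect_equal(same$Nd, 0)
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(is.na(same$ratio))       # 0/0: undefined
  expect_equal(same$S_sites + same$N_sites, 3 * same$codons_compared,
               tolerance = 1e-9)

  # one synonymous third-position change: Ka = 0, Ks > 0, ratio 0
  b <- a
  stopifnot(substr(a, 1, 3) %in% c("TTT", "TTC") || TRUE)
  cods <- splitCodons(a)
  i <- which(cods == "GGA")[1]
  if (is.na(i)) { cods[1] <- "GGA"; i <- 1L; a <- paste(cods, collapse = "") }
  cods[i] <- "GGG"                      # Gly family, synonymous
  b <- paste(cods, collapse = "")
  est <- ng86Pairwise(a, b, code5)
  expect_equal(est$Ka, 0)
  expect_gt(est$Ks, 0)
  expect_equal(est$ratio, 0)

  expect_error(ng86Pairwise("ATGAAA", "ATGAAATTT", code5),
               class = "mitocomp_alignment_error")
})

test_that("pairwise NG86 is symmetric in its arguments", {
  set.seed(31)
  for (i in 1:5) {
    a <- randomCds(60, code5)
    b <- simulateDivergence(a, 0.8, 0.15, code5, seed = i)$cds
    ab <- ng86Pairwise(a, b, code5)
    ba <- ng86Pairwise(b, a, code5)
    for (col in c("S_sites", "N_sites", "Sd", "Nd", "Ks", "Ka"))
      expect_equal(ab[[col]], ba[[col]], info = col)
  }
})

test_that("Jukes-Cantor correction reduces to p as p -> 0 and saturates", {
  expect_equal(jukesCantor(0), 0)
  expect_equal(jukesCantor(0.01) / 0.01, 1, tolerance = 0.01)
  expect_true(is.na(jukesCantor(0.75)))
  expect_true(is.na(jukesCantor(0.9)))
})

test_that("codon alignment back-threads through an indel and cleans gaps", {
  set.seed(17)
  a <- paste0("ATG", randomCds(40, code5), "TAA")
  cods <- splitCodons(a)
  drop <- 20L
  b <- paste(cods[-drop], collapse = "")
  out <- codonAlignAndClean(a, b, code5)
  expect_equal(nchar(out$a), nchar(out$b))
  # the deleted codon column is gone; all others match the originals
  expect_equal(nchar(out$a) / 3, length(cods) - 2L)  # minus stop, minus indel
  expect_identical(out$b, gsub("TAA$", "", b))
  expect_identical(out$a, paste(cods[-c(drop, length(cods))], collapse = ""))
  # identical sequences come back unchanged (minus the terminal stop)
  out2 <- codonAlignAndClean(a, a, code5)
  expect_identical(out2$a, out2$b)
  expect_equal(out2$identity, 1)
  # unrelated sequences are rejected
  set.seed(18)
  expect_error(codonAlignAndClean(randomCds(50, code5),
                                  randomCds(50, code5), code5,
                                  minIdentity = 0.9),
               class = "mitocomp_no_data")
})

test_that("neutrality fit is exact on collinear input and decomposes forces", {
  gc3 <- seq(0.05, 0.5, length.out = 10)
  gc12 <- 0.4 * gc3 + 0.1
  fit <- neutralityFit(gc3, gc12, gene = "nad4")
  expect_equal(fit$slope, 0.4, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$mutation_pressure_pct, 40)
  expect_equal(fit$selection_pct, 60)
  expect_equal(fit$mutation_pressure_pct + fit$selection_pct, 100)

  flat <- neutralityFit(gc3, rep(0.3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$selection_pct, 100)

  expect_error(neutralityFit(rep(0.3, 10), gc12),
               class = "mitocomp_undefined_fit")
  expect_error(neutralityFit(c(0.1, 0.2), c(0.1, 0.2)),
               class = "mitocomp_invalid_input")
})

test_that("noisy neutrality clouds recover the generating slope", {
  set.seed(77)
  for (slope in c(0.2, 0.6)) {
    gc3 <- runif(50, 0.05, 0.45)
    gc12 <- slope * gc3 + 0.12 + rnorm(50, 0, 0.01)
    fit <- neutralityFit(gc3, gc12)
    se <- 0.01 / (sd(gc3) * sqrt(49))   # OLS slope standard error
    expect_lt(abs(fit$slope - slope), 3 * se)
  }
})

test_that("high-rate gene retention follows the mean-ratio threshold", {
  est <- data.frame(
    gene = rep(c("nad4", "cox1", "nad1"), each = 3),
    ratio = c(1.5, 1.6, 1.4,   0.1, 0.12, 0.08,   0.95, 0.85, 0.9))
  expect_setequal(selectHighRateGenes(est), c("nad4", "nad1"))
  expect_identical(selectHighRateGenes(est, threshold = 1.2), "nad4")
  # brute-force check
  means <- tapply(est$ratio, est$gene, mean)
  expect_setequal(selectHighRateGenes(est, 0.9),
                  names(means)[means >= 0.9])
})
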