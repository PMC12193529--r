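#' Genetic code with synonymous-family structure
#'
#' Wraps an NCBI translation table as an S4 object carrying the codon to
#' amino-acid map, the start and stop codon sets, and the synonymous
#' families (equivalence classes of sense codons coding for the same
#' amino acid). The default, table 5, is the invertebrate mitochondrial
#' code, under which TGA codes Trp, ATA codes Met, AGA/AGG code Ser and
#' only TAA/TAG are stops, leaving 62 sense codons.
#'
#' @slot tableId NCBI translation-table number.
#' @slot codonMap named character vector of length 64 mapping codon to
#'   one-letter amino acid, `"*"` for stops.
#' @slot startCodons character vector of initiation codons.
#' @slot stopCodons character vector of stop codons.
#' @slot families named list, one entry per amino acid, each a character
#'   vector of its sense codons.
#' @name GeneticCode-class
#' @aliases GeneticCode
#' @exportClass GeneticCode
setClass("GeneticCode",
  representation(
    tableId = "integer",
    codonMap = "character",
    startCodons = "character",
    stopCodons = "character",
    families = "list"
  )
)

setValidity("GeneticCode", function(object) {
  msg <- character()
  if (length(object@codonMap) != 64L)
    msg <- c(msg, "codonMap must have 64 entries")
  sense <- names(object@codonMap)[object@codonMap != "*"]
  if (!setequal(unlist(object@families), sense))
    msg <- c(msg, "families must partition the sense codons")
  if (length(msg)) msg else TRUE
})

#' Construct a genetic code from an NCBI table id
#'
#' @param tableId NCBI translation-table number (default `5`, the
#'   invertebrate mitochondrial code).
#' @return A [GeneticCode-class] object.
#' @examples
#' code <- geneticCode(5)
#' length(senseCodons(code))  # 62
#' @export
geneticCode <- function(tableId = 5) {
  tableId <- as.integer(tableId)
  map <- Biostrings::getGeneticCode(as.character(tableId))
  starts <- attr(map, "alt_init_codons")
  # ATG initiates in every table; keep attribute-free named vector
  starts <- sort(unique(c("ATG", as.character(starts))))
  attributes(map) <- list(names = names(map))
  stops <- names(map)[map == "*"]
  sense <- map[map != "*"]
  fams <- split(names(sense), unname(sense))
  methods::new("GeneticCode",
    tableId = tableId, codonMap = map,
    startCodons = starts, stopCodons = stops, families = fams)
}

#' @describeIn GeneticCode-class sense codons of the code
#' @param code a [GeneticCode-class] object
#' @export
senseCodons <- function(code) {
  names(code@codonMap)[code@codonMap != "*"]
}

#' @describeIn GeneticCode-class stop codons of the code
#' @export
stopCodons <- function(code) code@stopCodons

#' @describeIn GeneticCode-class synonymous families (list by amino acid)
#' @export
codonFamilies <- function(code) code@families

#' @describeIn GeneticCode-class translate a codon vector to amino acids
#'   (`"X"` for codons containing non-ACGT letters, `"*"` for stops)
#' @param codons character vector of 3-letter codons
#' @export
translateCodons <- function(codons, code = geneticCode()) {
  aa <- unname(code@codonMap[codons])
  aa[is.na(aa)] <- "X"
  aa
}

setMethod("show", "GeneticCode", function(object) {
  cat("GeneticCode: NCBI translation table", object@tableId, "\n")
  cat("  sense codons:", sum(object@codonMap != "*"),
      " stop codons:", paste(object@stopCodons, collapse = ", "), "\n")
  cat("  start codons:", paste(object@startCodons, collapse = ", "), "\n")
})

#' Split a coding sequence into complete codons
#'
#' Frame is fixed at 0; a trailing 1-2 nt remainder (an incomplete stop
#' completed by polyadenylation in mitochondrial mRNAs) is dropped.
#'
#' @param cds nucleotide string, 5'->3' coding sense.
#' @return character vector of 3-letter codons (upper case).
#' @export
splitCodons <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds) %/% 3L
  if (n == 0L) return(character())
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
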