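#' Annotated mitochondrial genome
#'
#' Central container of the package: a (usually circular) mitochondrial
#' nucleotide sequence together with its gene annotation. Coordinates in
#' the feature table are 0-based half-open on the forward (heavy)
#' strand; a feature that spans the sequence origin of a circular genome
#' has `wrapsOrigin = TRUE` and `start > end`, and extraction uses
#' modular indexing so the deposited genome length is preserved for
#' composition statistics.
#'
#' @slot identifier accession-like identifier.
#' @slot organism organism name (free text).
#' @slot sequence a [Biostrings::DNAString] (IUPAC letters).
#' @slot circular logical, whether the molecule is circular.
#' @slot features data.frame with columns `gene` (canonical name or
#'   `"CR"`), `start`, `end` (0-based half-open), `strand` (+1/-1),
#'   `geneClass` (`PCG`/`tRNA`/`rRNA`/`CR`), `wrapsOrigin` (logical).
#'
#' @name Mitogenome-class
#' @aliases Mitogenome-class
#' @exportClass Mitogenome
setClass("Mitogenome",
  representation(
    identifier = "character",
    organism = "character",
    sequence = "DNAString",
    circular = "logical",
    features = "data.frame"
  )
)

.FEATURE_COLS <- c("gene", "start", "end", "strand", "geneClass", "wrapsOrigin")

setValidity("Mitogenome", function(object) {
  msg <- character()
  L <- length(object@sequence)
  if (L == 0L) msg <- c(msg, "sequence must be non-empty")
  ft <- object@features
  if (!all(.FEATURE_COLS %in% names(ft)))
    msg <- c(msg, paste("features must have columns:",
                        paste(.FEATURE_COLS, collapse = ", ")))
  else if (nrow(ft)) {
    if (any(ft$start < 0L) || any(ft$start >= L) ||
        any(ft$end < 0L) || any(ft$end > L))
      msg <- c(msg, "feature coordinates outside [0, length)")
    if (any(ft$start >= ft$end & !ft$wrapsOrigin))
      msg <- c(msg, "start >= end only permitted for origin-wrapping features")
    if (any(ft$wrapsOrigin) && !object@circular)
      msg <- c(msg, "origin-wrapping features require a circular genome")
    if (anyDuplicated(ft$gene))
      msg <- c(msg, paste("duplicated canonical gene(s):",
                          paste(unique(ft$gene[duplicated(ft$gene)]),
                                collapse = ", ")))
    if (!all(ft$strand %in% c(-1L, 1L)))
      msg <- c(msg, "strand must be +1 or -1")
    bad <- ft$geneClass != geneClassOf(ft$gene)
    if (any(bad))
      msg <- c(msg, paste("gene class inconsistent with name:",
                          paste(ft$gene[bad], collapse = ", ")))
    pcg <- ft[ft$geneClass == "PCG", , drop = FALSE]
    if (nrow(pcg)) {
      len <- ifelse(pcg$wrapsOrigin, (L - pcg$start) + pcg$end,
                    pcg$end - pcg$start)
      if (any(len < 3L)) msg <- c(msg, "PCG extracted length must be >= 3")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Mitogenome
#'
#' @param identifier accession-like identifier.
#' @param sequence nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param features feature table (see [Mitogenome-class]); `strand` may
#'   be given as `+1/-1`; `gene` names must be canonical.
#' @param organism organism name.
#' @param circular is the molecule circular?
#' @return a [Mitogenome-class] object.
#' @export
Mitogenome <- function(identifier, sequence, features,
                       organism = NA_character_, circular = TRUE) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  if (is.null(features$wrapsOrigin)) features$wrapsOrigin <- FALSE
  if (is.null(features$geneClass)) features$geneClass <- geneClassOf(features$gene)
  rownames(features) <- NULL
  methods::new("Mitogenome",
    identifier = as.character(identifier),
    organism = as.character(organism),
    sequence = sequence, circular = isTRUE(circular),
    features = features[, .FEATURE_COLS])
}

#' @describeIn Mitogenome-class accession-like identifier
#' @param x a `Mitogenome`
#' @export
identifier <- function(x) x@identifier

#' @describeIn Mitogenome-class organism name
#' @export
organism <- function(x) x@organism

#' @describeIn Mitogenome-class genome sequence as a
#'   [Biostrings::DNAString]
#' @export
genomeSequence <- function(x) x@sequence

#' @describeIn Mitogenome-class genome length in nucleotides
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn Mitogenome-class is the molecule circular?
#' @export
isCircularGenome <- function(x) x@circular

#' @describeIn Mitogenome-class the feature table (0-based half-open
#'   coordinates)
#' @export
featureTable <- function(x) x@features

setMethod("show", "Mitogenome", function(object) {
  cat("Mitogenome:", object@identifier,
      if (!is.na(object@organism)) paste0("(", object@organism, ")"), "\n")
  cat(" ", length(object@sequence), "bp,",
      if (object@circular) "circular" else "linear", "\n")
  cls <- table(factor(object@features$geneClass,
                      levels = c("PCG", "tRNA", "rRNA", "CR")))
  cat("  features:", nrow(object@features),
      sprintf("(%d PCG, %d tRNA, %d rRNA, %d CR)\n",
              cls[["PCG"]], cls[["tRNA"]], cls[["rRNA"]], cls[["CR"]]))
})
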