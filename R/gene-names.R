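# Canonical nomenclature for the 37 metazoan mitochondrial genes plus the
# control region, and the ancestral insect gene order used as the
# rearrangement reference.

.PCG_NAMES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
                "nad1", "nad2", "nad3", "nad4", "nad4l", "nad5", "nad6")
.RRNA_NAMES <- c("rrnS", "rrnL")
.TRNA_NAMES <- c("trnI", "trnQ", "trnM", "trnW", "trnC", "trnY",
                 "trnL1", "trnL2", "trnK", "trnD", "trnG", "trnA",
                 "trnR", "trnN", "trnS1", "trnS2", "trnE", "trnF",
                 "trnH", "trnT", "trnP", "trnV")

# ancestral insect (Drosophila-like) chromosomal order starting at trnI,
# with heavy(+)/light(-) strand orientation
.ANCESTRAL_ORDER <- data.frame(
  gene = c("trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY",
           "cox1", "trnL2", "cox2", "trnK", "trnD", "atp8", "atp6",
           "cox3", "trnG", "nad3", "trnA", "trnR", "trnN", "trnS1",
           "trnE", "trnF", "nad5", "trnH", "nad4", "nad4l", "trnT",
           "trnP", "nad6", "cob", "trnS2", "nad1", "trnL1", "rrnL",
           "trnV", "rrnS"),
  orientation = c(1L, -1L, 1L, 1L, 1L, -1L, -1L,
                  1L, 1L, 1L, 1L, 1L, 1L, 1L,
                  1L, 1L, 1L, 1L, 1L, 1L, 1L,
                  1L, -1L, -1L, -1L, -1L, -1L, 1L,
                  -1L, 1L, 1L, 1L, -1L, -1L, -1L,
                  -1L, -1L),
  stringsAsFactors = FALSE
)
.ANCESTRAL_ORDER$index <- seq_len(nrow(.ANCESTRAL_ORDER))

# coding-sense anticodons of the two serine / two leucine tRNA copies in
# the invertebrate mitochondrial tRNA set (used for disambiguation)
.ANTICODON_COPY <- c(
  GCT = "trnS1", TCT = "trnS1",  # AGN serine
  TGA = "trnS2",                 # UCN serine
  TAG = "trnL1",                 # CUN leucine
  TAA = "trnL2"                  # UUR leucine
)

#' Canonical mitochondrial gene names
#'
#' @return Character vector of the 37 canonical gene names (13 PCGs,
#'   2 rRNAs, 22 tRNAs); the control region is named `"CR"` and is not
#'   part of this set.
#' @export
canonicalGeneNames <- function() {
  c(.PCG_NAMES, .RRNA_NAMES, .TRNA_NAMES)
}

#' Gene class (PCG / tRNA / rRNA / CR) of a canonical name
#'
#' @param name canonical gene name(s).
#' @return character vector of classes.
#' @export
geneClassOf <- function(name) {
  vapply(name, function(g) {
    if (g %in% .PCG_NAMES) "PCG"
    else if (g %in% .TRNA_NAMES) "tRNA"
    else if (g %in% .RRNA_NAMES) "rRNA"
    else if (g == "CR") "CR"
    else stop("not a canonical gene name: ", g, call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}

# one synonym table, lower-cased keys with separators stripped
.SYNONYMS <- local({
  syn <- list(
    atp6 = c("atp6", "atpase6", "atpase subunit 6", "atp synthase f0 subunit 6"),
    atp8 = c("atp8", "atpase8", "atpase subunit 8", "atp synthase f0 subunit 8"),
    cox1 = c("cox1", "coi", "co1", "coxi", "cytochrome c oxidase subunit 1",
             "cytochrome c oxidase subunit i", "cytochrome oxidase subunit 1"),
    cox2 = c("cox2", "coii", "co2", "coxii", "cytochrome c oxidase subunit 2",
             "cytochrome c oxidase subunit ii"),
    cox3 = c("cox3", "coiii", "co3", "coxiii", "cytochrome c oxidase subunit 3",
             "cytochrome c oxidase subunit iii"),
    cob  = c("cob", "cytb", "cytochrome b", "cyt b", "cb"),
    nad1 = c("nad1", "nd1", "nadh1", "nadh dehydrogenase subunit 1"),
    nad2 = c("nad2", "nd2", "nadh2", "nadh dehydrogenase subunit 2"),
    nad3 = c("nad3", "nd3", "nadh3", "nadh dehydrogenase subunit 3"),
    nad4 = c("nad4", "nd4", "nadh4", "nadh dehydrogenase subunit 4"),
    nad4l = c("nad4l", "nd4l", "nadh4l", "nadh dehydrogenase subunit 4l"),
    nad5 = c("nad5", "nd5", "nadh5", "nadh dehydrogenase subunit 5"),
    nad6 = c("nad6", "nd6", "nadh6", "nadh dehydrogenase subunit 6"),
    rrnS = c("rrns", "12s", "12s rrna", "12s ribosomal rna", "s-rrna",
             "srrna", "small subunit ribosomal rna", "rns", "mt-rns"),
    rrnL = c("rrnl", "16s", "16s rrna", "16s ribosomal rna", "l-rrna",
             "lrrna", "large subunit ribosomal rna", "rnl", "mt-rnl"),
    trnI = c("trni", "trna-ile", "ile"),   trnQ = c("trnq", "trna-gln", "gln"),
    trnM = c("trnm", "trna-met", "met"),   trnW = c("trnw", "trna-trp", "trp"),
    trnC = c("trnc", "trna-cys", "cys"),   trnY = c("trny", "trna-tyr", "tyr"),
    trnK = c("trnk", "trna-lys", "lys"),   trnD = c("trnd", "trna-asp", "asp"),
    trnG = c("trng", "trna-gly", "gly"),
    trnR = c("trnr", "trna-arg", "arg"),   trnN = c("trnn", "trna-asn", "asn"),
    trnE = c("trne", "trna-glu", "glu"),   trnF = c("trnf", "trna-phe", "phe"),
    trnA = c("trna", "trna-ala", "ala"),
    trnH = c("trnh", "trna-his", "his"),   trnT = c("trnt", "trna-thr", "thr"),
    trnP = c("trnp", "trna-pro", "pro"),   trnV = c("trnv", "trna-val", "val"),
    trnS1 = c("trns1", "trna-ser1", "trns-agn", "trna-ser-agn"),
    trnS2 = c("trns2", "trna-ser2", "trns-ucn", "trna-ser-ucn"),
    trnL1 = c("trnl1", "trna-leu1", "trnl-cun", "trna-leu-cun"),
    trnL2 = c("trnl2", "trna-leu2", "trnl-uur", "trna-leu-uur"),
    CR = c("cr", "control region", "d-loop", "dloop", "at-rich region",
           "a+t-rich region", "putative control region")
  )
  tab <- unlist(lapply(names(syn), function(canon) {
    keys <- gsub("[ _-]+", "", syn[[canon]])
    stats::setNames(rep(canon, length(keys)), keys)
  }))
  tab
})

.normalizeLabel <- function(raw) gsub("[ _-]+", "", tolower(trimws(raw)))

#' Canonicalize a gene annotation label
#'
#' Maps the many RefSeq annotation dialects (COI/COX1/cox1, ND4L/nad4L,
#' cytb/cob, 16S/l-rRNA/rrnL, tRNA-Ile/trnI, ...) onto the canonical
#' 37-gene nomenclature, case-insensitively. The duplicated serine and
#' leucine tRNAs are resolved from an explicit copy number in the label
#' when present, else from the anticodon (`GCT`/`TCT` -> `trnS1`,
#' `TGA` -> `trnS2`, `TAG` -> `trnL1`, `TAA` -> `trnL2`).
#'
#' @param raw annotation label (from `/gene` or `/product`).
#' @param anticodon optional anticodon string used to disambiguate the
#'   two serine and two leucine tRNA copies.
#' @return A canonical gene name, or `"CR"` for the control region.
#'   Unrecognized labels raise an error of class `mitocomp_unknown_gene`;
#'   an undisambiguated trnS/trnL raises `mitocomp_ambiguous_trna`.
#' @examples
#' canonicalizeGeneName("ND4L")            # "nad4l"
#' canonicalizeGeneName("tRNA-Ser", "gct") # "trnS1"
#' @export
canonicalizeGeneName <- function(raw, anticodon = NULL) {
  if (length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop(.err("mitocomp_unknown_gene", "empty gene label"))
  key <- .normalizeLabel(raw)
  # anticodon in parentheses inside the label, e.g. "trnS(gct)"
  m <- regmatches(key, regexec("^([a-z0-9]+)\\(([a-z]{3})\\)$", key))[[1]]
  if (length(m) == 3L) {
    key <- m[2]
    if (is.null(anticodon)) anticodon <- m[3]
  }
  hit <- .SYNONYMS[key]
  if (!is.na(hit)) return(unname(hit))
  if (key %in% c("trns", "trnaser", "ser", "trnl", "trnaleu", "leu")) {
    if (!is.null(anticodon)) {
      ac <- toupper(gsub("U", "T", toupper(anticodon)))
      copy <- .ANTICODON_COPY[ac]
      if (!is.na(copy)) {
        want <- if (key %in% c("trns", "trnaser", "ser")) "trnS" else "trnL"
        if (startsWith(unname(copy), want)) return(unname(copy))
      }
    }
    stop(.err("mitocomp_ambiguous_trna", sprintf(
      "cannot assign '%s' to a serine/leucine tRNA copy without an anticodon or copy number",
      raw)))
  }
  stop(.err("mitocomp_unknown_gene",
            sprintf("unrecognized gene label: '%s'", raw)))
}

#' The ancestral insect mitochondrial gene order
#'
#' The canonical 37-gene arrangement of the insect mitogenome (the
#' Drosophila-like order), encoded as a gene-order signature: genes in
#' chromosomal order starting at *trnI* (index 1), each with its
#' heavy(+1)/light(-1) strand orientation. The control region sits
#' between *rrnS* and *trnI* and is excluded from the signature.
#'
#' @return data.frame with columns `gene`, `index` (1..37) and
#'   `orientation` (+1/-1), of class `GeneOrderSignature`.
#' @export
ancestralGeneOrder <- function() {
  sig <- .ANCESTRAL_ORDER[, c("gene", "index", "orientation")]
  class(sig) <- c("GeneOrderSignature", "data.frame")
  sig
}

# condition constructor shared across the package
.err <- function(class, msg, ...) {
  structure(class = c(class, "mitocomp_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), ...))
}
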