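# GenBank flat-file input/output.
#
# Only what annotated mitogenome records need: LOCUS, DEFINITION,
# ACCESSION, ORGANISM, a FEATURES table restricted to gene-bearing keys
# (CDS, tRNA, rRNA, gene, D-loop, misc_feature), and ORIGIN. Locations
# may use complement(), join() and origin-spanning joins on circular
# records. GenBank 1-based inclusive coordinates are converted to the
# package's 0-based half-open convention at this boundary.

.GB_FEATURE_KEYS <- c("CDS", "tRNA", "rRNA", "gene", "D-loop", "misc_feature")

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses one or more LOCUS records. Feature names are canonicalized via
#' [canonicalizeGeneName()] (the `/gene` qualifier is preferred, falling
#' back to `/product`; tRNA copies are disambiguated by the `/anticodon`
#' or `/note` qualifier when present, else by positional match against
#' the ancestral order). When a gene is annotated both as a bare `gene`
#' feature and as a typed CDS/tRNA/rRNA feature, the typed feature wins.
#' Two typed features claiming the same canonical gene raise an
#' annotation-conflict error listing both.
#'
#' @param file path to a GenBank flat file, or its content as a single
#'   string / character vector of lines (via `text`).
#' @param text GenBank record content, used instead of `file`.
#' @return a [Mitogenome-class], or a list of them for multi-record
#'   files.
#' @export
readGenBank <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  } else readLines(file, warn = FALSE)
  recs <- .splitRecords(lines)
  if (length(recs) == 0L)
    stop(.err("mitocomp_parse_error", "no LOCUS record found"))
  out <- lapply(recs, .parseOneRecord)
  if (length(out) == 1L) out[[1]] else out
}

.splitRecords <- function(lines) {
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  Map(function(s, e) lines[s:e], starts, ends)
}

.parseOneRecord <- function(lines) {
  locus <- lines[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  if (length(toks) < 3L || toks[1] != "LOCUS")
    stop(.err("mitocomp_parse_error", paste("malformed LOCUS line:", locus)))
  name <- toks[2]
  len <- suppressWarnings(as.integer(toks[3]))
  if (is.na(len))
    stop(.err("mitocomp_parse_error", paste("no sequence length on LOCUS line:", locus)))
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  acc <- grep("^ACCESSION", lines, value = TRUE)
  id <- if (length(acc)) strsplit(trimws(acc[1]), "\\s+")[[1]][2] else name
  if (is.na(id)) id <- name
  org <- grep("^  ORGANISM", lines, value = TRUE)
  organism <- if (length(org)) trimws(sub("^  ORGANISM", "", org[1])) else NA_character_

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart))
    stop(.err("mitocomp_parse_error", "no ORIGIN section found"))
  seq <- .parseOrigin(lines[(ostart[1] + 1L):length(lines)])
  if (nchar(seq) != len)
    stop(.err("mitocomp_parse_error", sprintf(
      "sequence length %d does not match LOCUS length %d", nchar(seq), len)))

  raw <- if (length(fstart))
    .parseFeatureBlock(lines[(fstart[1] + 1L):(ostart[1] - 1L)]) else list()
  features <- .resolveFeatures(raw, len, circular)
  Mitogenome(identifier = id, sequence = seq, features = features,
             organism = organism, circular = circular)
}

.parseOrigin <- function(lines) {
  lines <- lines[!grepl("^//", lines)]
  toupper(gsub("[^A-Za-z]", "", paste(lines, collapse = "")))
}

# returns a list of list(key, location, qualifiers=named character)
.parseFeatureBlock <- function(lines) {
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  isNew <- grepl("^ {5}\\S", lines)
  feats <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!isNew[i]) {
      stop(.err("mitocomp_parse_error",
                paste("unexpected feature-table line:", lines[i])))
    }
    m <- regmatches(lines[i], regexec("^ {5}(\\S+)\\s+(\\S.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      stop(.err("mitocomp_parse_error",
                paste("malformed feature line:", lines[i])))
    key <- m[2]; loc <- trimws(m[3])
    i <- i + 1L
    # location continuation lines (before the first qualifier)
    while (i <= length(lines) && !isNew[i] &&
           !grepl("^\\s+/", lines[i])) {
      loc <- paste0(loc, trimws(lines[i]))
      i <- i + 1L
    }
    quals <- character()
    while (i <= length(lines) && !isNew[i]) {
      q <- trimws(lines[i])
      i <- i + 1L
      while (i <= length(lines) && !isNew[i] && !grepl("^\\s+/", lines[i])) {
        q <- paste(q, trimws(lines[i]))
        i <- i + 1L
      }
      qm <- regmatches(q, regexec("^/([A-Za-z_]+)(=(.*))?$", q))[[1]]
      if (length(qm) >= 2L) {
        val <- if (length(qm) >= 4L && nzchar(qm[3])) gsub('^"|"$', "", qm[4]) else ""
        quals[qm[2]] <- val
      }
    }
    feats[[length(feats) + 1L]] <- list(key = key, location = loc,
                                        qualifiers = quals)
  }
  feats
}

# GenBank location -> list(start, end, strand, wraps) in 0-based half-open
.parseLocation <- function(loc, seqLen, circular) {
  orig <- loc
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
  } else parts <- loc
  iv <- lapply(parts, function(p) {
    pm <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", trimws(p)))[[1]]
    if (length(pm) == 3L) return(as.integer(pm[2:3]))
    pm <- regmatches(p, regexec("^(\\d+)$", trimws(p)))[[1]]
    if (length(pm) == 2L) return(rep(as.integer(pm[2]), 2L))
    stop(.err("mitocomp_parse_error",
              paste("cannot parse location:", orig)))
  })
  if (length(iv) == 1L) {
    a <- iv[[1]][1]; b <- iv[[1]][2]
    return(list(start = a - 1L, end = b, strand = strand, wraps = FALSE))
  }
  if (length(iv) == 2L && circular &&
      iv[[1]][2] == seqLen && iv[[2]][1] == 1L) {
    # origin-spanning join on a circular record
    return(list(start = iv[[1]][1] - 1L, end = iv[[2]][2],
                strand = strand, wraps = TRUE))
  }
  stop(.err("mitocomp_parse_error", paste(
    "unsupported multi-interval location (only origin-spanning joins",
    "on circular records are handled):", orig)))
}

.resolveFeatures <- function(raw, seqLen, circular) {
  empty <- data.frame(gene = character(), start = integer(), end = integer(),
                      strand = integer(), geneClass = character(),
                      wrapsOrigin = logical(), stringsAsFactors = FALSE)
  raw <- Filter(function(f) f$key %in% .GB_FEATURE_KEYS, raw)
  if (!length(raw)) return(empty)
  rows <- list()
  for (f in raw) {
    loc <- .parseLocation(f$location, seqLen, circular)
    q <- f$qualifiers
    label <- if (!is.na(q["gene"]) && nzchar(q["gene"])) q["gene"]
             else if (!is.na(q["product"])) q["product"] else NA_character_
    if (f$key %in% c("D-loop")) label <- "CR"
    if (is.na(label)) next                      # unnamed misc features
    anticodon <- NA_character_
    if (!is.na(q["anticodon"])) {
      am <- regmatches(q["anticodon"],
                       regexec("seq\\s*:\\s*([A-Za-z]{3})", q["anticodon"]))[[1]]
      anticodon <- if (length(am) == 2L) am[2] else q["anticodon"]
    } else if (!is.na(q["note"])) {
      am <- regmatches(q["note"],
                       regexec("anticodon\\s*:?\\s*([A-Za-z]{3})", q["note"]))[[1]]
      if (length(am) == 2L) anticodon <- am[2]
    }
    canon <- tryCatch(
      canonicalizeGeneName(label, if (!is.na(anticodon)) anticodon),
      mitocomp_ambiguous_trna = function(e) e,
      mitocomp_unknown_gene = function(e) e)
    if (f$key == "misc_feature" && methods::is(canon, "condition")) next
    rows[[length(rows) + 1L]] <- list(canon = canon, key = f$key, loc = loc,
                                      label = label)
  }
  if (!length(rows)) return(empty)
  # positional fallback for ambiguous trnS/trnL copies
  amb <- vapply(rows, function(r) methods::is(r$canon, "condition"), logical(1))
  ambClass <- vapply(rows, function(r)
    methods::is(r$canon, "mitocomp_ambiguous_trna"), logical(1))
  if (any(ambClass)) {
    assigned <- vapply(rows[!amb], function(r) r$canon, character(1))
    for (j in which(ambClass)) {
      rows[[j]]$canon <- .positionalTrnaAssign(rows, j, assigned)
      if (methods::is(rows[[j]]$canon, "condition")) stop(rows[[j]]$canon)
      assigned <- c(assigned, rows[[j]]$canon)
    }
  }
  if (any(vapply(rows, function(r) methods::is(r$canon, "condition"), logical(1)))) {
    bad <- Filter(function(r) methods::is(r$canon, "condition"), rows)
    stop(bad[[1]]$canon)
  }
  df <- do.call(rbind, lapply(rows, function(r) data.frame(
    gene = r$canon, key = r$key, start = r$loc$start, end = r$loc$end,
    strand = r$loc$strand, wrapsOrigin = r$loc$wraps,
    stringsAsFactors = FALSE)))
  # typed features (CDS/tRNA/rRNA/D-loop) win over bare 'gene' features
  typed <- df[df$key != "gene", , drop = FALSE]
  bare <- df[df$key == "gene" & !(df$gene %in% typed$gene), , drop = FALSE]
  if (anyDuplicated(typed$gene)) {
    dup <- unique(typed$gene[duplicated(typed$gene)])
    offending <- typed[typed$gene %in% dup, , drop = FALSE]
    stop(.err("mitocomp_annotation_conflict", paste0(
      "duplicated annotation for canonical gene(s) ",
      paste(dup, collapse = ", "), ": ",
      paste(sprintf("%s[%d..%d]", offending$gene, offending$start + 1L,
                    offending$end), collapse = ", "))))
  }
  out <- rbind(typed, bare)
  keyClass <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", `D-loop` = "CR",
                misc_feature = "CR", gene = NA_character_)
  out$geneClass <- unname(keyClass[out$key])
  fromName <- geneClassOf(out$gene)
  out$geneClass[is.na(out$geneClass)] <- fromName[is.na(out$geneClass)]
  mismatch <- out$geneClass != fromName
  if (any(mismatch))
    stop(.err("mitocomp_annotation_conflict", paste(
      "feature key inconsistent with gene name for:",
      paste(out$gene[mismatch], collapse = ", "))))
  out <- out[order(out$start), c("gene", "start", "end", "strand",
                                 "geneClass", "wrapsOrigin")]
  rownames(out) <- NULL
  out
}

# assign an ambiguous trnS/trnL feature to a copy by nearest match of the
# surrounding genes to the ancestral order
.positionalTrnaAssign <- function(rows, j, assigned) {
  lab <- .normalizeLabel(rows[[j]]$label)
  want <- if (lab %in% c("trns", "trnaser", "ser")) c("trnS1", "trnS2")
          else c("trnL1", "trnL2")
  free <- setdiff(want, assigned)
  if (length(free) == 1L) return(free)
  if (length(free) == 0L) return(rows[[j]]$canon)
  anc <- ancestralGeneOrder()
  # pick the copy whose ancestral neighbour is closest among resolved genes
  others <- Filter(function(r) is.character(r$canon), rows)
  if (!length(others)) return(rows[[j]]$canon)
  pos <- rows[[j]]$loc$start
  best <- NULL; bestd <- Inf
  for (cand in free) {
    ci <- anc$index[anc$gene == cand]
    nb <- anc$gene[anc$index %in% c(ci - 1L, ci + 1L)]
    for (r in others) {
      if (r$canon %in% nb) {
        d <- abs(r$loc$start - pos)
        if (d < bestd) { bestd <- d; best <- cand }
      }
    }
  }
  if (is.null(best)) rows[[j]]$canon else best
}

#' Serialize a Mitogenome as a GenBank flat file
#'
#' Writes LOCUS/ACCESSION/ORGANISM, a FEATURES table with one typed
#' feature per gene (CDS for PCGs, tRNA, rRNA, D-loop for the control
#' region) and the ORIGIN sequence block. Parsing the output with
#' [readGenBank()] reproduces sequence and feature coordinates exactly.
#'
#' @param x a [Mitogenome-class].
#' @param file optional path; when `NULL` the record is returned as a
#'   character vector of lines.
#' @return invisibly, the lines written.
#' @export
writeGenBank <- function(x, file = NULL) {
  L <- genomeLength(x)
  lines <- c(sprintf("LOCUS       %s%17d bp    DNA     %s INV",
                     identifier(x), L,
                     if (isCircularGenome(x)) "circular" else "linear"),
             sprintf("DEFINITION  %s mitochondrion%s.",
                     if (is.na(organism(x))) identifier(x) else organism(x),
                     if (isCircularGenome(x)) ", complete genome" else ""),
             sprintf("ACCESSION   %s", identifier(x)))
  if (!is.na(organism(x)))
    lines <- c(lines, sprintf("SOURCE      mitochondrion %s", organism(x)),
               sprintf("  ORGANISM  %s", organism(x)))
  lines <- c(lines, "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", L))
  keyOf <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  ft <- featureTable(x)
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    span <- if (f$wrapsOrigin)
      sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end)
    else sprintf("%d..%d", f$start + 1L, f$end)
    if (f$strand == -1L) span <- sprintf("complement(%s)", span)
    key <- keyOf[[f$geneClass]]
    lines <- c(lines, sprintf("     %-16s%s", key, span))
    if (f$geneClass != "CR")
      lines <- c(lines, sprintf('                     /gene="%s"', f$gene))
    else
      lines <- c(lines, '                     /note="putative control region"')
  }
  seq <- tolower(as.character(genomeSequence(x)))
  lines <- c(lines, "ORIGIN")
  starts <- seq(1L, nchar(seq), by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
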