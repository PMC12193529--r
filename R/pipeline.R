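# Study orchestration: load a genome set, run every analysis stage,
# write the result tables, the supermatrix and a run manifest.

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored. Values are returned as strings; [runPipeline()]
#' coerces the numeric ones.
#'
#' @param path configuration file path.
#' @return named list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*?)\\s*$",
                                 lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad))
    stop(.err("mitocomp_config_error",
              paste("unparseable config line:", lines[bad][1])))
  cfg <- stats::setNames(lapply(m, `[`, 3L), vapply(m, `[`, character(1), 2L))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.cfgDefaults <- list(code = 5, window = 100, step = 1,
                     kaks_threshold = 0.9, seed = 1, log_level = "info")

.logLevels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

.plog <- function(level, cfgLevel, ...) {
  if (.logLevels[[level]] >= .logLevels[[cfgLevel]])
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

#' Run the full comparative-mitogenome pipeline
#'
#' Loads the genome set, computes skew tables at all levels with their
#' skew-skew correlations, the RSCU matrix (concatenated PCGs per
#' genome), CAI profiles and per-gene summaries against the reference
#' usage table, Ka/Ks of every genome x PCG against the reference CDS
#' set, neutrality fits for the retained high-rate genes, gene-order
#' reports against the ancestral order, and the concatenated
#' 13 PCG + 2 rRNA supermatrix. Everything is written as TSV/FASTA into
#' a fresh versioned subdirectory (`run-001`, `run-002`, ...) of the
#' output directory, alongside a JSON manifest. A malformed genome is
#' logged and excluded, not fatal; the run is deterministic given
#' config and seed.
#'
#' @param config a named list or `RunConfig`: `input` (directory of
#'   GenBank files, or a vector of paths via `input_files`), optional
#'   `taxonomy` (TSV path with columns `genome_id`, `subfamily`, and
#'   optionally `tribe`), optional `reference_table` (codon-usage table
#'   path) and `reference_cds` (multi-FASTA, one CDS per PCG named by
#'   canonical gene), `code`, `window`, `step`, `kaks_threshold`,
#'   `out`, `seed`, `log_level`.
#' @param genomes optional list of [Mitogenome-class] objects, used
#'   instead of reading `input`.
#' @return invisibly, a `ResultBundle` list: the tables, the exclusion
#'   log, and `paths` of everything written.
#' @export
runPipeline <- function(config, genomes = NULL) {
  cfg <- utils::modifyList(.cfgDefaults, as.list(config))
  lvl <- as.character(cfg$log_level)
  code <- geneticCode(as.integer(cfg$code))

  exclusions <- data.frame(genome_id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  if (is.null(genomes)) {
    files <- if (!is.null(cfg$input_files)) cfg$input_files
      else if (!is.null(cfg$input)) {
        if (dir.exists(cfg$input))
          list.files(cfg$input, pattern = "\\.(gb|gbk|genbank)$",
                     full.names = TRUE)
        else strsplit(cfg$input, ";", fixed = TRUE)[[1]]
      } else character()
    genomes <- list()
    for (f in sort(files)) {
      g <- tryCatch(suppressWarnings(readGenBank(f)), error = function(e) e)
      if (methods::is(g, "error")) {
        .plog("warn", lvl, "excluding ", basename(f), ": ",
              conditionMessage(g))
        exclusions <- rbind(exclusions, data.frame(
          genome_id = basename(f), reason = conditionMessage(g),
          stringsAsFactors = FALSE))
      } else genomes <- c(genomes, if (is.list(g)) g else list(g))
    }
  }
  if (!length(genomes))
    stop(.err("mitocomp_config_error", "empty input genome set"))
  ids <- vapply(genomes, identifier, character(1))
  .plog("info", lvl, "loaded ", length(genomes), " genome(s)")

  bundle <- list(exclusions = exclusions)

  # --- composition -----------------------------------------------------
  levels <- c("whole_genome", "pcg_concat", "rrna_concat", "trna_concat",
              "pcg", "trna")
  bundle$skew <- lapply(stats::setNames(levels, levels), function(lv)
    skewTable(genomes, lv))
  corRows <- lapply(levels, function(lv) {
    tb <- bundle$skew[[lv]]
    r <- tryCatch(pearsonCorrelation(tb$at_skew, tb$gc_skew),
                  error = function(e) NULL)
    if (is.null(r)) NULL
    else data.frame(level = lv, n = r$n, r = r$r, stringsAsFactors = FALSE)
  })
  bundle$skew_correlations <- do.call(rbind, corRows)

  # --- codon usage -----------------------------------------------------
  rscuMat <- vapply(genomes, function(g)
    unname(rscu(codonCounts(concatenatePCGs(g), code), code)),
    numeric(length(senseCodons(code))))
  rownames(rscuMat) <- senseCodons(code)
  colnames(rscuMat) <- ids
  bundle$rscu <- data.frame(codon = rownames(rscuMat),
                            amino_acid = translateCodons(rownames(rscuMat),
                                                         code),
                            rscuMat, check.names = FALSE,
                            stringsAsFactors = FALSE)

  if (!is.null(cfg$reference_table)) {
    ref <- readCodonTable(cfg$reference_table)
    w <- caiWeights(ref, code)
    profRows <- list(); sumRows <- list()
    for (g in genomes) for (gene in concatOrder("PCG")) {
      pr <- slidingWindowCAI(extractGene(g, gene), w, code,
                             windowCodons = as.integer(cfg$window),
                             stepCodons = as.integer(cfg$step),
                             gene = gene, genomeId = identifier(g))
      profRows[[length(profRows) + 1L]] <- data.frame(
        genome_id = pr$genome_id, gene = gene,
        window_start = pr$window_starts, cai = pr$window_cai,
        stringsAsFactors = FALSE)
      sumRows[[length(sumRows) + 1L]] <- data.frame(
        genome_id = pr$genome_id, gene = gene, gene_cai = pr$gene_cai,
        peak_cai = pr$peak_cai, stringsAsFactors = FALSE)
    }
    bundle$cai_profiles <- do.call(rbind, profRows)
    bundle$cai_summary <- do.call(rbind, sumRows)
  }

  # --- selection -------------------------------------------------------
  if (!is.null(cfg$reference_cds)) {
    refCds <- .readFastaNamed(cfg$reference_cds)
    kaksRows <- list()
    for (g in genomes) for (gene in intersect(concatOrder("PCG"),
                                              names(refCds))) {
      q <- extractGene(g, gene)
      r <- refCds[[gene]]
      est <- tryCatch({
        pair <- if (nchar(q) == nchar(r)) list(a = q, b = r)
                else codonAlignAndClean(q, r, code)
        ng86Pairwise(pair$a, pair$b, code, gene = gene,
                     queryId = identifier(g), referenceId = "reference")
      }, error = function(e) e)
      if (methods::is(est, "error")) {
        .plog("warn", lvl, "Ka/Ks skipped for ", identifier(g), " x ",
              gene, ": ", conditionMessage(est))
      } else kaksRows[[length(kaksRows) + 1L]] <- est
    }
    bundle$kaks <- do.call(rbind, kaksRows)
    retained <- selectHighRateGenes(bundle$kaks,
                                    as.numeric(cfg$kaks_threshold))
    bundle$high_rate_genes <- retained
    fitRows <- list()
    for (gene in retained) {
      pts <- lapply(genomes, function(g)
        gcByPosition(extractGene(g, gene), code = code))
      fit <- tryCatch(neutralityFit(pts, gene = gene),
                      error = function(e) e)
      if (!methods::is(fit, "error"))
        fitRows[[length(fitRows) + 1L]] <- fit
      else .plog("warn", lvl, "neutrality fit skipped for ", gene, ": ",
                 conditionMessage(fit))
    }
    bundle$neutrality <- do.call(rbind, fitRows)
  }

  # --- gene order ------------------------------------------------------
  bundle$gene_orders <- geneOrderTable(genomes)
  orderRows <- lapply(genomes, function(g) {
    rep <- compareGeneOrder(geneOrderSignature(g))
    data.frame(genome_id = identifier(g),
               is_identical = rep$is_identical,
               breakpoint_count = rep$breakpoint_count,
               missing_genes = paste(rep$missing_genes, collapse = ","),
               inverted_genes = paste(rep$inverted_genes, collapse = ","),
               translocated_genes = paste(rep$translocated_genes,
                                          collapse = ","),
               stringsAsFactors = FALSE)
  })
  bundle$rearrangements <- do.call(rbind, orderRows)

  # --- outputs ---------------------------------------------------------
  if (!is.null(cfg$out)) {
    runDir <- .nextRunDir(cfg$out)
    .plog("info", lvl, "writing results to ", runDir)
    paths <- character()
    for (lv in levels)
      paths <- c(paths, .writeTsv(bundle$skew[[lv]],
                                  file.path(runDir, paste0("skew_", lv, ".tsv"))))
    paths <- c(paths, .writeTsv(bundle$skew_correlations,
                                file.path(runDir, "skew_correlations.tsv")))
    paths <- c(paths, .writeTsv(bundle$rscu, file.path(runDir, "rscu.tsv")))
    if (!is.null(bundle$cai_profiles)) {
      paths <- c(paths, .writeTsv(bundle$cai_profiles,
                                  file.path(runDir, "cai_profiles.tsv")))
      paths <- c(paths, .writeTsv(bundle$cai_summary,
                                  file.path(runDir, "cai_summary.tsv")))
    }
    if (!is.null(bundle$kaks)) {
      paths <- c(paths, .writeTsv(bundle$kaks, file.path(runDir, "kaks.tsv")))
      if (!is.null(bundle$neutrality))
        paths <- c(paths, .writeTsv(bundle$neutrality,
                                    file.path(runDir, "neutrality.tsv")))
    }
    paths <- c(paths, .writeTsv(bundle$gene_orders,
                                file.path(runDir, "gene_orders.tsv")))
    paths <- c(paths, .writeTsv(bundle$rearrangements,
                                file.path(runDir, "rearrangements.tsv")))
    if (nrow(exclusions))
      paths <- c(paths, .writeTsv(exclusions,
                                  file.path(runDir, "exclusions.tsv")))
    sm <- file.path(runDir, "supermatrix.fasta")
    exportSupermatrix(genomes, sm)
    paths <- c(paths, sm)
    if (!is.null(cfg$taxonomy)) {
      tax <- utils::read.table(cfg$taxonomy, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      summ <- summarizeByGroup(bundle$skew$whole_genome, tax,
                               values = c("at_percent", "at_skew", "gc_skew"))
      bundle$group_summary <- summ
      paths <- c(paths, .writeTsv(summ, file.path(runDir,
                                                  "group_summary.tsv")))
    }
    manifest <- list(package = "mitocomp",
                     version = as.character(utils::packageVersion("mitocomp")),
                     seed = as.integer(cfg$seed),
                     config = cfg[setdiff(names(cfg), "input_files")],
                     genomes = ids,
                     excluded = exclusions$genome_id,
                     outputs = basename(paths))
    jsonlite::write_json(manifest, file.path(runDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    bundle$paths <- c(paths, file.path(runDir, "manifest.json"))
    bundle$run_dir <- runDir
  }
  class(bundle) <- c("ResultBundle", "list")
  invisible(bundle)
}

.nextRunDir <- function(out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  existing <- list.dirs(out, recursive = FALSE, full.names = FALSE)
  n <- suppressWarnings(max(0L, as.integer(sub("^run-", "",
        existing[grepl("^run-\\d+$", existing)]))))
  runDir <- file.path(out, sprintf("run-%03d", n + 1L))
  dir.create(runDir)
  runDir
}

.readFastaNamed <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.list(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Per-group mean and sample standard deviation
#'
#' Summarizes the numeric columns of a per-genome table by taxonomy
#' group (default subfamily), plus an `overall` row. Standard deviation
#' is the sample (n-1) form; single-member groups get `NA`.
#'
#' @param table data.frame with a `genome_id` column (e.g. from
#'   [skewTable()]).
#' @param taxonomy data.frame mapping `genome_id` to `subfamily` (and
#'   optionally more columns).
#' @param values names of the numeric columns to summarize.
#' @param by taxonomy column to group on.
#' @return data.frame with one row per group and per-statistic `_mean`
#'   and `_sd` columns.
#' @export
summarizeByGroup <- function(table, taxonomy,
                             values = c("at_percent", "at_skew", "gc_skew"),
                             by = "subfamily") {
  unmapped <- setdiff(table$genome_id, taxonomy$genome_id)
  if (length(unmapped))
    stop(.err("mitocomp_missing_taxonomy", paste(
      "genome id(s) missing from taxonomy:",
      paste(unmapped, collapse = ", "))))
  grp <- taxonomy[[by]][match(table$genome_id, taxonomy$genome_id)]
  groups <- c(split(seq_len(nrow(table)), grp),
              list(overall = seq_len(nrow(table))))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    row <- data.frame(group = g, n = length(idx), stringsAsFactors = FALSE)
    for (v in values) {
      x <- table[[v]][idx]
      row[[paste0(v, "_mean")]] <- mean(x, na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- if (sum(!is.na(x)) > 1L) stats::sd(x, na.rm = TRUE)
                                 else NA_real_
    }
    row
  })
  do.call(rbind, rows)
}

#' Export the concatenated 13 PCG + 2 rRNA supermatrix
#'
#' One unaligned record per genome: the coding-sense concatenation of
#' the 13 protein-coding genes (fixed order, see [concatOrder()])
#' followed by rrnL and rrnS. Genomes missing any of the 15 genes are
#' excluded with a warning.
#'
#' @param genomes list of [Mitogenome-class] objects.
#' @param file output FASTA path, or `NULL` to only return the set.
#' @return invisibly, a [Biostrings::DNAStringSet] of the records.
#' @export
exportSupermatrix <- function(genomes, file = NULL) {
  if (methods::is(genomes, "Mitogenome")) genomes <- list(genomes)
  recs <- list()
  for (g in genomes) {
    seq <- tryCatch(paste0(concatenatePCGs(g), extractGene(g, "rrnL"),
                           extractGene(g, "rrnS")),
                    mitocomp_missing_gene = function(e) e)
    if (methods::is(seq, "condition")) {
      warning("supermatrix: excluding ", identifier(g), ": ",
              conditionMessage(seq), call. = FALSE)
    } else recs[[identifier(g)]] <- seq
  }
  out <- Biostrings::DNAStringSet(unlist(recs))
  if (!is.null(file)) Biostrings::writeXStringSet(out, file, width = 70L)
  invisible(out)
}
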