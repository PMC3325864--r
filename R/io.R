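# Readers and writers for the plain-text interchange formats used by the
# pipeline: dose-response plate TSVs, expression + flag TSV pairs, UTR
# FASTA, per-cell intensity TSVs, ranked bound-gene TSVs, and a minimal
# GEO series-matrix reader. All numeric readers normalise comma decimals
# ("0,04" -> 0.04) on ingest.

#' Read / write a dose-response plate TSV
#'
#' Columns: `drug`, `dose_uM`, `replicate`, `response` (plus optional
#' `condition`).
#'
#' @param path file path.
#' @param drug optional drug filter on read.
#' @return [dose_response_table()] (read) or the path, invisibly (write).
#' @export
read_plate_tsv <- function(path, drug = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(drug)) {
    d <- d[d$drug == drug, , drop = FALSE]
    if (!nrow(d)) .stopf("no rows for drug '%s' in %s", drug, path)
  }
  .as_plate(d)
}

#' @param table a [dose_response_table()].
#' @rdname read_plate_tsv
#' @export
write_plate_tsv <- function(table, path) {
  write.table(.as_plate(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write an expression matrix as signal + flag TSVs
#'
#' The signal TSV has a `probe_id` column followed by one column per
#' sample; the optional flag TSV mirrors it with `P`/`A` calls. Condition
#' labels default to the sample-name prefix before the last underscore
#' (`RIP_1` -> `RIP`).
#'
#' @param signals_path,flags_path file paths (flags optional).
#' @param conditions optional explicit condition labels per sample.
#' @return an [expression_matrix()] (read) or the signal path, invisibly
#'   (write).
#' @export
read_expression_tsv <- function(signals_path, flags_path = NULL,
                                conditions = NULL) {
  d <- read.delim(signals_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1L] != "probe_id") .stopf("first column must be probe_id")
  sig <- as.matrix(as.data.frame(lapply(d[-1L], .as_num)))
  rownames(sig) <- d$probe_id
  colnames(sig) <- names(d)[-1L]
  flags <- NULL
  if (!is.null(flags_path)) {
    f <- read.delim(flags_path, stringsAsFactors = FALSE, check.names = FALSE)
    flags <- as.matrix(f[-1L])
    rownames(flags) <- f$probe_id
    flags <- flags[rownames(sig), colnames(sig), drop = FALSE]
  }
  if (is.null(conditions)) conditions <- sub("_[^_]*$", "", colnames(sig))
  expression_matrix(sig, conditions = conditions, flags = flags)
}

#' @param x an [expression_matrix()].
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, signals_path, flags_path = NULL) {
  x <- .check_em(x)
  d <- data.frame(probe_id = rownames(x$signals), x$signals,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.table(d, signals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(flags_path) && !is.null(x$flags)) {
    f <- data.frame(probe_id = rownames(x$flags),
                    ifelse(x$flags, "P", "A"),
                    check.names = FALSE, stringsAsFactors = FALSE)
    write.table(f, flags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(signals_path)
}

#' Read / write 3'UTR sequences as FASTA
#'
#' Record ids are taken as gene symbols (first whitespace-delimited token).
#' DNA is transcribed to RNA (T to U) and uppercased on read.
#'
#' @param path FASTA file path.
#' @return a [utr_set()] (read) or the path, invisibly (write).
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  utr_set(ids, as.character(ss))
}

#' @param utrs a [utr_set()].
#' @rdname read_utr_fasta
#' @export
write_utr_fasta <- function(utrs, path) {
  if (!inherits(utrs, "utr_set")) .stopf("expected a utr_set")
  ss <- Biostrings::RNAStringSet(setNames(utrs$sequence, utrs$gene_symbol))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read / write per-cell intensity TSVs
#'
#' Columns: `cell_id`, `condition`, `nucleus`, `cytoplasm`.
#'
#' @param path file path.
#' @return data.frame of validated cell records (read) or the path,
#'   invisibly (write).
#' @export
read_cells_tsv <- function(path) {
  .check_cells(read.delim(path, stringsAsFactors = FALSE))
}

#' @param records per-cell records data.frame.
#' @rdname read_cells_tsv
#' @export
write_cells_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ranked bound-gene TSV
#'
#' Columns: `gene_symbol`, `fold_enrichment` (extra columns such as ARE
#' counts are preserved as attributes on read).
#'
#' @param path file path.
#' @return a [bound_gene_list()] (read) or the path, invisibly (write).
#' @export
read_bound_genes_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_symbol", "fold_enrichment") %in% names(d))) {
    .stopf("bound-gene TSV needs gene_symbol and fold_enrichment columns")
  }
  out <- bound_gene_list(d$gene_symbol, .as_num(d$fold_enrichment))
  extra <- setdiff(names(d), c("gene_symbol", "fold_enrichment"))
  for (cc in extra) {
    attr(out, cc) <- setNames(d[[cc]], d$gene_symbol)[out$gene_symbol]
  }
  out
}

#' @param genes a [bound_gene_list()].
#' @rdname read_bound_genes_tsv
#' @export
write_bound_genes_tsv <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged example: 50 top-enriched HuR-bound genes
#'
#' The 50 most enriched transcripts from a published doxorubicin RIP-chip
#' experiment on MCF-7 cells, ranked by linear fold enrichment of the
#' immunoprecipitated over the cytoplasmic fraction, with the number of
#' Transterm ARE consensus matches annotated on each gene's 3'UTR. 18 of
#' the 50 genes carry at least one ARE.
#'
#' @return a [bound_gene_list()] with an `are_count` attribute (named
#'   integer vector, ARE matches per gene).
#' @export
example_bound_genes <- function() {
  path <- system.file("extdata", "table2_top50.tsv", package = "ripare",
                      mustWork = TRUE)
  read_bound_genes_tsv(path)
}

#' Write an enrichment scan as TSV
#'
#' Columns `n`, `k`, `p`, `log10_p`, `gene_symbol`.
#'
#' @param scan an `"enrichment_scan"`.
#' @param path file path.
#' @export
write_scan_tsv <- function(scan, path) {
  if (!inherits(scan, "enrichment_scan")) .stopf("expected an enrichment_scan")
  write.table(scan$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal GEO series-matrix reader
#'
#' Parses the plain-text series-matrix format: sample titles/accessions
#' from the `!Sample_*` header lines and the expression table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Intended
#' for ingesting deposited array data (e.g. accession GSE33055) together
#' with a platform-annotation TSV for probe-to-gene mapping; no network
#' access is performed.
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @param conditions optional condition labels per sample (defaults to
#'   sample titles).
#' @return an [expression_matrix()] (no flags; the format carries none).
#' @export
read_series_matrix <- function(path, conditions = NULL) {
  lines <- readLines(path, warn = FALSE)
  titles <- NULL
  t_line <- grep("^!Sample_title\\b", lines, value = TRUE)
  if (length(t_line)) {
    titles <- gsub('"', "", strsplit(t_line[1L], "\t")[[1L]][-1L])
  }
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (!length(beg) || !length(end) || end[1L] <= beg[1L] + 1L) {
    .stopf("no series-matrix table found in %s", path)
  }
  tab <- read.delim(text = paste(lines[(beg[1L] + 1L):(end[1L] - 1L)],
                                 collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  sig <- as.matrix(as.data.frame(lapply(tab[-1L], .as_num)))
  rownames(sig) <- as.character(tab[[1L]])
  colnames(sig) <- names(tab)[-1L]
  if (is.null(conditions)) {
    conditions <- if (!is.null(titles) && length(titles) == ncol(sig)) titles
                  else colnames(sig)
  }
  expression_matrix(sig, conditions = conditions)
}
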