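# 3'UTR handling, ARE motif counting, EASE scores and the ranked nested
# enrichment scan.

# normalise a nucleotide string to uppercase RNA (T -> U); validate alphabet
.as_rna <- function(seqs, what = "sequence") {
  s <- chartr("tT", "uU", toupper(as.character(seqs)))
  bad <- grepl("[^ACGUN]", s)
  if (any(bad)) {
    .stopf("%s contains letters outside {A,C,G,U,N} (after T->U): e.g. '%s'",
           what, substr(s[which(bad)[1L]], 1L, 30L))
  }
  s
}

#' 3'UTR sequence set
#'
#' One RNA sequence per gene. DNA input is transcribed (T to U) and
#' uppercased on construction; soft-masked lowercase letters are treated as
#' their uppercase base.
#'
#' @param gene_symbol character gene symbols (unique).
#' @param sequence character nucleotide sequences over A/C/G/U/N (T allowed
#'   on input).
#' @return data.frame of class `"utr_set"` with columns `gene_symbol`,
#'   `sequence`, `length`.
#' @export
utr_set <- function(gene_symbol, sequence) {
  if (anyDuplicated(gene_symbol)) {
    .stopf("utr_set requires one sequence per gene; duplicated: %s",
           paste(unique(gene_symbol[duplicated(gene_symbol)]), collapse = ", "))
  }
  sequence <- .as_rna(sequence)
  out <- data.frame(gene_symbol = as.character(gene_symbol),
                    sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("utr_set", "data.frame")
  out
}

#' Select the longest 3'UTR per gene
#'
#' Collapses transcript-level UTR records to one sequence per gene by taking
#' the maximum-length variant; ties are broken lexicographically by
#' transcript id (deterministic, reported). Records with empty sequences
#' are dropped with a warning.
#'
#' @param records data.frame with columns `gene_symbol` (or `gene`),
#'   `transcript_id`, `sequence`.
#' @return a [utr_set()].
#' @export
select_longest_utr <- function(records) {
  if (!is.data.frame(records) || !nrow(records)) {
    .stopf("select_longest_utr() needs a non-empty data.frame of records")
  }
  nm <- names(records)
  gcol <- intersect(c("gene_symbol", "gene"), nm)[1L]
  if (is.na(gcol) || !all(c("transcript_id", "sequence") %in% nm)) {
    .stopf("records need gene_symbol (or gene), transcript_id and sequence columns")
  }
  seqs <- as.character(records$sequence)
  empty <- is.na(seqs) | nchar(seqs) == 0L
  if (any(empty)) {
    .warnf("dropped %d record(s) with empty sequences", sum(empty))
    records <- records[!empty, , drop = FALSE]
    if (!nrow(records)) .stopf("no records left after dropping empty sequences")
  }
  ord <- order(records[[gcol]], -nchar(as.character(records$sequence)),
               as.character(records$transcript_id))
  records <- records[ord, , drop = FALSE]
  first <- !duplicated(records[[gcol]])
  ties <- tapply(nchar(as.character(records$sequence)), records[[gcol]],
                 function(l) sum(l == max(l)) > 1L)
  if (any(ties)) {
    .msgf("select_longest_utr: %d gene(s) had length ties, broken by transcript id",
          sum(ties))
  }
  utr_set(records[[gcol]][first], records$sequence[first])
}

#' Count ARE motif matches in RNA sequences
#'
#' Counts the window start positions at which an IUPAC RNA pattern (default
#' the Transterm AU-rich element consensus `UAUUUAUWW`, W = A or U) matches,
#' overlapping windows allowed. `N` in a sequence never matches. Sequences
#' shorter than the pattern yield 0.
#'
#' @param sequence character vector of RNA/DNA sequences (T transcribed to
#'   U), or a [utr_set()].
#' @param pattern IUPAC RNA pattern.
#' @return integer vector of match counts.
#' @examples
#' count_are(c("UAUUUAUAA", "UAUUUAUGG"))  # 1, 0
#' @export
count_are <- function(sequence, pattern = "UAUUUAUWW") {
  if (inherits(sequence, "utr_set")) sequence <- sequence$sequence
  s <- .as_rna(sequence)
  pat <- Biostrings::RNAString(chartr("tT", "uU", toupper(pattern)))
  if (!length(s)) return(integer(0))
  subj <- Biostrings::RNAStringSet(s)
  # fixed = "subject": IUPAC codes in the pattern are expanded (W -> A|U)
  # while subject letters stay literal, so N in a sequence never matches.
  as.integer(Biostrings::vcountPattern(pat, subj, fixed = "subject"))
}

#' ARE catalogue against a background gene universe
#'
#' Counts ARE matches for the analysis genes and for a background set
#' filtered to UTRs of at least `min_utr_length` nucleotides (default 10,
#' the "longer than 9 nt" rule). Records the background size `N` and the
#' number `K` of background genes carrying at least one ARE; these feed the
#' EASE-score enrichment tests.
#'
#' @param utrs [utr_set()] of analysis genes.
#' @param background [utr_set()] of the background universe (ideally a
#'   superset of the analysis genes; a disjoint background is allowed with a
#'   warning).
#' @param pattern IUPAC RNA ARE pattern.
#' @param min_utr_length minimum UTR length retained (must be at least the
#'   pattern length).
#' @return object of class `"are_catalog"`: list with `pattern`, `counts`
#'   (named integer, analysis genes), `background_counts`, `N`, `K`,
#'   `min_utr_length`.
#' @export
build_catalog <- function(utrs, background, pattern = "UAUUUAUWW",
                          min_utr_length = 10) {
  if (!inherits(utrs, "utr_set") || !inherits(background, "utr_set")) {
    .stopf("utrs and background must be utr_set objects")
  }
  if (!nrow(background)) .stopf("background set is empty")
  if (min_utr_length < nchar(pattern)) {
    .stopf("min_utr_length (%d) is shorter than the pattern (%d nt)",
           min_utr_length, nchar(pattern))
  }
  keep_bg <- background$length >= min_utr_length
  if (any(!keep_bg)) {
    .msgf("build_catalog: %d background gene(s) below %d nt excluded",
          sum(!keep_bg), min_utr_length)
  }
  background <- background[keep_bg, , drop = FALSE]
  if (!nrow(background)) .stopf("background set is empty after length filter")
  keep_an <- utrs$length >= min_utr_length
  if (any(!keep_an)) {
    .msgf("build_catalog: %d analysis gene(s) below %d nt excluded",
          sum(!keep_an), min_utr_length)
  }
  utrs <- utrs[keep_an, , drop = FALSE]
  if (!all(utrs$gene_symbol %in% background$gene_symbol)) {
    .warnf("analysis genes are not all contained in the background set")
  }
  bg_counts <- setNames(count_are(background$sequence, pattern),
                        background$gene_symbol)
  counts <- setNames(count_are(utrs$sequence, pattern), utrs$gene_symbol)
  structure(list(pattern = pattern, counts = counts,
                 background_counts = bg_counts,
                 N = length(bg_counts), K = sum(bg_counts >= 1L),
                 min_utr_length = min_utr_length),
            class = "are_catalog")
}

#' ARE catalogue from precomputed counts
#'
#' Builds an [build_catalog()]-compatible catalogue directly from per-gene
#' ARE counts and stated background totals — useful when counts are
#' published alongside a ranked list (as in [example_bound_genes()]) but
#' the underlying sequences are not.
#'
#' @param counts named non-negative integer vector (gene -> ARE count).
#' @param K background ARE-positive gene count.
#' @param N background size (`K <= N`).
#' @param pattern the ARE pattern the counts refer to.
#' @return an `"are_catalog"`.
#' @export
are_catalog_from_counts <- function(counts, K, N, pattern = "UAUUUAUWW") {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    .stopf("counts must be a named vector (gene -> ARE count)")
  }
  if (any(counts < 0)) .stopf("ARE counts must be non-negative")
  if (K > N) .stopf("background positives K (%g) exceed N (%g)", K, N)
  structure(list(pattern = pattern,
                 counts = setNames(as.integer(counts), names(counts)),
                 background_counts = NULL,
                 N = as.integer(N), K = as.integer(K),
                 min_utr_length = nchar(pattern) + 1L),
            class = "are_catalog")
}

#' @export
print.are_catalog <- function(x, ...) {
  cat(sprintf("are_catalog: pattern %s, %d analysis genes, background N = %d, K = %d ARE-positive\n",
              x$pattern, length(x$counts), x$N, x$K))
  invisible(x)
}

#' EASE score (conservative one-sided Fisher enrichment p-value)
#'
#' The EASE score is the one-sided Fisher exact upper-tail p-value for
#' enrichment of positives in a gene list, computed after removing one
#' positive from the list cell: with `X ~ Hypergeometric(N, K, n)`,
#' `p = P(X >= k - 1)` (list total `n` unchanged). For `k <= 1` the score is
#' 1 by construction, penalising single-gene categories.
#'
#' @param k positives in the list (vectorised).
#' @param n list size.
#' @param K positives in the background.
#' @param N background size.
#' @return p-value(s) in (0, 1].
#' @export
ease_score <- function(k, n, K, N) {
  ln <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, ln); n <- rep_len(n, ln)
  K <- rep_len(K, ln); N <- rep_len(N, ln)
  if (any(k < 0)) .stopf("k must be >= 0 (got %g)", min(k))
  if (any(k > n)) .stopf("k (%g) exceeds list size n (%g)",
                         k[which(k > n)[1L]], n[which(k > n)[1L]])
  if (any(n > N)) .stopf("list size n (%g) exceeds background N (%g)",
                         n[which(n > N)[1L]], N[which(n > N)[1L]])
  if (any(k > K)) .stopf("k (%g) exceeds background positives K (%g)",
                         k[which(k > K)[1L]], K[which(k > K)[1L]])
  if (any(K > N)) .stopf("background positives K (%g) exceed N (%g)",
                         K[which(K > N)[1L]], N[which(K > N)[1L]])
  p <- phyper(k - 2, K, N - K, n, lower.tail = FALSE)
  p[k <= 1] <- 1
  pmin(p, 1)
}

#' Ranked nested ARE enrichment scan
#'
#' Walks down a ranked gene list (descending fold enrichment): for every
#' prefix length `n`, counts the ARE-positive genes `k_n` among the top `n`
#' and computes the EASE score against the catalogue background. The
#' reported optimum `argmax_n` is the smallest prefix attaining the minimal
#' p-value. Ranked genes missing from the catalogue (no annotated UTR) are
#' dropped with a reported count before scanning. The scan reports the raw
#' per-prefix curve; the minimum over n is not multiplicity-corrected.
#'
#' @param ranked a [bound_gene_list()] (or data.frame with `gene_symbol`,
#'   in rank order).
#' @param catalog an [are_catalog()].
#' @return object of class `"enrichment_scan"`: list with `table`
#'   (data.frame `n`, `k`, `p`, `log10_p`), `argmax_n`, `min_p`,
#'   `n_dropped`, `K`, `N`, `pattern`.
#' @export
nested_enrichment_scan <- function(ranked, catalog) {
  if (!inherits(catalog, "are_catalog")) .stopf("catalog must be an are_catalog")
  genes <- if (is.data.frame(ranked)) as.character(ranked$gene_symbol)
           else as.character(ranked)
  if (!length(genes)) .stopf("the ranked gene list is empty")
  known <- genes %in% names(catalog$counts)
  if (any(!known)) {
    .msgf("nested_enrichment_scan: dropped %d ranked gene(s) with no catalogued 3'UTR",
          sum(!known))
    genes <- genes[known]
  }
  if (!length(genes)) .stopf("no ranked genes have a catalogued 3'UTR")
  pos <- catalog$counts[genes] >= 1L
  n <- seq_along(genes)
  k <- cumsum(pos)
  p <- ease_score(k, n, catalog$K, catalog$N)
  argmax_n <- which.min(p)  # first index: smallest n on ties
  tab <- data.frame(n = n, k = as.integer(k), p = p, log10_p = log10(p),
                    gene_symbol = genes, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab, argmax_n = argmax_n, min_p = p[argmax_n],
                 n_dropped = sum(!known), K = catalog$K, N = catalog$N,
                 pattern = catalog$pattern),
            class = "enrichment_scan")
}

#' @export
print.enrichment_scan <- function(x, ...) {
  tab <- x$table
  cat(sprintf("enrichment_scan: %d ranked genes (%d dropped, no UTR), background K/N = %d/%d\n",
              nrow(tab), x$n_dropped, x$K, x$N))
  cat(sprintf("  max significance at n = %d: p = %.3g (k = %d ARE-positive)\n",
              x$argmax_n, x$min_p, tab$k[x$argmax_n]))
  cat(sprintf("  full list: %d/%d (%.1f%%) ARE-positive\n",
              tab$k[nrow(tab)], nrow(tab), 100 * tab$k[nrow(tab)] / nrow(tab)))
  invisible(x)
}

#' Plot the nested enrichment curve
#'
#' log10 EASE p-value against prefix size, with the optimum marked.
#'
#' @param x an `"enrichment_scan"`.
#' @param ... passed to [plot()].
#' @export
plot.enrichment_scan <- function(x, ...) {
  tab <- x$table
  plot(tab$n, tab$log10_p, type = "l", lwd = 2,
       xlab = "top n ranked genes", ylab = "log10 enrichment p-value", ...)
  abline(v = x$argmax_n, col = "forestgreen", lwd = 2)
  abline(h = 0, col = "grey70")
  invisible(x)
}
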