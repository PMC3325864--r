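#' Expression matrix with detection flags and provenance
#'
#' Container for a probe x sample microarray signal matrix with per-sample
#' condition labels and optional present/absent detection flags. Provenance
#' flags record which pipeline stages have been applied; each stage refuses
#' to run twice and enforces its prerequisites, so the stated order
#' (log2 transform, then optional 75th-percentile-shift normalisation and
#' median baselining, then flag and CV filters, then testing) cannot be
#' scrambled silently.
#'
#' @param signals numeric probe x sample matrix (raw linear scale unless
#'   `log2_transformed = TRUE`), with probe rownames and sample colnames.
#' @param conditions character vector (or named map) of condition labels,
#'   one per sample.
#' @param flags optional probe x sample matrix of detection calls, either
#'   logical (TRUE = present) or character `"P"`/`"A"`.
#' @param log2_transformed,normalized,baselined provenance of the input.
#' @return object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(signals, conditions, flags = NULL,
                              log2_transformed = FALSE, normalized = FALSE,
                              baselined = FALSE) {
  signals <- as.matrix(signals)
  if (is.null(rownames(signals))) {
    rownames(signals) <- sprintf("P%05d", seq_len(nrow(signals)))
  }
  if (is.null(colnames(signals))) {
    colnames(signals) <- sprintf("S%d", seq_len(ncol(signals)))
  }
  if (length(conditions) != ncol(signals)) {
    .stopf("need one condition label per sample (%d labels for %d samples)",
           length(conditions), ncol(signals))
  }
  conditions <- setNames(as.character(conditions), colnames(signals))
  if (!is.null(flags)) {
    flags <- as.matrix(flags)
    if (!identical(dim(flags), dim(signals))) {
      .stopf("flags dimensions (%s) do not match signals (%s)",
             paste(dim(flags), collapse = "x"),
             paste(dim(signals), collapse = "x"))
    }
    if (is.character(flags)) flags <- toupper(flags) == "P"
    storage.mode(flags) <- "logical"
    dimnames(flags) <- dimnames(signals)
  }
  structure(list(signals = signals, conditions = conditions, flags = flags,
                 provenance = list(log2 = isTRUE(log2_transformed),
                                   normalized = isTRUE(normalized),
                                   baselined = isTRUE(baselined),
                                   absent_filtered = FALSE,
                                   cv_filtered = FALSE)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  p <- x$provenance
  stages <- names(p)[unlist(p)]
  cat(sprintf("expression_matrix: %d probes x %d samples (%s)\n",
              nrow(x$signals), ncol(x$signals),
              paste(sprintf("%s=%d", unique(x$conditions),
                            tabulate(factor(x$conditions))), collapse = ", ")))
  cat("  stages applied:", if (length(stages)) paste(stages, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$signals)

.check_em <- function(x) {
  if (!inherits(x, "expression_matrix")) {
    .stopf("expected an expression_matrix")
  }
  x
}

#' Log2-transform microarray signals
#'
#' Element-wise log2 of the linear signals. Non-positive values are floored
#' to `epsilon` first (the number of floored cells is reported). Refuses to
#' run on data already log2 transformed.
#'
#' @param x an [expression_matrix()].
#' @param epsilon positive floor for non-positive signals.
#' @return the transformed [expression_matrix()].
#' @export
log2_transform <- function(x, epsilon = 1e-6) {
  x <- .check_em(x)
  if (x$provenance$log2) .stopf("signals are already log2 transformed")
  if (epsilon <= 0) .stopf("epsilon must be positive")
  bad <- x$signals <= 0
  if (any(bad)) {
    .msgf("log2_transform: floored %d non-positive signal(s) to %g",
          sum(bad), epsilon)
    x$signals[bad] <- epsilon
  }
  x$signals <- log2(x$signals)
  x$provenance$log2 <- TRUE
  .msgf("log2_transform: applied to %d probes x %d samples",
        nrow(x$signals), ncol(x$signals))
  x
}

#' Percentile-shift normalisation
#'
#' Per sample, subtracts that sample's `percentile`-th percentile of the
#' log2 signal (linear interpolation between order statistics), so that
#' afterwards each sample's chosen percentile equals zero. The default, 75,
#' is the standard percentile-shift used for single-channel arrays.
#'
#' @param x a log2-transformed [expression_matrix()].
#' @param percentile percentile in (0, 100).
#' @return the normalised [expression_matrix()].
#' @export
normalize_percentile_shift <- function(x, percentile = 75) {
  x <- .check_em(x)
  if (!x$provenance$log2) .stopf("normalisation requires log2-transformed signals")
  if (x$provenance$normalized) .stopf("signals are already normalised")
  q <- apply(x$signals, 2L, quantile, probs = percentile / 100,
             type = 7, names = FALSE)
  x$signals <- sweep(x$signals, 2L, q, "-")
  x$provenance$normalized <- TRUE
  .msgf("normalize_percentile_shift: %gth percentile shift per sample", percentile)
  x
}

#' Baseline each probe to its cross-sample median
#'
#' Per probe, subtracts the median of that probe's values across all
#' samples; afterwards every probe's cross-sample median is zero.
#'
#' @param x a normalised [expression_matrix()].
#' @return the baselined [expression_matrix()].
#' @export
baseline_to_median <- function(x) {
  x <- .check_em(x)
  if (!x$provenance$normalized) .stopf("baselining requires normalised signals")
  if (x$provenance$baselined) .stopf("signals are already baselined")
  med <- apply(x$signals, 1L, median)
  x$signals <- sweep(x$signals, 1L, med, "-")
  x$provenance$baselined <- TRUE
  .msgf("baseline_to_median: per-probe median baseline")
  x
}

#' Remove probes flagged absent in all samples
#'
#' A probe is retained iff it is flagged present in at least one sample.
#' With no flags supplied, all probes are kept and a warning is raised.
#'
#' @param x an [expression_matrix()].
#' @return the filtered [expression_matrix()].
#' @export
filter_absent <- function(x) {
  x <- .check_em(x)
  if (x$provenance$absent_filtered) .stopf("absent-flag filter already applied")
  if (is.null(x$flags)) {
    .warnf("no detection flags supplied; keeping all %d probes", nrow(x$signals))
    x$provenance$absent_filtered <- TRUE
    return(x)
  }
  keep <- rowSums(x$flags) >= 1L
  .msgf("filter_absent: removed %d of %d probes absent in all samples",
        sum(!keep), length(keep))
  x$signals <- x$signals[keep, , drop = FALSE]
  x$flags <- x$flags[keep, , drop = FALSE]
  x$provenance$absent_filtered <- TRUE
  x
}

#' Remove probes with high within-condition coefficient of variation
#'
#' Per probe and condition, the CV is sd/mean of the linear-scale
#' intensities (`2^log2signal`); a probe is removed if its CV exceeds
#' `cv_threshold` in any condition. Conditions with a single replicate have
#' undefined CV and do not count against the probe (a warning is raised).
#'
#' @param x a log2-transformed [expression_matrix()].
#' @param cv_threshold maximum allowed CV (default 0.5, i.e. 50%).
#' @return the filtered [expression_matrix()].
#' @export
filter_cv <- function(x, cv_threshold = 0.5) {
  x <- .check_em(x)
  if (!x$provenance$log2) .stopf("CV filter expects log2-transformed signals")
  if (x$provenance$cv_filtered) .stopf("CV filter already applied")
  if (cv_threshold <= 0) .stopf("cv_threshold must be positive")
  lin <- 2^x$signals
  conds <- unique(x$conditions)
  drop <- rep(FALSE, nrow(lin))
  for (cc in conds) {
    cols <- which(x$conditions == cc)
    if (length(cols) < 2L) {
      .warnf("condition '%s' has a single replicate; CV undefined, probes retained",
             cc)
      next
    }
    m <- rowMeans(lin[, cols, drop = FALSE])
    s <- apply(lin[, cols, drop = FALSE], 1L, sd)
    drop <- drop | (s / m > cv_threshold)
  }
  .msgf("filter_cv: removed %d of %d probes with CV > %g in any condition",
        sum(drop), length(drop), cv_threshold)
  x$signals <- x$signals[!drop, , drop = FALSE]
  if (!is.null(x$flags)) x$flags <- x$flags[!drop, , drop = FALSE]
  x$provenance$cv_filtered <- TRUE
  x
}

# vectorised row-wise Welch t statistics; cross-checked against t.test in
# the test suite
.welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    p[eq] <- 1          # zero variance, equal means: no evidence by convention
    p[degen & !eq] <- 0 # zero variance, different means
    t[eq] <- 0; t[degen & !eq] <- Inf * sign((ma - mb)[degen & !eq])
    df[degen] <- NA_real_
  }
  list(diff = ma - mb, t = t, df = df, p = p, n_degenerate = sum(degen))
}

#' Welch t-test contrast with Benjamini-Hochberg correction
#'
#' Per-probe two-sample Welch (unequal variance) t-test between two
#' conditions of a log2-scale expression matrix, with BH step-up adjustment
#' across the retained probes. The log2 fold change is
#' `mean(group_a) - mean(group_b)`; significance requires adjusted
#' p < `p_threshold` and a linear fold-change threshold, applied either to
#' the signed fold (`fold_rule = "positive"`, group_a over group_b) or to
#' its magnitude in both directions (`fold_rule = "absolute"`).
#'
#' @param x a log2-transformed [expression_matrix()].
#' @param group_a,group_b condition labels to contrast (a minus b).
#' @param p_threshold adjusted-p significance threshold.
#' @param fold_threshold linear fold-change threshold (> 1).
#' @param fold_rule `"positive"` or `"absolute"`.
#' @return data.frame of class `"ripchip_contrast"` with columns
#'   `probe_id`, `log2_fc`, `fold_change` (signed linear), `t`, `df`, `p`,
#'   `p_adj`, `significant`, plus attributes recording the groups and rule.
#' @export
welch_bh_contrast <- function(x, group_a, group_b, p_threshold = 0.05,
                              fold_threshold = 2,
                              fold_rule = c("positive", "absolute")) {
  x <- .check_em(x)
  fold_rule <- match.arg(fold_rule)
  if (!x$provenance$log2) .stopf("contrast expects log2-transformed signals")
  ca <- which(x$conditions == group_a)
  cb <- which(x$conditions == group_b)
  if (length(ca) < 2L || length(cb) < 2L) {
    .stopf("both groups need >= 2 samples ('%s': %d, '%s': %d)",
           group_a, length(ca), group_b, length(cb))
  }
  w <- .welch_rows(x$signals[, ca, drop = FALSE], x$signals[, cb, drop = FALSE])
  if (w$n_degenerate > 0) {
    .msgf("welch_bh_contrast: %d probe(s) with zero variance in both groups",
          w$n_degenerate)
  }
  p_adj <- p.adjust(w$p, method = "BH")
  fc <- 2^w$diff
  pass_fold <- if (fold_rule == "positive") fc > fold_threshold
               else 2^abs(w$diff) > fold_threshold
  out <- data.frame(probe_id = rownames(x$signals), log2_fc = w$diff,
                    fold_change = fc, t = w$t, df = w$df, p = w$p,
                    p_adj = p_adj,
                    significant = p_adj < p_threshold & pass_fold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "fold_rule") <- fold_rule
  attr(out, "provenance") <- x$provenance
  class(out) <- c("ripchip_contrast", "data.frame")
  out
}

#' Differential-expression contrast with absolute fold rule
#'
#' Convenience wrapper for the cytoplasmic control-vs-treated comparison:
#' identical machinery to [welch_bh_contrast()] with
#' `fold_rule = "absolute"`, so both up- and down-regulated probes pass.
#'
#' @inheritParams welch_bh_contrast
#' @return see [welch_bh_contrast()].
#' @export
de_contrast_cyto <- function(x, group_a, group_b, p_threshold = 0.05,
                             fold_threshold = 2) {
  welch_bh_contrast(x, group_a, group_b, p_threshold = p_threshold,
                    fold_threshold = fold_threshold, fold_rule = "absolute")
}

#' Bound gene list
#'
#' A ranked list of genes with their linear-scale fold enrichments, sorted
#' in descending order of enrichment, with unique gene symbols.
#'
#' @param gene_symbol character gene symbols.
#' @param fold_enrichment positive linear fold enrichments.
#' @return data.frame of class `"bound_gene_list"`.
#' @export
bound_gene_list <- function(gene_symbol, fold_enrichment) {
  fold_enrichment <- .as_num(fold_enrichment)
  if (any(!is.finite(fold_enrichment) | fold_enrichment <= 0)) {
    .stopf("fold enrichments must be positive and finite")
  }
  if (anyDuplicated(gene_symbol)) {
    .stopf("gene symbols must be unique; duplicated: %s",
           paste(unique(gene_symbol[duplicated(gene_symbol)]), collapse = ", "))
  }
  ord <- order(-fold_enrichment)
  out <- data.frame(gene_symbol = as.character(gene_symbol)[ord],
                    fold_enrichment = fold_enrichment[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("bound_gene_list", "data.frame")
  out
}

#' Select the bound gene list from the two RIP contrasts
#'
#' Combines the RIP-vs-IgG contrast (computed on unnormalised, unbaselined
#' log2 signals, positive fold rule) with the RIP-vs-cytoplasm contrast
#' (computed on normalised, baselined signals): probes significant in both
#' (adjusted p below threshold and linear fold change above threshold toward
#' the RIP sample) are mapped to gene symbols, each gene keeps the maximum
#' fold enrichment among its probes (taken from the RIP-vs-cytoplasm
#' contrast), and the result is sorted in descending enrichment order.
#'
#' @param rip_vs_igg,rip_vs_cyto contrasts from [welch_bh_contrast()].
#' @param probe_to_gene named character vector mapping probe ids to gene
#'   symbols.
#' @return a [bound_gene_list()] (possibly empty).
#' @export
select_bound_genes <- function(rip_vs_igg, rip_vs_cyto, probe_to_gene) {
  if (!length(probe_to_gene)) {
    .warnf("empty probe-to-gene mapping; returning an empty bound gene list")
    return(bound_gene_list(character(0), numeric(0)))
  }
  pass <- intersect(rip_vs_igg$probe_id[rip_vs_igg$significant &
                                          rip_vs_igg$fold_change > 0],
                    rip_vs_cyto$probe_id[rip_vs_cyto$significant &
                                           rip_vs_cyto$fold_change > 0])
  if (!length(pass)) return(bound_gene_list(character(0), numeric(0)))
  fe <- rip_vs_cyto$fold_change[match(pass, rip_vs_cyto$probe_id)]
  genes <- unname(probe_to_gene[pass])
  unmapped <- is.na(genes)
  if (any(unmapped)) {
    .msgf("select_bound_genes: dropped %d passing probe(s) with no gene mapping",
          sum(unmapped))
    genes <- genes[!unmapped]; fe <- fe[!unmapped]
  }
  if (!length(genes)) return(bound_gene_list(character(0), numeric(0)))
  best <- tapply(fe, genes, max)
  bound_gene_list(names(best), as.numeric(best))
}

#' @export
print.bound_gene_list <- function(x, n = 10, ...) {
  cat(sprintf("bound_gene_list: %d genes, fold enrichment %.3g .. %.3g\n",
              nrow(x), if (nrow(x)) max(x$fold_enrichment) else NA,
              if (nrow(x)) min(x$fold_enrichment) else NA))
  if (nrow(x)) print.data.frame(head(x, n))
  invisible(x)
}
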