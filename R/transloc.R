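# Nucleocytoplasmic translocation z-scores from per-cell compartment
# intensities.

.check_cells <- function(records) {
  if (!is.data.frame(records) || !nrow(records)) {
    .stopf("expected a non-empty data.frame of per-cell records")
  }
  nm <- names(records)
  ncol_ <- intersect(c("nucleus", "nucleus_signal"), nm)[1L]
  ccol <- intersect(c("cytoplasm", "cytoplasm_signal"), nm)[1L]
  if (is.na(ncol_) || is.na(ccol) || !("condition" %in% nm)) {
    .stopf("records need condition, nucleus and cytoplasm columns; found: %s",
           paste(nm, collapse = ", "))
  }
  out <- data.frame(
    cell_id = if ("cell_id" %in% nm) as.character(records$cell_id)
              else sprintf("cell%05d", seq_len(nrow(records))),
    condition = as.character(records$condition),
    nucleus = .as_num(records[[ncol_]]),
    cytoplasm = .as_num(records[[ccol]]),
    stringsAsFactors = FALSE)
  bad <- !is.finite(out$nucleus) | !is.finite(out$cytoplasm) |
    out$nucleus <= 0 | out$cytoplasm <= 0
  if (any(bad)) {
    .msgf("dropped %d cell record(s) with non-positive or missing signals",
          sum(bad))
    out <- out[!bad, , drop = FALSE]
    if (!nrow(out)) .stopf("no valid cell records left")
  }
  out
}

#' Per-cell compartment intensity ratio
#'
#' Quotient of the two compartment signals in the stated direction. Records
#' with non-positive signals are dropped with a reported count.
#'
#' @param records data.frame with `condition`, `nucleus` and `cytoplasm`
#'   columns (a `nucleus_signal`/`cytoplasm_signal` naming is also
#'   accepted).
#' @param direction `"cytoplasm_over_nucleus"` (default) or
#'   `"nucleus_over_cytoplasm"`.
#' @return numeric ratio per retained cell.
#' @export
cell_ratio <- function(records,
                       direction = c("cytoplasm_over_nucleus",
                                     "nucleus_over_cytoplasm")) {
  direction <- match.arg(direction)
  r <- .check_cells(records)
  if (direction == "cytoplasm_over_nucleus") r$cytoplasm / r$nucleus
  else r$nucleus / r$cytoplasm
}

#' Per-condition translocation z-scores
#'
#' Computes, over all cells pooled across conditions, the mean `mu` and
#' standard deviation `delta` of the per-cell compartment ratio; each
#' condition is then summarised by the mean ratio `x` of its own cells and
#' standardised as `z = (x - mu) / delta`. With the default direction
#' (cytoplasm over nucleus) z above zero reads as more cytoplasmic than the
#' pooled population and z below zero as more nuclear, matching the usual
#' high-content-screening sign convention for translocation assays. The
#' Methods-style nucleus-over-cytosol ratio is available via `direction`;
#' the z values then change monotonically (and exactly flip sign in
#' `log_ratio` mode).
#'
#' @inheritParams cell_ratio
#' @param log_ratio if TRUE, z-scores are computed on natural-log ratios
#'   (robust to the skew of raw ratios; makes direction flips exact
#'   antisymmetries).
#' @return object of class `"translocation_z"`: data.frame with one row per
#'   condition (`condition`, `n_cells`, `x`, `z`, `call`) and attributes
#'   `mu`, `delta`, `direction`, `log_ratio`.
#' @export
condition_z_scores <- function(records,
                               direction = c("cytoplasm_over_nucleus",
                                             "nucleus_over_cytoplasm"),
                               log_ratio = FALSE) {
  direction <- match.arg(direction)
  r <- .check_cells(records)
  ratio <- if (direction == "cytoplasm_over_nucleus") r$cytoplasm / r$nucleus
           else r$nucleus / r$cytoplasm
  if (log_ratio) ratio <- log(ratio)
  n_per <- table(r$condition)
  if (any(n_per < 2L)) {
    .warnf("condition(s) with fewer than 2 cells: %s",
           paste(names(n_per)[n_per < 2L], collapse = ", "))
  }
  mu <- mean(ratio)
  delta <- sd(ratio)
  x <- tapply(ratio, r$condition, mean)
  if (!is.finite(delta) || delta == 0) {
    .warnf("pooled standard deviation is zero; all z-scores set to 0")
    z <- setNames(rep(0, length(x)), names(x))
  } else {
    z <- (x - mu) / delta
  }
  out <- data.frame(condition = names(x),
                    n_cells = as.integer(n_per[names(x)]),
                    x = as.numeric(x), z = as.numeric(z),
                    call = localization_call(as.numeric(z)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mu") <- mu
  attr(out, "delta") <- delta
  attr(out, "direction") <- direction
  attr(out, "log_ratio") <- log_ratio
  class(out) <- c("translocation_z", "data.frame")
  out
}

#' Localisation call from a translocation z-score
#'
#' Below the threshold (default 0) the call is `"nuclear"`, otherwise
#' `"cytoplasmic"`; a z exactly at the threshold is called cytoplasmic.
#' The convention assumes z was computed with the default
#' cytoplasm-over-nucleus direction.
#'
#' @param z numeric z-score(s).
#' @param threshold decision threshold.
#' @return character vector of `"nuclear"` / `"cytoplasmic"`.
#' @export
localization_call <- function(z, threshold = 0) {
  ifelse(z < threshold, "nuclear", "cytoplasmic")
}

#' @export
print.translocation_z <- function(x, ...) {
  cat(sprintf("translocation_z (%s%s): pooled mu = %.4g, delta = %.4g\n",
              attr(x, "direction"),
              if (attr(x, "log_ratio")) ", log-ratio" else "",
              attr(x, "mu"), attr(x, "delta")))
  print.data.frame(x)
  invisible(x)
}

#' Plot per-condition translocation z-scores
#'
#' @param x a `"translocation_z"`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.translocation_z <- function(x, ...) {
  graphics::barplot(setNames(x$z, x$condition),
                    ylab = "translocation z-score", ...)
  abline(h = 0)
  invisible(x)
}
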