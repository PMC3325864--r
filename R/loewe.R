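#' Fixed-ratio two-drug design
#'
#' Describes a constant-ratio mixture design: at total dose `d` the component
#' doses are `dA = d * r / (1 + r)` and `dB = d / (1 + r)` where
#' `r = ratio_a_to_b` (default 10, e.g. rottlerin:doxorubicin 10:1).
#'
#' @param drug_a,drug_b component drug labels.
#' @param ratio_a_to_b positive A:B dose ratio.
#' @param total_doses optional vector of total mixture doses (uM).
#' @return object of class `"fixed_ratio_design"`.
#' @export
fixed_ratio_design <- function(drug_a = "A", drug_b = "B",
                               ratio_a_to_b = 10, total_doses = NULL) {
  if (!is.numeric(ratio_a_to_b) || length(ratio_a_to_b) != 1L ||
      !is.finite(ratio_a_to_b) || ratio_a_to_b <= 0) {
    .stopf("ratio_a_to_b must be a single positive number")
  }
  structure(list(drug_a = drug_a, drug_b = drug_b,
                 ratio_a_to_b = ratio_a_to_b, total_doses = total_doses),
            class = "fixed_ratio_design")
}

# split a total mixture dose into components under the fixed ratio
.split_dose <- function(design, total) {
  r <- design$ratio_a_to_b
  list(a = total * r / (1 + r), b = total / (1 + r))
}

#' Loewe combination index at given fractions affected
#'
#' For a fixed-ratio mixture achieving fraction affected `fa` at total dose
#' `D_mix` (obtained by inverting the mixture fit), the Loewe combination
#' index is
#' \deqn{CI(fa) = dA / D_A(fa) + dB / D_B(fa)}
#' where `dA`, `dB` are the ratio split of `D_mix` and `D_A(fa)`, `D_B(fa)`
#' the single-agent iso-effect doses. CI = 1 is Loewe additivity, CI > 1
#' antagonism, CI < 1 synergy. Fraction affected is defined per curve as the
#' fraction of its own fitted maximal effect, which makes the sham
#' combination (a drug mixed with itself) give CI = 1 exactly.
#'
#' @param fa fraction(s) affected in (0, 1).
#' @param fit_a,fit_b,fit_mix converged `"fourpl"` fits of the two single
#'   agents and of the mixture (on total dose).
#' @param design a [fixed_ratio_design()].
#' @return numeric CI value per `fa`.
#' @export
loewe_ci <- function(fa, fit_a, fit_b, fit_mix, design) {
  for (nm in c("fit_a", "fit_b", "fit_mix")) {
    f <- get(nm)
    if (inherits(f, "fourpl") && !isTRUE(f$converged)) {
      .stopf("%s has not converged", nm)
    }
  }
  d_mix <- invert_4pl(fit_mix, fa)
  comp <- .split_dose(design, d_mix)
  comp$a / invert_4pl(fit_a, fa) + comp$b / invert_4pl(fit_b, fa)
}

# single-start warm refit used by the bootstrap
.refit_4pl <- function(tab, start) {
  dose <- tab$dose_uM; resp <- tab$response
  l10d <- log10(dose)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      resp ~ bottom + (top - bottom) / (1 + 10^(hill * (l10d - l10ic50))),
      start = list(top = unname(start["top"]), bottom = unname(start["bottom"]),
                   l10ic50 = unname(log10(start["ic50"])),
                   hill = unname(start["hill"])),
      control = minpack.lm::nls.lm.control(maxiter = 80)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (any(!is.finite(cf))) return(NULL)
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  hill <- unname(cf["hill"]); ic50 <- unname(10^cf["l10ic50"])
  if (top < bottom) { tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill }
  list(ic50 = ic50, hill = hill, top = top, bottom = bottom, converged = TRUE)
}

# case-resample replicates within each dose
.resample_plate <- function(tab) {
  idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$dose_uM),
                       function(i) sample(i, length(i), replace = TRUE)),
                use.names = FALSE)
  tab[idx, , drop = FALSE]
}

#' Combination-index analysis of a fixed-ratio design
#'
#' Fits 4PL curves to the two single agents and the mixture, evaluates the
#' Loewe combination index over a grid of fractions affected, attaches
#' bootstrap confidence bands (case resampling of replicates within dose),
#' and classifies the interaction:
#' *antagonistic* if the lower band is above 1 on at least half of the grid,
#' *synergistic* if the upper band is below 1 likewise, *additive* if the
#' band straddles 1 on at least half of the grid, otherwise *indeterminate*.
#'
#' @param table_a,table_b,table_mix [dose_response_table()]s for drug A
#'   alone, drug B alone, and the mixture (responses vs total dose).
#' @param design a [fixed_ratio_design()].
#' @param n_boot bootstrap replicates (>= 1).
#' @param fa_grid fractions affected to evaluate.
#' @param conf band coverage (default 0.95).
#' @return object of class `"combination_result"`: a list with `fa_grid`,
#'   `ci`, `ci_lower`, `ci_upper`, `classification`, the three fits and the
#'   design. If any fit fails the result is classified `indeterminate` with
#'   the failure message attached.
#' @export
analyze_combination <- function(table_a, table_b, table_mix, design,
                                n_boot = 200,
                                fa_grid = seq(0.05, 0.95, by = 0.05),
                                conf = 0.95) {
  if (n_boot < 1) .stopf("n_boot must be >= 1")
  tabs <- list(a = .as_plate(table_a), b = .as_plate(table_b),
               mix = .as_plate(table_mix))
  fits <- lapply(tabs, function(t) tryCatch(fit_4pl(t), error = identity))
  failed <- vapply(fits, inherits, logical(1), "condition")
  if (any(failed)) {
    return(structure(list(fa_grid = fa_grid, ci = rep(NA_real_, length(fa_grid)),
                          ci_lower = NULL, ci_upper = NULL,
                          classification = "indeterminate",
                          failure = conditionMessage(fits[[which(failed)[1L]]]),
                          design = design, fits = fits),
                     class = "combination_result"))
  }

  ci_hat <- loewe_ci(fa_grid, fits$a, fits$b, fits$mix, design)

  boot <- matrix(NA_real_, nrow = n_boot, ncol = length(fa_grid))
  starts <- lapply(fits, coef)
  for (b in seq_len(n_boot)) {
    rb <- lapply(tabs, .resample_plate)
    fb <- Map(.refit_4pl, rb, starts)
    if (any(vapply(fb, is.null, logical(1)))) next
    boot[b, ] <- tryCatch(
      loewe_ci(fa_grid, fb$a, fb$b, fb$mix, design),
      error = function(e) rep(NA_real_, length(fa_grid)))
  }
  alpha <- (1 - conf) / 2
  qsafe <- function(v, p) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    quantile(v, probs = p, names = FALSE)
  }
  lo <- apply(boot, 2L, qsafe, p = alpha)
  hi <- apply(boot, 2L, qsafe, p = 1 - alpha)
  # band must contain the point estimate
  lo <- pmin(lo, ci_hat)
  hi <- pmax(hi, ci_hat)

  frac_ant <- mean(lo > 1)
  frac_syn <- mean(hi < 1)
  frac_add <- mean(lo <= 1 & hi >= 1)
  classification <- if (frac_ant >= 0.5) "antagonistic"
    else if (frac_syn >= 0.5) "synergistic"
    else if (frac_add >= 0.5) "additive"
    else "indeterminate"

  structure(list(fa_grid = fa_grid, ci = ci_hat, ci_lower = lo, ci_upper = hi,
                 classification = classification, n_boot = n_boot,
                 conf = conf, design = design, fits = fits),
            class = "combination_result")
}

#' @export
print.combination_result <- function(x, ...) {
  cat(sprintf("Loewe combination index: %s + %s (ratio %g:1)\n",
              x$design$drug_a, x$design$drug_b, x$design$ratio_a_to_b))
  cat(sprintf("  classification: %s\n", x$classification))
  if (!is.null(x$failure)) {
    cat("  fit failure:", x$failure, "\n")
    return(invisible(x))
  }
  mid <- which.min(abs(x$fa_grid - 0.5))
  cat(sprintf("  CI at fa = %.2f: %.3f [%.3f, %.3f] (%d bootstrap reps)\n",
              x$fa_grid[mid], x$ci[mid], x$ci_lower[mid], x$ci_upper[mid],
              x$n_boot))
  invisible(x)
}

#' Plot a combination-index curve with its bootstrap band
#'
#' @param x a `"combination_result"`.
#' @param ... passed to [plot()].
#' @export
plot.combination_result <- function(x, ...) {
  if (!is.null(x$failure)) .stopf("nothing to plot: %s", x$failure)
  ylim <- range(c(x$ci, x$ci_lower, x$ci_upper, 1), finite = TRUE)
  plot(x$fa_grid, x$ci, type = "b", pch = 16, ylim = ylim,
       xlab = "fraction affected", ylab = "combination index",
       main = sprintf("%s + %s: %s", x$design$drug_a, x$design$drug_b,
                      x$classification), ...)
  lines(x$fa_grid, x$ci_lower, lty = 2, col = "grey40")
  lines(x$fa_grid, x$ci_upper, lty = 2, col = "grey40")
  abline(h = 1, col = "firebrick")
  invisible(x)
}
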