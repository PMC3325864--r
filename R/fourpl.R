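#' Dose-response plate table
#'
#' Container for one drug/condition viability experiment: one row per
#' replicate measurement at each dose. Doses are in micromolar; responses
#' are arbitrary luminescence/viability units.
#'
#' @param dose numeric vector of doses (uM), strictly positive.
#' @param response numeric vector of responses, same length as `dose`.
#' @param drug single character drug label.
#' @param condition single character condition (e.g. cell line) label.
#' @param replicate optional integer replicate index per row.
#' @return A `data.frame` of class `"dose_response_table"` with columns
#'   `drug`, `condition`, `dose_uM`, `replicate`, `response`.
#' @examples
#' dose_response_table(c(0.1, 1, 10), c(90, 50, 10), drug = "doxorubicin")
#' @export
dose_response_table <- function(dose, response, drug = "drug",
                                condition = "", replicate = NULL) {
  dose <- .as_num(dose)
  response <- .as_num(response)
  if (length(dose) != length(response)) {
    .stopf("dose and response lengths differ (%d vs %d)",
           length(dose), length(response))
  }
  bad <- which(!is.finite(dose) | dose <= 0)
  if (length(bad)) {
    .stopf("all doses must be positive and finite; offending value %s at row %d",
           deparse(dose[bad[1L]]), bad[1L])
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(dose, dose, FUN = seq_along)
  }
  out <- data.frame(drug = as.character(drug), condition = as.character(condition),
                    dose_uM = dose, replicate = as.integer(replicate),
                    response = response, stringsAsFactors = FALSE)
  class(out) <- c("dose_response_table", "data.frame")
  out
}

# coerce data.frame-like input (incl. TSV reads) to the canonical columns
.as_plate <- function(table) {
  if (inherits(table, "dose_response_table")) return(table)
  if (!is.data.frame(table)) .stopf("expected a dose_response_table or data.frame")
  nm <- names(table)
  dcol <- intersect(c("dose_uM", "dose"), nm)[1L]
  rcol <- intersect(c("response", "viability"), nm)[1L]
  if (is.na(dcol) || is.na(rcol)) {
    .stopf("table must have dose (dose_uM) and response columns; found: %s",
           paste(nm, collapse = ", "))
  }
  dose_response_table(table[[dcol]], table[[rcol]],
                      drug = if ("drug" %in% nm) table$drug[1L] else "drug",
                      condition = if ("condition" %in% nm) table$condition[1L] else "",
                      replicate = if ("replicate" %in% nm) table$replicate else NULL)
}

# the 4PL mean function; decreasing in dose for hill > 0
.fourpl_fun <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic (4PL) dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + (top - bottom) / (1 + (d/IC50)^{hill})}
#' on log10 dose, the "log(inhibitor) vs response -- variable slope" model.
#' Initialisation is multi-start: `top`/`bottom` from the extreme responses,
#' IC50 from the dose pair bracketing the half-range response, and hill slope
#' started at 0.5, 1 and 2; the start with the lowest residual sum of squares
#' wins, ties going to the smallest hill. Responses are used untransformed and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} is computed on the fitted scale.
#'
#' @param table a [dose_response_table()] (or data.frame with `dose_uM` and
#'   `response` columns) with at least 4 distinct positive doses.
#' @return An object of class `"fourpl"`: a list with elements `ic50`,
#'   `hill`, `top`, `bottom`, `r_squared`, `converged`, `drug`, `condition`,
#'   `data`, `fitted.values`, `residuals` and `warnings`. A warning is
#'   attached (and raised) when the fitted IC50 lies outside the tested dose
#'   range. If no start converges the best parameters found are returned with
#'   `converged = FALSE`.
#' @seealso [invert_4pl()], [fold_resistance()], [predict.fourpl()]
#' @examples
#' tab <- dose_response_table(10^seq(-3, 1, length.out = 8),
#'                            .fourpl_ex(10^seq(-3, 1, length.out = 8)))
#' fit <- fit_4pl(tab)
#' coef(fit)
#' @export
fit_4pl <- function(table) {
  tab <- .as_plate(table)
  dose <- tab$dose_uM
  resp <- tab$response
  if (length(unique(dose)) < 4L) {
    .stopf("fit_4pl() needs >= 4 distinct doses; got %d", length(unique(dose)))
  }
  if (diff(range(resp)) == 0) {
    .stopf("all responses are identical; there is no curvature to fit")
  }

  top0 <- max(resp)
  bot0 <- min(resp)
  half <- (top0 + bot0) / 2
  # dose whose mean response brackets the half-range value
  mu <- tapply(resp, dose, mean)
  ds <- sort(unique(dose))
  mu <- mu[as.character(ds)]
  ic50_0 <- exp(mean(log(range(dose))))
  for (i in seq_len(length(ds) - 1L)) {
    if ((mu[i] - half) * (mu[i + 1L] - half) <= 0) {
      ic50_0 <- sqrt(ds[i] * ds[i + 1L])
      break
    }
  }

  l10d <- log10(dose)
  best <- NULL
  for (h in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) / (1 + 10^(hill * (l10d - l10ic50))),
        start = list(top = top0, bottom = bot0,
                     l10ic50 = log10(ic50_0), hill = h),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(coef(fit)))) next
    ss <- sum(residuals(fit)^2)
    if (is.null(best) || ss < best$ss * (1 - 1e-9)) {
      best <- list(fit = fit, ss = ss)
    }
  }

  warnings <- character(0)
  if (is.null(best)) {
    # no start converged: coarse direct search, reported as non-converged
    obj <- function(p) {
      sum((resp - .fourpl_fun(dose, p[1L], p[2L], 10^p[3L], p[4L]))^2)
    }
    op <- optim(c(top0, bot0, log10(ic50_0), 1), obj,
                control = list(maxit = 2000))
    cf <- c(top = op$par[1L], bottom = op$par[2L],
            l10ic50 = op$par[3L], hill = op$par[4L])
    converged <- FALSE
    fitted_v <- .fourpl_fun(dose, cf["top"], cf["bottom"], 10^cf["l10ic50"],
                            cf["hill"])
    warnings <- c(warnings, "no optimiser start converged; best parameters found are reported")
  } else {
    cf <- coef(best$fit)
    converged <- isTRUE(best$fit$convInfo$isConv)
    fitted_v <- as.numeric(fitted(best$fit))
  }

  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  ic50 <- unname(10^cf["l10ic50"]); hill <- unname(cf["hill"])
  # canonical orientation: top > bottom (model is invariant under the swap
  # top<->bottom, hill -> -hill)
  if (top < bottom) {
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }

  res <- resp - fitted_v
  ss_res <- sum(res^2)
  ss_tot <- sum((resp - mean(resp))^2)
  r2 <- 1 - ss_res / ss_tot

  if (ic50 < min(dose) || ic50 > max(dose)) {
    w <- sprintf("fitted IC50 (%.4g uM) lies outside the tested dose range [%.4g, %.4g]",
                 ic50, min(dose), max(dose))
    warnings <- c(warnings, w)
    .warnf("%s", w)
  }

  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom,
                 r_squared = r2, converged = converged,
                 drug = tab$drug[1L], condition = tab$condition[1L],
                 data = tab, fitted.values = fitted_v, residuals = res,
                 warnings = warnings),
            class = "fourpl")
}

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat(sprintf("4PL dose-response fit: %s%s\n", x$drug,
              if (nzchar(x$condition)) paste0(" (", x$condition, ")") else ""))
  cat(sprintf("  IC50   = %.*g uM\n  hill   = %.*g\n  top    = %.*g\n  bottom = %.*g\n",
              digits, x$ic50, digits, x$hill, digits, x$top, digits, x$bottom))
  cat(sprintf("  R-squared = %.*g, converged: %s\n", digits, x$r_squared,
              x$converged))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) {
  c(top = object$top, bottom = object$bottom,
    ic50 = object$ic50, hill = object$hill)
}

#' @export
summary.fourpl <- function(object, ...) {
  structure(list(fit = object,
                 n = nrow(object$data),
                 n_doses = length(unique(object$data$dose_uM)),
                 dose_range = range(object$data$dose_uM),
                 rmse = sqrt(mean(object$residuals^2))),
            class = "summary.fourpl")
}

#' @export
print.summary.fourpl <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d observations at %d doses spanning [%.4g, %.4g] uM; RMSE %.4g\n",
              x$n, x$n_doses, x$dose_range[1L], x$dose_range[2L], x$rmse))
  invisible(x)
}

#' Predict responses from a 4PL fit
#'
#' @param object a `"fourpl"` fit.
#' @param newdata numeric dose vector (uM), or a data.frame with a `dose_uM`
#'   (or `dose`) column. Defaults to the fitted doses.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.fourpl <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    dose <- object$data$dose_uM
  } else if (is.data.frame(newdata)) {
    dcol <- intersect(c("dose_uM", "dose"), names(newdata))[1L]
    if (is.na(dcol)) .stopf("newdata needs a dose_uM (or dose) column")
    dose <- newdata[[dcol]]
  } else {
    dose <- as.numeric(newdata)
  }
  .fourpl_fun(dose, object$top, object$bottom, object$ic50, object$hill)
}

#' @export
residuals.fourpl <- function(object, ...) object$residuals

#' @export
fitted.fourpl <- function(object, ...) object$fitted.values

#' Plot a 4PL fit on log10-dose axis
#'
#' @param x a `"fourpl"` fit.
#' @param n_curve points used to draw the fitted curve.
#' @param ... passed to [plot()].
#' @export
plot.fourpl <- function(x, n_curve = 200, ...) {
  d <- x$data
  plot(d$dose_uM, d$response, log = "x",
       xlab = "dose (uM)", ylab = "response",
       main = sprintf("%s: IC50 = %.3g uM", x$drug, x$ic50), ...)
  dd <- 10^seq(log10(min(d$dose_uM)), log10(max(d$dose_uM)),
               length.out = n_curve)
  lines(dd, predict(x, dd), col = "firebrick", lwd = 2)
  abline(v = x$ic50, lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate plates from a fitted 4PL curve
#'
#' Draws `nsim` synthetic quadruplicate plates from the fitted curve with
#' multiplicative Gaussian noise, using the same generative model as
#' [gen_dose_response()].
#'
#' @param object a `"fourpl"` fit.
#' @param nsim number of simulated plates.
#' @param seed integer seed.
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param ... unused.
#' @return list of [dose_response_table()] objects.
#' @export
simulate.fourpl <- function(object, nsim = 1, seed = 1, noise_cv = 0.05, ...) {
  doses <- sort(unique(object$data$dose_uM))
  reps <- max(table(object$data$dose_uM))
  lapply(seq_len(nsim), function(i) {
    gen_dose_response(params = coef(object), doses = doses,
                      config = generator_config(seed = seed + i - 1L,
                                                n_replicates = reps,
                                                noise_cv = noise_cv),
                      drug = object$drug, condition = object$condition)
  })
}

#' Invert a 4PL fit to the iso-effect dose
#'
#' Returns the dose producing fraction affected `fa`, where fa is the
#' fraction of the fitted maximal effect: the dose `D` with
#' `4PL(D) = bottom + (1 - fa) * (top - bottom)`. Algebraically,
#' `D = ic50 * (fa / (1 - fa))^(1/hill)`.
#'
#' @param fit a `"fourpl"` fit (or any list with `ic50` and `hill`).
#' @param fa fraction(s) affected, strictly inside (0, 1).
#' @return dose(s) in uM.
#' @examples
#' # at fa = 0.5 the iso-effect dose is the IC50 by definition
#' @export
invert_4pl <- function(fit, fa) {
  if (any(!is.finite(fa) | fa <= 0 | fa >= 1)) {
    .stopf("fa must lie strictly inside (0, 1); got %s",
           paste(format(fa[!is.finite(fa) | fa <= 0 | fa >= 1]), collapse = ", "))
  }
  fit$ic50 * (fa / (1 - fa))^(1 / fit$hill)
}

#' Fold resistance between two fitted lines
#'
#' Ratio of IC50s of a resistant over a parental fit for the same drug, e.g.
#' the roughly 250-fold doxorubicin resistance of an in-vitro selected MCF-7
#' population (IC50 10 uM vs 0.04 uM).
#'
#' @param resistant,parental converged `"fourpl"` fits for the same drug.
#' @return scalar IC50 ratio.
#' @export
fold_resistance <- function(resistant, parental) {
  if (!inherits(resistant, "fourpl") || !inherits(parental, "fourpl")) {
    .stopf("fold_resistance() expects two fourpl fits")
  }
  if (!isTRUE(resistant$converged) || !isTRUE(parental$converged)) {
    .stopf("both fits must have converged")
  }
  if (!identical(resistant$drug, parental$drug)) {
    .stopf("drug mismatch: '%s' vs '%s'", resistant$drug, parental$drug)
  }
  resistant$ic50 / parental$ic50
}

# tiny example curve used in roxygen examples
#' @keywords internal
.fourpl_ex <- function(d) .fourpl_fun(d, 100, 0, 0.04, 1)
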