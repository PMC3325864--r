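# Synthetic-data generators. Every input consumed by the analysis modules
# can be produced here with the statistical structure those analyses assume:
# 4PL viability plates in quadruplicate with multiplicative noise,
# fixed-ratio mixtures with a known deviation from Loewe additivity,
# two-condition replicated RIP-chip matrices with planted bound probes,
# 3'UTR sets with a controlled ARE background and planted top-rank
# enrichment, and lognormal per-cell compartment intensity populations.
#
# One shared integer seed drives a per-generator independent stream, so
# adding or re-running one generator never perturbs the draws of another.

#' Generator configuration
#'
#' @param seed integer seed shared by all generators (each generator derives
#'   its own independent stream from it).
#' @param n_replicates replicates per condition/dose (default 4,
#'   biological quadruplicate).
#' @param noise_cv coefficient of variation of the multiplicative
#'   measurement noise (default 0.05).
#' @param cells_per_condition cells per experimental point for the
#'   intensity generator (default 300).
#' @return object of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1L, n_replicates = 4L, noise_cv = 0.05,
                             cells_per_condition = 300L) {
  .stream_seed(seed, 0L)  # validates the seed
  if (n_replicates < 1L) .stopf("n_replicates must be >= 1")
  if (noise_cv < 0) .stopf("noise_cv must be >= 0")
  if (cells_per_condition < 1L) .stopf("cells_per_condition must be >= 1")
  structure(list(seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = as.numeric(noise_cv),
                 cells_per_condition = as.integer(cells_per_condition)),
            class = "generator_config")
}

.check_config <- function(config) {
  if (!inherits(config, "generator_config")) {
    .stopf("config must come from generator_config()")
  }
  config
}

.check_4pl_params <- function(params) {
  p <- as.list(params)
  need <- c("ic50", "hill", "top", "bottom")
  if (!all(need %in% names(p))) {
    .stopf("params must provide ic50, hill, top, bottom; missing: %s",
           paste(setdiff(need, names(p)), collapse = ", "))
  }
  p <- lapply(p[need], as.numeric)
  if (p$ic50 <= 0) .stopf("params: ic50 must be positive")
  if (p$top <= p$bottom) .stopf("params: top must exceed bottom")
  p
}

# noisy responses for one mean curve under the current RNG state
.noisy_responses <- function(mean_response, n_replicates, noise_cv) {
  n <- length(mean_response) * n_replicates
  eps <- if (noise_cv > 0) rnorm(n, 0, noise_cv) else numeric(n)
  rep(mean_response, each = n_replicates) * (1 + eps)
}

#' Simulate a 4PL viability plate
#'
#' Generates `n_replicates` responses per dose on the four-parameter
#' logistic curve with multiplicative Gaussian noise:
#' `response = 4PL(dose) * (1 + eps)`, `eps ~ N(0, noise_cv)`. Deterministic
#' for a fixed seed.
#'
#' @param params 4PL parameters: list or named vector with `ic50` (uM),
#'   `hill`, `top`, `bottom`.
#' @param doses strictly positive dose vector (uM).
#' @param config a [generator_config()].
#' @param drug,condition labels carried into the table.
#' @return a [dose_response_table()].
#' @examples
#' gen_dose_response(list(ic50 = 1, hill = 1, top = 100, bottom = 0),
#'                   doses = 10^seq(-2, 2), config = generator_config(1))
#' @export
gen_dose_response <- function(params, doses, config = generator_config(),
                              drug = "drug", condition = "") {
  p <- .check_4pl_params(params)
  config <- .check_config(config)
  bad <- which(!is.finite(doses) | doses <= 0)
  if (length(bad)) {
    .stopf("doses must be positive; offending value %s at position %d",
           deparse(doses[bad[1L]]), bad[1L])
  }
  mean_resp <- .fourpl_fun(doses, p$top, p$bottom, p$ic50, p$hill)
  resp <- withr::with_seed(
    .stream_seed(config$seed, 1L),
    .noisy_responses(mean_resp, config$n_replicates, config$noise_cv))
  dose_response_table(rep(doses, each = config$n_replicates), resp,
                      drug = drug, condition = condition,
                      replicate = rep(seq_len(config$n_replicates),
                                      times = length(doses)))
}

# Loewe generative model: at total dose d split dA/dB by the ratio; the
# produced effect e solves dA/(alpha DA(e)) + dB/(alpha DB(e)) = 1, i.e. the
# Loewe sum at e equals alpha. alpha = 1 is exact additivity, > 1
# antagonism, < 1 synergy.
.solve_loewe_effect <- function(da, db, pa, pb, alpha) {
  g <- function(fa) {
    Da <- pa$ic50 * (fa / (1 - fa))^(1 / pa$hill)
    Db <- pb$ic50 * (fa / (1 - fa))^(1 / pb$hill)
    da / (alpha * Da) + db / (alpha * Db) - 1
  }
  root <- tryCatch(
    uniroot(g, c(1e-9, 1 - 1e-9), tol = 1e-12)$root,
    error = function(e) NA_real_)
  root
}

#' Simulate a fixed-ratio two-drug mixture experiment
#'
#' Produces the three plates of a constant-ratio combination design: each
#' agent alone over `total_doses`, and their mixture where the total dose is
#' split by `ratio`. The mixture effect at each total dose is obtained by
#' numerically solving the Loewe equation with both component doses divided
#' by `alpha`, so that the true combination index equals `alpha` at every
#' achieved effect level: `alpha = 1` gives exact Loewe additivity,
#' `alpha > 1` antagonism, `alpha < 1` synergy. The two agents must share
#' `top` and `bottom` (a common effect scale is what makes the Loewe
#' construction well defined). Total doses whose solved effect lies outside
#' the response range of the agents are dropped with a report.
#'
#' @param params_a,params_b 4PL parameters of the two agents (shared
#'   top/bottom).
#' @param ratio A:B dose ratio (default 10).
#' @param alpha positive interaction factor (true combination index).
#' @param total_doses strictly positive total mixture doses (uM).
#' @param config a [generator_config()].
#' @param drug_a,drug_b labels.
#' @return list with elements `a`, `b`, `mix` ([dose_response_table()]s,
#'   the mixture indexed by total dose), `design`
#'   (a [fixed_ratio_design()]) and `dropped_doses`.
#' @export
gen_fixed_ratio_mixture <- function(params_a, params_b, ratio = 10,
                                    alpha = 1, total_doses,
                                    config = generator_config(),
                                    drug_a = "A", drug_b = "B") {
  pa <- .check_4pl_params(params_a)
  pb <- .check_4pl_params(params_b)
  config <- .check_config(config)
  if (alpha <= 0) .stopf("alpha must be positive")
  if (ratio <= 0) .stopf("ratio must be positive")
  if (pa$top != pb$top || pa$bottom != pb$bottom) {
    .stopf("the two agents must share top and bottom (common effect scale)")
  }
  if (any(!is.finite(total_doses) | total_doses <= 0)) {
    .stopf("total_doses must be positive")
  }
  design <- fixed_ratio_design(drug_a, drug_b, ratio_a_to_b = ratio,
                               total_doses = total_doses)

  comp <- .split_dose(design, total_doses)
  fa_mix <- mapply(.solve_loewe_effect, comp$a, comp$b,
                   MoreArgs = list(pa = pa, pb = pb, alpha = alpha))
  ok <- is.finite(fa_mix) & fa_mix > 1e-6 & fa_mix < 1 - 1e-6
  if (any(!ok)) {
    .msgf("gen_fixed_ratio_mixture: dropped %d total dose(s) with effect outside the agents' response range: %s",
          sum(!ok), paste(format(total_doses[!ok]), collapse = ", "))
  }
  kept <- total_doses[ok]
  if (!length(kept)) .stopf("no solvable total doses remain")
  mix_mean <- pa$top - fa_mix[ok] * (pa$top - pa$bottom)
  a_mean <- .fourpl_fun(total_doses, pa$top, pa$bottom, pa$ic50, pa$hill)
  b_mean <- .fourpl_fun(total_doses, pb$top, pb$bottom, pb$ic50, pb$hill)

  out <- withr::with_seed(.stream_seed(config$seed, 2L), {
    ra <- .noisy_responses(a_mean, config$n_replicates, config$noise_cv)
    rb <- .noisy_responses(b_mean, config$n_replicates, config$noise_cv)
    rm_ <- .noisy_responses(mix_mean, config$n_replicates, config$noise_cv)
    list(ra = ra, rb = rb, rm = rm_)
  })
  reps <- function(d) rep(seq_len(config$n_replicates), times = length(d))
  list(
    a = dose_response_table(rep(total_doses, each = config$n_replicates),
                            out$ra, drug = drug_a, replicate = reps(total_doses)),
    b = dose_response_table(rep(total_doses, each = config$n_replicates),
                            out$rb, drug = drug_b, replicate = reps(total_doses)),
    mix = dose_response_table(rep(kept, each = config$n_replicates),
                              out$rm, drug = paste0(drug_a, "+", drug_b),
                              replicate = reps(kept)),
    design = design,
    dropped_doses = total_doses[!ok])
}

#' Simulate a replicated two-condition RIP-chip dataset
#'
#' Emulates a replicated RNA-immunoprecipitation microarray design:
#' log-normal baseline intensities per probe, a planted log2 enrichment
#' added to the first condition (the RIP channel) for `n_bound` probes,
#' heteroscedastic multiplicative noise, a fraction of probes flagged
#' absent in every sample, and a fraction given within-condition CV above
#' 50% (under nonzero noise). Returns the raw linear-scale matrix together
#' with the ground truth for recovery testing.
#'
#' @param n_probes total probes.
#' @param n_bound number of bound probes (0 to `n_probes`).
#' @param config a [generator_config()].
#' @param conditions condition labels; the first one receives the planted
#'   enrichment. Use e.g. `c("RIP", "IgG", "cyto")` for the full
#'   three-sample design.
#' @param planted_log2 planted log2 enrichment, scalar or length `n_bound`
#'   (default 3; values above 1 keep bound probes separable).
#' @param frac_absent fraction of (non-bound) probes flagged absent in all
#'   samples.
#' @param frac_high_cv fraction of (non-bound) probes given high
#'   within-condition CV.
#' @return list with `matrix` (an [expression_matrix()], raw linear scale)
#'   and `truth` (list: `bound_probe_ids`, `planted_log2`,
#'   `absent_probe_ids`, `high_cv_probe_ids`, `probe_to_gene`).
#' @export
gen_ripchip_dataset <- function(n_probes, n_bound,
                                config = generator_config(),
                                conditions = c("RIP", "IgG"),
                                planted_log2 = 3, frac_absent = 0.05,
                                frac_high_cv = 0.02) {
  config <- .check_config(config)
  if (n_bound < 0 || n_bound > n_probes) {
    .stopf("need 0 <= n_bound <= n_probes (got %d of %d)", n_bound, n_probes)
  }
  if (length(conditions) < 2L) .stopf("need >= 2 conditions")
  planted_log2 <- rep_len(planted_log2, max(n_bound, 1L))[seq_len(n_bound)]
  probes <- sprintf("P%05d", seq_len(n_probes))
  genes <- setNames(sprintf("GENE%05d", seq_len(n_probes)), probes)
  nrep <- config$n_replicates

  res <- withr::with_seed(.stream_seed(config$seed, 3L), {
    base <- rnorm(n_probes, mean = 8, sd = 1.5)  # log2 of lognormal baseline
    bound <- sort(sample.int(n_probes, n_bound))
    rest <- setdiff(seq_len(n_probes), bound)
    n_abs <- min(length(rest), round(frac_absent * n_probes))
    absent <- sort(sample(rest, n_abs))
    rest2 <- setdiff(rest, absent)
    n_hcv <- min(length(rest2), round(frac_high_cv * n_probes))
    high_cv <- sort(sample(rest2, n_hcv))

    cv <- if (config$noise_cv > 0) {
      v <- config$noise_cv * runif(n_probes, 0.5, 1.5)  # heteroscedastic
      v[high_cv] <- 0.9
      v
    } else rep(0, n_probes)

    mean_log2 <- matrix(base, nrow = n_probes,
                        ncol = length(conditions) * nrep)
    rip_cols <- seq_len(nrep)  # first condition = RIP channel
    mean_log2[bound, rip_cols] <- mean_log2[bound, rip_cols] + planted_log2
    noise <- matrix(rnorm(length(mean_log2), 0, rep(cv, ncol(mean_log2))),
                    nrow = n_probes)
    signals <- 2^mean_log2 * pmax(1 + noise, 0.05)
    list(signals = signals, bound = bound, absent = absent,
         high_cv = high_cv)
  })

  sample_ids <- as.vector(vapply(conditions, function(cc)
    sprintf("%s_%d", cc, seq_len(nrep)), character(nrep)))
  rownames(res$signals) <- probes
  colnames(res$signals) <- sample_ids
  flags <- matrix(TRUE, n_probes, length(sample_ids),
                  dimnames = list(probes, sample_ids))
  flags[res$absent, ] <- FALSE

  list(matrix = expression_matrix(res$signals,
                                  conditions = rep(conditions, each = nrep),
                                  flags = flags),
       truth = list(bound_probe_ids = probes[res$bound],
                    planted_log2 = setNames(planted_log2, probes[res$bound]),
                    absent_probe_ids = probes[res$absent],
                    high_cv_probe_ids = probes[res$high_cv],
                    probe_to_gene = genes))
}

# IUPAC RNA code -> regex character class
.iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", U = "U", W = "[AU]", S = "[CG]",
           M = "[AC]", K = "[GU]", R = "[AG]", Y = "[CU]",
           B = "[CGU]", D = "[AGU]", H = "[ACU]", V = "[ACG]",
           N = "[ACGU]")
  chars <- strsplit(chartr("tT", "uU", toupper(pattern)), "")[[1L]]
  if (any(!chars %in% names(map))) {
    .stopf("pattern contains non-IUPAC letters: %s",
           paste(unique(chars[!chars %in% names(map)]), collapse = ", "))
  }
  paste(map[chars], collapse = "")
}

# destroy every motif occurrence in sequences meant to be ARE-negative
# (replacing the middle base with C, which the ARE alphabet lacks)
.scrub_pattern <- function(seqs, pattern) {
  rx <- .iupac_regex(pattern)
  mid <- (nchar(pattern) + 1L) %/% 2L
  repeat {
    hit <- regexpr(rx, seqs)
    if (all(hit < 0)) break
    i <- which(hit > 0)
    substr(seqs[i], hit[i] + mid - 1L, hit[i] + mid - 1L) <- "C"
  }
  seqs
}

#' Simulate a 3'UTR set with a ranked gene list and planted ARE enrichment
#'
#' Generates `n_genes` random-composition RNA sequences. Genes are
#' ARE-positive with probability `planted_prob` (default 0.9) within the
#' top `planted_top_k` ranks and `background_rate` elsewhere; every
#' positive gene receives at least one inserted motif instance and every
#' negative gene is scrubbed of chance matches, so gene-level ARE status is
#' exactly controlled. Ranks carry strictly descending synthetic fold
#' enrichments.
#'
#' @param n_genes number of genes.
#' @param mean_len mean UTR length in nucleotides (must fit the pattern).
#' @param background_rate probability that a non-planted gene carries an
#'   ARE, in `[0, 1]`.
#' @param planted_top_k ranks at the top of the list with elevated ARE
#'   probability (0 to `n_genes`).
#' @param config a [generator_config()].
#' @param planted_prob ARE probability within the planted top ranks.
#' @param pattern IUPAC RNA ARE pattern.
#' @return list with `utrs` (a [utr_set()]), `ranked` (a
#'   [bound_gene_list()] in rank order) and `truth` (list:
#'   `positive_genes`, `planted_top_k`).
#' @export
gen_utr_set <- function(n_genes, mean_len = 300, background_rate = 0.1,
                        planted_top_k = 0, config = generator_config(),
                        planted_prob = 0.9, pattern = "UAUUUAUWW") {
  config <- .check_config(config)
  plen <- nchar(pattern)
  if (mean_len < plen) {
    .stopf("mean_len (%g) is shorter than the pattern (%d nt); it cannot fit",
           mean_len, plen)
  }
  if (background_rate < 0 || background_rate > 1) {
    .stopf("background_rate must lie in [0, 1]")
  }
  if (planted_top_k < 0 || planted_top_k > n_genes) {
    .stopf("need 0 <= planted_top_k <= n_genes")
  }
  genes <- sprintf("G%05d", seq_len(n_genes))

  res <- withr::with_seed(.stream_seed(config$seed, 4L), {
    lens <- pmax(plen + 1L, round(rlnorm(n_genes, log(mean_len), 0.3)))
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
      character(1))
    prob <- ifelse(seq_len(n_genes) <= planted_top_k, planted_prob,
                   background_rate)
    positive <- runif(n_genes) < prob
    seqs <- .scrub_pattern(seqs, pattern)
    for (i in which(positive)) {
      inst <- paste(vapply(strsplit(chartr("tT", "uU", toupper(pattern)),
                                    "")[[1L]],
                           function(ch) if (ch == "W") sample(c("A", "U"), 1L)
                                        else ch, character(1)),
                    collapse = "")
      pos <- sample.int(lens[i] - plen + 1L, 1L)
      substr(seqs[i], pos, pos + plen - 1L) <- inst
    }
    list(seqs = seqs, positive = positive)
  })

  fold <- seq(40, 2, length.out = n_genes)
  list(utrs = utr_set(genes, res$seqs),
       ranked = bound_gene_list(genes, fold),
       truth = list(positive_genes = genes[res$positive],
                    planted_top_k = planted_top_k))
}

#' Simulate per-cell compartment intensity populations
#'
#' For each condition, draws `cells_per_condition` cells with lognormal
#' nucleus and cytoplasm signals whose natural-log intensity ratio
#' (cytoplasm over nucleus) is centred on the requested condition mean.
#' With `ratio_sd = 0` every cell of a condition has exactly the requested
#' log-ratio.
#'
#' @param condition_means named numeric vector: condition -> mean log-ratio
#'   (log cytoplasm/nucleus; negative = nuclear, positive = cytoplasmic).
#' @param config a [generator_config()].
#' @param base_log_nucleus mean log nucleus intensity.
#' @param signal_sd cell-to-cell SD of the log nucleus intensity.
#' @param ratio_sd cell-to-cell SD of the log-ratio.
#' @return data.frame of per-cell records (`cell_id`, `condition`,
#'   `nucleus`, `cytoplasm`).
#' @export
gen_cell_intensities <- function(condition_means,
                                 config = generator_config(),
                                 base_log_nucleus = log(500),
                                 signal_sd = 0.25, ratio_sd = 0.3) {
  config <- .check_config(config)
  if (!length(condition_means)) .stopf("need at least one condition")
  if (is.null(names(condition_means)) || any(!nzchar(names(condition_means)))) {
    .stopf("condition_means must be a named vector (condition -> mean log-ratio)")
  }
  n <- config$cells_per_condition
  withr::with_seed(.stream_seed(config$seed, 5L), {
    recs <- lapply(names(condition_means), function(cc) {
      lnuc <- rnorm(n, base_log_nucleus, signal_sd)
      lratio <- rnorm(n, condition_means[[cc]], ratio_sd)
      data.frame(cell_id = sprintf("%s_cell%04d", cc, seq_len(n)),
                 condition = cc, nucleus = exp(lnuc),
                 cytoplasm = exp(lnuc + lratio), stringsAsFactors = FALSE)
    })
    do.call(rbind, recs)
  })
}
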