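# shared fixtures: published IC50 parameter sets, canonical dose grids,
# and quiet wrappers (the pipeline narrates its stages via message()).

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# IC50s (uM) measured for the MCF-7 pair and rottlerin, hill 1, full
# 0-100% viability scale
PARAMS_DOXO_MCF7  <- list(ic50 = 0.04,  hill = 1, top = 100, bottom = 0)
PARAMS_ROTT_MCF7  <- list(ic50 = 0.005, hill = 1, top = 100, bottom = 0)
PARAMS_DOXO_DOXOR <- list(ic50 = 10,    hill = 1, top = 100, bottom = 0)

# 8 log-spaced doses, 0.1 nM .. 10 uM
DOSES_LOW  <- 10^seq(-4, 1, length.out = 8)
# 8 log-spaced doses, 0.1 .. 100 uM (resistant line)
DOSES_HIGH <- 10^seq(-1, 2, length.out = 8)

noiseless_fit <- function(params, doses = DOSES_LOW, drug = "drug",
                          condition = "") {
  tab <- gen_dose_response(params, doses,
                           generator_config(seed = 1, noise_cv = 0),
                           drug = drug, condition = condition)
  quiet(fit_4pl(tab))
}

# independent brute-force hypergeometric upper-tail sum via log-binomials
# (EASE: tail from k - 1)
ease_oracle <- function(k, n, K, N) {
  if (k <= 1) return(1)
  x <- (k - 1):min(n, K)
  min(1, sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))))
}

# full ripchip pipeline on a generated dataset -> bound gene list
run_ripchip_pipeline <- function(gen) {
  m <- log2_transform(gen$matrix)
  m_igg <- filter_cv(filter_absent(m))
  c_igg <- welch_bh_contrast(m_igg, "RIP", "IgG", fold_rule = "positive")
  m_cyt <- filter_cv(filter_absent(baseline_to_median(
    normalize_percentile_shift(m))))
  c_cyt <- welch_bh_contrast(m_cyt, "RIP", "cyto", fold_rule = "positive")
  select_bound_genes(c_igg, c_cyt, gen$truth$probe_to_gene)
}
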