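test_that("generator_config validates its fields", {
  expect_error(generator_config(seed = "a"), "integer")
  expect_error(generator_config(n_replicates = 0), "n_replicates")
  expect_error(generator_config(noise_cv = -0.1), "noise_cv")
})

test_that("all generators are byte-identical under a fixed seed", {
  cfg <- generator_config(seed = 42, cells_per_condition = 50)
  expect_identical(
    gen_dose_response(PARAMS_DOXO_MCF7, DOSES_LOW, cfg),
    gen_dose_response(PARAMS_DOXO_MCF7, DOSES_LOW, cfg))
  expect_identical(
    quiet(gen_fixed_ratio_mixture(PARAMS_ROTT_MCF7, PARAMS_DOXO_MCF7,
                                  total_doses = DOSES_LOW, config = cfg)),
    quiet(gen_fixed_ratio_mixture(PARAMS_ROTT_MCF7, PARAMS_DOXO_MCF7,
                                  total_doses = DOSES_LOW, config = cfg)))
  expect_identical(gen_ripchip_dataset(200, 5, cfg),
                   gen_ripchip_dataset(200, 5, cfg))
  expect_identical(gen_utr_set(50, 100, 0.2, 10, cfg),
                   gen_utr_set(50, 100, 0.2, 10, cfg))
  expect_identical(gen_cell_intensities(c(a = -1, b = 1), cfg),
                   gen_cell_intensities(c(a = -1, b = 1), cfg))
  # a different seed perturbs the draws
  cfg2 <- generator_config(seed = 43, cells_per_condition = 50)
  expect_false(identical(gen_dose_response(PARAMS_DOXO_MCF7, DOSES_LOW, cfg),
                         gen_dose_response(PARAMS_DOXO_MCF7, DOSES_LOW, cfg2)))
})

test_that("noiseless plates sit exactly on the curve with 50% at the IC50", {
  cfg <- generator_config(seed = 1, noise_cv = 0)
  tab <- gen_dose_response(list(ic50 = 1, hill = 1, top = 100, bottom = 0),
                           c(0.1, 0.5, 1, 2, 10), cfg)
  expect_equal(tab$response[tab$dose_uM == 1], rep(50, 4))
  expect_equal(tab$response[tab$dose_uM == 0.1], rep(100 / 1.1, 4))
  expect_error(gen_dose_response(PARAMS_DOXO_MCF7, c(1, -1), cfg), "-1")
})

test_that("doubling noise_cv leaves the mean response unchanged (3 SE)", {
  doses <- c(0.01, 0.04, 0.16, 1)
  truth <- 100 / (1 + doses / 0.04)
  for (cv in c(0.05, 0.10)) {
    sims <- vapply(1:200, function(s) {
      tab <- gen_dose_response(PARAMS_DOXO_MCF7, doses,
                               generator_config(seed = s, noise_cv = cv))
      tapply(tab$response, tab$dose_uM, mean)[as.character(doses)]
    }, numeric(length(doses)))
    m <- rowMeans(sims)
    se <- apply(sims, 1L, sd) / sqrt(ncol(sims))
    expect_true(all(abs(m - truth) <= 3 * se + 1e-12))
  }
})

test_that("a sham mixture (drug with itself, ratio 1:1, alpha 1) reproduces the single-agent curve", {
  p <- list(ic50 = 0.04, hill = 1.3, top = 100, bottom = 0)
  m <- gen_fixed_ratio_mixture(p, p, ratio = 1, alpha = 1,
                               total_doses = DOSES_LOW,
                               config = generator_config(seed = 9, noise_cv = 0))
  expect_length(m$dropped_doses, 0)
  # noiseless: mixture responses equal the single-agent curve at total dose
  curve <- 100 / (1 + (m$mix$dose_uM / 0.04)^1.3)
  expect_equal(m$mix$response, curve, tolerance = 1e-8)
})

test_that("the mixture generator encodes its alpha as the true combination index", {
  m <- gen_fixed_ratio_mixture(PARAMS_ROTT_MCF7, PARAMS_DOXO_MCF7, ratio = 10,
                               alpha = 2, total_doses = DOSES_LOW,
                               config = generator_config(seed = 2, noise_cv = 0))
  fits <- lapply(m[c("a", "b", "mix")], function(t) quiet(fit_4pl(t)))
  ci <- loewe_ci(c(0.25, 0.5, 0.75), fits$a, fits$b, fits$mix, m$design)
  expect_equal(ci, rep(2, 3), tolerance = 1e-3)
})

test_that("mixture doses with unattainable effects are dropped with a report", {
  # an extreme total dose drives the solved effect outside the agents'
  # measurable response range; that dose is dropped and reported
  p <- list(ic50 = 1, hill = 1, top = 100, bottom = 0)
  expect_message(
    m <- gen_fixed_ratio_mixture(p, p, ratio = 1, alpha = 1,
                                 total_doses = c(1, 1e8),
                                 config = generator_config(seed = 1,
                                                           noise_cv = 0)),
    "dropped 1 total dose")
  expect_equal(m$dropped_doses, 1e8)
  expect_equal(sort(unique(m$mix$dose_uM)), 1)
  expect_error(
    gen_fixed_ratio_mixture(p, list(ic50 = 1, hill = 1, top = 90, bottom = 0),
                            total_doses = 1, config = generator_config(1)),
    "share top and bottom")
})

test_that("ripchip generator plants recoverable structure", {
  cfg <- generator_config(seed = 11)
  g <- gen_ripchip_dataset(500, 10, cfg, conditions = c("RIP", "IgG", "cyto"))
  em <- g$matrix
  expect_equal(dim(em), c(500L, 12L))
  expect_true(all(g$truth$bound_probe_ids %in% rownames(em$signals)))
  expect_length(g$truth$absent_probe_ids, 25)  # 5% of 500
  expect_true(all(rowSums(em$flags[g$truth$absent_probe_ids, ]) == 0))
  expect_gt(min(g$truth$planted_log2), 1)
  # bound probes are not among the absent or high-CV probes
  expect_length(intersect(g$truth$bound_probe_ids,
                          c(g$truth$absent_probe_ids,
                            g$truth$high_cv_probe_ids)), 0)
  # planted enrichment shows in the raw signals
  lin <- em$signals
  rip <- rowMeans(lin[g$truth$bound_probe_ids, 1:4])
  igg <- rowMeans(lin[g$truth$bound_probe_ids, 5:8])
  expect_true(all(rip / igg > 4))
})

test_that("all probes flagged absent yields an empty matrix after filter_absent", {
  g <- gen_ripchip_dataset(50, 0, generator_config(seed = 3),
                           frac_absent = 1)
  m <- quiet(filter_absent(log2_transform(g$matrix)))
  expect_equal(nrow(m$signals), 0L)
})

test_that("UTR generator controls ARE status exactly", {
  cfg <- generator_config(seed = 5)
  # no background, nothing planted: every gene is ARE-free
  u0 <- gen_utr_set(200, 120, background_rate = 0, planted_top_k = 0,
                    config = cfg)
  expect_equal(sum(count_are(u0$utrs)), 0L)
  expect_length(u0$truth$positive_genes, 0)
  # positives always carry a detectable instance
  u1 <- gen_utr_set(200, 120, background_rate = 0.3, planted_top_k = 50,
                    config = cfg)
  counts <- setNames(count_are(u1$utrs), u1$utrs$gene_symbol)
  expect_true(all(counts[u1$truth$positive_genes] >= 1L))
  expect_true(all(counts[setdiff(u1$utrs$gene_symbol,
                                 u1$truth$positive_genes)] == 0L))
  # ranked list is strictly descending over all genes
  expect_true(all(diff(u1$ranked$fold_enrichment) < 0))
  expect_error(gen_utr_set(10, mean_len = 5, config = cfg), "cannot fit")
})

test_that("cell-intensity generator centres the log-ratio per condition", {
  cfg <- generator_config(seed = 8, cells_per_condition = 300)
  cells <- gen_cell_intensities(c(starved = -1, doxo = 1), cfg)
  expect_equal(nrow(cells), 600L)
  lr <- log(cells$cytoplasm / cells$nucleus)
  mts <- tapply(lr, cells$condition, mean)
  expect_equal(unname(mts["starved"]), -1, tolerance = 0.1)
  expect_equal(unname(mts["doxo"]), 1, tolerance = 0.1)
  # zero spread: every cell of a condition has exactly the requested ratio
  c0 <- gen_cell_intensities(c(a = 0.5, b = 0.5), cfg, ratio_sd = 0)
  r0 <- log(c0$cytoplasm / c0$nucleus)
  expect_equal(as.numeric(tapply(r0, c0$condition, var)), c(0, 0),
               tolerance = 1e-12)
  expect_error(gen_cell_intensities(c(1, 2), cfg), "named")
})
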