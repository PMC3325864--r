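# small deterministic matrix used across preprocessing tests
toy_em <- function(signals, conditions = c("RIP", "RIP", "IgG", "IgG"),
                   flags = NULL, ...) {
  expression_matrix(signals, conditions = conditions, flags = flags, ...)
}

test_that("log2 transform maps known values, floors non-positives, and refuses to re-run", {
  m <- toy_em(matrix(c(8, 1, 0, 4), 1), conditions = c("a", "a", "b", "b"))
  expect_message(t1 <- log2_transform(m, epsilon = 0.25), "floored 1")
  expect_equal(as.numeric(t1$signals), c(3, 0, -2, 2))
  expect_error(quiet(log2_transform(t1)), "already log2")
  expect_error(quiet(log2_transform(m, epsilon = 0)), "positive")
})

test_that("75th percentile shift uses linear interpolation and acts per sample", {
  sig <- cbind(s1 = c(0, 1, 2, 3, 4), s2 = rep(7, 5))
  m <- toy_em(sig, conditions = c("a", "b"), log2_transformed = TRUE)
  n <- quiet(normalize_percentile_shift(m))
  # linear-interpolated 75th percentile of {0,1,2,3,4} is 3
  expect_equal(unname(n$signals[, "s1"]), c(-3, -2, -1, 0, 1))
  # constant sample maps to all zeros; no cross-talk between samples
  expect_equal(unname(n$signals[, "s2"]), rep(0, 5))
  expect_equal(unname(quantile(n$signals[, "s1"], 0.75)), 0)
  expect_error(quiet(normalize_percentile_shift(n)), "already")
  expect_error(quiet(normalize_percentile_shift(
    toy_em(sig, conditions = c("a", "b")))), "log2")
})

test_that("median baselining centres each probe and enforces its prerequisite", {
  sig <- rbind(p1 = c(1, 2, 3, 6), p2 = c(1, 3, 1, 3), p3 = c(5, 5, 5, 5))
  m <- toy_em(sig, log2_transformed = TRUE)
  expect_error(quiet(baseline_to_median(m)), "normalised")
  mn <- quiet(normalize_percentile_shift(m, percentile = 50))
  b <- quiet(baseline_to_median(mn))
  expect_equal(unname(apply(b$signals, 1L, median)), c(0, 0, 0))
  # even sample count: midpoint median
  m2 <- toy_em(rbind(p = c(1, 3), q = c(5, 7)), conditions = c("a", "b"),
               log2_transformed = TRUE, normalized = TRUE)
  b2 <- quiet(baseline_to_median(m2))
  expect_equal(unname(b2$signals), rbind(c(-1, 1), c(-1, 1)))
})

test_that("absent-flag filter keeps probes present in at least one sample", {
  sig <- matrix(2, 3, 4, dimnames = list(c("all_absent", "one_present",
                                           "all_present"), NULL))
  flags <- rbind(rep(FALSE, 4), c(FALSE, TRUE, FALSE, FALSE), rep(TRUE, 4))
  m <- toy_em(sig, flags = flags, log2_transformed = TRUE)
  f <- quiet(filter_absent(m))
  expect_setequal(rownames(f$signals), c("one_present", "all_present"))
  expect_error(quiet(filter_absent(f)), "already")
  # no flags: all kept with a warning
  expect_warning(f2 <- filter_absent(toy_em(sig, log2_transformed = TRUE)),
                 "no detection flags")
  expect_equal(nrow(f2$signals), 3L)
})

test_that("CV filter works on linear-scale intensities with the stated threshold", {
  # replicates {10,20}: CV = sd/mean = 7.071/15 = 0.471 -> kept at 0.5
  # replicates {10,30}: CV = 14.14/20 = 0.707 -> removed
  sig <- log2(rbind(kept = c(10, 20, 5, 5), removed = c(10, 30, 5, 5),
                    flat = c(7, 7, 7, 7)))
  m <- toy_em(sig, conditions = c("a", "a", "b", "b"), log2_transformed = TRUE)
  f <- quiet(filter_cv(m, cv_threshold = 0.5))
  expect_setequal(rownames(f$signals), c("kept", "flat"))
  expect_error(quiet(filter_cv(f)), "already")
  # single-replicate condition: CV undefined there, probe retained, warning
  m1 <- toy_em(sig[, 1:3], conditions = c("a", "a", "b"),
               log2_transformed = TRUE)
  expect_warning(f1 <- filter_cv(m1), "single replicate")
  expect_setequal(rownames(f1$signals), c("kept", "flat"))
})

test_that("Welch/BH contrast matches t.test and a textbook BH oracle", {
  set.seed(31)
  n_probe <- 40
  sig <- matrix(rnorm(n_probe * 8, 6, 1), n_probe,
                dimnames = list(sprintf("p%02d", 1:n_probe), NULL))
  sig[1:5, 1:4] <- sig[1:5, 1:4] + 3
  m <- toy_em(sig, conditions = rep(c("RIP", "IgG"), each = 4),
              log2_transformed = TRUE)
  res <- welch_bh_contrast(m, "RIP", "IgG")

  # dual route 1: stats::t.test per probe
  p_tt <- vapply(seq_len(n_probe), function(i)
    t.test(sig[i, 1:4], sig[i, 5:8], var.equal = FALSE)$p.value, numeric(1))
  expect_equal(res$p, p_tt, tolerance = 1e-12)
  expect_equal(res$log2_fc, rowMeans(sig[, 1:4]) - rowMeans(sig[, 5:8]),
               ignore_attr = TRUE)

  # dual route 2: textbook BH step-up on the sorted p list
  ord <- order(p_tt)
  adj <- p_tt[ord] * n_probe / seq_len(n_probe)
  adj <- rev(cummin(rev(adj)))
  bh_manual <- numeric(n_probe); bh_manual[ord] <- pmin(adj, 1)
  expect_equal(res$p_adj, bh_manual, tolerance = 1e-12)

  # group means 6 and 4 in log2 mean a linear fold change of 4
  m2 <- toy_em(rbind(p = c(6, 6, 6.01, 4, 4, 4.01)),
               conditions = rep(c("RIP", "IgG"), each = 3),
               log2_transformed = TRUE)
  r2 <- welch_bh_contrast(m2, "RIP", "IgG")
  expect_equal(r2$fold_change, 4, tolerance = 0.05)
})

test_that("degenerate and identical groups follow the stated conventions", {
  sig <- rbind(ident = c(5, 5, 5, 5), shift = c(5, 5, 7, 7))
  m <- toy_em(sig, conditions = c("a", "a", "b", "b"), log2_transformed = TRUE)
  res <- quiet(welch_bh_contrast(m, "a", "b"))
  expect_equal(res$log2_fc[res$probe_id == "ident"], 0)
  expect_equal(res$p[res$probe_id == "ident"], 1)   # zero variance, equal means
  expect_equal(res$p[res$probe_id == "shift"], 0)   # zero variance, shifted
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(7)
  sig <- matrix(rnorm(300 * 8), 300)
  m <- toy_em(sig, conditions = rep(c("a", "b"), each = 4),
              log2_transformed = TRUE)
  res <- welch_bh_contrast(m, "a", "b")
  expect_true(all(res$p_adj >= res$p - 1e-15))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-15))
})

test_that("Welch p equals pooled-t p on equal-variance groups of 30", {
  set.seed(12)
  sig <- matrix(rnorm(50 * 60, 5, 1), 50)
  # equalise the two group variances exactly: Welch df then reduces to the
  # pooled 2n - 2 and the two tests must coincide
  for (i in seq_len(50)) {
    a <- sig[i, 1:30]; b <- sig[i, 31:60]
    sig[i, 31:60] <- mean(b) + (b - mean(b)) * sd(a) / sd(b)
  }
  m <- toy_em(sig, conditions = rep(c("a", "b"), each = 30),
              log2_transformed = TRUE)
  res <- welch_bh_contrast(m, "a", "b")
  p_pool <- vapply(seq_len(50), function(i)
    t.test(sig[i, 1:30], sig[i, 31:60], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(res$p, p_pool, tolerance = 1e-6)
})

test_that("the absolute fold rule admits both directions, the positive rule one", {
  sig <- rbind(up = c(8, 8, 8.1, 5, 5, 5.1), down = c(5, 5, 5.1, 8, 8, 8.1),
               null = rnorm(6, 6, 0.05))
  m <- toy_em(sig, conditions = rep(c("a", "b"), each = 3),
              log2_transformed = TRUE)
  abs_rule <- de_contrast_cyto(m, "a", "b")
  expect_setequal(abs_rule$probe_id[abs_rule$significant], c("up", "down"))
  pos_rule <- welch_bh_contrast(m, "a", "b", fold_rule = "positive")
  expect_setequal(pos_rule$probe_id[pos_rule$significant], "up")
})

test_that("select_bound_genes recovers planted truth and collapses probes by max enrichment", {
  g <- gen_ripchip_dataset(800, 12, generator_config(seed = 23),
                           conditions = c("RIP", "IgG", "cyto"))
  bl <- quiet(run_ripchip_pipeline(g))
  truth <- sort(unname(g$truth$probe_to_gene[g$truth$bound_probe_ids]))
  expect_setequal(bl$gene_symbol, truth)
  expect_true(all(diff(bl$fold_enrichment) <= 0))
  # enrichments are near the planted linear fold (2^3)
  expect_equal(median(bl$fold_enrichment), 8, tolerance = 0.25)

  # two probes of one gene: the max fold enrichment is kept
  con <- data.frame(probe_id = c("pA", "pB"), fold_change = c(3, 9),
                    significant = c(TRUE, TRUE))
  bl2 <- select_bound_genes(con, con, c(pA = "G1", pB = "G1"))
  expect_equal(bl2$fold_enrichment, 9)

  # nothing passing and empty mapping
  con0 <- data.frame(probe_id = "pA", fold_change = 3, significant = FALSE)
  expect_equal(nrow(select_bound_genes(con0, con0, c(pA = "G1"))), 0L)
  expect_warning(e <- select_bound_genes(con, con, character(0)), "empty")
  expect_equal(nrow(e), 0L)
})

test_that("the stated pipeline order is enforced", {
  g <- gen_ripchip_dataset(50, 0, generator_config(seed = 2))
  raw <- g$matrix
  expect_error(quiet(normalize_percentile_shift(raw)), "log2")
  expect_error(quiet(filter_cv(raw)), "log2")
  expect_error(quiet(welch_bh_contrast(raw, "RIP", "IgG")), "log2")
  m <- quiet(log2_transform(raw))
  expect_error(quiet(baseline_to_median(m)), "normalised")
})
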