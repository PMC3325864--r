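# ripare

Analysis toolbox for studying how an ARE-binding protein (the motivating
case is HuR/ELAVL1) shapes the response of breast cancer cell lines to a
cytotoxic drug such as doxorubicin. The package is aimed at wet-lab groups
and bioinformaticians who need the full quantitative chain behind such a
study as reusable, tested R functions:

* **Dose-response** — four-parameter logistic (4PL) fits of viability
  plates, `y = bottom + (top − bottom) / (1 + (d/IC50)^h)`, with IC50,
  hill slope, R², iso-effect inversion and fold-resistance ratios.
* **Drug combination** — the Loewe combination index for a fixed-ratio
  two-drug design, `CI(fa) = dA/DA(fa) + dB/DB(fa)`, with bootstrap bands
  and a synergy/additivity/antagonism classification.
* **RIP-chip** — the microarray filtering pipeline for RNA
  immunoprecipitation arrays: log2 transform, 75th-percentile-shift
  normalisation, median baselining, detection-flag and CV (>50%) filters,
  Welch t-tests with Benjamini–Hochberg correction and fold thresholds,
  and selection of the ranked bound-gene list.
* **ARE enrichment** — AU-rich element counting on 3'UTRs (Transterm
  consensus `UAUUUAUWW`) and a ranked nested enrichment scan using the
  EASE score, the conservative Fisher-exact variant
  `p = P(X ≥ k−1)`, `X ~ Hypergeom(N, K, n)`.
* **Translocation** — nucleocytoplasmic translocation z-scores
  `z = (x − μ)/δ` from per-cell compartment intensities (~300 cells per
  condition), with the below-zero-is-nuclear sign convention.
* **Synthetic data** — `gen_*()` generators that emulate every input with
  planted ground truth, so the whole pipeline is testable offline.

See the vignette `vignettes/analysis-methods.Rmd` for the models,
assumptions and design decisions.

## Worked example

```r
library(ripare)

cfg <- generator_config(seed = 42)                     # quadruplicate, CV 5%

## 1. IC50 of doxorubicin on the parental line (true IC50 0.04 uM)
plate <- gen_dose_response(list(ic50 = 0.04, hill = 1, top = 100, bottom = 0),
                           doses = 10^seq(-4, 1, length.out = 8), config = cfg,
                           drug = "doxorubicin", condition = "MCF-7")
fit <- fit_4pl(plate)
fit
#> 4PL dose-response fit: doxorubicin (MCF-7)
#>   IC50   = 0.04102 uM
#>   hill   = 0.9176
#>   top    = 98.41
#>   bottom = -0.8155
#>   R-squared = 0.9936, converged: TRUE

## 2. ~250-fold resistance of the selected line (true IC50 10 uM)
res <- fit_4pl(gen_dose_response(
  list(ic50 = 10, hill = 1, top = 100, bottom = 0),
  doses = 10^seq(-1, 2, length.out = 8), config = cfg,
  drug = "doxorubicin", condition = "MCF-7/DoxoR"))
fold_resistance(res, fit)
#> [1] 269.8315

## 3. Rottlerin + doxorubicin at 10:1, simulated 1.5-fold off additivity
mix <- gen_fixed_ratio_mixture(
  list(ic50 = 0.005, hill = 1, top = 100, bottom = 0),   # rottlerin
  list(ic50 = 0.04,  hill = 1, top = 100, bottom = 0),   # doxorubicin
  ratio = 10, alpha = 1.5, total_doses = 10^seq(-4, 1, length.out = 8),
  config = cfg, drug_a = "rottlerin", drug_b = "doxorubicin")
set.seed(42)
analyze_combination(mix$a, mix$b, mix$mix, mix$design, n_boot = 200)
#> Loewe combination index: rottlerin + doxorubicin (ratio 10:1)
#>   classification: antagonistic
#>   CI at fa = 0.50: 1.581 [1.157, 2.382] (200 bootstrap reps)

## 4. ARE enrichment over the packaged 50-gene ranked bound-gene list,
##    against a stated genome-scale background (N = 14678, K = 20% of N)
ranked <- example_bound_genes()
cat <- are_catalog_from_counts(attr(ranked, "are_count"),
                               K = 2936, N = 14678)
nested_enrichment_scan(ranked, cat)
#> enrichment_scan: 50 ranked genes (0 dropped, no UTR), background K/N = 2936/14678
#>   max significance at n = 44: p = 0.00859 (k = 17 ARE-positive)
#>   full list: 18/50 (36.0%) ARE-positive

## 5. Translocation: starved (nuclear) vs doxorubicin-treated (cytoplasmic)
cells <- gen_cell_intensities(c(starved = -0.8, doxo_4h = 0.7), cfg)
condition_z_scores(cells)
#> translocation_z (cytoplasm_over_nucleus): pooled mu = 1.297, delta = 0.9587
#>   condition n_cells         x         z        call
#> 1   doxo_4h     300 2.1334873  0.872697 cytoplasmic
#> 2   starved     300 0.4601461 -0.872697     nuclear
```

Reading the output: the refit IC50 (0.041 uM) recovers the generating
value within noise and the resistant/parental ratio lands near the true
250-fold. The combination index sits above 1 across the curve with its
bootstrap band clear of the additivity line, so the mixture is called
antagonistic. In the ranked-list scan, ARE-positive genes concentrate near
the top of the enrichment ranking, and the translocation z-scores separate
the nuclear (z < 0) from the cytoplasmic (z > 0) condition.

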