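---
title: "Models and methods: dose-response, Loewe combination index, RIP-chip filtering, ARE enrichment and translocation z-scores"
author: "ripare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripare)
```

ripare implements the quantitative analyses used to characterise how an
ARE-binding protein (HuR/ELAVL1 is the motivating case) shapes the response
of breast cancer cell lines to a cytotoxic drug such as doxorubicin: IC50
estimation from viability plates, Loewe combination-index analysis of a
fixed-ratio two-drug design, the RIP-chip microarray filtering pipeline that
yields a ranked list of protein-bound transcripts, an AU-rich-element (ARE)
enrichment scan over that ranking, and nucleocytoplasmic translocation
z-scores from per-cell immunofluorescence summaries. This vignette documents
the models, their assumptions, the tunable parameters, and the design
choices made where the underlying procedures left the details open.

## Dose-response: the 4PL model

Viability responses $y$ at dose $d$ are modelled with the four-parameter
logistic (4PL), the "log(inhibitor) vs response — variable slope" model of
standard curve-fitting software:

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
      {1 + (d/\mathrm{IC50})^{h}}.$$

`fit_4pl()` minimises least squares on log10 dose with multi-start
initialisation: `top`/`bottom` from the extreme responses, IC50 from the
dose pair bracketing the half-range response, and hill slope $h$ started at
0.5, 1 and 2. The best residual sum of squares wins; ties go to the smallest
hill. Decisions worth noting:

* **Free hill slope, relative IC50.** The IC50 is the inflection-based
  midpoint ("half of the maximum effect"), not an absolute EC50 against
  fixed 0/100 anchors. `top`/`bottom` are unconstrained.
* **Untransformed responses.** Luminescence counts are fitted as-is (no
  percent-of-control normalisation); $R^2 = 1 - SS_{res}/SS_{tot}$ is
  computed on that scale. Affine response transforms provably leave IC50
  and hill unchanged, and the test suite verifies this.
* **Canonical orientation.** The model is invariant under swapping
  top/bottom with $h \to -h$; fits are canonicalised to top > bottom.
* **Diagnostics.** At least 4 distinct doses are required; an IC50 outside
  the tested dose range attaches (and raises) a warning; if no start
  converges, the best parameters found are returned flagged
  `converged = FALSE`.

`invert_4pl()` gives the exact algebraic iso-effect dose
$D(f_a) = \mathrm{IC50}\,(f_a/(1-f_a))^{1/h}$ for fraction affected
$f_a$ (the fraction of the fitted maximal effect), and
`fold_resistance()` is the IC50 ratio of a resistant over a parental fit —
for the published MCF-7 pair (10 uM vs 0.04 uM) this is the ~250-fold
resistance figure.

## Loewe combination index

For a fixed-ratio mixture (`fixed_ratio_design()`, default 10:1 as in the
rottlerin:doxorubicin design) achieving $f_a$ at total dose $D_{mix}$, the
combination index is

$$CI(f_a) = \frac{d_A}{D_A(f_a)} + \frac{d_B}{D_B(f_a)},$$

with $d_A, d_B$ the ratio split of $D_{mix}$ and $D_A, D_B$ the single-agent
iso-effect doses. CI is estimated from three independent 4PL fits plus
algebraic inversion — a fully specified estimator of the same Loewe index
that mixed-effects combination tools report. Defining $f_a$ per curve
relative to its own fitted top/bottom makes the sham combination (a drug
mixed with itself) give CI = 1 exactly, which the tests assert to 1e-6.

`analyze_combination()` adds case-resampling bootstrap bands (replicates
resampled within dose, warm-started refits) and classifies the interaction:
**antagonistic** if the lower band exceeds 1 on at least half of the
$f_a$ grid (default 0.05–0.95 in steps of 0.05), **synergistic** if the
upper band is below 1 likewise, **additive** if the band straddles 1 on at
least half of the grid, otherwise **indeterminate**. The band rule is an
explicit stand-in for a "significantly above one" statement with no stated
test; it is calibrated in simulation (additive data classified additive in
well over 80% of runs).

## RIP-chip filtering pipeline

The microarray stages mirror the standard single-channel workflow for
RNA-immunoprecipitation arrays, with three contrasts: immunoprecipitate vs
IgG control (unnormalised, positive fold rule), immunoprecipitate vs
cytoplasmic RNA (normalised and baselined, positive fold rule), and
cytoplasmic control vs treated (normalised and baselined, absolute fold
rule).

1. `log2_transform()` — element-wise log2; non-positive raw signals are
   floored to a configurable epsilon with a reported count.
2. `normalize_percentile_shift()` — per sample, subtract the 75th
   percentile of log2 signal. Percentiles use linear interpolation between
   order statistics (R type 7, the common spreadsheet/NumPy default); the
   original array software's exact convention is undocumented.
3. `baseline_to_median()` — per probe, subtract the cross-sample median.
4. `filter_absent()` — keep probes flagged present in at least one sample
   of the contrast's sample set.
5. `filter_cv()` — remove probes whose within-condition coefficient of
   variation exceeds 50% in any condition. CV is computed on linear-scale
   intensities ($2^{\log_2}$ signal), CV being a linear-scale concept.
6. `welch_bh_contrast()` — per-probe Welch (unequal-variance) t-test,
   Benjamini–Hochberg step-up across retained probes, linear fold-change
   threshold 2. Zero-variance probes with equal means get p = 1 by
   convention. The row-wise implementation is cross-checked against
   `stats::t.test()` and a textbook BH computation in the test suite.

Provenance flags on the `expression_matrix` enforce this order: each stage
refuses to run twice or out of sequence. `select_bound_genes()` intersects
the probes passing both RIP contrasts, maps them to gene symbols, keeps the
maximum fold enrichment per gene (published bound-gene tables list one
value per gene), and sorts descending. The intersection (AND) of the two
RIP contrasts is a recorded choice; the exact boolean combination behind
published bound-gene counts is not spelled out anywhere we could follow.

## ARE enrichment scan

`select_longest_utr()` collapses transcript variants to the longest 3'UTR
per gene (ties broken lexicographically by transcript id).
`count_are()` counts IUPAC-pattern matches — default the Transterm ARE
consensus `UAUUUAUWW` (W = A or U) — at all window starts, overlapping
windows allowed, with `N` never matching; matching is delegated to
Biostrings. Since the enrichment analysis uses only gene-level presence
(`are_count >= 1`), the overlap convention does not affect the scan.

`ease_score()` implements the EASE score, the conservative variant of the
one-sided Fisher exact test in which one positive is removed from the
list cell before taking the hypergeometric upper tail:
$p = P(X \ge k-1)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, with
$p = 1$ whenever $k \le 1$. It is validated against brute-force tail
summation via log-binomial coefficients to 1e-10 relative, and the
penalisation property (EASE $\ge$ classical Fisher) is tested against
`fisher.test()`.

`nested_enrichment_scan()` walks the ranked bound-gene list in descending
fold-enrichment order: for every prefix length $n$ it counts ARE-positive
genes $k_n$ and computes the EASE score against the background
(`build_catalog()`, background restricted to UTRs longer than 9 nt; a
genome-scale background has $N$ = 14678 such genes). The reported optimum
is the smallest $n$ attaining the minimal p. The scan reports the raw
curve; the minimum over $n$ is a scan statistic and is deliberately not
multiplicity-corrected — a null-behaviour property test documents that the
minimum is stochastically smaller than any single-prefix p-value.

The packaged `example_bound_genes()` fixture is a published 50-gene
ranked list from a doxorubicin RIP-chip experiment with per-gene ARE
counts; 18 of its 50 genes (36%) carry at least one ARE. (The prose
accompanying the original table rounds this to 40%; the package preserves
the printed counts.) Reproducing the genome-scale scan optimum exactly
requires the full annotated UTR universe, in particular the unpublished
background positive count $K$, so scans against synthetic backgrounds state
their $(K, N)$ explicitly.

## Translocation z-scores

Per-cell compartment ratios are standardised as $z = (x - \mu)/\delta$,
where $\mu$ and $\delta$ are the mean and SD of the ratio over **all** cells
pooled across the conditions in the input (the pooling scope is the input
table boundary), and $x$ is a condition's mean ratio. Around 300 cells per
condition makes $z$ stable (seed-to-seed SD below 0.15 in the default
synthetic regime, tested).

The default ratio direction is **cytoplasm over nucleus**: the conventional
reading "z below zero = nuclear, above zero = cytoplasmic" is only coherent
when larger ratios mean more cytoplasmic protein, even though assay
write-ups often phrase the measurement as nucleus-over-cytosol. The
direction is configurable; on raw ratios a direction flip reverses the
ordering monotonically, and in `log_ratio = TRUE` mode it is an exact
antisymmetry (both behaviours are tested). Raw ratios are the default to
match the formula as usually written; the log mode exists because a pooled
SD on raw ratios is sensitive to their skew. `localization_call()` applies
the sign rule with z exactly at the threshold called cytoplasmic.

## Synthetic-data generators

The `gen_*()` family emulates every input, so each analysis stage can be
tested against planted ground truth:

* `gen_dose_response()` — responses on a 4PL curve with multiplicative
  Gaussian noise, $y = f(d)(1+\varepsilon)$, $\varepsilon \sim N(0, CV)$,
  in biological quadruplicate by default with CV 5% — typical luminescence
  assay behaviour. Default dose ranges span 0.1 nM – 10 uM (8 log-spaced
  points) for sensitive lines and 0.1 – 100 uM for the resistant line.
* `gen_fixed_ratio_mixture()` — the mixture effect at each total dose
  solves the Loewe equation with both component doses divided by a single
  scalar $\alpha$, so the true CI equals $\alpha$ at every effect level
  ($\alpha$ = 1 exact additivity; the simplest generative model whose true
  CI is known analytically). The two agents must share top/bottom — the
  construction needs a common effect scale. Doses whose solved effect falls
  outside the agents' response range are dropped with a report.
* `gen_ripchip_dataset()` — lognormal baselines (log2 mean 8, SD 1.5),
  planted log2 enrichment (default 3) in the RIP channel, heteroscedastic
  per-probe noise (CV spread uniformly 0.5–1.5x the configured CV), 5% of
  probes flagged absent everywhere, 2% given CV above 50% (under nonzero
  noise). Bound probes are never drawn from the absent/high-CV sets, so
  planted truth is exactly recoverable in the stated regime.
* `gen_utr_set()` — random-composition RNA sequences with lognormal
  lengths around a 300 nt mean; ARE status is controlled exactly (motif
  instances inserted into positives, chance matches scrubbed from
  negatives). The top-`planted_top_k` ranks are ARE-positive with
  probability 0.9 (an "elevated but imperfect" planting that keeps the
  scan's optimum near the planted boundary without making it degenerate),
  the rest at the configured background rate.
* `gen_cell_intensities()` — lognormal nucleus and cytoplasm signals whose
  natural-log ratio is centred per condition; cell-to-cell log-ratio SD
  defaults to 0.3, a realistic immunofluorescence population spread, with
  300 cells per condition.

One shared integer seed drives an independent derived stream per generator,
so outputs are byte-identical under a fixed seed and adding one generator
never perturbs another. What the generators do **not** emulate: probe
cross-hybridisation and array spatial artefacts, dye effects, segmentation
errors in imaging, or correlated (batch) noise — passing the planted-truth
tests therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to every failure mode of real data.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt least squares (minpack.lm) with the
multi-start scheme above; bootstrap refits warm-start from the point
estimate with a single start. Mixture effects are solved with `uniroot` to
1e-12 on the fraction-affected scale. Percentiles are linear-interpolated
order statistics; medians are midpoint medians. Comma-decimal numbers
("0,04") are normalised on file ingest.

The test and acceptance suites run at desk scale by design: 20-seed IC50
recovery, 100-simulation classification calibration at bootstrap depth 100,
2000-probe RIP-chip recovery with 50-seed null calibration, 700-gene
ranked scans over 100 seeds, and 1000-table EASE oracle sweeps — sizes
chosen so the whole suite completes in a few minutes while leaving the
stochastic acceptance margins wide.

## Known limitations

* Only 4PL curves are fitted; no 2PL/3PL constraints, biphasic models or
  outlier rejection.
* The CI estimator assumes all three curves are individually well fit;
  severely incomplete response ranges surface as `indeterminate` rather
  than being rescued by a joint model.
* The RIP-chip pipeline starts from extracted signals and detection flags;
  image-level feature extraction and background correction are upstream of
  it.
* The enrichment scan's minimum p-value is not corrected for scanning over
  prefixes — it should be read as a ranking diagnostic, not a calibrated
  significance level.
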