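# tmbsite

Quantifying how the site of a tumor biopsy shifts the tumor mutational
burden (TMB) score that clinicians act on.

## The problem

TMB — somatic nonsynonymous mutations per megabase (mut/Mb) from targeted
panel sequencing — gates immunotherapy eligibility through a fixed
pan-tumor threshold of 10 mut/Mb. In routine care the sequenced specimen
may come from the primary lesion or from any metastatic site, and
metastases of the same cancer can carry systematically different mutation
loads. `tmbsite` is a pipeline for measuring that biopsy-site effect in
specimen-level clinico-genomic data, for biostatisticians and
translational informaticians working with real-world genomic cohorts.

At its core, per cancer type, is an ordinary least squares model on the
log scale,

    log(TMB + 1) ~ biopsy_site + median_coverage + purity_pathologist + purity_computational,

from which site-versus-reference differences are obtained as estimated
marginal means (covariates at stratum means), re-gridded to the response
scale by the first-order delta method — m = exp(eta) − 1 with covariance
D (L Σ Lᵀ) Dᵀ, D = diag(exp(eta)) — and tested with t statistics on the
OLS residual df. So contrasts read directly in mut/Mb. Around this sit:
specimen selection (latest specimen per patient, pathologist purity
≥ 30%, site strata ≥ 50 per cancer type), TMB scoring from variant calls
(somatic nonsynonymous, allele frequency ≥ 5%, divided by panel Mb), the
dichotomous TMB-high analysis (percentage differences, cross-product odds
ratios with Woolf intervals, Pearson chi-square, skip rule at < 10 high
or low specimens), a metastasis-history-controlled design, and an exact
Wilcoxon signed-rank test for within-patient biopsy pairs ≤ 90 days
apart. A seeded synthetic cohort generator with an analytic ground-truth
effect table backs all parameter-recovery testing.

## Worked example

```r
library(tmbsite)

cfg <- cohort_config(
  site_effects = data.frame(
    cancer_type = "NSCLC",
    site        = c("lung", "brain", "adrenal"),
    is_primary  = c(TRUE, FALSE, FALSE),
    delta_log   = c(0, 0.35, 0.40),      # shifts on the log(TMB+1) scale
    n_specimens = c(300, 120, 80)),
  mu_log = 2, sigma_log = 0.6,
  beta_coverage = 0.1, beta_purity_path = 0.05,
  seed = 11)
cohort <- generate_cohort(cfg)

sel <- select_cohort(cohort$specimens, c(NSCLC = "lung"))
sel$counts
#>           input latest_specimen   purity_filter  stratum_filter
#>             549             500             441             441

run_all(sel$specimens, c(NSCLC = "lung"))
#>   cancer_type contrast_type       site reference_site estimate        se   ci_low  ci_high      p_value n_site n_reference
#> 1       NSCLC        pooled metastatic        primary 3.196621 0.5351790 2.144770 4.248473 4.839282e-09    178         263
#> 2       NSCLC          site    adrenal           lung 3.095682 0.7751885 1.572101 4.619263 7.643928e-05     72         263
#> 3       NSCLC          site      brain           lung 3.264855 0.6615330 1.964656 4.565053 1.142050e-06    106         263
#> 4       NSCLC          site       lung           lung 0.000000 0.0000000 0.000000 0.000000 1.000000e+00    263         263
```

Reading the output: after filtering (549 specimens → 441 analyzable),
brain biopsies score an estimated 3.26 mut/Mb higher than primary lung
biopsies (95% CI 2.0–4.6), adrenal 3.10 mut/Mb higher — against generator
ground truth of 3.10 and 3.64 mut/Mb (`true_effect_table(cfg)`). The
pooled row shows the coarser metastatic-vs-primary comparison that can
mask opposite-signed site effects. The same cohort flows on to
`tabulate_high()`/`compare_sites()` for the TMB-high analysis,
`run_met_controlled()` for the metastasis-documented restriction, and
`find_biopsy_pairs()` + `paired_site_test()` for the paired design;
`run_pipeline(run_config(...))` chains everything and writes result
tables plus a JSON manifest of thresholds and filter counts.

See `vignettes/biopsy-site-tmb.Rmd` for the model, the generator's
assumptions, and the design decisions.

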