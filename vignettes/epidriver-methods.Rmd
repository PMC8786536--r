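---
title: "Methods: integrated methylation-expression driver-gene analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated methylation-expression driver-gene analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidriver)
```

## The analysis

`epidriver` implements an integrated tumor/normal analysis that combines
promoter DNA methylation with gene expression to nominate *epigenetically
altered driver genes*, and validates a candidate marker against clinical
endpoints. The stages are:

1. **Preprocessing.** Expression declared as FPKM is renormalized to TPM
   (each sample column scaled to sum to $10^6$). CpG probes are filtered
   (unannotated probes and probes with missing beta values are dropped) and
   mapped to promoters, defined as the window from 800 bp upstream to
   200 bp downstream of the TSS (strand-aware by default, mirrored on the
   minus strand; configurable). A gene's promoter methylation per sample is
   the unweighted mean beta of its mapped probes.
2. **Differential calling.** Per gene, tumor vs normal is compared with a
   two-sided Wilcoxon rank-sum test, both for expression (TPM) and promoter
   methylation (beta). Expression calls require
   $|\log_2 \mathrm{FC}| > 1$ and Benjamini–Hochberg FDR $< 0.05$;
   methylation calls use the raw $p < 0.05$ with the sign of
   $\Delta\beta = \bar\beta_\mathrm{tumor} - \bar\beta_\mathrm{normal}$ and
   no effect-size threshold. All threshold comparisons are strict.
3. **EI/ES classification.** A gene is *epigenetically induced* (EI) when
   expression is up and promoter methylation is down; *epigenetically
   suppressed* (ES) when expression is down and methylation is up.
   Discordant or incomplete combinations are unclassified. EI/ES genes are
   then filtered by the Spearman correlation between promoter methylation
   and expression, computed across all samples (tumor and normal pooled),
   keeping genes with $\rho < 0$ (strict).
4. **Network enrichment.** The surviving genes are mapped onto an
   undirected protein-interaction network. For each tested gene with
   degree $a+b$, where $a$ of its neighbors belong to the EI/ES background
   set, enrichment is scored with the one-sided Fisher exact test on the
   table $[[a, b], [K-a, N-K-b]]$, i.e. the hypergeometric upper tail
   $P(X \ge a)$ with population $N$ (all network nodes) and $K$ marked
   genes (EI/ES genes present in the network). Drivers are genes with
   adjusted $p < 0.05$ **and** marked-neighbor proportion
   $a/(a+b) > 0.10$, both strict.
5. **Clinical validation.** Marker staining scores 1–4 are dichotomized
   (1–2 low, 3–4 high). Association with clinicopathological strata uses
   the 2×2 chi-squared test; survival uses Kaplan–Meier curves, the
   two-group log-rank test, and univariate plus multivariate Cox
   proportional-hazards models; diagnostic separation uses the
   rank-statistic AUC.

## Key parameter choices

| Parameter | Default | Why |
|---|---|---|
| promoter window | −800/+200 bp of TSS | standard promoter definition for 450K-style probe mapping |
| expression FC | $|\log_2\mathrm{FC}| > 1$, BH FDR < 0.05 | the published screening criteria |
| methylation call | raw $p < 0.05$, sign of $\Delta\beta$ | methylation differences are small on the beta scale; an FC cut is not meaningful |
| correlation filter | Spearman $\rho < 0$, pooled samples | EI/ES is defined by anticorrelation; pooling uses all information and matches how methylation–expression coupling acts in both tissue states |
| driver criteria | enrichment FDR < 0.05 and proportion > 0.10 | the published selection rule |
| Cox ties | Efron | the standard default; more accurate than Breslow with tied event times |

Several points are genuinely open in this design and were fixed as follows:

- **Fold change estimator**: $\log_2((\bar x_T + 1)/(\bar x_N + 1))$ with a
  pseudocount of 1 (configurable). On TPM scales the pseudocount is
  negligible for expressed genes and stabilizes near-zero means.
- **Strand handling**: promoters are strand-aware by default; an
  unstranded mode treats every gene as plus-strand. A probe inside
  overlapping promoter windows contributes to every overlapped gene — no
  arbitrary tie-break.
- **Multiplicity for enrichment**: Benjamini–Hochberg over all tested
  genes by default; a Bonferroni option exists because published FDR
  columns of this kind are sometimes Bonferroni-style. The background size
  $K$ is always computed from the data, never hard-coded.
- **Test sidedness**: enrichment is one-sided (greater); this is the form
  under which the published per-gene p-values are reproducible from their
  printed counts. Under that reading, the printed "neighbor gene" count is
  the *non*-marked neighbor count, so a gene's degree is $a + b$ — the only
  interpretation consistent with both the printed proportions and the
  printed p-values.
- **Wilcoxon exactness**: when both groups have at most 10 observations
  the two-sided p-value is computed by full enumeration of rank
  assignments (average ranks, so ties are handled exactly); larger groups
  use the normal approximation with tie and continuity correction. The
  enumeration threshold is configurable.

## The synthetic-data generator

Real tumor cohorts cannot ship with the package, so every stage is
exercised against a generator (`sim_config()`, `simulate_omics()`,
`simulate_network()`, `simulate_cohort()`) that reproduces the statistical
structure the analysis assumes, together with ground-truth labels.

**Omics.** Gene expression is log-normal per gene (gene-specific baseline
$\mu_g \sim N(5, 1.5^2)$ on the log2 scale, residual sd 0.6); planted EI
genes gain `expr_effect` log2 units in tumor samples, ES genes lose them.
Promoter methylation is logit-normal per probe around a gene-level target;
planted EI genes lose `meth_effect` (beta scale) in tumor samples, ES
genes gain it. The logit-normal location is solved numerically
(vectorized Newton iteration over a fixed quadrature grid) so the marginal
beta *mean* equals the target — placing the location at `logit(target)`
would shrink group-mean differences toward 0.5 and the planted
$\Delta\beta$ would systematically undershoot. Planted genes share a
per-sample standard-normal latent factor that enters expression with
weight `+coupling` and methylation with `-coupling`, which induces the
negative Spearman correlation the filter looks for. Each gene carries 1–3
CpG probes placed uniformly inside its own promoter window. Defaults: 41
tumor/normal pairs, 2000 genes, 60 EI + 20 ES, `expr_effect = 2`,
`meth_effect = 0.3`, `coupling = 0.8`.

**Network.** The background graph is grown by preferential attachment
(10 edges per new node, hence mean degree ≈ 20, matching the heavy-tailed
degree structure of curated interaction resources at this package's
scaled-down default of 2000 nodes). Node names are shuffled so planted
genes are not biased toward old, high-degree nodes. Four planted drivers
are drawn from the planted EI/ES genes; a fraction `driver_wiring = 0.5`
of each driver's edges is rewired to EI/ES nodes, planting the enriched
neighborhoods the Fisher stage must find. The graph remains simple.

**Cohort.** Each of 80 patients has a latent binary marker state; staining
scores are drawn from {3,4} for marker-high and {1,2} for marker-low, so
IHC dichotomization recovers the state. Survival is exponential with
baseline hazard $\log 2 / 50$ per month multiplied by
$\exp(\text{marker\_log\_hr})$ for marker-high patients
(default $\log 4.465$); censoring is independent uniform on
(0, 120] months. TNM stage is associated with the marker through a
log-odds shift (`stage_assoc = 2.2`) but has **no** direct hazard effect,
so the univariate marker hazard ratio is estimated without confounding.

All draws flow from the single config seed (with fixed per-generator
offsets), and each generator restores the caller's RNG state; identical
config + seed reproduces byte-identical outputs.

**What the generator does not emulate**: array chemistry and probe
cross-reactivity, batch and purity effects, copy-number or mutational
layers, correlated gene modules, non-proportional hazards, and informative
censoring. Passing recovery tests therefore demonstrates the pipeline's
correctness and power under clean planted signal, not its behavior on the
messier correlation structure of real cohorts.

## Numerical and degenerate-input choices

- The hypergeometric tail is accumulated in log space
  (`lchoose` + log-sum-exp); no approximation at any table size.
- Constant vectors: Wilcoxon on identical values returns $p = 1$; Spearman
  on a constant vector is undefined and reported as `NA` (such genes fail
  the correlation filter); a constant-beta gene yields $p = 1$ and no
  call.
- Degree-zero genes in the enrichment stage get $p = 1$, proportion 0, and
  a flag rather than an error.
- A sample column summing to zero is an error naming the sample; an empty
  edge list yields an empty network with a warning; a stage failure in
  `run_pipeline()` aborts with the stage name.
- Quantile dichotomization sends ties at the cut to "low"; an all-equal
  vector yields a single "low" group with a warning, and downstream
  two-group operations refuse degenerate single-group input.

## Problem sizes used in the test and acceptance runs

The packaged checks run the generator at its defaults (2000 genes,
41 pairs, 2000-node network) for recovery measurements — EI/ES recall and
driver recovery are averaged over 5 seeds, Cox hazard-ratio recovery over
20 cohorts of 500 patients, and log-rank null calibration over 200
cohorts of 80 — sizes chosen so each property is measured with useful
precision while the whole suite stays quick to run. Unit tests use smaller
configurations (200–600 genes) that exercise the same code paths.

## Known limitations

- Unpaired Wilcoxon tests are used even when tumor/normal pairing is
  recorded, matching the published design; a paired alternative is a
  natural extension but is not the default.
- The correlation filter has no significance threshold on $\rho$ — any
  negative rank correlation passes; with 82 samples weak negative
  correlations pass easily.
- The multivariate Cox covariate set is chosen by univariate screening at
  $p < 0.05$; this is the conventional, not the optimal, selection rule.
- Chi-squared continuity correction is an explicit per-analysis argument
  (`none` default) rather than a global rule, because published 2×2 tables
  of this kind mix corrected and uncorrected values.
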