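# rhizometa

Multi-study meta-analysis of paired rhizosphere vs bulk-soil bacterial
communities from 16S rRNA amplicon count tables.

Plant roots concentrate labile carbon in the soil directly around them, and
the bacterial community there — the rhizosphere — is consistently different
from root-free bulk soil: usually less rich, more copiotroph-dominated
(higher rRNA operon copy numbers), with a different dormancy-gene profile
and different co-occurrence network structure. Testing whether such shifts
are general requires pooling many independent paired studies, each with its
own sequencing depth, covariates and noise. **rhizometa** is a
tidyverse-native R package for that workflow: per-study community analysis,
study-level effect sizes, and a formal random-effects meta-analysis, plus a
synthetic multi-study generator with known ground truth so every stage is
testable offline.

## The model at the core

Each study contributes, per community variable, a log response ratio and
its sampling variance

```
lnRR = ln(X_t / X_c)
v    = S_t^2 / (n_t X_t^2) + S_c^2 / (n_c X_c^2)
```

(`t` = rhizosphere, `c` = bulk soil; group means, SDs and sizes). Studies
are pooled by a DerSimonian–Laird random-effects model with weights
`w = 1 / (v + tau^2)`; 95% CIs come from 999 bootstrap resamples of
studies, and pooled effects are reported as percent change
`(exp(lnRR) - 1) * 100`. Heterogeneity is partitioned (`Q_T = Q_W + Q_B`)
for categorical moderators, publication bias is assessed by Egger
regression and Duval–Tweedie trim-and-fill, and predictor importance is
scored by summed Akaike (AICc) weights over all covariate subsets.

Upstream of the meta-analysis the package implements rarefaction, alpha
diversity (observed richness, Shannon, Pielou, Faith PD), Bray–Curtis /
PCoA / PERMANOVA, ALDEx-style compositional differential abundance (CLR on
128 Dirichlet Monte-Carlo instances, Wilcoxon + BH), co-occurrence networks
(Spearman + BH, random-matrix-theory threshold, greedy modularity, Zi/Pi
node roles, natural connectivity, betweenness-ordered robustness curves),
and community-weighted traits (rRNA operon copies, toxin–antitoxin and
sporulation gene systems, NSTI > 2 filtering, FAPROTAX-style
taxonomy-rule functions).

## Worked example

```r
library(rhizometa)

# a synthetic corpus: 8 paired studies, 120 taxa, known ground truth
bundle <- generate_study_set(synth_config(n_studies = 8, n_taxa = 120, seed = 2024))

res <- run_pipeline(bundle$counts, bundle$metadata,
                    tree = bundle$tree, traits = bundle$traits,
                    depth = 10000, n_boot = 999, seed = 1)
tidy(res$pooled)
#> # A tibble: 7 × 9
#>   term    group     k estimate conf.low conf.high    tau2 pct.change significant
#>   <chr>   <chr> <int>    <dbl>    <dbl>     <dbl>   <dbl>      <dbl> <lgl>
#> 1 richne… over…     8 -4.80e-3 -8.67e-3  -7.82e-4 0          -0.479  TRUE
#> 2 shannon over…     8 -9.63e-3 -1.98e-2   6.29e-3 0          -0.958  FALSE
#> 3 pielou  over…     8 -8.16e-3 -1.81e-2   8.99e-3 0          -0.812  FALSE
#> 4 faith_… over…     8 -6.09e-4 -9.90e-4   8.30e-5 0          -0.0609 FALSE
#> 5 weight… over…     8  1.35e-1  9.37e-2   1.79e-1 2.12e-3    14.4    TRUE
#> 6 toxin_… over…     8  1.49e-2 -1.51e-2   4.30e-2 0           1.50   FALSE
#> 7 sporul… over…     8 -2.79e-2 -5.20e-2   2.35e-3 1.83e-4    -2.75   FALSE
```

Read: across the 8 studies, rarefied richness is significantly *lower* in
the rhizosphere (−0.48%, bootstrap CI excluding 0) while the
community-weighted mean rRNA operon copy number is significantly *higher*
(+14.4%) — the copiotroph enrichment this generator was configured to
plant. `autoplot(res$pooled)` draws the forest-style percent-change plot.

Publication-bias diagnostics for any one variable:

```r
trim_and_fill(res$records[res$records$variable == "richness", ])
#> Trim-and-fill: k0 = 1 missing on the left, pooled lnRR -0.0048 -> -0.0064 (Egger p = 0.842)
```

Networks, differential abundance and ordinations are separate verbs
(`filter_and_correlate()`, `rmt_threshold()`, `build_network()`,
`greedy_modules()`, `node_roles()`, `robustness_curve()`,
`diff_abundance()`, `pcoa_ordination()`, `permanova_test()`), each taking
and returning plain tibbles or igraph/dist objects. A thin CLI wrapper
(`inst/cli/rhizometa`, subcommands `simulate`, `diversity`, `diffabund`,
`network`, `traits`, `meta`, `pipeline`) exposes the same functions for
shell pipelines. See `vignettes/rhizometa-methods.Rmd` for the full
methods account.

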