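---
title: "Methods: paired rhizosphere/bulk-soil bacteriome meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired rhizosphere/bulk-soil bacteriome meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plant roots reshape the soil microbiome: the rhizosphere (soil under direct
root influence) typically hosts a less rich, more copiotroph-dominated
bacterial community than the surrounding bulk soil. Quantifying that
"rhizosphere effect" across many independent 16S rRNA amplicon studies
requires a chain of per-study community analyses followed by a formal
random-effects meta-analysis. **rhizometa** implements that chain as a
tested, reusable pipeline:

1. per-sample diversity (rarefaction, observed richness, Shannon, Pielou,
   Faith phylogenetic diversity, Bray–Curtis/PCoA, PERMANOVA);
2. compositional differential abundance (CLR on Dirichlet Monte-Carlo
   instances, Wilcoxon + Benjamini–Hochberg, standardized effect);
3. co-occurrence network topology (random-matrix-theory correlation
   threshold, greedy modularity, Zi/Pi node roles, natural connectivity,
   betweenness-ordered robustness);
4. community-weighted traits and rule-based functions (rRNA operon copy
   number, toxin–antitoxin and sporulation gene systems, NSTI filtering);
5. a log response ratio (lnRR) random-effects meta-analysis with bootstrap
   confidence intervals, heterogeneity partitioning, Egger regression,
   trim-and-fill and all-subsets predictor importance.

Because real multi-study corpora are large, external and heterogeneous, the
package ships a synthetic multi-study generator with fully known ground
truth; every stage is validated against closed forms, brute-force
re-implementations, independent packages (metafor) and recovery
simulations.

# The effect-size model

For a variable $X$ measured in both compartments of study $i$,

$$\mathrm{lnRR}_i = \ln(X_{t,i}/X_{c,i}), \qquad
v_i = \frac{S_{t,i}^2}{n_{t,i} X_{t,i}^2} + \frac{S_{c,i}^2}{n_{c,i} X_{c,i}^2},$$

with $t$ the rhizosphere group, $c$ the bulk-soil group, $S$ sample
standard deviations (n − 1 denominator) and $n$ group sizes. A group of
size 1 contributes $S = 0$ and is flagged; a non-positive group mean makes
the log undefined and the record is skipped with a logged reason.

Pooling uses the random-effects model with DerSimonian–Laird between-study
variance $\tau^2$ (floored at 0) and weights $w_i = 1/(v_i + \tau^2)$. The
95% CI comes from 999 nonparametric bootstrap resamples of studies
(percentile method, $\tau^2$ re-estimated per resample); a fixed seed gives
bit-identical CIs. For interpretability the pooled mean $\overline{\mathrm{lnRR}}$
and both CI bounds are converted to a percent change
$(e^{\overline{\mathrm{lnRR}}} - 1)\times 100\%$; the conversion
round-trips exactly. The bootstrap resamples *studies* (not effect sizes
within groups); with $k$ studies per variable this is the natural
exchangeable unit.

Categorical moderator analysis partitions total heterogeneity
$Q_T = Q_W + Q_B$ using the common random-effects weights, so the identity
holds to machine precision; $Q_B$ is referred to $\chi^2_{G-1}$. Subgroups
with fewer than 10 studies are dropped (and logged) before partitioning.

Publication-bias diagnostics follow the classic recipes: Egger's
regression of the standardized effect on precision (intercept t-test,
df = k − 2), and Duval–Tweedie trim-and-fill with the iterative rank-based
L0 estimator, DerSimonian–Laird centring, and mirror imputation. The
missing-studies side defaults to the sign of Egger's intercept and can be
forced. Predictor importance fits all subsets of up to six study-level
covariates by variance-weighted least squares, converts AICc to Akaike
weights (AICc rather than AIC because per-variable study counts can be
modest), and scores each predictor by the summed weight of models
containing it, with the conventional 0.8 cutoff.

# Diversity and compositional choices

* **Rarefaction** (default 10,000 reads) is a single seed-controlled draw
  without replacement; samples below the depth are dropped, never resampled
  with replacement, and the drop count is logged.
* **Shannon is in natural log**, consistent with Pielou
  $J = H/\ln S$ (undefined at $S \le 1$) and with the natural-log effect
  size.
* **Faith PD includes the path to the root** by default (switchable via
  `include_root`).
* **PERMANOVA** permutes labels within studies when a `strata` factor is
  supplied, respecting the paired multi-study design; the p-value is
  $(1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$.
* **Differential abundance** draws 128 Dirichlet(counts + 0.5) Monte-Carlo
  instances per sample; the 0.5 prior resolves zeros. Each instance is
  CLR-transformed ($\mathrm{clr}_i = \ln x_i - \overline{\ln x}$, so CLR
  values and reported differences are in natural-log units). The per-taxon
  p is the arithmetic mean of per-instance two-sided Wilcoxon rank-sum
  p-values (a Welch t is available via `test = "t"`; the rank-sum test is
  the primary choice), then Benjamini–Hochberg across taxa. The Wilcoxon
  step is a vectorised normal approximation with tie and continuity
  correction, unit-tested to machine precision against
  `stats::wilcox.test(exact = FALSE)`. The standardized effect is the
  median over instances of a random cross-group CLR difference divided by
  the larger of the two within-group random-pair dispersions.

# Network choices

Taxa below 0.02% mean relative abundance are removed before pairwise
Spearman correlation (two-sided p via the t approximation, BH across all
pairs). The correlation threshold $\rho^\ast$ is chosen by the
random-matrix-theory transition: for each candidate the thresholded
matrix's eigenvalue spectrum is unfolded with a cubic smoothing spline, and
the nearest-neighbour spacing distribution is tested against the Poisson
law $e^{-s}$ by a $\chi^2$ goodness of fit (20 equal-width bins on [0, 3],
consistency declared at p > 0.05); the smallest consistent candidate wins.
Degenerate eigenvalues are collapsed before unfolding, and spectra with
fewer than 10 spacings are treated as untestable (consistent), which makes
threshold-invariant inputs return the smallest candidate. Every constant is
an argument.

Edges require both BH q < 0.05 and $|\rho| \ge \rho^\ast$; isolated nodes
are dropped and logged; the edge sign is kept as an attribute but ignored
by topology metrics. Modules come from igraph's agglomerative greedy
modularity maximisation on the unweighted graph ($|\rho|$ weights
optional); when the greedy merge path ends below the trivial single-module
partition (possible on highly symmetric graphs), the single-module
partition with Q = 0 is returned instead, so Q(returned) ≥ Q(single
module) always holds. Node roles use the within-module degree z-score Zi
(0 when the module's degrees have zero variance) and participation
coefficient $P_i = 1 - \sum_s (k_{is}/k_i)^2$, with the four-way
classification at Zi = 2.5 and Pi = 0.62; boundary equalities fall to the
peripheral side because the published definitions are strict in both
directions.

Robustness curves compute betweenness once on the intact graph and remove
nodes smallest-betweenness-first (as the sort is specified; `order =
"desc"` and `"random"` are provided for sensitivity analysis), ties broken
by node id for determinism, recording natural connectivity
$\ln\big(\tfrac1N \sum_i e^{\lambda_i}\big)$ after each removal up to 80%
of nodes. Natural connectivity is evaluated with a log-sum-exp shift for
numerical stability. One empirical caveat found during validation: with
each graph ranked by its *own* betweenness, the curves of a graph and a
denser variant can cross in the noisy late tail, so the tests assert
mean-curve dominance and exact pointwise dominance under a common removal
order (the latter is guaranteed by the edge-monotonicity of natural
connectivity) rather than pointwise dominance under independent orders.

# Traits and functions

Gene-content prediction itself is out of scope; the package consumes a
per-taxon trait table (rRNA operon copies, toxin–antitoxin and sporulation
gene counts, NSTI). Taxa with NSTI > 2 are removed (strict inequality; a
taxon at exactly 2 is retained). The community-weighted mean operon count
$\sum_i p_i c_i$ is the heterotrophy (copiotroph/oligotroph) proxy; its
abundances are *not* copy-number corrected by default, since the trait is
the copy number itself and the correction would be partially
self-referential. Dormancy-system and function abundances *are* corrected
by 16S copy number by default (both switchable). Dormancy abundances are
community-weighted means per read, not totals (a community-aggregated
trait); all outputs depend only on relative abundances and are invariant
to count rescaling. Functions are matched by taxonomy rules (one stanza
per function; `Rank:value` inclusions, `-Rank:value` exclusions; strict
parser that rejects unknown ranks), and a taxon may carry several
functions.

# The synthetic generator

`generate_study_set()` emulates a multi-study paired corpus: a log-normal
base composition (σ = 1.5, giving the skewed rank-abundance curve typical
of 16S data, which makes the 0.02% network filter meaningful), taxon-level
compartment log-fold effects for a configurable fraction of taxa, a
study-level random effect of variance τ² entering additively on the log
scale as `delta + sign(delta) * u_study` (so it cancels for null taxa),
block-correlated latent abundances (a per-sample block factor shared by
taxa of the same block) to induce co-occurrence structure, and multinomial
read sampling at negative-binomial depths. Rhizosphere-enriched taxa
receive higher operon copy counts and toxin–antitoxin gene loads
(copiotroph coupling); the tree is a random coalescent over the taxon ids;
all randomness flows from one seed with a fixed draw order, so identical
configs give bit-identical bundles.

The generator's "study-level true lnRR" per variable is defined on the
latent-median (noise-free) composition; finite-depth realized richness and
PD truths have no closed form, which the tests respect by checking
directions and recoveries rather than exact values. The generator does
*not* simulate raw reads, chimeras, primer bias or sequencing error, and
its taxonomy/trait labels are synthetic stand-ins — passing tests
demonstrate correctness of the computations and calibration of the
statistics under a plausible generative model, not biological fidelity of
any particular dataset.

# Validation design choices

* **Coverage**: with k = 40 studies, true lnRR = ln 0.95 and τ² = 0.01
  (5 samples per group, CV 0.2), the 999-resample percentile bootstrap CI
  covers the truth in ~94% of 200 replicates, and the median recovered τ²
  is within a factor of 2 of the truth.
* **Type-I error**: PERMANOVA (null Poisson counts, random labels, 99
  permutations), the Q_B χ² test (three equal null subgroups) and Egger's
  regression all hold their size in [0.03, 0.08] over 500 replicates.
  Egger's null is simulated under the test's own model (known within-study
  variances, τ² = 0): with group-estimated lnRR variances or extra
  heterogeneity the classic test is known to be anticonservative, a
  property of the published test rather than of this implementation.
* **Trim-and-fill recovery**: the L0 estimator agrees with
  `metafor::trimfill` exactly on identical inputs. A funnel-plot method
  needs a funnel: with homogeneous precisions the censoring of 5 of 40
  studies is undetectable (metafor likewise returns k0 = 0), so the
  recovery simulation draws within-study variances log-uniformly over
  [0.001, 0.1] — precisions spanning two orders of magnitude, as in real
  multi-study amplicon corpora — under which the median recovered k0 is 5
  and Egger's intercept is positive in ~95% of censored replicates.
* **Problem sizes**: the end-to-end checks use 12 studies × 5 samples per
  compartment × 150 taxa at depth ~20,000 (rarefied to 10,000), and the
  simulation studies use 200–500 replicates with reduced permutation and
  bootstrap counts where only calibration is at stake; these sizes were
  chosen to exercise every code path at desk scale.

# Known limitations

* The generator's compositional model is a stand-in; none of its
  distributional choices are estimated from data.
* The RMT threshold recipe (spline unfolding, binning, χ² consistency) is
  one published variant; all constants are exposed as arguments.
* Egger's test and trim-and-fill inherit the known small-sample and
  heterogeneity caveats of the original methods.
* The t-approximation for Spearman p-values is asymptotic; below ~8
  samples the network q-values are conservative at best (the builder
  refuses fewer than 4 samples).
* lnRR requires strictly positive group means; variables that can be zero
  in a compartment (e.g. a rare function's abundance) can drop studies
  from their meta-analysis, and the log notes every skip.
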