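---
title: "Methods: augmented-design analysis and core collection construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmented-design analysis and core collection construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germcore)
```

This vignette is the package's account of its statistical machinery: the
models, the estimators, the places where a genuine design choice had to be
made, and what the test suite does and does not demonstrate.

## The augmented block design model

All plot-level analysis assumes Federer's augmented RCBD: `b` blocks, `c`
check varieties replicated `r` times in every block, and unreplicated test
entries distributed across blocks. The working model is additive,

$$y_{ij} = \mu + \tau_i + \beta_j + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, V_e),$$

with genotype effects $\tau_i$, block effects $\beta_j$ and independent plot
error. Because only checks are replicated, block effects are estimated from
the checks: $\hat\beta_j$ is the block's check mean minus the grand check
mean, so $\sum_j \hat\beta_j = 0$ by construction, and a test entry's
adjusted value is its observation minus its block's effect. Adjustment is
purely arithmetic — negative adjusted values are legitimate and are not
floored.

**Error stratum.** The error variance is estimated from the residuals of the
additive block + check fit on *all* check plots, with
$df = bcr - b - c + 1$, which reduces to the classical $(b-1)(c-1)$
check-by-block interaction when $r = 1$. We deliberately do not average a
check's replicate plots before computing the error stratum: residuals of
block-level check *means* estimate $V_e/r$, not the plot-scale $V_e$, and
every downstream quantity (critical differences, heritability) needs the
plot scale. Block effects themselves are computed from block check means,
which under a balanced layout is identical either way.

The ANOVA reports blocks (ignoring treatments), treatments adjusted for
blocks — partitioned into checks, tests (from the adjusted values) and
checks-vs-tests (by subtraction, keeping the strata exactly additive) — and
the error stratum. The implementation follows the design algebra directly;
the test suite checks it against an independent sequential least-squares fit
(`lm(y ~ block + treatment)`) on randomized small designs.

**Critical differences.** The four Federer comparison standard errors
(check–check $\sqrt{2V_e/b}$; test–test, same block $\sqrt{2V_e}$; test–test,
different blocks $\sqrt{2V_e(c+1)/c}$; test–check
$\sqrt{V_e(1 + 1/b + 1/c + 1/bc)}$) are multiplied by the two-sided $t$
critical value on the error df; $\alpha$ defaults to 0.05 everywhere.
Promising accessions are tests whose adjusted mean beats the best check by
more than CD(test–check).

## Genetic variability parameters

For each trait the phenotypic variance is estimated from the adjusted test
means. One subtlety matters: an adjusted value carries the block-effect
estimation error, so

$$\operatorname{var}(\text{adjusted mean}) = V_g + V_e + V_e/(rc).$$

`variability_params()` therefore uses $\hat V_p = \operatorname{var}(\text{adj}) -
\hat V_e/(rc)$ and $\hat V_g = \hat V_p - \hat V_e$, which makes the
decomposition $V_p = V_g + V_e$ exact and the heritability estimator
$h^2 = 100\,V_g/V_p$ unbiased on simulated data (the naive
$\hat V_p = \operatorname{var}(\text{adj})$ leaves a downward bias of roughly
$100\,(1-h^2)\,V_e/(rc\,V_p)$ points; `ve_inflation = FALSE` restores it for
comparison). $V_g$ is floored at zero, with a warning, when error swamps
signal.

From these: $GCV = 100\sqrt{V_g}/\bar x$, $PCV = 100\sqrt{V_p}/\bar x$,
$GA = k\sqrt{V_p}\,h^2/100$ with $k = 2.063$ (the standardized selection
differential at 5% selected fraction; configurable), and $GG = 100\,GA/\bar
x$. Two identities hold algebraically and are asserted on every output:
$h^2 = 100\,(GCV/PCV)^2$ and $GG = 100\,GA/\bar x$. Category labels use the
conventional cutoffs — heritability: below 30 Low, 30–60 Medium, above 60
High; CV, GA and GG: below 10 Low, 10–20 Medium, above 20 High — with
boundaries closed on the lower side (exactly 30 is Medium), since published
tables never disambiguate the boundary.

The packaged reference trait table (`inst/extdata/mungbean_trait_reference.csv`,
from a published large-scale mungbean characterization) stores the *smaller*
of the two printed coefficients of variation as GCV. In the original table
the column order is ambiguous, but only this reading satisfies
$h^2 = 100(GCV/PCV)^2$ for every row (e.g. terminal leaf length:
$(5.98/13.17)^2 \cdot 100 = 20.62$, the printed heritability), and
$GCV \le PCV$ is forced by $V_g \le V_p$.

## The synthetic collection generator

`generate_collection()` draws, per accession, a genotype vector from
$N(0, D R D)$ where $R$ is the configured genotypic correlation matrix and
$D = \operatorname{diag}(\sqrt{V_g})$; checks receive one genotype reused
across every replicate plot. Block effects are i.i.d. normal, shared across
traits up to a per-trait scale (default $0.5\sqrt{V_e}$ — moderate field
heterogeneity); plot errors are independent $N(0, V_e)$. Qualitative
descriptor states and geographic groups are accession attributes drawn once
from configured frequency vectors. Each stage uses a named sub-stream of the
master seed, so changing, say, the error draw does not perturb the layout.

Defaults emulate a national-genebank mungbean trial: 3903 tests, 50 blocks,
5 named checks twice per block, 21 quantitative traits whose means and
variance components are derived from the reference trait table
($V_p = SD^2$, $V_g = h^2 V_p$), and 7 qualitative traits with 5/3/3/3/2/4/9
states. Where the generator had to go beyond what any published table
states, the choices are: normal trait distributions (no distributional claim
exists for the real traits; several are visibly skewed, so a log-normal
option would be a natural extension), an identity genotypic correlation
matrix by default (no correlation matrix is published), and geometric-decay
state frequencies for qualitative traits (only diversity indices, not
frequencies, are published). Consequently, passing tests demonstrate the
*estimators and samplers*, not realism of trait joint distributions: real
collections have correlated, skewed traits and spatial field trends the
generator does not emulate.

## Distances and core sampling

**Gower.** The default dissimilarity is Gower's coefficient on the trait
table (range-normalized absolute differences for quantitative traits, 0/1
mismatches for qualitative ones, pairwise deletion of missing values with
weight renormalization), computed via `cluster::daisy()`; entries live in
$[0,1]$. The pipeline, like phenotype-only core tools generally, uses the
quantitative traits; Euclidean-on-standardized is available as an option.
Constant traits are dropped with a warning.

**Objectives.** For a candidate core: E-NE is the mean distance from each
entry to its nearest other entry (diversity — larger is better), A-NE the
mean distance from each collection accession to its nearest entry
(representativeness — smaller is better; entries contribute zero), E-E the
mean pairwise entry distance. `optimize_core()` maximizes
$w_{EN}\,\widetilde{E\text{-}NE} - w_{AN}\,\widetilde{A\text{-}NE}$ where
each tilde quantity is rescaled by its range over an ensemble of 200 random
cores of the same size — the two objectives live on different scales and
some normalization is required for the mixed weighting; the random-core
range is cheap, stable and data-driven.

**Search.** Random-descent local search over the single-swap neighborhood,
20 restarts, stopping a restart after 50,000 consecutive non-improving
proposals (with a 20× total-proposal safety cap). The engine is compiled
(Rcpp) and evaluates a proposal read-only from cached nearest/second-nearest
entry tables, rescanning only accessions whose cached neighbours involve the
leaving entry; tables are rebuilt on the rare acceptances. Strict
improvement (tolerance $10^{-12}$) is required, forced entries are never
swapped out, and all randomness flows through R's RNG, so results are exactly
reproducible under a seed. On small instances ($n \le 12$, core size
$\le 4$) the search attains the exhaustively enumerated optimum in 100 of
100 random cases in the test suite.

**PowerCore-style sampler.** True PowerCore self-selects its core size; to
honour a fixed size the package uses greedy maximum class coverage
(quantitative traits discretized into Sturges-rule classes
($\lceil \log_2 n \rceil + 1$ bins on the collection range), qualitative
states as-is), adding the accession that covers the most uncovered classes —
ties resolved toward the accession covering the rarest class, then the
lowest id — and filling any remaining slots by maximin (E-NE-greedy)
additions. Achieved class coverage is reported rather than erroring when the
requested size cannot cover everything.

**PCSS.** Correlation-matrix PCA on the standardized quantitative traits;
components with eigenvalue above 1 are retained (the conventional Kaiser
rule, and the retained components in published trait PCAs are exactly those
above 1); an accession's contribution is the share-weighted sum of its
squared scores on the retained components, and the top contributions are
kept. Fully deterministic; ties break by ascending accession id, as they do
everywhere in the package.

**Geographic coverage.** `enforce_geography()` swaps one member in per
missing group, choosing the (incoming, outgoing) pair that best preserves
the core's weighted objective, never removing forced entries or the last
representative of another group, and erroring when groups outnumber slots.

## Core evaluation

Hu's indices take $MD\%$ and $VD\%$ as the percentage of traits with a
significant two-sample Welch $t$ and variance-ratio $F$ test respectively
($\alpha = 0.05$), and $CR\%$, $VR\%$ as the mean core/collection ratios of
ranges and CVs. The variance-ratio $F$ is used for $VD\%$ (the convention of
the index's source) while the per-trait battery reports the Brown–Forsythe
Levene test separately — the two answer subtly different robustness
questions and published tables report both. The conventional quality gate —
a good core has $MD\% < 20$ and $CR\% > 80$ — is how the pipeline filters
candidates before maximizing E-NE (ties: higher class coverage, then higher
VR%). That codified rule is this package's formalization of a narrative
choice; reports label the gate outcome explicitly.

Shannon indices per qualitative trait use natural logs: $H' = -\sum p_i \ln
p_i$ over observed states, $H_{max} = \ln k$ with $k$ the number of
descriptor states *declared by the descriptor* (an unobserved state lowers
evenness rather than silently shrinking $k$), $J' = H'/H_{max}$.

The two-sample battery: Welch $t$; Newman–Keuls, which with exactly two
groups degenerates to a studentized-range comparison on the pooled variance
(`ptukey` with 2 means); Brown–Forsythe Levene (median-centered);
Wilcoxon rank-sum with normal approximation, continuity and tie correction
(intended sample sizes are in the hundreds); two-sample Kolmogorov–Smirnov;
the Scholz–Stephens two-sample Anderson–Darling (continuous version, with
the published variance formula and critical-value interpolation for the
p-value — no installed package provides it, so it is implemented here and
checked against an independent reference evaluation and a null-uniformity
simulation); and a Kullback–Leibler *distance* computed as symmetrized
discrete KL over shared Sturges bins on the pooled sample with additive
smoothing $\varepsilon = 1/(2n_{pooled})$ — the concept is standard but no
estimator is canonical, so the choice is documented rather than defended.

The sign tests compare per-trait means (and variances) by exact two-sided
binomial on the counts of traits where the core exceeds the collection, ties
dropped. The Mantel test correlates the lower triangles of the two trait
correlation matrices and permutes row/column labels simultaneously,
$p = (1 + \#\{r^* \ge r\})/(B + 1)$, one-sided, $B = 999$ by default, seeded.

## PCA, clustering, correlations

PCA is always on the correlation matrix (traits have heterogeneous units),
so eigenvalues sum to the trait count and a component's variance share is
$100\lambda/p$. Loading signs are arbitrary in principle; the package fixes
each component so its largest-magnitude loading is positive. Hierarchical
clustering defaults to Ward linkage on Euclidean distances of standardized
traits (published work in this area names the distance but rarely the
linkage; Ward is the default because it gives the compact clusters such
studies describe), with average and complete available, Newick export via
`ape`, and flat cuts via `cutree`.

## Numerical and degenerate-input policy

Missing trait values are carried as `NA` and handled by pairwise deletion
(Gower), mean imputation with a warning (PCA), or omission (summary
statistics). Constant traits are dropped with warnings wherever a range or
variance is required, and an error is raised only when nothing usable
remains. Identical samples short-circuit the $t$/$F$ tests (statistic 0,
p 1) to avoid 0/0. All tie-breaks are by ascending accession id. Every
stochastic stage takes its seed from a named sub-stream of one master seed;
two runs with the same configuration are byte-identical.

## Problem sizes used by the test suite

The suite exercises the full pipeline at 150–1000 test accessions with cores
of 10%, heritability recovery on 50 replicates of an 800-accession, 50-block
design per heritability level, optimizer oracle equivalence on 100 random
instances with $n \le 12$, and the generator's convergence properties at up
to 2500 accessions. These sizes give stable Monte-Carlo behaviour for every
asserted tolerance while keeping a complete run of the suite in the
single-digit minutes on one CPU; the same estimators run unchanged at the
full genebank scale (the generator's 3903-accession default).

## Known limitations

- The ABD analysis is the classical fixed-effects computation; no REML/mixed
  model alternative, and no spatial trend correction within blocks.
- No genotype-by-environment modelling beyond the Bartlett homogeneity
  screen; multi-environment data are analysed per environment.
- Distances are phenotypic only; no marker-based distances.
- The optimizer is single-objective (weighted sum); it returns one core, not
  a Pareto front, and the PowerCore approximation fixes the core size
  a priori rather than self-selecting it.
- Qualitative traits are treated as exact accession attributes; observer
  error in descriptor scoring is not modelled.
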