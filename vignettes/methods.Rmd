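---
title: "Methods: ordination, variance partitioning, effect sizes and co-occurrence networks for soil ionome and enzyme profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilionet)
```

## The setting

The package models a common design in long-term fertilization research:
several fixed experimental sites, each carrying a plot fertilized with
mineral N–P–K only (CF) and a plot receiving mineral plus organic
fertilizer (COF), sampled with replicate plots per treatment. Two
multivariate responses are measured per soil sample: the concentrations
of exchangeable ions (the soil ionome; 19 elements by default) and the
potential activities of extracellular enzymes involved in C, N, P and S
cycling (7 by default, in nmol h⁻¹ g⁻¹ soil). The default design is 4
sites × 2 treatments × 3 replicates = 24 samples, so each treatment
pools n = 12 samples across sites.

Four questions are asked of such data, and the package implements one
stage per question: do profiles cluster by treatment and site
(ordination)? how much variance do pH, site and fertilization each
explain (variance partitioning)? which variables respond to organic
amendment, and how strongly (effect sizes)? and which ions and enzymes
co-vary strongly enough to suggest coupled dynamics (network
inference)?

## Ordination

Profiles are compared with the Bray–Curtis index,
$d_{ij} = \sum_v |x_{iv}-x_{jv}| / \sum_v (x_{iv}+x_{jv})$, which is
bounded in [0, 1], ignores joint absences and needs non-negative input;
two all-zero samples have no defined dissimilarity and are an error.

`nmds()` embeds the dissimilarity matrix in $k$ dimensions (default 2)
by minimizing Kruskal stress-1,
$$S_1=\sqrt{\frac{\sum_{i<j}(\hat d_{ij}-D_{ij})^2}{\sum_{i<j}D_{ij}^2}},$$
where $D$ are configuration distances and $\hat d$ is the least-squares
monotone (isotonic) regression of $D$ on the rank order of the input
dissimilarities. Numerical choices:

* **Optimizer.** Iterative majorization: each iteration fits $\hat d$
  by pool-adjacent-violators, rescales it to a fixed sum of squares
  (without which the configuration could collapse toward the origin),
  and applies the Guttman transform. The *reported* stress is always
  re-evaluated from the raw, unscaled monotone fit, which makes it
  invariant under rotation, reflection, translation and uniform scaling
  of the configuration.
* **Monotone non-increase by construction.** If an update ever fails to
  decrease the re-evaluated stress the step is rolled back and the
  restart stops, so the per-iteration stress trace is non-increasing —
  a testable invariant rather than a hope.
* **Ties.** Primary tie handling: tied dissimilarities may fit their
  configuration distances in any order (implemented by breaking rank
  ties on ascending $D$ before pooling). This is the common default in
  ecological ordination software.
* **Starts.** The first restart uses classical metric scaling of the
  dissimilarities; the remaining `n_restarts − 1` (default 19) are
  seeded random Gaussian configurations. The lowest-stress restart
  wins, so more restarts can never worsen the result — also tested.
  Returned coordinates are centered, rotated to principal axes, and
  sign-fixed for determinism.
* **Convergence.** A restart stops when the relative stress decrease
  falls below `tol` (default 1e-7) or when stress itself falls below
  `tol`: near-perfect ordinal embeddings drive stress to zero
  geometrically, and a purely relative criterion would never fire
  there. Hitting `max_iter` (default 500) returns `converged = FALSE`
  with a warning rather than an error.

Shepard diagnostics accompany every fit: the non-linear $R^2 = 1 -
\sum(D-\hat d)^2/\sum(D-\bar D)^2$ of the monotone fit, the linear
$R^2$ (squared Pearson correlation of $D$ with the original
dissimilarities), and a per-sample misfit (the sum of squared monotone
residuals over pairs involving the sample) used for bubble sizing in
`plot.nmds()` — larger bubbles mark worse-fitted samples.

## Variance partitioning

Profile tables are first Hellinger-transformed,
$y'_{iv}=\sqrt{y_{iv}/\sum_v y_{iv}}$, giving every sample unit sum of
squares and making the data appropriate for Euclidean-projection
methods. The response is then column-centered; no column
standardization is applied, as the row normalization already equalizes
sample totals.

Explained variance for a set of predictor blocks is the redundancy
statistic: the fraction of total centered variance captured by the
least-squares projection of the response onto the predictor space,
adjusted by the Ezekiel correction
$R^2_{adj} = 1-(1-R^2)\frac{n-1}{n-m-1}$. The adjustment is what makes
three-way partitioning meaningful: unique and shared fractions are
obtained by inclusion–exclusion over the seven non-empty block unions
(e.g. $a = R^2_{adj}(ABC)-R^2_{adj}(BC)$), the eight fractions sum to
one exactly, and *shared fractions can be negative* — raw $R^2$ cannot
produce the negative interaction contributions that adjusted
partitioning legitimately reports.

Encoding: site enters as indicator columns with the first level dropped
(3 columns for 4 sites), fertilization as one indicator, pH as a single
centered numeric column, treated as a factor in its own right alongside
the design factors. If two blocks overlap (up to complete duplication)
the union projection uses the column-space rank; within a single block,
dependent columns are an error naming the aliased columns.

The unique fractions a, b, c are individually testable by partial
redundancy analysis: the pseudo-F of the focal block's extra variance
over the covariate-only model, with a null distribution generated by
permuting reduced-model residuals, and
$p = (1+\#\{F^* \ge F\})/(1+n_{perm})$ (999 permutations by default;
the add-one form bounds p below by $1/(n_{perm}+1)$). Shared fractions
are not expressible as a single constrained model and are not tested.

## Effect sizes

For each variable the log response ratio compares the pooled COF mean
with the pooled CF mean: $R=\ln(\bar X_{COF}/\bar X_{CF})$, with
delta-method sampling variance
$v = SD^2_{COF}/(n_{COF}\bar X^2_{COF}) + SD^2_{CF}/(n_{CF}\bar
X^2_{CF})$, weight $w = 1/v$, confidence interval $R \pm \lambda\sqrt
v$ ($\lambda = 1.96$ for 95%), and a significance call exactly when the
interval excludes zero.

Two interpretation decisions are fixed here and matter for comparisons:

* **Pooling.** Means, SDs and n are computed over all samples of a
  treatment pooled across sites (n = 12 under the default design), not
  per site and then averaged. The pooled SD therefore contains
  between-site variance, which makes the interval conservative for the
  treatment contrast when site effects are large — a property, not a
  bug, of the pooled reading.
* **No heterogeneity variance.** The weighted summary is per variable;
  no between-study $\tau^2$ is added, because each variable is a single
  two-group contrast, not a pooled collection of independent studies.

Variables with a non-positive group mean have no defined log ratio and
are kept in the output table with an `excluded_reason` rather than
silently dropped. A zero sampling variance (both SDs zero) collapses
the interval to a point and leaves the weight undefined, flagged the
same way.

## Co-occurrence networks

Within each fertilization group (n = 12), all pairwise Pearson
correlations are computed, with two-sided p-values from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. An edge is admitted exactly
when $|r| > 0.58$ and $p < 0.05$. Two readings are deliberate:

* **Magnitude, not signed, cutoff.** A signed rule $r > 0.58$ could
  never produce negative edges, yet negative co-occurrence is half the
  biology here (e.g. a generalist enzyme negatively coupled to metal
  availability); the magnitude rule admits them and records the sign.
* **Cutoff redundancy at n = 12.** The two-sided 5% critical
  correlation at n = 12 is $r \approx 0.576$, so with the 0.58 cutoff
  the correlation rule dominates and every admitted edge is
  automatically significant — asserted as a property test. No multiple
  testing correction is applied to edge p-values by default (the
  admission rule is a raw per-pair threshold); tightening `p_cutoff`
  achieves an equivalent effect if desired.

Modes restrict eligible pairs: `enzyme-ion` admits only cross-category
edges, `ion-ion` only ion pairs. Nodes with no admitted edge are not
counted — a convention consistent with published co-occurrence graphs
whose node counts fall below the number of measured variables. Summary
statistics report the average degree in both conventions: edges/nodes
(the convention matching published "average degrees" in this
literature) and the standard 2·edges/nodes, labeled unambiguously.
Path length and diameter are computed over connected pairs and
components. Communities come from Louvain modularity optimization (the
algorithm behind Gephi's modularity tool) on the unweighted, unsigned
graph at resolution 1, seeded for determinism, with Newman modularity
$Q=\sum_c(e_c/m-(d_c/2m)^2)$; the generalist ranking sorts nodes by
degree with alphabetical tie-breaks and reports each node's fraction of
negative incident edges. Export formats are GraphML (round-trippable),
GEXF 1.2 and a TSV edge list.

## The synthetic generator

`generate_dataset()` simulates the measurement process the chain
assumes. For variable $v$ at site $s$ under treatment $t$ the cell mean
is $m_{svt} = \mu_v\, e_{sv}\, \exp(\delta_v[t=\mathrm{COF}])$:
lognormal baselines $\mu_v$ (around 10 units), multiplicative site
effects $e_{sv}=\exp(N(0,\sigma_{site}))$ with $\sigma_{site}=0.5$ by
default (site-dominated variance, as field data show), and planted log
response ratios $\delta_v$. Replicates are lognormal with coefficient
of variation `noise_cv` (default 0.2, a typical within-plot CV for soil
assays) around the *arithmetic* cell mean — the lognormal location is
shifted by $-\sigma^2/2$, so planted effects live on cell means and the
log response ratio recovers $\delta_v$ without the lognormal mean bias.
Correlation blocks give member variables a shared per-sample latent
factor on the log scale with configured loadings in [−1, 1]; the
induced within-cell correlation between members is the product of their
loadings, so mixed-sign loadings plant negative edges. pH is normal
around 6.5 for COF and depressed by 1.0 under CF (long-term mineral
fertilization acidifies soil), with per-site offsets (SD 0.3) and
replicate noise (SD 0.15), clamped to [0, 14].

Default planted effects follow the response directions this literature
reports: strong Al depression (−1.2) and P increase (+1.0) under
organic amendment, moderate increases for Cd, Mo, Zn, Cu and several
hydrolases, moderate decreases for Pb, La, Ni, Co, Fe, zero elsewhere.
Two default correlation blocks plant recoverable network structure: a
negatively loaded generalist enzyme tied to acid-mobilized metals, and
a positive block of organically mobilized ions.

Draws consume one seeded stream in a fixed documented order (baselines,
site effects, pH offsets, latent factors, noise), so identical
configurations are bit-identical and the ground truth
(`truth_report()`) is exact.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: measured soil values are not actually
lognormal with a common CV; real between-variable covariance is far
richer than a few latent blocks; site effects in nature correlate
across variables (real geochemistry) rather than being drawn
independently; and detection limits, censoring and measurement error
structure of ICP-MS and fluorometric assays are absent. Recovery
results on synthetic data bound what the chain can do under its own
assumptions, not its field performance.

## Calibration harnesses and problem sizes

Two test harnesses deliberately set `site_effect_sd = 0`:

* the type-I-error check of the confidence-interval rule (planted
  $\delta = 0$, 500 seeds): the delta-method variance assumes the
  pooled samples are the iid sampling unit, and between-site shifts —
  which appear identically in both treatment groups and so cancel from
  the ratio of pooled means while still inflating the pooled SD — would
  make the interval conservative by construction. Calibration of the
  rule itself is meaningful only under its own sampling assumption.
* the planted-block network recovery check (50 seeds, both treatment
  groups): independent per-variable site shifts are variable-specific
  noise that dilutes within-block correlation; they test robustness to
  confounding, not the admission rule, and the recovery claim is about
  the rule. Block loadings of 0.95 are used, within the generator's
  documented high-loading regime (at loading 0.9 the implied pairwise
  correlation is 0.81, for which the per-pair detection probability at
  n = 12 is materially below 1, so near-certain per-pair recovery
  requires the upper part of the regime).

Simulation sizes used by the test suite — 200 seeds for effect-size
recovery, 500 for interval calibration, 50 for oracle-equivalence loops
and network recovery, 400 replicates × 99 permutations for the size of
the partial-RDA permutation test — keep each property estimate's Monte
Carlo error comfortably inside the asserted band while the full suite
runs in about a minute.

## Known limitations

* Published stress values, variance fractions, response-ratio extremes
  and edge counts from any specific field study are functions of that
  study's raw measurements; the package reproduces the *procedures* and
  the recomputable summary conventions, not those numbers.
* The NMDS optimizer, like all of its family, finds local minima;
  restarts mitigate but do not guarantee the global optimum.
* Permutation tests are exchangeability-based; with only 24 samples the
  discreteness of the permutation distribution is visible at small
  $\alpha$.
* The network admission rule is a marginal-correlation filter; it does
  not distinguish direct from indirect association, and no claim of
  conditional independence (as in Gaussian graphical models) is made.
* Louvain partitions can be degenerate across seeds on small graphs;
  the seed is fixed for reproducibility, and modularity is always
  re-checkable against the reported partition.
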