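# soilionet

Statistical analysis chain for long-term soil fertilization trials that
profile **exchangeable ions** (the soil ionome) and **extracellular
enzyme activities** across sites and fertilization treatments. The
package is aimed at soil ecologists comparing mineral-only fertilization
(CF) with mineral-plus-organic amendment (COF) in multi-site factorial
designs, and bundles the four analyses such studies chain together:

1. **Ordination** — Bray–Curtis dissimilarities
   *d<sub>ij</sub> = Σ|x<sub>iv</sub> − x<sub>jv</sub>| / Σ(x<sub>iv</sub> + x<sub>jv</sub>)*
   embedded by nonmetric multidimensional scaling (iterative majorization
   with isotonic regression), reporting Kruskal stress-1
   *S = √(Σ(d̂ − D)² / ΣD²)* and Shepard-diagram R² diagnostics.
2. **Variance partitioning** — the variance of the Hellinger-transformed
   profile matrix is split among pH, site and fertilization (and all
   their interactions) by redundancy analysis with the Ezekiel adjusted
   R², *R²<sub>adj</sub> = 1 − (1 − R²)(n − 1)/(n − m − 1)*, so shared
   fractions may legitimately be negative; unique fractions are tested
   by permuting reduced-model residuals.
3. **Effect sizes** — per-variable natural-log response ratios
   *R = ln(X̄<sub>COF</sub>/X̄<sub>CF</sub>)* with sampling variance
   *v = SD²<sub>COF</sub>/(n X̄²<sub>COF</sub>) + SD²<sub>CF</sub>/(n X̄²<sub>CF</sub>)*,
   weights *w = 1/v*, and 95% confidence intervals *R ± 1.96√v*.
4. **Co-occurrence networks** — all pairwise Pearson correlations within
   a treatment group; edges admitted when |r| > 0.58 **and** p < 0.05;
   graph summaries (sign counts, both average-degree conventions, path
   length, diameter, cumulative degree distribution), Louvain
   communities with Newman modularity, generalist ranking, and
   GraphML/GEXF export for Gephi.

A seeded synthetic-data generator emulates the underlying study design —
2 treatments × 4 sites × 3 replicates = 24 samples, 19 ions + 7
enzymes — with planted log response ratios, multiplicative site effects,
a pH covariate depressed under CF, lognormal noise, and latent-factor
correlation blocks, so the whole chain is testable end to end and
parameter recovery can be measured against known truth.

## Worked example

```r
library(soilionet)

bundle <- run_pipeline(pipeline_config(generate = TRUE, seed = 7,
                                       n_restarts = 5, n_permutations = 49))
print(bundle)
```

```
Soil ionome/enzyme analysis report

Design: 4 site(s) x 2 treatment(s), 3 replicates/cell, 24 samples (balanced)

NMDS stress: ions 0.1585, enzymes 0.1318
VPA explained: ions 84.22%, enzymes 83.47%
Response ratios: 14 of 26 variables significant
CF_enzyme_ion    25 nodes,  34 edges (18+/16-), modularity 0.449
CF_ion_ion       19 nodes,  39 edges (23+/16-), modularity 0.397
COF_enzyme_ion   23 nodes,  35 edges (20+/15-), modularity 0.384
COF_ion_ion      18 nodes,  31 edges (19+/12-), modularity 0.504
```

Reading the output: the NMDS stress values (0–1 scale; < 0.2 is a usable
two-dimensional embedding) describe how faithfully the Bray–Curtis
rank order is preserved; "explained" is the adjusted-R² fraction of
profile variance attributable to pH, site, fertilization and their
interactions; each network line counts connected nodes, admitted edges
by correlation sign, and the modularity of the Louvain partition.
Individual stages are available directly — e.g.

```r
d  <- generate_dataset(synth_config(seed = 1))
rr <- rr_table(d$ions, d$enzymes, d$metadata)
rr[rr$variable_id %in% c("Al", "P"), c("variable_id", "R", "ci_low", "ci_high")]
#>   variable_id       R  ci_low ci_high
#>            Al -1.2035 -1.4587 -0.9482
#>             P  0.8996  0.6088  1.1905
```

recovering the generator's planted effects (−1.2 for Al, +1.0 for P)
within their own confidence intervals. A thin command-line wrapper
lives at `inst/scripts/run_pipeline.R`.

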