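# dietmb

Downstream analysis of dietary DNA metabarcoding in R: from a denoised
ZOTU-by-sample read-count table to a cleaned presence–absence diet
matrix, frequency-of-occurrence and origin-status summaries, Hill
diversity with coverage-based rarefaction/extrapolation, and multivariate
diet-composition inference.

## Who this is for

Molecular ecologists running diet studies from fecal samples. After
denoising (e.g. Unoise3) and taxonomy assignment you hold a table of read
counts for zero-radius OTUs (ZOTUs) across diet samples, PCR/extraction
blanks and positive controls. The scientific questions — what is eaten,
how often, how completely was the diet sampled, does composition shift
with season or sex — all sit downstream of that table, and that
downstream is what this package implements. It was built around a fecal
metabarcoding study of an omnivorous island skink (73 samples, 77 dietary
taxa, 389 presence detections) and ships a synthetic-data module
reproducing that study's statistical structure, so every stage runs and
is tested without any sequence data.

## What it computes

**Cleaning cascade.** Three filters with auditable reports, in
configurable order: a per-sample threshold (cells < 0.3% of their
sample's reads are zeroed — lab contaminants and sequencing errors), a
blank-maximum filter (diet reads below a ZOTU's maximum count in any
blank/negative are zeroed), and a per-ZOTU threshold (cells < 0.74% of
their ZOTU's reads are zeroed — tag-jump mitigation). Then ZOTUs are
aggregated to taxa, counts become presence/absence over diet samples, and
empty samples/taxa are dropped.

**Summaries.** Frequency of occurrence `FO = 100 * detections /
n_samples`, detections by kingdom and origin status (cryptogenic /
endemic / introduced / native), group means with standard errors,
tie-corrected Kruskal–Wallis contrasts, Shapiro–Wilk normality check.

**Diversity.** Hill diversity as generalized mean rarity
`D = (Σ pᵢ rᵢ^ι)^(1/ι)`, `rᵢ = 1/pᵢ`, with `ι = 1, 0, −1` giving
richness, exponential Shannon entropy, and inverse Simpson. Sample
coverage `Ĉ(n) = 1 − (f₁/n)·[(n−1)f₁/((n−1)f₁+2f₂)]` from singleton and
doubleton counts, with exact hypergeometric interpolation below `n` and
Chao1-anchored extrapolation above, plus seeded multinomial bootstrap
confidence bands.

**Composition.** Jaccard distances and NMDS (via vegan), and a
multivariate binomial GLM: per-taxon ridge-stabilized logistic
regressions whose per-term Wald statistics are summed across taxa and
tested by Monte Carlo resampling from the reduced model; per-taxon tests
with free step-down adjustment; AIC model selection across candidate
formulas.

## Worked example

The study's published per-taxon table can be rebuilt as a fixture and
pushed through the summary and diversity stages:

```r
library(dietmb)

fx <- table1_fixture()
m  <- table1_presence_matrix(fx)      # 77 taxa x 73 samples
s  <- detection_summaries(m, fx$taxa)
head(s, 3)
#>                   taxon detections fo_pct  kingdom      status
#> 12     Heterospilus sp.         29  39.73 Animalia cryptogenic
#> 16 Pheidole megacephala         29  39.73 Animalia  introduced
#> 2    Porcellionidae sp.         25  34.25 Animalia cryptogenic

group_mean_detections(s, by = "kingdom")
#>      group n_taxa     mean       se
#> 1 Animalia     39 4.256410 1.203749
#> 2  Plantae     38 5.868421 1.028174

kruskal_wallis(fx$counts, fx$taxa$kingdom)
#> $H
#> [1] 6.33122
#>
#> $df
#> [1] 1
#>
#> $p
#> [1] 0.01186307

fr <- abundance_freqs(fx$counts)
fr
#> <abundance_freqs> n = 389 detections, S_obs = 77 taxa, f1 = 34, f2 = 12
estimate_coverage(fr, fr$n)       # coverage at the observed 389 detections
#> [1] 0.9127551
estimate_coverage(fr, 2 * fr$n)   # extrapolated to twice that
#> [1] 0.9569802
```

Reading those numbers: plants are detected more often per taxon than
animals (5.87 vs 4.26 mean detections; the tie-corrected Kruskal–Wallis
`H = 6.33` on 1 df, `p = .012`, says the difference is unlikely under
exchangeability), and with 34 of 77 taxa seen only once the estimated
sample coverage is 91.3% at the observed effort, rising to 95.7% when
extrapolated to twice the detections — i.e. roughly 4–9% of individual
dietary "items" in the underlying community belong to taxa never
detected.

A full synthetic run, from raw reads with injected contamination and
tag-jumping to a cleaned matrix and a season test:

```r
sim <- simulate_presence(diet_sim_params(seed = 7))
zt  <- simulate_zotu_table(sim$matrix, read_sim_params(seed = 7),
                           sim$metadata)
res <- run_filter_cascade(zt$table, zt$taxa, filter_config())
fit <- fit_binomial_mglm(res$matrix, zt$table$samples, ~ season * sex)
multivariate_test(fit, "season", n_resamples = 999, seed = 1)
```

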