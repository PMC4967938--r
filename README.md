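# pathconcord

Which animal model best mimics a human disease at the pathway level?
`pathconcord` answers this for two-class transcriptomic studies by comparing
*pathway regulation profiles* rather than individual differentially
expressed genes. Gene-to-gene comparisons of the same human/mouse
inflammation datasets have famously supported opposite conclusions depending
on filtering choices; working at the pathway level with a no-cutoff
enrichment statistic removes the arbitrary thresholds that drive that
disagreement. The package is aimed at translational researchers who hold a
panel of case/control expression datasets (e.g. human diseases and candidate
mouse models) and a curated pathway collection, and want a standardized,
reproducible ranking of which models track which diseases.

## The method

For each dataset, every gene is scored by the signal-to-noise metric

    s_g = (mu_case - mu_ctrl) / (sigma_case + sigma_ctrl)

(sample SDs, each floored at `max(0.2 |mu|, 0.2)`), and genes are ranked by
descending `s_g`. For a gene set *S* with `N_H` detectable members in a list
of `N` genes, the weighted Kolmogorov–Smirnov running sum adds
`|s_j|^p / N_R` at members (`N_R = sum over S of |s_j|^p`, weight `p = 1`)
and subtracts `1/(N - N_H)` elsewhere; the enrichment score ES is the
signed extreme of the walk. A gene-set permutation null (random same-size
sets, 1,000 draws by default) yields the normalized score
`NES = ES / mean |null ES of the same sign|`, a nominal p, and a
permutation FDR q. Sets outside the 15–500 detectable-size window are not
tested.

Each pathway is then called **up** (q ≤ 0.25, NES > 0), **down** (q ≤ 0.25,
NES < 0) or **null** (not changed, or too few genes detectable). For two
models, concordance is measured by predictive values

    PPV = |Up1 ∩ Up2| / |Up2|,   NPV = |Down1 ∩ Down2| / |Down2|,

compared against the chance expectation (model 1's base rate of calls:
if 10% of pathways are up in model 1, an independent model 2 would reach
PPV = 10%), and tested with a Pearson chi-squared test on the 3×3
up/down/null contingency table (df = 4). Across a cohort, species-group
differences are assessed with Kruskal–Wallis plus Dunn's Bonferroni-corrected
post-hoc tests, and significant-pair counts with a two-sample proportions
test. A synthetic-data module generates datasets with planted,
overlap-controlled pathway regulation so the entire chain is testable
end to end.

## Worked example

```r
library(pathconcord)

# one synthetic two-class study: 1,000 genes, 20 pathways of 30 genes,
# 2 planted up- and 2 down-regulated pathways, 10 vs 10 samples
sim <- simulate_dataset(simulation_design(seed = 1))
fit <- gsea(sim$dataset, sim$sets, gsea_params(n_perm = 200, seed = 1))
fit
#> GSEA fit: 20 gene sets (20 tested), 1000 ranked genes, 200 permutations
#>   sets at FDR <= 0.25: 2 up, 2 down

head(summary(fit)[, 1:6], 3)
#>      set size        ES       NES   p_nominal q_fdr
#> 1 SET_02   30 0.9381443 2.7812761 0.010101010     0
#> 2 SET_01   30 0.9536082 2.7380410 0.009433962     0
#> 3 SET_12   30 0.3963178 1.1373148 0.259259259     1

pathway_states(fit, sim$sets, id = "model1")
#> Pathway profile 'model1' (FDR <= 0.25): 2 up, 2 down, 16 null of 20
```

The two planted up-regulated pathways (`SET_01`, `SET_02`) top the table
with NES ≈ 2.7–2.8 at q = 0, and the three-state profile recovers exactly
the planted 2 up / 2 down truth. Comparing two models whose planted
regulation overlaps by half:

```r
pair <- simulate_model_pair(simulation_design(seed = 7), rho = 0.5)
fits <- lapply(list(A = pair$dataset_A, B = pair$dataset_B), gsea,
               sets = pair$sets, params = gsea_params(n_perm = 200, seed = 2))
profs <- Map(pathway_states, fits, id = names(fits))
compare_pair(profs$A, profs$B)
#> Pair A vs B: mean PV 0.50, delta over chance +40.0 points, chi2 p = 0.0987
```

The estimated mean predictive value (0.50) matches the designed overlap
ρ = 0.5; it sits 40 percentage points above the 10% chance level given each
model's 2-of-20 base rate of up and of down calls. For many datasets, feed a
named list into `run_pipeline()` (or the wrapper script in
`inst/scripts/run_pipeline.R`) to get the pairwise concordance matrix,
species-group statistics, and the shared-pathway NES report for a chosen
subgroup.

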