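---
title: "Pathway-level concordance of disease models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level concordance of disease models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconcord)
```

# The problem and the model

Whether a mouse model "mimics" a human disease depends strongly on how the
transcriptomes are compared. Single-gene comparisons require a
differential-expression cutoff, and the choice of cutoff alone can flip the
conclusion. `pathconcord` instead compares *pathway regulation profiles*:
each dataset is reduced to a three-state call (up / down / null) per pathway
using a no-cutoff enrichment statistic over all detected genes, and two
models are compared by how well one profile predicts the other.

The pipeline has four statistical layers, each exposed as its own function
so every step can be validated in isolation:

1. **Ranking** (`signal_to_noise`). Genes are scored by
   $s_g = (\mu_{case} - \mu_{ctrl}) / (\sigma_{case} + \sigma_{ctrl})$ with
   sample ($n-1$) standard deviations. Each class SD is floored at
   $\max(0.2\,|\mu|, 0.2)$ — the conventional signal-to-noise variance
   adjustment. The floor guarantees a strictly positive denominator (a
   zero-variance gene cannot produce an infinite score) and damps the
   scores of near-constant genes whose tiny SDs would otherwise dominate
   the ranking. Ties are broken by ascending gene symbol so the ranking is
   identical across platforms and locales.

2. **Enrichment** (`enrichment_score`, `permutation_null`,
   `normalize_and_test`, `gsea`). The weighted Kolmogorov–Smirnov running
   sum walks the ranked list; member positions add $|s_j|^p / N_R$ (with
   $N_R = \sum_{hits} |s_j|^p$ and weight $p = 1$), other positions
   subtract $1/(N - N_H)$. The enrichment score is the extreme of the walk
   with the largest absolute value, sign kept. The null model is **gene-set
   permutation**: random same-size gene sets redrawn from the ranked
   universe. This is stated explicitly because phenotype permutation — the
   other common choice — gives a different null: gene-set permutation asks
   whether *this* set is more coherently extreme than a random set of equal
   size on the same ranking, and remains well-defined for small sample
   sizes where phenotype permutation starves.

3. **Calling** (`pathway_states`). A pathway is up if its FDR
   $q \le 0.25$ and NES $> 0$, down if $q \le 0.25$ and NES $< 0$, and null
   otherwise — where "otherwise" deliberately absorbs pathways with too few
   (or too many) detectable genes and untested pathways, so every pathway
   of the reference collection always has exactly one state. The 0.25
   threshold is the conventional exploratory GSEA level; the boundary is
   inclusive.

4. **Concordance** (`predictive_values`, `chance_expectation`,
   `chi_squared_test`, `compare_models`). PPV is the fraction of model 2's
   up-calls that model 1 shares; NPV the same for down-calls. The chance
   expectation is model 1's base rate of calls: under independence of the
   two profiles, the expected PPV equals $|Up_1| / N_{pathways}$. The gain
   over chance is reported in **percentage points** (observed minus
   expected predictive value) — an interpretation choice, made because a
   relative ("fold") change would explode for sparse profiles. Significance
   per pair comes from a Pearson chi-squared test on the 3×3 up/down/null
   contingency table (df = 4), uncorrected across pairs.

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `n_perm` | 1000 | permutations | standard gene-set-permutation depth; 200 is used in the package's own validation runs for speed, which leaves the p-value granularity at 1/201 |
| `weight` | 1 | exponent on \|score\| | the "weighted" statistic; 0 gives the classic KS walk |
| `min_size`, `max_size` | 15, 500 | detectable genes | below 15 the permutation null is too coarse; above 500 sets are too diffuse to interpret |
| `fdr_threshold` | 0.25 | q | exploratory GSEA convention; inclusive boundary |
| `alpha` | 0.05 | p | pairwise chi-squared significance, uncorrected |
| `delta` (generator) | 2 | per-gene noise SDs | a strong but not degenerate pathway shift; drives near-perfect recovery at 10 vs 10 samples |

# Numerical choices

* **Nominal p guard.** $p = (k + 1)/(n + 1)$ over same-signed null draws,
  so a finite permutation run never reports $p = 0$.
* **NES by sign.** ES is normalized by the mean magnitude of *same-signed*
  null scores. If no same-signed null draw exists the set is flagged
  `not_testable` rather than given an arbitrary NES.
* **FDR pooling.** Permutation scores are normalized per set (by that
  set's own same-signed null means) and pooled into one null-NES
  distribution per direction across all tested sets; the q ratio uses only
  same-signed values in numerator and denominator and is clipped to
  [0, 1]. Per-set-size stratification is *not* done — a documented
  simplification that is exact here because the collection sizes are
  homogeneous after the size filter, and conservative otherwise.
  Size-excluded sets are excluded from both testing and the observed-NES
  denominator.
* **ES ties.** When the positive and negative extremes of the walk have
  equal magnitude (possible with integer scores), the positive extreme is
  kept; the comparison carries a 1e-12 tolerance so floating-point noise
  cannot flip the choice between equivalent implementations.
* **All-zero hit scores.** If every member sits at score 0 (so
  $N_R = 0$), hits are weighted uniformly $1/N_H$ — the $p = 0$ limit of
  the statistic — instead of dividing by zero.
* **Zero-margin contingency rows/columns** carry no information and are
  dropped with the df adjusted (e.g. a 3×2 effective table has df = 2),
  rather than patched with pseudocounts; a fully degenerate table reports
  $p = 1$ with a warning.
* **Undefined predictive values** (zero up- or down-calls in the
  predictor) are excluded from averages rather than set to 0, so sparse
  profiles are not penalized; both prediction directions are computed and
  the pair summary averages the defined values of all four.
* **Kruskal–Wallis on constant data.** The tie-corrected statistic is
  0/0; the package returns $H = 0$, $p = 1$ (no evidence of group
  differences) instead of NaN.
* **Determinism.** Every stochastic step takes a seed; the pipeline
  expands its global seed into per-dataset substreams derived from the
  dataset *id* (not its position), so adding or reordering datasets leaves
  the other results bit-identical, and result tables are canonicalized by
  id so output is independent of manifest order.

# The synthetic-data generator

`simulation_design()` describes a two-class microarray-like study:
per-gene baselines $\mu_g \sim N(8, 2)$ on a log2-like intensity scale,
i.i.d. Gaussian noise with per-gene SD $\sigma_g$ (default 1), and
pathway-coherent shifts: members of a planted up-regulated set gain
$+\delta\sigma_g$ in case samples (down-regulated: $-\delta\sigma_g$).
Expressing $\delta$ in SD units makes recovery thresholds scale-free.
The default condition — 1,000 genes, 20 disjoint sets of 30, 10 vs 10
samples, $\delta = 2$, 2 up- and 2 down-regulated sets per model — plants a
10% base rate of calls per direction, deliberately matching the worked
chance-expectation example (10% up ⇒ expected PPV 10%) so that designed
overlap and chance level are cleanly separated quantities.

`simulate_model_pair()` gives model B a controlled fraction $\rho$ of
model A's regulated sets, same direction, the rest drawn from unregulated
sets. The shared count is $\mathrm{round}(\rho\,(n_{up}+n_{down}))$,
allocated up-first, so the *designed-profile* mean predictive value equals
$\rho$ exactly at every grid point of $\rho \in \{0, 0.25, 0.5, 0.75, 1\}$
— the estimated concordance can therefore be read directly against the
designed truth.

What the generator does **not** emulate: probe-level redundancy (the
collapse module is tested on its own explicit fixtures), inter-gene
correlation within pathways beyond the shared mean shift, batch effects,
RNA-seq count noise, and unbalanced designs beyond what the sample-size
fields allow. Passing the recovery tests therefore shows the chain is
correct and calibrated under clean coherent-shift conditions; it does not
show robustness to correlated noise or platform artifacts in real data.

# Validation problem sizes

The package validates itself at desk scale: exhaustive brute-force
enrichment walks on all small lists (N ≤ 8, subsets ≤ 3); 200 random
contingency tables against the textbook chi-squared formula; null
calibration from 50 replicates of the δ = 0 condition at 200 permutations
(1,000 set-level p-values) plus 2,000 profile shuffles for the chi-squared
rejection rate; a 10⁴-shuffle Monte-Carlo check of the chance expectation;
and a 5 × 10 (ρ grid × seeds) recovery sweep. The acceptance script runs
the same quantities at slightly reduced replication (30 null replicates,
5 seeds per ρ) plus a full 8 + 9-dataset synthetic cohort.

# Known limitations

* Pairwise values sharing a dataset are not independent; the
  Kruskal–Wallis/Dunn species tests ignore this (as is conventional for
  this design), so their p-values are approximate.
* The permutation FDR is the GSEA-style ratio estimate, not a
  Benjamini–Hochberg adjustment; with few tested sets it is coarse, and
  different tool versions legitimately disagree by small amounts.
* Whether expression values should be log-transformed before ranking is
  deliberately left to the caller: values are used exactly as given, and
  `expression_dataset(scale_note = )` only records the assumed scale for
  provenance.
* The mouse→human fallback (uppercasing symbols) is a heuristic; an
  explicit ortholog table should be supplied whenever available, and
  one-to-many ortholog expansion is out of scope (collisions re-collapse
  by the max-mean rule).
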