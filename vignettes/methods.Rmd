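---
title: "Methods: from OTU counts to co-occurrence communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OTU counts to co-occurrence communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

otunet implements the downstream statistics of a low-biomass 16S amplicon
study — bronchial brushings from COPD patients stratified by CT-defined
subtype (severe = visible structural change, mild = none) and healthy
controls — as a reusable, testable pipeline. This vignette explains the
model behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions the implementation commits to.

## The analysis chain

```{r, eval = FALSE}
library(otunet)
d <- simulate_dataset(sim_config(seed = 1))
bundle <- run_pipeline(d$counts, d$metadata, pipeline_config(seed = 1),
                       outdir = "run1")
```

Stages run in a fixed order, enforced by transform-state flags on the genus
table (`counts` → `relative`/`hellinger`), so a mis-ordered call errors
rather than silently computing on the wrong scale:

1. **Contamination screen.** In low-biomass libraries, reagent bacteria
   make up a larger share of the reads the less template DNA a sample
   yields. For every OTU and each of the three library amplification runs
   we test Spearman's rho between the OTU's relative abundance and the
   run's per-sample amplicon concentration; an OTU with `rho < 0` and
   `P < 0.05` in any run is removed wholesale. P-values use the exact
   permutation null for n ≤ 10 samples and the t approximation above that;
   ties get average ranks throughout the package. A constant concentration
   vector makes rho undefined, so that run is skipped with a warning.
2. **Depth control.** Samples under 700 reads are discarded and survivors
   are rarefied (subsampled without replacement, i.e. multivariate
   hypergeometric) to a common 722 reads. A 710-read sample passes the
   nominal discard rule but cannot yield 722 reads, so the effective
   discard threshold is `max(min_reads, rarefy_depth)`; the run log records
   when this raise occurs. OTU rows that end up all-zero are kept so ids
   stay stable.
3. **Genus aggregation and rare-genus filter.** Counts of OTUs classified
   to the same genus are summed; OTUs without a genus-level classification
   are dropped (their mass is reported). Genera under 0.01% of the grand
   total read count are removed. The alternative reading of that
   threshold — mean per-sample relative abundance — is available via
   `filter_rare_genera(method = "mean_relative")`; fraction-of-total is the
   default because it is the stricter, scale-free interpretation for
   rarefied tables.
4. **Transforms.** `to_relative()` closes each column to 1;
   `hellinger_transform()` takes square roots of relative abundances so
   each column has unit Euclidean norm, making distance geometry sensible
   for compositional counts.
5. **Diversity and ordination.** Pielou's evenness (Shannon entropy over
   `ln S`, defined as 0 for a single-taxon sample), Chao1 (with the
   bias-corrected branch when no doubletons exist), rarefaction curves by
   repeated subsampling, Bray-Curtis dissimilarity
   `d(x,y) = Σ|x−y| / Σ(x+y)` on the Hellinger table, classical PCoA, and
   PERMANOVA re-derived from the pseudo-F definition
   `F = (SS_b/(a−1)) / (SS_w/(N−a))` with label-permutation P-values.
6. **Group screens.** Any per-sample scalar (a genus's Hellinger
   abundance, a diversity index, a principal coordinate) is first
   season-corrected — the per-season median is subtracted, removing the
   processing-batch shift between winter- and summer-handled samples —
   then compared between groups with a two-sided Wilcoxon-Mann-Whitney
   test. Benjamini-Hochberg adjustment is applied within one screening
   family per run: all genera of a grouping form one family, and the
   tested PCoA axes form another. The distance matrix itself is never
   season-corrected; PERMANOVA runs on the uncorrected distances, since the
   correction is defined for per-sample scalars.
7. **Co-occurrence network.** On relative abundances of genera present in
   ≥ 5 samples, pairwise Spearman correlations are tested against a
   compositionality-aware permutation null in the ReBoot/CCREPE spirit:
   each genus is permuted independently across samples, every sample is
   re-closed to sum 1, and the whole correlation matrix is recomputed;
   the two-sided P is `(#{|rho_null| ≥ |rho_obs|} + 1)/(n_perm + 1)` over
   1000 rounds. An edge requires `rho ≥ 0.5` *and* `P < 0.05`. Edges are
   then re-derived on season-corrected abundances and kept only if they
   still satisfy both criteria ("robust"). Communities are the connected
   components of the robust graph; components of ≤ 2 genera are kept in
   the data but flagged as unreported. Each node carries an association
   score — mean relative abundance in severe samples minus mean in
   mild + control — whose sign drives the conventional red/blue coloring.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 700 | discard threshold on library size (reads) |
| `rarefy_depth` | 722 | common subsampling depth (reads) |
| `rare_genus_fraction` | 1e-4 | genus filter on fraction of all reads |
| `contamination_alpha` | 0.05 | per-run significance of the screen |
| `min_prevalence` | 5 | samples a genus must be detected in |
| `rho_threshold` | 0.5 | Spearman an edge must reach |
| `alpha` | 0.05 | permutation-P threshold for an edge |
| `n_perm` | 1000 | permutation rounds |
| `min_community_size_report` | 3 | smallest displayed community |

Two policy switches exist because the verbal rules admit two readings,
both shipped: `network_config(mode = "absolute")` admits strong negative
correlations as edges (default is positive-only, since the communities of
interest are positively co-varying), and `robustness = "p_only"` re-checks
only the P criterion after seasonal correction (default re-checks both,
because the edge definition is conjunctive).

## Numerical conventions

* Average ranks for all ties; a constant vector has undefined rho and can
  never form an edge or a contamination flag.
* Permutation P-values use the add-one estimator, so P is never zero.
* Wilcoxon tests are exact (full enumeration) when the pooled sample size
  is ≤ 20 and tie-free, otherwise the tie-corrected normal approximation
  with continuity correction; an all-tied comparison is defined as P = 1
  (the normal approximation would otherwise be 0/0).
* PCoA retains negative eigenvalues in the report, excludes them from the
  coordinates and the proportion explained, and fixes each axis's sign so
  its largest-magnitude loading is positive.
* Exhaustive PERMANOVA (`n_perm = "exhaustive"`) enumerates all distinct
  label assignments — used for validation at small n.
* All randomness flows from one seed; the pipeline derives fixed per-stage
  offsets (+101 rarefaction, +202 PERMANOVA, +303 network), so a stage
  rerun is stable regardless of execution order, and two runs of the same
  config are byte-identical.
* The season-corrected pass of the robustness filter permutes the
  corrected values *without* per-sample re-closure: after median
  subtraction values may be negative and no longer form a composition, so
  renormalization is undefined there. The uncorrected pass keeps the full
  permute-and-re-close scheme.

## What the generator emulates — and what it does not

`simulate_dataset()` draws genus log-abundances as

```
eta[g, s] = baseline[g] + z[block(g), s] + effect[block(g)]·severe(s)
            + shift·winter(s)·seasonAffected(g) + noise[g, s]
```

closes each sample to a composition by softmax, and samples reads
multinomially at a depth uniform on 722–4789 reads, so column sums equal
the drawn depths exactly — the table looks like a closed, variable-depth
amplicon library. Contaminant OTUs join the composition with expected
relative abundance proportional to `concentration^(-strength)`, the
concentration being log-normal per sample and recorded for all three
library runs (the run-to-sample mapping of the original design is not
modeled, so one value fills all three columns).

Defaults describe a 25-sample cohort (12 severe, 4 mild, 9 controls),
40 genera with four planted blocks of 6/6/5/5 co-varying genera, 10
contaminant OTUs, and 6 season-affected genera. Three structural choices
deserve explanation, all fixed during generator calibration and then left
alone:

* **Equal marginal dispersion.** Block members get their variance from the
  shared factor (sd 1.8) plus small residual noise (sd 0.5); background
  genera get independent overdispersion of matching total sd
  (`sqrt(1.8² + 0.5²)`). If background genera were low-noise instead, the
  compositional denominator — dominated by whichever block happens to
  surge — would correlate *all* of them above the 0.5 edge threshold, a
  genuine closure artifact that would swamp the planted structure. Giving
  every genus the same marginal variance makes block membership a statement
  about correlation structure, which is what the network estimates.
* **Orthogonalized block factors.** The four latent factors are Gaussian
  scores orthogonalized against the intercept and each other. With only 25
  samples, raw independent factors align by chance often enough to merge
  two planted blocks — the dataset would then contradict its own ground
  truth. Orthogonalization makes "distinct communities" actually hold in
  every generated dataset.
* **Season-affected genera are planted, not background.** They carry the
  small residual noise plus the winter shift (+2 on the log scale), so
  their co-variation is attributable to season alone. They are drawn from
  outside the blocks, keeping the two planted structures disjoint.

The generator does **not** emulate: sequencing error, chimeras, taxonomy
misclassification, phylogenetic structure, overdispersed (negative
binomial) counts beyond the log-normal mixing, run-specific concentration
differences, or genuine ecological interactions beyond monotone
co-variation. Passing tests therefore demonstrate that the pipeline
recovers the statistical structures it assumes — not that those structures
exhaust real lung-microbiome data.

## Validation experiments and problem sizes

The test suite validates each statistic against an independent oracle
(closed forms, exhaustive enumeration, hypergeometric moments,
`vegan::vegdist`/`adonis2` cross-checks) and then checks pipeline-level
properties at the cohort scale the package targets: block recovery over 10
generator seeds at the 1000-permutation defaults (adjusted Rand index vs
planted blocks, count of reported communities), contamination-screen
sensitivity and false-flag rate over 20 seeds at 10 planted contaminants
among 200 OTUs, seasonal-edge removal and block-edge retention over 10
seeds, permutation-edge calibration over 200 independent-genus tables at
200 permutations, and PERMANOVA size over 500 null datasets at 199
permutations. These sizes give stable Monte-Carlo estimates while keeping
a full run in a few minutes on one core.

Two experiment-specific configurations are deliberate: edge-*removal* is
measured in a blocks-absent, low-overdispersion configuration because
"purely season-driven" presumes within-season independence — with strong
blocks present, closure induces genuine within-season dependence that a
location correction cannot and should not remove; and the PC1
group-contrast experiment uses a group-dominant composition
(`block_group_effect = ±2.5`, factor sd 1.0), since at the
recovery defaults the block factors intentionally dominate the ordination
and PC1 aligns with a factor rather than the group axis.

## Known limitations

* The contamination screen inherits the limits of correlation screening:
  genuinely rare taxa that co-vary negatively with concentration by chance
  are occasionally flagged (the false-flag rate is ~2% under the default
  conditions), and contaminants whose abundance is concentration-independent
  escape it.
* Median-based season correction removes location shifts only. Seasonal
  presence/absence patterns (a taxon entirely absent in one season's
  libraries) survive rank correlation after correction and are not removable
  by this design.
* Connected components are a deliberately simple community definition: one
  spurious edge can merge two communities. The rho ≥ 0.5 gate keeps the
  spurious-edge rate low at n = 25, but larger genus panels would need a
  modularity-based method, which is out of scope here.
* P-values from the 1000-round permutation null have a resolution floor of
  ~1e-3; tabled zeros are impossible by construction (add-one estimator).
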