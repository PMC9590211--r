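---
title: "rhizovir: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rhizovir: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizovir)
```

# What the package computes

`rhizovir` analyses soil viral communities from read-mapping summaries of
three library types — a size-fractionated DNA virome, a total metagenome
and a metatranscriptome — collected over a factorial field design
(compartment × crop rotation × growth stage × replicate plot). The
pipeline stages, in fixed order:

1. **detect** — a vOTU is *present* in a sample when ≥ 75% of its contig
   length is covered ≥ 1× (`call_presence`, inclusive threshold);
   presence per DNA library is OR-merged.
2. **quantify** — relative abundance as CPM:
   `count / (genome kb) / (library depth in millions)`. The per-sample
   abundance is the median of the CPM values available from the two DNA
   libraries, then masked by merged presence.
3. **activity** — gene-level metatranscriptome counts are group-filtered
   (a gene is zeroed in every replicate of a treatment group whose summed
   count is < 4), converted to TPM (same RPKM-form normalisation by gene
   length and depth — columns are deliberately *not* rescaled to 10^6,
   matching the source convention; the naming caveat is documented on
   `compute_gene_tpm`), and a vOTU is *active* in a sample when its
   transcribed genes reach ≥ 1 gene per 10 kb of genome
   (`k × 10^4 ≥ L`, equivalently `k ≥ ceiling(L/10^4)`).
4. **ecology** — Shannon H (natural log) on CPM profiles; Bray–Curtis on
   square-root CPM; NMDS (Kruskal stress-1); PERMANOVA (sequential sums
   of squares over Gower-centred `−½ J D² J`); Mantel (Pearson, row/column
   permutation); a random-intercept mixed model of host log-abundance on
   co-occurring active vOTUs (the Kill-the-Winner signal).
5. **differential** — a deliberately simplified negative-binomial test of
   rhizosphere vs bulk gene activity (below).
6. **classify** — temperate/lytic lifestyle, host-prediction filtering,
   ssRNA phage completeness and RdRp genus/species clustering.
7. **priming** — vOTUs active in the seedling rhizosphere under
   continuous cropping and absent from it under virgin rotation.
8. **report** — the headline proportion summaries (half-up rounding to
   one decimal).

All rule thresholds (0.75 breadth, 4-read group filter, 1 gene/10 kb,
p < 0.05 host filter) are configuration values defaulting to the
published rules, and every run manifest records them. All threshold
comparisons are inclusive (≥) except the host-prediction filter, which is
strict (p < 0.05), both matching the stated rules.

# The simplified differential test

The published analysis used a full shrinkage-based NB framework. This
package implements a documented approximation
(`size_factors` + `nb_wald_test`): median-of-ratios size factors,
method-of-moments dispersion per gene (pooled within condition, floored
at 1e−8), per-condition NB means fitted by Newton iteration with
log-size-factor offsets, and a Wald statistic on the log2 fold change.
Two deliberate deviations from textbook choices:

* the Wald statistic is referred to a **t distribution with n − 2 df**
  rather than the normal: at the replication level this test is used at
  (4 + 4 samples) the normal reference rejects at ~9% nominal 5%, outside
  the calibration band the test suite enforces ([0.03, 0.07]);
* a condition whose counts sum to zero receives a 0.5 continuity
  correction so the statistic stays finite (no shrinkage is available to
  do this job).

No dispersion shrinkage, outlier replacement or independent filtering is
performed; label tables from external tools can be supplied directly to
`enrichment_summary`. Genes with all-zero counts are excluded from
testing and from the Benjamini–Hochberg denominator.

# Self-contained statistics

The ecology statistics are implemented in the package rather than
delegated, so their permutation and optimisation details are explicit and
testable; `vegan`, `lme4` and base `aov`/`TukeyHSD` appear only as
independent oracles in the test suite.

* **NMDS** fits disparities by pool-adjacent-violators isotonic
  regression on the dissimilarity order (Kruskal's primary approach to
  ties: tie blocks are sub-ordered by current configuration distance) and
  updates the configuration by SMACOF-style majorization with a
  step-halving safeguard, so stress is monotone non-increasing within a
  start — a property the tests assert. Start 1 is seeded from classical
  metric scaling, the remaining `n_starts − 1` (default 20) are random;
  convergence tolerance 1e−6 on the stress decrease.
* **PERMANOVA** uses sequential (type-I) sums of squares with terms in
  the declared order, default `(compartment, rotation)`; the interaction
  is available behind a flag but off by default (the additive model is
  the conservative reading of the reported tests). P-values use free
  permutation of sample labels with the add-one rule
  `p = (1 + #{F_perm ≥ F_obs}) / (1 + n_perm)`, so p is never 0. The
  default permutation count is 9999 (not stated in the source; chosen as
  the common ecology default) and `"exhaustive"` enumerates all `n!`
  relabelings for small fixtures.
* **Mantel** correlates upper triangles (Pearson) and permutes one
  matrix's rows and columns simultaneously; one-sided (greater).
* The **mixed model** `y = β₀ + β₁x + u_group + ε` is fitted by REML with
  the variance ratio `θ = σ²_u/σ²` profiled out (1-D optimisation on
  `log(1+θ)`), collapsing to OLS when `θ → 0`. The slope test uses
  Satterthwaite degrees of freedom from a numeric gradient of
  `Var(β̂₁)` in the variance components and a numeric REML Hessian.

# The synthetic world

`simulation_config()` states one world; tests and calibrations run
against it rather than against tuned scenarios. Where the study states a
quantity, the default copies it; where it does not, a value was chosen
once on field-realism grounds and is not revisited:

| parameter | default | where it comes from |
|---|---|---|
| design | 3 compartments × 2 rotations × 3 stages × 4 plots | the field trial layout |
| `active_fraction` | 0.78 | 78.1% of dsDNA vOTUs were active |
| `priming_set_size` | 0.185 × n_votus | 196 of 1059 vOTUs primed |
| `ktw_slope` | −0.039 | the reported host-abundance slope |
| `n_votus` | 150 | scaled down from 1059 for desk-size runs |
| `genome_length_law` | log-normal, median 30 kb, ≥ 10 kb (proviruses ≥ 5 kb) | typical soil dsDNA phage contigs above the recovery floor |
| `genes_per_kb` | 1.0 | typical phage coding density |
| `library_size_law` | log-normal, median 2 M reads | desk-scale sequencing depth |
| `nb_dispersion` | 0.5 | strongly overdispersed soil counts |
| `breadth_delta` | 1 | saturation scale of `1 − exp(−depth/δ)` |
| `unmapped_fraction` | 0.3 | typical soil mapping rates |
| `leak_rate` | 0.01 | low-level spurious transcript assignment |
| `enriched_bulk/rhizo_fraction` | 0.10 / 0.025 | bulk ≫ rhizosphere enrichment, while ~87% of ubiquitously expressed genes stay non-differential so median-of-ratios normalisation remains valid |

Generative model: per-sample vOTU compositions are Dirichlet draws around
a treatment-group centre; the group centre is the global centre displaced
on the log scale by fixed compartment/rotation effect vectors scaled by
the effect parameters. The displacement is deterministic and the
Dirichlet noise sits at the *sample* level, so that with zero effects all
samples are i.i.d. and the PERMANOVA/Mantel permutation null is exact —
the type-I calibration tests depend on this. DNA counts are
negative-binomial around composition × depth; breadth follows
`1 − exp(−depth/δ)` so presence calls are stochastic near the 0.75
threshold. RNA counts are nonzero only for the expressed genes of
planted-active vOTUs (each active vOTU expresses at least
`ceiling(L/10^4) + 1` genes, so the activity rule is recoverable), plus a
leak. Host 16S log10 abundance is depressed by `ktw_slope` per
co-occurring active vOTU assigned to the host.

Three definitions worth knowing when reading the tests:

* **dispersion 0 is the deterministic limit** (`counts = round(mean)`),
  not the Poisson limit, so the "noiseless regime recovers the planted
  activity matrix and priming set exactly" invariant is literal. Use any
  small positive dispersion for Poisson-like noise.
* **the priming ground truth is the rule applied to the planted activity
  matrix**: membership is defined by the activity pattern, so an
  active-set vOTU whose random activity happens to satisfy the rule *is*
  a priming vOTU. The forced core of size `priming_set_size` is a subset
  by construction.
* **planted enrichment labels live on the always-active vOTUs** (active
  in every sample, hence compartment-symmetric at baseline). Genes of
  priming vOTUs are genuinely rhizosphere-biased — the generator forces
  their seedling rhizosphere activity — so a differential call on them is
  correct behaviour, and label-recovery F1 is evaluated on the
  always-active pool only.

What the generator does **not** emulate: sequence content (no reads or
genomes beyond coordinates), compositional closure artefacts from real
mapping pipelines, spatial autocorrelation among plots, multi-mapping
ambiguity, and the tail behaviour of real library-size distributions. A
green recovery test therefore establishes that the rules and statistics
recover what they define under the stated noise model — not that the
upstream bioinformatics would.

# Numerical and degenerate-input choices

* GFF3 coordinates (1-based inclusive) are converted to 0-based
  half-open at the single reader entry point.
* A sample present in only one DNA library keeps that library's CPM
  (median over available observations) instead of having the missing
  value counted as zero, which would halve abundances.
* All-zero abundance profiles give `NA` Shannon diversity with a
  warning; all-zero sample pairs give Bray–Curtis 0 with a warning.
* Dedup and RdRp clustering are greedy length-sorted (CD-HIT-like,
  matching the published dedup tool), *not* single linkage; ties in
  length break lexicographically by id, making clustering deterministic.
* The RdRp genus/species thresholds have **no defaults**: the published
  values live in an external reference, so the classify stage refuses to
  cluster without explicit thresholds.
* Percent summaries round half-up to one decimal (base `round()` is
  half-to-even and would print some of the reported values differently).
* `two_way_anova` returns `F = 0, p = 1` for a constant response and
  collapses to one-way ANOVA when a factor has one level.
* Priming's "absent under virgin rotation" is read as *not active*
  (default); a not-detected variant is available through the
  `max_active_virgin` knob.
* The ≥ 4-read filter's "across the replicates" is read as the **sum
  over a treatment group's replicates** (the group-level decision that
  matches zeroing "in each sample replicate"); a per-replicate reading
  sits behind `activity_per_replicate`.
* The differential contrast pools soil samples across growth stages by
  default (`diff_stage` restricts to one stage); root samples are
  summarised but never tested.
* Sequencing depth means **total library reads**, not mapped reads; the
  generator records library sizes as column sums divided by
  `1 − unmapped_fraction`.

# Test-suite scaling

The calibration criteria (type-I error in [0.03, 0.07] over ≥ 400 null
simulations for PERMANOVA, Mantel and the NB test; NB power ≥ 0.8 at a
planted 8-fold change with 4 + 4 samples) run on deliberately small
worlds — 12-sample single-stage designs with 40 vOTUs and 99-permutation
tests — to fit a single-CPU budget. 99 permutations put the add-one
p-value on the grid `k/100`, so the 0.05 level is attainable exactly and
the rejection probability under the null is exactly 0.05. Dataset-scale
results (1059 vOTUs, the 196-member priming set, the reported PERMANOVA
variance ranges) are not reproducible at desk scale; the acceptance
script instead recomputes the printed proportion summaries from their
printed counts.

# Known limitations

* The NB test is an approximation: no shrinkage means noisier fold
  changes for low-count genes than the published analysis would report.
* Satterthwaite df relies on numeric derivatives; for boundary fits
  (`σ²_u ≈ 0`) it falls back to the OLS df, which is slightly liberal
  for few groups.
* NMDS with few points and many ties can stop in local minima; raise
  `n_starts` for publication-grade ordinations.
* The CLI runs prerequisite stages in memory when a single stage is
  requested; stage outputs are re-derived, not re-read, which keeps the
  "no stage re-reads raw files" contract but costs recomputation.
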