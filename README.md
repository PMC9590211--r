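# rhizovir

Detection, activity and ecology of soil viral populations from virome,
metagenome and metatranscriptome count data.

## The problem

Soil viruses (mostly bacteriophages) shape microbial communities through
lysis and through the expression of host-derived metabolic genes, but
DNA sequencing alone cannot say which recovered viruses are *doing*
anything. Combining a size-fractionated DNA virome, a total metagenome
and a metatranscriptome over a crop-field factorial design (soil
compartment × crop rotation × growth stage × replicate plot) makes three
questions tractable, and this package implements the analysis layer for
all three — everything downstream of read mapping:

1. **Which viral populations (vOTUs) are present and how abundant are
   they?** Presence: breadth of coverage ≥ 0.75. Abundance:
   CPM = count / (genome kb) / (depth in millions), median across DNA
   libraries, masked by presence.
2. **Which are active, where and when?** A vOTU is active in a sample
   when its transcribed genes reach ≥ 1 gene per 10 kb of genome
   (k·10⁴ ≥ L), after a ≥ 4-read group-level transcript filter.
3. **What does activity structure look like ecologically?** Shannon H,
   Bray–Curtis on √CPM, NMDS (Kruskal stress-1), PERMANOVA
   (R² = SS_term/SS_total, pseudo-F, free permutation), Mantel tests, a
   simplified negative-binomial rhizosphere-vs-bulk differential test,
   temperate/lytic and ssRNA-phage (Leviviricetes MP/CP/RdRp) rules, and
   "viral priming": vOTUs active in the seedling rhizosphere under
   continuous cropping yet absent from it under virgin rotation —
   candidate locally adapted viruses persisting from the previous
   season's crop. A random-intercept mixed model of host log-abundance
   against co-occurring active vOTUs quantifies the Kill-the-Winner
   signal (fitted by REML, Satterthwaite df).

The ecology statistics are self-contained implementations (tested
against vegan/lme4/base-R oracles), and a bundled synthetic-data
generator produces complete input bundles with planted ground truth —
active matrix, priming set, enriched-gene labels, a planted
Kill-the-Winner slope — so every stage has a recoverable answer.

## Worked example

```r
library(rhizovir)

cfg <- simulation_config(seed = 42, n_votus = 80, n_ssrna_votus = 10,
                         replicates = 4)
bundle_dir <- file.path(tempdir(), "bundle")
sim <- simulate_bundle(cfg, bundle_dir)

run_pipeline(pipeline_config(bundle_dir, file.path(tempdir(), "run"),
                             seed = 1, n_permutations = 999))

read_table_tsv(file.path(tempdir(), "run", "summaries.tsv"))
#>                         label num den percent
#> 1             temperate_dsDNA  16  80    20.0
#> 2            detected_overall  80  80   100.0
#> 3              active_overall  63  80    78.8
#> ...
read_table_tsv(file.path(tempdir(), "run", "permanova.tsv"))
#>          term df    ss    r2    f     p
#> 1 compartment  1 0.707 0.335 34.5 0.001
#> 2    rotation  1 0.480 0.228 23.4 0.001
#> 3    Residual 45 0.922 0.437   NA    NA
```

Reading the output: 63/80 vOTUs (78.8%) were transcriptionally active —
the generator plants an active fraction of 0.78, mirroring the scale of
the study this pipeline reproduces. PERMANOVA attributes 33.5% of
Bray–Curtis variance to soil compartment and 22.8% to crop rotation
(both p = 0.001 at 999 permutations, add-one rule). The recovered
priming set matched the planted one exactly in this run
(`priming_set.tsv`, 16/16), and the mixed-model slope of host abundance
on active vOTUs came out at −0.029 against a planted −0.039 (single run;
the test suite shows the estimator is unbiased over 100 seeds).

The same stages are scriptable from the shell:

```sh
inst/cli/rhizovir simulate --config sim.json      # write a bundle
inst/cli/rhizovir run --config pipeline.json      # all eight stages
```

where the JSON config carries `simulation_config()` /
`pipeline_config()` fields.

## Layout

- `R/` — implementation (types/IO, simulator, detection, activity,
  ecology statistics, differential test, classification, priming,
  pipeline, CLI)
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/rhizovir-methods.Rmd` — the models, rules, synthetic world
  and design decisions in detail
- `inst/extdata/lysogeny_pfam_list.txt` — the 29 lysogeny-associated
  Pfam accessions used by the lifestyle rule
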