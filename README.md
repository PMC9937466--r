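# prspath — pathway-based polygenic risk scores

Genome-wide polygenic risk scores (PRSs) summarize an individual's genetic
liability as one number, discarding how risk distributes across biological
processes. `prspath` implements the *pathway polygenic* alternative: for
each individual and each gene set (pathway) *k* it computes

```
PRS_ik = sum_{j=1..m_k} beta_j * G_ij
```

where `m_k` is the number of LD-clumped SNPs annotated to pathway *k*,
`beta_j` the GWAS effect size from an external base sample, and `G_ij` the
allele dosage in the genotyped target sample. It is aimed at statistical
geneticists who want per-pathway liability estimates for enrichment
analysis, tissue/cell-type specificity readouts, or supervised
disease-subtype stratification.

The package covers:

* **Harmonization and QC** — PLINK-1 bed/bim/fam and dosage-TSV input,
  GWAS summary-statistics ingestion with configurable column maps, removal
  of strand-ambiguous (A/T, G/C) SNPs, allele-orientation alignment,
  missingness/MAF/Hardy–Weinberg (exact mid-P) filters.
* **Annotation** — SNP-to-gene mapping from GTF with strand-aware
  35 kb/10 kb window extension, GMT gene sets filtered to 10–2000 genes,
  MHC/APOE exclusion regions, and a 5-Mb coordinate-shift negative
  control.
* **Pathway-aware clumping** — a single bit-flag pass that is exactly
  equivalent to greedy P-value-ordered clumping run on every pathway
  independently (oracle-verified in the tests).
* **Competitive enrichment** — per-pathway empirical P-values
  `(#{P_n < P_0} + 1)/(N + 1)` from size-matched null SNP sets drawn from
  the clumped genic background.
* **Subtype stratification** — lasso (`cv.glmnet`, MSE-selected penalty)
  over enriched, re-thresholded pathway PRSs with strict train/test
  separation, a shift negative control, leave-one-cohort-out mode, and a
  genome-wide C+T baseline.
* **Expression specificity** — 11-quantile specificity gene sets per
  tissue/cell type with top-quantile and linear-trend tests, Fisher
  meta-combination, rank-normalized gene relevance scores, and Kendall
  tau-b agreement.
* **Synthetic data** — LD-blocked genotypes, point-normal causal
  architectures with 1–30% pathway enrichment at a target h², per-SNP
  GWAS, subtype generators, and a full ranking-recovery benchmark.

## Worked example

Everything below is synthetic and runs in a few seconds.

```r
library(prspath)

## simulate a small cohort: 600 base + 400 target individuals, 500 SNPs
panel <- simulate_genotypes(1000, 500, seed = 11)
land  <- simulate_gene_sets(panel, n_pathways = 40, seed = 12)
flags <- build_membership(panel, extend_gene_bounds(land$genes), land$sets,
                          min_genes = 1)
truth <- assign_causal_pathways(flags, k_causal = 8, seed = 13)
y     <- simulate_phenotype(panel, truth, h2 = 0.5, seed = 14)

## GWAS on the base sample, harmonize with the disjoint target sample
gwas  <- run_gwas(subset_individuals(panel, 1:600), y[1:600])
study <- harmonize(gwas, subset_individuals(panel, 601:1000))

## fit pathway PRSs with competitive enrichment (1,000 permutations)
fit <- prset(study, land$genes, land$sets, y[601:1000],
             n_perm = 1000, min_genes = 1, seed = 15)
print(fit)
print(head(summary(fit), 3))
```

Output from this exact script:

```
Pathway PRS fit
  individuals: 400
  pathways scored: 40
  background SNPs: 55
  top pathways (competitive P): pw_0004 (0.00599), pw_0006 (0.0839), pw_0013 (0.0909)
Competitive pathway enrichment (3 pathways)
  pathway  m p_observed p_competitive
1 pw_0004 13  3.806e-37      0.005994
2 pw_0006 11  4.306e-28      0.083916
3 pw_0013 16  1.658e-30      0.090909
```

Reading the numbers: each row is one pathway; `m` is its clumped SNP
count; `p_observed` is the P-value of regressing the phenotype on that
pathway's standardized PRS in the 400 target individuals; and
`p_competitive` is the fraction (plus pseudo-count) of 1,000 size-matched
random genic SNP sets that achieved a smaller association P — raw
association P-values are astronomically small for *every* pathway in this
dense toy simulation, and it is the competitive comparison that separates
them. Checking against the simulated truth, the three top-ranked pathways
are all truly causal, with pw_0004 carrying the highest realized
enrichment (39% of its SNPs causal, including spillover from overlapping
sets).

The rank-agreement of the whole analysis with the simulated truth:

```r
kendall_agreement(-log10(fit$enrichment$p_competitive),
                  unname(truth$enrichment[fit$enrichment$pathway]))
#> [1] 0.3378292
```

## Command-line use

Pipelines can also be driven from a plain key=value config file via
`run_pipeline()` or the wrapper in `inst/scripts/prspath-cli.R`:

```sh
Rscript inst/scripts/prspath-cli.R run.cfg
```

with e.g. `command = enrich`, input paths, `permutations = 10000`,
`seed = 5`. Every run writes its output tables plus a JSON manifest
(hashed inputs, effective parameters, seed, wall time, warnings) so any
result can be traced and replayed.

## Documentation

The methods vignette (`vignettes/pathway-prs-methods.Rmd`) describes the
model, every tunable parameter with its default and rationale, the
synthetic-data generator and what passing tests do and do not demonstrate,
numerical edge-case handling, and known limitations.
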