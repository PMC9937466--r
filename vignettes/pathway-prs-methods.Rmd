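---
title: "Pathway polygenic risk scores: models, parameters and design choices"
author: "prspath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway polygenic risk scores: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The pathway polygenic model

A genome-wide polygenic risk score collapses an individual's genetic
liability into a single number.  When diseases are heterogeneous —
different biological routes leading to the same diagnosis — that collapse
discards exactly the structure one would like to exploit.  The pathway
polygenic view instead assigns each individual one score per gene set
(pathway):

$$\mathrm{PRS}_{ik} = \sum_{j=1}^{m_k} \beta_j \, G_{ij}$$

where $m_k$ is the number of LD-clumped SNPs annotated to pathway $k$,
$\beta_j$ is the SNP effect estimated in an external GWAS (the *base*
sample), and $G_{ij}$ is the allele dosage of individual $i$ in the
genotyped *target* sample.  All scores are standardized to mean 0, sd 1
(sample standard deviation, $n-1$ denominator).

### Pathway-aware clumping

Clumping is performed *within each pathway independently*, so that a SNP
shared by several pathways can serve as the index SNP of one and still be
counted in another.  Naively this means re-clumping per pathway; the
package instead runs one pass in which every SNP carries a bit per pathway
and an index SNP clears the bits of linked SNPs (same chromosome, within
the window, $r^2$ at or above the threshold) only for pathways the index
itself currently belongs to.  A SNP stripped of every bit disappears.
This pass is *exactly* equivalent to running greedy P-value-ordered
clumping separately on each pathway's SNPs, and the test suite asserts
bitwise equality against an independent greedy oracle on hundreds of
random instances.

Numerical conventions: LD $r^2$ is the squared Pearson correlation of
mean-imputed dosages computed from the target panel itself; ties on the
GWAS P-value are broken by genomic position and then SNP id so the visit
order is a total order and results are reproducible.  Defaults follow
common C+T practice: $r^2 \ge 0.1$, 250 kb window, P-value ceiling 1.

### Annotation

SNPs are annotated to genes from a GTF, with gene bounds extended 35 kb
upstream and 10 kb downstream (strand-aware: "upstream" means the 5' side)
to capture proximal regulatory variation.  Coordinates are 1-based
inclusive and the overlap test is closed-interval.  Pathways come from GMT
files; after intersecting with the genes present in the GTF, sets with
fewer than 10 or more than 2000 genes are discarded as over-specific or
over-broad.  The extended MHC (chr6:25–34 Mb) is excluded by default and
the APOE region (chr19:44–46 Mb) can be added for dementia-type outcomes.
SNPs inside excluded regions belong to no pathway and not to the genic
background.

### Competitive enrichment

Association alone conflates pathway signal with pathway size.  The
competitive null asks: does this pathway's PRS explain more than a random
set of the same number of independent genic SNPs?  A *background* pathway
of all genic SNPs is clumped once; for a pathway with $m$ clumped SNPs,
$N$ null sets of $m$ background SNPs are drawn without replacement and
scored with the GWAS weights of the drawn SNPs.  With $P_0$ the observed
association P-value (phenotype regressed on the PRS, threshold 1) and
$P_n$ the null P-values,

$$P_{\mathrm{competitive}} = \frac{\sum_{n=1}^{N} I(P_n < P_0) + 1}{N + 1},$$

so the smallest attainable value is $1/(N+1)$ and ties count as "not
smaller".  The default is $N = 10{,}000$ permutations; simulation-scale
analyses in this package use $N = 1{,}000$.  Null draws use one seeded
generator with per-pathway sub-streams derived from the run seed and the
pathway name, so results do not depend on the order in which pathways are
processed.  Internally the $N$ null regressions are evaluated from
precomputed cross-products of per-SNP score contributions — algebraically
identical to scoring each null set and refitting (the tests assert
equality to machine precision).

### Phenotype handling

Covariates are removed before any PRS model: continuous outcomes by
ordinary least squares residuals, binary outcomes by a covariate-only
logistic fit whose deviance residuals become the working outcome.  The
residual type is a genuine free choice — we default to deviance residuals
and expose response residuals via `type`; note that only response
residuals are exactly orthogonal to the covariates (GLM score equations),
deviance residuals only approximately so.  Separation in the logistic fit
is detected (including the silent case where `glm` converges to fitted
probabilities of 0/1 without warning) and reported as an error rather
than propagated.

### Threshold optimization

For prediction-oriented uses, each pathway PRS is recomputed over a grid
of GWAS P-value thresholds (default
5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1) and the
threshold maximizing training $R^2$ is kept, ties resolved towards the
larger (more inclusive) threshold.  Enrichment analyses never threshold
(threshold fixed at 1).

## Subtype stratification

The supervised pipeline mirrors the intended clinical setting: a
well-powered case/control GWAS provides weights; a modest genotyped sample
with known subtypes trains a classifier.  Within each training split
(default 80%, stratified by label): competitive enrichment is computed,
pathways with competitive $P < 0.05$ are kept, each is re-thresholded for
maximal training $R^2$, and a lasso (`glmnet::cv.glmnet`, Gaussian fit to
the 0/1 label, penalty chosen by 5-fold cross-validated MSE) combines the
standardized pathway scores.  Test individuals contribute nothing to
enrichment, thresholding, or standardization (test scores are scaled by
training means/sds), and the reported $R^2$ is the squared Pearson
correlation between predictions and test labels.  We chose this $R^2$
definition because the upstream literature reports "model $R^2$" without
formal definition; squared correlation is invariant to affine prediction
rescaling, which suits penalized predictors.

Two deliberate choices deserve notice.  First, the MSE-minimal lasso
penalty (`lambda_rule = "min"`) retains occasional small spurious
coefficients under a pure-noise label; the sparser one-standard-error rule
is available (`lambda_rule = "1se"`) and is the variant for which
"permuted labels give an intercept-only model" holds in at least 80% of
seeds.  Second, enrichment is recomputed once per training split, not once
per inner CV fold; the alternative is statistically cleaner but an order
of magnitude slower, and the outer train/test separation already prevents
test leakage.

The **coordinate-shift control** re-runs the identical pipeline with every
gene displaced 5 Mb along its chromosome, destroying the biological
meaning of membership while preserving the number of pathways, their SNP
counts, and all model flexibility.  Shifted coordinates wrap modulo the
chromosome length; a gene whose shifted span would straddle the chromosome
end is relocated to base 1 (length preserved, logged) rather than split —
wrapping keeps pathway SNP counts comparable, which is the entire point of
a matched negative control.  A leave-one-cohort-out mode covers
multi-cohort targets: every cohort serves exactly once as the test set.

## Expression-specificity pathways

For tissue or cell-type analyses, a gene's specificity in tissue $t$ is
its expression there divided by its total expression across tissues
(genes expressed nowhere are removed first).  Per tissue, genes are split
into 11 quantiles: quantile 1 holds exactly the non-expressed genes and
the remaining genes form 10 equal-count bins of increasing specificity
(ties and boundaries resolved by ascending specificity then gene id; bin
sizes differ by at most one when counts do not divide evenly).  Each bin
is one gene set.  Two readouts are supported: the *top-quantile* test
reports the competitive P-value of the most-specific bin; the *linear*
test regresses $-\log_{10}$ competitive P on quantile rank and reports the
one-sided P-value for a positive slope.  P-values across tissues can be
combined with Fisher's method ($-2\sum \ln p$ on $2k$ df).

Literature-derived gene relevance scores are rank-normalized: with $n$
scored genes, a gene of rank $r$ (ascending in the raw score, so the
best-supported gene has $r = n$) receives $(r+1)/(n+1)$; unscored genes
receive 0.  The direction of that ranking is ambiguous in common usage,
so the opposite convention sits behind a flag; the default makes the
top-scored gene's normalized value 1.  A pathway's relevance is the mean
over its members (unscored members count 0), which normalizes for pathway
size.  Agreement between an enrichment ranking and such scores uses
Kendall's tau-b — the tie-corrected variant, essential because relevance
scores are mostly zeros.

## The synthetic-data generator

The generator emulates the features of cohort genotype data that the
method actually exercises, at desk scale:

* **LD-blocked genotypes.**  Haplotypes follow a Markov chain along each
  chromosome: within an LD block, adjacent alleles have correlation
  $\sqrt{r^2_{\mathrm{block}}}$ (so adjacent dosage $r^2$ equals the
  requested value in expectation, decaying geometrically with distance)
  and blocks are independent.  The minor-allele frequency is drawn per
  block, uniform in (0.05, 0.5) by default: allele frequencies are shared
  along a block because strong LD between binary alleles of very
  different frequencies is mathematically infeasible (the joint-frequency
  bound), just as real haplotype blocks share frequency history.
  Requested combinations violating the bound raise an error.
* **Genome layout.**  20 chromosomes of 250 SNPs at 30 kb spacing.  Genes
  occupy one SNP position each, separated by two intergenic SNPs, strand
  alternating; after the 35 kb/10 kb extension each gene window covers
  two SNP positions and windows of distinct genes are disjoint, so one
  third of SNPs are non-genic and gene-set spillover arises only through
  genes genuinely shared between sets — mirroring the premise that
  non-causal pathways contain essentially no causal variants.  Pathways
  are random gene sets of 10–30 genes (300 sets by default).
* **Causal architecture.**  50 pathways are drawn as causal; each gets an
  enrichment fraction uniform on {1%, …, 30%} and `round(fraction ×
  members)` (at least 1) of its member SNPs become causal.  Effects are
  point-normal: causal $\beta \sim N(0, \cdot)$ (the scale is arbitrary —
  it cancels in the noise calibration), non-causal $\beta = 0$.  The true
  enrichment of *every* pathway is its realized causal-member fraction,
  including spillover through shared genes, and pathways are ranked by it.
* **Phenotype.**  $Y = X\beta + \varepsilon$ with $X$ the column-
  standardized causal genotypes and
  $\mathrm{var}(\varepsilon) = \mathrm{var}(X\beta)(1-h^2)/h^2$ — the
  unique scaling for which the genetic variance fraction equals $h^2$.
  (A noise law sometimes quoted as
  "$\mathrm{sd} = \mathrm{var}(X\beta)(1-h^2)$" is dimensionally
  inconsistent; the implemented form is what any variance-ratio reading
  of $h^2$ requires, and heritability recovery is verified within
  $\pm 0.02$ at $n = 50{,}000$.)
* **GWAS.**  Per-SNP simple linear regression on the base sample, disjoint
  from the target sample by construction.
* **Subtypes.**  All individuals are cases of the base trait; the subtype
  label is Bernoulli with logit proportional to the standardized true-β
  score of the driver pathways, with the slope solved numerically so the
  between-subtype mean difference of that score equals the requested
  shift (in sd units).

What the generator does **not** emulate: realistic human LD maps and
recombination hotspots, MAF-dependent effect-size coupling, population
stratification, genotyping error, and the scale of real cohorts.  Passing
tests on this synthetic data demonstrate the correctness and internal
calibration of the machinery — clumping equivalence, permutation
calibration, heritability recovery, ranking recovery under a known truth —
not the field performance of pathway PRSs on any particular cohort.

### Benchmark problem sizes

The packaged benchmark uses base GWAS $n = 10{,}000$, target $n = 5{,}000$,
5,000 SNPs, 300 pathways (50 causal), $N = 1{,}000$ permutations and three
seeded repetitions per heritability level ($h^2 \in \{0.1, 0.5\}$, six
runs in total).  These sizes were chosen as the desk-scale rendition of
the published simulation design; rank agreement at this scale sits below
what 50k–250k-sample GWASs achieve, since both the effect-size estimates
and the target-sample association P-values are noisier, and the package
reports whatever the run produces.  The per-pathway ranking statistic is
Kendall's tau-b between $-\log_{10}$ competitive P and the true
enrichment.

## Degenerate inputs and numerical edges

* Constant (monomorphic) score columns standardize to 0 with a warning;
  constant PRSs are an error in association fits.
* Monomorphic SNPs get $\beta = 0$, $P = 1$ in the GWAS scan and zero LD
  with everything during clumping.
* Missing dosages: QC statistics see true missingness; scoring and LD use
  per-SNP mean imputation (the conventional choice, switchable in
  principle by pre-imputing the panel).
* The Hardy–Weinberg filter uses a mid-P exact test on hard calls
  (dosages rounded to 0/1/2), the standard reproducible choice when only
  a threshold is prescribed.
* Empty pathway after the P-value ceiling: an empty retained list, not an
  error; a pathway with no overlapping SNP is dropped with a log entry.

## Known limitations

* Gene-set membership is fixed windows around gene bodies; no
  eQTL/chromatin SNP-to-gene linking.
* Lasso subtype models are linear in the pathway scores; interactions and
  non-linearities are out of scope.
* The permutation null matches null sets on SNP count only (not on MAF
  spectrum or LD structure), following the method's published definition.
* Competitive P-values saturate at $1/(N+1)$, which limits the resolution
  of rankings among strongly enriched pathways unless $N$ is raised.
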