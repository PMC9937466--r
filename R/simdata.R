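#' Simulate LD-blocked genotypes
#'
#' Generates hard-call dosages (0/1/2) from a haplotype Markov chain:
#' within each LD block adjacent SNPs have allele correlation
#' `sqrt(within_block_r2)` (so adjacent dosage r-squared is
#' `within_block_r2` in expectation, decaying geometrically with distance),
#' and SNPs in different blocks are independent.  The minor-allele
#' frequency is drawn per block (uniform in `maf_range`): frequencies are
#' shared along an LD block, which keeps any requested LD level feasible
#' for binary alleles and mirrors the shared history of real haplotype
#' blocks.  SNPs are laid out on equally spaced positions across
#' `ceiling(n_snps / snps_per_chr)` chromosomes.
#'
#' @param n_individuals,n_snps panel dimensions.
#' @param block_size SNPs per LD block.
#' @param within_block_r2 target adjacent-SNP r-squared inside blocks, in
#'   \[0, 1\].
#' @param maf_range block MAF range, inside (0, 0.5\].
#' @param seed integer seed (fixed seed gives an identical panel).
#' @param snps_per_chr SNPs per chromosome (default 250).
#' @param spacing_bp distance between adjacent SNPs in bp (default 20 kb).
#' @param missing_rate fraction of dosages set missing at random.
#' @return A [genotype_panel()] with attribute `chrom_lengths` (named
#'   vector, for [shift_annotation()]).
#' @export
simulate_genotypes <- function(n_individuals, n_snps, block_size = 20,
                               within_block_r2 = 0.8,
                               maf_range = c(0.05, 0.5), seed = NULL,
                               snps_per_chr = 250, spacing_bp = 30000,
                               missing_rate = 0) {
  if (within_block_r2 < 0 || within_block_r2 > 1)
    stop("infeasible within_block_r2 (must lie in [0, 1])")
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2])
  r <- sqrt(within_block_r2)
  n <- n_individuals; m <- n_snps
  nh <- 2L * n
  .with_seed(seed, {
    D <- matrix(0L, n, m)
    block_id <- (seq_len(m) - 1) %/% block_size
    chr_id <- (seq_len(m) - 1) %/% snps_per_chr + 1L
    maf <- stats::runif(max(block_id) + 1, maf_range[1], maf_range[2])[block_id + 1]
    prev <- NULL
    for (j in seq_len(m)) {
      p <- maf[j]
      new_chain <- j == 1 || block_id[j] != block_id[j - 1] ||
        chr_id[j] != chr_id[j - 1]
      if (new_chain) {
        a <- stats::rbinom(nh, 1L, p)
      } else {
        # per-step transition keeps marginal p and adjacent correlation r
        p1 <- p + r * (1 - p)        # P(1 | previous = 1)
        p0 <- p * (1 - r)            # P(1 | previous = 0)
        if (p1 > 1 || p1 < 0 || p0 > 1 || p0 < 0)
          stop("infeasible r2/MAF combination")
        u <- stats::runif(nh)
        a <- ifelse(prev == 1L, u < p1, u < p0) + 0L
      }
      D[, j] <- a[1:n] + a[(n + 1):nh]
      prev <- a
    }
    if (missing_rate > 0)
      D[stats::runif(length(D)) < missing_rate] <- NA
    within <- (seq_len(m) - 1) %% snps_per_chr + 1L
    map <- data.frame(
      snp = sprintf("snp_%02d_%04d", chr_id, within),
      chr = as.character(chr_id),
      pos = within * spacing_bp,
      a1 = c("A", "A", "T", "T")[(seq_len(m) - 1) %% 4 + 1],
      a2 = c("G", "C", "G", "C")[(seq_len(m) - 1) %% 4 + 1],
      stringsAsFactors = FALSE)
    panel <- genotype_panel(D, map)
    cl <- rep((snps_per_chr + 1) * spacing_bp, max(chr_id))
    names(cl) <- as.character(seq_len(max(chr_id)))
    attr(panel, "chrom_lengths") <- cl
    panel
  })
}

#' Subset a panel by individuals
#' @param panel a `genotype_panel`.
#' @param idx integer row indices.
#' @return A `genotype_panel` (panel-level attributes preserved).
#' @export
subset_individuals <- function(panel, idx) {
  out <- genotype_panel(panel$dosage[idx, , drop = FALSE], panel$map,
                        sample_id = panel$sample_id[idx])
  attr(out, "chrom_lengths") <- attr(panel, "chrom_lengths")
  out
}

#' Simulate a gene and pathway landscape over a panel
#'
#' Tiles genes along each chromosome (each gene spans `gene_span_snps`
#' consecutive SNP positions, separated by `gene_gap_snps` intergenic SNPs,
#' alternating strand) and draws pathways as random gene sets of uniform
#' size in `set_size_range`.
#'
#' @param panel a `genotype_panel` from [simulate_genotypes()].
#' @param gene_span_snps SNPs covered by each gene body.
#' @param gene_gap_snps intergenic SNPs between consecutive genes.
#' @param n_pathways number of gene sets.
#' @param set_size_range inclusive range of genes per set.
#' @param seed integer seed.
#' @return List with `genes` (a [gene_table()]), `sets`
#'   (a [gene_set_collection()]) and `chrom_lengths`.
#' @export
simulate_gene_sets <- function(panel, gene_span_snps = 1, gene_gap_snps = 2,
                               n_pathways = 300, set_size_range = c(10, 30),
                               seed = NULL) {
  map <- panel$map
  unit <- gene_span_snps + gene_gap_snps
  rows <- list(); gi <- 0
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    pos <- map$pos[idx]
    starts <- seq(1, length(idx) - gene_span_snps + 1, by = unit)
    for (s in starts) {
      gi <- gi + 1
      rows[[gi]] <- data.frame(
        gene = sprintf("g_%05d", gi), chr = ch,
        start = pos[s], end = pos[s + gene_span_snps - 1],
        strand = if (gi %% 2 == 0) "-" else "+",
        stringsAsFactors = FALSE)
    }
  }
  genes <- gene_table(do.call(rbind, rows))
  .with_seed(seed, {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_pathways,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes$gene, k))
    names(sets) <- sprintf("pw_%04d", seq_len(n_pathways))
    list(genes = genes, sets = gene_set_collection(sets, source = "simulated"),
         chrom_lengths = attr(panel, "chrom_lengths"))
  })
}

#' Assign causal pathways and causal SNPs
#'
#' Draws `k_causal` pathways without replacement, assigns each an
#' enrichment fraction uniformly from `fractions` (default 1-30% in 1%
#' steps), and selects `round(fraction * members)` (at least 1) of its
#' member SNPs as causal.  The union over causal pathways is the causal
#' SNP list.  The true enrichment of *every* pathway is the fraction of
#' its members that ended up causal (including spillover from overlapping
#' sets), and pathways are ranked by decreasing true enrichment.
#'
#' @param flags a `membership_flags`.
#' @param k_causal number of causal pathways.
#' @param fractions candidate enrichment fractions.
#' @param seed integer seed.
#' @return An object of class `simulation_truth`: list with
#'   `causal_pathways`, `assigned_fraction` (named), `causal_snps`,
#'   `enrichment` (named, all pathways), `rank` (1 = most enriched),
#'   `seed`.
#' @export
assign_causal_pathways <- function(flags, k_causal = 50,
                                   fractions = seq(0.01, 0.30, by = 0.01),
                                   seed = NULL) {
  M <- flags$membership
  paths <- colnames(M)
  if (k_causal > length(paths)) stop("k_causal exceeds the number of pathways")
  .with_seed(seed, {
    causal_pw <- sample(paths, k_causal)
    frac <- stats::setNames(sample(fractions, k_causal, replace = TRUE), causal_pw)
    causal <- character(0)
    for (pw in causal_pw) {
      members <- rownames(M)[M[, pw]]
      if (length(members) == 0) next
      nc <- max(1L, round(frac[[pw]] * length(members)))
      causal <- c(causal, sample(members, nc))
    }
    causal <- unique(causal)
    enr <- apply(M, 2, function(b) {
      mem <- rownames(M)[b]
      if (length(mem) == 0) 0 else mean(mem %in% causal)
    })
    structure(list(causal_pathways = causal_pw, assigned_fraction = frac,
                   causal_snps = causal, enrichment = enr,
                   rank = rank(-enr, ties.method = "min"),
                   seed = seed),
              class = "simulation_truth")
  })
}

#' Simulate a quantitative trait at a target heritability
#'
#' `Y = X beta + eps` with `X` the column-standardized causal genotype
#' matrix, causal effects drawn i.i.d. normal (point-normal architecture:
#' non-causal SNPs have beta = 0) and noise variance
#' `var(X beta) * (1 - h2)/h2`, the unique scaling for which the genetic
#' variance fraction `var(X beta)/var(Y)` equals `h2` in expectation.
#' The effect-size scale is arbitrary (absorbed by the noise scaling).
#'
#' @param panel a `genotype_panel`.
#' @param truth a `simulation_truth` or character vector of causal SNP ids.
#' @param h2 target SNP heritability, in (0, 1).
#' @param seed integer seed.
#' @param null_trait if `TRUE`, returns pure noise (no causal SNPs needed).
#' @return Numeric phenotype with attributes `beta` (named causal effects),
#'   `genetic` (the genetic values X beta) and `h2`.
#' @export
simulate_phenotype <- function(panel, truth, h2, seed = NULL,
                               null_trait = FALSE) {
  n <- length(panel$sample_id)
  if (null_trait)
    return(.with_seed(seed, structure(stats::rnorm(n), beta = numeric(0),
                                      genetic = rep(0, n), h2 = 0)))
  stopifnot(h2 > 0, h2 < 1)
  causal <- if (inherits(truth, "simulation_truth")) truth$causal_snps else
    as.character(truth)
  if (length(causal) == 0) stop("no causal SNP (use null_trait = TRUE for a null trait)")
  idx <- match(causal, panel$map$snp)
  if (anyNA(idx)) stop("causal SNP(s) absent from panel")
  .with_seed(seed, {
    X <- scale(.impute_mean(panel$dosage[, idx, drop = FALSE]))
    keep <- !is.na(X[1, ]) & apply(X, 2, function(v) all(is.finite(v)))
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0) stop("zero genetic variance: all causal SNPs monomorphic")
    beta <- stats::rnorm(ncol(X), 0, h2)
    g <- as.vector(X %*% beta)
    vg <- stats::var(g)
    if (vg == 0) stop("zero genetic variance")
    y <- g + stats::rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
    structure(y, beta = stats::setNames(beta, causal[keep]), genetic = g, h2 = h2)
  })
}

#' Per-SNP association scan (GWAS)
#'
#' Simple linear regression of the phenotype on each SNP's dosage,
#' returning effect size, standard error and two-sided P-value per SNP.
#' Monomorphic SNPs get beta = 0 and P = 1 and are flagged.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype numeric vector (one value per individual).
#' @return A `summary_stats` object (effect allele = panel A1) with
#'   attribute `monomorphic` (SNP ids).
#' @export
run_gwas <- function(panel, phenotype) {
  y <- as.numeric(phenotype)
  n <- length(y)
  if (n < 10) stop("need at least 10 individuals")
  if (n != length(panel$sample_id)) stop("phenotype length mismatch")
  D <- panel$dosage
  if (anyNA(D)) D <- .impute_mean(D)
  cmean <- colMeans(D)
  # chunked cross-products keep the transient memory footprint small
  m <- ncol(D)
  Sxx <- Sxy <- numeric(m)
  for (lo in seq(1L, m, by = 500L)) {
    hi <- min(lo + 499L, m)
    Dc <- D[, lo:hi, drop = FALSE]
    storage.mode(Dc) <- "double"
    Sxx[lo:hi] <- colSums(Dc^2)
    Sxy[lo:hi] <- as.vector(crossprod(y, Dc))
  }
  Sxx <- Sxx - n * cmean^2
  Sxy <- Sxy - n * cmean * mean(y)
  Syy <- sum((y - mean(y))^2)
  mono <- Sxx <= 1e-12
  beta <- ifelse(mono, 0, Sxy / pmax(Sxx, 1e-300))
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- ifelse(mono, NA_real_, sqrt(rss / ((n - 2) * pmax(Sxx, 1e-300))))
  tt <- ifelse(mono | se == 0, 0, beta / se)
  p <- ifelse(mono, 1, pmax(2 * stats::pt(-abs(tt), df = n - 2),
                            .Machine$double.xmin))
  out <- summary_stats(data.frame(
    snp = panel$map$snp, chr = panel$map$chr, pos = panel$map$pos,
    a1 = panel$map$a1, a2 = panel$map$a2, beta = beta, p = p, n = n,
    stringsAsFactors = FALSE))
  attr(out, "se") <- stats::setNames(se, panel$map$snp)
  attr(out, "monomorphic") <- panel$map$snp[mono]
  out
}

#' Benchmark enrichment recovery by Kendall rank agreement
#'
#' Full simulation study: for each heritability level and repetition,
#' simulates an LD-blocked panel, a gene/pathway landscape and causal
#' pathways; simulates the trait; runs the GWAS on a base sample and
#' harmonizes it with a disjoint target sample; builds membership, clumps,
#' and computes competitive P-values; then reports the Kendall tau-b
#' between the -log10 competitive P-values and the true pathway enrichment
#' across all pathways.
#'
#' @param n_base,n_target base (GWAS) and target sample sizes (disjoint
#'   draws from one simulated population).
#' @param n_snps,snps_per_chr,block_size,within_block_r2,maf_range,spacing_bp
#'   genotype parameters (see [simulate_genotypes()]).
#' @param n_pathways,set_size_range,gene_span_snps,gene_gap_snps landscape
#'   parameters (see [simulate_gene_sets()]).
#' @param k_causal causal pathways per repetition.
#' @param h2 heritability levels to cover.
#' @param n_perm permutations for competitive P-values.
#' @param reps repetitions per heritability level.
#' @param seed master seed; every repetition derives its own sub-stream.
#' @param upstream_bp,downstream_bp gene-window extension.
#' @param r2_threshold,window_bp clumping parameters.
#' @return List of class `enrichment_benchmark`: `results` (data.frame
#'   `h2`, `rep`, `tau`, `n_base`, `n_target`) and `median_tau`.
#' @export
benchmark_enrichment <- function(n_base = 10000, n_target = 5000,
                                 n_snps = 5000, snps_per_chr = 250,
                                 block_size = 20, within_block_r2 = 0.8,
                                 maf_range = c(0.05, 0.5), spacing_bp = 30000,
                                 n_pathways = 300, set_size_range = c(10, 30),
                                 gene_span_snps = 1, gene_gap_snps = 2,
                                 k_causal = 50, h2 = c(0.1, 0.5),
                                 n_perm = 1000, reps = 3, seed = 1,
                                 upstream_bp = 35000, downstream_bp = 10000,
                                 r2_threshold = 0.1, window_bp = 250000) {
  rows <- list()
  for (h in h2) for (r in seq_len(reps)) {
    rs <- .substream_seed(seed, paste0("bench_h", h, "_rep", r))
    tau <- .benchmark_once(n_base, n_target, n_snps, snps_per_chr, block_size,
                           within_block_r2, maf_range, spacing_bp, n_pathways,
                           set_size_range, gene_span_snps, gene_gap_snps,
                           k_causal, h, n_perm, rs, upstream_bp, downstream_bp,
                           r2_threshold, window_bp)
    rows[[length(rows) + 1]] <- data.frame(h2 = h, rep = r, tau = tau,
                                           n_base = n_base, n_target = n_target)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, median_tau = stats::median(results$tau)),
            class = "enrichment_benchmark")
}

.benchmark_once <- function(n_base, n_target, n_snps, snps_per_chr, block_size,
                            within_block_r2, maf_range, spacing_bp, n_pathways,
                            set_size_range, gene_span_snps, gene_gap_snps,
                            k_causal, h2, n_perm, seed, upstream_bp,
                            downstream_bp, r2_threshold, window_bp) {
  panel <- simulate_genotypes(n_base + n_target, n_snps,
                              block_size = block_size,
                              within_block_r2 = within_block_r2,
                              maf_range = maf_range, seed = seed,
                              snps_per_chr = snps_per_chr,
                              spacing_bp = spacing_bp)
  land <- simulate_gene_sets(panel, gene_span_snps = gene_span_snps,
                             gene_gap_snps = gene_gap_snps,
                             n_pathways = n_pathways,
                             set_size_range = set_size_range,
                             seed = .substream_seed(seed, "landscape"))
  ext <- extend_gene_bounds(land$genes, upstream_bp, downstream_bp)
  flags_all <- build_membership(panel, ext, land$sets)
  truth <- assign_causal_pathways(flags_all, k_causal = k_causal,
                                  seed = .substream_seed(seed, "causal"))
  y <- simulate_phenotype(panel, truth, h2, seed = .substream_seed(seed, "pheno"))
  base_idx <- seq_len(n_base)
  target_idx <- n_base + seq_len(n_target)
  base <- subset_individuals(panel, base_idx)
  target <- subset_individuals(panel, target_idx)
  rm(panel); gc(FALSE)
  stats <- run_gwas(base, y[base_idx])
  rm(base); gc(FALSE)
  study <- harmonize(stats, target)
  rm(target); gc(FALSE)
  flags <- build_membership(study, ext, land$sets)
  enr <- enrich_all(study, flags, y[target_idx], N = n_perm,
                    seed = .substream_seed(seed, "perm"),
                    r2_threshold = r2_threshold, window_bp = window_bp)
  truth_enr <- truth$enrichment[enr$pathway]
  kendall_agreement(-log10(enr$p_competitive), unname(truth_enr))
}

#' @export
print.enrichment_benchmark <- function(x, ...) {
  cat("<enrichment_benchmark> ", nrow(x$results), " runs; median tau = ",
      format(x$median_tau, digits = 3), "\n", sep = "")
  print.data.frame(x$results)
  invisible(x)
}

#' Simulate disease subtypes driven by chosen pathways
#'
#' Treats all panel individuals as cases of a base trait and draws a binary
#' subtype label from a logistic model whose linear predictor is the
#' standardized true-effect genetic score restricted to the driver
#' pathways' member SNPs, scaled so that the standardized mean difference
#' of that score between the two subtypes is approximately `shift`.
#'
#' @param panel a `genotype_panel`.
#' @param flags a `membership_flags` over the panel's SNPs.
#' @param driver_pathways pathway name(s) whose signal separates subtypes.
#' @param beta named true SNP effects (zero or absent for non-causal SNPs).
#' @param shift target standardized mean difference (>= 0; 0 gives labels
#'   independent of all scores).
#' @param seed integer seed.
#' @return An object of class `subtype_truth`: list with `labels` (0/1),
#'   `driver_pathways`, `shift`, `score` (the standardized driver score),
#'   `seed`.
#' @export
simulate_subtypes <- function(panel, flags, driver_pathways, beta, shift = 1,
                              seed = NULL) {
  stopifnot(shift >= 0)
  if (!all(driver_pathways %in% colnames(flags$membership)))
    stop("unknown driver pathway(s)")
  n <- length(panel$sample_id)
  members <- rownames(flags$membership)[
    rowSums(flags$membership[, driver_pathways, drop = FALSE]) > 0]
  b <- beta[intersect(members, names(beta))]
  b <- b[b != 0]
  .with_seed(seed, {
    if (shift == 0 || length(b) == 0) {
      z <- rep(0, n)
      labels <- stats::rbinom(n, 1, 0.5)
    } else {
      idx <- match(names(b), panel$map$snp)
      raw <- as.vector(.impute_mean(panel$dosage[, idx, drop = FALSE]) %*% b)
      if (stats::sd(raw) == 0) stop("driver score has zero variance")
      z <- as.vector(scale(raw))
      cc <- .solve_logistic_shift(shift)
      labels <- stats::rbinom(n, 1, stats::plogis(cc * z))
    }
    structure(list(labels = labels, driver_pathways = driver_pathways,
                   shift = shift, score = z, seed = seed),
              class = "subtype_truth")
  })
}

# Slope c such that, for z ~ N(0,1) and P(y=1|z) = plogis(c z), the mean
# difference E[z|y=1] - E[z|y=0] equals `shift` (max ~1.6 as c -> Inf).
.solve_logistic_shift <- function(shift) {
  delta <- function(cc) {
    f <- function(z) z * stats::plogis(cc * z) * stats::dnorm(z)
    4 * stats::integrate(f, -8, 8)$value
  }
  if (shift >= delta(60)) stop("requested shift exceeds the attainable maximum")
  stats::uniroot(function(cc) delta(cc) - shift, c(1e-6, 60))$root
}
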