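# Fixtures and independent oracles used across test files.

# Small deterministic panel: 3 samples x 2 SNPs with known column sums.
toy_panel <- function() {
  D <- matrix(c(0, 1, 2,
                0, 0, 2), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("rs1", "rs2")))
  genotype_panel(D, data.frame(snp = c("rs1", "rs2"), chr = "1",
                               pos = c(1000L, 2000L), a1 = "A", a2 = "G"))
}

# Wrap an explicit membership matrix + background into membership_flags.
manual_flags <- function(panel, M, background = NULL) {
  if (is.null(background)) background <- rowSums(M) > 0
  structure(list(snp = panel$map$snp,
                 membership = M,
                 background = stats::setNames(background, panel$map$snp),
                 n_genes = stats::setNames(rep(NA_integer_, ncol(M)), colnames(M)),
                 genes_per_set = stats::setNames(vector("list", ncol(M)), colnames(M)),
                 log = character()),
            class = "membership_flags")
}

# Independent greedy clumping oracle: clump one membership set on its own,
# re-deriving LD from the raw dosages each iteration (no shared code with
# clump_pathways beyond the panel itself).
oracle_clump <- function(study, members, r2_threshold, window_bp, p_ceiling = 1) {
  map <- study$panel$map
  p <- study$stats$p
  D <- study$panel$dosage
  if (anyNA(D)) {
    cm <- colMeans(D, na.rm = TRUE)
    ii <- which(is.na(D), arr.ind = TRUE)
    D[ii] <- cm[ii[, 2]]
  }
  alive <- members[p[match(members, map$snp)] <= p_ceiling]
  kept <- character()
  while (length(alive)) {
    ix <- match(alive, map$snp)
    o <- order(p[ix], map$pos[ix], map$snp[ix])
    idx <- alive[o[1]]
    kept <- c(kept, idx)
    ii <- match(idx, map$snp)
    rem <- setdiff(alive, idx)
    if (length(rem)) {
      ri <- match(rem, map$snp)
      close <- map$chr[ri] == map$chr[ii] & abs(map$pos[ri] - map$pos[ii]) <= window_bp
      r2 <- rep(0, length(rem))
      if (any(close))
        r2[close] <- suppressWarnings(stats::cor(D[, ii], D[, ri[close], drop = FALSE]))^2
      r2[is.na(r2)] <- 0
      rem <- rem[!(close & r2 >= r2_threshold)]
    }
    alive <- rem
  }
  sort(kept)
}

# Random clumping instance: panel + GWAS + overlapping random memberships.
random_clump_instance <- function(seed, max_snps = 60, max_paths = 8) {
  set.seed(seed)
  n_snp <- sample(15:max_snps, 1)
  npw <- sample(2:max_paths, 1)
  panel <- simulate_genotypes(80, n_snp, block_size = 5, within_block_r2 = 0.7,
                              seed = seed, snps_per_chr = 30, spacing_bp = 50000)
  stats <- run_gwas(panel, rnorm(80))
  study <- harmonize(stats, panel)
  M <- matrix(runif(n_snp * npw) < 0.35, n_snp, npw,
              dimnames = list(panel$map$snp, paste0("P", seq_len(npw))))
  bg <- rowSums(M) > 0 | runif(n_snp) < 0.5
  M[!bg, ] <- FALSE
  list(study = study, flags = manual_flags(panel, M, bg))
}

# Exact HWE probabilities by direct (non-log) enumeration -- an independent
# arithmetic path used as oracle for hwe_exact_midp.
oracle_hwe_midp <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n1 <- 2 * n_aa + n_ab
  rare <- min(n1, 2 * n - n1)
  het <- seq(rare %% 2, rare, by = 2)
  pr <- sapply(het, function(h) {
    hom_rare <- (rare - h) / 2
    hom_com <- n - hom_rare - h
    # multinomial genotype probability conditional on allele counts
    2^h * factorial(n) / (factorial(hom_rare) * factorial(h) * factorial(hom_com))
  })
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, het)]
  sum(pr[pr < obs - 1e-12]) + 0.5 * sum(pr[abs(pr - obs) <= 1e-12])
}

# Small end-to-end simulated study (base GWAS + disjoint target).
small_study <- function(seed, n_base = 300, n_target = 300, n_snps = 300,
                        n_pathways = 30, k_causal = 5, h2 = 0.4) {
  panel <- simulate_genotypes(n_base + n_target, n_snps, seed = seed,
                              snps_per_chr = 100, spacing_bp = 50000)
  land <- simulate_gene_sets(panel, n_pathways = n_pathways,
                             set_size_range = c(5, 12),
                             seed = seed + 1)
  ext <- extend_gene_bounds(land$genes)
  flags_all <- build_membership(panel, ext, land$sets, min_genes = 1)
  truth <- assign_causal_pathways(flags_all, k_causal, seed = seed + 2)
  y <- simulate_phenotype(panel, truth, h2, seed = seed + 3)
  gw <- run_gwas(subset_individuals(panel, seq_len(n_base)), y[seq_len(n_base)])
  study <- harmonize(gw, subset_individuals(panel, n_base + seq_len(n_target)))
  flags <- build_membership(study, ext, land$sets, min_genes = 1)
  list(panel = panel, land = land, ext = ext, truth = truth, y = y,
       study = study, flags = flags,
       y_target = as.numeric(y[n_base + seq_len(n_target)]))
}
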