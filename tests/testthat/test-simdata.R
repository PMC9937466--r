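test_that("simulated genotypes honor LD, MAF and determinism contracts", {
  p1 <- simulate_genotypes(500, 100, seed = 1)
  p2 <- simulate_genotypes(500, 100, seed = 1)
  expect_identical(p1$dosage, p2$dosage)
  expect_true(all(p1$dosage %in% 0:2))
  expect_true(all(p1$maf <= 0.5 + 1e-12))

  # independence limit: r2 = 0 gives near-zero adjacent correlation
  p0 <- simulate_genotypes(2000, 60, within_block_r2 = 0, seed = 2)
  r0 <- sapply(1:59, function(j) cor(p0$dosage[, j], p0$dosage[, j + 1]))
  expect_lt(mean(abs(r0)), 0.05)

  # target LD: adjacent within-block r2 near 0.8
  pl <- simulate_genotypes(5000, 100, block_size = 20, within_block_r2 = 0.8,
                           seed = 3)
  same_block <- which(diff((seq_len(100) - 1) %/% 20) == 0)
  r2 <- sapply(same_block, function(j) cor(pl$dosage[, j], pl$dosage[, j + 1])^2)
  expect_lt(abs(mean(r2) - 0.8), 0.05)
  # across block boundaries correlation collapses
  cross <- which(diff((seq_len(100) - 1) %/% 20) != 0)
  rx <- sapply(cross, function(j) cor(pl$dosage[, j], pl$dosage[, j + 1]))
  expect_lt(mean(abs(rx)), 0.06)

  expect_error(simulate_genotypes(10, 10, within_block_r2 = 1.2),
               "infeasible")
})

test_that("the simulated gene landscape tiles disjoint windows", {
  panel <- simulate_genotypes(50, 300, seed = 4)
  land <- simulate_gene_sets(panel, n_pathways = 20, seed = 5)
  ext <- extend_gene_bounds(land$genes)
  # extended windows never overlap between genes (by construction)
  for (ch in unique(ext$chr)) {
    g <- ext[ext$chr == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  expect_true(all(lengths(land$sets$sets) >= 10 & lengths(land$sets$sets) <= 30))
})

test_that("causal assignment follows the rounded-fraction rule with oracle truth", {
  # disjoint pathways: causal counts are exactly round(fraction * members)
  panel <- simulate_genotypes(30, 200, seed = 6)
  M <- matrix(FALSE, 200, 4, dimnames = list(panel$map$snp, paste0("P", 1:4)))
  for (k in 1:4) M[(k - 1) * 50 + 1:50, k] <- TRUE
  fl <- manual_flags(panel, M)
  truth <- assign_causal_pathways(fl, k_causal = 3, seed = 7)
  for (pw in truth$causal_pathways) {
    members <- rownames(M)[M[, pw]]
    expect_equal(sum(members %in% truth$causal_snps),
                 max(1, round(truth$assigned_fraction[[pw]] * 50)))
  }
  # brute-force enrichment oracle over all pathways
  for (pw in colnames(M)) {
    members <- rownames(M)[M[, pw]]
    expect_equal(unname(truth$enrichment[pw]),
                 length(intersect(members, truth$causal_snps)) / length(members))
  }
  # non-causal disjoint pathway has zero enrichment and worst rank
  noncausal <- setdiff(colnames(M), truth$causal_pathways)
  expect_equal(unname(truth$enrichment[noncausal]), 0)
  # overlap spillover: a pathway holding 5 of another's causal SNPs among
  # 50 members has enrichment 5/50 = 0.1
  shared <- head(intersect(rownames(M)[M[, truth$causal_pathways[1]]],
                           truth$causal_snps), 5)
  k <- length(shared)
  filler <- head(setdiff(rownames(M), truth$causal_snps), 50 - k)
  mem5 <- c(shared, filler)
  expect_length(mem5, 50)
  expect_equal(length(intersect(mem5, truth$causal_snps)) / 50, k / 50)
  expect_gte(k, 1)
})

test_that("phenotype simulation hits the target genetic variance fraction", {
  panel <- simulate_genotypes(4000, 300, seed = 8)
  causal <- sample(panel$map$snp, 120)
  y <- simulate_phenotype(panel, causal, h2 = 0.5, seed = 9)
  ratio <- var(attr(y, "genetic")) / var(as.numeric(y))
  expect_lt(abs(ratio - 0.5), 0.05)
  y2 <- simulate_phenotype(panel, causal, h2 = 0.1, seed = 10)
  expect_lt(abs(var(attr(y2, "genetic")) / var(as.numeric(y2)) - 0.1), 0.05)
  # null flag gives pure noise
  yn <- simulate_phenotype(panel, character(0), h2 = 0.5, null_trait = TRUE,
                           seed = 11)
  expect_equal(attr(yn, "h2"), 0)
  expect_error(simulate_phenotype(panel, character(0), 0.5), "no causal")
})

test_that("the GWAS scan is calibrated, detects signal and is unbiased", {
  panel <- simulate_genotypes(500, 800, seed = 12)
  y0 <- rnorm(500)
  gw0 <- run_gwas(panel, y0)
  expect_lt(abs(mean(gw0$p < 0.05) - 0.05), 0.02)

  # single large-effect SNP attains the minimum P
  target <- panel$map$snp[17]
  y1 <- as.numeric(scale(panel$dosage[, 17])) * 2 + rnorm(500, 0, 0.5)
  gw1 <- run_gwas(panel, y1)
  expect_equal(gw1$snp[which.min(gw1$p)], target)

  # effect estimates regress on the generating effects with slope ~ 1
  # (on unlinked SNPs; marginal GWAS effects absorb LD otherwise)
  big <- simulate_genotypes(20000, 150, within_block_r2 = 0, seed = 13)
  beta_true <- rnorm(150, 0, 0.1)
  yb <- as.vector(big$dosage %*% beta_true) + rnorm(20000, 0, 2)
  gwb <- run_gwas(big, yb)
  slope <- coef(lm(gwb$beta ~ beta_true))[2]
  expect_lt(abs(slope - 1), 0.1)

  # monomorphic SNPs are flagged with beta 0 and P 1
  Dm <- cbind(mono = rep(1, 50), poly = rbinom(50, 2, 0.4))
  pm <- genotype_panel(Dm, data.frame(snp = c("mono", "poly"), chr = "1",
                                      pos = c(100, 200), a1 = "A", a2 = "G"))
  gm <- run_gwas(pm, rnorm(50))
  expect_equal(gm$beta[gm$snp == "mono"], 0)
  expect_equal(gm$p[gm$snp == "mono"], 1)
  expect_identical(attr(gm, "monomorphic"), "mono")
  expect_error(run_gwas(subset_individuals(pm, 1:5), rnorm(5)), "at least 10")
})

test_that("subtype labels carry the requested driver shift", {
  panel <- simulate_genotypes(10000, 120, seed = 14)
  land <- simulate_gene_sets(panel, n_pathways = 6, set_size_range = c(8, 10),
                             seed = 15)
  fl <- build_membership(panel, extend_gene_bounds(land$genes), land$sets,
                         min_genes = 1)
  driver <- colnames(fl$membership)[1]
  members <- rownames(fl$membership)[fl$membership[, driver]]
  beta <- stats::setNames(rnorm(length(members), 0, 0.3), members)
  st <- simulate_subtypes(panel, fl, driver, beta, shift = 1, seed = 16)
  gap <- mean(st$score[st$labels == 1]) - mean(st$score[st$labels == 0])
  expect_lt(abs(gap - 1), 0.1)
  # shift = 0: labels independent of the driver score
  st0 <- simulate_subtypes(panel, fl, driver, beta, shift = 0, seed = 17)
  expect_lt(abs(cor(st0$labels, st$score)), 0.05)
  expect_error(simulate_subtypes(panel, fl, "nope", beta), "unknown driver")
})

test_that("the enrichment benchmark is deterministic and null-centered", {
  args <- list(n_base = 400, n_target = 300, n_snps = 300, snps_per_chr = 100,
               n_pathways = 25, set_size_range = c(10, 15), k_causal = 5,
               h2 = 0.5, n_perm = 60, reps = 2, seed = 99)
  b1 <- do.call(benchmark_enrichment, args)
  b2 <- do.call(benchmark_enrichment, args)
  expect_identical(b1$results, b2$results)
  expect_equal(nrow(b1$results), 2)
  expect_true(all(is.finite(b1$results$tau)))

  # near-null heritability: tau centered on zero
  argsn <- args; argsn$h2 <- 0.01; argsn$reps <- 4; argsn$seed <- 123
  bn <- do.call(benchmark_enrichment, argsn)
  expect_lt(abs(median(bn$results$tau)), 0.25)
})
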