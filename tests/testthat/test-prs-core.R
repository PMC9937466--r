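test_that("bit-flag clumping reproduces the worked shared-membership case", {
  # index SNP in {G1}; linked SNP a in {G1, G2}; linked SNP b in {G1}:
  # a keeps only G2, b loses every membership and disappears.
  set.seed(5)
  x <- rbinom(60, 2, 0.4)
  D <- cbind(idx = x, a = x, b = x, far = rbinom(60, 2, 0.4))
  map <- data.frame(snp = colnames(D), chr = "1",
                    pos = c(1000, 2000, 3000, 900000), a1 = "A", a2 = "G")
  panel <- genotype_panel(D, map)
  stats <- summary_stats(data.frame(snp = colnames(D), a1 = "A", a2 = "G",
                                    beta = 0.1,
                                    p = c(1e-6, 1e-4, 1e-3, 0.5)))
  study <- harmonize(stats, panel)
  M <- cbind(G1 = c(TRUE, TRUE, TRUE, FALSE),
             G2 = c(FALSE, TRUE, FALSE, TRUE))
  rownames(M) <- colnames(D)
  fl <- manual_flags(panel, M, background = rep(TRUE, 4))
  cl <- clump_pathways(study, fl, r2_threshold = 0.5, window_bp = 250000)
  expect_identical(cl$retained$G1, "idx")
  expect_setequal(cl$retained$G2, c("a", "far"))
  expect_false("b" %in% unlist(cl$retained))
  expect_setequal(cl$background, c("idx", "far"))
})

test_that("no clumping happens when all pairwise r2 sit below threshold", {
  inst <- random_clump_instance(404)
  cl <- clump_pathways(inst$study, inst$flags, r2_threshold = 1.01,
                       window_bp = 1e9)
  M <- inst$flags$membership
  for (k in colnames(M))
    expect_setequal(cl$retained[[k]], rownames(M)[M[, k]])
})

test_that("bit-flag clumping equals the per-pathway greedy oracle", {
  for (s in c(11, 57, 123, 321, 555, 777, 901, 1234)) {
    inst <- random_clump_instance(s)
    cl <- clump_pathways(inst$study, inst$flags, r2_threshold = 0.15,
                         window_bp = 120000, p_ceiling = 0.9)
    for (k in colnames(inst$flags$membership)) {
      mem <- inst$flags$snp[inst$flags$membership[, k]]
      expect_identical(sort(cl$retained[[k]]),
                       oracle_clump(inst$study, mem, 0.15, 120000, 0.9))
    }
    bgm <- inst$flags$snp[inst$flags$background]
    expect_identical(sort(cl$background),
                     oracle_clump(inst$study, bgm, 0.15, 120000, 0.9))
  }
})

test_that("PRS computation is the stated weighted dosage sum", {
  D <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1"))
  panel <- genotype_panel(D, data.frame(snp = "rs1", chr = "1", pos = 100,
                                        a1 = "A", a2 = "G"))
  ss <- summary_stats(data.frame(snp = "rs1", a1 = "A", a2 = "G",
                                 beta = 0.5, p = 0.1))
  study <- harmonize(ss, panel)
  expect_equal(as.numeric(compute_prs(study, "rs1")), c(0, 0.5, 1.0))

  D3 <- matrix(c(2, 1, 0), 1, 3, dimnames = list(NULL, paste0("r", 1:3)))
  p3 <- genotype_panel(D3, data.frame(snp = paste0("r", 1:3), chr = "1",
                                      pos = 1:3 * 100, a1 = "A", a2 = "G"))
  s3 <- harmonize(summary_stats(data.frame(snp = paste0("r", 1:3), a1 = "A",
                                           a2 = "G", beta = c(0.1, -0.2, 0.3),
                                           p = 0.5)), p3)
  expect_equal(as.numeric(compute_prs(s3, paste0("r", 1:3))), 0)
  # all-zero effects give all-zero scores
  s0 <- harmonize(summary_stats(data.frame(snp = paste0("r", 1:3), a1 = "A",
                                           a2 = "G", beta = 0, p = 0.5)), p3)
  expect_equal(as.numeric(compute_prs(s0, paste0("r", 1:3))), 0)
  # zero SNPs past the threshold: zero vector, count 0, warning
  expect_warning(z <- compute_prs(s3, paste0("r", 1:3), threshold = 1e-10),
                 "no SNP")
  expect_equal(attr(z, "n_snps"), 0L)
})

test_that("PRS is linear over disjoint SNP sets and order invariant", {
  s <- small_study(77)
  snps <- s$study$stats$snp[1:20]
  a <- compute_prs(s$study, snps[1:10])
  b <- compute_prs(s$study, snps[11:20])
  ab <- compute_prs(s$study, snps)
  expect_equal(as.numeric(ab), as.numeric(a) + as.numeric(b), tolerance = 1e-12)
  sh <- compute_prs(s$study, sample(snps))
  expect_equal(as.numeric(sh), as.numeric(ab), tolerance = 1e-12)
})

test_that("clumping r2 equals squared Pearson correlation of imputed dosages", {
  # two identical columns must clump at any threshold; weakly correlated must not
  set.seed(31)
  x <- rbinom(100, 2, 0.5); y <- rbinom(100, 2, 0.5)
  D <- cbind(a = x, b = x, c = y)
  D[1, "b"] <- NA   # mean imputation keeps r2 just below 1
  panel <- genotype_panel(D, data.frame(snp = c("a", "b", "c"), chr = "1",
                                        pos = c(100, 200, 300), a1 = "A",
                                        a2 = "G"))
  study <- harmonize(summary_stats(data.frame(snp = c("a", "b", "c"),
                                              a1 = "A", a2 = "G", beta = 0.1,
                                              p = c(0.01, 0.5, 0.9))), panel)
  Di <- D; Di[1, "b"] <- mean(D[-1, "b"])
  r2_ab <- cor(Di[, "a"], Di[, "b"])^2
  r2_ac <- cor(Di[, "a"], Di[, "c"])^2
  fl <- manual_flags(panel, matrix(TRUE, 3, 1, dimnames = list(c("a", "b", "c"), "P")))
  cl <- clump_pathways(study, fl, r2_threshold = r2_ab - 1e-6, window_bp = 1000)
  expect_false("b" %in% cl$retained$P)
  cl2 <- clump_pathways(study, fl, r2_threshold = max(r2_ab, r2_ac) + 1e-6,
                        window_bp = 1000)
  expect_setequal(cl2$retained$P, c("a", "b", "c"))
})

test_that("standardization gives exact z-scores and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(z <- standardize_scores(m), "constant")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  z2 <- suppressWarnings(standardize_scores(z))
  expect_equal(unname(z2), unname(z))
  expect_true(attr(z, "standardized"))
})

test_that("phenotype residualization has the expected projection behavior", {
  set.seed(2)
  y <- rnorm(200); y <- y - mean(y)
  x <- rnorm(200); x <- x - mean(x)
  x <- x - y * sum(x * y) / sum(y * y)     # orthogonal to y
  r <- residualize_phenotype(y, data.frame(x = x))
  expect_equal(unname(r), unname(y), tolerance = 1e-10)
  expect_equal(unname(residualize_phenotype(y, data.frame(y = y))),
               rep(0, 200), tolerance = 1e-10)
})

test_that("logistic residuals are uncorrelated with the covariates", {
  set.seed(3)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  # response residuals are exactly orthogonal to covariates (score equations)
  r2 <- residualize_phenotype(y, data.frame(x = x), family = "logistic",
                              type = "response")
  expect_lt(abs(cor(r2, x)), 0.02)
  # deviance residuals are only approximately decorrelated
  r <- residualize_phenotype(y, data.frame(x = x), family = "logistic")
  expect_lt(abs(cor(r, x)), 0.1)
  # separation is reported, not silently fitted
  xs <- c(rep(0, 50), rep(1, 50))
  expect_error(residualize_phenotype(xs, data.frame(z = xs), "logistic"),
               "separation")
})

test_that("association reporting matches lm and is calibrated under the null", {
  set.seed(4)
  y <- rnorm(50); x <- rnorm(50)
  a <- fit_association(y, x)
  fit <- summary(lm(y ~ x))
  expect_equal(a$r2, fit$r.squared, tolerance = 1e-12)
  expect_equal(a$p, fit$coefficients[2, 4], tolerance = 1e-12)
  expect_error(fit_association(y, rep(1, 50)), "constant")

  p <- fit_association(x, x)
  expect_equal(p$r2, 1)

  # null calibration: uniform slope P-values
  hits <- mean(replicate(600, fit_association(rnorm(300), rnorm(300))$p < 0.05))
  expect_lt(abs(hits - 0.05), 0.02)

  # closed-form variance decomposition: y = 2x + e with var explained 0.5
  n <- 100000
  xx <- rnorm(n)
  yy <- 2 * xx + rnorm(n, 0, 2)
  expect_lt(abs(fit_association(yy, xx)$r2 - 0.5), 0.01)
})

test_that("threshold selection maximizes training R2 with sensible ties", {
  s <- small_study(55)
  snps <- s$study$stats$snp[1:15]
  single <- select_best_threshold(s$study, snps, s$y_target, grid = 1)
  expect_equal(single$threshold, 1)
  full <- fit_association(s$y_target, compute_prs(s$study, snps, 1))
  expect_equal(single$association$r2, full$r2)
  dup <- select_best_threshold(s$study, snps, s$y_target,
                               grid = c(0.5, 1, 1, 0.5))
  base <- select_best_threshold(s$study, snps, s$y_target, grid = c(0.5, 1))
  expect_equal(dup$threshold, base$threshold)
  expect_equal(dup$association$r2, base$association$r2)
  expect_error(select_best_threshold(s$study, snps, s$y_target,
                                     grid = numeric(0)), "empty")
})

test_that("thresholding recovers the informative cut in a power simulation", {
  # only SNPs with small GWAS P are truly predictive; 0.05 should beat 1.0
  wins <- 0
  for (seed in 1:12) {
    set.seed(seed)
    n <- 300
    sig <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
    noise <- matrix(rbinom(n * 24, 2, 0.3), n, 24)
    D <- cbind(sig, noise)
    colnames(D) <- paste0("v", 1:32)
    panel <- genotype_panel(D, data.frame(snp = colnames(D), chr = "1",
                                          pos = 1:32 * 1e6, a1 = "A", a2 = "G"))
    beta <- c(rep(0.4, 8), rnorm(24, 0, 0.4))
    pval <- c(runif(8, 1e-6, 0.04), runif(24, 0.06, 1))
    study <- harmonize(summary_stats(data.frame(snp = colnames(D), a1 = "A",
                                                a2 = "G", beta = beta,
                                                p = pval)), panel)
    y <- as.numeric(scale(sig %*% rep(0.4, 8))) + rnorm(n, 0, 1)
    best <- select_best_threshold(study, colnames(D), y, grid = c(0.05, 1))
    if (best$threshold == 0.05) wins <- wins + 1
  }
  expect_gte(wins / 12, 0.9)
})
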