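test_that("dosage TSV reading computes MAF from the written data", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("sample\trs1\trs2",
               "s1\t0\t0",
               "s2\t1\t0",
               "s3\t2\t2"), tmp)
  panel <- read_genotypes(tmp, format = "dosage")
  # column sums 3 and 2 over 3 samples: allele freqs 0.5 and 1/3
  expect_equal(unname(panel$maf), c(0.5, 1 / 3), tolerance = 1e-12)
  expect_equal(unname(panel$missingness), c(0, 0))
})

test_that("panels round-trip through both writers", {
  panel <- toy_panel()
  tsv <- tempfile(fileext = ".tsv"); mapf <- tempfile(fileext = ".map")
  write_dosage_tsv(panel, tsv, map_path = mapf)
  back <- read_genotypes(tsv, format = "dosage",
                         map = utils::read.table(mapf, header = TRUE,
                                                 colClasses = "character"))
  expect_equal(unname(back$dosage), unname(panel$dosage))
  expect_equal(back$map$snp, panel$map$snp)

  pre <- tempfile()
  write_plink1(panel, pre)
  back2 <- read_genotypes(pre, format = "plink1")
  expect_equal(unname(back2$dosage), unname(panel$dosage))
  expect_equal(back2$map$a1, panel$map$a1)
  expect_equal(back2$map$pos, panel$map$pos)
})

test_that("plink reader rejects malformed bed files", {
  panel <- toy_panel()
  pre <- tempfile()
  write_plink1(panel, pre)
  raw <- readBin(paste0(pre, ".bed"), "raw", 100)
  writeBin(c(raw, as.raw(0)), paste0(pre, ".bed"))   # wrong length
  expect_error(read_genotypes(pre, format = "plink1"), "inconsistent")
  writeBin(as.raw(c(0, 0, 1, raw[-(1:3)])), paste0(pre, ".bed"))
  expect_error(read_genotypes(pre, format = "plink1"), "magic")
})

test_that("panel construction enforces invariants", {
  map <- data.frame(snp = c("a", "a"), chr = "1", pos = c(1, 2),
                    a1 = "A", a2 = "G")
  expect_error(genotype_panel(matrix(0, 2, 2), map), "duplicate")
  map2 <- data.frame(snp = c("a", "b"), chr = "1", pos = c(1, 2),
                     a1 = "A", a2 = "G")
  expect_error(genotype_panel(matrix(c(0, 3), 1, 2), map2), "\\[0, 2\\]")
  map2$pos <- c(0L, 2L)
  expect_error(genotype_panel(matrix(0, 1, 2), map2), "positive")
})

test_that("hwe_exact_midp matches an independent enumeration oracle", {
  cases <- list(c(25, 50, 25), c(10, 20, 70), c(0, 10, 90), c(40, 20, 40),
                c(3, 5, 2), c(1, 0, 9))
  for (cs in cases)
    expect_equal(hwe_exact_midp(cs[1], cs[2], cs[3]),
                 oracle_hwe_midp(cs[1], cs[2], cs[3]), tolerance = 1e-10)
  # perfect HWE proportions sit at the distribution mode
  expect_gt(hwe_exact_midp(25, 50, 25), 0.5)
})

test_that("qc_filter applies the three filters and logs reasons", {
  set.seed(7)
  n <- 100
  D <- cbind(
    good = rbinom(n, 2, 0.3),
    high_miss = replace(rbinom(n, 2, 0.3), 1:3, NA),     # missingness 0.03
    rare = rbinom(n, 2, 0.004),                          # MAF ~0.005
    hwe_bad = rep(c(0, 2), n / 2)                        # no heterozygotes
  )
  # force the intended marginal properties exactly
  D[, "rare"] <- c(1, rep(0, n - 1))                     # MAF 0.005
  map <- data.frame(snp = colnames(D), chr = "1", pos = 1:4 * 1000,
                    a1 = "A", a2 = "G")
  panel <- genotype_panel(D, map)
  out <- qc_filter(panel, miss_max = 0.02, maf_min = 0.01, hwe_p_min = 1e-8)
  expect_identical(out$map$snp, "good")
  log <- attr(out, "drop_log")
  expect_setequal(log$reason[match(c("high_miss", "rare", "hwe_bad"), log$snp)],
                  c("missingness", "maf", "hwe"))
  # HWE-perfect counts (25, 50, 25) are retained
  D2 <- cbind(rep(c(0, 1, 1, 2), 25))
  p2 <- genotype_panel(D2, data.frame(snp = "ok", chr = "1", pos = 1000,
                                      a1 = "A", a2 = "G"))
  expect_identical(qc_filter(p2)$map$snp, "ok")
  expect_error(qc_filter(panel, miss_max = 0, maf_min = 0.6), "every SNP")
})

test_that("qc_filter output does not depend on SNP order", {
  set.seed(21)
  panel <- simulate_genotypes(200, 40, seed = 3, missing_rate = 0.01)
  perm <- sample(40)
  shuffled <- genotype_panel(panel$dosage[, perm], panel$map[perm, ])
  a <- qc_filter(panel, maf_min = 0.1)
  b <- qc_filter(shuffled, maf_min = 0.1)
  expect_setequal(a$map$snp, b$map$snp)
})

test_that("summary statistics reader converts OR and drops invalid rows", {
  tmp <- tempfile()
  writeLines(c("SNP\tA1\tA2\tOR\tP",
               "rs1\tA\tG\t1.0\t0.5",
               "rs2\tA\tC\t2.0\t0.01",
               "rs3\tT\tC\t1.5\t0"), tmp)
  ss <- read_summary_stats(tmp, column_map = c(snp = "SNP", a1 = "A1",
                                               a2 = "A2", or = "OR", p = "P"))
  expect_equal(ss$beta[ss$snp == "rs1"], 0)
  expect_equal(ss$beta[ss$snp == "rs2"], log(2))
  expect_false("rs3" %in% ss$snp)          # P = 0 outside (0, 1]
  expect_equal(attr(ss, "drop_log")$snp, "rs3")
  expect_error(read_summary_stats(tmp, column_map = c(snp = "SNP", a1 = "A1",
                                                      a2 = "A2", p = "P")),
               "effect column")

  writeLines(c("SNP\tA1\tA2\tBETA\tP",
               "rs1\tA\tG\t0.1\t0.5",
               "rs1\tA\tC\t0.2\t0.1"), tmp)
  expect_error(read_summary_stats(tmp, column_map = c(snp = "SNP", a1 = "A1",
                                                      a2 = "A2", beta = "BETA",
                                                      p = "P")),
               "rs1")
})

test_that("summary statistics round-trip through the TSV writer", {
  ss <- summary_stats(data.frame(snp = c("rs1", "rs2"), chr = "1",
                                 pos = c(10L, 20L), a1 = c("A", "T"),
                                 a2 = c("G", "C"), beta = c(0.2, -0.1),
                                 p = c(0.5, 0.01), n = 100))
  tmp <- tempfile()
  write_summary_stats(ss, tmp)
  back <- read_summary_stats(tmp, column_map = c(snp = "snp", chr = "chr",
                                                 pos = "pos", a1 = "a1",
                                                 a2 = "a2", beta = "beta",
                                                 p = "p", n = "n"))
  expect_equal(back$beta, ss$beta)
  expect_equal(back$p, ss$p)
})

test_that("harmonize drops ambiguous/mismatched SNPs and aligns beta signs", {
  D <- matrix(1, 2, 4)
  map <- data.frame(snp = paste0("rs", 1:4), chr = "1", pos = 1:4 * 1000,
                    a1 = c("A", "A", "A", "A"), a2 = c("G", "G", "C", "G"))
  panel <- genotype_panel(D, map)
  ss <- summary_stats(data.frame(
    snp = paste0("rs", 1:5),
    a1 = c("A", "G", "A", "T", "A"), a2 = c("T", "A", "G", "C", "G"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5), p = rep(0.5, 5)))
  hs <- harmonize(ss, panel)
  # rs1 ambiguous (A/T); rs3 mismatched (A/G vs A/C); rs5 not in panel
  expect_setequal(hs$stats$snp, c("rs2", "rs4"))
  # rs2: stats effect allele G equals panel A2 (other allele A) -> beta flipped
  expect_equal(hs$stats$beta[hs$stats$snp == "rs2"], -0.2)
  # rs4: stats T/C complements to A/G = panel orientation -> kept, same sign
  expect_equal(hs$stats$beta[hs$stats$snp == "rs4"], 0.4)
  expect_true(all(c("ambiguous", "allele mismatch") %in% hs$drop_log$reason))

  # idempotence: re-harmonizing its own output changes nothing
  hs2 <- harmonize(hs$stats, hs$panel)
  expect_equal(hs2$stats$beta, hs$stats$beta)
  expect_identical(hs2$stats$snp, hs$stats$snp)
  expect_identical(hs2$panel$dosage, hs$panel$dosage)

  ss_disjoint <- summary_stats(data.frame(snp = "zz", a1 = "A", a2 = "G",
                                          beta = 0.1, p = 0.5))
  expect_error(harmonize(ss_disjoint, panel), "shared")
})
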