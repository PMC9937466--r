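#' Construct a genotype panel
#'
#' A genotype panel holds additive allele dosages (copies of the counted
#' allele A1, values in \[0, 2\], missing allowed) for a set of samples and
#' SNPs, together with the variant map and per-SNP summaries (minor-allele
#' frequency, missingness) computed from the data.
#'
#' @param dosage numeric matrix, samples x SNPs; values in \[0, 2\] or `NA`.
#' @param map data.frame with columns `snp`, `chr`, `pos`, `a1`, `a2`
#'   (1-based positions; A1 is the counted allele).
#' @param sample_id optional character vector of sample identifiers;
#'   defaults to the dosage row names or `S1..Sn`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `map`, `sample_id`, `maf`, `missingness`.
#' @export
genotype_panel <- function(dosage, map, sample_id = NULL) {
  dosage <- as.matrix(dosage)
  # integer storage (hard calls) is kept as-is to halve the memory footprint
  if (!storage.mode(dosage) %in% c("double", "integer"))
    storage.mode(dosage) <- "double"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp", "chr", "pos", "a1", "a2")
  if (!all(need %in% names(map)))
    stop("map must have columns: ", paste(need, collapse = ", "))
  map$snp <- as.character(map$snp)
  map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$snp))
    stop("duplicate SNP id(s): ",
         paste(unique(map$snp[duplicated(map$snp)]), collapse = ", "))
  if (ncol(dosage) != nrow(map))
    stop("dosage has ", ncol(dosage), " columns but map has ", nrow(map), " SNPs")
  if (any(map$pos <= 0L, na.rm = TRUE)) stop("SNP positions must be strictly positive")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2] (or be missing)")
  if (is.null(sample_id)) sample_id <- rownames(dosage)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(dosage)))
  dimnames(dosage) <- list(sample_id, map$snp)

  af <- colMeans(dosage, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  structure(list(
    dosage = dosage,
    map = map,
    sample_id = as.character(sample_id),
    maf = pmin(af, 1 - af),
    missingness = colMeans(is.na(dosage))
  ), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", length(x$sample_id), " samples x ",
      nrow(x$map), " SNPs\n", sep = "")
  cat("  chromosomes:", paste(unique(x$map$chr), collapse = ", "), "\n")
  cat(sprintf("  MAF range: %.3f-%.3f; mean missingness: %.4f\n",
              suppressWarnings(min(x$maf, na.rm = TRUE)),
              suppressWarnings(max(x$maf, na.rm = TRUE)),
              mean(x$missingness)))
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$sample_id)

#' @rdname n_samples
#' @export
n_snps <- function(panel) nrow(panel$map)

# 2-bit PLINK-1 genotype codes -> A1 dosage (00 hom A1, 10 het, 11 hom A2,
# 01 missing), SNP-major layout.
.plink_decode_table <- function() {
  tab <- matrix(NA_real_, 256, 4)
  for (b in 0:255) {
    for (k in 0:3) {
      code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
      tab[b + 1, k + 1] <- switch(code + 1L, 2, NA_real_, 1, 0)
    }
  }
  tab
}

.read_plink1 <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim"); fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  bimdf <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("chr", "snp", "cm", "pos", "a1", "a2"),
                             colClasses = c("character", "character", "numeric",
                                            "integer", "character", "character"))
  famdf <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(famdf); m <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.info(bed)$size)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK-1 bed file (bad magic bytes): ", bed)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major bed files are supported")
  bpv <- ceiling(n / 4)
  if (length(raw) != 3 + bpv * m)
    stop("bed file length ", length(raw), " inconsistent with ", n,
         " samples x ", m, " SNPs")
  tab <- .plink_decode_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  D <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    g <- tab[body[, j] + 1L, , drop = FALSE]  # bpv x 4, row-wise sample order
    D[, j] <- as.vector(t(g))[seq_len(n)]
  }
  genotype_panel(D, bimdf[, c("snp", "chr", "pos", "a1", "a2")],
                 sample_id = as.character(famdf[[2]]))
}

.read_dosage_tsv <- function(path, map = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("dosage TSV needs a sample id column plus >= 1 SNP column")
  ids <- as.character(df[[1]])
  D <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(D) <- "double"
  snps <- colnames(D)
  if (is.null(map)) {
    # Minimal map for matrix-only input: ids must be resolvable later; use
    # placeholder coordinates on one chromosome in column order.
    map <- data.frame(snp = snps, chr = "1", pos = seq_along(snps),
                      a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  }
  genotype_panel(D, map, sample_id = ids)
}

#' Read target genotypes
#'
#' Reads a genotype panel either from a PLINK-1 fileset (`prefix.bed/.bim/.fam`,
#' SNP-major 2-bit coding) or from a plain dosage TSV (header row: sample id
#' column followed by one column per SNP; one row per sample; dosages in
#' \[0, 2\], `NA` for missing).
#'
#' @param path file path: the PLINK prefix (without extension) or the TSV file.
#' @param format `"plink1"` or `"dosage"`.
#' @param map optional variant map for dosage TSVs (columns `snp`, `chr`,
#'   `pos`, `a1`, `a2`); a placeholder map is built when omitted.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("plink1", "dosage"), map = NULL) {
  format <- match.arg(format)
  switch(format,
         plink1 = .read_plink1(path),
         dosage = .read_dosage_tsv(path, map = map))
}

#' Write a panel as a dosage TSV
#'
#' @param panel a `genotype_panel`.
#' @param path output file.
#' @param map_path optional path for a side-car variant map TSV so that a
#'   round-trip preserves coordinates and alleles.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(panel, path, map_path = NULL) {
  df <- data.frame(sample = panel$sample_id, panel$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(panel$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a panel as a PLINK-1 fileset
#'
#' Dosages must be hard calls (0/1/2 or missing); fractional dosages are
#' rejected rather than silently rounded.
#'
#' @param panel a `genotype_panel`.
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#' @return `prefix`, invisibly.
#' @export
write_plink1 <- function(panel, prefix) {
  D <- panel$dosage
  if (any(abs(D - round(D)) > 1e-9, na.rm = TRUE))
    stop("write_plink1 requires hard-call dosages (0/1/2)")
  n <- nrow(D); m <- ncol(D)
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(D) & round(D) == 2] <- 0L
  code[!is.na(D) & round(D) == 1] <- 2L
  code[!is.na(D) & round(D) == 0] <- 3L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  bytes <- raw(3 + bpv * m)
  bytes[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(m)) {
    cj <- c(code[, j], rep(0L, pad))
    q <- matrix(cj, nrow = 4)
    b <- q[1, ] + q[2, ] * 4L + q[3, ] * 16L + q[4, ] * 64L
    bytes[3 + (j - 1) * bpv + seq_len(bpv)] <- as.raw(b)
  }
  writeBin(bytes, paste0(prefix, ".bed"))
  utils::write.table(
    data.frame(panel$map$chr, panel$map$snp, 0, panel$map$pos,
               panel$map$a1, panel$map$a2),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(panel$sample_id, panel$sample_id, 0, 0, 0, -9),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Subset a panel to a set of SNPs (in the given order)
#' @param panel a `genotype_panel`.
#' @param snps character vector of SNP ids (must exist in the panel).
#' @return A `genotype_panel`.
#' @export
subset_snps <- function(panel, snps) {
  idx <- match(snps, panel$map$snp)
  if (anyNA(idx)) stop("unknown SNP id(s): ",
                       paste(snps[is.na(idx)][1:min(5, sum(is.na(idx)))], collapse = ", "))
  genotype_panel(panel$dosage[, idx, drop = FALSE], panel$map[idx, , drop = FALSE],
                 sample_id = panel$sample_id)
}

#' Exact Hardy-Weinberg equilibrium test (mid-P)
#'
#' Exact conditional test on hard-call genotype counts, reporting the mid-P
#' value: the sum of probabilities of heterozygote counts strictly less
#' probable than the observed one, plus half the probability of outcomes
#' exactly as probable.
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom A1, het, hom A2).
#' @return mid-P value in \[0, 1\].
#' @export
hwe_exact_midp <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(NA_real_)
  n1 <- 2 * n_aa + n_ab            # copies of allele 1
  rare <- min(n1, 2 * n - n1)
  het <- seq(rare %% 2, rare, by = 2)
  logp <- het * log(2) +
    lfactorial(n) - lfactorial((rare - het) / 2) - lfactorial(het) -
    lfactorial(n - (rare + het) / 2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_ab, het)]
  if (is.na(obs)) return(NA_real_)
  tol <- 1e-12
  sum(p[p < obs - tol]) + 0.5 * sum(p[abs(p - obs) <= tol])
}

#' Genotype quality-control filter
#'
#' Removes SNPs with missingness above `miss_max`, minor-allele frequency
#' below `maf_min`, or an exact Hardy-Weinberg mid-P below `hwe_p_min`
#' (defaults match standard GWAS target QC: missingness > 0.02, MAF < 0.01,
#' HWE P < 1e-8).  HWE is tested on hard calls (dosages rounded to 0/1/2);
#' QC statistics always see the true missingness (no imputation here).
#'
#' @param panel a `genotype_panel`.
#' @param miss_max maximum tolerated missingness fraction.
#' @param maf_min minimum minor-allele frequency.
#' @param hwe_p_min minimum HWE exact mid-P.
#' @return The filtered `genotype_panel`, with a `drop_log` attribute
#'   (data.frame `snp`, `reason`).
#' @export
qc_filter <- function(panel, miss_max = 0.02, maf_min = 0.01, hwe_p_min = 1e-8) {
  stopifnot(miss_max >= 0, miss_max <= 1, maf_min >= 0, maf_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1)
  hard <- round(panel$dosage)
  hwe <- vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[, j]; g <- g[!is.na(g)]
    hwe_exact_midp(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))
  bad_miss <- panel$missingness > miss_max
  bad_maf <- is.na(panel$maf) | panel$maf < maf_min
  bad_hwe <- !is.na(hwe) & hwe < hwe_p_min
  log <- rbind(.drop_log(panel$map$snp[bad_miss], "missingness"),
               .drop_log(panel$map$snp[bad_maf & !bad_miss], "maf"),
               .drop_log(panel$map$snp[bad_hwe & !bad_miss & !bad_maf], "hwe"))
  keep <- !(bad_miss | bad_maf | bad_hwe)
  if (!any(keep)) stop("qc_filter removed every SNP")
  out <- genotype_panel(panel$dosage[, keep, drop = FALSE],
                        panel$map[keep, , drop = FALSE],
                        sample_id = panel$sample_id)
  attr(out, "drop_log") <- log
  out
}
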