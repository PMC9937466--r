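#' Read GWAS summary statistics
#'
#' Reads a whitespace/tab-delimited summary-statistics file through a column
#' map, converting odds ratios to additive log-odds effect sizes
#' (`beta = log(OR)`) when an `or` column is mapped instead of `beta`.
#' Rows with a non-finite effect size or a P-value outside (0, 1\] are
#' dropped and counted in the drop log.
#'
#' @param path input file with a header row.
#' @param column_map named character vector mapping roles to file column
#'   names.  Mandatory roles: `snp`, `a1` (effect allele), `a2`
#'   (other allele), `p`, and one of `beta` / `or`.  Optional: `chr`,
#'   `pos`, `n`.
#' @return An object of class `summary_stats`: a data.frame with columns
#'   `snp`, `chr`, `pos`, `a1`, `a2`, `beta`, `p`, `n`, carrying a
#'   `drop_log` attribute.
#' @export
read_summary_stats <- function(path,
                               column_map = c(snp = "SNP", chr = "CHR", pos = "BP",
                                              a1 = "A1", a2 = "A2", beta = "BETA",
                                              p = "P")) {
  if (!file.exists(path)) stop("missing file: ", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  mandatory <- c("snp", "a1", "a2", "p")
  if (!all(mandatory %in% names(column_map)))
    stop("column_map must define roles: ", paste(mandatory, collapse = ", "))
  if (!any(c("beta", "or") %in% names(column_map)))
    stop("column_map must define an effect column ('beta' or 'or')")
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols))
    stop("mapped column(s) absent from file: ", paste(missing_cols, collapse = ", "))

  get <- function(role) if (role %in% names(column_map)) df[[column_map[[role]]]] else NULL
  if ("beta" %in% names(column_map)) {
    beta <- as.numeric(get("beta"))
  } else {
    or <- as.numeric(get("or"))
    if (any(or <= 0, na.rm = TRUE)) stop("odds ratios must be positive")
    beta <- log(or)
  }
  out <- data.frame(
    snp = as.character(get("snp")),
    chr = if (is.null(get("chr"))) NA_character_ else as.character(get("chr")),
    pos = if (is.null(get("pos"))) NA_integer_ else as.integer(get("pos")),
    a1 = toupper(as.character(get("a1"))),
    a2 = toupper(as.character(get("a2"))),
    beta = beta,
    p = as.numeric(get("p")),
    n = if (is.null(get("n"))) NA_real_ else as.numeric(get("n")),
    stringsAsFactors = FALSE)
  summary_stats(out)
}

#' Construct a summary-statistics object
#'
#' @param df data.frame with columns `snp`, `a1`, `a2`, `beta`, `p`
#'   (optionally `chr`, `pos`, `n`).
#' @return A `summary_stats` data.frame; rows with invalid `beta`/`p` are
#'   dropped and logged in the `drop_log` attribute.
#' @export
summary_stats <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("chr", "pos", "n")) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[, c("snp", "chr", "pos", "a1", "a2", "beta", "p", "n")]
  bad <- !is.finite(df$beta) | !is.finite(df$p) | df$p <= 0 | df$p > 1
  log <- .drop_log(df$snp[bad], "invalid beta or p")
  df <- df[!bad, , drop = FALSE]
  if (any(df$a1 == df$a2)) stop("effect allele equals other allele for: ",
                                paste(utils::head(df$snp[df$a1 == df$a2]), collapse = ", "))
  if (anyDuplicated(df$snp))
    stop("duplicate SNP id(s) in summary statistics: ",
         paste(unique(df$snp[duplicated(df$snp)]), collapse = ", "))
  rownames(df) <- NULL
  structure(df, drop_log = log, class = c("summary_stats", "data.frame"))
}

#' Write summary statistics as TSV
#' @param stats a `summary_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Harmonize summary statistics with a genotype panel
#'
#' Intersects the GWAS and the target panel by SNP id, removes
#' strand-ambiguous SNPs (A/T and G/C), and expresses every retained effect
#' size for the panel's counted allele (A1): when the GWAS effect allele
#' matches the panel A2 the sign of beta is flipped; allele pairs that match
#' neither orientation are retried after strand complement and otherwise
#' dropped as mismatched.
#'
#' @param stats a `summary_stats` object.
#' @param panel a `genotype_panel`.
#' @return An object of class `harmonized_study`: list with `panel` (SNPs in
#'   harmonized order), `stats` (aligned, beta on the panel A1 allele) and
#'   `drop_log`.
#' @export
harmonize <- function(stats, panel) {
  if (nrow(stats) == 0 || n_snps(panel) == 0) stop("empty input to harmonize()")
  log <- .empty_drop_log()

  amb <- .is_ambiguous(stats$a1, stats$a2)
  log <- rbind(log, .drop_log(stats$snp[amb], "ambiguous"))
  stats <- stats[!amb, , drop = FALSE]

  common <- intersect(stats$snp, panel$map$snp)
  log <- rbind(log, .drop_log(setdiff(stats$snp, common), "absent from panel"))
  log <- rbind(log, .drop_log(setdiff(panel$map$snp, common), "absent from GWAS"))
  if (length(common) == 0) stop("no SNPs shared between summary statistics and panel")

  s <- stats[match(common, stats$snp), , drop = FALSE]
  m <- panel$map[match(common, panel$map$snp), , drop = FALSE]

  same <- s$a1 == m$a1 & s$a2 == m$a2
  flip <- s$a1 == m$a2 & s$a2 == m$a1
  csa1 <- unname(.COMPLEMENT[s$a1]); csa2 <- unname(.COMPLEMENT[s$a2])
  same2 <- !same & !flip & !is.na(csa1) & csa1 == m$a1 & csa2 == m$a2
  flip2 <- !same & !flip & !is.na(csa1) & csa1 == m$a2 & csa2 == m$a1
  keep <- same | flip | same2 | flip2
  log <- rbind(log, .drop_log(common[!keep], "allele mismatch"))

  s <- s[keep, , drop = FALSE]
  s$beta <- ifelse(flip[keep] | flip2[keep], -s$beta, s$beta)
  m <- m[keep, , drop = FALSE]
  s$a1 <- m$a1; s$a2 <- m$a2   # record the orientation actually scored

  out_panel <- subset_snps(panel, m$snp)
  rownames(s) <- NULL
  structure(list(panel = out_panel,
                 stats = structure(s, class = c("summary_stats", "data.frame")),
                 drop_log = log),
            class = "harmonized_study")
}

#' @export
print.harmonized_study <- function(x, ...) {
  cat("<harmonized_study> ", length(x$panel$sample_id), " samples x ",
      nrow(x$stats), " harmonized SNPs (", nrow(x$drop_log), " dropped)\n", sep = "")
  invisible(x)
}
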