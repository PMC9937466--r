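#' Gene expression specificity
#'
#' Divides the expression of each gene by its total expression across
#' tissues, so specificity ranges from 0 (not expressed in the tissue) to 1
#' (exclusively expressed there) and each gene's specificities sum to 1.
#' Genes not expressed in any tissue must be removed beforehand.
#'
#' @param expression non-negative numeric matrix, genes x tissues, with
#'   dimnames.
#' @return An object of class `specificity_matrix`: the row-normalized
#'   matrix.
#' @export
compute_specificity <- function(expression) {
  expression <- as.matrix(expression)
  if (any(expression < 0, na.rm = TRUE)) stop("expression must be non-negative")
  tot <- rowSums(expression)
  if (any(tot == 0))
    stop("gene(s) not expressed in any tissue; filter them first: ",
         paste(utils::head(rownames(expression)[tot == 0]), collapse = ", "))
  structure(expression / tot, class = c("specificity_matrix", "matrix", "array"))
}

#' Expression-specificity quantile gene sets
#'
#' Per tissue, splits genes into `n_quantiles` groups of increasing
#' expression specificity: quantile 1 contains exactly the genes with zero
#' expression in that tissue; the remaining genes are divided into
#' `n_quantiles - 1` equal-count bins by specificity (ties and bin
#' boundaries resolved by ascending specificity then gene id, assigning
#' ties to the lower bin), so the top quantile holds the most specifically
#' expressed genes.  Each bin becomes one gene set named `tissue@qK`.
#'
#' @param spec a `specificity_matrix`.
#' @param n_quantiles number of quantiles (default 11).
#' @return A [gene_set_collection()] with one set per tissue and quantile.
#' @export
build_quantile_sets <- function(spec, n_quantiles = 11) {
  stopifnot(n_quantiles >= 2)
  sets <- list()
  for (tis in colnames(spec)) {
    v <- spec[, tis]
    zero <- names(v)[v == 0]
    posg <- names(v)[v > 0]
    if (length(posg) == 0) stop("all genes have zero expression in tissue ", tis)
    nbins <- n_quantiles - 1
    if (length(posg) < nbins)
      stop("tissue ", tis, " has fewer expressed genes (", length(posg),
           ") than bins (", nbins, ")")
    ord <- posg[order(v[posg], posg)]
    # equal-count bins (sizes differ by at most one when counts don't
    # divide evenly); ties resolved by the (specificity, gene id) sort
    bin <- ceiling(seq_along(ord) * nbins / length(ord))
    if (length(zero)) sets[[paste0(tis, "@q1")]] <- zero
    for (b in seq_len(nbins))
      sets[[paste0(tis, "@q", b + 1)]] <- ord[bin == b]
  }
  gene_set_collection(sets, source = "specificity")
}

#' Top-quantile enrichment readout
#'
#' Reports the competitive P-value of the gene set made of the genes in the
#' top expression-specificity quantile for a tissue.
#'
#' @param enrichment a `prset_enrichment` (or data.frame with `pathway` and
#'   `p_competitive`).
#' @param tissue tissue name.
#' @param n_quantiles number of quantiles used when building the sets.
#' @return The competitive P-value of `tissue@q<n_quantiles>`.
#' @export
top_quantile_test <- function(enrichment, tissue, n_quantiles = 11) {
  nm <- paste0(tissue, "@q", n_quantiles)
  i <- match(nm, enrichment$pathway)
  if (is.na(i)) stop("no enrichment result for ", nm)
  enrichment$p_competitive[i]
}

#' Linear trend enrichment readout
#'
#' Fits an ordinary least-squares regression of the -log10 competitive
#' P-values of the quantile gene sets on the quantile ranks and reports the
#' one-sided P-value for a positive slope (signal increasing with
#' expression specificity).
#'
#' @param p_competitive competitive P-values across quantiles.
#' @param ranks quantile ranks (same length, >= 3 values).
#' @return One-sided P-value for slope > 0 (0.5 with a warning when the
#'   dependent values are constant).
#' @export
linear_trend_test <- function(p_competitive, ranks = seq_along(p_competitive)) {
  if (length(p_competitive) < 3) stop("need at least 3 quantile results")
  yl <- -log10(p_competitive)
  if (stats::sd(yl) == 0) {
    warning("constant -log10 competitive P across quantiles; P = 0.5")
    return(0.5)
  }
  fit <- stats::lm(yl ~ ranks)
  sm <- summary(fit)$coefficients
  tval <- sm["ranks", "t value"]
  stats::pt(tval, df = fit$df.residual, lower.tail = FALSE)
}

#' Rank-normalized gene relevance scores and pathway relevance
#'
#' Given raw per-gene relevance scores (e.g. literature-derived disease
#' scores; genes without a score count as 0), ranks the `n` scored genes
#' and assigns each the normalized score `(r + 1)/(n + 1)`, where `r` is
#' the gene's rank.  Under the default ascending convention the
#' highest-scoring gene has `r = n` and normalized score 1 (the opposite
#' reading of the rank direction is available via `direction`).  A
#' pathway's relevance score is the mean normalized score over its member
#' genes (unscored members contribute 0), which accounts for pathway size.
#'
#' @param raw_scores named non-negative numeric vector of raw scores for the
#'   scored genes.
#' @param sets a `gene_set_collection`.
#' @param direction `"ascending"` (largest raw score gets r = n, default) or
#'   `"descending"`.
#' @return List with `genes` (data.frame `gene`, `raw`, `normalized`) and
#'   `pathways` (named numeric pathway relevance scores).
#' @export
relevance_scores <- function(raw_scores, sets,
                             direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  if (any(raw_scores < 0)) stop("raw scores must be >= 0")
  if (is.null(names(raw_scores))) stop("raw_scores must be named by gene")
  n <- length(raw_scores)
  r <- rank(raw_scores, ties.method = "average")
  if (direction == "descending") r <- n + 1 - r
  norm <- pmin((r + 1) / (n + 1), 1)
  lookup <- stats::setNames(norm, names(raw_scores))
  pw <- vapply(sets$sets, function(g) {
    v <- lookup[g]; v[is.na(v)] <- 0
    mean(v)
  }, numeric(1))
  list(genes = data.frame(gene = names(raw_scores), raw = unname(raw_scores),
                          normalized = unname(norm), stringsAsFactors = FALSE),
       pathways = pw)
}

#' Kendall rank agreement (tau-b)
#'
#' Tie-corrected Kendall correlation, used to compare inferred pathway
#' enrichment (-log10 competitive P) with an external pathway ranking.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return Kendall tau-b; `NA` with a warning when either input is all-tied.
#' @export
kendall_agreement <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("all-tied input; Kendall tau undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

#' Fisher's method for combining P-values
#'
#' Combines k independent P-values via `X2 = -2 * sum(log p)` referred to a
#' chi-square distribution with 2k degrees of freedom.
#'
#' @param p P-values in (0, 1].
#' @return Combined P-value.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) stop("no P-values to combine")
  stopifnot(all(p > 0), all(p <= 1))
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}
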