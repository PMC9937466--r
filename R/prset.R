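#' Fit pathway polygenic risk scores with competitive enrichment
#'
#' The central fitting function: from a harmonized study (GWAS effect sizes
#' aligned to a target genotype panel), gene models and gene sets, it
#' builds SNP-by-pathway membership, performs pathway-aware LD clumping,
#' computes one standardized PRS per pathway per individual
#' (`PRS_ik = sum_j beta_j G_ij` over the pathway's clumped SNPs), tests
#' each pathway PRS against the (residualized) phenotype, and attaches an
#' empirical competitive P-value per pathway from size-matched null SNP
#' sets drawn from the clumped genic background.
#'
#' @param study a `harmonized_study` (see [harmonize()]).
#' @param genes a raw `gene_table`; extended internally by
#'   `upstream_bp`/`downstream_bp`.
#' @param sets a `gene_set_collection`.
#' @param phenotype numeric outcome per panel individual (binary outcomes
#'   are residualized on `covariates` through a logistic fit).
#' @param covariates optional covariate data.frame.
#' @param family `"linear"` or `"logistic"` residualization of the
#'   phenotype; `"auto"` picks logistic for 0/1 outcomes with covariates.
#' @param n_perm permutations for competitive P-values (default 10000).
#' @param upstream_bp,downstream_bp gene-window extension (35 kb / 10 kb).
#' @param exclude exclusion regions, e.g. [default_exclusions()].
#' @param r2_threshold,window_bp,p_ceiling clumping parameters.
#' @param min_genes,max_genes pathway size filter (10-2000 genes).
#' @param standardize standardize score columns (mean 0, sd 1)?
#' @param seed integer seed for the permutation null.
#' @return An object of class `prset`: list with `scores`
#'   (a `pathway_scores` matrix), `enrichment` (a `prset_enrichment`),
#'   `clump`, `flags`, `phenotype` (the residualized outcome), `call`.
#' @seealso [enrich_all()], [clump_pathways()], [stratify_subtypes()]
#' @export
prset <- function(study, genes, sets, phenotype, covariates = NULL,
                  family = c("auto", "linear", "logistic"),
                  n_perm = 10000, upstream_bp = 35000, downstream_bp = 10000,
                  exclude = NULL, r2_threshold = 0.1, window_bp = 250000,
                  p_ceiling = 1, min_genes = 10, max_genes = 2000,
                  standardize = TRUE, seed = NULL) {
  family <- match.arg(family)
  if (family == "auto")
    family <- if (all(phenotype %in% c(0, 1)) && !is.null(covariates))
      "logistic" else "linear"
  y <- if (is.null(covariates) && family == "linear") as.numeric(phenotype)
  else residualize_phenotype(phenotype, covariates, family)

  ext <- extend_gene_bounds(genes, upstream_bp, downstream_bp)
  flags <- build_membership(study, ext, sets, exclude = exclude,
                            min_genes = min_genes, max_genes = max_genes)
  clump <- clump_pathways(study, flags, r2_threshold = r2_threshold,
                          window_bp = window_bp, p_ceiling = p_ceiling)
  enr <- enrich_all(study, flags, y, N = n_perm, seed = seed, clump = clump)
  scores <- pathway_scores(study, clump, thresholds = 1,
                           standardize = standardize)
  structure(list(scores = scores, enrichment = enr, clump = clump,
                 flags = flags, phenotype = y, call = match.call()),
            class = "prset")
}

#' @export
print.prset <- function(x, ...) {
  cat("Pathway PRS fit\n")
  cat("  individuals: ", nrow(x$scores), "\n", sep = "")
  cat("  pathways scored: ", ncol(x$scores), "\n", sep = "")
  cat("  background SNPs: ", length(x$clump$background), "\n", sep = "")
  top <- utils::head(x$enrichment, 3)
  cat("  top pathways (competitive P): ",
      paste(sprintf("%s (%.3g)", top$pathway, top$p_competitive),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.prset <- function(object, ...) {
  e <- object$enrichment
  out <- data.frame(pathway = e$pathway, m = e$m, p_observed = e$p_observed,
                    p_competitive = e$p_competitive, stringsAsFactors = FALSE)
  class(out) <- c("summary.prset", "data.frame")
  out
}

#' @export
print.summary.prset <- function(x, ...) {
  cat("Competitive pathway enrichment (", nrow(x), " pathways)\n", sep = "")
  print.data.frame(utils::head(x, 15), digits = 4)
  if (nrow(x) > 15) cat("  ...\n")
  invisible(x)
}

#' Per-pathway association coefficients of a prset fit
#' @param object a `prset` fit.
#' @param ... unused.
#' @return Named numeric: the competitive P-value per pathway (the fit's
#'   primary per-pathway statistic).
#' @export
coef.prset <- function(object, ...) {
  stats::setNames(object$enrichment$p_competitive, object$enrichment$pathway)
}

#' Pathway scores for new individuals
#'
#' Computes the fitted pathway PRSs (same clumped SNP sets and thresholds)
#' for a new harmonized study sharing the fit's SNP index.
#'
#' @param object a `prset` fit.
#' @param newstudy a `harmonized_study` for the new individuals (omit to
#'   return the fitted score matrix).
#' @param ... unused.
#' @return A `pathway_scores` matrix.
#' @export
predict.prset <- function(object, newstudy = NULL, ...) {
  if (is.null(newstudy)) return(object$scores)
  pathway_scores(newstudy, object$clump,
                 thresholds = attr(object$scores, "thresholds"),
                 standardize = attr(object$scores, "standardized"))
}

#' Plot competitive enrichment of a prset fit
#' @param x a `prset` fit.
#' @param top number of pathways displayed.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the plotted heights.
#' @export
plot.prset <- function(x, top = 20, ...) {
  e <- utils::head(x$enrichment, top)
  h <- -log10(e$p_competitive)
  graphics::barplot(rev(h), horiz = TRUE, names.arg = rev(e$pathway),
                    las = 1, xlab = expression(-log[10] ~ "competitive P"),
                    cex.names = 0.6, ...)
  invisible(h)
}
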