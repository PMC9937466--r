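#' Pathway-aware LD clumping (bit-flag single pass)
#'
#' Performs greedy P-value-ordered LD clumping independently within every
#' pathway and within the genic background, using a single bit-flag pass:
#' each SNP carries one membership bit per pathway, and an index SNP clears
#' the bits of linked SNPs (same chromosome, within `window_bp`, squared
#' Pearson correlation of mean-imputed dosages >= `r2_threshold`) only for
#' the pathways the index itself currently belongs to.  The result is
#' exactly the set of SNPs that per-pathway greedy clumping would retain:
#' repeatedly take the unclumped member SNP with the smallest GWAS P (<=
#' `p_ceiling`) as index and drop linked members.  Ties on P are broken by
#' genomic position, then SNP id.  SNPs stripped of every membership are
#' absent from all retained lists.
#'
#' @param study a `harmonized_study`.
#' @param flags a `membership_flags` built on the same study.
#' @param r2_threshold LD pruning threshold (default 0.1).
#' @param window_bp clumping window in bp (default 250 kb).
#' @param p_ceiling only SNPs with GWAS P <= this value take part (default 1).
#' @return An object of class `clump_result`: list with `retained` (named
#'   list of SNP-id vectors per pathway), `background` (retained genic SNP
#'   ids), and `params`.
#' @export
clump_pathways <- function(study, flags, r2_threshold = 0.1,
                           window_bp = 250000, p_ceiling = 1) {
  stopifnot(window_bp > 0, r2_threshold >= 0, p_ceiling > 0, p_ceiling <= 1)
  map <- study$panel$map
  stopifnot(identical(flags$snp, map$snp))
  pvals <- study$stats$p

  in_universe <- (flags$background | rowSums(flags$membership) > 0) & pvals <= p_ceiling
  u <- which(in_universe)
  paths <- colnames(flags$membership)
  if (length(u) == 0) {
    empty <- stats::setNames(rep(list(character()), length(paths)), paths)
    return(structure(list(retained = empty, background = character(),
                          params = list(r2_threshold = r2_threshold,
                                        window_bp = window_bp,
                                        p_ceiling = p_ceiling)),
                     class = "clump_result"))
  }

  A <- cbind(flags$membership[u, , drop = FALSE],
             `.background` = flags$background[u])
  pos <- map$pos[u]; chr <- map$chr[u]; ids <- map$snp[u]; pv <- pvals[u]

  # standardized mean-imputed dosages for LD
  Z <- .impute_mean(study$panel$dosage[, u, drop = FALSE])
  Z <- scale(Z)
  Z[is.na(Z)] <- 0  # monomorphic: zero vector, r2 = 0 with everything
  nind <- nrow(Z)

  # per-chromosome position-sorted views for window lookups
  ord_chr <- split(seq_along(u), chr)
  ord_chr <- lapply(ord_chr, function(ix) ix[order(pos[ix])])
  chr_rank <- integer(length(u))   # rank of each SNP inside its chromosome
  for (ix in ord_chr) chr_rank[ix] <- seq_along(ix)

  visit <- order(pv, pos, ids)
  for (i in visit) {
    bits <- A[i, ]
    if (!any(bits)) next
    cvec <- ord_chr[[chr[i]]]
    p0 <- pos[i]
    lo <- findInterval(p0 - window_bp - 0.5, pos[cvec]) + 1L
    hi <- findInterval(p0 + window_bp + 0.5, pos[cvec])
    nb <- cvec[lo:hi]
    nb <- nb[nb != i]
    if (length(nb) == 0) next
    alive <- rowSums(A[nb, which(bits), drop = FALSE]) > 0
    nb <- nb[alive]
    if (length(nb) == 0) next
    r <- crossprod(Z[, i], Z[, nb, drop = FALSE]) / (nind - 1)
    hit <- nb[as.vector(r)^2 >= r2_threshold]
    if (length(hit)) A[hit, bits] <- FALSE
  }

  retained <- lapply(paths, function(k) ids[A[, k]])
  names(retained) <- paths
  structure(list(retained = retained,
                 background = ids[A[, ".background"]],
                 params = list(r2_threshold = r2_threshold,
                               window_bp = window_bp, p_ceiling = p_ceiling)),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("<clump_result> ", length(x$retained), " pathways; background: ",
      length(x$background), " independent genic SNPs\n", sep = "")
  cat(sprintf("  r2 >= %.3g within %d bp, P ceiling %.3g\n",
              x$params$r2_threshold, x$params$window_bp, x$params$p_ceiling))
  invisible(x)
}

#' Compute a polygenic risk score
#'
#' PRS of individual i over the retained SNP set: sum over SNPs j with GWAS
#' P <= `threshold` of `beta_j * G_ij`, with missing dosages mean-imputed at
#' scoring time.
#'
#' @param study a `harmonized_study`.
#' @param retained character vector of SNP ids (e.g. one pathway's clumped set).
#' @param threshold GWAS P-value threshold (default 1: no thresholding).
#' @return Numeric score vector (one per individual) with attribute
#'   `n_snps`, the number of SNPs actually summed.
#' @export
compute_prs <- function(study, retained, threshold = 1) {
  idx <- match(retained, study$stats$snp)
  if (anyNA(idx)) stop("retained SNP(s) not in study: ",
                       paste(utils::head(retained[is.na(idx)]), collapse = ", "))
  idx <- idx[study$stats$p[idx] <= threshold]
  n <- length(study$panel$sample_id)
  if (length(idx) == 0) {
    warning("no SNP passes threshold ", threshold, "; returning zero scores")
    return(structure(stats::setNames(rep(0, n), study$panel$sample_id), n_snps = 0L))
  }
  D <- .impute_mean(study$panel$dosage[, idx, drop = FALSE])
  sc <- as.vector(D %*% study$stats$beta[idx])
  structure(stats::setNames(sc, study$panel$sample_id), n_snps = length(idx))
}

#' Pathway score matrix
#'
#' Computes the individuals-by-pathways PRS matrix from a clumping result,
#' one column per pathway at the given per-pathway P-value threshold(s).
#'
#' @param study a `harmonized_study`.
#' @param clump a `clump_result`.
#' @param thresholds single threshold or named vector (per pathway);
#'   default 1.
#' @param standardize standardize columns to mean 0 / sd 1 (default TRUE)?
#' @return Numeric matrix with attributes `thresholds` and `standardized`;
#'   class `pathway_scores`.
#' @export
pathway_scores <- function(study, clump, thresholds = 1, standardize = TRUE) {
  paths <- names(clump$retained)
  if (length(thresholds) == 1 && is.null(names(thresholds)))
    thresholds <- stats::setNames(rep(thresholds, length(paths)), paths)
  if (!all(paths %in% names(thresholds)))
    stop("thresholds missing for some pathways")
  S <- matrix(0, length(study$panel$sample_id), length(paths),
              dimnames = list(study$panel$sample_id, paths))
  for (k in paths) {
    if (length(clump$retained[[k]]) == 0) next
    S[, k] <- suppressWarnings(compute_prs(study, clump$retained[[k]], thresholds[[k]]))
  }
  out <- structure(S, thresholds = thresholds[paths], standardized = FALSE,
                   class = c("pathway_scores", "matrix", "array"))
  if (standardize) out <- standardize_scores(out) else out
}

#' Standardize a score matrix
#'
#' Column-wise z-scores using the sample (n-1) standard deviation.  Constant
#' columns are set to 0 with a warning.  Idempotent.
#'
#' @param scores numeric matrix (individuals x pathways).
#' @return The standardized matrix (attribute `standardized = TRUE`).
#' @export
standardize_scores <- function(scores) {
  m <- colMeans(scores)
  s <- apply(scores, 2, stats::sd)
  const <- !is.finite(s) | s == 0
  if (any(const))
    warning("constant score column(s) set to 0: ",
            paste(colnames(scores)[const], collapse = ", "))
  s[const] <- 1
  out <- sweep(sweep(scores, 2, m, "-"), 2, s, "/")
  out[, const] <- 0
  attrs <- attributes(scores)
  for (a in setdiff(names(attrs), c("dim", "dimnames")))
    attr(out, a) <- attrs[[a]]
  attr(out, "standardized") <- TRUE
  class(out) <- class(scores)
  out
}

#' Residualize a phenotype on covariates
#'
#' Regresses the outcome on the covariates and returns residuals to be used
#' as the outcome of downstream PRS association models.  Binary outcomes use
#' a covariate-only logistic fit and return its pseudo residuals (deviance
#' residuals by default; response residuals behind `type`).
#'
#' @param pheno numeric outcome (0/1 for `family = "logistic"`).
#' @param covariates data.frame/matrix of covariates (or `NULL`: centered /
#'   intercept-only residuals).
#' @param family `"linear"` or `"logistic"`.
#' @param type residual type for logistic fits: `"deviance"` or `"response"`.
#' @return Residual vector aligned to the input individuals.
#' @export
residualize_phenotype <- function(pheno, covariates = NULL,
                                  family = c("linear", "logistic"),
                                  type = c("deviance", "response")) {
  family <- match.arg(family); type <- match.arg(type)
  if (is.null(covariates)) {
    dat <- data.frame(.y = pheno)
    form <- .y ~ 1
  } else {
    dat <- data.frame(.y = pheno, as.data.frame(covariates))
    if (anyNA(dat)) stop("missing values in phenotype/covariates; remove them first")
    form <- .y ~ .
  }
  if (family == "linear") {
    return(stats::residuals(stats::lm(form, data = dat)))
  }
  if (!all(pheno %in% c(0, 1))) stop("logistic family requires a 0/1 outcome")
  fit <- withCallingHandlers(
    stats::glm(form, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        stop("separation in the covariate-only logistic fit; drop or coarsen ",
             "the offending covariate", call. = FALSE)
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  if (!is.null(covariates) && (any(mu < 1e-8) || any(mu > 1 - 1e-8)))
    stop("separation in the covariate-only logistic fit; drop or coarsen ",
         "the offending covariate", call. = FALSE)
  stats::residuals(fit, type = type)
}

#' Association of a (residualized) phenotype with a PRS
#'
#' Ordinary least squares of the phenotype on the score; reports the model
#' R-squared and the two-sided slope P-value.
#'
#' @param residual_pheno numeric outcome vector.
#' @param prs numeric score vector of equal length (non-constant).
#' @return An object of class `prs_association`: list with `r2`, `p`,
#'   `slope`, `n`.
#' @export
fit_association <- function(residual_pheno, prs) {
  if (length(residual_pheno) != length(prs)) stop("length mismatch")
  if (length(prs) < 3) stop("need at least 3 observations")
  st <- .assoc_stats(residual_pheno, prs)
  if (is.na(st[["r2"]])) stop("constant PRS: association undefined")
  structure(as.list(st), class = "prs_association")
}

#' @export
print.prs_association <- function(x, ...) {
  cat(sprintf("<prs_association> R2 = %.4g, P = %.3g (n = %d)\n",
              x$r2, x$p, as.integer(x$n)))
  invisible(x)
}

#' Default P-value threshold grid
#' @return Numeric vector of thresholds.
#' @export
default_threshold_grid <- function() {
  c(5e-8, 1e-5, 1e-3, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 1)
}

#' Select the best P-value threshold for a pathway PRS
#'
#' Recomputes the PRS at every grid threshold and returns the one maximizing
#' the training R-squared of `residual_pheno ~ PRS` (ties broken towards the
#' larger, more inclusive threshold).
#'
#' @param study a `harmonized_study`.
#' @param retained clumped SNP ids for the pathway.
#' @param residual_pheno outcome vector.
#' @param grid candidate thresholds (duplicates ignored).
#' @return List with `threshold`, `association` (a `prs_association`), and
#'   `n_snps`.
#' @export
select_best_threshold <- function(study, retained, residual_pheno,
                                  grid = default_threshold_grid()) {
  grid <- sort(unique(grid))
  if (length(grid) == 0) stop("empty threshold grid")
  best <- NULL
  for (th in grid) {
    prs <- suppressWarnings(compute_prs(study, retained, th))
    if (attr(prs, "n_snps") == 0 || stats::sd(prs) == 0) next
    a <- fit_association(residual_pheno, prs)
    if (is.null(best) || a$r2 >= best$association$r2)
      best <- list(threshold = th, association = a,
                   n_snps = attr(prs, "n_snps"))
  }
  if (is.null(best)) stop("no threshold yields a scoreable SNP set")
  best
}
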