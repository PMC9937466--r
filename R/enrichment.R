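#' Background pool of independent genic SNPs
#'
#' The competitive null draws SNP sets from the clumped "background"
#' pathway: all genic SNPs, LD-clumped as one set.
#'
#' @param clump a `clump_result`.
#' @return Character vector of background SNP ids.
#' @export
build_background <- function(clump) {
  bg <- clump$background
  if (length(bg) == 0) stop("empty clumped background")
  bg
}

#' Sample size-matched null SNP sets
#'
#' Each null set is a uniform without-replacement draw of `m` distinct SNPs
#' from the background pool; draws are reproducible given `seed`.
#'
#' @param background character vector of background SNP ids.
#' @param m null-set size (matched to the pathway's clumped SNP count).
#' @param N number of null sets (>= 1).
#' @param seed optional integer seed.
#' @return List of `N` character vectors of length `m`.
#' @export
sample_null_sets <- function(background, m, N, seed = NULL) {
  if (N < 1) stop("N must be >= 1")
  if (m > length(background))
    stop("null-set size m = ", m, " exceeds background size ", length(background))
  .with_seed(seed, replicate(N, background[sample.int(length(background), m)],
                             simplify = FALSE))
}

#' Competitive P-value from permutation nulls
#'
#' `(#\{n : P_n < P_0\} + 1) / (N + 1)`: the pseudo-count avoids competitive
#' P-values of 0, so the smallest achievable value is `1/(N+1)`.  Ties
#' (`P_n = P_0`) count as "not smaller" (strict inequality).
#'
#' @param p_observed observed association P-value of the pathway (P0).
#' @param p_nulls association P-values of the null sets.
#' @return Competitive P-value in `[1/(N+1), 1]`.
#' @export
competitive_pvalue <- function(p_observed, p_nulls) {
  if (length(p_nulls) == 0) stop("empty null P-value list")
  stopifnot(p_observed > 0, p_observed <= 1, all(p_nulls > 0), all(p_nulls <= 1))
  (sum(p_nulls < p_observed) + 1) / (length(p_nulls) + 1)
}

# Fast permutation machinery: association P of y on sums of pre-weighted
# per-SNP score contributions, computed from crossproducts.  Algebraically
# identical to fit_association(y, compute_prs(...)) for every null set.
.null_pvalues <- function(Sbg, y, idxm, chunk = 4000L) {
  n <- length(y); N <- ncol(idxm); m <- nrow(idxm)
  s1 <- colSums(Sbg)
  yS <- as.vector(crossprod(y, Sbg))
  C <- crossprod(Sbg)
  ybar <- mean(y); Syy <- sum((y - ybar)^2)
  out <- numeric(N)
  for (lo in seq(1L, N, by = chunk)) {
    hi <- min(lo + chunk - 1L, N)
    ids <- idxm[, lo:hi, drop = FALSE]
    cols <- hi - lo + 1L
    Sv <- colSums(matrix(s1[ids], m))
    Syv <- colSums(matrix(yS[ids], m))
    Zs <- Matrix::sparseMatrix(i = as.vector(ids), j = rep(seq_len(cols), each = m),
                               x = 1, dims = c(nrow(C), cols))
    W <- as.matrix(C %*% Zs)
    Svv <- colSums(matrix(W[cbind(as.vector(ids), rep(seq_len(cols), each = m))], m))
    varv <- Svv - Sv^2 / n
    covv <- Syv - ybar * Sv
    p <- rep(1, cols)
    ok <- varv > 1e-12 * pmax(Svv, 1e-300) & Syy > 0
    r2 <- numeric(cols)
    r2[ok] <- pmin(covv[ok]^2 / (varv[ok] * Syy), 1)
    tt <- sqrt(r2[ok] * (n - 2) / pmax(1 - r2[ok], 1e-300))
    p[ok] <- pmax(2 * stats::pt(-tt, df = n - 2), .Machine$double.xmin)
    out[lo:hi] <- p
  }
  out
}

#' Competitive pathway enrichment for every pathway
#'
#' For each pathway: the observed association P-value (P0) comes from
#' regressing the (residualized) phenotype on the pathway PRS computed over
#' its clumped SNPs at threshold 1; `N` size-matched null sets are drawn
#' from the clumped genic background, scored with the harmonized GWAS
#' weights of the drawn SNPs, and tested identically; the competitive
#' P-value is `(#\{P_n < P_0\} + 1)/(N + 1)`.  Null draws use a
#' deterministic per-pathway sub-stream derived from `seed` and the pathway
#' name, so results do not depend on pathway order.
#'
#' @param study a `harmonized_study`.
#' @param flags a `membership_flags`.
#' @param residual_pheno outcome vector (one per panel individual).
#' @param N number of permutations (default 10000).
#' @param seed integer seed for the null draws.
#' @param clump optional precomputed `clump_result` (recomputed otherwise).
#' @param r2_threshold,window_bp,p_ceiling clumping parameters used when
#'   `clump` is not supplied.
#' @return An object of class `prset_enrichment`: data.frame with columns
#'   `pathway`, `m`, `p_observed`, `p_competitive`, `n_perm`, `seed`,
#'   sorted by competitive then observed P.
#' @export
enrich_all <- function(study, flags, residual_pheno, N = 10000, seed = NULL,
                       clump = NULL, r2_threshold = 0.1, window_bp = 250000,
                       p_ceiling = 1) {
  if (N < 1) stop("N must be >= 1")
  y <- as.numeric(residual_pheno)
  if (length(y) != length(study$panel$sample_id))
    stop("phenotype length does not match panel")
  if (is.null(clump))
    clump <- clump_pathways(study, flags, r2_threshold = r2_threshold,
                            window_bp = window_bp, p_ceiling = p_ceiling)
  bg <- build_background(clump)
  bg_idx <- match(bg, study$stats$snp)
  Dbg <- .impute_mean(study$panel$dosage[, bg_idx, drop = FALSE])
  Sbg <- sweep(Dbg, 2, study$stats$beta[bg_idx], "*")

  paths <- names(clump$retained)
  res <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    nm <- paths[k]
    snps <- clump$retained[[nm]]
    m <- length(snps)
    if (m == 0) next
    prs <- compute_prs(study, snps, 1)
    if (stats::sd(prs) == 0) next
    p0 <- fit_association(y, prs)$p
    idxm <- .with_seed(.substream_seed(seed, nm),
                       vapply(seq_len(N),
                              function(i) sample.int(length(bg), m),
                              integer(m)))
    if (m == 1) idxm <- matrix(idxm, nrow = 1)
    pn <- .null_pvalues(Sbg, y, idxm)
    res[[k]] <- data.frame(pathway = nm, m = m, p_observed = p0,
                           p_competitive = competitive_pvalue(p0, pn),
                           n_perm = N,
                           seed = if (is.null(seed)) NA_integer_ else seed,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no pathway could be scored")
  out <- out[order(out$p_competitive, out$p_observed), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, clump = clump, class = c("prset_enrichment", "data.frame"))
}

#' @export
print.prset_enrichment <- function(x, ...) {
  cat("<prset_enrichment> ", nrow(x), " pathways, N = ", x$n_perm[1],
      " permutations\n", sep = "")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more\n", sep = "")
  invisible(x)
}
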