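#' Stratified train/test split with CV folds
#'
#' Splits individuals into training and test sets stratified by the binary
#' label, and assigns stratified cross-validation folds within the training
#' set.  Reproducible given `seed`.
#'
#' @param labels 0/1 vector (one per individual).
#' @param train_fraction fraction of individuals used for training, in (0,1).
#' @param k_folds number of CV folds.
#' @param seed optional integer seed.
#' @return List with `train` / `test` (integer indices) and `folds` (fold id
#'   per training individual, aligned to `train`).
#' @export
split_train_test <- function(labels, train_fraction = 0.8, k_folds = 5, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab < k_folds))
    stop("each class needs at least k_folds = ", k_folds, " members")
  .with_seed(seed, {
    train <- integer()
    for (cl in c(0, 1)) {
      ix <- which(labels == cl)
      train <- c(train, sample(ix, round(length(ix) * train_fraction)))
    }
    train <- sort(train)
    test <- setdiff(seq_along(labels), train)
    folds <- integer(length(train))
    for (cl in c(0, 1)) {
      jx <- which(labels[train] == cl)
      folds[jx] <- sample(rep_len(seq_len(k_folds), length(jx)))
    }
    list(train = train, test = test, folds = folds)
  })
}

#' Train a subtype classification model (lasso over pathway PRSs)
#'
#' Fits a generalized linear model with lasso regularization of the 0/1
#' subtype label on the standardized pathway score matrix, selecting the
#' penalty by k-fold cross-validated mean squared error
#' (`glmnet::cv.glmnet`, Gaussian family by default, mirroring MSE-based
#' selection; a logistic fit is available via `family`).
#'
#' @param x numeric matrix of training scores (individuals x pathways).
#' @param y 0/1 training labels.
#' @param foldid optional fold assignment (one per row of `x`).
#' @param k_folds folds when `foldid` is absent.
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @param lambda_rule `"min"` (penalty with the smallest CV MSE, default) or
#'   `"1se"` (sparsest penalty within one standard error of the minimum;
#'   markedly sparser under a null signal).
#' @param seed optional seed (controls fold assignment when `foldid` is
#'   absent).
#' @return An object of class `subtype_model`: list with `coef` (named,
#'   sparse in effect), `intercept`, `lambda`, `pathways`, `family`.
#' @export
train_subtype_model <- function(x, y, foldid = NULL, k_folds = 5,
                                family = c("gaussian", "binomial"),
                                lambda_rule = c("min", "1se"), seed = NULL) {
  family <- match.arg(family)
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (ncol(x) == 0) {
    warning("no pathway available; intercept-only model")
    return(structure(list(coef = numeric(0), intercept = mean(y), lambda = NA_real_,
                          pathways = character(0), family = family),
                     class = "subtype_model"))
  }
  if (ncol(x) == 1) {
    # lasso path degenerates for a single predictor; use the OLS solution
    fit <- stats::lm(y ~ x[, 1])
    cf <- stats::setNames(unname(stats::coef(fit)[2]), colnames(x))
    return(structure(list(coef = cf, intercept = unname(stats::coef(fit)[1]),
                          lambda = 0, pathways = colnames(x), family = family),
                     class = "subtype_model"))
  }
  .with_seed(seed, {
    if (is.null(foldid)) foldid <- sample(rep_len(seq_len(k_folds), nrow(x)))
    cv <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                            type.measure = "mse")
    s <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- as.vector(stats::coef(cv, s = s))
    structure(list(coef = stats::setNames(cf[-1], colnames(x)),
                   intercept = cf[1], lambda = s,
                   pathways = colnames(x), family = family),
              class = "subtype_model")
  })
}

#' @export
print.subtype_model <- function(x, ...) {
  nz <- sum(x$coef != 0)
  cat("<subtype_model> ", length(x$pathways), " pathways, ", nz,
      " with nonzero coefficient (lambda = ", format(x$lambda, digits = 3),
      ")\n", sep = "")
  invisible(x)
}

#' @export
coef.subtype_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coef)
}

#' @export
predict.subtype_model <- function(object, newdata, ...) {
  if (length(object$pathways) == 0)
    return(rep(object$intercept, nrow(as.matrix(newdata))))
  newdata <- as.matrix(newdata)
  if (!all(object$pathways %in% colnames(newdata)))
    stop("newdata lacks pathway column(s)")
  lp <- object$intercept +
    as.vector(newdata[, object$pathways, drop = FALSE] %*% object$coef)
  if (object$family == "binomial") stats::plogis(lp) else lp
}

#' Evaluate a subtype model on held-out data
#'
#' Model R-squared: the squared Pearson correlation between the predicted
#' values and the 0/1 labels of the test set.  Constant predictions give
#' R-squared 0 with a warning.
#'
#' @param model a `subtype_model`.
#' @param test_scores score matrix for test individuals.
#' @param test_labels 0/1 labels.
#' @return Numeric R-squared.
#' @export
evaluate_model <- function(model, test_scores, test_labels) {
  pred <- predict(model, test_scores)
  if (stats::sd(pred) == 0 || stats::sd(test_labels) == 0) {
    warning("constant predictions or labels; R2 defined as 0")
    return(0)
  }
  stats::cor(pred, test_labels)^2
}

# Subset a harmonized study to a set of individuals (row indices).
#' Subset a harmonized study by individuals
#' @param study a `harmonized_study`.
#' @param idx integer row indices.
#' @return A `harmonized_study` for those individuals.
#' @export
subset_samples <- function(study, idx) {
  p <- study$panel
  structure(list(panel = genotype_panel(p$dosage[idx, , drop = FALSE], p$map,
                                        sample_id = p$sample_id[idx]),
                 stats = study$stats, drop_log = study$drop_log),
            class = "harmonized_study")
}

# Scores at per-pathway thresholds for a fixed clumped SNP assignment,
# standardized by *training* mean/sd (applied unchanged to test data).
.scores_for <- function(study, retained, thresholds, center = NULL, scl = NULL) {
  S <- matrix(0, length(study$panel$sample_id), length(retained),
              dimnames = list(study$panel$sample_id, names(retained)))
  for (k in names(retained))
    S[, k] <- suppressWarnings(compute_prs(study, retained[[k]], thresholds[[k]]))
  if (is.null(center)) {
    center <- colMeans(S)
    scl <- apply(S, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  }
  out <- sweep(sweep(S, 2, center, "-"), 2, scl, "/")
  attr(out, "center") <- center; attr(out, "scale") <- scl
  out
}

#' Supervised disease-subtype stratification from pathway PRSs
#'
#' End-to-end supervised pipeline: split individuals into training and test
#' (stratified by subtype), residualize the label on covariates if given,
#' build pathway membership (optionally on 5-Mb-shifted annotation as a
#' negative control), clump and assess competitive enrichment on the
#' training sample only, re-threshold each enriched pathway (competitive
#' P < `enrich_alpha`) to maximize training R-squared, fit the lasso subtype
#' model on the training scores, and report the test R-squared.  Enrichment
#' and threshold selection never see test individuals.
#'
#' @param study a `harmonized_study` for all target individuals.
#' @param genes raw (unextended) `gene_table`.
#' @param sets a `gene_set_collection`.
#' @param labels 0/1 subtype label per individual.
#' @param covariates optional covariate data.frame (residualized out of the
#'   label by a covariate-only logistic fit).
#' @param train_fraction,k_folds split parameters (default 80\% / 5 folds).
#' @param enrich_alpha competitive-P cutoff defining enriched pathways.
#' @param n_perm permutations for the competitive P-values.
#' @param upstream_bp,downstream_bp gene-window extension.
#' @param exclude exclusion regions (list of [genomic_region()]).
#' @param shift_bp if non-`NULL`, apply [shift_annotation()] with this shift
#'   before extension (requires `chrom_lengths`).
#' @param chrom_lengths named chromosome lengths (needed for `shift_bp`).
#' @param grid threshold grid for per-pathway optimization.
#' @param r2_threshold,window_bp clumping parameters.
#' @param min_genes,max_genes pathway size filter.
#' @param split optional precomputed split (as returned by
#'   [split_train_test()]); overrides the random split.
#' @param seed integer seed.
#' @return An object of class `subtype_stratification`: list with `r2`
#'   (test R-squared), `model`, `enrichment`, `enriched` (pathway names),
#'   `thresholds`, `split`.
#' @export
stratify_subtypes <- function(study, genes, sets, labels, covariates = NULL,
                              train_fraction = 0.8, k_folds = 5,
                              enrich_alpha = 0.05, n_perm = 10000,
                              upstream_bp = 35000, downstream_bp = 10000,
                              exclude = NULL, shift_bp = NULL,
                              chrom_lengths = NULL,
                              grid = default_threshold_grid(),
                              r2_threshold = 0.1, window_bp = 250000,
                              min_genes = 10, max_genes = 2000,
                              split = NULL, seed = NULL) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (!is.null(shift_bp)) {
    if (is.null(chrom_lengths)) stop("shift_bp requires chrom_lengths")
    genes <- shift_annotation(genes, shift_bp, chrom_lengths)
  }
  ext <- extend_gene_bounds(genes, upstream_bp, downstream_bp)
  flags <- build_membership(study, ext, sets, exclude = exclude,
                            min_genes = min_genes, max_genes = max_genes)
  if (is.null(split))
    split <- split_train_test(labels, train_fraction, k_folds, seed = seed)
  tr <- split$train; te <- split$test

  study_tr <- subset_samples(study, tr)
  study_te <- subset_samples(study, te)
  y_tr <- if (is.null(covariates)) as.numeric(labels[tr]) else
    residualize_phenotype(labels[tr], covariates[tr, , drop = FALSE], "logistic")

  clump <- clump_pathways(study_tr, flags, r2_threshold = r2_threshold,
                          window_bp = window_bp, p_ceiling = 1)
  enr <- enrich_all(study_tr, flags, y_tr, N = n_perm, seed = seed, clump = clump)
  enriched <- enr$pathway[enr$p_competitive < enrich_alpha]

  if (length(enriched) == 0) {
    warning("no enriched pathway at alpha = ", enrich_alpha,
            "; intercept-only model")
    model <- train_subtype_model(matrix(numeric(0), length(tr), 0), labels[tr])
    return(structure(list(r2 = 0, model = model, enrichment = enr,
                          enriched = character(0), thresholds = numeric(0),
                          split = split),
                     class = "subtype_stratification"))
  }
  thresholds <- vapply(enriched, function(k)
    select_best_threshold(study_tr, clump$retained[[k]], y_tr, grid)$threshold,
    numeric(1))
  retained <- clump$retained[enriched]
  x_tr <- .scores_for(study_tr, retained, thresholds)
  x_te <- .scores_for(study_te, retained, thresholds,
                      center = attr(x_tr, "center"), scl = attr(x_tr, "scale"))
  model <- train_subtype_model(x_tr, labels[tr], foldid = split$folds, seed = seed)
  r2 <- suppressWarnings(evaluate_model(model, x_te, labels[te]))
  structure(list(r2 = r2, model = model, enrichment = enr, enriched = enriched,
                 thresholds = thresholds, split = split),
            class = "subtype_stratification")
}

#' @export
print.subtype_stratification <- function(x, ...) {
  cat("<subtype_stratification> ", length(x$enriched), " enriched pathways; test R2 = ",
      format(x$r2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Shifted-annotation negative control
#'
#' Runs the stratification pipeline twice on the same split: once with the
#' true gene annotation and once with gene coordinates displaced by
#' `shift_bp` (default 5 Mb), which removes the biological meaning of
#' gene-set membership while keeping model flexibility matched.
#'
#' @inheritParams stratify_subtypes
#' @param shift_bp displacement in bp for the control run.
#' @param ... passed through to [stratify_subtypes()].
#' @return List with `unshifted` and `shifted` (both
#'   `subtype_stratification`), plus `r2` (named numeric pair).
#' @export
run_shift_control <- function(study, genes, sets, labels, chrom_lengths,
                              shift_bp = 5e6, split = NULL, seed = NULL, ...) {
  if (is.null(split))
    split <- split_train_test(labels, seed = seed)
  fit0 <- stratify_subtypes(study, genes, sets, labels, split = split,
                            seed = seed, ...)
  fit1 <- stratify_subtypes(study, genes, sets, labels, split = split,
                            seed = seed, shift_bp = shift_bp,
                            chrom_lengths = chrom_lengths, ...)
  list(unshifted = fit0, shifted = fit1,
       r2 = c(unshifted = fit0$r2, shifted = fit1$r2))
}

#' Single-trait prediction with pathway PRSs
#'
#' The same supervised machinery as subtype stratification, with the
#' case/control status as the label.
#'
#' @inheritParams stratify_subtypes
#' @param case_control 0/1 case-control status per individual.
#' @param ... passed through to [stratify_subtypes()].
#' @return A `subtype_stratification` object (test R-squared in `$r2`).
#' @export
predict_single_trait <- function(study, genes, sets, case_control, ...) {
  stratify_subtypes(study, genes, sets, labels = case_control, ...)
}

#' Genome-wide clumping + thresholding baseline
#'
#' Standard single-score C+T: greedy genome-wide clumping (no pathway
#' restriction), threshold chosen to maximize training R-squared, evaluated
#' on the test set as the squared correlation between the score and the
#' label.
#'
#' @param study a `harmonized_study`.
#' @param labels 0/1 (or continuous) outcome per individual.
#' @param split train/test split from [split_train_test()].
#' @param grid threshold grid.
#' @param r2_threshold,window_bp clumping parameters.
#' @return List with `r2` (test), `threshold`, `n_snps`.
#' @export
genomewide_ct <- function(study, labels, split,
                          grid = default_threshold_grid(),
                          r2_threshold = 0.1, window_bp = 250000) {
  map <- study$panel$map
  flags <- structure(list(
    snp = map$snp,
    membership = matrix(TRUE, nrow(map), 1, dimnames = list(map$snp, "genomewide")),
    background = stats::setNames(rep(TRUE, nrow(map)), map$snp),
    n_genes = c(genomewide = NA_integer_),
    genes_per_set = list(genomewide = character(0)),
    log = character()), class = "membership_flags")
  study_tr <- subset_samples(study, split$train)
  study_te <- subset_samples(study, split$test)
  clump <- clump_pathways(study_tr, flags, r2_threshold = r2_threshold,
                          window_bp = window_bp)
  best <- select_best_threshold(study_tr, clump$retained$genomewide,
                                as.numeric(labels[split$train]), grid)
  sc_te <- suppressWarnings(compute_prs(study_te, clump$retained$genomewide,
                                        best$threshold))
  r2 <- if (stats::sd(sc_te) == 0) 0 else
    stats::cor(sc_te, as.numeric(labels[split$test]))^2
  list(r2 = r2, threshold = best$threshold, n_snps = best$n_snps)
}

#' Repeated-split stratification
#'
#' Repeats the full supervised pipeline over `n_splits` independent
#' stratified 80/20 splits and reports the test R-squared per split and
#' their median, the conventional summary for fold-to-fold variability.
#'
#' @inheritParams stratify_subtypes
#' @param n_splits number of repeated splits (default 5).
#' @param ... passed through to [stratify_subtypes()].
#' @return List with `per_split` (data.frame `split`, `r2`, `n_enriched`)
#'   and `median_r2`.
#' @export
stratify_cv <- function(study, genes, sets, labels, n_splits = 5,
                        seed = NULL, ...) {
  rows <- lapply(seq_len(n_splits), function(i) {
    si <- .substream_seed(seed, paste0("split", i))
    fit <- stratify_subtypes(study, genes, sets, labels, seed = si, ...)
    data.frame(split = i, r2 = fit$r2, n_enriched = length(fit$enriched))
  })
  per_split <- do.call(rbind, rows)
  list(per_split = per_split, median_r2 = stats::median(per_split$r2))
}

#' Leave-one-cohort-out stratification
#'
#' With `C` cohorts, runs the stratification pipeline `C` times, each time
#' holding one cohort out as the test set (every cohort appears exactly once
#' as test).
#'
#' @inheritParams stratify_subtypes
#' @param cohort cohort label per individual.
#' @param ... passed through to [stratify_subtypes()].
#' @return data.frame with one row per cohort (`cohort`, `r2`,
#'   `n_enriched`).
#' @export
stratify_loco <- function(study, genes, sets, labels, cohort, k_folds = 5,
                          seed = NULL, ...) {
  cohort <- as.character(cohort)
  out <- lapply(unique(cohort), function(co) {
    te <- which(cohort == co); tr <- which(cohort != co)
    folds <- .with_seed(.substream_seed(seed, co),
                        sample(rep_len(seq_len(k_folds), length(tr))))
    fit <- stratify_subtypes(study, genes, sets, labels,
                             split = list(train = tr, test = te, folds = folds),
                             seed = seed, ...)
    data.frame(cohort = co, r2 = fit$r2, n_enriched = length(fit$enriched),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
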