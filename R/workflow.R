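# Orchestration: configuration, subcommand dispatch, manifests.

.SCHEMA <- list(
  common = c("command", "out_dir", "seed"),
  score = c("genotypes", "genotype_format", "summary_stats", "gtf", "gmt",
            "phenotype", "r2", "window_kb", "p_ceiling", "thresholds",
            "no_standardize", "upstream_kb", "downstream_kb", "min_genes",
            "max_genes"),
  enrich = c("genotypes", "genotype_format", "summary_stats", "gtf", "gmt",
             "phenotype", "permutations", "r2", "window_kb",
             "upstream_kb", "downstream_kb", "min_genes", "max_genes"),
  stratify = c("genotypes", "genotype_format", "summary_stats", "gtf", "gmt",
               "phenotype", "train_frac", "folds", "enrich_alpha",
               "permutations", "shift_control", "r2", "window_kb",
               "upstream_kb", "downstream_kb", "min_genes", "max_genes"),
  specificity = c("expression", "n_quantiles"),
  simulate = c("n_individuals", "n_snps", "block_size", "within_block_r2",
               "maf_min", "maf_max", "h2", "n_pathways", "k_causal"),
  benchmark = c("n_base", "n_target", "n_snps", "n_pathways", "k_causal",
                "h2", "permutations", "reps")
)

#' Read a key=value run configuration
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' allowed.  Values are parsed as numbers where possible.
#'
#' @param path configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

.validate_config <- function(config) {
  if (is.null(config$command)) stop("config must set 'command'")
  cmd <- config$command
  if (!cmd %in% names(.SCHEMA)[-1]) stop("unknown command: ", cmd)
  allowed <- c(.SCHEMA$common, .SCHEMA[[cmd]])
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s) for command '", cmd, "': ",
         paste(unknown, collapse = ", "))
  cmd
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.sumstats_column_map <- function(path) {
  hdr <- names(utils::read.table(path, header = TRUE, nrows = 1,
                                 check.names = FALSE))
  aliases <- list(snp = c("SNP", "snp"), chr = c("CHR", "chr"),
                  pos = c("BP", "POS", "pos"), a1 = c("A1", "a1"),
                  a2 = c("A2", "a2"), beta = c("BETA", "beta"),
                  or = c("OR", "or"), p = c("P", "p"), n = c("N", "n"))
  out <- character()
  for (role in names(aliases)) {
    hit <- intersect(aliases[[role]], hdr)
    if (length(hit)) out[role] <- hit[1]
  }
  out
}

.load_study_inputs <- function(config) {
  fmt <- if (is.null(config$genotype_format)) "plink1" else config$genotype_format
  panel <- read_genotypes(config$genotypes, format = fmt)
  stats <- read_summary_stats(config$summary_stats,
                              column_map = .sumstats_column_map(config$summary_stats))
  study <- harmonize(stats, panel)
  genes <- read_gene_table(config$gtf)
  sets <- read_gmt(config$gmt)
  ph <- utils::read.table(config$phenotype, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  y <- ph[[2]][match(study$panel$sample_id, as.character(ph[[1]]))]
  if (anyNA(y)) stop("phenotype missing for some panel individuals")
  list(study = study, genes = genes, sets = sets, phenotype = y)
}

#' Run a configured pipeline
#'
#' Executes one subcommand (`score`, `enrich`, `stratify`, `specificity`,
#' `simulate`, or `benchmark`) from a validated configuration, writes its
#' output tables plus a machine-readable JSON manifest (inputs hashed,
#' every effective parameter, seed, wall time, collected warnings) into
#' `out_dir`, and removes partial outputs on error.
#'
#' @param config named list or path to a key=value config file (see
#'   [read_run_config()]).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cmd <- .validate_config(config)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) NULL else as.integer(config$seed)
  t0 <- Sys.time()
  warns <- character()
  written <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    .write_tsv(df, p)
    written <<- c(written, p)
    p
  }
  result <- withCallingHandlers(
    tryCatch(.dispatch_command(cmd, config, seed, emit),
             error = function(e) {
               unlink(written)
               stop(e)
             }),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  inputs <- Filter(function(x) is.character(x) && length(x) == 1 && file.exists(x),
                   config)
  manifest <- list(
    command = cmd,
    parameters = config,
    effective_seed = seed,
    input_hashes = lapply(inputs, function(f) unname(tools::md5sum(f))),
    outputs = basename(written),
    warnings = warns,
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.dispatch_command <- function(cmd, config, seed, emit) {
  gv <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  if (cmd %in% c("score", "enrich", "stratify")) {
    inp <- .load_study_inputs(config)
    up <- gv("upstream_kb", 35) * 1000; down <- gv("downstream_kb", 10) * 1000
    r2 <- gv("r2", 0.1); win <- gv("window_kb", 250) * 1000
    mng <- gv("min_genes", 10); mxg <- gv("max_genes", 2000)
  }
  switch(cmd,
    score = {
      fit <- prset(inp$study, inp$genes, inp$sets, inp$phenotype,
                   n_perm = 1, upstream_bp = up, downstream_bp = down,
                   r2_threshold = r2, window_bp = win,
                   p_ceiling = gv("p_ceiling", 1),
                   min_genes = mng, max_genes = mxg,
                   standardize = !isTRUE(gv("no_standardize", FALSE) == 1),
                   seed = seed)
      emit(data.frame(sample = rownames(fit$scores), fit$scores,
                      check.names = FALSE), "scores.tsv")
      assoc <- do.call(rbind, lapply(names(fit$clump$retained), function(k) {
        sc <- fit$scores[, k]
        if (stats::sd(sc) == 0) return(NULL)
        a <- fit_association(fit$phenotype, sc)
        data.frame(pathway = k, n_snps = length(fit$clump$retained[[k]]),
                   threshold = 1, r2 = a$r2, p = a$p)
      }))
      emit(assoc, "associations.tsv")
      fit
    },
    enrich = {
      fit <- prset(inp$study, inp$genes, inp$sets, inp$phenotype,
                   n_perm = gv("permutations", 10000),
                   upstream_bp = up, downstream_bp = down,
                   min_genes = mng, max_genes = mxg,
                   r2_threshold = r2, window_bp = win, seed = seed)
      emit(data.frame(pathway = fit$enrichment$pathway,
                      m_snps = fit$enrichment$m,
                      p_observed = fit$enrichment$p_observed,
                      p_competitive = fit$enrichment$p_competitive,
                      n_perm = fit$enrichment$n_perm), "enrichment.tsv")
      fit
    },
    stratify = {
      fit <- stratify_subtypes(inp$study, inp$genes, inp$sets, inp$phenotype,
                               train_fraction = gv("train_frac", 0.8),
                               k_folds = gv("folds", 5),
                               enrich_alpha = gv("enrich_alpha", 0.05),
                               n_perm = gv("permutations", 10000),
                               upstream_bp = up, downstream_bp = down,
                               min_genes = mng, max_genes = mxg,
                               r2_threshold = r2, window_bp = win, seed = seed)
      emit(data.frame(pathway = names(fit$model$coef),
                      coefficient = unname(fit$model$coef)), "model.tsv")
      emit(data.frame(metric = "test_r2", value = fit$r2), "metrics.tsv")
      fit
    },
    specificity = {
      expr <- as.matrix(utils::read.table(config$expression, header = TRUE,
                                          sep = "\t", row.names = 1,
                                          check.names = FALSE))
      expr <- expr[rowSums(expr) > 0, , drop = FALSE]
      spec <- compute_specificity(expr)
      qs <- build_quantile_sets(spec, n_quantiles = gv("n_quantiles", 11))
      emit(data.frame(set = names(qs$sets), n_genes = lengths(qs$sets)),
           "quantile_sets.tsv")
      qs
    },
    simulate = {
      panel <- simulate_genotypes(gv("n_individuals", 2000),
                                  gv("n_snps", 1000),
                                  block_size = gv("block_size", 20),
                                  within_block_r2 = gv("within_block_r2", 0.8),
                                  maf_range = c(gv("maf_min", 0.05),
                                                gv("maf_max", 0.5)),
                                  seed = seed)
      land <- simulate_gene_sets(panel, n_pathways = gv("n_pathways", 100),
                                 set_size_range = c(3, 8),
                                 seed = .substream_seed(seed, "landscape"))
      flags <- build_membership(panel, extend_gene_bounds(land$genes),
                                land$sets, min_genes = 1)
      truth <- assign_causal_pathways(flags, k_causal = gv("k_causal", 10),
                                      seed = .substream_seed(seed, "causal"))
      y <- simulate_phenotype(panel, truth, gv("h2", 0.5),
                              seed = .substream_seed(seed, "pheno"))
      emit(data.frame(sample = panel$sample_id, phenotype = as.numeric(y)),
           "phenotype.tsv")
      emit(data.frame(pathway = names(truth$enrichment),
                      enrichment = unname(truth$enrichment),
                      rank = unname(truth$rank)), "truth.tsv")
      emit(data.frame(snp = truth$causal_snps), "causal_snps.tsv")
      emit(data.frame(sample = panel$sample_id, panel$dosage,
                      check.names = FALSE), "dosages.tsv")
      list(panel = panel, truth = truth, phenotype = y)
    },
    benchmark = {
      bm <- benchmark_enrichment(n_base = gv("n_base", 2000),
                                 n_target = gv("n_target", 1000),
                                 n_snps = gv("n_snps", 1000),
                                 n_pathways = gv("n_pathways", 100),
                                 k_causal = gv("k_causal", 20),
                                 h2 = gv("h2", 0.5),
                                 n_perm = gv("permutations", 200),
                                 reps = gv("reps", 2), seed = seed)
      emit(bm$results, "benchmark.tsv")
      emit(data.frame(metric = "median_tau", value = bm$median_tau),
           "benchmark_summary.tsv")
      bm
    })
}
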