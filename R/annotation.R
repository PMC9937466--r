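#' Construct a gene table
#'
#' @param df data.frame with columns `gene`, `chr`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates; strand `+` or `-`).
#' @return A `gene_table` data.frame.
#' @export
gene_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("gene", "chr", "start", "end", "strand")
  if (!all(need %in% names(df)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  df$gene <- as.character(df$gene); df$chr <- as.character(df$chr)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("gene start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  rownames(df) <- NULL
  structure(df[, need], class = c("gene_table", "data.frame"))
}

#' Read gene models from a GTF file
#'
#' Parses a GRCh37-style GTF via `rtracklayer::import()`.  Gene bounds are
#' taken from `gene` features when present, otherwise from the span of all
#' features sharing the same identifier.
#'
#' @param path GTF file.
#' @param id_field attribute used as the gene identifier, `"gene_id"` or
#'   `"gene_name"` (gene-set files usually carry symbols, GTFs carry both).
#' @return A [gene_table()].
#' @export
read_gene_table <- function(path, id_field = c("gene_id", "gene_name")) {
  id_field <- match.arg(id_field)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type) && any(md$type == "gene")) gr <- gr[md$type == "gene"]
  ids <- S4Vectors::mcols(gr)[[id_field]]
  if (is.null(ids)) stop("GTF attribute not found: ", id_field)
  df <- data.frame(gene = as.character(ids),
                   chr = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  # collapse multi-feature genes to their span
  if (anyDuplicated(df$gene)) {
    sp <- split(df, df$gene)
    df <- do.call(rbind, lapply(sp, function(g)
      data.frame(gene = g$gene[1], chr = g$chr[1], start = min(g$start),
                 end = max(g$end), strand = g$strand[1], stringsAsFactors = FALSE)))
  }
  gene_table(df)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, tab-separated gene list).
#' @param source label recorded for all sets in this file.
#' @return A `gene_set_collection`: list with `sets` (named list of gene-id
#'   vectors) and `source` (named character).
#' @export
read_gmt <- function(path, source = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  gene_set_collection(sets, source = source)
}

#' Construct a gene-set collection
#' @param sets named list of character vectors of gene ids.
#' @param source source label (recycled across sets).
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "user") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0)) stop("empty gene set(s): ",
                                    paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  structure(list(sets = sets,
                 source = stats::setNames(rep_len(source, length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection a `gene_set_collection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, unname(collection$source[nm]), collection$sets[[nm]]),
          collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Extend gene bounds by regulatory windows
#'
#' Extends each gene `upstream_bp` towards its 5' end and `downstream_bp`
#' towards its 3' end (strand-aware), flooring at base 1.  Defaults are the
#' conventional 35 kb upstream / 10 kb downstream windows used to capture
#' proximal regulatory variation.
#'
#' @param genes a `gene_table`.
#' @param upstream_bp,downstream_bp window lengths in bp (>= 0).
#' @return The extended `gene_table`.
#' @export
extend_gene_bounds <- function(genes, upstream_bp = 35000, downstream_bp = 10000) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$start - upstream_bp, genes$start - downstream_bp)
  e <- ifelse(plus, genes$end + downstream_bp, genes$end + upstream_bp)
  genes$start <- as.integer(pmax(1, s))
  genes$end <- as.integer(e)
  genes
}

#' Shift gene annotation (negative control)
#'
#' Displaces every gene by `shift_bp` along its chromosome so that gene-set
#' membership loses its biological meaning while marginal pathway sizes stay
#' comparable.  Coordinates wrap modulo the chromosome length; a gene whose
#' shifted span would straddle the chromosome end is relocated to start at
#' base 1 (length preserved) and flagged in the `wrapped` attribute.
#'
#' @param genes a `gene_table`.
#' @param shift_bp shift in bp (> 0); 5 Mb by convention.
#' @param chrom_lengths named numeric vector of chromosome lengths covering
#'   every gene.
#' @return The shifted `gene_table` with attribute `wrapped` (gene ids).
#' @export
shift_annotation <- function(genes, shift_bp = 5e6, chrom_lengths) {
  stopifnot(shift_bp > 0)
  if (!all(genes$chr %in% names(chrom_lengths)))
    stop("chrom_lengths missing chromosome(s): ",
         paste(setdiff(unique(genes$chr), names(chrom_lengths)), collapse = ", "))
  L <- unname(chrom_lengths[genes$chr])
  len <- genes$end - genes$start
  s2 <- ((genes$start - 1 + shift_bp) %% L) + 1
  wrapped <- (s2 + len) > L
  s2[wrapped] <- 1
  genes$start <- as.integer(s2)
  genes$end <- as.integer(s2 + len)
  attr(genes, "wrapped") <- genes$gene[wrapped]
  genes
}

#' Genomic exclusion region
#'
#' @param chr chromosome; `start`,`end` 1-based inclusive bounds; `label`
#'   free text (e.g. `"MHC"`).
#' @return A one-row `genomic_region` data.frame.
#' @export
genomic_region <- function(chr, start, end, label = "") {
  stopifnot(start <= end)
  structure(data.frame(chr = as.character(chr), start = as.integer(start),
                       end = as.integer(end), label = label,
                       stringsAsFactors = FALSE),
            class = c("genomic_region", "data.frame"))
}

#' Standard exclusion regions
#'
#' The extended MHC (chr6:25-34 Mb) is excluded in all analyses by
#' convention; the APOE region (chr19:44-46 Mb) additionally for
#' Alzheimer-type outcomes.
#'
#' @param apoe also exclude the APOE region?
#' @return A list of [genomic_region()] objects.
#' @export
default_exclusions <- function(apoe = FALSE) {
  out <- list(genomic_region("6", 25e6, 34e6, "MHC"))
  if (apoe) out <- c(out, list(genomic_region("19", 44e6, 46e6, "APOE")))
  out
}

#' Read exclusion regions from a BED-like TSV
#'
#' Input is 0-based half-open (BED convention) and converted to 1-based
#' inclusive on read.  Columns: chrom, start, end, optional label.
#'
#' @param path input file (no header).
#' @return A list of [genomic_region()] objects.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  lab <- if (ncol(df) >= 4) df[[4]] else rep("", nrow(df))
  lapply(seq_len(nrow(df)), function(i)
    genomic_region(df[[1]][i], df[[2]][i] + 1L, df[[3]][i], lab[i]))
}

#' Build SNP-by-pathway membership flags
#'
#' Maps SNPs of a harmonized study to (already extended) genes by closed
#' 1-based interval overlap and genes to pathways, producing the boolean
#' bit-flag membership matrix mutated during pathway clumping.  SNPs inside
#' any exclusion region belong to no pathway and are excluded from the genic
#' background.  Pathways are filtered by gene count after intersection with
#' the gene table (defaults 10-2000 genes) and dropped when no SNP overlaps.
#'
#' @param study a `harmonized_study` (or a bare `genotype_panel`, e.g. when
#'   annotating simulated SNPs before any GWAS exists).
#' @param genes an extended `gene_table`.
#' @param sets a `gene_set_collection`.
#' @param exclude list of [genomic_region()]s (or `NULL`).
#' @param min_genes,max_genes retained pathway size range (gene count).
#' @return An object of class `membership_flags`: list with `snp` (ids, study
#'   order), `membership` (logical SNP x pathway matrix), `background`
#'   (logical: genic and not excluded), `n_genes` (per retained pathway),
#'   `genes_per_set` (provenance), `log` (character messages).
#' @export
build_membership <- function(study, genes, sets, exclude = NULL,
                             min_genes = 10, max_genes = 2000) {
  stopifnot(min_genes <= max_genes)
  map <- if (inherits(study, "genotype_panel")) study$map else study$panel$map
  log <- character()

  known <- unique(genes$gene)
  kept_sets <- list()
  for (nm in names(sets$sets)) {
    gs <- intersect(sets$sets[[nm]], known)
    if (length(gs) < min_genes || length(gs) > max_genes) {
      log <- c(log, paste0("pathway ", nm, " outside size range (",
                           length(gs), " mappable genes)"))
    } else kept_sets[[nm]] <- gs
  }
  if (length(kept_sets) == 0) stop("no pathway within the gene-count range")

  snp_gr <- GenomicRanges::GRanges(map$chr, IRanges::IRanges(map$pos, map$pos))
  gene_gr <- GenomicRanges::GRanges(genes$chr, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  snp_i <- S4Vectors::queryHits(hits)
  gene_i <- S4Vectors::subjectHits(hits)

  excluded <- rep(FALSE, nrow(map))
  if (length(exclude)) {
    for (rg in exclude) {
      excluded <- excluded | (map$chr == rg$chr & map$pos >= rg$start & map$pos <= rg$end)
    }
  }
  background <- rep(FALSE, nrow(map))
  background[unique(snp_i)] <- TRUE
  background <- background & !excluded

  # gene id -> SNP indices
  by_gene <- split(snp_i, genes$gene[gene_i])
  M <- matrix(FALSE, nrow(map), length(kept_sets),
              dimnames = list(map$snp, names(kept_sets)))
  for (k in seq_along(kept_sets)) {
    idx <- unique(unlist(by_gene[kept_sets[[k]]], use.names = FALSE))
    if (length(idx)) M[idx, k] <- TRUE
  }
  M[excluded | !background, ] <- FALSE

  empty <- colSums(M) == 0
  if (any(empty)) {
    log <- c(log, paste0("pathway ", colnames(M)[empty], " has no overlapping SNP"))
    M <- M[, !empty, drop = FALSE]
    kept_sets <- kept_sets[!empty]
  }
  if (ncol(M) == 0) stop("no pathway with overlapping SNPs")

  structure(list(snp = map$snp,
                 membership = M,
                 background = stats::setNames(background, map$snp),
                 n_genes = lengths(kept_sets),
                 genes_per_set = kept_sets,
                 log = log),
            class = "membership_flags")
}

#' @export
print.membership_flags <- function(x, ...) {
  cat("<membership_flags> ", length(x$snp), " SNPs x ", ncol(x$membership),
      " pathways; ", sum(x$background), " background (genic) SNPs\n", sep = "")
  invisible(x)
}

#' Summarize a membership matrix
#' @param object a `membership_flags`.
#' @param ... unused.
#' @return data.frame (pathway, n_genes, n_snps).
#' @export
summary.membership_flags <- function(object, ...) {
  data.frame(pathway = colnames(object$membership),
             n_genes = unname(object$n_genes[colnames(object$membership)]),
             n_snps = unname(colSums(object$membership)),
             stringsAsFactors = FALSE)
}
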