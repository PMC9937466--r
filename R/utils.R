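# Internal helpers shared across modules.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_ambiguous <- function(a1, a2) {
  ok <- a1 %in% names(.COMPLEMENT) & a2 %in% names(.COMPLEMENT)
  ok & unname(.COMPLEMENT[a1]) == a2
}

# Evaluate `expr` under a local RNG state seeded with `seed` (NULL = use the
# current stream).  The caller's .Random.seed is always restored.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-stream seed derived from a run seed and a character key
# (e.g. a pathway name), so per-pathway permutations are order-independent.
.substream_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% 2146483647
  as.integer((as.numeric(seed) + h) %% 2146483647 + 1)
}

# Mean-impute missing entries of a dosage matrix, column-wise.
.impute_mean <- function(D) {
  if (!anyNA(D)) return(D)
  cm <- colMeans(D, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(D), arr.ind = TRUE)
  D[idx] <- cm[idx[, 2L]]
  D
}

# Simple-regression association of y on x: returns r2, two-sided slope P,
# slope and n.  Algebraically identical to summary(lm(y ~ x)).
.assoc_stats <- function(y, x) {
  n <- length(y)
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) return(c(r2 = NA_real_, p = NA_real_, slope = NA_real_, n = n))
  r <- stats::cor(y, x)
  r2 <- r * r
  if (r2 >= 1) {
    p <- .Machine$double.xmin
  } else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  c(r2 = r2, p = p, slope = r * stats::sd(y) / sx, n = n)
}

.empty_drop_log <- function() {
  data.frame(snp = character(), reason = character(), stringsAsFactors = FALSE)
}

.drop_log <- function(snp, reason) {
  if (length(snp) == 0) return(.empty_drop_log())
  data.frame(snp = as.character(snp), reason = rep_len(reason, length(snp)),
             stringsAsFactors = FALSE)
}
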