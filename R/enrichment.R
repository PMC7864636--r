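#' Shuffle intervals within their chromosomes
#'
#' Each interval is replaced by a uniformly random interval of identical
#' length on the same chromosome (the null model behind the permutation
#' overlap test: random genomic regions of the same size on the same
#' chromosome). Shuffled intervals may overlap each other.
#'
#' @param x Interval data frame.
#' @param sizes Named numeric vector of chromosome lengths (bp); see
#'   [read_chrom_sizes()].
#' @param seed Optional integer; when given, the RNG is seeded for a
#'   deterministic result.
#' @param exclude Optional interval data frame; placements overlapping any
#'   excluded region are rejected and redrawn (up to 1000 attempts each).
#' @return Interval data frame of shuffled intervals (lengths, chromosomes,
#'   names and scores preserved).
#' @export
shuffle_intervals <- function(x, sizes, seed = NULL, exclude = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(x) == 0) return(x)
  L <- sizes[x$chrom]
  if (any(is.na(L))) stop("chromosome missing from sizes: ",
                          x$chrom[which(is.na(L))[1]])
  len <- x$end - x$start
  if (any(len > L)) stop("interval longer than its chromosome")
  new_start <- floor(stats::runif(nrow(x)) * (L - len + 1))
  out <- x
  out$start <- new_start
  out$end <- new_start + len
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (attempt in 1:1000) {
      bad <- .overlaps_any(.gr(out), .gr(exclude))
      if (!any(bad)) break
      ns <- floor(stats::runif(sum(bad)) * (L[bad] - len[bad] + 1))
      out$start[bad] <- ns
      out$end[bad] <- ns + len[bad]
    }
    if (any(.overlaps_any(.gr(out), .gr(exclude))))
      stop("could not place intervals outside excluded regions")
  }
  rownames(out) <- NULL
  out
}

#' Fraction of query intervals overlapping a feature set
#'
#' @param query Interval data frame.
#' @param features Interval data frame (e.g. ATAC-seq peaks).
#' @return Fraction in \[0, 1\] of query intervals with >= 1 bp overlap with
#'   at least one feature.
#' @export
overlap_fraction <- function(query, features) {
  if (nrow(query) == 0) stop("empty query set")
  mean(.overlaps_any(.gr(query), .gr(features)))
}

#' Permutation test of interval overlap enrichment
#'
#' The observed statistic is the fraction of query intervals overlapping the
#' feature set. The null distribution is built by repeatedly shuffling the
#' query intervals within their chromosomes ([shuffle_intervals()]) and
#' recomputing the statistic. The empirical p-value uses the add-one
#' estimator `(r + 1) / (n_iter + 1)` where `r` counts null statistics at
#' least as extreme as the observed one; when no null value reaches the
#' observed statistic the printed result reports `p < 1/n_iter`.
#'
#' @param query,features Interval data frames.
#' @param sizes Named chromosome lengths (bp).
#' @param n_iter Number of shuffles (default 10,000).
#' @param tail `"upper"` (enrichment, default) or `"lower"` (depletion).
#' @param seed Integer RNG seed; results are reproducible bit-for-bit given
#'   `(seed, n_iter)`.
#' @param exclude Optional exclusion regions passed to [shuffle_intervals()].
#' @return A `permutation_result`: list with `observed`, `null_stats`,
#'   `fold` (observed / mean null), `pvalue_empirical`, `tail`, `seed`,
#'   `n_iter`.
#' @export
permutation_enrichment <- function(query, features, sizes, n_iter = 10000,
                                   tail = c("upper", "lower"), seed = NULL,
                                   exclude = NULL) {
  tail <- match.arg(tail)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- overlap_fraction(query, features)
  n <- nrow(query)
  len <- query$end - query$start
  L <- sizes[query$chrom]
  if (any(is.na(L))) stop("chromosome missing from sizes")
  if (any(len > L)) stop("interval longer than its chromosome")
  ## per-chromosome reduced feature ranges (1-based closed for IRanges)
  by_chrom <- split(seq_len(n), query$chrom)
  feat <- lapply(names(by_chrom), function(ch) {
    f <- features[features$chrom == ch, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = f$start + 1, end = f$end))
  })
  names(feat) <- names(by_chrom)
  use_exclude <- !is.null(exclude) && nrow(exclude) > 0
  null_stats <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    if (use_exclude) {
      sh <- shuffle_intervals(query, sizes, exclude = exclude)
      null_stats[b] <- overlap_fraction(sh, features)
    } else {
      ns <- floor(stats::runif(n) * (L - len + 1))
      hit <- 0L
      for (ch in names(by_chrom)) {
        i <- by_chrom[[ch]]
        ir <- IRanges::IRanges(start = ns[i] + 1, width = len[i])
        hit <- hit + sum(.overlaps_any(ir, feat[[ch]]))
      }
      null_stats[b] <- hit / n
    }
  }
  r <- if (tail == "upper") sum(null_stats >= observed) else
    sum(null_stats <= observed)
  mean_null <- mean(null_stats)
  structure(list(observed = observed, null_stats = null_stats,
                 fold = if (mean_null > 0) observed / mean_null else NA_real_,
                 pvalue_empirical = (r + 1) / (n_iter + 1),
                 tail = tail, seed = seed, n_iter = n_iter,
                 n_exceed = r),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result (", x$tail, " tail, n_iter = ", x$n_iter, ")\n",
      sep = "")
  cat("  observed = ", format(x$observed),
      ", null mean = ", format(mean(x$null_stats)),
      ", fold = ", format(x$fold), "\n", sep = "")
  if (x$n_exceed == 0) {
    cat("  p < ", format(1 / x$n_iter),
        " (empirical estimate ", format(x$pvalue_empirical), ")\n", sep = "")
  } else {
    cat("  p = ", format(x$pvalue_empirical), "\n", sep = "")
  }
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Tests independence in a 2x2 contingency table (e.g. variants inside /
#' outside a set of enhancers crossed with nominal GWAS association,
#' p < 0.05). Pearson chi-square without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of non-negative counts; all marginals must be
#'   positive.
#' @return List with `statistic` and `pvalue`.
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all marginals must be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ht$statistic), pvalue = unname(ht$p.value))
}

#' Compare expression between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test on `log(FPKM + 1)` (the log transform
#' does not change ranks; it is applied for consistency with how the values
#' are summarized elsewhere). Exact enumeration is used for small untied
#' samples (both n <= 20); otherwise the normal approximation with tie
#' correction.
#'
#' @param values_a,values_b Non-empty numeric FPKM vectors.
#' @return List with `statistic` (rank-sum W for group a), `pvalue`, and
#'   `method`.
#' @export
compare_expression <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("both groups must be non-empty")
  x <- log(values_a + 1)
  y <- log(values_b + 1)
  if (length(unique(c(x, y))) == 1)
    return(list(statistic = NA_real_, pvalue = 1,
                method = "all values tied"))
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- max(length(x), length(y)) <= 20 && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = FALSE))
  list(statistic = unname(ht$statistic), pvalue = unname(ht$p.value),
       method = if (use_exact) "exact Wilcoxon rank-sum" else
         "Wilcoxon rank-sum, normal approximation with tie correction")
}
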