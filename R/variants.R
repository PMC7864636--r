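#' Intersect GWAS variants with genomic intervals
#'
#' Keeps the variants whose 1 bp position falls inside any interval
#' (BEDTools-intersect semantics); each variant is reported once even when
#' covered by several intervals.
#'
#' @param variants Variant data frame (`chrom`, `pos` 1-based, `id`,
#'   `pvalue`); see [read_variant_table()].
#' @param intervals Interval data frame.
#' @return The subset of `variants` falling inside `intervals`, in input
#'   order.
#' @export
intersect_variants <- function(variants, intervals) {
  if (nrow(variants) == 0) return(variants)
  keep <- .overlaps_any(.variant_gr(variants), .gr(intervals))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests (e.g. variants mapping inside the
#'   elements of interest).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The adjusted threshold `alpha / n_tests`; a variant is called
#'   significant when its p-value is strictly below it.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  alpha / n_tests
}

#' Group significant variants into loci
#'
#' Single-linkage chaining: significant variants on the same chromosome
#' within `merge_dist` bp of each other (inclusive) join the same locus.
#' The lead variant is the one with the smallest p-value (ties broken by
#' lower position).
#'
#' @param sig_variants Variant data frame of significant variants.
#' @param merge_dist Linkage distance in bp (default 500,000, mirroring the
#'   novelty radius).
#' @return Data frame with one row per locus: `locus_id`, `chrom`, `start`,
#'   `end` (0-based half-open span over member positions), `lead_id`,
#'   `lead_pvalue`, `n_members`; member tables in attribute `"members"`.
#' @export
cluster_loci <- function(sig_variants, merge_dist = 500000) {
  v <- sig_variants[order(sig_variants$chrom, sig_variants$pos), , drop = FALSE]
  if (nrow(v) == 0) {
    out <- data.frame(locus_id = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      lead_id = character(), lead_pvalue = numeric(),
                      n_members = integer(), stringsAsFactors = FALSE)
    attr(out, "members") <- list()
    return(out)
  }
  new_loc <- c(TRUE, v$chrom[-1] != v$chrom[-nrow(v)] |
                       diff(v$pos) > merge_dist)
  id <- cumsum(new_loc)
  members <- split(v, id)
  rows <- lapply(seq_along(members), function(i) {
    m <- members[[i]]
    lead <- m[order(m$pvalue, m$pos), ][1, ]
    data.frame(locus_id = i, chrom = m$chrom[1],
               start = min(m$pos) - 1, end = max(m$pos),
               lead_id = lead$id, lead_pvalue = lead$pvalue,
               n_members = nrow(m), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- unname(lapply(members, function(m) {
    rownames(m) <- NULL
    m
  }))
  out
}

#' Flag loci as novel by distance to known loci
#'
#' A locus is novel when every member variant lies at least `min_dist` bp
#' from every known-locus interval. Distance is 0 when the variant falls
#' inside a known interval and otherwise the bp offset to the nearest
#' contained base (an immediately adjacent base is 1 bp away). "At least"
#' is inclusive: a distance of exactly `min_dist` still counts as novel.
#'
#' @param loci Locus data frame from [cluster_loci()].
#' @param known Interval data frame of known risk loci.
#' @param min_dist Minimum separation in bp (default 500,000).
#' @return `loci` with an added logical column `novel`.
#' @export
flag_novel <- function(loci, known, min_dist = 500000) {
  members <- attr(loci, "members")
  if (nrow(loci) == 0) {
    loci$novel <- logical()
    attr(loci, "members") <- members
    return(loci)
  }
  ## distance from a 1-based variant position to a known interval:
  ## 0 inside, otherwise bp offset to the nearest contained base
  ## (an adjacent base is 1 bp away)
  loci$novel <- vapply(members, function(m) {
    if (nrow(known) == 0) return(TRUE)
    for (i in seq_len(nrow(m))) {
      k <- known[known$chrom == m$chrom[i], , drop = FALSE]
      if (nrow(k) == 0) next
      p <- m$pos[i]
      d <- ifelse(p > k$start & p <= k$end, 0,
                  ifelse(p <= k$start, k$start + 1 - p, p - k$end))
      if (min(d) < min_dist) return(FALSE)
    }
    TRUE
  }, logical(1))
  attr(loci, "members") <- members
  loci
}

#' Select significant variants
#'
#' @param variants Variant data frame.
#' @param threshold Significance threshold from [bonferroni_threshold()].
#' @return Variants with `pvalue` strictly below `threshold`.
#' @export
significant_variants <- function(variants, threshold) {
  out <- variants[variants$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
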