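## internal: FPKM lookup for a stage, aligned to a gene table
.stage_fpkm <- function(genes, fpkm, stage) {
  if (!stage %in% names(fpkm))
    stop("stage '", stage, "' not present in FPKM table")
  idx <- match(genes$gene_id, fpkm$gene_id)
  if (any(is.na(idx))) stop("gene(s) missing from FPKM table")
  fpkm[[stage]][idx]
}

## internal: bp distance from a 1-based TSS point to a 0-based half-open interval
.tss_distance <- function(tss, start, end) {
  p <- tss - 1  # 0-based point
  ifelse(p >= start & p < end, 0, ifelse(p < start, start - p, p - (end - 1)))
}

#' Nearest expressed gene for an enhancer
#'
#' Genes are first filtered for expression (`FPKM >= min_fpkm` at the given
#' stage) on the enhancer's chromosome; among those, the gene whose TSS is
#' closest to the interval wins (distance 0 when the TSS falls inside).
#' Ties are broken by the lower TSS coordinate.
#'
#' @param interval One-row interval data frame (or list with `chrom`,
#'   `start`, `end`).
#' @param genes Gene table (`gene_id`, `chrom`, `tss`, `strand`); see
#'   [read_gene_table()].
#' @param fpkm FPKM table with `gene_id` plus one column per stage.
#' @param stage Stage whose expression filters the genes (e.g. `"PP2"`).
#' @param min_fpkm Expression cutoff (default 1).
#' @return One-row data frame with `gene_id`, `chrom`, `tss`, `strand`,
#'   `fpkm`, `distance`, or a zero-row frame when no expressed gene exists
#'   on the chromosome.
#' @export
nearest_expressed_gene <- function(interval, genes, fpkm, stage,
                                   min_fpkm = 1) {
  expr <- .stage_fpkm(genes, fpkm, stage)
  keep <- genes$chrom == interval$chrom & expr >= min_fpkm
  g <- genes[keep, , drop = FALSE]
  g$fpkm <- expr[keep]
  if (nrow(g) == 0) {
    g$distance <- numeric(0)
    return(g)
  }
  g$distance <- .tss_distance(g$tss, interval$start, interval$end)
  g <- g[order(g$distance, g$tss), , drop = FALSE]
  out <- g[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expressed genes in the same TAD as an enhancer
#'
#' Returns the genes whose TSS lies inside any topologically associated
#' domain overlapping the interval, filtered for expression at the given
#' stage. TADs must be non-overlapping.
#'
#' @param interval One-row interval data frame.
#' @param tads Interval data frame of TAD calls.
#' @param genes,fpkm,stage,min_fpkm See [nearest_expressed_gene()].
#' @return Data frame of expressed genes in the shared TAD(s), sorted by
#'   position; zero rows (with a warning) when the interval lies in no TAD.
#' @export
genes_in_tad <- function(interval, tads, genes, fpkm, stage, min_fpkm = 1) {
  if (nrow(tads) > 1) {
    o <- order(tads$chrom, tads$start)
    tt <- tads[o, ]
    same <- tt$chrom[-1] == tt$chrom[-nrow(tt)]
    if (any(same & tt$start[-1] < tt$end[-nrow(tt)]))
      stop("overlapping TADs")
  }
  hit <- .overlaps_any(.gr(tads),
                              .gr(as.data.frame(interval[c("chrom", "start",
                                                           "end")])))
  td <- tads[hit, , drop = FALSE]
  expr <- .stage_fpkm(genes, fpkm, stage)
  if (nrow(td) == 0) {
    warning("interval overlaps no TAD")
    out <- genes[0, , drop = FALSE]
    out$fpkm <- numeric(0)
    return(out)
  }
  gp <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(start = genes$tss, width = 1))
  inside <- .overlaps_any(gp, .gr(td))
  g <- genes[inside & expr >= min_fpkm, , drop = FALSE]
  g$fpkm <- expr[inside & expr >= min_fpkm]
  g <- g[order(g$chrom, g$tss), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Nearest expressed gene for every interval in a set
#'
#' Vectorized convenience wrapper around [nearest_expressed_gene()].
#'
#' @param intervals Interval data frame.
#' @inheritParams nearest_expressed_gene
#' @return Data frame with one row per interval: the interval columns plus
#'   `gene_id`, `tss`, `gene_fpkm`, `distance` (`NA` when unassigned).
#' @export
assign_target_genes <- function(intervals, genes, fpkm, stage, min_fpkm = 1) {
  res <- lapply(seq_len(nrow(intervals)), function(r) {
    hit <- nearest_expressed_gene(intervals[r, ], genes, fpkm, stage,
                                  min_fpkm)
    if (nrow(hit) == 0)
      data.frame(gene_id = NA_character_, tss = NA_real_,
                 gene_fpkm = NA_real_, distance = NA_real_)
    else
      data.frame(gene_id = hit$gene_id, tss = hit$tss, gene_fpkm = hit$fpkm,
                 distance = hit$distance)
  })
  cbind(intervals[, c("chrom", "start", "end"), drop = FALSE],
        do.call(rbind, res))
}
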