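#' Read a chromatin-state segmentation
#'
#' BED4 where column 4 is a chromatin-state label (e.g. from a ChromHMM-style
#' model: TssA, TssFlnk, TssBiv, Repr, EnhA, EnhP, CTCF, Quies). Segments must
#' be non-overlapping within a chromosome and each segment length must be a
#' positive multiple of `bin_size`. Adjacent records with the same state are
#' kept as written; merging runs is the job of [extract_enhancers()].
#'
#' @param path BED4 file path.
#' @param bin_size Genomic bin size in bp (default 200).
#' @param stage Optional stage label (e.g. "PP2") attached to the object.
#' @return A `state_segmentation` object: list with `segments` (data frame
#'   `chrom`, `start`, `end`, `state`, sorted), `bin_size`, `stage`, `states`.
#' @export
read_segmentation <- function(path, bin_size = 200, stage = NA_character_) {
  iv <- read_bed(path)
  if (nrow(iv) > 0 && any(is.na(iv$name)))
    stop("segmentation requires a state label in column 4")
  state_segmentation(iv$chrom, iv$start, iv$end, iv$name,
                     bin_size = bin_size, stage = stage)
}

#' Construct a chromatin-state segmentation
#'
#' @param chrom,start,end Segment coordinates (0-based half-open).
#' @param state State labels, one per segment.
#' @inheritParams read_segmentation
#' @return A `state_segmentation` object; see [read_segmentation()].
#' @export
state_segmentation <- function(chrom, start, end, state, bin_size = 200,
                               stage = NA_character_) {
  seg <- genomic_intervals(chrom, start, end)[, c("chrom", "start", "end")]
  seg$state <- as.character(state)
  if (any(is.na(seg$state))) stop("state labels must be non-missing")
  o <- order(seg$chrom, seg$start)
  seg <- seg[o, , drop = FALSE]
  rownames(seg) <- NULL
  len <- seg$end - seg$start
  if (any(len %% bin_size != 0)) {
    i <- which(len %% bin_size != 0)[1]
    stop("segment ", seg$chrom[i], ":", seg$start[i], "-", seg$end[i],
         " length is not a multiple of bin_size = ", bin_size)
  }
  if (nrow(seg) > 1) {
    same <- seg$chrom[-1] == seg$chrom[-nrow(seg)]
    olap <- same & seg$start[-1] < seg$end[-nrow(seg)]
    if (any(olap)) {
      i <- which(olap)[1] + 1
      stop("overlapping segments at ", seg$chrom[i], ":", seg$start[i])
    }
  }
  structure(list(segments = seg, bin_size = bin_size, stage = stage,
                 states = sort(unique(seg$state))),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("state_segmentation:", nrow(x$segments), "segments,",
      length(unique(x$segments$chrom)), "chromosome(s), bin_size =",
      x$bin_size, "\n")
  cat("  stage:", x$stage, " states:", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

#' Write a segmentation as BED4
#'
#' @param seg A `state_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  s <- seg$segments
  write_bed(genomic_intervals(s$chrom, s$start, s$end, name = s$state), path)
}

#' Read a GWAS variant table
#'
#' Tab-separated file with a header. Positions are 1-based (GWAS convention).
#' Rows with an association p-value outside (0, 1] are dropped; the number of
#' dropped rows is reported via a message and the `"n_dropped"` attribute.
#'
#' @param path Input path.
#' @param columns Named character vector mapping the required fields
#'   (`chrom`, `pos`, `id`, `pvalue`) to column names in the file.
#' @return Data frame with columns `chrom`, `pos`, `id`, `pvalue`, in file
#'   order, with attribute `n_dropped`.
#' @export
read_variant_table <- function(path,
                               columns = c(chrom = "chrom", pos = "pos",
                                           id = "id", pvalue = "pvalue")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(tab))
  if (length(missing) > 0)
    stop("missing column(s) in variant table: ", paste(missing, collapse = ", "))
  v <- data.frame(chrom = as.character(tab[[columns[["chrom"]]]]),
                  pos = as.numeric(tab[[columns[["pos"]]]]),
                  id = as.character(tab[[columns[["id"]]]]),
                  pvalue = as.numeric(tab[[columns[["pvalue"]]]]),
                  stringsAsFactors = FALSE)
  bad <- is.na(v$pvalue) | v$pvalue <= 0 | v$pvalue > 1 | is.na(v$pos) | v$pos < 1
  if (any(bad))
    message("read_variant_table: dropped ", sum(bad),
            " row(s) with invalid position or p-value")
  v <- v[!bad, , drop = FALSE]
  rownames(v) <- NULL
  attr(v, "n_dropped") <- sum(bad)
  v
}

#' Write a variant table
#'
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `pvalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  utils::write.table(variants[, c("chrom", "pos", "id", "pvalue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## internal: variants -> GRanges of 1 bp points
.variant_gr <- function(v) {
  if (nrow(v) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(v$chrom, IRanges::IRanges(start = v$pos, width = 1))
}

#' Construct an intra-chromosomal contact matrix
#'
#' @param counts Symmetric non-negative matrix of contact counts (dense).
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp (default 10,000).
#' @param weights Optional per-bin balancing weights (`NA` for masked bins).
#' @return A `contact_matrix` object: list with `counts`, `chrom`,
#'   `resolution`, `n_bins`, `weights`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", resolution = 10000,
                           weights = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), check.attributes = FALSE)))
    stop("counts must be symmetric")
  if (!is.null(weights) && length(weights) != nrow(counts))
    stop("weights length must equal n_bins")
  structure(list(counts = unname(counts), chrom = chrom,
                 resolution = resolution, n_bins = nrow(counts),
                 weights = weights),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "-", x$n_bins, "bins @", x$resolution, "bp;",
      format(sum(x$counts), big.mark = ","), "total counts",
      if (is.null(x$weights)) "(unbalanced)" else "(balanced)", "\n")
  invisible(x)
}

#' Read a contact matrix from triplet text
#'
#' Whitespace-separated lines `bin_i bin_j count` with 0-based bin indices;
#' only one triangle is required and counts are mirrored. A duplicate entry
#' for the same (unordered) pixel is an error.
#'
#' @param path Input path.
#' @param resolution Bin size in bp.
#' @param chrom Chromosome name to attach.
#' @param n_bins Number of bins; inferred as max index + 1 when `NULL`.
#' @return A `contact_matrix` object.
#' @export
read_contact_matrix <- function(path, resolution = 10000, chrom = "chr1",
                                n_bins = NULL) {
  tab <- utils::read.table(path, col.names = c("i", "j", "count"))
  if (any(tab$count < 0)) stop("negative contact count")
  if (any(tab$count != floor(tab$count)) || any(tab$i != floor(tab$i)) ||
      any(tab$j != floor(tab$j)))
    stop("bin indices and counts must be integers")
  lo <- pmin(tab$i, tab$j)
  hi <- pmax(tab$i, tab$j)
  if (anyDuplicated(paste(lo, hi)))
    stop("duplicate triplet for pixel (",
         lo[duplicated(paste(lo, hi))][1], ",",
         hi[duplicated(paste(lo, hi))][1], ")")
  if (is.null(n_bins)) n_bins <- max(hi) + 1
  m <- matrix(0, n_bins, n_bins)
  m[cbind(lo + 1, hi + 1)] <- tab$count
  m[cbind(hi + 1, lo + 1)] <- tab$count
  contact_matrix(m, chrom = chrom, resolution = resolution)
}

#' Write a contact matrix as triplet text
#'
#' Writes the non-zero upper triangle (including the diagonal) as
#' `bin_i bin_j count` with 0-based indices.
#'
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(m, path) {
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(idx[, 1] - 1, idx[, 2] - 1,
                   format(m$counts[idx], scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' BED-like tab-separated file with columns `chrom`, `start`, `end`,
#' `gene_id`, `strand` (no header). The TSS is resolved from the strand:
#' `start` for `+` genes, `end` for `-` genes, reported 1-based.
#'
#' @param path Input path.
#' @return Data frame with columns `gene_id`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @export
read_gene_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "gene_id",
                                         "strand"))
  if (!all(tab$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
             tss = ifelse(tab$strand == "+", tab$start + 1, tab$end),
             strand = tab$strand, stringsAsFactors = FALSE)
}

#' Read a per-stage expression (FPKM) table
#'
#' Tab-separated with header: a `gene_id` column plus one numeric column per
#' stage. FPKM values must be finite and non-negative.
#'
#' @param path Input path.
#' @return Data frame with `gene_id` plus one FPKM column per stage.
#' @export
read_fpkm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) stop("fpkm table requires a gene_id column")
  vals <- as.matrix(tab[, setdiff(names(tab), "gene_id"), drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("FPKM values must be finite and non-negative")
  tab
}

#' Write a per-stage expression table
#'
#' @param fpkm Data frame as returned by [read_fpkm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(fpkm, path) {
  utils::write.table(fpkm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
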