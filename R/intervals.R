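#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`,
#' `name`, `score`. Coordinates are 0-based half-open (`[start, end)`),
#' the convention used throughout the package.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions; must exceed `start`.
#' @param name Optional labels (recycled).
#' @param score Optional numeric scores (recycled).
#' @return A data frame with columns `chrom`, `start`, `end`, `name`, `score`.
#' @examples
#' genomic_intervals("chr1", 100, 300, name = "E1")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0) {
    if (any(is.na(chrom) | !nzchar(chrom))) stop("chrom must be non-empty")
    if (any(is.na(start) | is.na(end))) stop("start/end must be finite")
    if (any(start < 0)) stop("start must be >= 0")
    if (any(end <= start)) stop("end must be > start")
  }
  data.frame(chrom = chrom, start = start, end = end,
             name = rep_len(as.character(name), n),
             score = rep_len(as.numeric(score), n),
             stringsAsFactors = FALSE)
}

## internal: intervals data frame -> GRanges (1-based closed, as GRanges expects)
.gr <- function(x) {
  if (is.null(x) || nrow(x) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

## internal: overlapsAny without the benign "no sequence levels in common"
## warning when the two sets live on disjoint chromosomes
.overlaps_any <- function(a, b) {
  suppressWarnings(IRanges::overlapsAny(a, b))
}

## internal: GRanges -> intervals data frame (0-based half-open)
.from_gr <- function(gr) {
  genomic_intervals(as.character(GenomicRanges::seqnames(gr)),
                    GenomicRanges::start(gr) - 1,
                    GenomicRanges::end(gr))
}

#' Read a BED file
#'
#' Parses BED3+ with optional name (column 4) and score (column 5).
#' `track`, `browser` and `#` comment lines are skipped. Coordinates are
#' stored 0-based half-open.
#'
#' @param path Path to a tab-separated BED file.
#' @param zero_based If `TRUE` (BED convention, default) coordinates are taken
#'   as 0-based half-open; if `FALSE` they are taken as 1-based inclusive and
#'   converted.
#' @return Interval data frame (see [genomic_intervals()]), in file order.
#' @export
read_bed <- function(path, zero_based = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0) return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("line ", lineno[which(nf < 3)[1]], ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop("line ", lineno[which(bad)[1]], ": non-integer coordinates")
  if (!zero_based) start <- start - 1
  bad <- start < 0 | end <= start
  if (any(bad))
    stop("line ", lineno[which(bad)[1]], ": invalid interval (end <= start or start < 0)")
  name <- ifelse(nf >= 4, vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  score <- suppressWarnings(as.numeric(
    ifelse(nf >= 5, vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, ""), NA_character_)))
  genomic_intervals(chrom, start, end, name = name, score = score)
}

#' Write intervals to a BED file
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  has_name <- !is.null(x$name) && any(!is.na(x$name))
  has_score <- !is.null(x$score) && any(!is.na(x$score))
  if (has_name || has_score)
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name)))
  if (has_score)
    cols <- c(cols, list(ifelse(is.na(x$score), ".", format(x$score, trim = TRUE))))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Intersect two interval sets
#'
#' Returns the genomic regions covered by both sets (e.g. accessible-chromatin
#' peaks clipped to the enhancers that contain them).
#'
#' @param a,b Interval data frames.
#' @return Interval data frame of intersected regions.
#' @export
interval_intersection <- function(a, b) {
  .from_gr(GenomicRanges::intersect(.gr(a), .gr(b)))
}

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path Input path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  stats::setNames(as.numeric(tab$length), tab$chrom)
}
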