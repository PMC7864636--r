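#' Extract active-enhancer elements from a segmentation
#'
#' Maximal runs of adjacent segments carrying the given state (on the same
#' chromosome, with no gap) are merged into single enhancer elements. The
#' consecutive-bin count `k` is the merged length divided by the bin size.
#'
#' @param seg A `state_segmentation` (see [read_segmentation()]).
#' @param state State label to extract (default `"EnhA"`, active enhancer).
#' @return Data frame with columns `chrom`, `start`, `end`, `k`, `stage`,
#'   sorted by position.
#' @export
extract_enhancers <- function(seg, state = "EnhA") {
  stopifnot(inherits(seg, "state_segmentation"))
  if (!state %in% seg$states)
    stop("state '", state, "' not present in segmentation alphabet (",
         paste(seg$states, collapse = ", "), ")")
  s <- seg$segments[seg$segments$state == state, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      k = numeric(), stage = character(),
                      stringsAsFactors = FALSE)
  if (nrow(s) == 0) return(empty)
  o <- order(s$chrom, s$start)
  s <- s[o, , drop = FALSE]
  new_run <- c(TRUE, s$chrom[-1] != s$chrom[-nrow(s)] |
                       s$start[-1] != s$end[-nrow(s)])
  run_end <- c(new_run[-1], TRUE)  # last record of each run
  out <- data.frame(
    chrom = s$chrom[new_run],
    start = s$start[new_run],
    end = s$end[run_end],
    stringsAsFactors = FALSE)
  out$k <- (out$end - out$start) / seg$bin_size
  out$stage <- rep_len(as.character(seg$stage), nrow(out))
  rownames(out) <- NULL
  out
}

#' Fit the Poisson model for enhancer bin counts
#'
#' Models the number of consecutive bins covered by active-enhancer elements
#' in one cell type as Poisson. The maximum-likelihood rate is the arithmetic
#' mean of the bin counts. Because elements have at least one bin, the plain
#' mean slightly overestimates the rate of an underlying zero-truncated
#' process; `truncated = TRUE` instead solves the zero-truncated Poisson MLE
#' `lam / (1 - exp(-lam)) = mean(k)`.
#'
#' @param elements Enhancer data frame from [extract_enhancers()].
#' @param alpha_se Significance threshold below which an element is called a
#'   stretch enhancer (default 0.001).
#' @param truncated Use the zero-truncated MLE (default `FALSE`).
#' @return A `poisson_model` object: list with `lam` and `alpha_se`.
#' @export
fit_poisson_rate <- function(elements, alpha_se = 0.001, truncated = FALSE) {
  if (is.null(elements) || nrow(elements) == 0)
    stop("cannot fit Poisson rate on an empty element set")
  if (alpha_se <= 0 || alpha_se >= 1) stop("alpha_se must be in (0,1)")
  m <- mean(elements$k)
  lam <- m
  if (truncated) {
    if (m <= 1) stop("zero-truncated MLE undefined for mean(k) <= 1")
    lam <- stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                          interval = c(1e-9, m), tol = 1e-10)$root
  }
  structure(list(lam = lam, alpha_se = alpha_se), class = "poisson_model")
}

#' @export
print.poisson_model <- function(x, ...) {
  cat("poisson_model: lam =", format(x$lam), " alpha_se =", format(x$alpha_se),
      "\n")
  invisible(x)
}

#' Classify enhancers as stretch vs typical
#'
#' Assigns each element the inclusive upper-tail probability
#' `P(X >= k | X ~ Poisson(lam))` of its consecutive-bin count, and labels it
#' a stretch enhancer (`SE`) when that p-value is strictly below the model's
#' threshold, otherwise a typical enhancer (`TE`).
#'
#' @param elements Enhancer data frame from [extract_enhancers()].
#' @param model A `poisson_model` from [fit_poisson_rate()].
#' @return `elements` with added columns `pvalue` and `klass`.
#' @export
classify_stretch <- function(elements, model) {
  stopifnot(inherits(model, "poisson_model"))
  if (nrow(elements) > 0 && any(elements$k < 1))
    stop("elements must span at least one bin (k >= 1)")
  elements$pvalue <- stats::ppois(elements$k - 1, model$lam,
                                  lower.tail = FALSE)
  elements$klass <- ifelse(elements$pvalue < model$alpha_se, "SE", "TE")
  elements
}

#' Count peaks overlapping each enhancer
#'
#' Overlap requires at least 1 bp (BEDTools-intersect semantics); a peak
#' spanning two elements is counted once for each.
#'
#' @param elements Enhancer data frame.
#' @param peaks Interval data frame of peaks (e.g. ATAC-seq).
#' @return Integer vector of peak counts, one per element.
#' @export
count_peaks_per_enhancer <- function(elements, peaks) {
  GenomicRanges::countOverlaps(.gr(elements), .gr(peaks))
}

#' Summarize per-enhancer peak counts into standard bins
#'
#' @param counts Integer vector from [count_peaks_per_enhancer()].
#' @return Named numeric vector of fractions over bins
#'   `0`, `1`, `2-3`, `>=4` (sums to 1).
#' @export
peak_count_summary <- function(counts) {
  if (length(counts) == 0) stop("no counts to summarize")
  bins <- cut(counts, breaks = c(-Inf, 0, 1, 3, Inf),
              labels = c("0", "1", "2-3", ">=4"))
  prop.table(table(bins))
}
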