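#' Identify progenitor-specific stretch enhancers
#'
#' Applies the three-criterion filter over a developmental time course:
#' (i) the element is a stretch enhancer (SE) at the PP2 (late pancreatic
#' progenitor) stage; (ii) it is not classified SE at the ES, DE or GT
#' stages; (iii) it is classified neither TE nor SE in islets. "Not
#' classified as" means zero bp of overlap with any element of that class at
#' that stage. PP1 status does not enter the filter.
#'
#' @param stages Named list of classified enhancer data frames (from
#'   [classify_stretch()]), one per stage; must include `ES`, `DE`, `GT`,
#'   `PP2` and `islet`.
#' @return Data frame of retained PP2 SE elements (the PSSE set).
#' @export
identify_psse <- function(stages) {
  required <- c("ES", "DE", "GT", "PP2", "islet")
  missing <- setdiff(required, names(stages))
  if (length(missing) > 0)
    stop("missing required stage(s): ", paste(missing, collapse = ", "))
  pp2 <- stages$PP2
  pp2_se <- pp2[pp2$klass == "SE", , drop = FALSE]
  if (nrow(pp2_se) == 0) return(pp2_se)
  excl <- rbind(
    do.call(rbind, lapply(stages[c("ES", "DE", "GT")], function(s)
      s[s$klass == "SE", c("chrom", "start", "end"), drop = FALSE])),
    stages$islet[, c("chrom", "start", "end"), drop = FALSE])
  keep <- !.overlaps_any(.gr(pp2_se), .gr(excl))
  out <- pp2_se[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromatin-state dynamics of PSSE across stages
#'
#' Assigns each PSSE one chromatin state per stage -- the state covering the
#' majority of its bp over its span, with ties broken by a fixed state
#' priority -- and tabulates the fraction of PSSE in each state per stage.
#' A PSSE with no segmentation coverage at a stage is reported as
#' `"undefined"`.
#'
#' @param psse Interval data frame of PSSE (from [identify_psse()]).
#' @param segmentations Named list of `state_segmentation` objects, one per
#'   stage.
#' @param priority Character vector of state labels used to break bp ties;
#'   states not listed rank after listed ones, alphabetically.
#' @return List with `states` (character matrix, PSSE x stage) and
#'   `fractions` (data frame, stage x state, each row summing to 1).
#' @export
state_dynamics <- function(psse, segmentations,
                           priority = c("EnhA", "EnhP", "TssFlnk", "TssA",
                                        "TssBiv", "CTCF", "Repr", "Quies")) {
  if (nrow(psse) == 0) stop("empty PSSE set")
  stages <- names(segmentations)
  gr_p <- .gr(psse)
  assign_one <- function(seg) {
    s <- seg$segments
    gr_s <- .gr(s)
    hits <- GenomicRanges::findOverlaps(gr_p, gr_s)
    q <- S4Vectors::queryHits(hits)
    su <- S4Vectors::subjectHits(hits)
    ov <- pmin(psse$end[q], s$end[su]) - pmax(psse$start[q], s$start[su])
    out <- rep("undefined", nrow(psse))
    if (length(q) > 0) {
      key <- paste(q, s$state[su], sep = "\r")
      bp <- tapply(ov, key, sum)
      parts <- strsplit(names(bp), "\r", fixed = TRUE)
      qi <- as.integer(vapply(parts, `[[`, "", 1L))
      st <- vapply(parts, `[[`, "", 2L)
      rank <- match(st, priority)
      rank[is.na(rank)] <- length(priority) + match(st[is.na(rank)],
                                                    sort(unique(st)))
      for (i in unique(qi)) {
        sel <- qi == i
        best <- which(sel)[order(-bp[sel], rank[sel])][1]
        out[i] <- st[best]
      }
    }
    out
  }
  states <- vapply(segmentations, assign_one, character(nrow(psse)))
  states <- matrix(states, nrow = nrow(psse),
                   dimnames = list(NULL, stages))
  labels <- sort(unique(as.vector(states)))
  fr <- t(apply(states, 2, function(col)
    table(factor(col, levels = labels)) / length(col)))
  fractions <- as.data.frame(fr)
  list(states = states, fractions = fractions)
}

#' Tissue-specificity z-score of a signal
#'
#' Compares the signal in a target tissue to the mean and standard deviation
#' of all other (background) tissues:
#' `z = (x_target - mean(bg)) / sd(bg)` with the sample (n-1) sd.
#'
#' @param signal Numeric vector of signals (e.g. H3K27ac tag density), one
#'   per tissue.
#' @param target Index of the target tissue within `signal`.
#' @return The z-score (scalar).
#' @export
tissue_specificity_z <- function(signal, target) {
  if (!is.numeric(signal) || any(!is.finite(signal)))
    stop("signal must be finite numeric")
  if (target < 1 || target > length(signal)) stop("target index out of range")
  bg <- signal[-target]
  if (length(bg) < 3) stop("need at least 3 background tissues")
  s <- stats::sd(bg)
  if (s == 0) stop("background sd is zero; z-score undefined")
  (signal[target] - mean(bg)) / s
}
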