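#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generators:
#' a small genome tiled into 10 kb placement slots, per-stage active
#' enhancers with zero-truncated Poisson bin counts, a set of constitutive
#' stretch enhancers shared by all stages, a planted set of
#' progenitor-specific stretch enhancers (active-enhancer chromatin only at
#' PP2, poised earlier, absent in islets), accessible-chromatin peaks nested
#' in enhancers, GWAS variants with association signal planted only inside
#' accessible PSSE chromatin, a distance-decaying Hi-C contact matrix with
#' multiplicative bin biases and planted loops, and stage-resolved
#' expression with a PP2 boost for PSSE-proximal genes.
#'
#' @param n_chroms,chrom_length Number and length (bp) of chromosomes.
#' @param bin_size Chromatin-state bin size (bp).
#' @param stages Stage labels, in developmental order.
#' @param enhancer_rate Background (typical) enhancers per Mb per stage.
#' @param length_lambda Poisson rate of background enhancer bin counts
#'   (zero-truncated, capped at `te_max_bins`).
#' @param te_max_bins Upper cap on background bin counts, keeping the
#'   background strictly inside the typical-enhancer range.
#' @param se_count Planted stretch enhancers at PP2 (shared + specific).
#' @param se_min_bins,se_extra_bins_lambda Planted SE bin counts are
#'   `se_min_bins + Poisson(se_extra_bins_lambda)`.
#' @param psse_fraction Fraction of planted PP2 SE that are
#'   progenitor-specific.
#' @param peak_per_enhancer_prob Probability an active enhancer carries an
#'   accessible-chromatin peak.
#' @param n_variants Total GWAS variants.
#' @param planted_sig_rate Fraction of variants inside accessible PSSE
#'   chromatin that carry planted association signal (p ~ 1e-8 scale).
#' @param background_sig_rate Fraction of remaining variants given planted
#'   signal (default 0: association is PSSE-specific).
#' @param null_p_floor Lower bound of the null p-value distribution
#'   (uniform on `(null_p_floor, 1]`), keeping unplanted variants clear of
#'   any realized Bonferroni threshold so the planted signal is the only
#'   sub-threshold mass; set to 0 for a pure Uniform(0,1) null.
#' @param n_known_loci Known risk loci planted far (> 1 Mb) from every PSSE.
#' @param n_genes Genes with simulated TSS and expression.
#' @param hic List of Hi-C settings: `n_bins`, `resolution`,
#'   `decay_exponent`, `bias_sd` (log-normal bin biases), `scale` (expected
#'   diagonal count), `loops` (data frame `bin_i`, `bin_j`, `fold`),
#'   `loop_shape` (`"3x3"` or `"1px"`).
#' @param seed Base RNG seed; each generator derives its own stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 1e7, bin_size = 200,
                       stages = c("ES", "DE", "GT", "PP1", "PP2", "islet"),
                       enhancer_rate = 25, length_lambda = 3,
                       te_max_bins = 8, se_count = 40, se_min_bins = 15,
                       se_extra_bins_lambda = 5, psse_fraction = 0.25,
                       peak_per_enhancer_prob = 0.9, n_variants = 20000,
                       planted_sig_rate = 0.6, background_sig_rate = 0,
                       null_p_floor = 2e-3, n_known_loci = 5, n_genes = 400,
                       hic = list(), seed = 1234L) {
  hic_def <- list(n_bins = 300, resolution = 10000, decay_exponent = 1,
                  bias_sd = 0.2, scale = 300,
                  loops = data.frame(bin_i = c(40, 100, 150, 200, 250),
                                     bin_j = c(60, 125, 170, 230, 270),
                                     fold = 10),
                  loop_shape = "3x3")
  loops_override <- if ("loops" %in% names(hic)) hic["loops"] else NULL
  hic <- utils::modifyList(hic_def, hic[setdiff(names(hic), "loops")])
  if (!is.null(loops_override)) hic$loops <- loops_override$loops
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              bin_size = bin_size, stages = stages,
              enhancer_rate = enhancer_rate, length_lambda = length_lambda,
              te_max_bins = te_max_bins, se_count = se_count,
              se_min_bins = se_min_bins,
              se_extra_bins_lambda = se_extra_bins_lambda,
              psse_fraction = psse_fraction,
              peak_per_enhancer_prob = peak_per_enhancer_prob,
              n_variants = n_variants,
              planted_sig_rate = planted_sig_rate,
              background_sig_rate = background_sig_rate,
              null_p_floor = null_p_floor, n_known_loci = n_known_loci,
              n_genes = n_genes, hic = hic, seed = as.integer(seed))
  stopifnot(cfg$psse_fraction >= 0, cfg$psse_fraction <= 1,
            cfg$planted_sig_rate >= 0, cfg$planted_sig_rate <= 1,
            cfg$enhancer_rate >= 0, cfg$length_lambda > 0,
            cfg$hic$decay_exponent > 0)
  structure(cfg, class = "sim_config")
}

#' Chromosome sizes of a simulated genome
#'
#' @param cfg A [sim_config()].
#' @return Named numeric vector of chromosome lengths.
#' @export
sim_chrom_sizes <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                  paste0("chr", seq_len(cfg$n_chroms)))
}

## internal: zero-truncated Poisson draws, optionally capped at kmax
.rztpois <- function(n, lambda, kmax = Inf) {
  lo <- stats::ppois(0, lambda)
  hi <- if (is.finite(kmax)) stats::ppois(kmax, lambda) else 1
  stats::qpois(stats::runif(n, lo, hi), lambda)
}

#' Simulate per-stage chromatin-state segmentations
#'
#' The genome is tiled into 10 kb slots; planted elements occupy distinct
#' slots with at least one quiescent bin on each side, so elements never
#' merge across slots. Three element classes are planted: constitutive
#' stretch enhancers (active at every stage including islets), PSSE (active
#' only at PP2, poised enhancer chromatin at ES/DE/GT/PP1, quiescent in
#' islets), and per-stage background typical enhancers with zero-truncated
#' Poisson bin counts capped below the stretch range. Known risk loci are
#' placed more than 1 Mb from every PSSE. Accessible-chromatin peaks are
#' planted inside active enhancers.
#'
#' @param cfg A [sim_config()].
#' @return List with `segmentations` (named list of `state_segmentation`),
#'   `peaks` (named list of interval data frames per stage), `known_loci`
#'   (interval data frame), and `truth` (list with `psse`, `shared_se`).
#' @export
simulate_segmentations <- function(cfg) {
  set.seed(cfg$seed + 1L)
  slot_bp <- 10000
  slot_bins <- slot_bp / cfg$bin_size
  slots_per_chrom <- floor(cfg$chrom_length / slot_bp)
  chroms <- names(sim_chrom_sizes(cfg))
  slots <- data.frame(chrom = rep(chroms, each = slots_per_chrom),
                      start = rep((seq_len(slots_per_chrom) - 1) * slot_bp,
                                  cfg$n_chroms))
  n_slots <- nrow(slots)
  n_psse <- round(cfg$psse_fraction * cfg$se_count)
  n_shared <- cfg$se_count - n_psse
  n_bg <- round(cfg$enhancer_rate * cfg$n_chroms * cfg$chrom_length / 1e6)
  if (n_slots < n_psse + n_shared + cfg$n_known_loci + n_bg)
    stop("genome too small for the requested number of elements")

  take <- sample.int(n_slots, n_psse + n_shared)
  psse_slots <- take[seq_len(n_psse)]
  shared_slots <- take[n_psse + seq_len(n_shared)]
  ## known loci: slots > 1 Mb from every PSSE slot (same chromosome)
  far <- vapply(seq_len(n_slots), function(s) {
    same <- psse_slots[slots$chrom[psse_slots] == slots$chrom[s]]
    length(same) == 0 ||
      min(abs(slots$start[same] - slots$start[s])) > 1e6
  }, logical(1))
  known_pool <- setdiff(which(far), take)
  if (length(known_pool) < cfg$n_known_loci)
    stop("genome too small to place known loci away from PSSE")
  known_slots <- sample(known_pool, cfg$n_known_loci)
  bg_pool <- setdiff(seq_len(n_slots), take)

  place <- function(slot_idx, k) {
    # element of k bins inside its slot, >= 1 bin clear of both edges
    k <- pmin(k, slot_bins - 2)
    off <- floor(stats::runif(length(slot_idx)) * (slot_bins - k - 1)) + 1
    start <- slots$start[slot_idx] + off * cfg$bin_size
    data.frame(chrom = slots$chrom[slot_idx], start = start,
               end = start + k * cfg$bin_size, k = k,
               stringsAsFactors = FALSE)
  }
  k_shared <- cfg$se_min_bins + stats::rpois(n_shared,
                                             cfg$se_extra_bins_lambda)
  k_psse <- cfg$se_min_bins + stats::rpois(n_psse, cfg$se_extra_bins_lambda)
  shared <- place(shared_slots, k_shared)
  psse <- place(psse_slots, k_psse)

  segmentations <- list()
  peaks <- list()
  for (stage in cfg$stages) {
    bg_slots <- sample(bg_pool, n_bg)
    k_bg <- .rztpois(n_bg, cfg$length_lambda, kmax = cfg$te_max_bins)
    bg <- place(bg_slots, k_bg)
    active <- rbind(shared, bg)
    poised <- NULL
    if (stage == "PP2") {
      active <- rbind(active, psse)
    } else if (stage != "islet" && nrow(psse) > 0) {
      poised <- psse
    }
    elems <- rbind(
      if (nrow(active) > 0) cbind(active, state = "EnhA"),
      if (!is.null(poised) && nrow(poised) > 0) cbind(poised, state = "EnhP"))
    elems <- elems[order(elems$chrom, elems$start), , drop = FALSE]
    ## fill gaps with quiescent state
    seg_list <- lapply(chroms, function(ch) {
      e <- elems[elems$chrom == ch, , drop = FALSE]
      bounds <- c(0, as.vector(rbind(e$start, e$end)), cfg$chrom_length)
      starts <- bounds[-length(bounds)]
      ends <- bounds[-1]
      state <- rep("Quies", length(starts))
      if (nrow(e) > 0) state[seq(2, length(state), by = 2)] <- e$state
      keep <- ends > starts
      data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                 state = state[keep], stringsAsFactors = FALSE)
    })
    seg <- do.call(rbind, seg_list)
    segmentations[[stage]] <- state_segmentation(seg$chrom, seg$start,
                                                 seg$end, seg$state,
                                                 bin_size = cfg$bin_size,
                                                 stage = stage)
    ## one accessible-chromatin peak per active enhancer, w.p. peak_per_enhancer_prob
    has_peak <- stats::runif(nrow(active)) < cfg$peak_per_enhancer_prob
    pk <- active[has_peak, , drop = FALSE]
    if (nrow(pk) > 0) {
      pw <- pmin(400, pk$end - pk$start)
      po <- floor(stats::runif(nrow(pk)) * (pk$end - pk$start - pw + 1))
      peaks[[stage]] <- genomic_intervals(pk$chrom, pk$start + po,
                                          pk$start + po + pw)
    } else {
      peaks[[stage]] <- genomic_intervals(character(), numeric(), numeric())
    }
  }
  known <- genomic_intervals(slots$chrom[known_slots],
                             slots$start[known_slots],
                             slots$start[known_slots] + slot_bp)
  o <- order(psse$chrom, psse$start)
  list(segmentations = segmentations, peaks = peaks, known_loci = known,
       truth = list(psse = psse[o, , drop = FALSE],
                    shared_se = shared[order(shared$chrom, shared$start), ,
                                       drop = FALSE]))
}

#' Simulate GWAS variants with planted PSSE association
#'
#' Positions are uniform over the genome. Variants falling inside the
#' accessible chromatin of PSSE carry planted association signal
#' (p-values on the 1e-8 scale) with probability `planted_sig_rate`;
#' all other variants draw null p-values uniform on `(null_p_floor, 1]`
#' (see [sim_config()]).
#'
#' @param cfg A [sim_config()].
#' @param psse_atac Interval data frame: accessible-chromatin peaks inside
#'   PSSE (e.g. from [interval_intersection()]).
#' @return List with `variants` (data frame `chrom`, `pos`, `id`, `pvalue`)
#'   and `truth` (same rows plus logical `planted`).
#' @export
simulate_variants <- function(cfg, psse_atac) {
  set.seed(cfg$seed + 2L)
  sizes <- sim_chrom_sizes(cfg)
  n <- cfg$n_variants
  chrom <- sample(names(sizes), n, replace = TRUE,
                  prob = sizes / sum(sizes))
  pos <- 1 + floor(stats::runif(n) * sizes[chrom])
  v <- data.frame(chrom = chrom, pos = as.numeric(pos),
                  id = sprintf("rs%06d", seq_len(n)),
                  pvalue = cfg$null_p_floor +
                    stats::runif(n) * (1 - cfg$null_p_floor),
                  stringsAsFactors = FALSE)
  inside <- .overlaps_any(.variant_gr(v), .gr(psse_atac))
  planted <- inside & stats::runif(n) < cfg$planted_sig_rate
  if (cfg$background_sig_rate > 0) {
    extra <- !planted & stats::runif(n) < cfg$background_sig_rate
    planted_bg <- extra
    v$pvalue[planted_bg] <- 10^stats::runif(sum(planted_bg), -10, -8)
  }
  v$pvalue[planted] <- 10^stats::runif(sum(planted), -10, -8)
  truth <- v
  truth$planted <- planted
  list(variants = v, truth = truth)
}

#' Simulate a Hi-C contact matrix with planted loops
#'
#' Expected counts decay with distance as `scale * (1 + d)^-decay_exponent`,
#' are modulated by log-normal per-bin biases, and are multiplied by `fold`
#' at planted loop pixels (a 3x3 neighborhood or a single pixel, per
#' `loop_shape`). Observed counts are Poisson draws, symmetrized.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (a `contact_matrix`), `truth` (the planted
#'   loop data frame), and `biases` (true per-bin biases).
#' @export
simulate_contact_matrix <- function(cfg) {
  set.seed(cfg$seed + 3L)
  h <- cfg$hic
  n <- h$n_bins
  b <- exp(stats::rnorm(n, 0, h$bias_sd))
  d <- abs(row(diag(n)) - col(diag(n)))
  lam <- h$scale * (1 + d)^(-h$decay_exponent) * outer(b, b)
  loops <- h$loops
  if (!is.null(loops) && nrow(loops) > 0) {
    r <- if (identical(h$loop_shape, "3x3")) -1:1 else 0
    for (k in seq_len(nrow(loops))) {
      ii <- pmax(1, pmin(n, loops$bin_i[k] + 1 + r))
      jj <- pmax(1, pmin(n, loops$bin_j[k] + 1 + r))
      lam[ii, jj] <- lam[ii, jj] * loops$fold[k]
      lam[jj, ii] <- lam[jj, ii] * loops$fold[k]
    }
  }
  up <- which(upper.tri(lam, diag = TRUE))
  m <- matrix(0, n, n)
  m[up] <- stats::rpois(length(up), lam[up])
  m <- m + t(m) - diag(diag(m))
  list(matrix = contact_matrix(m, chrom = "chr1", resolution = h$resolution),
       truth = loops, biases = b)
}

#' Simulate gene annotations
#'
#' TSS positions uniform over the genome, random strands.
#'
#' @param cfg A [sim_config()].
#' @return Gene table (`gene_id`, `chrom`, `tss`, `strand`).
#' @export
simulate_genes <- function(cfg) {
  set.seed(cfg$seed + 4L)
  sizes <- sim_chrom_sizes(cfg)
  chrom <- sample(names(sizes), cfg$n_genes, replace = TRUE,
                  prob = sizes / sum(sizes))
  g <- data.frame(gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
                  chrom = chrom,
                  tss = 1 + floor(stats::runif(cfg$n_genes) * sizes[chrom]),
                  strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                  stringsAsFactors = FALSE)
  g <- g[order(g$chrom, g$tss), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Simulate stage-resolved expression
#'
#' Background genes draw log-normal FPKM independently per stage. The gene
#' nearest each planted PSSE receives a multiplicative boost at PP2 and a
#' reduction in islets, emulating expression that rises along the pancreatic
#' lineage, peaks at the late-progenitor stage, and falls in mature islets.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene table from [simulate_genes()].
#' @param psse_truth Planted PSSE data frame (`truth$psse` from
#'   [simulate_segmentations()]).
#' @param pp2_boost,islet_factor Multiplicative effects (defaults 4 and
#'   0.25).
#' @return List with `fpkm` (data frame `gene_id` + one column per stage)
#'   and `truth` (data frame `gene_id`, `pp2_boost`, `islet_factor` for
#'   boosted genes).
#' @export
simulate_expression <- function(cfg, genes, psse_truth, pp2_boost = 4,
                                islet_factor = 0.25) {
  set.seed(cfg$seed + 5L)
  n <- nrow(genes)
  fpkm <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (stage in cfg$stages)
    fpkm[[stage]] <- exp(stats::rnorm(n, 1, 1))
  boosted <- character(0)
  if (!is.null(psse_truth) && nrow(psse_truth) > 0) {
    for (r in seq_len(nrow(psse_truth))) {
      same <- which(genes$chrom == psse_truth$chrom[r])
      if (length(same) == 0) next
      dd <- .tss_distance(genes$tss[same], psse_truth$start[r],
                          psse_truth$end[r])
      boosted <- c(boosted, genes$gene_id[same[which.min(dd)]])
    }
    boosted <- unique(boosted)
    idx <- match(boosted, fpkm$gene_id)
    if ("PP2" %in% cfg$stages)
      fpkm$PP2[idx] <- fpkm$PP2[idx] * pp2_boost
    if ("islet" %in% cfg$stages)
      fpkm$islet[idx] <- fpkm$islet[idx] * islet_factor
  }
  list(fpkm = fpkm,
       truth = data.frame(gene_id = boosted, pp2_boost = pp2_boost,
                          islet_factor = islet_factor,
                          stringsAsFactors = FALSE))
}
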