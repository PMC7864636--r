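#' Default pipeline configuration
#'
#' All analysis thresholds are surfaced here with their standard values:
#' stretch-enhancer alpha 0.001, 10,000 permutation iterations, Bonferroni
#' family-wise alpha 0.05, 500 kb locus merge and novelty distances, loop
#' candidate/final p-value cutoffs 0.01 and 1e-5, 20 kb loop collapse.
#'
#' @param simulate Generate all inputs with the synthetic module (`TRUE`,
#'   default) or read them from the paths in `inputs`.
#' @param sim Named list of [sim_config()] overrides.
#' @param inputs Named list of input paths (required when
#'   `simulate = FALSE`): `segmentations` (named list of BED4 paths per
#'   stage), `peaks` (named list per stage), `variants`, `known_loci`,
#'   `genes`, `fpkm`, `matrix`, optionally `tads`, `chrom_sizes`.
#' @param alpha_se Stretch-enhancer significance threshold.
#' @param n_iter Permutation iterations.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param merge_dist,novel_dist Locus grouping / novelty distances (bp).
#' @param min_fpkm Expression cutoff for target-gene assignment.
#' @param loops Named list of [loop_params()] overrides.
#' @param seed Seed for the simulation and permutation streams.
#' @return A config list consumable by [run_pipeline()].
#' @export
pipeline_config <- function(simulate = TRUE, sim = list(), inputs = list(),
                            alpha_se = 0.001, n_iter = 10000, alpha = 0.05,
                            merge_dist = 500000, novel_dist = 500000,
                            min_fpkm = 1, loops = list(), seed = 1234L) {
  list(simulate = simulate, sim = sim, inputs = inputs, alpha_se = alpha_se,
       n_iter = n_iter, alpha = alpha, merge_dist = merge_dist,
       novel_dist = novel_dist, min_fpkm = min_fpkm, loops = loops,
       seed = as.integer(seed))
}

## internal: validate config before any stage runs
.validate_config <- function(config) {
  defaults <- pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config)
  if (!isTRUE(config$simulate)) {
    req <- c("segmentations", "peaks", "variants", "known_loci", "genes",
             "fpkm", "matrix", "chrom_sizes")
    missing <- setdiff(req, names(config$inputs))
    if (length(missing) > 0)
      stop("simulate = FALSE but input path(s) missing: ",
           paste(missing, collapse = ", "))
  }
  config
}

## internal: run one stage with error attribution
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: input acquisition (simulated or
#' read from files), stretch-enhancer calling per stage, PSSE
#' identification, permutation overlap enrichment of PP2 stretch enhancers
#' against accessible chromatin, GWAS-variant prioritization (intersection
#' with PSSE, Bonferroni threshold, locus grouping, novelty flags), Hi-C
#' balancing and loop calling, and target-gene assignment for PSSE. Writes
#' per-stage BED/TSV outputs plus a JSON run manifest with per-stage counts;
#' the run is deterministic given the config, so rerunning writes an
#' identical manifest.
#'
#' @param config A list from [pipeline_config()], or the path to a YAML
#'   file holding one.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `manifest`, the output `paths`, and the
#'   in-memory `objects` (classified stages, PSSE, loci, loops, targets,
#'   plus simulation `truth` when simulated).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  ## --- inputs -------------------------------------------------------------
  inp <- .stage("inputs", {
    if (isTRUE(config$simulate)) {
      cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
      seg <- simulate_segmentations(cfg)
      genes <- simulate_genes(cfg)
      expr <- simulate_expression(cfg, genes, seg$truth$psse)
      hic <- simulate_contact_matrix(cfg)
      list(cfg = cfg, segmentations = seg$segmentations, peaks = seg$peaks,
           known_loci = seg$known_loci, genes = genes, fpkm = expr$fpkm,
           matrix = hic$matrix, tads = NULL,
           sizes = sim_chrom_sizes(cfg),
           truth = list(psse = seg$truth$psse,
                        shared_se = seg$truth$shared_se,
                        loops = hic$truth, expression = expr$truth))
    } else {
      io <- config$inputs
      segs <- lapply(io$segmentations, read_segmentation)
      for (s in names(segs)) segs[[s]]$stage <- s
      list(cfg = NULL, segmentations = segs,
           peaks = lapply(io$peaks, read_bed),
           known_loci = read_bed(io$known_loci),
           genes = read_gene_table(io$genes),
           fpkm = read_fpkm_table(io$fpkm),
           matrix = read_contact_matrix(io$matrix),
           tads = if (!is.null(io$tads)) read_bed(io$tads) else NULL,
           sizes = read_chrom_sizes(io$chrom_sizes))
    }
  })

  truth <- inp$truth
  stages <- names(inp$segmentations)

  ## --- stretch-enhancer calling -------------------------------------------
  classified <- .stage("enhancer_calling", {
    lapply(inp$segmentations, function(seg) {
      el <- extract_enhancers(seg, "EnhA")
      classify_stretch(el, fit_poisson_rate(el, alpha_se = config$alpha_se))
    })
  })
  for (s in stages) {
    cl <- classified[[s]]
    paths[[paste0("se_", s)]] <- file.path(outdir, paste0("enhancers_", s,
                                                          ".bed"))
    write_bed(genomic_intervals(cl$chrom, cl$start, cl$end, name = cl$klass,
                                score = round(-log10(cl$pvalue), 4)),
              paths[[paste0("se_", s)]])
  }

  ## --- PSSE ---------------------------------------------------------------
  psse <- .stage("psse_identification", identify_psse(classified))
  paths$psse <- file.path(outdir, "psse.bed")
  write_bed(psse[, c("chrom", "start", "end")], paths$psse)

  ## --- permutation enrichment ---------------------------------------------
  enr <- .stage("interval_enrichment", {
    pp2 <- classified$PP2
    pp2_se <- pp2[pp2$klass == "SE", , drop = FALSE]
    permutation_enrichment(pp2_se, inp$peaks$PP2, inp$sizes,
                           n_iter = config$n_iter, seed = config$seed)
  })

  ## --- variant prioritization ---------------------------------------------
  psse_atac <- interval_intersection(inp$peaks$PP2, psse)
  if (isTRUE(config$simulate)) {
    sv <- .stage("inputs", simulate_variants(inp$cfg, psse_atac))
    variants <- sv$variants
    truth$variants <- sv$truth
  } else {
    variants <- .stage("inputs", read_variant_table(config$inputs$variants))
  }
  prio <- .stage("variant_prioritization", {
    in_psse <- intersect_variants(variants, psse)
    threshold <- if (nrow(in_psse) > 0)
      bonferroni_threshold(nrow(in_psse), config$alpha) else NA_real_
    sig <- if (nrow(in_psse) > 0)
      significant_variants(in_psse, threshold) else in_psse
    loci <- flag_novel(cluster_loci(sig, config$merge_dist),
                       inp$known_loci, config$novel_dist)
    list(in_psse = in_psse, threshold = threshold, sig = sig, loci = loci)
  })
  paths$loci <- file.path(outdir, "loci.tsv")
  utils::write.table(prio$loci, paths$loci, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- Hi-C loops ---------------------------------------------------------
  lp <- do.call(loop_params, config$loops)
  loops <- .stage("hic_loops", call_loops(inp$matrix, lp))
  fl <- final_loops(loops)
  paths$loops <- file.path(outdir, "loops.tsv")
  write_loops(loops, paths$loops, chrom = inp$matrix$chrom,
              resolution = inp$matrix$resolution)

  ## --- target genes -------------------------------------------------------
  targets <- .stage("target_genes", {
    if (nrow(psse) > 0)
      assign_target_genes(psse, inp$genes, inp$fpkm, "PP2",
                          min_fpkm = config$min_fpkm)
    else NULL
  })
  if (!is.null(targets)) {
    paths$targets <- file.path(outdir, "targets.tsv")
    utils::write.table(targets, paths$targets, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## --- manifest -----------------------------------------------------------
  manifest <- list(
    seed = config$seed,
    config = config[c("simulate", "alpha_se", "n_iter", "alpha",
                      "merge_dist", "novel_dist", "min_fpkm", "seed")],
    counts = list(
      n_enhancers = lapply(classified, nrow),
      n_se = lapply(classified, function(x) sum(x$klass == "SE")),
      n_psse = nrow(psse),
      n_variants_in_psse = nrow(prio$in_psse),
      threshold = prio$threshold,
      n_significant = nrow(prio$sig),
      n_loci = nrow(prio$loci),
      n_novel = sum(prio$loci$novel),
      n_loops = nrow(fl)),
    enrichment = list(observed = enr$observed, fold = enr$fold,
                      pvalue = enr$pvalue_empirical))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, paths = paths,
                 objects = list(classified = classified, psse = psse,
                                enrichment = enr, variants = variants,
                                loci = prio$loci, loops = loops,
                                final_loops = fl, targets = targets,
                                truth = truth)))
}
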