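small_cfg <- function(...) {
  sim_config(n_chroms = 2, chrom_length = 5e6, enhancer_rate = 25,
             se_count = 12, n_variants = 3000, n_genes = 80,
             hic = list(n_bins = 120), ...)
}

test_that("generators are pure functions of the config seed", {
  cfg <- small_cfg(seed = 555)
  a <- simulate_segmentations(cfg)
  b <- simulate_segmentations(cfg)
  expect_identical(a, b)
  atac <- a$peaks$PP2
  expect_identical(simulate_variants(cfg, atac), simulate_variants(cfg, atac))
  expect_identical(simulate_contact_matrix(cfg)$matrix$counts,
                   simulate_contact_matrix(cfg)$matrix$counts)
  g <- simulate_genes(cfg)
  expect_identical(simulate_expression(cfg, g, a$truth$psse),
                   simulate_expression(cfg, g, a$truth$psse))
  # a different seed changes the data
  expect_false(identical(a$truth$psse,
                         simulate_segmentations(small_cfg(seed = 556))$truth$psse))
})

test_that("simulated segmentations round-trip losslessly through the readers", {
  cfg <- small_cfg(seed = 601)
  sim <- simulate_segmentations(cfg)
  f <- withr::local_tempfile()
  write_segmentation(sim$segmentations$PP2, f)
  back <- read_segmentation(f, bin_size = cfg$bin_size, stage = "PP2")
  expect_equal(back$segments, sim$segmentations$PP2$segments)

  sv <- simulate_variants(cfg, sim$peaks$PP2)
  f2 <- withr::local_tempfile()
  write_variant_table(sv$variants, f2)
  back2 <- read_variant_table(f2)
  expect_equal(back2$pos, sv$variants$pos)
  expect_equal(back2$pvalue, sv$variants$pvalue)

  hic <- simulate_contact_matrix(cfg)
  f3 <- withr::local_tempfile()
  write_contact_matrix(hic$matrix, f3)
  expect_equal(read_contact_matrix(f3, n_bins = cfg$hic$n_bins)$counts,
               hic$matrix$counts)
})

test_that("the planted PSSE truth set is recovered exactly by the calling chain", {
  for (seed in c(611, 612, 613)) {
    cfg <- small_cfg(seed = seed)
    sim <- simulate_segmentations(cfg)
    cl <- lapply(sim$segmentations, function(s) {
      el <- extract_enhancers(s, "EnhA")
      classify_stretch(el, fit_poisson_rate(el))
    })
    got <- identify_psse(cl)[, c("chrom", "start", "end")]
    want <- sim$truth$psse[, c("chrom", "start", "end")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("psse_fraction = 0 plants nothing progenitor-specific", {
  cfg <- small_cfg(seed = 617, psse_fraction = 0)
  sim <- simulate_segmentations(cfg)
  expect_equal(nrow(sim$truth$psse), 0)
  cl <- lapply(sim$segmentations, function(s) {
    el <- extract_enhancers(s, "EnhA")
    classify_stretch(el, fit_poisson_rate(el))
  })
  expect_equal(nrow(identify_psse(cl)), 0)
})

test_that("planted variants are the only sub-threshold mass and are all recovered", {
  # default scale: the realized Bonferroni threshold sits below the null
  # p-value floor, so separation holds by construction
  cfg <- sim_config(seed = 619)
  sim <- simulate_segmentations(cfg)
  psse_iv <- sim$truth$psse
  atac_in_psse <- interval_intersection(sim$peaks$PP2, psse_iv)
  sv <- simulate_variants(cfg, atac_in_psse)
  in_psse <- intersect_variants(sv$variants, psse_iv)
  thr <- bonferroni_threshold(nrow(in_psse))
  sig <- significant_variants(in_psse, thr)
  expect_equal(sort(sig$id), sort(sv$truth$id[sv$truth$planted]))
})

test_that("with no planted signal and an unfloored null, significance is calibrated", {
  # expected significant count = n_inside * (0.05 / n_inside) = 0.05
  hits <- 0
  for (seed in 701:720) {
    cfg <- small_cfg(seed = seed, planted_sig_rate = 0, null_p_floor = 0)
    sim <- simulate_segmentations(cfg)
    sv <- simulate_variants(cfg, interval_intersection(sim$peaks$PP2,
                                                       sim$truth$psse))
    in_psse <- intersect_variants(sv$variants, sim$truth$psse)
    if (nrow(in_psse) == 0) next
    thr <- bonferroni_threshold(nrow(in_psse))
    hits <- hits + nrow(significant_variants(in_psse, thr))
  }
  # 20 replicates, each Binomial(n_inside, 0.05/n_inside): mean 1, 99.9% < 7
  expect_lte(hits, 7)
})

test_that("contact simulation plants recoverable loops and biases", {
  cfg <- sim_config(seed = 733, hic = list(n_bins = 200, bias_sd = 0.15,
                                           loops = data.frame(bin_i = c(50, 120),
                                                              bin_j = c(70, 150),
                                                              fold = 10)))
  sim <- simulate_contact_matrix(cfg)
  fl <- final_loops(call_loops(sim$matrix))
  expect_equal(nrow(fl), 2)
  for (k in 1:2) {
    d <- pmax(abs(fl$bin_i - sim$truth$bin_i[k]),
              abs(fl$bin_j - sim$truth$bin_j[k]))
    expect_lte(min(d), 2)
  }
  # balancing tracks the planted biases (Poisson noise and decay edge
  # effects bound the agreement away from exactness)
  bal <- balance_matrix(sim$matrix)
  expect_gt(cor(bal$weights, sim$biases), 0.9)
})

test_that("expression boosts give the rank-sum test its intended power", {
  # many progenitor-specific elements -> a sizeable boosted gene group
  cfg <- sim_config(seed = 739, se_count = 80, psse_fraction = 1,
                    n_known_loci = 0)
  sim <- simulate_segmentations(cfg)
  genes <- simulate_genes(cfg)
  reject <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    ex <- simulate_expression(cfg_r, genes, sim$truth$psse, pp2_boost = 4)
    boosted <- ex$fpkm$gene_id %in% ex$truth$gene_id
    # compare a boosted sample against background at matched size
    a <- ex$fpkm$PP2[boosted]
    b <- ex$fpkm$PP2[!boosted][seq_len(min(200, sum(!boosted)))]
    if (compare_expression(a, b)$pvalue < 0.05) reject <- reject + 1
  }
  expect_gt(reject / n_rep, 0.8)
  # and without a boost the test is near-null
  ex0 <- simulate_expression(cfg, genes, sim$truth$psse, pp2_boost = 1,
                             islet_factor = 1)
  boosted <- ex0$fpkm$gene_id %in% ex0$truth$gene_id
  p0 <- compare_expression(ex0$fpkm$PP2[boosted],
                           ex0$fpkm$PP2[!boosted])$pvalue
  expect_gt(p0, 0.001)
})
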