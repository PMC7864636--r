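genes_fix <- data.frame(
  gene_id = c("GA", "GB", "GC", "GD"),
  chrom = c("chr1", "chr1", "chr1", "chr2"),
  tss = c(500, 2000, 9000, 700),
  strand = c("+", "-", "+", "+"),
  stringsAsFactors = FALSE)
fpkm_fix <- data.frame(gene_id = c("GA", "GB", "GC", "GD"),
                       PP2 = c(0.5, 2, 3, 8),
                       islet = c(4, 0, 0, 0),
                       stringsAsFactors = FALSE)
enh <- data.frame(chrom = "chr1", start = 900, end = 1300)

test_that("expression filtering precedes proximity", {
  # GA (FPKM 0.5) is nearer than GB (FPKM 2): GB wins at PP2
  hit <- nearest_expressed_gene(enh, genes_fix, fpkm_fix, "PP2")
  expect_equal(hit$gene_id, "GB")
  expect_equal(hit$distance, 2000 - 1 - (1300 - 1))
  # at islet, only GA is expressed
  expect_equal(nearest_expressed_gene(enh, genes_fix, fpkm_fix,
                                      "islet")$gene_id, "GA")
  # TSS inside the interval: distance 0
  inside <- nearest_expressed_gene(data.frame(chrom = "chr1", start = 1900,
                                              end = 2100),
                                   genes_fix, fpkm_fix, "PP2")
  expect_equal(inside$distance, 0)
  # no expressed gene on the chromosome: explicit no-assignment
  none <- nearest_expressed_gene(data.frame(chrom = "chr2", start = 0,
                                            end = 100),
                                 genes_fix, fpkm_fix, "islet")
  expect_equal(nrow(none), 0)
})

test_that("equidistant TSS ties break to the lower coordinate; oracle agreement", {
  set.seed(73)
  for (rep in 1:10) {
    n <- 30
    g <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                    tss = sample(1:5000, n), strand = "+",
                    stringsAsFactors = FALSE)
    fp <- data.frame(gene_id = g$gene_id, PP2 = round(runif(n) * 4, 1))
    iv <- data.frame(chrom = "chr1", start = 2000, end = 2400)
    hit <- nearest_expressed_gene(iv, g, fp, "PP2")
    # exhaustive scan oracle
    expr <- fp$PP2 >= 1
    d <- vapply(g$tss, function(t) {
      p <- t - 1
      if (p >= iv$start && p < iv$end) 0
      else min(abs(p - iv$start), abs(p - (iv$end - 1)))
    }, numeric(1))
    cand <- which(expr)
    if (length(cand) == 0) {
      expect_equal(nrow(hit), 0)
    } else {
      best <- cand[order(d[cand], g$tss[cand])][1]
      expect_equal(hit$gene_id, g$gene_id[best])
      expect_equal(hit$distance, d[best])
      expect_true(all(hit$distance <= d[cand]))
    }
  }
  # explicit tie: TSS 100 bp left and right of the interval
  g2 <- data.frame(gene_id = c("L", "R"), chrom = "chr1",
                   tss = c(901, 1500), strand = "+",
                   stringsAsFactors = FALSE)
  # interval [1000,1400): left gene 0-based 900 -> 100 bp; right 1499 -> 100 bp
  fp2 <- data.frame(gene_id = c("L", "R"), PP2 = c(5, 5))
  tie <- nearest_expressed_gene(data.frame(chrom = "chr1", start = 1000,
                                           end = 1400), g2, fp2, "PP2")
  expect_equal(tie$gene_id, "L")
})

test_that("raising the expression cutoff never adds genes", {
  set.seed(79)
  g <- data.frame(gene_id = sprintf("g%02d", 1:20), chrom = "chr1",
                  tss = sample(1:20000, 20), strand = "+",
                  stringsAsFactors = FALSE)
  fp <- data.frame(gene_id = g$gene_id, PP2 = runif(20) * 5)
  tads <- data.frame(chrom = "chr1", start = c(0, 10000),
                     end = c(10000, 20000))
  iv <- data.frame(chrom = "chr1", start = 3000, end = 3400)
  sets <- lapply(c(0.5, 1, 2, 4), function(cut)
    genes_in_tad(iv, tads, g, fp, "PP2", min_fpkm = cut)$gene_id)
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("TAD gene lookup keys on TSS containment and validates TADs", {
  tads <- data.frame(chrom = "chr1", start = c(0, 5000),
                     end = c(5000, 12000))
  # enhancer in TAD 1: GA (tss 500) and GB (tss 2000) share it; GB expressed
  got <- genes_in_tad(enh, tads, genes_fix, fpkm_fix, "PP2")
  expect_equal(got$gene_id, "GB")
  # a TSS at 1-based 5000 is the last base of TAD [0,5000); 5001 starts the next
  edge <- data.frame(gene_id = c("GE", "GF"), chrom = "chr1",
                     tss = c(5000, 5001), strand = "+",
                     stringsAsFactors = FALSE)
  fpe <- data.frame(gene_id = c("GE", "GF"), PP2 = c(9, 9))
  expect_equal(genes_in_tad(enh, tads, edge, fpe, "PP2")$gene_id, "GE")
  in2 <- data.frame(chrom = "chr1", start = 6000, end = 6400)
  expect_equal(genes_in_tad(in2, tads, edge, fpe, "PP2")$gene_id, "GF")

  expect_error(genes_in_tad(enh, data.frame(chrom = "chr1",
                                            start = c(0, 4000),
                                            end = c(5000, 9000)),
                            genes_fix, fpkm_fix, "PP2"), "overlapping")
  expect_warning(out <- genes_in_tad(data.frame(chrom = "chr2", start = 0,
                                                end = 100),
                                     tads, genes_fix, fpkm_fix, "PP2"),
                 "no TAD")
  expect_equal(nrow(out), 0)
})

test_that("TAD membership matches the all-pairs containment oracle", {
  set.seed(83)
  for (rep in 1:10) {
    bounds <- sort(sample(seq(0, 5e4, by = 1000), 6))
    tads <- data.frame(chrom = "chr1", start = bounds[c(1, 3, 5)],
                       end = bounds[c(2, 4, 6)])
    n <- 40
    g <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                    tss = sample(1:5e4, n), strand = "+",
                    stringsAsFactors = FALSE)
    fp <- data.frame(gene_id = g$gene_id, PP2 = runif(n) * 3)
    iv_start <- sample(seq(0, 48000, by = 400), 1)
    iv <- data.frame(chrom = "chr1", start = iv_start, end = iv_start + 1500)
    got <- suppressWarnings(genes_in_tad(iv, tads, g, fp, "PP2"))
    in_tads <- tads[tads$start < iv$end & tads$end > iv$start, , drop = FALSE]
    want <- g$gene_id[vapply(seq_len(n), function(i)
      fp$PP2[i] >= 1 && any(g$tss[i] - 1 >= in_tads$start &
                              g$tss[i] - 1 < in_tads$end), logical(1))]
    expect_equal(sort(got$gene_id), sort(want))
  }
})
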