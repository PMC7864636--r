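# Brute-force reference implementations used as independent oracles.
# All deliberately O(n*m) or per-bin scans, sharing no code with the package.

# >= 1 bp overlap between one interval and each row of a set
bf_hits <- function(chrom, start, end, set) {
  which(set$chrom == chrom & set$start < end & set$end > start)
}

bf_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    length(bf_hits(a$chrom[i], a$start[i], a$end[i], b)) > 0, logical(1))
}

bf_count_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i)
    length(bf_hits(a$chrom[i], a$start[i], a$end[i], b)), integer(1))
}

# PSSE filter by exhaustive all-pairs scan
bf_psse <- function(stages) {
  pp2 <- stages$PP2
  se <- pp2[pp2$klass == "SE", , drop = FALSE]
  excl <- rbind(stages$ES[stages$ES$klass == "SE", c("chrom", "start", "end")],
                stages$DE[stages$DE$klass == "SE", c("chrom", "start", "end")],
                stages$GT[stages$GT$klass == "SE", c("chrom", "start", "end")],
                stages$islet[, c("chrom", "start", "end")])
  keep <- !bf_overlaps_any(se, excl)
  out <- se[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# random classified enhancer set on a small genome
rand_classified <- function(n, chroms = c("chr1", "chr2"), genome = 1e5,
                            se_prob = 0.3) {
  start <- floor(runif(n) * (genome - 5000))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + 200 * sample(1:20, n, TRUE),
             k = 1, stage = "x",
             pvalue = runif(n),
             klass = sample(c("SE", "TE"), n, TRUE,
                            prob = c(se_prob, 1 - se_prob)),
             stringsAsFactors = FALSE)
}

# donut expected count by explicit double loop (no shared code)
bf_donut <- function(m, weights, e, i0, j0, inner, outer) {
  n <- nrow(m)
  i <- i0 + 1
  j <- j0 + 1
  vals <- c()
  for (ip in 1:n) for (jp in 1:n) {
    r <- max(abs(ip - i), abs(jp - j))
    if (r <= inner || r > outer) next
    if (ip == i || jp == j) next
    dref <- e[abs(ip - jp) + 1]
    if (!is.finite(dref) || dref <= 0) next
    v <- m[ip, jp] / (weights[ip] * weights[jp]) / dref
    if (is.finite(v)) vals <- c(vals, v)
  }
  if (length(vals) == 0) return(NA_real_)
  mean(vals) * e[abs(i - j) + 1] * weights[i] * weights[j]
}

# single-linkage grouping of positions by transitive closure (naive)
bf_cluster <- function(chrom, pos, merge_dist) {
  n <- length(pos)
  id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (chrom[a] == chrom[b] && abs(pos[a] - pos[b]) <= merge_dist &&
          id[a] != id[b]) {
        id[id == id[b]] <- id[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(id, unique(id))
}
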