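#' Loop-calling parameters
#'
#' Defaults follow common practice for 10 kb matrices: donut radii
#' `donut_inner = 2`, `donut_outer = 5` bins; candidate pixels at Poisson
#' p < 0.01 and at least `min_diag_dist` bins off the diagonal; candidates
#' within 20 kb of each other collapsed to their most significant pixel;
#' final loops at p < 1e-5.
#'
#' @param resolution Matrix resolution in bp.
#' @param donut_inner,donut_outer Inner (exclusive) and outer (inclusive)
#'   Chebyshev radii of the donut, in bins.
#' @param p_candidate Candidate-pixel p-value threshold.
#' @param p_final Final-loop p-value threshold.
#' @param collapse_dist Collapse radius in bp (single linkage, Chebyshev).
#' @param min_diag_dist Minimum pixel distance from the diagonal, in bins.
#' @param max_dist Optional maximum pixel distance in bp.
#' @return A `loop_params` list.
#' @export
loop_params <- function(resolution = 10000, donut_inner = 2, donut_outer = 5,
                        p_candidate = 0.01, p_final = 1e-5,
                        collapse_dist = 20000, min_diag_dist = 2,
                        max_dist = NULL) {
  if (donut_inner <= 0 || donut_inner > donut_outer)
    stop("need 0 < donut_inner <= donut_outer")
  if (p_candidate <= 0 || p_candidate >= 1 || p_final <= 0 || p_final >= 1)
    stop("thresholds must be in (0,1)")
  structure(list(resolution = resolution, donut_inner = donut_inner,
                 donut_outer = donut_outer, p_candidate = p_candidate,
                 p_final = p_final, collapse_dist = collapse_dist,
                 min_diag_dist = min_diag_dist, max_dist = max_dist),
            class = "loop_params")
}

## internal: accept contact_matrix or plain matrix
.cm_counts <- function(M) {
  if (inherits(M, "contact_matrix")) M$counts else as.matrix(M)
}

#' Balance a contact matrix (iterative proportional fitting)
#'
#' Finds per-bin weights `c_i > 0` such that the balanced matrix
#' `M*_ij = M_ij / (c_i * c_j)` has (near-)equal row sums, removing
#' multiplicative per-bin biases (coverage, mappability). Bins with zero
#' marginal are masked (`NA` weight). Weights are scaled so the mean
#' balanced row sum over unmasked bins is 1. The raw-to-balanced factor for
#' pixel (i, j) is `c_i * c_j`.
#'
#' @param M A `contact_matrix` or symmetric non-negative matrix.
#' @param tol Convergence tolerance on the maximum relative row-sum
#'   deviation.
#' @param max_iter Maximum iterations; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @return A `balancing_result`: list with `weights` (length n, `NA` at
#'   masked bins), `converged`, `iterations`, `residual`.
#' @export
balance_matrix <- function(M, tol = 1e-5, max_iter = 1000) {
  m <- .cm_counts(M)
  n <- nrow(m)
  mask <- rowSums(m) == 0
  weights <- rep(NA_real_, n)
  if (all(mask))
    return(structure(list(weights = weights, converged = TRUE,
                          iterations = 0L, residual = 0),
                     class = "balancing_result"))
  mm <- m[!mask, !mask, drop = FALSE]
  cc <- rep(1, nrow(mm))
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    s <- as.vector(mm %*% (1 / cc)) / cc
    sbar <- mean(s)
    resid <- max(abs(s / sbar - 1))
    if (resid < tol) break
    cc <- cc * sqrt(s / sbar)
  }
  s <- as.vector(mm %*% (1 / cc)) / cc
  weights[!mask] <- cc * sqrt(mean(s))
  structure(list(weights = weights, converged = resid < tol,
                 iterations = it, residual = resid),
            class = "balancing_result")
}

#' @export
print.balancing_result <- function(x, ...) {
  cat("balancing_result:", sum(!is.na(x$weights)), "of", length(x$weights),
      "bins balanced;", if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations (residual", format(x$residual), ")\n")
  invisible(x)
}

#' Expected balanced contact by genomic distance
#'
#' The distance-decay reference curve: `e(d)` is the mean balanced contact
#' over all unmasked pixels separated by `d` bins.
#'
#' @param M A `contact_matrix` or matrix of raw counts.
#' @param weights Balancing weights (from [balance_matrix()]).
#' @return Numeric vector of length `n_bins`; element `d + 1` is `e(d)`.
#'   `NA` where a distance has no unmasked pixel.
#' @export
expected_by_distance <- function(M, weights) {
  m <- .cm_counts(M)
  n <- nrow(m)
  B <- m / outer(weights, weights)
  vapply(0:(n - 1), function(d) {
    v <- B[cbind(seq_len(n - d), seq_len(n - d) + d)]
    v <- v[is.finite(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
}

#' Donut-background expected count for one pixel
#'
#' The expected raw count at pixel (i, j) is estimated from the donut
#' region only: the Chebyshev annulus `donut_inner < r <= donut_outer`
#' around the pixel, excluding the center row and column. Each donut pixel's
#' balanced value is divided by the decay reference at its own distance;
#' the mean of these ratios, multiplied by the reference at the center's
#' distance, gives the expected balanced count, which is transformed back to
#' the raw scale via the raw-to-balanced factor `c_i * c_j`.
#'
#' @param M A `contact_matrix` or matrix of raw counts.
#' @param weights Balancing weights.
#' @param e Decay reference from [expected_by_distance()].
#' @param pixel Integer pair `(bin_i, bin_j)`, 0-based, `bin_i < bin_j`.
#' @param params A [loop_params()] list.
#' @return Expected raw count (lambda), or `NA` when the pixel is
#'   untestable (empty donut after clipping/masking).
#' @export
donut_expected <- function(M, weights, e, pixel, params = loop_params()) {
  m <- .cm_counts(M)
  n <- nrow(m)
  i <- pixel[1] + 1
  j <- pixel[2] + 1
  p <- params$donut_inner
  w <- params$donut_outer
  d0 <- abs(j - i)
  if (d0 < params$min_diag_dist)
    stop("pixel closer than min_diag_dist to the diagonal")
  if (!is.finite(weights[i]) || !is.finite(weights[j])) return(NA_real_)
  if (!is.finite(e[d0 + 1]) || e[d0 + 1] <= 0) return(NA_real_)
  ii <- max(1, i - w):min(n, i + w)
  jj <- max(1, j - w):min(n, j + w)
  grid <- expand.grid(ip = ii, jp = jj)
  cheb <- pmax(abs(grid$ip - i), abs(grid$jp - j))
  sel <- cheb > p & cheb <= w & grid$ip != i & grid$jp != j
  grid <- grid[sel, , drop = FALSE]
  if (nrow(grid) == 0) return(NA_real_)
  bal <- m[cbind(grid$ip, grid$jp)] /
    (weights[grid$ip] * weights[grid$jp])
  ref <- e[abs(grid$ip - grid$jp) + 1]
  ratio <- bal / ref
  ratio <- ratio[is.finite(ratio) & ref > 0]
  if (length(ratio) == 0) return(NA_real_)
  mean(ratio) * e[d0 + 1] * weights[i] * weights[j]
}

## internal: summed-area table; S[(i+1),(j+1)] = sum of m[1..i, 1..j]
.sat <- function(m) {
  n <- nrow(m)
  S <- matrix(0, n + 1, n + 1)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  S
}

## internal: clipped rectangle sums from a summed-area table (vectorized)
.boxsum <- function(S, n, r1, r2, c1, c2) {
  r1 <- pmax(r1, 1); c1 <- pmax(c1, 1)
  r2 <- pmin(r2, n); c2 <- pmin(c2, n)
  out <- S[cbind(r2 + 1, c2 + 1)] - S[cbind(r1, c2 + 1)] -
    S[cbind(r2 + 1, c1)] + S[cbind(r1, c1)]
  out[r1 > r2 | c1 > c2] <- 0
  out
}

#' Call chromatin loops with a donut-background Poisson test
#'
#' For every pixel at least `min_diag_dist` bins off the diagonal, the
#' expected raw count is estimated from the donut background
#' ([donut_expected()]) and the observed raw count is tested against
#' `Poisson(lambda)` (inclusive upper tail). Pixels with p below
#' `p_candidate` are candidates; candidates with no neighboring candidate
#' within Chebyshev distance 1 are removed as likely false positives;
#' surviving candidates within `collapse_dist` of each other are collapsed
#' by single linkage and represented by their most significant pixel (ties:
#' lexicographically smaller (i, j)); representatives with p below
#' `p_final` form the final loop list.
#'
#' @param M A `contact_matrix` (or raw matrix).
#' @param params A [loop_params()] list; when `M` is a `contact_matrix` its
#'   resolution overrides `params$resolution`.
#' @param weights Optional balancing weights; computed via
#'   [balance_matrix()] when `NULL`.
#' @return Data frame of candidate pixels surviving the neighbor filter:
#'   `bin_i`, `bin_j` (0-based), `distance_bp`, `observed`, `expected`,
#'   `pvalue`, `cluster_id`, `is_representative`, `is_final`, sorted by
#'   pixel. Attribute `"n_tested"` gives the number of testable pixels.
#' @export
call_loops <- function(M, params = loop_params(), weights = NULL) {
  m <- .cm_counts(M)
  resolution <- if (inherits(M, "contact_matrix")) M$resolution else
    params$resolution
  n <- nrow(m)
  empty <- data.frame(bin_i = integer(), bin_j = integer(),
                      distance_bp = numeric(), observed = numeric(),
                      expected = numeric(), pvalue = numeric(),
                      cluster_id = integer(), is_representative = logical(),
                      is_final = logical())
  attr(empty, "n_tested") <- 0L
  if (n == 0 || sum(m) == 0) return(empty)
  if (is.null(weights)) weights <- balance_matrix(m)$weights
  e <- expected_by_distance(m, weights)
  p <- params$donut_inner
  w <- params$donut_outer

  ## ratio matrix: balanced value / decay reference at its own distance
  B <- m / outer(weights, weights)
  dmat <- abs(row(m) - col(m))
  Em <- matrix(e[dmat + 1], n, n)
  Rm <- B / Em
  V <- is.finite(Rm) & Em > 0
  R0 <- ifelse(V, Rm, 0)
  Ssum <- .sat(R0)
  Scnt <- .sat(V + 0)
  ## row/column prefix sums (leading zero) for the center cross
  rp <- cbind(0, t(apply(R0, 1, cumsum)))
  rc <- cbind(0, t(apply(V + 0, 1, cumsum)))
  cp <- rbind(0, apply(R0, 2, cumsum))
  cc <- rbind(0, apply(V + 0, 2, cumsum))

  sel <- which(dmat >= params$min_diag_dist & upper.tri(m), arr.ind = TRUE)
  if (!is.null(params$max_dist))
    sel <- sel[dmat[sel] * resolution <= params$max_dist, , drop = FALSE]
  i <- sel[, 1]
  j <- sel[, 2]
  d0 <- j - i

  rowseg <- function(pr, rows, c1, c2) {
    c1 <- pmax(c1, 1); c2 <- pmin(c2, n)
    out <- pr[cbind(rows, c2 + 1)] - pr[cbind(rows, c1)]
    out[c1 > c2] <- 0
    out
  }
  colseg <- function(pc, cols, r1, r2) {
    r1 <- pmax(r1, 1); r2 <- pmin(r2, n)
    out <- pc[cbind(r2 + 1, cols)] - pc[cbind(r1, cols)]
    out[r1 > r2] <- 0
    out
  }
  donut_stat <- function(S, pr, pc) {
    .boxsum(S, n, i - w, i + w, j - w, j + w) -
      .boxsum(S, n, i - p, i + p, j - p, j + p) -
      (rowseg(pr, i, j - w, j + w) - rowseg(pr, i, j - p, j + p)) -
      (colseg(pc, j, i - w, i + w) - colseg(pc, j, i - p, i + p))
  }
  dsum <- donut_stat(Ssum, rp, cp)
  dcnt <- donut_stat(Scnt, rc, cc)

  ratio_mean <- ifelse(dcnt > 0, dsum / dcnt, NA_real_)
  lambda <- ratio_mean * e[d0 + 1] * weights[i] * weights[j]
  testable <- is.finite(lambda) & lambda > 0
  observed <- m[cbind(i, j)]
  pvalue <- rep(NA_real_, length(i))
  pvalue[testable] <- stats::ppois(observed[testable] - 1, lambda[testable],
                                   lower.tail = FALSE)
  cand <- which(testable & pvalue < params$p_candidate)
  attr_n <- sum(testable)
  if (length(cand) == 0) {
    attr(empty, "n_tested") <- attr_n
    return(empty)
  }
  ci <- i[cand]
  cj <- j[cand]
  cp_val <- pvalue[cand]

  ## neighbor filter: >= 1 other candidate within Chebyshev distance 1
  cheb <- pmax(abs(outer(ci, ci, "-")), abs(outer(cj, cj, "-")))
  keep <- rowSums(cheb <= 1) >= 2
  ci <- ci[keep]; cj <- cj[keep]; cp_val <- cp_val[keep]
  if (length(ci) == 0) {
    attr(empty, "n_tested") <- attr_n
    return(empty)
  }

  ## single-linkage collapse within collapse_dist (Chebyshev, in bins)
  collapse_bins <- floor(params$collapse_dist / resolution)
  if (length(ci) == 1) {
    cluster <- 1L
  } else {
    dd <- pmax(abs(outer(ci, ci, "-")), abs(outer(cj, cj, "-")))
    hc <- stats::hclust(stats::as.dist(dd), method = "single")
    cluster <- stats::cutree(hc, h = collapse_bins)
  }
  ord <- order(cp_val, ci, cj)
  rep_idx <- ord[!duplicated(cluster[ord])]
  is_rep <- seq_along(ci) %in% rep_idx

  out <- data.frame(bin_i = ci - 1L, bin_j = cj - 1L,
                    distance_bp = (cj - ci) * resolution,
                    observed = m[cbind(ci, cj)],
                    expected = lambda[cand][keep],
                    pvalue = cp_val,
                    cluster_id = as.integer(cluster),
                    is_representative = is_rep,
                    is_final = is_rep & cp_val < params$p_final)
  out <- out[order(out$bin_i, out$bin_j), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- attr_n
  out
}

#' Final loop list from a loop-call table
#'
#' @param calls Data frame from [call_loops()].
#' @return The rows flagged `is_final` (the collapsed, significant loops).
#' @export
final_loops <- function(calls) {
  out <- calls[calls$is_final, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write loop calls as a BEDPE-style table
#'
#' @param calls Data frame from [call_loops()].
#' @param path Output path.
#' @param chrom Chromosome name.
#' @param resolution Bin size in bp.
#' @return `path`, invisibly.
#' @export
write_loops <- function(calls, path, chrom = "chr1", resolution = 10000) {
  bedpe <- data.frame(chrom1 = chrom,
                      start1 = calls$bin_i * resolution,
                      end1 = (calls$bin_i + 1) * resolution,
                      chrom2 = chrom,
                      start2 = calls$bin_j * resolution,
                      end2 = (calls$bin_j + 1) * resolution,
                      observed = calls$observed,
                      expected = calls$expected,
                      pvalue = calls$pvalue,
                      cluster_id = calls$cluster_id,
                      is_final = calls$is_final)
  utils::write.table(bedpe, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
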