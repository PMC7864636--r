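# exact distance-decay matrix with unit biases (no noise)
decay_matrix <- function(n, scale = 100, alpha = 1) {
  d <- abs(row(diag(n)) - col(diag(n)))
  scale * (1 + d)^(-alpha)
}

test_that("balancing a constant matrix gives equal weights and unit row sums", {
  m <- matrix(1, 20, 20)
  bal <- balance_matrix(m)
  expect_true(bal$converged)
  expect_equal(max(bal$weights) / min(bal$weights), 1, tolerance = 1e-6)
  B <- m / outer(bal$weights, bal$weights)
  expect_equal(unname(rowSums(B)), rep(1, 20), tolerance = 1e-4)
})

test_that("balancing recovers planted multiplicative biases up to scale", {
  set.seed(41)
  b <- exp(rnorm(80, 0, 0.3))
  m <- outer(b, b) * 7
  bal <- balance_matrix(m, tol = 1e-8)
  expect_true(bal$converged)
  rel <- (bal$weights / mean(bal$weights)) / (b / mean(b))
  expect_lt(max(abs(rel - 1)), 1e-3)
})

test_that("zero-marginal bins are masked; non-convergence is reported, not thrown", {
  m <- matrix(1, 10, 10)
  m[3, ] <- 0; m[, 3] <- 0
  bal <- balance_matrix(m)
  expect_true(is.na(bal$weights[3]))
  expect_true(all(!is.na(bal$weights[-3])))

  set.seed(43)
  b <- exp(rnorm(30, 0, 1))
  hard <- outer(b, b)
  bal2 <- balance_matrix(hard, tol = 1e-12, max_iter = 2)
  expect_false(bal2$converged)
  expect_true(is.finite(bal2$residual))
})

test_that("expected-by-distance reproduces the generating decay and the diagonal means", {
  n <- 40
  m <- decay_matrix(n)
  w <- rep(1, n)
  e <- expected_by_distance(m, w)
  expect_equal(e, 100 * (1 + 0:(n - 1))^(-1), tolerance = 1e-12)

  set.seed(47)
  r <- matrix(rpois(n * n, 5), n, n)
  r <- (r + t(r))
  w2 <- runif(n, 0.5, 2)
  w2[c(4, 9)] <- NA  # masked bins are excluded from every diagonal mean
  e2 <- expected_by_distance(r, w2)
  B <- r / outer(w2, w2)
  for (d in c(0, 1, 7, 23)) {
    v <- B[cbind(1:(n - d), (1 + d):n)]
    expect_equal(e2[d + 1], mean(v[is.finite(v)]))
  }
})

test_that("donut expectation: flat background, hot-center locality, enumeration oracle", {
  n <- 60
  m <- matrix(8, n, n)
  w <- rep(1, n)
  e <- expected_by_distance(m, w)
  lam <- donut_expected(m, w, e, pixel = c(20, 30))
  expect_equal(lam, 8, tolerance = 1e-12)

  # a hot center pixel does not contaminate its own expectation: with the
  # background decay reference held fixed, the donut sees only background
  m2 <- m
  m2[21, 31] <- m2[31, 21] <- 800
  lam2 <- donut_expected(m2, w, e, pixel = c(20, 30))
  expect_equal(lam2, 8, tolerance = 1e-12)

  set.seed(53)
  r <- matrix(rpois(n * n, 6), n, n)
  r <- r + t(r)
  wb <- runif(n, 0.5, 2)
  er <- expected_by_distance(r, wb)
  for (px in list(c(5, 12), c(30, 44), c(0, 59), c(56, 59))) {
    got <- donut_expected(r, wb, er, pixel = px)
    want <- bf_donut(r, wb, er, px[1], px[2], inner = 2, outer = 5)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("call_loops' vectorized expectations agree with per-pixel donut_expected", {
  set.seed(59)
  n <- 50
  lam <- decay_matrix(n, scale = 60)
  m <- matrix(rpois(n * n, lam), n, n)
  m <- floor((m + t(m)) / 2)
  m <- m + t(m) - diag(diag(m))  # symmetrize
  bal <- balance_matrix(m)
  e <- expected_by_distance(m, bal$weights)
  # force full reporting by setting permissive candidate threshold
  params <- loop_params(p_candidate = 0.999999, p_final = 1e-5)
  calls <- call_loops(m, params, weights = bal$weights)
  pick <- calls[sample(nrow(calls), 15), ]
  for (r in seq_len(nrow(pick))) {
    want <- donut_expected(m, bal$weights, e,
                           pixel = c(pick$bin_i[r], pick$bin_j[r]), params)
    expect_equal(pick$expected[r], want, tolerance = 1e-9)
  }
})

test_that("a pure decay matrix yields no final loops; calls are deterministic", {
  set.seed(61)
  n <- 120
  lam <- decay_matrix(n, scale = 200)
  m <- matrix(0, n, n)
  up <- which(upper.tri(lam, diag = TRUE))
  m[up] <- rpois(length(up), lam[up])
  m <- m + t(m) - diag(diag(m))
  c1 <- call_loops(m)
  c2 <- call_loops(m)
  expect_identical(c1, c2)
  expect_equal(nrow(final_loops(c1)), 0)
  expect_true(all(diff(c1$bin_i) >= 0))  # sorted by pixel
})

test_that("a planted 3x3 block yields exactly one final loop at its most significant pixel", {
  set.seed(67)
  n <- 100
  lam <- decay_matrix(n, scale = 300)
  i0 <- 31; j0 <- 61  # 1-based centers
  lam[i0 + (-1:1), j0 + (-1:1)] <- lam[i0 + (-1:1), j0 + (-1:1)] * 12
  lam[j0 + (-1:1), i0 + (-1:1)] <- lam[j0 + (-1:1), i0 + (-1:1)] * 12
  m <- matrix(0, n, n)
  up <- which(upper.tri(lam, diag = TRUE))
  m[up] <- rpois(length(up), lam[up])
  m <- m + t(m) - diag(diag(m))
  calls <- call_loops(m)
  fl <- final_loops(calls)
  expect_equal(nrow(fl), 1)
  expect_lte(max(abs(fl$bin_i - (i0 - 1)), abs(fl$bin_j - (j0 - 1))), 1)
  # representative carries the cluster's smallest p-value
  clu <- calls[calls$cluster_id == fl$cluster_id, ]
  expect_equal(fl$pvalue, min(clu$pvalue))
})

test_that("an isolated enriched pixel is removed by the neighbor filter", {
  n <- 80
  m <- decay_matrix(n, scale = 200)
  m <- round(m)
  m[21, 51] <- m[51, 21] <- m[21, 51] * 15  # single hot pixel, exact background
  calls <- call_loops(m)
  expect_equal(nrow(calls), 0)
  expect_gt(attr(calls, "n_tested"), 0)
})

test_that("loop calls are invariant under global rescaling of balancing weights", {
  set.seed(71)
  n <- 90
  lam <- decay_matrix(n, scale = 250)
  lam[40:42, 70:72] <- lam[40:42, 70:72] * 10
  lam[70:72, 40:42] <- lam[70:72, 40:42] * 10
  m <- matrix(0, n, n)
  up <- which(upper.tri(lam, diag = TRUE))
  m[up] <- rpois(length(up), lam[up])
  m <- m + t(m) - diag(diag(m))
  w <- balance_matrix(m)$weights
  a <- call_loops(m, weights = w)
  b <- call_loops(m, weights = w * 3.7)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-9)
  expect_equal(final_loops(a)[, c("bin_i", "bin_j")],
               final_loops(b)[, c("bin_i", "bin_j")])
})

test_that("empty matrices give empty results", {
  expect_equal(nrow(call_loops(matrix(0, 30, 30))), 0)
  expect_equal(nrow(call_loops(matrix(numeric(), 0, 0))), 0)
})
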