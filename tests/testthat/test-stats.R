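test_that("signed-rank p-values match full sign enumeration (independent oracle)", {
  # direct 2^n enumeration, written independently of the package's DP route
  enum_p <- function(d) {
    nz <- d[d != 0]; n <- length(nz)
    r <- rank(abs(nz))
    V <- sum(r[nz > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- signs %*% r
    p_le <- mean(Vs <= V + 1e-9); p_ge <- mean(Vs >= V - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(42)
  for (k in 1:6) {
    d <- round(rnorm(sample(5:8, 1), 0.4, 1), 2)
    d <- d[d != 0]
    if (length(d) < 3) next
    res <- wilcoxon_signed_rank(d)
    expect_true(res$exact)
    expect_equal(res$p_value, enum_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the base-R exact reference on untied data", {
  set.seed(7)
  for (k in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
  # degenerate all-zero differences
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
})

test_that("Mann-Whitney agrees with the base-R exact reference", {
  set.seed(8)
  for (k in 1:5) {
    x <- rnorm(6); y <- rnorm(7, 0.8)
    ours <- mann_whitney(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  big <- mann_whitney(rnorm(30), rnorm(30, 0.5))
  expect_false(big$exact)
  ref <- wilcox.test(rnorm(3), rnorm(3))  # smoke only; approximate path below
  expect_true(big$p_value > 0 && big$p_value < 1)
})

test_that("Spearman matches permutation enumeration and the base-R exact reference", {
  # independent oracle: enumerate permutations via filtered grid expansion
  perm_p <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    rho <- cor(rx, ry)
    gr <- as.matrix(expand.grid(rep(list(1:n), n)))
    gr <- gr[apply(gr, 1, function(v) length(unique(v)) == n), , drop = FALSE]
    rhos <- apply(gr, 1, function(p) cor(rx, ry[p]))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  }
  set.seed(9)
  for (n in c(5, 6)) {
    x <- rnorm(n); y <- 0.6 * x + rnorm(n)
    ours <- spearman(x, y)
    expect_true(ours$exact)
    expect_equal(ours$p_value, perm_p(x, y), tolerance = 1e-12)
  }
  for (n in c(6, 7)) {
    x <- rnorm(n); y <- rnorm(n)
    ours <- spearman(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(ours$estimate, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("perfectly monotone data give rho = 1 with the enumeration point mass", {
  x <- c(2, 5, 9, 11, 15, 20)
  res <- spearman(x, x^3 + 1)
  expect_equal(res$estimate, 1)
  expect_equal(res$p_value, 2 / factorial(6), tolerance = 1e-12)
})

test_that("test sizes are calibrated: type-I error near nominal, high power for the cohort shift", {
  set.seed(123)
  # type I: paired null
  rej <- mean(replicate(400, {
    wilcoxon_signed_rank(rnorm(12), rnorm(12))$p_value < 0.05
  }))
  expect_gt(rej, 0.015); expect_lt(rej, 0.095)
  # power at the cohort's ECV effect size (shift ~4 +- 1.5 points, n = 12)
  pow <- mean(replicate(200, {
    pre <- rnorm(12, 24.2, 3)
    post <- pre + rnorm(12, 4, 1.5)
    wilcoxon_signed_rank(pre, post)$p_value < 0.05
  }))
  expect_gt(pow, 0.9)
})
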