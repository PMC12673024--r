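# Nonparametric statistics used to analyse paired pre/post cohorts:
# Wilcoxon matched-pairs signed rank (paired data), Mann-Whitney (sex
# differences), Spearman correlation. Exact p-values are computed by full
# enumeration/dynamic programming for small samples and flagged; larger
# samples fall back to the standard normal (or t) approximations with tie
# corrections.

.stat_result <- function(statistic, p, method, exact, n, estimate = NULL,
                         degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = min(1, max(0, p)),
                 method = method, exact = exact, n = n, estimate = estimate,
                 degenerate = degenerate), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s, n = %s)%s\n", x$method,
              x$statistic, x$p_value, if (x$exact) "exact" else "approximate",
              paste(x$n, collapse = "+"),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# distribution of the sum of a subset of (possibly tied, doubled) ranks via
# dynamic programming; returns P(W = w) over w = 0..sum(r2)/?? on the 2x grid
.signed_rank_dp <- function(r2) {
  tot <- sum(r2)
  f <- numeric(tot + 1); f[1] <- 1
  for (r in r2) {
    g <- f
    idx <- (r + 1):(tot + 1)
    g[idx] <- g[idx] + f[idx - r]
    f <- g
  }
  f / 2^length(r2)
}

#' Wilcoxon matched-pairs signed rank test
#'
#' Two-sided test of a paired difference. Zero differences are dropped
#' (all-zero input returns p = 1 with a degenerate flag); ties receive
#' mid-ranks. For n <= 25 informative pairs the p-value is exact, from the
#' full sign-enumeration distribution of the rank sum (computed by dynamic
#' programming over doubled mid-ranks, which is identical to enumerating all
#' 2^n sign assignments); above that a normal approximation with tie and
#' continuity corrections is used and flagged.
#'
#' @param x,y paired numeric vectors (or `y = NULL` for differences in `x`).
#' @return a `stat_result` with statistic V (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  d <- d[!is.na(d)]
  if (length(d) < 3) stop("need at least 3 pairs")
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0)
    return(.stat_result(0, 1, "wilcoxon-signed-rank", TRUE, length(d),
                        degenerate = TRUE))
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))
    pm <- .signed_rank_dp(r2)
    w2 <- as.integer(round(2 * V))
    p_le <- sum(pm[seq_len(w2 + 1)])
    p_ge <- sum(pm[(w2 + 1):length(pm)])
    p <- min(1, 2 * min(p_le, p_ge))
    .stat_result(V, p, "wilcoxon-signed-rank", TRUE, n)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    .stat_result(V, 2 * pnorm(-abs(z)), "wilcoxon-signed-rank", FALSE, n)
  }
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided two-sample test. For combined samples of at most 16
#' observations the p-value is exact, from full enumeration of all
#' choose(n1+n2, n1) group assignments of the (mid-)ranks; larger samples
#' use the tie-corrected normal approximation with continuity correction.
#'
#' @param x,y the two samples.
#' @return a `stat_result` with the U statistic of `x`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (min(n1, n2) < 3) stop("need at least 3 observations per group")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 16) {
    cmb <- utils::combn(n1 + n2, n1)
    rsums <- colSums(matrix(r[cmb], nrow = n1))
    Us <- rsums - n1 * (n1 + 1) / 2
    dev <- abs(Us - n1 * n2 / 2)
    p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-9)
    .stat_result(U, p, "mann-whitney", TRUE, c(n1, n2))
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    .stat_result(U, 2 * pnorm(-abs(z)), "mann-whitney", FALSE, c(n1, n2))
  }
}

#' Spearman rank correlation
#'
#' Two-sided test of monotone association. The coefficient uses mid-ranks.
#' For n <= 8 the p-value is exact by full permutation enumeration
#' (P(|rho_perm| >= |rho_obs|)); larger samples use the t approximation.
#'
#' @param x,y numeric vectors of equal length.
#' @return a `stat_result`; `estimate` holds rho.
#' @export
spearman <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(.stat_result(NA_real_, 1, "spearman", TRUE, n, estimate = NA_real_,
                        degenerate = TRUE))
  rho <- cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    .stat_result(rho, p, "spearman", TRUE, n, estimate = rho)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    .stat_result(rho, p, "spearman", FALSE, n, estimate = rho)
  }
}

# all permutations of 1..n (n <= 8 -> at most 40320 rows)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}
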