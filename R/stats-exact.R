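#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by the point-probability rule: with
#' both margins fixed, the p-value is the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one (a
#' relative tolerance of 1e-7 guards against floating-point ties, the
#' conventional definition). This is the test used to call differential
#' m6A sites.
#'
#' @param a,b,c,d Nonnegative integer cell counts; rows are conditions,
#'   columns modified/unmodified.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact2(8, 2, 2, 8)   # ~0.023
#' @export
fisher_exact2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("cell counts must be nonnegative integers",
                 class = "tailshift_validation_error")
  }
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of two samples. When
#' `n1 + n2 <= exact_limit` the p-value is exact: the tie-aware null
#' distribution of the rank sum is built by a shift (generating-function)
#' algorithm over the observed midranks, equivalent to enumerating all
#' `choose(n1+n2, n1)` group assignments. Larger samples use the normal
#' approximation with tie correction and continuity correction. Used for
#' per-transcript poly(A)-tail-length comparisons.
#'
#' @param x,y Numeric samples (group 1 / group 2).
#' @param exact_limit Use the exact path when `length(x) + length(y)` is at
#'   most this (default 12).
#' @return List with `u` (U statistic of `x`) and `p_value`.
#' @examples
#' mann_whitney(c(80, 85, 90), c(50, 55, 60))$p_value  # 0.1 exact
#' @export
mann_whitney <- function(x, y, exact_limit = 12) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    rlang::abort("both samples must be non-empty",
                 class = "tailshift_validation_error")
  }
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])                  # rank sum of x
  u1 <- w1 - n1 * (n1 + 1) / 2               # U statistic of x
  if (n1 + n2 <= exact_limit) {
    p <- mw_exact_p(r, n1)
  } else {
    p <- mw_normal_p(r, n1, n2, u1)
  }
  list(u = u1, p_value = p)
}

# exact two-sided p by the shift algorithm over (doubled) midranks:
# distribution of the group-1 rank sum across all equally likely subsets
mw_exact_p <- function(r, n1) {
  N <- length(r)
  ir <- as.integer(round(2 * r))             # midranks -> integers
  total <- sum(ir)
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (v in ir) {
    kmax <- n1
    for (k in kmax:1) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) f[k + 1, nz + v] <- f[k + 1, nz + v] + f[k, nz]
    }
  }
  counts <- f[n1 + 1, ]
  sums <- which(counts > 0) - 1L
  cnt <- counts[counts > 0]
  obs <- sum(ir[seq_len(n1)])
  mu <- n1 * total / N
  dev_obs <- abs(obs - mu)
  sum(cnt[abs(sums - mu) >= dev_obs - 1e-9]) / sum(cnt)
}

# normal approximation with tie correction and continuity correction
mw_normal_p <- function(r, n1, n2, u1) {
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- (n1 * n2 / 12) * (N + 1 - tie_term)
  if (sigma2 <= 0) return(1)               # all values tied
  z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * pnorm(-z))
}
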