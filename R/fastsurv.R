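# Vectorized two-group log-rank and univariate Cox fitters.
#
# The permutation stages of the screen evaluate B rounds x G genes of
# log-rank and univariate Cox statistics; these fitters compute all genes of
# one round in a handful of matrix operations. Observed (non-permuted)
# statistics in user-facing records always come from survival::survdiff /
# survival::coxph; agreement between the two routes is asserted in the test
# suite. The Cox fitter uses the Breslow tie approximation (identical to
# Efron when event times are distinct, as in the simulated cohorts).

# Columnwise cumulative sum via one flattened cumsum plus column-offset
# correction (much faster than apply(m, 2, cumsum) for wide matrices).
col_cumsum <- function(m) {
  n <- nrow(m)
  v <- matrix(cumsum(m), n)
  if (ncol(v) > 1) {
    off <- c(0, v[n, -ncol(v)])
    v <- sweep(v, 2, off)
  }
  dimnames(v) <- dimnames(m)
  v
}

# Columnwise reverse cumulative sum (sum of the value and everything below).
col_revcumsum <- function(m) {
  n <- nrow(m)
  col_cumsum(m[n:1, , drop = FALSE])[n:1, , drop = FALSE]
}

# Two-group log-rank chi-square (1 df) for many group assignments at once.
# time, event: length-n vectors; Z: n x G logical matrix (TRUE = "high").
# Returns a list(stat, p) of length-G vectors.
fast_logrank <- function(time, event, Z) {
  Z <- as.matrix(Z)
  n <- length(time)
  ord <- order(time)
  tt <- time[ord]
  ev <- event[ord]
  Zs <- Z[ord, , drop = FALSE] + 0
  f <- factor(tt, levels = unique(tt))
  counts <- as.vector(table(f))
  D <- as.vector(rowsum(ev, f, reorder = FALSE))          # deaths per time
  D1 <- rowsum(Zs * ev, f, reorder = FALSE)               # deaths in high group
  R1 <- rowsum(Zs, f, reorder = FALSE)                    # group members at each time
  # at-risk counts: all rows with time >= t
  Y <- rev(cumsum(rev(counts)))
  Y1 <- col_revcumsum(R1)
  use <- D > 0
  Yu <- Y[use]
  Du <- D[use]
  Y1u <- Y1[use, , drop = FALSE]
  frac <- Y1u / Yu
  OE <- colSums(D1[use, , drop = FALSE] - Du * frac)
  Vv <- colSums(Du * frac * (1 - frac) * (Yu - Du) / pmax(Yu - 1, 1))
  stat <- ifelse(Vv > 0, OE^2 / Vv, 0)
  p <- ifelse(Vv > 0, stats::pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(stat = stat, p = p)
}

# Univariate Cox partial-likelihood Newton iterations over the columns of X
# (n x G), in compiled code. Breslow ties. Returns list(coef, se, p).
fast_cox <- function(time, event, X, max_iter = 25, tol = 1e-9) {
  X <- as.matrix(X)
  ord <- order(-time)            # decreasing: risk set = prefix of rows
  fit <- .cox_newton(time[ord], as.integer(event[ord]), X[ord, , drop = FALSE],
                     as.integer(max_iter), tol)
  b <- fit$coef
  I <- fit$info
  se <- ifelse(I > 1e-12, 1 / sqrt(I), NA_real_)
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  list(coef = b, se = se, p = p)
}
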