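#' Canonical correlation between a promoter CpG block and expression
#'
#' Finds the linear combination `U = X %*% alpha` of a gene's promoter CpG
#' beta values maximizing the correlation with the gene's expression
#' `V = beta_coef * y`, under the unit-variance constraints Var(U) =
#' Var(V) = 1. With a single expression variable this is the exact
#' specialization of canonical correlation analysis: the weight direction is
#' `solve(S_xx, S_xy)` (the multiple-regression direction) and the canonical
#' correlation `r` equals the multiple correlation coefficient of `y` on
#' `X`.
#'
#' Sign convention: `(alpha, beta)` and `(-alpha, -beta)` give the same
#' correlation, so `alpha` is oriented such that `U` correlates
#' non-negatively with the sample-wise mean promoter methylation; the sign
#' of the expression scaling that then makes `cor(U, V) >= 0` is returned as
#' `beta_sign` and encodes the regulatory direction (negative =
#' hypermethylation associated with lower expression).
#'
#' A rank-deficient or ill-conditioned CpG covariance is handled by a
#' pseudoinverse (relative tolerance 1e-8); `ridge = TRUE` instead adds
#' `1e-6 * trace(S_xx)/p` to the diagonal.
#'
#' @param X Numeric matrix, samples x CpGs (p >= 1, n >= 3).
#' @param y Numeric vector of expression values, length `nrow(X)`.
#' @param ridge Use a small ridge instead of the pseudoinverse.
#' @return A list: `alpha` (weights, named by CpG; Var(X alpha) = 1 on the
#'   centered training data), `beta_sign` (-1 or 1), `r` (canonical
#'   correlation, in \[0,1\]), `means` (training CpG means used for
#'   centering).
#' @export
canonical_correlation <- function(X, y, ridge = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  y <- as.vector(y)
  stopifnot(length(y) == n)
  if (n < 3) stop("canonical correlation needs at least 3 samples", call. = FALSE)
  if (stats::sd(y) < 1e-12) stop("expression is constant: canonical correlation undefined", call. = FALSE)
  if (all(apply(X, 2, stats::var) < 1e-10)) {
    stop("all CpG columns are (near-)constant", call. = FALSE)
  }
  means <- colMeans(X)
  Xc <- sweep(X, 2, means)
  Sxx <- crossprod(Xc) / (n - 1)
  Sxy <- crossprod(Xc, y - mean(y)) / (n - 1)
  if (ridge) {
    Sxx <- Sxx + diag(1e-6 * sum(diag(Sxx)) / p, p)
    alpha <- solve(Sxx, Sxy)
  } else {
    alpha <- pseudo_solve(Sxx, Sxy, rtol = 1e-8)
  }
  u <- drop(Xc %*% alpha)
  su <- stats::sd(u)
  if (su < 1e-12) {
    stop("degenerate CpG block: canonical variate has zero variance", call. = FALSE)
  }
  alpha <- drop(alpha) / su
  u <- u / su
  # orient so U tracks mean promoter methylation upward
  m_cor <- stats::cor(u, rowMeans(Xc))
  if (is.finite(m_cor) && m_cor < 0) {
    alpha <- -alpha
    u <- -u
  }
  r_signed <- stats::cor(u, y)
  beta_sign <- if (r_signed < 0) -1L else 1L
  names(alpha) <- colnames(X)
  list(alpha = alpha, beta_sign = beta_sign, r = abs(r_signed), means = means)
}

# Minimum-norm solve via SVD with relative singular-value tolerance.
pseudo_solve <- function(A, b, rtol = 1e-8) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d)
  if (!any(keep)) stop("covariance matrix is numerically zero", call. = FALSE)
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], b)) / s$d[keep])
}

#' Methylation pattern score (MPS) for new samples
#'
#' Applies stored CCA weights to a methylation matrix:
#' `MPS_k = sum_j alpha_j * (x_kj - center_j)`. Columns of `X_new` are
#' matched to `names(alpha)` by CpG id; probes missing from `X_new` raise an
#' error naming them. With `center = NULL` the raw (uncentered) linear score
#' is returned.
#'
#' @param alpha Named weight vector from [canonical_correlation()].
#' @param X_new Samples x CpGs matrix containing the training probes.
#' @param center Optional named vector of training CpG means.
#' @return Numeric vector of scores, named by sample.
#' @export
compute_mps <- function(alpha, X_new, center = NULL) {
  X_new <- as.matrix(X_new)
  probes <- names(alpha)
  if (is.null(probes)) {
    if (ncol(X_new) != length(alpha)) {
      stop("unnamed alpha must match ncol(X_new)", call. = FALSE)
    }
  } else {
    missing_probes <- setdiff(probes, colnames(X_new))
    if (length(missing_probes) > 0) {
      stop(sprintf("CpG probe(s) absent from new data: %s",
                   paste(missing_probes, collapse = ", ")), call. = FALSE)
    }
    X_new <- X_new[, probes, drop = FALSE]
  }
  if (!is.null(center)) X_new <- sweep(X_new, 2, center[probes %||% seq_along(alpha)])
  drop(X_new %*% alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation of average promoter methylation with expression
#'
#' The Pearson correlation between the sample-wise mean of the promoter CpG
#' block and expression — the single-number summary the canonical
#' correlation is compared against (the equal-weight combination lies in the
#' CCA search space, so `r >= abs(pearson_avg)` always).
#'
#' @inheritParams canonical_correlation
#' @return Pearson correlation (scalar).
#' @export
average_methylation_correlation <- function(X, y) {
  stats::cor(rowMeans(as.matrix(X)), y)
}

#' Per-gene methylation patterns for a cohort
#'
#' Runs [canonical_correlation()] for every gene present in both the
#' promoter map and the expression matrix with at least one CpG surviving in
#' the methylation matrix. Genes whose promoter CpGs are all near-constant
#' (variance < 1e-10), or whose expression is constant, are skipped with a
#' message rather than an error.
#'
#' @param meth Samples x CpGs beta matrix.
#' @param expr Samples x genes expression matrix (sample-aligned with
#'   `meth`).
#' @param pmap Promoter map as from [read_promoter_map()].
#' @param ridge Passed to [canonical_correlation()].
#' @return An object of class `gene_patterns`: a named list, one entry per
#'   eligible gene, each with `gene_id`, `p`, `alpha`, `means`, `beta_sign`,
#'   `r`, `pearson_avg` and the per-sample training `mps`.
#' @export
per_gene_patterns <- function(meth, expr, pmap, ridge = FALSE) {
  stopifnot(identical(rownames(meth), rownames(expr)))
  genes <- intersect(names(pmap), colnames(expr))
  out <- list()
  skipped <- character(0)
  for (g in genes) {
    cpgs <- intersect(pmap[[g]], colnames(meth))
    if (length(cpgs) == 0) {
      skipped <- c(skipped, g)
      next
    }
    X <- meth[, cpgs, drop = FALSE]
    y <- expr[, g]
    if (all(apply(X, 2, stats::var) < 1e-10) || stats::sd(y) < 1e-12) {
      skipped <- c(skipped, g)
      next
    }
    cc <- canonical_correlation(X, y, ridge = ridge)
    out[[g]] <- list(
      gene_id = g,
      p = length(cpgs),
      alpha = cc$alpha,
      means = cc$means,
      beta_sign = cc$beta_sign,
      r = cc$r,
      pearson_avg = average_methylation_correlation(X, y),
      mps = compute_mps(cc$alpha, meth, center = cc$means)
    )
  }
  if (length(skipped) > 0) {
    message(sprintf("per_gene_patterns: skipped %d gene(s) with no usable promoter CpGs or constant data: %s",
                    length(skipped), paste(utils::head(skipped, 5), collapse = ", ")))
  }
  if (length(out) == 0) stop("no eligible genes for pattern estimation", call. = FALSE)
  structure(out, class = "gene_patterns")
}

#' Assemble the samples x genes MPS matrix
#'
#' @param patterns A `gene_patterns` object.
#' @return Numeric matrix, samples x genes, of training MPS values.
#' @export
mps_matrix <- function(patterns) {
  stopifnot(inherits(patterns, "gene_patterns"))
  do.call(cbind, lapply(patterns, function(p) {
    m <- matrix(p$mps, ncol = 1, dimnames = list(names(p$mps), p$gene_id))
    m
  }))
}
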