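#' Screening configuration
#'
#' Parameters of the two-stage survival screen: a median-split log-rank
#' stage calibrated by `B` label permutations, then a univariate Cox stage
#' with a permutation-estimated false-discovery-rate cutoff on the Cox
#' p-values.
#'
#' @param n_permutations Number of permutation rounds `B` (default 100).
#' @param empirical_p_threshold Stage-1 empirical-p cutoff (default 0.01; at
#'   B = 100 this requires the observed p to undercut all permuted ones).
#' @param logrank_alpha Stage-1 raw log-rank significance level.
#' @param cox_alpha Stage-2 raw Cox significance level.
#' @param fdr_target Target false discovery rate for the stage-2 cutoff.
#' @param seed Seed driving all permutation randomness.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_permutations = 100, empirical_p_threshold = 0.01,
                          logrank_alpha = 0.05, cox_alpha = 0.05,
                          fdr_target = 0.01, seed = 1) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  for (v in c(empirical_p_threshold, logrank_alpha, cox_alpha, fdr_target)) {
    if (v <= 0 || v >= 1) stop("thresholds must lie in (0,1)", call. = FALSE)
  }
  structure(list(
    n_permutations = as.integer(n_permutations),
    empirical_p_threshold = empirical_p_threshold,
    logrank_alpha = logrank_alpha, cox_alpha = cox_alpha,
    fdr_target = fdr_target, seed = as.integer(seed)
  ), class = "screen_config")
}

#' Median split into high/low groups
#'
#' Samples with a score strictly above the median are labelled `"high"`,
#' those at or below it `"low"`.
#'
#' @param scores Numeric vector (>= 2 values, not all identical).
#' @return Factor with levels `low`, `high`, named like `scores`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("median split needs at least 2 samples", call. = FALSE)
  med <- stats::median(scores)
  if (all(scores == scores[1])) {
    stop("all scores identical: median split is degenerate", call. = FALSE)
  }
  g <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  names(g) <- names(scores)
  g
}

#' Two-group log-rank test
#'
#' Wraps [survival::survdiff()] for a two-level grouping of a cohort's
#' overall survival.
#'
#' @param groups Factor/vector with two levels, one entry per sample.
#' @param clin Clinical table with `os_time`, `os_event` (sample-aligned
#'   with `groups`).
#' @return A list: `stat` (chi-square, 1 df) and `p`.
#' @export
logrank_test <- function(groups, clin) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("both groups must be non-empty", call. = FALSE)
  if (sum(clin$os_event) < 1) stop("log-rank test needs at least one event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(clin$os_time, clin$os_event) ~ groups)
  stat <- sd$chisq
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Permutation empirical p-value for one gene's MPS
#'
#' Permutes the survival outcome (time, event) pairs jointly against the
#' scores `B` times, re-runs the median-split log-rank test, and returns the
#' add-one empirical p-value `(1 + #\{b : p_b <= p_obs\}) / (B + 1)`. At
#' B = 100 the stage-1 rule `empirical_p < 0.01` therefore requires the
#' observed p-value to be smaller than every permuted one.
#'
#' @param scores Per-sample MPS vector.
#' @param clin Clinical table aligned with `scores`.
#' @param config A [screen_config()] (supplies `B` and the seed).
#' @return A list: `p_obs`, `empirical_p`, `perm_p` (length-B vector).
#' @export
permutation_empirical_p <- function(scores, clin, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  g <- median_split(scores)
  obs <- logrank_test(g, clin)
  B <- config$n_permutations
  n <- nrow(clin)
  perms <- permutation_rounds(n, B, config$seed)
  Z <- matrix(g == "high", ncol = 1)
  perm_p <- vapply(seq_len(B), function(b) {
    idx <- perms[, b]
    fast_logrank(clin$os_time[idx], clin$os_event[idx], Z)$p
  }, numeric(1))
  list(
    p_obs = obs$p,
    empirical_p = (1 + sum(perm_p <= obs$p)) / (B + 1),
    perm_p = perm_p
  )
}

# One shared permutation per round across all genes, reproducible from seed.
permutation_rounds <- function(n, B, seed) {
  set.seed(seed)
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

#' Univariate Cox regression of survival on a continuous score
#'
#' Wraps [survival::coxph()] (Efron ties) with the MPS as a single
#' continuous covariate; non-convergence or a degenerate covariate is
#' reported via `converged = FALSE` rather than an error.
#'
#' @param scores Per-sample continuous score.
#' @param clin Clinical table aligned with `scores`.
#' @return A list: `coef`, `hr`, `p` (Wald), `converged`.
#' @export
univariate_cox <- function(scores, clin) {
  if (sum(clin$os_event) < 1) stop("Cox regression needs at least one event", call. = FALSE)
  if (stats::sd(scores) < 1e-12) {
    return(list(coef = NA_real_, hr = NA_real_, p = NA_real_, converged = FALSE))
  }
  fit <- tryCatch(
    suppressWarnings(survival::coxph(
      survival::Surv(clin$os_time, clin$os_event) ~ scores, ties = "efron"
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(stats::coef(fit))) {
    return(list(coef = NA_real_, hr = NA_real_, p = NA_real_, converged = FALSE))
  }
  s <- summary(fit)
  list(
    coef = unname(stats::coef(fit)),
    hr = unname(s$conf.int[1, "exp(coef)"]),
    p = unname(s$coefficients[1, "Pr(>|z|)"]),
    converged = TRUE
  )
}

#' Permutation-based FDR cutoff on Cox p-values
#'
#' Searches the sorted observed p-values for the largest cutoff `p0` whose
#' estimated FDR is at most `fdr_target`, where the estimate averages, over
#' permutation rounds, the number of permuted p-values at or below `p0`
#' divided by the number of observed p-values at or below `p0`.
#'
#' @param p_obs Observed univariate Cox p-values (one per gene).
#' @param perm_p Matrix of permuted p-values, rounds x genes (each round
#'   sharing one permutation across genes).
#' @param fdr_target Target FDR.
#' @return A list: `p0` (NA if no candidate meets the target),
#'   `fdr_estimate` at `p0`, and `pass` (logical per gene, `p_obs <= p0`).
#' @export
permutation_fdr_cutoff <- function(p_obs, perm_p, fdr_target = 0.01) {
  perm_p <- as.matrix(perm_p)
  stopifnot(ncol(perm_p) == length(p_obs))
  candidates <- sort(unique(p_obs[is.finite(p_obs)]))
  best_p0 <- NA_real_
  best_fdr <- NA_real_
  for (p0 in candidates) {
    n_obs <- sum(p_obs <= p0, na.rm = TRUE)
    if (n_obs == 0) next
    fdr <- mean(rowSums(perm_p <= p0)) / n_obs
    if (fdr <= fdr_target) {
      best_p0 <- p0
      best_fdr <- fdr
    }
  }
  pass <- if (is.na(best_p0)) rep(FALSE, length(p_obs)) else !is.na(p_obs) & p_obs <= best_p0
  list(p0 = best_p0, fdr_estimate = best_fdr, pass = pass)
}

#' Two-stage survival screen over all gene patterns
#'
#' Stage 1 splits each gene's MPS at its median and requires the log-rank
#' p-value both below `logrank_alpha` and below all `B` label-permutation
#' replicates (empirical p < `empirical_p_threshold`). Stage 2 fits a
#' univariate Cox model on each surviving gene's continuous MPS and retains
#' genes with Wald p below both `cox_alpha` and the permutation FDR cutoff
#' `p0` at `fdr_target`. One permutation per round is shared across genes,
#' preserving between-gene correlation in the null store.
#'
#' @param patterns A `gene_patterns` object, or directly a samples x genes
#'   MPS matrix.
#' @param clin Clinical table aligned with the MPS rows.
#' @param config A [screen_config()].
#' @return An object of class `screen_result`: `records` (per-gene
#'   data.frame with `gene_id`, `logrank_p`, `empirical_p`, `cox_coef`,
#'   `cox_hr`, `cox_p`, `passed_stage1`, `passed_stage2`) and `summary`
#'   (list with `p0`, `fdr_estimate`, `n_genes`, `stage1_count`,
#'   `stage2_count`, `B`, `seed`).
#' @export
screen_genes <- function(patterns, clin, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  mps <- if (inherits(patterns, "gene_patterns")) mps_matrix(patterns) else as.matrix(patterns)
  stopifnot(nrow(mps) == nrow(clin))
  G <- ncol(mps)
  B <- config$n_permutations
  n <- nrow(clin)

  groups <- apply(mps, 2, function(s) s > stats::median(s))   # n x G, TRUE = high
  degenerate <- apply(mps, 2, function(s) all(s == s[1]))

  # observed stage-1 statistics via survival::survdiff
  logrank_p <- rep(NA_real_, G)
  for (j in seq_len(G)) {
    if (degenerate[j]) next
    logrank_p[j] <- logrank_test(factor(ifelse(groups[, j], "high", "low"),
                                        levels = c("low", "high")), clin)$p
  }

  # shared permutation store, stage 1
  perms <- permutation_rounds(n, B, config$seed)
  count_le <- rep(0L, G)
  for (b in seq_len(B)) {
    idx <- perms[, b]
    pb <- fast_logrank(clin$os_time[idx], clin$os_event[idx], groups)$p
    count_le <- count_le + (pb <= logrank_p)
  }
  empirical_p <- (1 + count_le) / (B + 1)
  passed1 <- !degenerate & !is.na(logrank_p) &
    logrank_p < config$logrank_alpha & empirical_p < config$empirical_p_threshold

  records <- data.frame(
    gene_id = colnames(mps) %||% sprintf("g%d", seq_len(G)),
    logrank_p = logrank_p,
    empirical_p = empirical_p,
    cox_coef = NA_real_, cox_hr = NA_real_, cox_p = NA_real_,
    passed_stage1 = passed1, passed_stage2 = FALSE,
    stringsAsFactors = FALSE
  )

  p0 <- NA_real_
  fdr_estimate <- NA_real_
  if (any(passed1)) {
    sub <- which(passed1)
    for (j in sub) {
      cx <- univariate_cox(mps[, j], clin)
      records$cox_coef[j] <- cx$coef
      records$cox_hr[j] <- cx$hr
      records$cox_p[j] <- cx$p
    }
    ok <- sub[!is.na(records$cox_p[sub])]
    if (length(ok) > 0) {
      # fresh permutation substream for the Cox stage
      perms2 <- permutation_rounds(n, B, config$seed + 1L)
      perm_store <- matrix(NA_real_, B, length(ok))
      for (b in seq_len(B)) {
        idx <- perms2[, b]
        perm_store[b, ] <- fast_cox(clin$os_time[idx], clin$os_event[idx],
                                    mps[, ok, drop = FALSE])$p
      }
      cut <- permutation_fdr_cutoff(records$cox_p[ok], perm_store, config$fdr_target)
      p0 <- cut$p0
      fdr_estimate <- cut$fdr_estimate
      records$passed_stage2[ok] <- cut$pass & records$cox_p[ok] < config$cox_alpha
    }
  }

  structure(list(
    records = records,
    summary = list(
      p0 = p0, fdr_estimate = fdr_estimate, n_genes = G,
      stage1_count = sum(records$passed_stage1),
      stage2_count = sum(records$passed_stage2),
      B = B, seed = config$seed
    )
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Survival screen: %d genes -> stage 1 (log-rank + %d permutations): %d -> stage 2 (Cox, FDR cutoff p0=%s): %d\n",
    s$n_genes, s$B, s$stage1_count,
    ifelse(is.na(s$p0), "NA", format(s$p0, digits = 3)), s$stage2_count
  ))
  invisible(x)
}
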