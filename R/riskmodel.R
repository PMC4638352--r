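#' Multivariable Cox feature selection on screened genes
#'
#' Fits one multivariable Cox model on all screened genes' continuous MPS
#' values jointly, retains genes with Wald p below `alpha`, and refits on
#' the retained set to produce the final coefficients. Hazard ratios are
#' `exp(coef)` with Wald 95% confidence intervals; genes with negative
#' coefficients are classified protective, positive ones risk. If the full
#' joint fit fails to converge, a ridge-stabilized fit (penalty 1e-3) is
#' used for the selection step and a message notes this.
#'
#' @param mps Samples x genes MPS matrix restricted to screened genes.
#' @param clin Clinical table aligned with `mps`.
#' @param alpha Wald p-value threshold for retaining a gene (default 0.01).
#' @return A list of class `cox_selection`: `table` (per retained gene:
#'   `gene_id`, `coef`, `hr`, `p`, `ci_lower`, `ci_upper`, `role`), the
#'   refitted `coxph` object as `fit`, and `screened` (input gene ids).
#' @export
fit_multivariable_cox <- function(mps, clin, alpha = 0.01) {
  mps <- as.matrix(mps)
  if (ncol(mps) < 1) stop("screened gene set is empty", call. = FALSE)
  if (sum(clin$os_event) < 1) stop("Cox regression needs at least one event", call. = FALSE)
  genes <- colnames(mps)
  df <- as.data.frame(mps)
  safe <- make.names(genes, unique = TRUE)
  colnames(df) <- safe
  df$.time <- clin$os_time
  df$.event <- clin$os_event
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~", paste(safe, collapse = " + ")))

  full <- tryCatch(
    suppressWarnings(survival::coxph(form, data = df, ties = "efron")),
    error = function(e) NULL
  )
  if (is.null(full) || any(!is.finite(stats::coef(full)))) {
    message("fit_multivariable_cox: full joint fit unstable; using ridge-stabilized fit (penalty 1e-3) for selection")
    form_r <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~ survival::ridge(",
      paste(safe, collapse = ", "), ", theta = 1e-3)"
    ))
    full <- survival::coxph(form_r, data = df, ties = "efron")
    cf <- stats::coef(full)
    se <- sqrt(diag(stats::vcov(full)))
    pvals <- 2 * stats::pnorm(-abs(cf / se))
    names(pvals) <- safe
  } else {
    sm <- summary(full)
    pvals <- sm$coefficients[, "Pr(>|z|)"]
    names(pvals) <- safe
  }

  keep <- safe[pvals < alpha]
  if (length(keep) == 0) stop("no gene passed the multivariable Cox threshold", call. = FALSE)

  form2 <- stats::as.formula(paste("survival::Surv(.time, .event) ~", paste(keep, collapse = " + ")))
  refit <- suppressWarnings(survival::coxph(form2, data = df, ties = "efron"))
  sm2 <- summary(refit)
  cf <- stats::coef(refit)
  ci <- stats::confint(refit)
  tab <- data.frame(
    gene_id = genes[match(keep, safe)],
    coef = unname(cf),
    hr = unname(exp(cf)),
    p = unname(sm2$coefficients[, "Pr(>|z|)"]),
    ci_lower = unname(exp(ci[, 1])),
    ci_upper = unname(exp(ci[, 2])),
    stringsAsFactors = FALSE
  )
  tab$role <- ifelse(tab$coef < 0, "protective", "risk")
  structure(list(table = tab, fit = refit, screened = genes, alpha = alpha),
            class = "cox_selection")
}

#' Methylation risk score from gene coefficients
#'
#' `MRS_k = sum_j c_j * MPS_jk` over the featured genes, with high/low
#' groups split at the median (`> median` is high), or at a supplied
#' threshold.
#'
#' @param coefs Named coefficient vector (names = gene ids), or a
#'   `cox_selection` / `mrs_model` object.
#' @param mps Samples x genes MPS matrix containing the featured genes.
#' @param threshold Optional split threshold; default is the median MRS of
#'   the supplied samples.
#' @return A data.frame of class `mrs_vector`: `sample_id`, `mrs`, `group`,
#'   with the threshold in `attr(, "threshold")`.
#' @export
compute_mrs <- function(coefs, mps, threshold = NULL) {
  if (inherits(coefs, "mrs_model")) coefs <- stats::coef(coefs)
  if (inherits(coefs, "cox_selection")) {
    coefs <- stats::setNames(coefs$table$coef, coefs$table$gene_id)
  }
  mps <- as.matrix(mps)
  missing_genes <- setdiff(names(coefs), colnames(mps))
  if (length(missing_genes) > 0) {
    stop(sprintf("featured gene(s) absent from MPS matrix: %s",
                 paste(missing_genes, collapse = ", ")), call. = FALSE)
  }
  mrs <- drop(mps[, names(coefs), drop = FALSE] %*% coefs)
  if (is.null(threshold)) threshold <- stats::median(mrs)
  out <- data.frame(
    sample_id = rownames(mps) %||% sprintf("s%d", seq_along(mrs)),
    mrs = mrs,
    group = factor(ifelse(mrs > threshold, "high", "low"), levels = c("low", "high")),
    stringsAsFactors = FALSE
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("mrs_vector", "data.frame")
  out
}

#' Kaplan-Meier comparison of two groups with a five-year rate
#'
#' Product-limit survival curves per group via [survival::survfit()], the
#' survival probability at the horizon (default 1825 days = 5 years), and
#' the two-group log-rank p-value (NA, flagged, when no events occurred).
#'
#' @param groups Two-level factor per sample.
#' @param clin Clinical table aligned with `groups`.
#' @param horizon Evaluation time in days.
#' @return A list of class `km_estimate`: `fit` (the `survfit` object),
#'   `five_year_rate` (named per group), `logrank_p`, `horizon`, `n`
#'   (group sizes).
#' @export
km_estimate <- function(groups, clin, horizon = 1825) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2) stop("both groups must be non-empty", call. = FALSE)
  fit <- survival::survfit(survival::Surv(clin$os_time, clin$os_event) ~ groups)
  sm <- summary(fit, times = horizon, extend = TRUE)
  rate <- stats::setNames(sm$surv, sub("^groups=", "", as.character(sm$strata)))
  lr_p <- NA_real_
  if (sum(clin$os_event) >= 1) {
    lr_p <- logrank_test(groups, clin)$p
  } else {
    message("km_estimate: no events in either group; log-rank p undefined")
  }
  structure(list(
    fit = fit,
    five_year_rate = rate[levels(groups)],
    logrank_p = lr_p,
    horizon = horizon,
    n = table(groups)
  ), class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate (horizon %g days)\n", x$horizon))
  for (g in names(x$five_year_rate)) {
    cat(sprintf("  %-6s n=%3d  S(horizon)=%s\n", g, x$n[[g]],
                format(x$five_year_rate[[g]], digits = 4)))
  }
  cat(sprintf("  log-rank p = %s\n", format(x$logrank_p, digits = 4)))
  invisible(x)
}

#' Receptor-stratified survival comparison
#'
#' Crosses a receptor status (ER, PR or Her2) with the MRS high/low
#' grouping: a four-way comparison over `receptor +/- x MRS high/low`, plus
#' a two-way high-vs-low MRS comparison within each receptor state. Samples
#' with unknown receptor status are excluded; a stratum with no samples
#' skips its contrast with a message.
#'
#' @param mrs An `mrs_vector` (from [compute_mrs()] or [predict.mrs_model()]).
#' @param clin Clinical table aligned by `sample_id`.
#' @param receptor One of `"er"`, `"pr"`, `"her2"`.
#' @param horizon Evaluation horizon in days.
#' @return A list with elements `four_way` (a `km_estimate` over the
#'   crossed strata, or NULL) and `within` (named list of two-way
#'   `km_estimate`s, one per receptor state present).
#' @export
stratified_survival <- function(mrs, clin, receptor = c("er", "pr", "her2"),
                                horizon = 1825) {
  receptor <- match.arg(receptor)
  clin <- clin[match(mrs$sample_id, clin$sample_id), , drop = FALSE]
  status <- clin[[receptor]]
  known <- status %in% c("+", "-")
  if (sum(known) < 2) stop("need receptor labels for at least 2 samples", call. = FALSE)
  cl <- clin[known, , drop = FALSE]
  grp <- mrs$group[known]
  st <- status[known]

  four_way <- NULL
  cross <- factor(paste0(receptor, st, " & ", grp, "-MRS"))
  if (nlevels(droplevels(cross)) >= 2) {
    f <- survival::survfit(survival::Surv(cl$os_time, cl$os_event) ~ cross)
    sm <- summary(f, times = horizon, extend = TRUE)
    sd <- tryCatch(survival::survdiff(survival::Surv(cl$os_time, cl$os_event) ~ cross),
                   error = function(e) NULL)
    four_way <- structure(list(
      fit = f,
      five_year_rate = stats::setNames(sm$surv, sub("^cross=", "", as.character(sm$strata))),
      logrank_p = if (is.null(sd)) NA_real_ else
        stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE),
      horizon = horizon,
      n = table(droplevels(cross))
    ), class = "km_estimate")
  }

  within <- list()
  for (s in intersect(c("+", "-"), unique(st))) {
    sel <- st == s
    g <- droplevels(grp[sel])
    if (nlevels(g) < 2) {
      message(sprintf("stratified_survival: %s%s stratum has a single MRS group; contrast skipped", receptor, s))
      next
    }
    within[[paste0(receptor, s)]] <- km_estimate(g, cl[sel, , drop = FALSE], horizon = horizon)
  }
  list(four_way = four_way, within = within)
}

#' Fit the full methylation risk-score model
#'
#' The end-to-end estimator: per-gene canonical-correlation methylation
#' patterns ([per_gene_patterns()]), the two-stage permutation-calibrated
#' survival screen ([screen_genes()]), multivariable Cox feature selection
#' ([fit_multivariable_cox()]) on the screened genes, and the training-set
#' MRS with its median split and Kaplan-Meier comparison.
#'
#' The fitted object stores, per featured gene, the CCA weight vector,
#' training CpG means and regulatory direction, so the score transfers to
#' methylation-only cohorts via [predict.mrs_model()] without expression
#' data.
#'
#' @param meth Samples x CpGs beta matrix.
#' @param expr Samples x genes expression matrix.
#' @param pmap Promoter map (gene -> CpG ids).
#' @param clin Clinical table.
#' @param screen A [screen_config()].
#' @param cox_alpha Multivariable Cox retention threshold (default 0.01).
#' @param horizon Five-year horizon in days (default 1825).
#' @param ridge Passed to [per_gene_patterns()].
#' @return An object of class `mrs_model`.
#' @export
mrs_fit <- function(meth, expr, pmap, clin, screen = screen_config(),
                    cox_alpha = 0.01, horizon = 1825, ridge = FALSE) {
  aligned <- filter_missing(meth, expr, clin)
  patterns <- per_gene_patterns(aligned$meth, aligned$expr, pmap, ridge = ridge)
  mps <- mps_matrix(patterns)
  scr <- screen_genes(mps, aligned$clin, screen)
  featured_pool <- scr$records$gene_id[scr$records$passed_stage2]
  if (length(featured_pool) == 0) {
    stop("no genes survived the survival screen; cannot fit a risk model", call. = FALSE)
  }
  sel <- fit_multivariable_cox(mps[, featured_pool, drop = FALSE], aligned$clin,
                               alpha = cox_alpha)
  coefs <- stats::setNames(sel$table$coef, sel$table$gene_id)
  mrs <- compute_mrs(coefs, mps)
  km <- km_estimate(mrs$group, aligned$clin, horizon = horizon)
  structure(list(
    selection = sel,
    patterns = patterns[sel$table$gene_id],
    screen = scr,
    mrs = mrs,
    threshold = attr(mrs, "threshold"),
    km = km,
    clin = aligned$clin,
    horizon = horizon,
    n_genes_eligible = length(patterns)
  ), class = "mrs_model")
}

#' @export
coef.mrs_model <- function(object, ...) {
  stats::setNames(object$selection$table$coef, object$selection$table$gene_id)
}

#' @export
print.mrs_model <- function(x, ...) {
  tab <- x$selection$table
  cat(sprintf("Methylation risk score model: %d featured genes (%d protective, %d risk)\n",
              nrow(tab), sum(tab$role == "protective"), sum(tab$role == "risk")))
  cat(sprintf("Cascade: %d eligible -> %d (log-rank stage) -> %d (Cox FDR stage) -> %d featured\n",
              x$n_genes_eligible, x$screen$summary$stage1_count,
              x$screen$summary$stage2_count, nrow(tab)))
  cat(sprintf("Training median-MRS split at %s; 5-year survival low %.1f%% vs high %.1f%% (log-rank p = %s)\n",
              format(x$threshold, digits = 4),
              100 * x$km$five_year_rate[["low"]], 100 * x$km$five_year_rate[["high"]],
              format(x$km$logrank_p, digits = 3)))
  invisible(x)
}

#' @export
summary.mrs_model <- function(object, ...) {
  structure(list(table = object$selection$table,
                 screen = object$screen$summary,
                 km = object$km,
                 threshold = object$threshold), class = "summary.mrs_model")
}

#' @export
print.summary.mrs_model <- function(x, ...) {
  cat("Featured genes (multivariable Cox):\n")
  tab <- x$table
  tab$hr <- signif(tab$hr, 3)
  tab$p <- signif(tab$p, 3)
  tab$ci_lower <- signif(tab$ci_lower, 3)
  tab$ci_upper <- signif(tab$ci_upper, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("\nScreen: %d genes, stage1 %d, stage2 %d, p0 = %s, B = %d\n",
              x$screen$n_genes, x$screen$stage1_count, x$screen$stage2_count,
              format(x$screen$p0, digits = 3), x$screen$B))
  print(x$km)
  invisible(x)
}

#' Transfer the fitted risk score to a new (methylation-only) cohort
#'
#' Recomputes each featured gene's MPS from the stored CCA weights and
#' training CpG means on the new methylation matrix — no expression data or
#' refitting is involved — and sums the stored Cox coefficients into the
#' MRS. Probes absent from the new platform use the shared-CpG sub-vector
#' of the weights; with `reduced_panel = TRUE`, featured genes with no
#' shared probes at all are dropped and the MRS is the sum over the
#' remaining genes (the reduced-probe-platform case). By default the new
#' cohort is split at its own median MRS; `use_training_threshold = TRUE`
#' reuses the training split point.
#'
#' @param object A fitted `mrs_model`.
#' @param newdata Samples x CpGs beta matrix.
#' @param clin Optional clinical table for the new cohort; when given, a
#'   `km_estimate` at the model's horizon is attached.
#' @param reduced_panel Drop featured genes absent from the platform
#'   instead of erroring.
#' @param use_training_threshold Split at the training median instead of
#'   the new cohort's.
#' @param ... Unused.
#' @return An `mrs_vector`; if `clin` was supplied, with the KM comparison
#'   in `attr(, "km")`, and always with the genes used in
#'   `attr(, "genes_used")`.
#' @export
predict.mrs_model <- function(object, newdata, clin = NULL,
                              reduced_panel = FALSE,
                              use_training_threshold = FALSE, ...) {
  newdata <- as.matrix(newdata)
  tab <- object$selection$table
  scores <- list()
  used <- character(0)
  for (g in tab$gene_id) {
    pat <- object$patterns[[g]]
    shared <- intersect(names(pat$alpha), colnames(newdata))
    if (length(shared) == 0) {
      if (!reduced_panel) {
        stop(sprintf("featured gene '%s' has no probes on this platform; set reduced_panel = TRUE to drop it", g),
             call. = FALSE)
      }
      next
    }
    if (length(shared) < length(pat$alpha) && !reduced_panel) {
      stop(sprintf("gene '%s' is missing probe(s) %s; set reduced_panel = TRUE to use the shared subset",
                   g, paste(setdiff(names(pat$alpha), shared), collapse = ", ")), call. = FALSE)
    }
    scores[[g]] <- compute_mps(pat$alpha[shared], newdata,
                               center = pat$means[shared])
    used <- c(used, g)
  }
  if (length(used) == 0) stop("no featured gene shares probes with the new platform", call. = FALSE)
  mps_new <- do.call(cbind, scores)
  colnames(mps_new) <- used
  coefs <- stats::setNames(tab$coef, tab$gene_id)[used]
  thr <- if (use_training_threshold) object$threshold else NULL
  out <- compute_mrs(coefs, mps_new, threshold = thr)
  attr(out, "genes_used") <- used
  if (!is.null(clin)) {
    clin <- clin[match(out$sample_id, clin$sample_id), , drop = FALSE]
    attr(out, "km") <- km_estimate(out$group, clin, horizon = object$horizon)
  }
  out
}

#' Kaplan-Meier plot of the fitted risk groups
#'
#' @param x A fitted `mrs_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mrs_model <- function(x, ...) {
  graphics::plot(x$km$fit, col = c("#2166ac", "#b2182b"), lwd = 2,
                 xlab = "Days", ylab = "Overall survival", mark.time = TRUE, ...)
  graphics::abline(v = x$horizon, lty = 3, col = "grey40")
  graphics::legend("bottomleft", bty = "n", lwd = 2, col = c("#2166ac", "#b2182b"),
                   legend = sprintf("%s-MRS (5y %.1f%%)", c("low", "high"),
                                    100 * x$km$five_year_rate[c("low", "high")]))
  graphics::title(sub = sprintf("log-rank p = %s", format(x$km$logrank_p, digits = 3)))
  invisible(x)
}

#' Compare the MRS against standard clinical prognostic factors
#'
#' Fits univariate Cox models for the MRS and each binary clinical factor
#' (age at diagnosis <=55 vs >=56, stage I&II vs III&IV, tumor size 1-2 vs
#' 3-4), and one multivariable model with all of them jointly. Samples
#' missing a covariate are excluded listwise per model, with a message.
#' This is a reporting utility; it plays no part in feature selection.
#'
#' @param mrs An `mrs_vector`.
#' @param clin Clinical table aligned by `sample_id`.
#' @return A data.frame with one row per covariate: univariate and
#'   multivariable hazard ratios and Wald p-values.
#' @export
clinical_cox_comparison <- function(mrs, clin) {
  clin <- clin[match(mrs$sample_id, clin$sample_id), , drop = FALSE]
  df <- data.frame(
    mrs = mrs$mrs,
    age = ifelse(clin$age_group %in% c("<=55", ">=56"),
                 as.numeric(clin$age_group == ">=56"), NA),
    stage = ifelse(clin$stage_group %in% c("I&II", "III&IV"),
                   as.numeric(clin$stage_group == "III&IV"), NA),
    size = ifelse(clin$size_group %in% c("1-2", "3-4"),
                  as.numeric(clin$size_group == "3-4"), NA),
    .time = clin$os_time, .event = clin$os_event
  )
  vars <- c("mrs", "age", "stage", "size")
  uni <- t(vapply(vars, function(v) {
    sub <- df[!is.na(df[[v]]), , drop = FALSE]
    if (nrow(sub) < nrow(df)) {
      message(sprintf("clinical_cox_comparison: %d sample(s) excluded from univariate '%s' model",
                      nrow(df) - nrow(sub), v))
    }
    f <- suppressWarnings(survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .event) ~", v)), data = sub
    ))
    s <- summary(f)
    c(s$conf.int[1, "exp(coef)"], s$coefficients[1, "Pr(>|z|)"])
  }, numeric(2)))
  complete <- stats::complete.cases(df[vars])
  if (any(!complete)) {
    message(sprintf("clinical_cox_comparison: %d sample(s) excluded listwise from the multivariable model",
                    sum(!complete)))
  }
  mf <- suppressWarnings(survival::coxph(
    survival::Surv(.time, .event) ~ mrs + age + stage + size,
    data = df[complete, , drop = FALSE]
  ))
  ms <- summary(mf)
  data.frame(
    covariate = vars,
    hr_univariate = unname(uni[, 1]),
    p_univariate = unname(uni[, 2]),
    hr_multivariable = unname(ms$conf.int[vars, "exp(coef)"]),
    p_multivariable = unname(ms$coefficients[vars, "Pr(>|z|)"]),
    stringsAsFactors = FALSE
  )
}

#' Martingale residuals of the refitted multivariable Cox model
#'
#' @param object A fitted `mrs_model`.
#' @param ... Passed to [stats::residuals()] on the underlying `coxph` fit.
#' @export
residuals.mrs_model <- function(object, ...) {
  stats::residuals(object$selection$fit, ...)
}
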