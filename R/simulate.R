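#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-cohort generator. Defaults
#' describe the study conditions the package is exercised under: a
#' 200-sample cohort with 300 genes, promoter blocks of 2-15 CpGs, 6
#' planted prognostic genes with log-hazard 1.2 per standard deviation of
#' the true pattern score (a strong multigene signal whose genes remain
#' marginally detectable at this cohort size), an even mix of negative and
#' positive
#' methylation-to-expression regulation, 30% censoring, and a baseline
#' hazard whose mean survival equals the 5-year horizon (1825 days).
#'
#' @param n_samples Number of samples.
#' @param n_genes Number of genes.
#' @param cpgs_per_gene Integer range (length 2) of promoter CpGs per gene.
#' @param n_planted Number of genes whose true pattern score drives hazard.
#' @param effect_size Log-hazard per standard deviation of a planted gene's
#'   true pattern score.
#' @param direction_mix Probability that a gene's methylation-to-expression
#'   loading is negative (hypermethylation lowers expression).
#' @param noise_sd Standard deviation of the additive expression noise.
#' @param censor_rate Target fraction of samples censored (must be < 1).
#' @param baseline_hazard Baseline event rate, events per day.
#' @param receptor_effect Optional additive log-hazard for receptor-negative
#'   samples (applied to ER, PR and Her2 independently); 0 keeps receptor
#'   status independent of outcome.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_genes = 300, cpgs_per_gene = c(2, 15),
                       n_planted = 6, effect_size = 1.2, direction_mix = 0.5,
                       noise_sd = 0.5, censor_rate = 0.3,
                       baseline_hazard = 1 / 1825, receptor_effect = 0,
                       seed = 1) {
  stopifnot(n_samples >= 2, n_genes >= 1, length(cpgs_per_gene) == 2,
            cpgs_per_gene[1] >= 1, cpgs_per_gene[2] >= cpgs_per_gene[1],
            n_planted >= 0, n_planted <= n_genes,
            direction_mix >= 0, direction_mix <= 1,
            noise_sd >= 0, baseline_hazard > 0)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  }
  structure(list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    cpgs_per_gene = as.integer(cpgs_per_gene), n_planted = as.integer(n_planted),
    effect_size = effect_size, direction_mix = direction_mix,
    noise_sd = noise_sd, censor_rate = censor_rate,
    baseline_hazard = baseline_hazard, receptor_effect = receptor_effect,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a methylation/expression/survival cohort with known truth
#'
#' Generates a cohort with the structure the downstream analysis assumes.
#' Per gene, a latent Gaussian factor shared by the gene's promoter CpGs
#' plus probe-specific noise is pushed through a logistic link to produce
#' correlated beta values strictly inside (0,1); expression is an intercept
#' plus a signed weighted sum of the CpGs' logit-scale values plus Gaussian
#' noise, the sign being negative with probability `direction_mix`.
#' Survival times are exponential with log-hazard
#' `effect_size * standardized true pattern score` summed over planted
#' genes; censoring is independent exponential, calibrated so the expected
#' censored fraction equals `censor_rate`. Receptor statuses are
#' Bernoulli(0.5), independent of hazard unless `receptor_effect` is set.
#'
#' Each gene draws from its own seed-derived substream, so enlarging
#' `n_genes` does not perturb earlier genes' data.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `meth`, `expr`
#'   (samples x features matrices), `pmap` (promoter map), `clin` (clinical
#'   table) and `truth` (per-gene `data.frame`: `gene_id`, `planted`,
#'   `sign`, `hazard_coef`, `weights` comma-joined; plus the true per-sample
#'   pattern scores in `attr(truth, "scores")`).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  G <- config$n_genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  gene_ids <- sprintf("G%04d", seq_len(G))

  set.seed(config$seed)
  planted <- sort(sample.int(G, config$n_planted))

  meth_cols <- vector("list", G)
  pmap <- vector("list", G)
  names(pmap) <- gene_ids
  expr <- matrix(NA_real_, n, G, dimnames = list(sample_ids, gene_ids))
  scores <- matrix(NA_real_, n, G, dimnames = list(sample_ids, gene_ids))
  signs <- integer(G)
  weights <- vector("list", G)

  for (g in seq_len(G)) {
    set.seed(gene_substream(config$seed, g))
    p_range <- seq(config$cpgs_per_gene[1], config$cpgs_per_gene[2])
    p <- p_range[sample.int(length(p_range), 1)]
    mu <- stats::runif(p, -2, 2)        # probe baseline, logit scale
    load <- stats::runif(p, 0.5, 1)     # shared-factor loading
    w <- stats::runif(p, 0.5, 1.5)
    w <- w / sum(w)                     # true CpG weight vector
    s <- if (stats::runif(1) < config$direction_mix) -1L else 1L
    f <- stats::rnorm(n)                # per-sample latent factor
    z <- matrix(mu, n, p, byrow = TRUE) +
      outer(f, load) + matrix(stats::rnorm(n * p, sd = 0.3), n, p)
    beta <- stats::plogis(z)
    raw_score <- drop(z %*% w)
    scores[, g] <- (raw_score - mean(raw_score)) / stats::sd(raw_score)
    expr[, g] <- 5 + s * raw_score + stats::rnorm(n, sd = config$noise_sd)
    cpg_ids <- sprintf("cg%04d_%02d", g, seq_len(p))
    colnames(beta) <- cpg_ids
    meth_cols[[g]] <- beta
    pmap[[g]] <- cpg_ids
    signs[g] <- s
    weights[[g]] <- w
  }
  meth <- do.call(cbind, meth_cols)
  rownames(meth) <- sample_ids

  set.seed(cohort_substream(config$seed))
  er <- ifelse(stats::runif(n) < 0.5, "+", "-")
  pr <- ifelse(stats::runif(n) < 0.5, "+", "-")
  her2 <- ifelse(stats::runif(n) < 0.5, "+", "-")

  lp <- rep(0, n)
  if (length(planted) > 0) {
    lp <- config$effect_size * rowSums(scores[, planted, drop = FALSE])
  }
  if (config$receptor_effect != 0) {
    lp <- lp + config$receptor_effect *
      ((er == "-") + (pr == "-") + (her2 == "-"))
  }
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = rate)
  if (config$censor_rate > 0) {
    lambda_c <- calibrate_censoring(rate, config$censor_rate)
    t_cens <- stats::rexp(n, rate = lambda_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  os_time <- pmin(t_event, t_cens)
  os_event <- as.numeric(t_event <= t_cens)

  clin <- data.frame(
    sample_id = sample_ids,
    os_time = os_time,
    os_event = os_event,
    age_group = ifelse(stats::runif(n) < 0.5, "<=55", ">=56"),
    stage_group = ifelse(stats::runif(n) < 0.7, "I&II", "III&IV"),
    size_group = ifelse(stats::runif(n) < 0.6, "1-2", "3-4"),
    er = er, pr = pr, her2 = her2,
    stringsAsFactors = FALSE
  )
  rownames(clin) <- sample_ids

  truth <- data.frame(
    gene_id = gene_ids,
    planted = seq_len(G) %in% planted,
    sign = signs,
    hazard_coef = ifelse(seq_len(G) %in% planted, config$effect_size, 0),
    weights = vapply(weights, function(w) paste(signif(w, 8), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  attr(truth, "scores") <- scores

  structure(list(meth = meth, expr = expr, pmap = pmap, clin = clin,
                 truth = truth, config = config),
            class = "sim_cohort")
}

# Seed substreams: fixed affine maps into the 32-bit range keep per-gene and
# cohort-level draws disjoint and stable as n_genes grows.
gene_substream <- function(seed, g) {
  (as.double(seed) * 1009 + g * 7919) %% 2147483647
}
cohort_substream <- function(seed) {
  (as.double(seed) * 2654435761) %% 2147483647
}

# Solve mean(lambda_c / (lambda_c + rate)) = target for the exponential
# censoring rate; exact for exponential event times.
calibrate_censoring <- function(rate, target) {
  f <- function(lc) mean(lc / (lc + rate)) - target
  stats::uniroot(f, lower = min(rate) * 1e-8, upper = max(rate) * 1e8,
                 tol = 1e-12)$root
}

#' Write a simulated cohort as the standard file set
#'
#' Emits `methylation.tsv`, `expression.tsv`, `clinical.tsv`,
#' `promoter_map.tsv` (the dialects the readers accept) and `truth.tsv`
#' into `dir`.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    meth = file.path(dir, "methylation.tsv"),
    expr = file.path(dir, "expression.tsv"),
    clin = file.path(dir, "clinical.tsv"),
    pmap = file.path(dir, "promoter_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_id_matrix(cohort$meth, paths[["meth"]], "cpg_id")
  write_id_matrix(cohort$expr, paths[["expr"]], "gene_id")
  write_clinical_table(cohort$clin, paths[["clin"]])
  write_promoter_map(cohort$pmap, paths[["pmap"]])
  utils::write.table(cohort$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
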