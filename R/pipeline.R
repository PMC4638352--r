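#' Pipeline configuration
#'
#' Collects everything the file-based pipeline ([run_subcommand()]) needs:
#' input paths (defaulting to the files `simulate` writes into `out_dir`),
#' the simulation and screening configurations, and the analysis flags.
#'
#' @param out_dir Directory all stages read from and write to.
#' @param seed Integer seed, recorded in every output; also the default
#'   seed of `sim` and `screen`.
#' @param sim A [sim_config()] for the `simulate` stage.
#' @param screen A [screen_config()] for the `screen` stage.
#' @param meth,expr,clin,pmap Optional explicit input paths; by default the
#'   `simulate` outputs under `out_dir` are used.
#' @param horizon Five-year horizon in days.
#' @param cox_alpha Multivariable Cox retention threshold.
#' @param reduced_panel Allow scoring platforms missing featured genes.
#' @param ridge Ridge-stabilized CCA covariance inversion.
#' @param orientation Matrix file orientation for the readers.
#' @param use_training_threshold Reuse the training MRS split point when
#'   scoring new cohorts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            sim = sim_config(seed = seed),
                            screen = screen_config(seed = seed),
                            meth = NULL, expr = NULL, clin = NULL, pmap = NULL,
                            horizon = 1825, cox_alpha = 0.01,
                            reduced_panel = FALSE, ridge = FALSE,
                            orientation = "features_rows",
                            use_training_threshold = FALSE) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), sim = sim, screen = screen,
    meth = meth, expr = expr, clin = clin, pmap = pmap,
    horizon = horizon, cox_alpha = cox_alpha,
    reduced_panel = reduced_panel, ridge = ridge, orientation = orientation,
    use_training_threshold = use_training_threshold
  ), class = "pipeline_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

provenance_line <- function(config) {
  sprintf("# seed=%d config_md5=%s", config$seed, config_hash(config))
}

write_tsv_with_provenance <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

stage_input <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing '%s': run the '%s' subcommand before '%s'",
                 basename(path), stage, needed_by), call. = FALSE)
  }
  path
}

#' Run one pipeline stage
#'
#' File-based pipeline over the package's functions, one stage at a time:
#' `simulate` writes a synthetic cohort; `mps` estimates per-gene
#' methylation patterns (`patterns.tsv`, `mps.tsv`); `screen` runs the
#' two-stage survival screen (`screen.tsv`, `screen_summary.json`); `fit`
#' selects the featured genes and writes the transferable model
#' (`model.json`); `score` computes the per-sample MRS from methylation
#' alone (`mrs.tsv`); `km` compares the median-split risk groups
#' (`km.tsv`); `report` aggregates the cascade into `report.json`. Every
#' output embeds the seed and a config digest; a stage whose inputs are
#' missing names the stage to run first.
#'
#' @param name One of `simulate`, `mps`, `screen`, `fit`, `score`, `km`,
#'   `report`.
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths written by the stage.
#' @export
run_subcommand <- function(name = c("simulate", "mps", "screen", "fit", "score", "km", "report"),
                           config) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$out_dir, f)
  in_meth <- config$meth %||% od("methylation.tsv")
  in_expr <- config$expr %||% od("expression.tsv")
  in_clin <- config$clin %||% od("clinical.tsv")
  in_pmap <- config$pmap %||% od("promoter_map.tsv")

  switch(name,
    simulate = {
      paths <- write_cohort(simulate_cohort(config$sim), config$out_dir)
      message(sprintf("simulate: wrote %d-sample, %d-gene cohort to %s",
                      config$sim$n_samples, config$sim$n_genes, config$out_dir))
      invisible(paths)
    },
    mps = {
      for (f in c(in_meth, in_expr, in_clin, in_pmap)) stage_input(f, "simulate", "mps")
      meth <- read_methylation_matrix(in_meth, config$orientation)
      expr <- read_expression_matrix(in_expr, config$orientation)
      clin <- read_clinical_table(in_clin)
      pmap <- read_promoter_map(in_pmap)
      al <- filter_missing(meth, expr, clin)
      pats <- per_gene_patterns(al$meth, al$expr, pmap, ridge = config$ridge)
      ptab <- data.frame(
        gene_id = vapply(pats, `[[`, character(1), "gene_id"),
        p = vapply(pats, `[[`, numeric(1), "p"),
        r = vapply(pats, `[[`, numeric(1), "r"),
        pearson_avg = vapply(pats, `[[`, numeric(1), "pearson_avg"),
        beta_sign = vapply(pats, `[[`, integer(1), "beta_sign"),
        alpha = vapply(pats, function(x) paste(format(x$alpha, digits = 17), collapse = ","), character(1)),
        cpg_means = vapply(pats, function(x) paste(format(x$means, digits = 17), collapse = ","), character(1)),
        cpgs = vapply(pats, function(x) paste(names(x$alpha), collapse = ","), character(1)),
        stringsAsFactors = FALSE
      )
      write_tsv_with_provenance(ptab, od("patterns.tsv"), config)
      mm <- mps_matrix(pats)
      mdf <- data.frame(sample_id = rownames(mm), mm, check.names = FALSE)
      write_tsv_with_provenance(mdf, od("mps.tsv"), config)
      message(sprintf("mps: %d eligible genes", length(pats)))
      invisible(c(od("patterns.tsv"), od("mps.tsv")))
    },
    screen = {
      mps_path <- stage_input(od("mps.tsv"), "mps", "screen")
      stage_input(in_clin, "simulate", "screen")
      mps <- read_mps_file(mps_path)
      clin <- read_clinical_table(in_clin)
      clin <- clin[match(rownames(mps), clin$sample_id), , drop = FALSE]
      scr <- screen_genes(mps, clin, config$screen)
      write_tsv_with_provenance(scr$records, od("screen.tsv"), config)
      jsonlite::write_json(
        c(scr$summary, list(config_md5 = config_hash(config))),
        od("screen_summary.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      message(sprintf("screen: stage1 %d, stage2 %d of %d genes",
                      scr$summary$stage1_count, scr$summary$stage2_count,
                      scr$summary$n_genes))
      invisible(c(od("screen.tsv"), od("screen_summary.json")))
    },
    fit = {
      rec_path <- stage_input(od("screen.tsv"), "screen", "fit")
      mps_path <- stage_input(od("mps.tsv"), "mps", "fit")
      pat_path <- stage_input(od("patterns.tsv"), "mps", "fit")
      stage_input(in_clin, "simulate", "fit")
      rec <- utils::read.delim(rec_path, comment.char = "#")
      mps <- read_mps_file(mps_path)
      pats <- read_patterns_file(pat_path)
      clin <- read_clinical_table(in_clin)
      clin <- clin[match(rownames(mps), clin$sample_id), , drop = FALSE]
      pool <- rec$gene_id[rec$passed_stage2]
      if (length(pool) == 0) stop("no genes passed the screen; nothing to fit", call. = FALSE)
      sel <- fit_multivariable_cox(mps[, pool, drop = FALSE], clin, alpha = config$cox_alpha)
      mrs <- compute_mrs(sel, mps)
      model <- list(
        genes = sel$table$gene_id,
        coef = sel$table$coef,
        hr = sel$table$hr,
        p = sel$table$p,
        ci_lower = sel$table$ci_lower,
        ci_upper = sel$table$ci_upper,
        role = sel$table$role,
        threshold = attr(mrs, "threshold"),
        patterns = lapply(sel$table$gene_id, function(g) {
          pp <- pats[[g]]
          list(gene_id = g, cpgs = names(pp$alpha),
               alpha = unname(pp$alpha), means = unname(pp$means),
               beta_sign = pp$beta_sign)
        }),
        horizon = config$horizon,
        seed = config$seed,
        config_md5 = config_hash(config)
      )
      jsonlite::write_json(model, od("model.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      message(sprintf("fit: %d featured genes of %d screened", nrow(sel$table), length(pool)))
      invisible(od("model.json"))
    },
    score = {
      model_path <- stage_input(od("model.json"), "fit", "score")
      model <- jsonlite::read_json(model_path, simplifyVector = TRUE)
      stage_input(in_meth, "simulate", "score")
      meth <- read_methylation_matrix(in_meth, config$orientation)
      mrs <- score_from_model(model, meth,
                              reduced_panel = config$reduced_panel,
                              threshold = if (config$use_training_threshold) model$threshold else NULL)
      write_tsv_with_provenance(mrs, od("mrs.tsv"), config)
      message(sprintf("score: MRS for %d samples over %d genes",
                      nrow(mrs), length(attr(mrs, "genes_used"))))
      invisible(od("mrs.tsv"))
    },
    km = {
      mrs_path <- stage_input(od("mrs.tsv"), "score", "km")
      mrs <- utils::read.delim(mrs_path, comment.char = "#")
      stage_input(in_clin, "simulate", "km")
      clin <- read_clinical_table(in_clin)
      clin <- clin[match(mrs$sample_id, clin$sample_id), , drop = FALSE]
      km <- km_estimate(factor(mrs$group, levels = c("low", "high")), clin,
                        horizon = config$horizon)
      sm <- summary(km$fit)
      steps <- data.frame(
        group = sub("^groups=", "", as.character(sm$strata)),
        time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event, surv = sm$surv
      )
      rates <- data.frame(
        group = c("five_year_low", "five_year_high", "logrank_p"),
        time = NA, n_risk = NA, n_event = NA,
        surv = c(km$five_year_rate[["low"]], km$five_year_rate[["high"]], km$logrank_p)
      )
      write_tsv_with_provenance(rbind(steps, rates), od("km.tsv"), config)
      message(sprintf("km: 5-year survival low %.1f%% vs high %.1f%%, log-rank p = %.3g",
                      100 * km$five_year_rate[["low"]], 100 * km$five_year_rate[["high"]],
                      km$logrank_p))
      invisible(od("km.tsv"))
    },
    report = {
      scr_path <- stage_input(od("screen_summary.json"), "screen", "report")
      scr <- jsonlite::read_json(scr_path, simplifyVector = TRUE)
      model_path <- stage_input(od("model.json"), "fit", "report")
      model <- jsonlite::read_json(model_path, simplifyVector = TRUE)
      kmt <- utils::read.delim(stage_input(od("km.tsv"), "km", "report"), comment.char = "#")
      rates <- stats::setNames(kmt$surv, kmt$group)
      rep <- list(
        n_genes = scr$n_genes,
        stage1_count = scr$stage1_count,
        stage2_count = scr$stage2_count,
        n_featured = length(model$genes),
        featured_genes = model$genes,
        n_protective = sum(model$role == "protective"),
        n_risk = sum(model$role == "risk"),
        five_year_low = unname(rates["five_year_low"]),
        five_year_high = unname(rates["five_year_high"]),
        logrank_p = unname(rates["logrank_p"]),
        seed = config$seed,
        config_md5 = config_hash(config)
      )
      jsonlite::write_json(rep, od("report.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      invisible(od("report.json"))
    }
  )
}

read_mps_file <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

read_patterns_file <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    cpgs <- strsplit(df$cpgs[i], ",")[[1]]
    list(
      gene_id = df$gene_id[i],
      alpha = stats::setNames(as.numeric(strsplit(df$alpha[i], ",")[[1]]), cpgs),
      means = stats::setNames(as.numeric(strsplit(df$cpg_means[i], ",")[[1]]), cpgs),
      beta_sign = df$beta_sign[i],
      r = df$r[i], pearson_avg = df$pearson_avg[i]
    )
  })
  names(out) <- df$gene_id
  out
}

# Score a methylation-only cohort from a serialized model (list form of
# model.json); mirrors predict.mrs_model.
score_from_model <- function(model, meth, reduced_panel = FALSE, threshold = NULL) {
  pats <- model$patterns
  if (is.data.frame(pats)) pats <- split(pats, seq_len(nrow(pats)))
  scores <- list()
  used <- character(0)
  for (pp in pats) {
    g <- pp$gene_id
    alpha <- stats::setNames(unlist(pp$alpha), unlist(pp$cpgs))
    means <- stats::setNames(unlist(pp$means), unlist(pp$cpgs))
    shared <- intersect(names(alpha), colnames(meth))
    if (length(shared) < length(alpha) && !reduced_panel) {
      stop(sprintf("gene '%s' is missing probes on this platform; enable reduced_panel", g), call. = FALSE)
    }
    if (length(shared) == 0) next
    scores[[g]] <- compute_mps(alpha[shared], meth, center = means[shared])
    used <- c(used, g)
  }
  if (length(used) == 0) stop("no featured gene shares probes with the platform", call. = FALSE)
  mm <- do.call(cbind, scores)
  colnames(mm) <- used
  coefs <- stats::setNames(model$coef, model$genes)[used]
  out <- compute_mrs(coefs, mm, threshold = threshold)
  attr(out, "genes_used") <- used
  out
}
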