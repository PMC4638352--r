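test_that("multivariable selection keeps strong planted genes and is exp/log consistent", {
  kept <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 150
    mps <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(sprintf("S%03d", 1:n), sprintf("g%02d", 1:10)))
    lp <- mps[, 1] - mps[, 2] + 0.8 * mps[, 3]
    clin <- make_clin(rexp(n, exp(lp) / 1825), rep(1, n), ids = rownames(mps))
    sel <- fit_multivariable_cox(mps, clin, alpha = 0.01)
    all(c("g01", "g02", "g03") %in% sel$table$gene_id)
  }, logical(1))
  expect_gte(mean(kept), 0.8)

  set.seed(3)
  n <- 150
  mps <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("S%03d", 1:n), sprintf("g%02d", 1:4)))
  clin <- make_clin(rexp(n, exp(mps[, 1]) / 100), rep(1, n), ids = rownames(mps))
  sel <- fit_multivariable_cox(mps, clin, alpha = 0.05)
  expect_true(all(abs(log(sel$table$hr) - sel$table$coef) < 1e-9))
  expect_equal(sum(sel$table$role == "protective"), sum(sel$table$coef < 0))
  expect_equal(sum(sel$table$role == "risk"), sum(sel$table$coef > 0))
})

test_that("the MRS is the stated weighted sum with a median split", {
  coefs <- c(gA = 1, gB = -2, gC = 0.5)
  mps <- matrix(c(2, 1, 4), nrow = 1, dimnames = list("S1", c("gA", "gB", "gC")))
  expect_equal(compute_mrs(coefs, mps, threshold = 0)$mrs, 2)

  mps0 <- matrix(0, nrow = 5, ncol = 3,
                 dimnames = list(sprintf("S%d", 1:5), names(coefs)))
  expect_equal(compute_mrs(coefs, mps0, threshold = -1)$mrs, rep(0, 5))

  # scaling all coefficients leaves the median-split groups unchanged
  set.seed(23)
  mpsr <- matrix(rnorm(60), 20, 3, dimnames = list(sprintf("S%02d", 1:20), names(coefs)))
  a <- compute_mrs(coefs, mpsr)
  b <- compute_mrs(3.7 * coefs, mpsr)
  expect_equal(b$mrs, 3.7 * a$mrs, tolerance = 1e-12)
  expect_identical(b$group, a$group)

  expect_error(compute_mrs(c(coefs, gZ = 1), mpsr), "gZ")
})

test_that("Kaplan-Meier estimates match empirical and hand-computed tables", {
  # no censoring: S(horizon) is the observed surviving fraction
  clin <- make_clin(c(100, 200, 300, 400, rep(2000, 6)), c(rep(1, 4), rep(0, 6)))
  clin$os_event[5:10] <- 0
  grp <- factor(rep(c("a", "b"), 5))
  # single pooled check via one group against a no-event group is artificial;
  # use all samples in one stratum against a duplicated stratum instead
  clin2 <- rbind(clin, clin)
  clin2$sample_id <- sprintf("S%02d", 1:20)
  km <- km_estimate(factor(rep(c("a", "b"), each = 10)), clin2, horizon = 1825)
  expect_equal(unname(km$five_year_rate), c(0.6, 0.6))

  # censoring-only cohort: survival stays at 1, log-rank flagged NA
  cens <- make_clin(c(10, 20, 30, 40), rep(0, 4))
  km0 <- suppressMessages(km_estimate(factor(c("a", "a", "b", "b")), cens))
  expect_true(all(km0$five_year_rate == 1))
  expect_true(is.na(km0$logrank_p))

  # 8-sample mixed censoring vs the hand-computed product-limit table
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 0, 1, 1, 0, 1, 1, 0)
  # by hand: S = 7/8, *5/6, *4/5, *2/3, *1/2 at t = 1,3,4,6,7
  expected <- c(0.875, 0.875 * 5 / 6, 0.875 * 5 / 6 * 4 / 5,
                0.875 * 5 / 6 * 4 / 5 * 2 / 3,
                0.875 * 5 / 6 * 4 / 5 * 2 / 3 / 2)
  both <- make_clin(c(time, 50, 60), c(event, 1, 1), ids = sprintf("S%02d", 1:10))
  km8 <- km_estimate(factor(c(rep("mix", 8), "other", "other")), both)
  sm <- summary(km8$fit)
  mix <- sm$surv[grepl("mix", as.character(sm$strata))]
  expect_equal(mix, expected, tolerance = 1e-12)
})

test_that("receptor stratification crosses status with MRS groups", {
  set.seed(29)
  n <- 120
  mrs_vals <- rnorm(n)
  ids <- sprintf("S%03d", 1:n)
  er <- sample(c("+", "-"), n, replace = TRUE)
  clin <- make_clin(rexp(n, exp(2 * (mrs_vals > median(mrs_vals))) / 1825),
                    rep(1, n), ids = ids, er = er)
  mps <- matrix(mrs_vals, ncol = 1, dimnames = list(ids, "g1"))
  mrs <- compute_mrs(c(g1 = 1), mps)
  out <- stratified_survival(mrs, clin, "er")
  expect_length(out$within, 2)
  expect_equal(nlevels(droplevels(factor(names(out$four_way$five_year_rate)))), 4)
  # the planted direction: high MRS fares worse within each receptor state
  for (w in out$within) {
    expect_lt(w$five_year_rate[["high"]], w$five_year_rate[["low"]])
  }

  # one receptor state only: the four-way collapses to the two-way contrast
  clin_all <- make_clin(rexp(n), rbinom(n, 1, 0.7), ids = ids, er = "+")
  out2 <- stratified_survival(mrs, clin_all, "er")
  expect_length(out2$within, 1)
  expect_named(out2$within, "er+")
})

test_that("within-receptor log-rank p-values are uniform under the null", {
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 60
    ids <- sprintf("S%03d", 1:n)
    clin <- make_clin(rexp(n), rbinom(n, 1, 0.8), ids = ids,
                      er = sample(c("+", "-"), n, replace = TRUE))
    mps <- matrix(rnorm(n), ncol = 1, dimnames = list(ids, "g1"))
    out <- stratified_survival(compute_mrs(c(g1 = 1), mps), clin, "er")
    out$within[["er-"]]$logrank_p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("the fitted model transfers exactly and supports reduced panels", {
  co <- simulate_cohort(sim_config(n_samples = 120, n_genes = 40, n_planted = 6,
                                   effect_size = 1.5, seed = 37))
  fit <- suppressMessages(mrs_fit(co$meth, co$expr, co$pmap, co$clin,
                                  screen_config(seed = 37)))
  expect_s3_class(fit, "mrs_model")
  expect_gte(nrow(fit$selection$table), 1)

  # transfer identity on the training inputs
  tr <- predict(fit, co$meth)
  expect_identical(tr$mrs, fit$mrs$mrs)
  expect_identical(tr$group, fit$mrs$group)

  # reduced panel: dropping genes leaves the partial sum over the rest
  genes <- fit$selection$table$gene_id
  if (length(genes) >= 3) {
    drop_genes <- genes[1:2]
    keep_probes <- setdiff(colnames(co$meth), unlist(co$pmap[drop_genes]))
    red <- predict(fit, co$meth[, keep_probes], reduced_panel = TRUE)
    kept <- setdiff(genes, drop_genes)
    coefs <- coef(fit)[kept]
    manual <- drop(vapply(kept, function(g) {
      p <- fit$patterns[[g]]
      compute_mps(p$alpha, co$meth, center = p$means)
    }, numeric(nrow(co$meth))) %*% coefs)
    expect_equal(red$mrs, unname(manual), tolerance = 1e-12)
    expect_setequal(attr(red, "genes_used"), kept)
  }

  # a missing featured gene without the flag is an error
  g1 <- genes[1]
  probes <- setdiff(colnames(co$meth), co$pmap[[g1]])
  expect_error(predict(fit, co$meth[, probes]), g1)
})

test_that("the clinical-factor comparison reports the MRS as prognostic when it is", {
  set.seed(61)
  n <- 150
  ids <- sprintf("S%03d", 1:n)
  mrs_vals <- rnorm(n)
  clin <- make_clin(rexp(n, exp(mrs_vals) / 1825), rep(1, n), ids = ids)
  clin$age_group <- sample(c("<=55", ">=56"), n, replace = TRUE)
  clin$stage_group <- sample(c("I&II", "III&IV"), n, replace = TRUE)
  clin$size_group <- sample(c("1-2", "3-4"), n, replace = TRUE)
  mps <- matrix(mrs_vals, ncol = 1, dimnames = list(ids, "g1"))
  tab <- clinical_cox_comparison(compute_mrs(c(g1 = 1), mps), clin)
  expect_equal(tab$covariate, c("mrs", "age", "stage", "size"))
  expect_lt(tab$p_univariate[1], 1e-6)
  expect_lt(tab$p_multivariable[1], 1e-6)
  # null clinical factors stay null
  expect_gt(min(tab$p_univariate[-1]), 0.001)

  # listwise exclusion is reported when a covariate is unknown
  clin$age_group[1] <- "unknown"
  expect_message(clinical_cox_comparison(compute_mrs(c(g1 = 1), mps), clin),
                 "excluded")
})

test_that("transferred scores separate survival in a held-out methylation-only cohort", {
  worse <- vapply(1:10, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 300, n_genes = 30, n_planted = 6,
                                     effect_size = 1.5, seed = s))
    train <- rownames(co$meth)[1:150]
    test <- rownames(co$meth)[151:300]
    fit <- try(suppressMessages(mrs_fit(
      co$meth[train, ], co$expr[train, ], co$pmap,
      co$clin[train, ], screen_config(seed = s)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) return(NA)
    # held-out samples carry methylation and outcome only
    sc <- predict(fit, co$meth[test, ], clin = co$clin[test, ])
    km <- attr(sc, "km")
    km$five_year_rate[["high"]] < km$five_year_rate[["low"]]
  }, logical(1))
  expect_gte(mean(worse, na.rm = TRUE), 0.9)
})
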