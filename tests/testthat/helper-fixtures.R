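# Shared fixture builders. All fixtures are generated in code.

# Minimal clinical table around survival times/events.
make_clin <- function(time, event, ids = sprintf("S%02d", seq_along(time)),
                      er = "+", pr = "+", her2 = "+") {
  n <- length(time)
  df <- data.frame(
    sample_id = ids,
    os_time = time,
    os_event = event,
    age_group = rep(c("<=55", ">=56"), length.out = n),
    stage_group = rep("I&II", n),
    size_group = rep("1-2", n),
    er = rep(er, length.out = n),
    pr = rep(pr, length.out = n),
    her2 = rep(her2, length.out = n),
    stringsAsFactors = FALSE
  )
  rownames(df) <- df$sample_id
  df
}

# Write a features-in-rows TSV matrix file (the reader's on-disk dialect).
write_matrix_fixture <- function(m, path, id_col = "cpg_id") {
  tm <- t(m)
  df <- data.frame(id = rownames(tm), tm, check.names = FALSE)
  colnames(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent grid-search oracle for the canonical correlation with p = 2 or
# p = 3 CpGs: exhaustive search over unit directions at ~1e-3 angular
# resolution, maximizing |cor(X w, y)|.
grid_search_r <- function(X, y, n_theta = 3142) {
  p <- ncol(X)
  best <- 0
  if (p == 2) {
    for (theta in seq(0, pi, length.out = n_theta)) {
      w <- c(cos(theta), sin(theta))
      u <- X %*% w
      if (sd(u) > 1e-12) best <- max(best, abs(cor(u, y)))
    }
  } else if (p == 3) {
    for (theta in seq(0, pi, length.out = 180)) {
      for (phi in seq(0, pi, length.out = 180)) {
        w <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
        u <- X %*% w
        if (sd(u) > 1e-12) best <- max(best, abs(cor(u, y)))
      }
    }
  } else stop("oracle supports p <= 3")
  best
}

# Independent observed-minus-expected log-rank computation (direct loop over
# distinct event times).
manual_logrank <- function(time, event, group) {
  g1 <- group == levels(factor(group))[1]
  oe <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    Y <- sum(at_risk); Y1 <- sum(at_risk & g1)
    oe <- oe + d1 - d * Y1 / Y
    if (Y > 1) v <- v + d * (Y1 / Y) * (1 - Y1 / Y) * (Y - d) / (Y - 1)
  }
  stat <- oe^2 / v
  list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}
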