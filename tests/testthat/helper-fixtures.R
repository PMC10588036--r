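# shared fixture builders (everything generated in code; no data files)

make_cohort <- function(time, event, ...) {
  as_survival_cohort(data.frame(subject_id = seq_along(time),
                                time = time, event = event, ...))
}

# hand-built hazard_tree from a nodes table (members not needed for
# routing or summaries)
make_tree <- function(nodes, variables = unique(stats::na.omit(nodes$variable))) {
  structure(list(nodes = nodes, members = list(), params = tree_params(),
                 variables = variables, n = NA_integer_),
            class = "hazard_tree")
}

# fixture encoding the first levels seen in a peptide + miRNA risk tree:
# root on log natriuretic peptide at 6, the low side on the raw miRNA
# relative level at 1.5 (low peptide & high miRNA = lowest risk)
fig_tree <- function() {
  make_tree(data.frame(
    id = c(1L, 2L, 3L, 4L, 5L),
    depth = c(0L, 1L, 1L, 2L, 2L),
    parent = c(NA, 1L, 1L, 2L, 2L),
    terminal = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    variable = c("log_ntprobnp", "mir133a", NA, NA, NA),
    cutoff = c(6, 1.5, NA, NA, NA),
    n = NA_integer_, events = NA_integer_,
    log_hr = NA_real_, wald_z2 = NA_real_, p_value = NA_real_))
}

# small random survival fixture with mixed censoring
random_fixture <- function(n, seed, n_vars = 2, hazard = 0.3) {
  set.seed(seed)
  tev <- rexp(n, hazard)
  cen <- stats::runif(n, 0.5, 6)
  df <- data.frame(subject_id = seq_len(n),
                   time = pmin(tev, cen),
                   event = as.numeric(tev <= cen))
  for (k in seq_len(n_vars)) {
    df[[paste0("x", k)]] <- if (k %% 2 == 0) stats::rbinom(n, 1, 0.5)
    else stats::rnorm(n)
  }
  as_survival_cohort(df)
}

# independent brute-force Harrell c-index by full pair enumeration
cindex_oracle <- function(score, time, event) {
  conc <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # orient so a is the earlier observed time
      a <- i; b <- j
      if (time[j] < time[i]) { a <- j; b <- i }
      if (time[a] == time[b]) {
        # tied times: usable only when exactly one is an event
        if (event[a] + event[b] != 1) next
        if (event[b] == 1) { tmp <- a; a <- b; b <- tmp }
      } else if (event[a] != 1) next
      usable <- usable + 1
      if (score[a] > score[b]) conc <- conc + 1
      else if (score[a] == score[b]) conc <- conc + 0.5
    }
  }
  conc / usable
}

# independent brute-force best-split search: exhaustive midpoint cutoffs,
# univariate coxph per candidate, max Wald chi-square with the package's
# documented tie-break order
best_split_oracle <- function(cohort, variables, params) {
  best <- NULL
  for (vn in sort(variables)) {
    u <- sort(unique(cohort[[vn]]))
    if (length(u) < 2) next
    for (ct in (u[-1] + u[-length(u)]) / 2) {
      ind <- as.numeric(cohort[[vn]] > ct)
      nl <- sum(ind == 0); nr <- sum(ind == 1)
      el <- sum(cohort$event[ind == 0]); er <- sum(cohort$event[ind == 1])
      if (nl < params$min_node_n || nr < params$min_node_n ||
          el < params$min_node_events || er < params$min_node_events) next
      ft <- tryCatch(suppressWarnings(survival::coxph(
        survival::Surv(cohort$time, cohort$event) ~ ind, ties = "efron")),
        error = function(e) NULL)
      if (is.null(ft)) next
      beta <- unname(coef(ft)); se <- sqrt(ft$var[1, 1])
      if (!is.finite(beta) || abs(beta) > 15) next
      z2 <- (beta / se)^2
      p <- stats::pchisq(z2, 1, lower.tail = FALSE)
      if (p >= params$alpha_split) next
      cand <- list(variable = vn, cutoff = ct, wald_z2 = z2, p = p)
      if (is.null(best) || cand$wald_z2 > best$wald_z2 + 1e-12) best <- cand
    }
  }
  best
}
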