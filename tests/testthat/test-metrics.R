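test_that("incidence rate is events per 100 patient-years", {
  expect_equal(incidence_rate(5, 250), 2)
  expect_equal(incidence_rate(0, 100), 0)
  expect_error(incidence_rate(3, 0), "person_years")
  # exponential simulation: events / person-years estimates the hazard
  set.seed(1)
  n <- 5000; h <- 0.1
  t <- rexp(n, h); cen <- runif(n, 0.5, 5.5)
  time <- pmin(t, cen); ev <- as.numeric(t <= cen)
  ir <- incidence_rate(sum(ev), sum(time))
  se <- 100 * sqrt(sum(ev)) / sum(time)
  expect_lt(abs(ir - 10), 3 * se)
})

test_that("node summaries conserve counts and recover planted ratios", {
  # hand-built depth-2 tree with 4 leaves and hazards 0.05/0.15/0.35/0.7
  tr <- make_tree(data.frame(
    id = 1:7, depth = c(0, 1, 1, 2, 2, 2, 2),
    parent = c(NA, 1, 1, 2, 2, 3, 3),
    terminal = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    variable = c("u1", "u2", "u2", NA, NA, NA, NA),
    cutoff = c(0, 0, 0, NA, NA, NA, NA),
    n = NA_integer_, events = NA_integer_,
    log_hr = NA_real_, wald_z2 = NA_real_, p_value = NA_real_))
  set.seed(2)
  n <- 2000
  u1 <- rnorm(n); u2 <- rnorm(n)
  hz <- ifelse(u1 <= 0, ifelse(u2 <= 0, 0.05, 0.15),
               ifelse(u2 <= 0, 0.35, 0.7))
  t <- rexp(n, hz)
  cen <- runif(n, 40, 60)  # near-complete follow-up for the recovery check
  co <- make_cohort(pmin(t, cen), as.numeric(t <= cen), u1 = u1, u2 = u2)
  ns <- node_summaries(tr, co)
  expect_equal(sum(ns$n), n)
  expect_equal(sum(ns$events), sum(co$event))
  expect_equal(ns$node[ns$reference], 4)      # lowest-hazard leaf
  expect_equal(ns$rank[ns$node == 4], 1L)
  expect_equal(ns$hr[ns$reference], 1)
  planted <- c(1, 3, 7, 14)
  expect_true(all(abs(ns$hr / planted - 1) <= 0.25))
  # single-node tree
  tr1 <- make_tree(data.frame(id = 1L, depth = 0L, parent = NA_integer_,
                              terminal = TRUE, variable = NA_character_,
                              cutoff = NA_real_, n = NA_integer_,
                              events = NA_integer_, log_hr = NA_real_,
                              wald_z2 = NA_real_, p_value = NA_real_))
  ns1 <- node_summaries(tr1, co)
  expect_equal(nrow(ns1), 1)
  expect_equal(ns1$hr, 1)
  expect_equal(ns1$rank, 1L)
})

test_that("IRV evaluates the worked example and detects homogeneity", {
  # two nodes of 50: A 5 events / 250 py (IR 2), B 15 / 250 (IR 6),
  # overall 20 / 500 (IR 4)
  expect_equal(irv(node_n = c(50, 50), node_ir = c(2, 6), overall_ir = 4,
                   N = 100), 2)
  expect_equal(irv(node_n = c(30, 70), node_ir = c(5, 5), overall_ir = 5,
                   N = 100), 0)
  # invariant under node relabeling
  expect_equal(irv(node_n = c(70, 30), node_ir = c(5, 2), overall_ir = 4.1,
                   N = 100),
               irv(node_n = c(30, 70), node_ir = c(2, 5), overall_ir = 4.1,
                   N = 100))
  expect_error(irv(node_n = c(10, 10), node_ir = c(1, 2), overall_ir = 1,
                   N = 30), "equal N")
  expect_error(irv(node_n = 0, node_ir = 1, overall_ir = 1, N = 0), "N must")
  # moving events to the high-IR node (fixed person-years) raises IRV
  lo <- irv(node_n = c(50, 50), node_ir = c(3, 5), overall_ir = 4, N = 100)
  hi <- irv(node_n = c(50, 50), node_ir = c(2, 6), overall_ir = 4, N = 100)
  expect_gt(hi, lo)
})

test_that("Kaplan-Meier steps match hand-computed product limits", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  kmc <- km_curve(c(1, 2, 3, 4), c(0, 0, 0, 0))
  expect_true(all(kmc$surv == 1))
  # interleaved censoring: events at 1 and 3, censorings at 2 and 4
  km2 <- km_curve(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km2$surv[km2$time == 1], 0.75)
  expect_equal(km2$surv[km2$time == 3], 0.75 * 0.5)
  # no censoring: KM equals the empirical survival function
  set.seed(3)
  t <- rexp(30)
  km3 <- km_curve(t, rep(1, 30))
  expect_equal(km3$surv, 1 - seq_len(30) / 30)
})

test_that("cumulative/dynamic AUC matches pair enumeration without censoring", {
  set.seed(4)
  n <- 150
  t <- rexp(n, 0.4) + 0.01
  co <- make_cohort(t, 1)
  m <- sample(1:6, n, replace = TRUE)  # ordinal marker with ties
  for (tt in c(1, 2, 3)) {
    case <- t <= tt; ctrl <- t > tt
    oracle <- mean(outer(m[case], m[ctrl],
                         function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(cd_auc(m, co, tt, weighted = FALSE), oracle)
    expect_equal(cd_auc(m, co, tt, weighted = TRUE), oracle)  # G == 1
  }
  # perfect marker
  expect_equal(cd_auc(-t, co, 2), 1)
  expect_error(cd_auc(m, co, max(t) + 1), "no cases or no controls")
})

test_that("cumulative/dynamic AUC is near 0.5 for an uninformative marker", {
  mid <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 1000
    t <- rexp(n, 0.3); cen <- runif(n, 0.5, 6)
    co <- make_cohort(pmin(t, cen), as.numeric(t <= cen))
    cd_auc(rnorm(n), co, 2)
  }, numeric(1))
  expect_gte(mean(mid >= 0.45 & mid <= 0.55), 0.9)
})

test_that("integrated AUC is a convex combination with sane invariances", {
  set.seed(5)
  n <- 300
  t <- rexp(n, 0.4); cen <- runif(n, 0.5, 6)
  co <- make_cohort(pmin(t, cen), as.numeric(t <= cen))
  m <- rnorm(n) - 0.8 * log(t + 0.05)
  ia <- iauc(m, co, t0 = 0.25, t1 = 5)
  expect_equal(sum(ia$grid$weight), 1)
  expect_gte(ia$iauc, min(ia$grid$auc))
  expect_lte(ia$iauc, max(ia$grid$auc))
  # invariant under strictly increasing marker transforms
  expect_equal(iauc(exp(m), co)$iauc, ia$iauc)
  # perfect marker with no censoring
  co2 <- make_cohort(t, 1)
  expect_equal(iauc(-t, co2)$iauc, 1)
  expect_error(iauc(m, co, t0 = 40, t1 = 50), "no events|t0 < t1")
})

test_that("ordinal node risk yields a stable iAUC across windows", {
  g <- generate_cohort(serve_like_spec(600), seed = 6)
  truth_rank <- rank(g$truth$node_hazards)
  node <- hrcart:::route_truth_all(g$truth, as.data.frame(g$cohort))
  marker <- unname(truth_rank[as.character(node)])
  vals <- c(iauc(marker, g$cohort, 0.25, 5)$iauc,
            iauc(marker, g$cohort, 0.5, 4)$iauc,
            iauc(marker, g$cohort, 1, 5)$iauc)
  expect_lte(diff(range(vals)), 0.05)
  expect_true(all(vals > 0.5))
})

test_that("risk bands reproduce the low/intermediate/high/very-high pattern", {
  s <- data.frame(node = 1:6, hr = c(1, 2.0, 4.0, 6.1, 7.1, 12.0),
                  reference = c(TRUE, rep(FALSE, 5)))
  b <- risk_bands(s)
  expect_identical(as.character(b$band),
                   c("low", "intermediate", "intermediate", "high", "high",
                     "very high"))
  # all HRs under the first edge -> all low
  s2 <- data.frame(node = 1:3, hr = c(1, 1.2, 1.9),
                   reference = c(TRUE, FALSE, FALSE))
  expect_true(all(risk_bands(s2)$band == "low"))
  # band assignment is monotone in HR
  s3 <- data.frame(node = 1:5, hr = sort(runif(5, 0.5, 15)),
                   reference = c(TRUE, rep(FALSE, 4)))
  expect_false(is.unsorted(risk_bands(s3)$band))
})
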