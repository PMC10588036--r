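test_that("split enumeration covers midpoints and respects admissibility", {
  co <- random_fixture(100, seed = 1, n_vars = 2)  # x1 continuous, x2 binary
  pars <- tree_params(min_node_n = 5, min_node_events = 1)
  e2 <- enumerate_splits(co, "x2", pars)
  expect_equal(nrow(e2), 1)            # binary -> one candidate
  expect_equal(e2$cutoff, 0.5)
  e1 <- enumerate_splits(co, "x1", pars)
  k <- length(unique(co$x1))
  expect_equal(nrow(e1), k - 1)        # k distinct values -> k-1 candidates
  expect_equal(e1$n_left + e1$n_right, rep(100L, k - 1))
  # constant variable -> empty candidate list
  co$xc <- 7
  expect_equal(nrow(enumerate_splits(co, "xc", pars)), 0)
  # thinned candidates are a subset of the exhaustive ones
  thin <- enumerate_splits(co, "x1", tree_params(min_node_n = 5,
                                                 min_node_events = 1,
                                                 max_cutpoints = 10))
  expect_lte(nrow(thin), 10)
  expect_true(all(thin$cutoff %in% e1$cutoff))
  adm_thin <- thin$cutoff[thin$admissible]
  adm_full <- e1$cutoff[e1$admissible]
  expect_true(all(adm_thin %in% adm_full))
})

test_that("split scoring returns the univariate Cox Wald statistic", {
  co <- random_fixture(200, seed = 2, n_vars = 1)
  sc <- score_split(co, "x1", median(co$x1))
  ref <- survival::coxph(survival::Surv(time, event) ~ I(x1 > median(x1)),
                         data = as.data.frame(co), ties = "efron")
  expect_equal(sc$log_hr, unname(coef(ref)), tolerance = 1e-6)
  z2 <- (coef(ref) / sqrt(ref$var[1, 1]))^2
  expect_equal(sc$wald_z2, unname(z2), tolerance = 1e-6)
  expect_equal(sc$p_value, unname(pchisq(z2, 1, lower.tail = FALSE)),
               tolerance = 1e-8)
  # degenerate: everyone on one side
  bad <- score_split(co, "x1", max(co$x1) + 1)
  expect_false(bad$admissible)
})

test_that("split scoring is calibrated under the null", {
  below <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 400
    t <- rexp(n, 0.3); cen <- runif(n, 0.5, 6)
    co <- make_cohort(pmin(t, cen), as.numeric(t <= cen),
                      x = rbinom(n, 1, 0.5))
    score_split(co, "x", 0.5)$wald_z2 < qchisq(0.95, 1)
  }, logical(1))
  expect_gte(mean(below), 0.88)
  expect_lte(mean(below), 0.995)
})

test_that("a planted hazard-ratio-3 split wins the candidate search", {
  wins <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 400
    x <- rbinom(n, 1, 0.5)
    noise <- rnorm(n)
    t <- rexp(n, 0.15 * 3^x)
    cen <- runif(n, 0.5, 6)
    co <- make_cohort(pmin(t, cen), as.numeric(t <= cen),
                      x = x, noise = noise)
    bs <- best_split(co, c("x", "noise"),
                     tree_params(min_node_n = 30, min_node_events = 5))
    !is.null(bs) && bs$variable == "x"
  }, logical(1))
  expect_gte(mean(wins), 0.86)
})

test_that("best split equals exhaustive brute force on small fixtures", {
  pars <- tree_params(min_node_n = 8, min_node_events = 2)
  for (s in 1:8) {
    co <- random_fixture(60, seed = 100 + s, n_vars = 3)
    got <- best_split(co, c("x1", "x2", "x3"), pars)
    want <- best_split_oracle(co, c("x1", "x2", "x3"), pars)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$variable, want$variable)
      expect_equal(got$cutoff, want$cutoff)
      expect_equal(got$wald_z2, want$wald_z2, tolerance = 1e-6)
    }
  }
})

test_that("trees are invariant to row order and partition the cohort", {
  g <- generate_cohort(two_level_spec(400), two_level_truth(), seed = 3)
  vars <- c("age", "diabetes", "log_ntprobnp", "log_mir133a")
  pars <- tree_params(max_depth = 2, max_cutpoints = 40)
  tr <- grow_tree(g$cohort, vars, pars)
  set.seed(4)
  perm <- sample(nrow(g$cohort))
  co_perm <- as_survival_cohort(as.data.frame(g$cohort)[perm, ])
  tr2 <- grow_tree(co_perm, vars, pars)
  expect_equal(tr$nodes, tr2$nodes)
  # terminal members partition the cohort
  term <- terminal_nodes(tr)
  mem <- unlist(tr$members[as.character(term)])
  expect_setequal(mem, g$cohort$subject_id)
  expect_equal(length(mem), nrow(g$cohort))
  expect_equal(sum(tr$nodes$n[tr$nodes$terminal]), nrow(g$cohort))
  # every training subject routes to the node whose member set contains it
  routed <- assign_node(tr, as.data.frame(g$cohort))
  for (id in term) {
    expect_setequal(g$cohort$subject_id[routed == id],
                    tr$members[[as.character(id)]])
  }
})

test_that("stopping rules bound depth and tighten with smaller alpha", {
  g <- generate_cohort(serve_like_spec(400), seed = 5)
  vars <- c("age", "diabetes", "sixmwd", "log_ntprobnp", "log_mir133a")
  t3 <- grow_tree(g$cohort, vars, tree_params(max_depth = 3,
                                              max_cutpoints = 25))
  expect_lte(sum(t3$nodes$terminal), 8)
  expect_lte(max(t3$nodes$depth), 3)
  t_strict <- grow_tree(g$cohort, vars,
                        tree_params(max_depth = 3, max_cutpoints = 25,
                                    alpha_split = 1e-6))
  expect_lte(max(t_strict$nodes$depth), max(t3$nodes$depth))
  # cohort smaller than 2 * min_node_n -> root-only with warning
  tiny <- as_survival_cohort(as.data.frame(g$cohort)[1:40, ])
  expect_warning(t0 <- grow_tree(tiny, vars, tree_params(min_node_n = 30)),
                 "root-only")
  expect_equal(sum(t0$nodes$terminal), 1)
})

test_that("routing follows cutoffs with <= going left and flags missing", {
  tr <- fig_tree()
  # low peptide, high miRNA -> lowest-risk node (right child of node 2)
  expect_equal(assign_node(tr, data.frame(log_ntprobnp = 5.5,
                                          mir133a = 1.6)), 5L)
  expect_equal(assign_node(tr, data.frame(log_ntprobnp = 5.5,
                                          mir133a = 1.2)), 4L)
  expect_equal(assign_node(tr, data.frame(log_ntprobnp = 6.4,
                                          mir133a = 1.6)), 3L)
  # boundary values go left
  expect_equal(assign_node(tr, data.frame(log_ntprobnp = 6,
                                          mir133a = 1.5)), 4L)
  expect_warning(out <- assign_node(tr, data.frame(log_ntprobnp = 5.5,
                                                   mir133a = NA)),
                 "unassignable")
  expect_true(is.na(out))
})

test_that("bagging reports frequencies, retention and OOB error deterministically", {
  g <- generate_cohort(two_level_spec(300), two_level_truth(), seed = 6)
  vars <- c("age", "diabetes", "log_ntprobnp", "log_mir133a")
  pars <- tree_params(max_depth = 2, max_cutpoints = 20)
  bg <- bagging_select(g$cohort, vars, B = 15, params = pars, seed = 9)
  expect_true(all(bg$frequency >= 0 & bg$frequency <= 1))
  expect_true(all(bg$retained %in% vars))
  expect_true(all(bg$frequency[bg$retained] >= bg$retention))
  bg2 <- bagging_select(g$cohort, vars, B = 15, params = pars, seed = 9)
  expect_identical(bg$frequency, bg2$frequency)
  expect_identical(bg$oob_iauc, bg2$oob_iauc)
  # informative variable selected more often than pure noise
  expect_gt(bg$frequency[["log_ntprobnp"]], bg$frequency[["age"]])
  expect_true(is.finite(bg$oob_iauc_mean))
})
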