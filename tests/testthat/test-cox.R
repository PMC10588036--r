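test_that("symmetric data give a zero coefficient", {
  set.seed(1)
  x <- rnorm(40)
  t <- rexp(40, 0.5)
  co <- make_cohort(time = c(t, t), event = 1, x = c(x, -x))
  ft <- fit_cox(co, "x")
  expect_lt(abs(ft$coefficients[["x"]]), 1e-6)
  expect_true(ft$converged)
})

test_that("coefficient equals the grid-search partial-likelihood maximizer", {
  # 4 subjects, all events, no ties: hand-written partial likelihood
  t <- c(1, 2, 3, 4); d <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  pl <- function(beta) {
    # risk sets at each event time, in time order
    sum(vapply(1:4, function(i) {
      rs <- which(t >= t[i])
      beta * x[i] - log(sum(exp(beta * x[rs])))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  beta_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  ft <- fit_cox(make_cohort(t, d, x = x), "x")
  expect_lt(abs(ft$coefficients[["x"]] - beta_grid), 1e-3)
})

test_that("a true hazard ratio of 3 is recovered at n = 2000", {
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rbinom(2000, 1, 0.5)
    t <- rexp(2000, 0.1 * 3^x)
    ft <- fit_cox(make_cohort(t, 1, x = x), "x")
    hr <- exp(ft$coefficients[["x"]])
    hr >= 2.7 && hr <= 3.3
  }, logical(1))
  expect_gte(mean(inside), 0.93)
})

test_that("degenerate designs are rejected or flagged", {
  co <- random_fixture(60, seed = 2, n_vars = 2)
  co$x3 <- 2 * co$x1
  expect_error(fit_cox(co, c("x1", "x3")), "collinear")
  co$xc <- 1
  expect_error(fit_cox(co, "xc"), "constant")
  expect_error(fit_cox(make_cohort(c(1, 2), c(1, 0), x = c(1, 0)), "x"),
               ">= 2 events")
  # perfect separation: earliest events all in one group -> flagged
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  sep <- make_cohort(t, 1, x = rep(c(1, 0), each = 4))
  ft <- fit_cox(sep, "x")
  expect_false(ft$converged)
})

test_that("Efron and Breslow fits coincide without ties", {
  co <- random_fixture(80, seed = 5)
  fe <- fit_cox(co, c("x1", "x2"))
  fb <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                        data = as.data.frame(co), ties = "breslow")
  expect_lt(max(abs(fe$coefficients - coef(fb))), 1e-6)
})

test_that("miRNA association adjusts through the nested models", {
  expect_identical(model_spec(1), c("asv", "age", "male"))
  expect_true(all(model_spec(1) %in% model_spec(2)))
  expect_true(all(model_spec(2) %in% model_spec(3)))
  # miRNA generated as a noisy proxy of log NT-proBNP: adjusting for the
  # peptide (model 3) attenuates the miRNA association seen in model 1
  set.seed(6)
  n <- 2000
  lognt <- rnorm(n, 7.2, 1.1)
  mir <- -0.8 * lognt + rnorm(n, 0, 0.6)
  t <- rexp(n, exp(-4 + 0.6 * lognt))
  cen <- runif(n, 0.5, 5.5)
  co <- make_cohort(pmin(t, cen), as.numeric(t <= cen),
                    asv = rbinom(n, 1, .5), age = rnorm(n, 70, 9),
                    male = rbinom(n, 1, .9), sbp_lt120 = rbinom(n, 1, .4),
                    diabetes = rbinom(n, 1, .4), diuretic = rbinom(n, 1, .85),
                    afib = rbinom(n, 1, .3), cardiac_device = rbinom(n, 1, .5),
                    sixmwd = rnorm(n, 330, 120), log_ntprobnp = lognt,
                    log_mir133a = mir)
  co$arm <- ifelse(co$asv == 1, "ASV", "control")
  m1 <- mirna_association(co, "log_mir133a", model = 1)
  m3 <- mirna_association(co, "log_mir133a", model = 3)
  b1 <- m1$hr[m1$hr$covariate == "log_mir133a", ]
  b3 <- m3$hr[m3$hr$covariate == "log_mir133a", ]
  expect_lt(b1$hr, 1)           # inverse association before adjustment
  expect_lt(b1$p, 0.001)
  expect_lt(abs(log(b3$hr)), abs(log(b1$hr)))  # attenuated by the peptide
  # subgroup fit drops the arm covariate and filters rows
  ms <- mirna_association(co, "log_mir133a", model = 1, subgroup = "ASV")
  expect_false("asv" %in% ms$hr$covariate)
  expect_equal(ms$n, sum(co$asv == 1))
})

test_that("c-index matches exhaustive pair enumeration and its invariances", {
  co <- make_cohort(time = c(1, 2, 2, 3, 4, 5, 6, 7),
                    event = c(1, 0, 1, 1, 0, 1, 0, 0))
  set.seed(7)
  sc <- c(5, 3, 3, 4, 1, 2, 2, 0)
  expect_equal(harrell_cindex(sc, co),
               cindex_oracle(sc, co$time, co$event))
  # larger random check incl. score ties
  co2 <- random_fixture(120, seed = 8)
  sc2 <- round(rnorm(120), 1)
  expect_equal(harrell_cindex(sc2, co2),
               cindex_oracle(sc2, co2$time, co2$event))
  # independent library cross-check
  cc <- survival::concordance(survival::Surv(co2$time, co2$event) ~ sc2,
                              reverse = TRUE)
  expect_equal(harrell_cindex(sc2, co2), unname(cc$concordance))
  # perfect and uninformative scores
  co3 <- make_cohort(time = 1:10, event = 1)
  expect_equal(harrell_cindex(-(1:10), co3), 1)
  expect_equal(harrell_cindex(rep(1, 10), co3), 0.5)
  # invariance under strictly increasing transform
  expect_equal(harrell_cindex(exp(sc2), co2), harrell_cindex(sc2, co2))
  expect_error(harrell_cindex(1:3, make_cohort(1:3, 0)), "no usable pairs")
})

test_that("delta c-index behaves at the null and under a real signal", {
  co <- random_fixture(150, seed = 10)
  sc <- rnorm(150)
  d0 <- delta_cindex(sc, sc, co, n_boot = 120, seed = 1)
  expect_equal(d0$delta, 0)
  expect_true(d0$ci[1] <= 0 && d0$ci[2] >= 0)
  d0b <- delta_cindex(sc, sc, co, n_boot = 120, seed = 1)
  expect_identical(d0$ci, d0b$ci)  # seed determinism
  # true linear predictor added to noise
  set.seed(11)
  n <- 600
  x <- rnorm(n)
  t <- rexp(n, 0.2 * exp(0.9 * x))
  cen <- runif(n, 0.5, 6)
  co2 <- make_cohort(pmin(t, cen), as.numeric(t <= cen))
  d1 <- delta_cindex(rnorm(n), x, co2, n_boot = 150, seed = 2)
  expect_gt(d1$delta, 0)
  expect_gt(d1$ci[1], 0)
})

test_that("cNRI and IDI vanish for identical models and flip on swap", {
  g <- generate_cohort(serve_like_spec(300), seed = 12)
  co <- g$cohort
  r0 <- cnri_idi(co, c("age", "male"), c("age", "male"),
                 n_perturb = 30, seed = 3)
  expect_equal(r0$cnri, 0)
  expect_equal(r0$idi, 0)
  ra <- cnri_idi(co, c("age"), c("age", "log_ntprobnp"),
                 n_perturb = 30, seed = 4)
  rb <- cnri_idi(co, c("age", "log_ntprobnp"), c("age"),
                 n_perturb = 30, seed = 4)
  expect_equal(ra$cnri, -rb$cnri, tolerance = 1e-10)
  expect_equal(ra$idi, -rb$idi, tolerance = 1e-10)
  expect_error(cnri_idi(co, "age", c("age", "male"), horizon = 99,
                        n_perturb = 10, seed = 1), "horizon")
})

test_that("adding the true log-hazard term yields positive cNRI and IDI", {
  set.seed(13)
  n <- 1000
  x <- rnorm(n); z <- rnorm(n)
  t <- rexp(n, 0.15 * exp(0.9 * x))
  cen <- runif(n, 0.5, 6)
  co <- make_cohort(pmin(t, cen), as.numeric(t <= cen), z = z, x = x)
  r <- cnri_idi(co, "z", c("z", "x"), horizon = 2, n_perturb = 150, seed = 5)
  expect_gt(r$cnri, 0)
  expect_gt(r$cnri_ci[1], 0)
  expect_gt(r$idi, 0)
  expect_gt(r$idi_ci[1], 0)
})
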