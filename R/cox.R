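#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron-tie-corrected partial likelihood (via
#' \code{survival::coxph}) on complete cases, returning coefficients,
#' hazard ratios with Wald 95% CIs, per-coefficient Wald p-values and the
#' log partial likelihood. Exactly collinear covariates raise an error
#' naming the offending pair; monotone-likelihood (separation) fits are
#' returned flagged non-convergent rather than silently.
#'
#' @param cohort a `survival_cohort`.
#' @param covariates character vector of numeric covariate columns.
#' @param weights optional case weights (used by perturbation resampling).
#' @return object of class `cox_model_fit`: list with `coefficients`,
#'   `vcov`, `hr` (data.frame with `hr`, `lo`, `hi`, `p`), `n`, `events`,
#'   `loglik`, `ties`, `converged`, and the underlying `fit`.
#' @export
fit_cox <- function(cohort, covariates, weights = NULL) {
  stopifnot(length(covariates) >= 1)
  absent <- setdiff(covariates, names(cohort))
  if (length(absent) > 0) {
    stop("covariate(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  dat <- as.data.frame(cohort)[, c("time", "event", covariates)]
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  if (sum(dat$event) < 2) stop("need >= 2 events", call. = FALSE)
  if (length(covariates) > 1) {
    cm <- suppressWarnings(stats::cor(dat[, covariates, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (any(abs(cm) > 1 - 1e-12)) {
      idx <- which(abs(cm) > 1 - 1e-12, arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", covariates[idx[1]], " and ",
           covariates[idx[2]], call. = FALSE)
    }
  }
  const <- vapply(covariates, function(v) stats::var(dat[[v]]) == 0,
                  logical(1))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(covariates[const], collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  w <- if (is.null(weights)) NULL else weights[cc]
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron", weights = w,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  converged <- all(is.finite(beta)) && all(abs(beta) < 15)
  hr <- data.frame(covariate = covariates,
                   coef = unname(beta),
                   hr = exp(unname(beta)),
                   lo = exp(unname(beta) - 1.96 * se),
                   hi = exp(unname(beta) + 1.96 * se),
                   p = 2 * stats::pnorm(-abs(unname(beta) / se)))
  structure(list(coefficients = beta, vcov = stats::vcov(fit), hr = hr,
                 n = fit$n, events = fit$nevent,
                 loglik = fit$loglik[length(fit$loglik)],
                 ties = "efron", converged = converged, fit = fit,
                 covariates = covariates),
            class = "cox_model_fit")
}

#' @export
print.cox_model_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Efron ties): n = %d, events = %d%s\n",
              x$n, x$events,
              if (!x$converged) " [NOT CONVERGED: possible separation]"
              else ""))
  df <- x$hr
  df[, -1] <- lapply(df[, -1], function(v) signif(v, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Nested clinical adjustment models
#'
#' The three nested clinical models used for incremental-value analysis:
#' model 1 = treatment arm (ASV), age, sex; model 2 adds the SBP < 120
#' mmHg flag, diabetes, diuretic use, atrial fibrillation, cardiac device
#' and 6-min walk distance; model 3 adds log(NT-proBNP).
#'
#' @param model 0 (empty, unadjusted), 1, 2 or 3.
#' @return character vector of covariate names.
#' @export
model_spec <- function(model) {
  m1 <- c("asv", "age", "male")
  m2 <- c(m1, "sbp_lt120", "diabetes", "diuretic", "afib",
          "cardiac_device", "sixmwd")
  m3 <- c(m2, "log_ntprobnp")
  switch(as.character(model),
         "0" = character(0), "1" = m1, "2" = m2, "3" = m3,
         stop("model must be 0, 1, 2 or 3", call. = FALSE))
}

#' Association of a miRNA with the outcome, adjusted per nested model
#'
#' Fits the Cox model of the (log-scale) miRNA level plus the covariates of
#' the requested nested clinical model, optionally within one treatment
#' arm. The hazard ratio is per one-unit increase on the analysis scale
#' (log relative units by default; `per_sd` rescales to per-SD).
#'
#' @param cohort a `survival_cohort`.
#' @param mirna_name column holding log-transformed miRNA levels.
#' @param model 0-3, see [model_spec()].
#' @param subgroup optional value of `arm` to filter on ("control"/"ASV").
#' @param per_sd if TRUE, standardize the miRNA column first.
#' @return a `cox_model_fit`; the miRNA row of `$hr` carries the marker HR.
#' @export
mirna_association <- function(cohort, mirna_name, model = 0,
                              subgroup = NULL, per_sd = FALSE) {
  dat <- as.data.frame(cohort)
  if (!is.null(subgroup)) dat <- dat[dat$arm == subgroup, , drop = FALSE]
  if (per_sd) {
    dat[[mirna_name]] <- dat[[mirna_name]] /
      stats::sd(dat[[mirna_name]], na.rm = TRUE)
  }
  covs <- model_spec(model)
  covs <- setdiff(covs, if (!is.null(subgroup)) "asv" else character(0))
  fit_cox(as_survival_cohort(dat), c(mirna_name, covs))
}

#' Harrell's concordance index
#'
#' Direct pair-counting implementation: a pair is usable when the subject
#' with the shorter observed time had the event (censored-censored pairs
#' and pairs where only the longer time is an event are unusable; tied
#' event times with both events are unusable). A usable pair is concordant
#' when the earlier-event subject has the higher risk score; score ties
#' count 1/2.
#'
#' @param risk_scores numeric vector, higher = riskier.
#' @param cohort a `survival_cohort` aligned with `risk_scores`.
#' @return c-index in [0, 1].
#' @export
harrell_cindex <- function(risk_scores, cohort) {
  stopifnot(length(risk_scores) == nrow(cohort))
  t <- cohort$time; d <- cohort$event; s <- risk_scores
  n <- length(t)
  conc <- 0; usable <- 0
  # vectorized over the event subjects
  for (i in which(d == 1)) {
    cmp <- (t > t[i]) | (t == t[i] & d == 0)
    cmp[i] <- FALSE
    usable <- usable + sum(cmp)
    conc <- conc + sum(s[i] > s[cmp]) + 0.5 * sum(s[i] == s[cmp])
  }
  if (usable == 0) stop("no usable pairs: c-index undefined", call. = FALSE)
  conc / usable
}

#' Improvement in c-index with a paired bootstrap CI
#'
#' Point estimate `c(augmented) - c(base)` plus a percentile CI and
#' two-sided p-value from paired subject-level bootstrap resampling.
#'
#' @param base_scores,augmented_scores risk scores on the same subjects.
#' @param cohort a `survival_cohort`.
#' @param n_boot bootstrap replicates (default 300; < 100 warns).
#' @param seed integer seed (mandatory).
#' @return list with `delta`, `ci` (length 2), `p`, `n_boot`, `seed`.
#' @export
delta_cindex <- function(base_scores, augmented_scores, cohort,
                         n_boot = 300, seed) {
  stopifnot(length(base_scores) == nrow(cohort),
            length(augmented_scores) == nrow(cohort))
  if (n_boot < 100) warning("n_boot < 100: CI will be unstable",
                            call. = FALSE)
  point <- harrell_cindex(augmented_scores, cohort) -
    harrell_cindex(base_scores, cohort)
  set.seed(seed)
  n <- nrow(cohort)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    co <- as_survival_cohort(within(as.data.frame(cohort)[idx, ],
                                    subject_id <- seq_len(n)))
    tryCatch(harrell_cindex(augmented_scores[idx], co) -
               harrell_cindex(base_scores[idx], co),
             error = function(e) NA_real_)
  }, numeric(1))
  reps <- reps[is.finite(reps)]
  ci <- unname(stats::quantile(reps, c(.025, .975), type = 7))
  se <- stats::sd(reps)
  p <- if (se > 0) 2 * stats::pnorm(-abs(point / se)) else
    as.numeric(point == 0)
  list(delta = point, ci = ci, p = p, n_boot = n_boot, seed = seed)
}

# Breslow-baseline predicted event probability at a horizon:
# P(T <= horizon | x) = 1 - exp(-H0(horizon) * exp(lp)), uncentered
predicted_risk <- function(fit, cohort, horizon) {
  bh <- survival::basehaz(fit$fit, centered = FALSE)
  keep <- bh$time <= horizon
  h0 <- if (any(keep)) max(bh$hazard[keep]) else 0
  lp <- stats::predict(fit$fit, newdata = as.data.frame(cohort),
                       type = "lp", reference = "zero")
  1 - exp(-h0 * exp(unname(lp)))
}

# censoring-distribution KM evaluated at arbitrary times.
# left = TRUE gives the left limit G(t-). Optional weights.
censoring_km <- function(time, event, at, left = FALSE, weights = NULL) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1,
                          weights = weights, se.fit = FALSE)
  st <- sf$time; ss <- sf$surv
  eval1 <- function(tt) {
    keep <- if (left) st < tt else st <= tt
    if (!any(keep)) 1 else ss[max(which(keep))]
  }
  vapply(at, eval1, numeric(1))
}

# IPCW case/control weights at a horizon; returns list(case, control, w)
ipcw_weights <- function(time, event, horizon, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(time))
  g_tm <- censoring_km(time, event, time, left = TRUE, weights = weights)
  g_h <- censoring_km(time, event, horizon, left = FALSE, weights = weights)
  case <- time <= horizon & event == 1
  control <- time > horizon
  w_case <- ifelse(case & g_tm > 0, weights / g_tm, 0)
  w_ctrl <- ifelse(control & g_h > 0, weights / g_h, 0)
  list(case = case, control = control, w_case = w_case, w_ctrl = w_ctrl)
}

# core cNRI/IDI estimator given predicted risks and IPCW weights
nri_idi_point <- function(p_base, p_aug, ipcw) {
  sgn <- sign(p_aug - p_base)
  wc <- ipcw$w_case; wn <- ipcw$w_ctrl
  if (sum(wc) == 0 || sum(wn) == 0) {
    stop("no cases or no controls at the horizon", call. = FALSE)
  }
  cnri <- sum(wc * sgn) / sum(wc) - sum(wn * sgn) / sum(wn)
  idi <- (sum(wc * p_aug) / sum(wc) - sum(wn * p_aug) / sum(wn)) -
    (sum(wc * p_base) / sum(wc) - sum(wn * p_base) / sum(wn))
  c(cnri = cnri, idi = idi)
}

#' Continuous NRI and IDI for survival outcomes at a fixed horizon
#'
#' Incremental value of the augmented over the base Cox model at time
#' `horizon`: predicted event probabilities at the horizon come from each
#' model's Breslow baseline hazard; case/control status at the horizon is
#' weighted by inverse-probability-of-censoring (censoring-distribution
#' Kaplan-Meier) weights. The continuous NRI is the difference between
#' cases and controls in the IPCW mean sign of the risk change (range
#' [-2, 2]); the IDI is the change in discrimination slope (mean case risk
#' minus mean control risk). Confidence intervals and p-values come from
#' perturbation resampling: each replicate refits both models and the
#' censoring KM under i.i.d. exponential(1) subject weights.
#'
#' @param cohort a `survival_cohort`.
#' @param base_covariates,augmented_covariates covariate sets of the nested
#'   models (base must be a subset of augmented); fitted on common
#'   complete cases.
#' @param horizon prediction horizon in years (default 2).
#' @param n_perturb perturbation replicates (default 300).
#' @param seed integer seed (mandatory).
#' @return object of class `reclassification_result`: list with `horizon`,
#'   `cnri`, `cnri_ci`, `cnri_p`, `idi`, `idi_ci`, `idi_p`, `n`, `events`,
#'   `n_perturb`, `seed`.
#' @export
cnri_idi <- function(cohort, base_covariates, augmented_covariates,
                     horizon = 2, n_perturb = 300, seed) {
  dat <- as.data.frame(cohort)
  use <- stats::complete.cases(
    dat[, c("time", "event", union(base_covariates, augmented_covariates)),
        drop = FALSE])
  dat <- dat[use, , drop = FALSE]
  if (max(dat$time) < horizon) {
    stop("horizon beyond last observed time", call. = FALSE)
  }
  co <- as_survival_cohort(dat)
  fb <- fit_cox(co, base_covariates)
  fa <- fit_cox(co, augmented_covariates)
  p_base <- predicted_risk(fb, co, horizon)
  p_aug <- predicted_risk(fa, co, horizon)
  ipcw <- ipcw_weights(dat$time, dat$event, horizon)
  point <- nri_idi_point(p_base, p_aug, ipcw)

  set.seed(seed)
  n <- nrow(dat)
  reps <- matrix(NA_real_, n_perturb, 2)
  for (b in seq_len(n_perturb)) {
    w <- stats::rexp(n)
    est <- tryCatch({
      fbw <- fit_cox(co, base_covariates, weights = w)
      faw <- fit_cox(co, augmented_covariates, weights = w)
      ip <- ipcw_weights(dat$time, dat$event, horizon, weights = w)
      nri_idi_point(predicted_risk(fbw, co, horizon),
                    predicted_risk(faw, co, horizon), ip)
    }, error = function(e) c(NA_real_, NA_real_))
    reps[b, ] <- est
  }
  ok <- is.finite(reps[, 1]) & is.finite(reps[, 2])
  reps <- reps[ok, , drop = FALSE]
  ci <- apply(reps, 2, stats::quantile, probs = c(.025, .975), type = 7)
  sds <- apply(reps, 2, stats::sd)
  pv <- ifelse(sds > 0, 2 * stats::pnorm(-abs(point / sds)),
               as.numeric(point == 0))
  structure(list(horizon = horizon,
                 cnri = unname(point["cnri"]), cnri_ci = unname(ci[, 1]),
                 cnri_p = unname(pv[1]),
                 idi = unname(point["idi"]), idi_ci = unname(ci[, 2]),
                 idi_p = unname(pv[2]),
                 n = nrow(dat), events = sum(dat$event),
                 n_perturb = n_perturb, seed = seed),
            class = "reclassification_result")
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat(sprintf("Reclassification at %.3g years (n = %d, events = %d):\n",
              x$horizon, x$n, x$events))
  cat(sprintf("  cNRI %.3f (%.3f; %.3f), p = %.3g\n",
              x$cnri, x$cnri_ci[1], x$cnri_ci[2], x$cnri_p))
  cat(sprintf("  IDI  %.3f (%.3f; %.3f), p = %.3g\n",
              x$idi, x$idi_ci[1], x$idi_ci[2], x$idi_p))
  invisible(x)
}
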