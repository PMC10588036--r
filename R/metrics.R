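#' Incidence rate per 100 patient-years
#'
#' @param events number of events in the group.
#' @param person_years summed observed follow-up of the group, > 0.
#' @return `100 * events / person_years`.
#' @export
incidence_rate <- function(events, person_years) {
  if (any(person_years <= 0)) {
    stop("undefined: person_years must be > 0", call. = FALSE)
  }
  100 * events / person_years
}

#' Per-terminal-node risk summaries of a fitted tree
#'
#' For each terminal node: subjects, events, person-years and the
#' incidence rate per 100 patient-years; hazard ratios versus the
#' reference node (the terminal node with the lowest IR) from a single
#' Cox fit on terminal-node indicators; and the ordinal risk rank (IR
#' ascending, reference = 1). A node whose HR is non-estimable (e.g. zero
#' events against a zero-event reference) is flagged with `NA` limits.
#'
#' @param tree a `hazard_tree`.
#' @param cohort the cohort the tree was fitted on (or any cohort whose
#'   subjects can all be routed).
#' @return data.frame with one row per terminal node: `node`, `n`,
#'   `events`, `person_years`, `ir`, `hr`, `hr_lo`, `hr_hi`, `rank`,
#'   `reference`.
#' @export
node_summaries <- function(tree, cohort) {
  dat <- as.data.frame(cohort)
  node <- assign_node(tree, dat)
  if (anyNA(node)) stop("every subject must be assignable", call. = FALSE)
  ids <- terminal_nodes(tree)
  agg <- lapply(ids, function(id) {
    sub <- dat[node == id, , drop = FALSE]
    data.frame(node = id, n = nrow(sub), events = sum(sub$event),
               person_years = sum(sub$time),
               ir = incidence_rate(sum(sub$event), sum(sub$time)))
  })
  out <- do.call(rbind, agg)
  out$rank <- rank(out$ir, ties.method = "first")
  ref <- out$node[which.min(out$ir)]
  out$reference <- out$node == ref
  out$hr <- 1; out$hr_lo <- NA_real_; out$hr_hi <- NA_real_
  if (length(ids) > 1) {
    f <- stats::relevel(factor(node, levels = ids), ref = as.character(ref))
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(dat$time, dat$event) ~ f,
                      ties = "efron"))
    beta <- stats::coef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    lev <- sub("^f", "", names(beta))
    for (k in seq_along(beta)) {
      i <- which(out$node == as.integer(lev[k]))
      if (is.finite(beta[k]) && abs(beta[k]) < 15) {
        out$hr[i] <- exp(beta[k])
        out$hr_lo[i] <- exp(beta[k] - 1.96 * se[k])
        out$hr_hi[i] <- exp(beta[k] + 1.96 * se[k])
      } else {
        out$hr[i] <- NA_real_
      }
    }
  }
  rownames(out) <- NULL
  out[order(out$node), c("node", "n", "events", "person_years", "ir",
                         "hr", "hr_lo", "hr_hi", "rank", "reference")]
}

# internal: ordinal node risk (rank of in-bag IR, ascending), named by
# terminal node id; cheap version of node_summaries without the HR fit
node_rank_by_ir <- function(tree, cohort) {
  dat <- as.data.frame(cohort)
  node <- suppressWarnings(assign_node(tree, dat))
  ids <- terminal_nodes(tree)
  ir <- vapply(ids, function(id) {
    sel <- !is.na(node) & node == id
    py <- sum(dat$time[sel])
    if (py <= 0) 0 else incidence_rate(sum(dat$event[sel]), py)
  }, numeric(1))
  rk <- rank(ir, ties.method = "first")
  names(rk) <- as.character(ids)
  rk
}

#' Incidence-rate variation index
#'
#' `IRV = (1/N) * sum_i n_i * |IR_i - IR|` over the `f` terminal nodes,
#' where `IR` is the pooled incidence rate of the whole population (total
#' events over total person-years) and `IR_i`, `n_i` the rate and size of
#' node i. Units follow IR: events per 100 patient-years. IRV is zero iff
#' every node rate equals the overall rate, and grows with the dispersion
#' of node risks.
#'
#' @param node_n vector of node sizes `n_i` (or a [node_summaries()]
#'   data.frame, in which case `node_ir` and `N` are taken from it).
#' @param node_ir vector of node incidence rates `IR_i`.
#' @param overall_ir pooled incidence rate of the population.
#' @param N total subjects; must equal `sum(node_n)`.
#' @return IRV in events per 100 patient-years.
#' @export
irv <- function(node_n, node_ir = NULL, overall_ir = NULL, N = NULL) {
  if (is.data.frame(node_n)) {
    s <- node_n
    if (is.null(overall_ir)) {
      overall_ir <- incidence_rate(sum(s$events), sum(s$person_years))
    }
    node_ir <- s$ir
    node_n <- s$n
  }
  if (is.null(N)) N <- sum(node_n)
  if (N == 0) stop("N must be > 0", call. = FALSE)
  if (sum(node_n) != N) stop("sum(n_i) must equal N", call. = FALSE)
  sum(node_n * abs(node_ir - overall_ir)) / N
}

#' Kaplan-Meier curve
#'
#' Product-limit estimator (events precede censorings at tied times) via
#' \code{survival::survfit}, returned as a tidy step table.
#'
#' @param times observed follow-up times.
#' @param events 0/1 event indicators.
#' @return data.frame: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_curve <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, se.fit = FALSE)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Cumulative/dynamic time-dependent AUC at time t
#'
#' Cases are subjects with an observed event by time `t` (cumulative),
#' controls are subjects still under observation beyond `t` (dynamic).
#' With `weighted = TRUE` (default), case/control contributions carry
#' inverse-probability-of-censoring weights from the
#' censoring-distribution Kaplan-Meier (G(t-) for cases at their event
#' time, G(t) for controls), the standard IPCW estimator; otherwise the
#' plain empirical AUC of cases versus controls is returned. Marker ties
#' contribute 1/2.
#'
#' @param marker risk marker, one value per subject (higher = riskier;
#'   ordinal allowed).
#' @param cohort a `survival_cohort`.
#' @param t evaluation time within the observed follow-up range.
#' @param weighted use IPCW weights (default TRUE).
#' @return AUC(t) in [0, 1].
#' @export
cd_auc <- function(marker, cohort, t, weighted = TRUE) {
  stopifnot(length(marker) == nrow(cohort))
  time <- cohort$time; event <- cohort$event
  case <- time <= t & event == 1
  ctrl <- time > t
  if (sum(case) == 0 || sum(ctrl) == 0) {
    stop("undefined: no cases or no controls at t", call. = FALSE)
  }
  if (weighted) {
    g_tm <- censoring_km(time, event, time, left = TRUE)
    g_t <- censoring_km(time, event, t, left = FALSE)
  } else {
    g_tm <- rep(1, length(time)); g_t <- 1
  }
  cd_auc_core(marker, time, event, t, g_tm, g_t)
}

# AUC(t) given precomputed censoring-KM values (g_tm at each subject's
# time, left limit; g_t at t)
cd_auc_core <- function(marker, time, event, t, g_tm, g_t) {
  case <- time <= t & event == 1
  ctrl <- time > t
  w_case <- ifelse(case & g_tm > 0, 1 / g_tm, 0)
  w_ctrl <- ifelse(ctrl & g_t > 0, 1 / g_t, 0)
  weighted_auc(marker[case], w_case[case], marker[ctrl], w_ctrl[ctrl])
}

# weighted case-vs-control AUC with 1/2 credit for marker ties,
# O(n log n) via cumulative control weights
weighted_auc <- function(mi, wi, mj, wj) {
  o <- order(mj)
  mjs <- mj[o]; cw <- cumsum(wj[o])
  n_lt <- findInterval(mi, mjs, left.open = TRUE)
  n_le <- findInterval(mi, mjs)
  w_lt <- ifelse(n_lt == 0, 0, cw[pmax(n_lt, 1)])
  w_le <- ifelse(n_le == 0, 0, cw[pmax(n_le, 1)])
  sum(wi * (w_lt + 0.5 * (w_le - w_lt))) / (sum(wi) * sum(cw[length(cw)]))
}

#' Integrated cumulative/dynamic AUC over a follow-up window
#'
#' AUC(t) is evaluated on the grid of distinct event times inside
#' `[t0, t1]` and averaged with weights proportional to the Kaplan-Meier
#' event mass at each grid time (normalized to 1 over the window); a
#' uniform weighting is available. The optional CI is a subject-level
#' bootstrap percentile interval.
#'
#' @param marker risk marker, one value per subject.
#' @param cohort a `survival_cohort`.
#' @param t0,t1 window in years (defaults 0.25 = 3 months, and 5).
#' @param weighting `"km"` (event-mass, default) or `"uniform"`.
#' @param weighted_auc IPCW AUC(t) (default TRUE); FALSE for the naive
#'   estimator.
#' @param n_boot bootstrap replicates for the CI (0 = point estimate only).
#' @param seed integer seed (required when `n_boot > 0`).
#' @return list with `iauc`, `grid` (data.frame `time`, `auc`, `weight`),
#'   and when bootstrapped `ci` and `n_boot`.
#' @export
iauc <- function(marker, cohort, t0 = 0.25, t1 = 5,
                 weighting = c("km", "uniform"), weighted_auc = TRUE,
                 n_boot = 0, seed = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(t0 < t1, length(marker) == nrow(cohort))
  point <- function(mk, co) {
    time <- co$time; event <- co$event
    grid <- sort(unique(time[event == 1 & time >= t0 & time <= t1]))
    grid <- grid[grid < max(time)]  # need controls beyond t
    if (length(grid) == 0) stop("no events in window", call. = FALSE)
    km <- km_curve(co$time, co$event)
    sleft <- function(tt) {
      prior <- km$surv[km$time < tt]
      if (length(prior) == 0) 1 else prior[length(prior)]
    }
    mass <- vapply(grid, function(tt) {
      i <- which(km$time == tt)
      sleft(tt) - km$surv[i]
    }, numeric(1))
    w <- if (weighting == "km") mass / sum(mass) else
      rep(1 / length(grid), length(grid))
    if (weighted_auc) {
      g_tm <- censoring_km(time, event, time, left = TRUE)
      g_grid <- censoring_km(time, event, grid, left = FALSE)
    } else {
      g_tm <- rep(1, length(time)); g_grid <- rep(1, length(grid))
    }
    aucs <- vapply(seq_along(grid), function(k)
      cd_auc_core(mk, time, event, grid[k], g_tm, g_grid[k]),
      numeric(1))
    list(iauc = sum(w * aucs),
         grid = data.frame(time = grid, auc = aucs, weight = w))
  }
  est <- point(marker, cohort)
  out <- list(iauc = est$iauc, grid = est$grid)
  if (n_boot > 0) {
    if (is.null(seed)) stop("seed required for bootstrap CI", call. = FALSE)
    set.seed(seed)
    n <- nrow(cohort)
    dat <- as.data.frame(cohort)
    reps <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      bo <- dat[idx, , drop = FALSE]; bo$subject_id <- seq_len(n)
      tryCatch(point(marker[idx], as_survival_cohort(bo))$iauc,
               error = function(e) NA_real_)
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    out$ci <- unname(stats::quantile(reps, c(.025, .975), type = 7))
    out$n_boot <- n_boot
  }
  out
}

#' Group terminal nodes into ordered risk bands by hazard ratio
#'
#' Nodes are assigned to `low`, `intermediate`, `high` or `very high`
#' bands by their HR versus the reference node, against configurable
#' edges (default 2, 5, 10, which reproduces a low / intermediate / high /
#' very-high grouping of HRs such as 1, 2-4, 6-7, 12). The reference node
#' is always `low`.
#'
#' @param summaries a [node_summaries()] data.frame.
#' @param band_edges increasing numeric vector of three HR edges.
#' @return data.frame `node`, `hr`, `band` (ordered factor).
#' @export
risk_bands <- function(summaries, band_edges = c(2, 5, 10)) {
  stopifnot(length(band_edges) == 3, !is.unsorted(band_edges))
  lv <- c("low", "intermediate", "high", "very high")
  band <- cut(summaries$hr, breaks = c(-Inf, band_edges, Inf),
              labels = lv, right = FALSE)
  band[summaries$reference] <- "low"
  data.frame(node = summaries$node, hr = summaries$hr,
             band = factor(band, levels = lv, ordered = TRUE))
}
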