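#' Growth parameters for the hazard-ratio splitting tree
#'
#' @param max_depth maximum tree depth (root = depth 0); default 3, which
#'   caps the tree at eight terminal nodes.
#' @param min_node_n minimum subjects per child node (default 30).
#' @param min_node_events minimum events per child node (default 5).
#' @param alpha_split significance level the best split's Wald p-value
#'   must beat for the split to be made (default 0.05).
#' @param max_cutpoints per variable: maximum number of candidate cutoffs
#'   retained (evenly thinned from the exhaustive midpoint list);
#'   `Inf` = exhaustive.
#' @return list of class `tree_params`.
#' @export
tree_params <- function(max_depth = 3, min_node_n = 30,
                        min_node_events = 5, alpha_split = 0.05,
                        max_cutpoints = Inf) {
  stopifnot(max_depth >= 0, min_node_n >= 1, min_node_events >= 0,
            alpha_split > 0, alpha_split <= 1, max_cutpoints >= 1)
  structure(list(max_depth = max_depth, min_node_n = min_node_n,
                 min_node_events = min_node_events,
                 alpha_split = alpha_split,
                 max_cutpoints = max_cutpoints),
            class = "tree_params")
}

# fast univariate Cox fit of a binary right-side indicator.
# Returns c(log_hr, se) or NULL on failure.
cox_indicator_fit <- function(time, event, ind) {
  y <- survival::Surv(time, event)
  fit <- tryCatch(suppressWarnings(
    survival::coxph.fit(matrix(as.numeric(ind), ncol = 1), y,
                        strata = NULL, offset = NULL, init = 0,
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 25),
                        weights = NULL, method = "efron",
                        rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients[1])) return(NULL)
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(se) || se <= 0 || abs(fit$coefficients[1]) > 15) {
    return(NULL)
  }
  c(log_hr = unname(fit$coefficients[1]), se = unname(se))
}

#' Enumerate candidate splits for one variable within a node
#'
#' Candidate cutoffs are the midpoints between consecutive distinct
#' observed values ("<= goes left"); a binary variable therefore yields a
#' single candidate. When `max_cutpoints` is finite the exhaustive list is
#' thinned to at most that many cutoffs (evenly by order statistic), so
#' any thinned candidate set is a subset of the exhaustive one.
#' Candidates whose children would violate the minimum size or event
#' counts are marked inadmissible.
#'
#' @param cohort_subset a `survival_cohort` (the node's subjects).
#' @param variable numeric covariate name.
#' @param params a [tree_params()].
#' @return data.frame of `SplitCandidate`s: `variable`, `cutoff`,
#'   `n_left`, `n_right`, `events_left`, `events_right`, `admissible`
#'   (empty for a constant variable).
#' @export
enumerate_splits <- function(cohort_subset, variable,
                             params = tree_params()) {
  v <- cohort_subset[[variable]]
  ok <- !is.na(v)
  u <- sort(unique(v[ok]))
  if (length(u) < 2) {
    return(data.frame(variable = character(0), cutoff = numeric(0),
                      n_left = integer(0), n_right = integer(0),
                      events_left = integer(0), events_right = integer(0),
                      admissible = logical(0)))
  }
  cutoffs <- (u[-1] + u[-length(u)]) / 2
  if (is.finite(params$max_cutpoints) &&
      length(cutoffs) > params$max_cutpoints) {
    keep <- unique(round(seq(1, length(cutoffs),
                             length.out = params$max_cutpoints)))
    cutoffs <- cutoffs[keep]
  }
  ev <- cohort_subset$event[ok]
  vv <- v[ok]
  res <- lapply(cutoffs, function(ct) {
    l <- vv <= ct
    data.frame(variable = variable, cutoff = ct,
               n_left = sum(l), n_right = sum(!l),
               events_left = sum(ev[l]), events_right = sum(ev[!l]))
  })
  out <- do.call(rbind, res)
  out$admissible <- out$n_left >= params$min_node_n &
    out$n_right >= params$min_node_n &
    out$events_left >= params$min_node_events &
    out$events_right >= params$min_node_events
  out
}

#' Score a candidate split by its Cox hazard-ratio Wald statistic
#'
#' Fits the univariate Cox model of the right-side indicator
#' (`variable > cutoff`) within the node and records the log hazard ratio,
#' its Wald chi-square `(log HR / SE)^2` and p-value. A non-convergent fit
#' (e.g. all events on one side) marks the candidate inadmissible.
#'
#' @param cohort_subset node subjects.
#' @param variable,cutoff the candidate.
#' @return one-row data.frame with `variable`, `cutoff`, `log_hr`,
#'   `wald_z2`, `p_value`, `admissible` plus child counts.
#' @export
score_split <- function(cohort_subset, variable, cutoff) {
  v <- cohort_subset[[variable]]
  ok <- !is.na(v)
  ind <- v[ok] > cutoff
  base <- data.frame(variable = variable, cutoff = cutoff,
                     n_left = sum(!ind), n_right = sum(ind),
                     events_left = sum(cohort_subset$event[ok][!ind]),
                     events_right = sum(cohort_subset$event[ok][ind]))
  if (sum(ind) == 0 || sum(!ind) == 0) {
    return(cbind(base, log_hr = NA, wald_z2 = NA, p_value = NA,
                 admissible = FALSE))
  }
  ft <- cox_indicator_fit(cohort_subset$time[ok], cohort_subset$event[ok],
                          ind)
  if (is.null(ft)) {
    return(cbind(base, log_hr = NA, wald_z2 = NA, p_value = NA,
                 admissible = FALSE))
  }
  z2 <- (ft["log_hr"] / ft["se"])^2
  cbind(base, log_hr = unname(ft["log_hr"]), wald_z2 = unname(z2),
        p_value = unname(stats::pchisq(z2, 1, lower.tail = FALSE)),
        admissible = TRUE)
}

#' Best admissible split of a node
#'
#' Scores every admissible candidate over the given variables and returns
#' the one maximizing the Wald chi-square of the split hazard ratio,
#' provided its p-value beats `alpha_split`. Ties are broken by smaller
#' p-value, then lexicographic variable name, then smaller cutoff.
#'
#' @param cohort_subset node subjects.
#' @param variables candidate split variables.
#' @param params a [tree_params()].
#' @return one-row data.frame (the winning scored candidate) or `NULL`
#'   when no admissible significant candidate exists.
#' @export
best_split <- function(cohort_subset, variables, params = tree_params()) {
  best <- NULL
  for (vn in sort(variables)) {
    cand <- enumerate_splits(cohort_subset, vn, params)
    cand <- cand[cand$admissible, , drop = FALSE]
    if (nrow(cand) == 0) next
    for (k in seq_len(nrow(cand))) {
      sc <- score_split(cohort_subset, vn, cand$cutoff[k])
      if (!sc$admissible || !is.finite(sc$wald_z2)) next
      if (sc$p_value >= params$alpha_split) next
      if (is.null(best) ||
          sc$wald_z2 > best$wald_z2 + 1e-12 ||
          (abs(sc$wald_z2 - best$wald_z2) <= 1e-12 &&
           (sc$p_value < best$p_value - 1e-15 ||
            (abs(sc$p_value - best$p_value) <= 1e-15 &&
             (sc$variable < best$variable ||
              (sc$variable == best$variable &&
               sc$cutoff < best$cutoff)))))) {
        best <- sc
      }
    }
  }
  best
}

#' Grow a hazard-ratio splitting survival tree
#'
#' Recursive partitioning in the CART style, with the split criterion
#' being the Wald chi-square of the Cox log hazard ratio of each candidate
#' binary split. Growth stops at `max_depth`, when children would violate
#' minimum size/event counts, or when no candidate's p-value beats
#' `alpha_split`. Node ids are assigned breadth-first (root = 1). Rows
#' with a missing split variable are excluded from that node's split fit
#' and routed nowhere at prediction (no surrogate splits).
#'
#' @param cohort a `survival_cohort`.
#' @param variables candidate split variables.
#' @param params a [tree_params()].
#' @return object of class `hazard_tree`: list with `nodes` (data.frame:
#'   `id`, `depth`, `parent`, `terminal`, `variable`, `cutoff`, `n`,
#'   `events`, plus split statistics), `members` (list of subject-id
#'   vectors per node), `params`, `variables`, `n`.
#' @export
grow_tree <- function(cohort, variables, params = tree_params()) {
  stopifnot(nrow(cohort) > 0)
  absent <- setdiff(variables, names(cohort))
  if (length(absent) > 0) {
    stop("variable(s) not in cohort: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) < 2 * params$min_node_n) {
    warning("cohort smaller than 2 * min_node_n: root-only tree",
            call. = FALSE)
  }
  dat <- as.data.frame(cohort)
  nodes <- list()
  members <- list()
  # queue entries: (id, depth, parent, row indices); ids assigned on entry
  queue <- list(list(id = 1L, depth = 0L, parent = NA_integer_,
                     idx = seq_len(nrow(dat))))
  next_id <- 2L
  while (length(queue) > 0) {
    nd <- queue[[1]]; queue <- queue[-1]
    sub <- as_survival_cohort(dat[nd$idx, , drop = FALSE])
    rec <- data.frame(id = nd$id, depth = nd$depth, parent = nd$parent,
                      terminal = TRUE, variable = NA_character_,
                      cutoff = NA_real_, n = nrow(sub),
                      events = sum(sub$event), log_hr = NA_real_,
                      wald_z2 = NA_real_, p_value = NA_real_)
    can_split <- nd$depth < params$max_depth &&
      nrow(sub) >= 2 * params$min_node_n
    if (can_split) {
      bs <- best_split(sub, variables, params)
      if (!is.null(bs)) {
        rec$terminal <- FALSE
        rec$variable <- bs$variable
        rec$cutoff <- bs$cutoff
        rec$log_hr <- bs$log_hr
        rec$wald_z2 <- bs$wald_z2
        rec$p_value <- bs$p_value
        v <- dat[[bs$variable]][nd$idx]
        lidx <- nd$idx[!is.na(v) & v <= bs$cutoff]
        ridx <- nd$idx[!is.na(v) & v > bs$cutoff]
        queue <- c(queue,
                   list(list(id = next_id, depth = nd$depth + 1L,
                             parent = nd$id, idx = lidx)),
                   list(list(id = next_id + 1L, depth = nd$depth + 1L,
                             parent = nd$id, idx = ridx)))
        next_id <- next_id + 2L
      }
    }
    nodes[[length(nodes) + 1L]] <- rec
    members[[as.character(nd$id)]] <- dat$subject_id[nd$idx]
  }
  nodes <- do.call(rbind, nodes)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, members = members, params = params,
                 variables = variables, n = nrow(dat)),
            class = "hazard_tree")
}

#' Terminal node ids of a fitted tree
#' @param tree a `hazard_tree`.
#' @return integer vector.
#' @export
terminal_nodes <- function(tree) {
  tree$nodes$id[tree$nodes$terminal]
}

#' Route covariate rows to terminal nodes
#'
#' Deterministic routing: at each internal node, rows with
#' `value <= cutoff` go to the left child (the lower node id). Rows
#' missing a split variable are unassignable and return `NA` with a
#' warning (no surrogate splits).
#'
#' @param tree a `hazard_tree`.
#' @param newdata data.frame holding the tree's split variables.
#' @return integer vector of terminal node ids (NA when unassignable).
#' @export
assign_node <- function(tree, newdata) {
  nodes <- tree$nodes
  children <- function(id) sort(nodes$id[!is.na(nodes$parent) &
                                           nodes$parent == id])
  out <- rep(NA_integer_, nrow(newdata))
  route1 <- function(row) {
    id <- 1L
    repeat {
      k <- which(nodes$id == id)
      if (nodes$terminal[k]) return(id)
      v <- row[[nodes$variable[k]]]
      if (is.null(v) || is.na(v)) return(NA_integer_)
      ch <- children(id)
      id <- if (v <= nodes$cutoff[k]) ch[1] else ch[2]
    }
  }
  for (i in seq_len(nrow(newdata))) {
    out[i] <- route1(newdata[i, , drop = FALSE])
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " row(s) unassignable (missing split variable)",
            call. = FALSE)
  }
  out
}

#' @export
print.hazard_tree <- function(x, ...) {
  cat(sprintf("Hazard-ratio splitting tree: n = %d, %d terminal node(s)\n",
              x$n, sum(x$nodes$terminal)))
  render <- function(id, indent) {
    k <- which(x$nodes$id == id)
    nd <- x$nodes[k, ]
    pad <- strrep("  ", indent)
    if (nd$terminal) {
      cat(sprintf("%s[%d] terminal: n = %d, events = %d\n",
                  pad, nd$id, nd$n, nd$events))
    } else {
      cat(sprintf(
        "%s[%d] %s <= %.4g  (HR right/left = %.3g, chisq = %.3g, p = %.2g)\n",
        pad, nd$id, nd$variable, nd$cutoff, exp(nd$log_hr), nd$wald_z2,
        nd$p_value))
      ch <- sort(x$nodes$id[!is.na(x$nodes$parent) & x$nodes$parent == id])
      render(ch[1], indent + 1)
      render(ch[2], indent + 1)
    }
  }
  render(1L, 0)
  invisible(x)
}

#' Serialize a fitted tree to JSON
#' @param tree a `hazard_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  jsonlite::write_json(list(
    nodes = tree$nodes,
    member_counts = lapply(tree$members, length),
    params = unclass(tree$params),
    variables = tree$variables, n = tree$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bagged variable selection and out-of-bag error for the hazard tree
#'
#' For each of `B` bootstrap resamples (with replacement, size n) a tree
#' is grown; the variables appearing in any split are recorded, and the
#' out-of-bag subjects are routed through that tree to obtain an ordinal
#' risk (in-bag node rank by incidence rate), whose out-of-bag integrated
#' cumulative/dynamic AUC is the per-iteration error measure. Variables
#' whose selection frequency reaches `retention` are retained.
#'
#' @param cohort a `survival_cohort`.
#' @param variables candidate split variables.
#' @param B bootstrap iterations (>= 1); 1000 for a full run.
#' @param params a [tree_params()].
#' @param seed integer seed (mandatory).
#' @param retention retention threshold on selection frequency
#'   (default 0.5).
#' @param iauc_window length-2 window (years) for the OOB iAUC.
#' @return object of class `bagging_report`: list with `B`, `frequency`
#'   (named vector), `retained`, `oob_iauc_mean`, `oob_iauc_sd`,
#'   `oob_iauc` (per-iteration values, NA when undefined), `seed`.
#' @export
bagging_select <- function(cohort, variables, B = 1000,
                           params = tree_params(), seed,
                           retention = 0.5, iauc_window = c(0.25, 5)) {
  stopifnot(B >= 1)
  set.seed(seed)
  n <- nrow(cohort)
  dat <- as.data.frame(cohort)
  sel <- matrix(FALSE, B, length(variables),
                dimnames = list(NULL, variables))
  oob_iauc <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag <- dat[idx, , drop = FALSE]
    inbag$subject_id <- seq_len(n)
    tr <- tryCatch(
      suppressWarnings(grow_tree(as_survival_cohort(inbag), variables,
                                 params)),
      error = function(e) NULL)
    if (is.null(tr)) next
    used <- unique(stats::na.omit(tr$nodes$variable))
    sel[b, used] <- TRUE
    oob <- dat[setdiff(seq_len(n), unique(idx)), , drop = FALSE]
    if (nrow(oob) < 10 || sum(oob$event) < 2) next
    rk <- node_rank_by_ir(tr, as_survival_cohort(inbag))
    node_oob <- suppressWarnings(assign_node(tr, oob))
    okr <- !is.na(node_oob)
    if (sum(okr) < 10 || sum(oob$event[okr]) < 2) next
    marker <- unname(rk[as.character(node_oob[okr])])
    oob_iauc[b] <- tryCatch(
      iauc(marker, as_survival_cohort(oob[okr, , drop = FALSE]),
           t0 = iauc_window[1], t1 = iauc_window[2])$iauc,
      error = function(e) NA_real_)
  }
  freq <- colMeans(sel)
  structure(list(B = B, frequency = freq,
                 retained = names(freq)[freq >= retention],
                 oob_iauc_mean = mean(oob_iauc, na.rm = TRUE),
                 oob_iauc_sd = stats::sd(oob_iauc, na.rm = TRUE),
                 oob_iauc = oob_iauc, retention = retention, seed = seed),
            class = "bagging_report")
}

#' @export
print.bagging_report <- function(x, ...) {
  cat(sprintf("Bagged selection over B = %d trees (seed %d)\n", x$B,
              x$seed))
  cat("selection frequency:\n")
  print(round(sort(x$frequency, decreasing = TRUE), 3))
  cat("retained: ", paste(x$retained, collapse = ", "), "\n")
  cat(sprintf("OOB iAUC: %.3f +/- %.3f\n", x$oob_iauc_mean, x$oob_iauc_sd))
  invisible(x)
}
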