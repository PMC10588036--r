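#' Default pipeline configuration
#'
#' A pipeline config drives [run_pipeline()]: simulate (or read) a cohort,
#' describe it, fit the nested Cox models for the miRNA marker, grow the
#' hazard-ratio tree, run bagged variable selection, and compute node
#' metrics (incidence rates, HRs, IRV, iAUC, risk bands). All stochastic
#' stages derive child seeds from the single top-level `seed`.
#'
#' @param out_dir output directory for persisted artifacts.
#' @param seed top-level integer seed.
#' @param n_subjects synthetic cohort size (ignored when `cohort_path`
#'   given).
#' @param cohort_path optional CSV of an existing cohort; when `NULL` the
#'   default synthetic cohort is generated.
#' @param tree_variables candidate split variables for the tree.
#' @param mirna marker column for the incremental-value analysis.
#' @param bag_B bagging iterations.
#' @param params a [tree_params()].
#' @param horizon reclassification horizon in years.
#' @param iauc_window length-2 evaluation window in years.
#' @param n_perturb perturbation replicates for cNRI/IDI.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 20301L, n_subjects = 587,
                            cohort_path = NULL,
                            tree_variables = c(
                              "age", "asv", "male", "sbp_lt120", "diabetes",
                              "diuretic", "cardiac_device", "sixmwd",
                              "afib", "log_ntprobnp", "log_mir133a"),
                            mirna = "log_mir133a", bag_B = 50,
                            params = tree_params(), horizon = 2,
                            iauc_window = c(0.25, 5), n_perturb = 100) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_subjects = n_subjects, cohort_path = cohort_path,
                 tree_variables = tree_variables, mirna = mirna,
                 bag_B = bag_B, params = params, horizon = horizon,
                 iauc_window = iauc_window, n_perturb = n_perturb),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tp <- do.call(tree_params, if (is.null(y$params)) list() else y$params)
  args <- y[setdiff(names(y), "params")]
  args$params <- tp
  do.call(pipeline_config, args)
}

# canonical config hash: JSON with sorted keys through a temp file
config_hash <- function(config) {
  x <- unclass(config)
  x <- x[order(names(x))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full risk-stratification pipeline
#'
#' Stage order: simulate/ingest -> describe -> cox -> tree -> bag ->
#' metrics -> report. Every intermediate artifact is written under the
#' configured output directory (CSV for tables, JSON for fits and the
#' tree). A stage failure yields a partial report with the failure
#' context; downstream stages are skipped.
#'
#' @param config a [pipeline_config()] (undeclared tree variables are
#'   rejected before any computation).
#' @return list of class `run_report`: `config_hash`, `package_version`,
#'   `seed`, per-stage `stages` (status, wall-time seconds, warnings,
#'   outputs), and the key results (`event_fraction`, `n_terminal`,
#'   `irv`, `iauc`, `retained`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  # validate declared variables against the input schema before any compute
  declared <- if (is.null(config$cohort_path)) {
    spec <- serve_like_spec(config$n_subjects)
    c("subject_id", "time", "event", "arm",
      vapply(spec$covariates, function(cv) cv$name, character(1)),
      vapply(spec$derived, function(dv) dv$name, character(1)))
  } else {
    names(utils::read.csv(config$cohort_path, nrows = 1))
  }
  absent <- setdiff(c(config$tree_variables, config$mirna), declared)
  if (length(absent) > 0) {
    stop("validation error: undeclared tree variable(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config_hash = config_hash(config),
                 package_version =
                   as.character(utils::packageVersion("hrcart")),
                 seed = config$seed, stages = list())
  state <- new.env()
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible())
    }
    warns <- character(0)
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failed <<- TRUE
      report$stages[[name]] <<- list(status = "failed",
                                     error = conditionMessage(res),
                                     wall_time = dt, warnings = warns)
    } else {
      report$stages[[name]] <<- list(status = "ok", wall_time = dt,
                                     warnings = warns, outputs = res)
    }
  }

  run_stage("simulate", function() {
    if (!is.null(config$cohort_path)) {
      state$cohort <- read_cohort(config$cohort_path)
      state$truth <- NULL
    } else {
      gen <- generate_cohort(serve_like_spec(config$n_subjects),
                             serve_like_truth(), seed = config$seed)
      state$cohort <- gen$cohort
      state$truth <- gen$truth
      write_truth(gen$truth, file.path(config$out_dir, "truth.json"))
    }
    absent <- setdiff(config$tree_variables, names(state$cohort))
    if (length(absent) > 0) {
      stop("validation error: undeclared tree variable(s): ",
           paste(absent, collapse = ", "))
    }
    p <- file.path(config$out_dir, "cohort.csv")
    write_cohort(state$cohort, p)
    list(cohort = p, n = nrow(state$cohort),
         event_fraction = mean(state$cohort$event))
  })

  run_stage("describe", function() {
    bt <- baseline_table(state$cohort, "event")
    p <- file.path(config$out_dir, "baseline_table.csv")
    utils::write.csv(bt, p, row.names = FALSE)
    list(baseline_table = p, n_variables = nrow(bt))
  })

  run_stage("cox", function() {
    fits <- lapply(0:3, function(m) {
      ft <- mirna_association(state$cohort, config$mirna, model = m)
      row <- ft$hr[ft$hr$covariate == config$mirna, ]
      list(model = m, hr = row$hr, lo = row$lo, hi = row$hi, p = row$p,
           n = ft$n, events = ft$events)
    })
    p <- file.path(config$out_dir, "mirna_models.json")
    jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA)
    m2 <- intersect(model_spec(2), names(state$cohort))
    rec <- cnri_idi(state$cohort, m2, c(m2, config$mirna),
                    horizon = config$horizon,
                    n_perturb = config$n_perturb,
                    seed = config$seed + 11L)
    state$reclass <- rec
    list(mirna_models = p, cnri = rec$cnri, idi = rec$idi)
  })

  run_stage("tree", function() {
    tr <- grow_tree(state$cohort, config$tree_variables, config$params)
    state$tree <- tr
    p <- file.path(config$out_dir, "tree.json")
    write_tree(tr, p)
    txt <- file.path(config$out_dir, "tree.txt")
    sink(txt); print(tr); sink()
    list(tree = p, n_terminal = sum(tr$nodes$terminal))
  })

  run_stage("bag", function() {
    bg <- bagging_select(state$cohort, config$tree_variables,
                         B = config$bag_B, params = config$params,
                         seed = config$seed + 23L,
                         iauc_window = config$iauc_window)
    state$bag <- bg
    p <- file.path(config$out_dir, "bagging.json")
    jsonlite::write_json(list(B = bg$B, frequency = as.list(bg$frequency),
                              retained = bg$retained,
                              oob_iauc_mean = bg$oob_iauc_mean,
                              oob_iauc_sd = bg$oob_iauc_sd),
                         p, auto_unbox = TRUE, digits = NA)
    list(bagging = p, retained = bg$retained)
  })

  run_stage("metrics", function() {
    ns <- node_summaries(state$tree, state$cohort)
    p <- file.path(config$out_dir, "node_summaries.csv")
    utils::write.csv(ns, p, row.names = FALSE)
    bands <- risk_bands(ns)
    utils::write.csv(bands, file.path(config$out_dir, "risk_bands.csv"),
                     row.names = FALSE)
    rk <- node_rank_by_ir(state$tree, state$cohort)
    node <- assign_node(state$tree, as.data.frame(state$cohort))
    marker <- unname(rk[as.character(node)])
    ia <- iauc(marker, state$cohort, t0 = config$iauc_window[1],
               t1 = config$iauc_window[2], n_boot = 200,
               seed = config$seed + 31L)
    utils::write.csv(ia$grid, file.path(config$out_dir, "auc_t.csv"),
                     row.names = FALSE)
    km_all <- lapply(ns$node, function(id) {
      sel <- node == id
      cbind(node = id, km_curve(state$cohort$time[sel],
                                state$cohort$event[sel]))
    })
    utils::write.csv(do.call(rbind, km_all),
                     file.path(config$out_dir, "km_by_node.csv"),
                     row.names = FALSE)
    state$metrics <- list(
      irv = irv(ns), iauc = ia$iauc, iauc_ci = ia$ci,
      overall_ir = incidence_rate(sum(state$cohort$event),
                                  sum(state$cohort$time)))
    c(list(node_summaries = p), state$metrics)
  })

  run_stage("report", function() {
    res <- list(
      event_fraction = mean(state$cohort$event),
      n_terminal = sum(state$tree$nodes$terminal),
      irv = state$metrics$irv, iauc = state$metrics$iauc,
      overall_ir = state$metrics$overall_ir,
      cnri = state$reclass$cnri, idi = state$reclass$idi,
      retained = state$bag$retained)
    jsonlite::write_json(res, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    res
  })

  report$ok <- !failed
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, config %s): %s\n", x$seed,
              substr(x$config_hash, 1, 8),
              if (x$ok) "complete" else "FAILED"))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %s%s\n", nm, st$status,
                if (!is.null(st$wall_time))
                  sprintf(" (%.1fs)", st$wall_time) else ""))
  }
  invisible(x)
}
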