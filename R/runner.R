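# Orchestration: scenarios x repetitions x strategies with reproducible
# per-repetition seeding.

#' Run one simulation scenario
#'
#' Builds the scenario's correlation design once, computes the true
#' parameters, calibrates the missingness intercept once, then for each
#' repetition draws a complete dataset, imposes missingness and applies every
#' strategy to the identical incomplete dataset. Each repetition uses a child
#' seed derived from (base_seed, scenario id, repetition), so results are a
#' pure function of the configuration and are independent of execution
#' order.
#'
#' @param cfg A [scenario_config()].
#' @param strategies List of [strategy_spec()]s (default: the study's ten).
#' @param reps Number of repetitions (default `cfg$reps`).
#' @param base_seed Base seed (default `cfg$base_seed`).
#' @param verbose Print progress every 100 repetitions?
#' @return A list of class `scenario_result`: `records` (repetition-level
#'   estimate records), `performance` (a [performance_summary()] table),
#'   `selection` (per-repetition selected-set sizes), plus `sigma`, `truth`,
#'   `miss_model` and `cfg`.
#' @export
run_scenario <- function(cfg, strategies = NULL, reps = NULL,
                         base_seed = NULL, verbose = FALSE) {
  validate_scenario(cfg)
  strategies <- strategies %||% default_strategies(cfg$p)
  reps <- as.integer(reps %||% cfg$reps)
  base_seed <- as.integer(base_seed %||% cfg$base_seed)
  stopifnot(reps >= 2L)

  sigma <- build_sigma(cfg)
  truth <- conditional_regression(sigma)
  miss_model <- calibrate_gamma0(missingness_model(sigma, cfg$miss_or),
                                 sigma, cfg$missing_prop)

  rep_seeds <- derive_seeds(base_seed, reps, tag = cfg$id)
  all_records <- vector("list", reps)
  sel_records <- vector("list", reps)
  for (r in seq_len(reps)) {
    sub <- derive_seeds(rep_seeds[r], 2L + length(strategies), "rep")
    dat <- draw_complete(sigma, cfg$n, seed = sub[1])
    inc <- impose_missingness(dat, miss_model, seed = sub[2])
    recs <- lapply(seq_along(strategies), function(k) {
      rec <- apply_strategy(inc, strategies[[k]], m = cfg$m, seed = sub[2L + k])
      rec$rep <- r
      rec
    })
    rec <- do.call(rbind, recs)
    rec$scenario <- cfg$id
    all_records[[r]] <- rec
    sel_records[[r]] <- data.frame(
      scenario = cfg$id, rep = r,
      strategy = rec$strategy[rec$estimand == "muY"],
      n_selected = rec$n_selected[rec$estimand == "muY"],
      stringsAsFactors = FALSE)
    if (verbose && r %% 100L == 0L) {
      message(sprintf("[%s] repetition %d/%d", cfg$id, r, reps))
    }
  }
  records <- do.call(rbind, all_records)
  structure(list(
    records = records,
    performance = performance_summary(records, truth),
    selection = do.call(rbind, sel_records),
    sigma = sigma, truth = truth, miss_model = miss_model, cfg = cfg
  ), class = "scenario_result")
}

#' Define a study plan
#'
#' @param scenarios List of [scenario_config()]s (default: [scenario_grid()]).
#' @param strategies Strategy names to run (default: all ten).
#' @param reps Repetitions per scenario (overrides each scenario's own).
#' @param base_seed Base seed (overrides each scenario's own).
#' @param out_dir Output directory for [run_study()].
#' @return A list of class `study_plan`.
#' @export
study_plan <- function(scenarios = scenario_grid(), strategies = NULL,
                       reps = NULL, base_seed = NULL, out_dir = ".") {
  ids <- vapply(scenarios, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("scenario ids must be unique", call. = FALSE)
  structure(list(scenarios = scenarios, strategies = strategies,
                 reps = reps, base_seed = base_seed, out_dir = out_dir),
            class = "study_plan")
}

#' Run a full study and write result files
#'
#' Executes every scenario of the plan, writing per-scenario record CSVs,
#' per-scenario and combined performance-summary CSVs, a selection-size
#' diagnostics CSV and a plain-text run manifest capturing the full
#' configuration. Scenario failures are caught, recorded in the manifest,
#' and reflected in a nonzero `n_failed` in the returned summary.
#'
#' @param plan A [study_plan()].
#' @param verbose Print progress?
#' @return Invisibly, a list with the combined `performance` table, the
#'   per-scenario results and `n_failed`.
#' @export
run_study <- function(plan, verbose = FALSE) {
  stopifnot(inherits(plan, "study_plan"))
  dir.create(plan$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  failures <- character(0)
  for (cfg in plan$scenarios) {
    strategies <- plan$strategies
    if (!is.null(strategies) && is.character(strategies)) {
      strategies <- default_strategies(cfg$p)[strategies]
    }
    res <- tryCatch(
      run_scenario(cfg, strategies = strategies, reps = plan$reps,
                   base_seed = plan$base_seed, verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", cfg$id, conditionMessage(res)))
      next
    }
    results[[cfg$id]] <- res
    utils::write.csv(res$records,
                     file.path(plan$out_dir, paste0("records_", cfg$id, ".csv")),
                     row.names = FALSE)
    result_report(res$performance,
                  file.path(plan$out_dir, paste0("summary_", cfg$id, ".csv")))
    utils::write.csv(res$selection,
                     file.path(plan$out_dir, paste0("selection_", cfg$id, ".csv")),
                     row.names = FALSE)
  }
  combined <- if (length(results)) {
    do.call(rbind, lapply(results, function(r) as.data.frame(r$performance)))
  } else {
    NULL
  }
  if (!is.null(combined)) {
    rownames(combined) <- NULL
    utils::write.csv(combined, file.path(plan$out_dir, "summary_combined.csv"),
                     row.names = FALSE)
  }
  manifest <- c(
    sprintf("package: auximp %s", as.character(utils::packageVersion("auximp"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("scenarios: %s", paste(vapply(plan$scenarios, `[[`, character(1), "id"),
                                   collapse = ",")),
    sprintf("strategies: %s",
            if (is.null(plan$strategies)) "all"
            else paste(plan$strategies, collapse = ",")),
    sprintf("reps: %s", plan$reps %||% "per-scenario"),
    sprintf("base_seed: %s", plan$base_seed %||% "per-scenario"),
    if (length(failures)) paste0("failed: ", failures) else "failed: none"
  )
  writeLines(manifest, file.path(plan$out_dir, "manifest.txt"))
  invisible(list(performance = combined, results = results,
                 n_failed = length(failures)))
}
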