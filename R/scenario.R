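#' Define a simulation scenario
#'
#' A scenario fixes the dimensions and strength parameters of one cell of the
#' simulation design: the sample size `n`, the number of continuous auxiliary
#' variables `p` (split into three groups whose mean correlations with the
#' incomplete outcome `Y` are 0.4, 0.2 and 0.1), the target missingness
#' proportion in `Y`, the per-standard-deviation odds ratio of missingness,
#' the number of imputations `m` and the number of simulation repetitions.
#'
#' Auxiliary group sizes default to an equal three-way split of `p`, with any
#' remainder assigned to the weakest group (group 3).
#'
#' @param n Sample size per simulated dataset.
#' @param p Number of auxiliary variables.
#' @param missing_prop Target proportion of missing values in `Y` (in (0,1)).
#' @param miss_or Odds ratio of missingness per 1-SD increase in each variable
#'   entering the missingness model.
#' @param group_sizes Integer vector of length 3; auxiliary count per group.
#' @param group_mean_cor Target mean correlation of each group with `Y`.
#' @param target_power Design power for the two-sided test of the exposure
#'   coefficient.
#' @param alpha Significance level of that test.
#' @param m Number of imputations.
#' @param reps Number of simulation repetitions.
#' @param base_seed Base seed from which all repetition seeds are derived.
#' @param id Scenario identifier; autogenerated from `n`, `p` and the
#'   missingness settings when omitted.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(n = 250, p = 25)
#' @export
scenario_config <- function(n, p,
                            missing_prop = 0.3,
                            miss_or = 1.2,
                            group_sizes = NULL,
                            group_mean_cor = c(0.4, 0.2, 0.1),
                            target_power = 0.8,
                            alpha = 0.05,
                            m = 30,
                            reps = 2000,
                            base_seed = 20260918L,
                            id = NULL) {
  n <- as.integer(n); p <- as.integer(p)
  if (is.null(group_sizes)) {
    group_sizes <- rep(p %/% 3L, 3L)
    group_sizes[3] <- group_sizes[3] + p - sum(group_sizes)
  }
  group_sizes <- as.integer(group_sizes)
  if (is.null(id)) {
    id <- sprintf("n%d_p%d_miss%d_or%g", n, p, round(100 * missing_prop), miss_or)
  }
  cfg <- structure(list(
    id = id, n = n, p = p,
    group_sizes = group_sizes, group_mean_cor = group_mean_cor,
    target_power = target_power, alpha = alpha,
    missing_prop = missing_prop, miss_or = miss_or,
    m = as.integer(m), reps = as.integer(reps),
    base_seed = as.integer(base_seed)
  ), class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  with(cfg, {
    if (length(group_sizes) != 3L || any(group_sizes <= 0L)) {
      stop("group_sizes must be three positive counts", call. = FALSE)
    }
    if (sum(group_sizes) != p) stop("group_sizes must sum to p", call. = FALSE)
    if (n <= 0L) stop("n must be positive", call. = FALSE)
    if (missing_prop <= 0 || missing_prop >= 1) {
      stop("missing_prop must lie in (0,1)", call. = FALSE)
    }
    if (miss_or <= 0) stop("miss_or must be positive", call. = FALSE)
    if (!(alpha > 0 && alpha < target_power && target_power < 1)) {
      stop("need 0 < alpha < target_power < 1", call. = FALSE)
    }
    if (m < 2L) stop("m must be at least 2", call. = FALSE)
  })
  invisible(cfg)
}

#' The six study scenarios
#'
#' Returns the scenario grid of the simulation study: the four (n, p)
#' combinations (250, 25), (250, 83), (1000, 100) and (1000, 333) at 30\%
#' missingness with missingness odds ratio 1.2, plus two variants of the
#' (1000, 100) scenario with 50\% missingness and with odds ratio 2.0.
#'
#' @param reps Number of repetitions per scenario.
#' @param base_seed Base seed shared by the grid.
#' @return A named list of [scenario_config()] objects.
#' @export
scenario_grid <- function(reps = 2000, base_seed = 20260918L) {
  grid <- list(
    scenario_config(250, 25, reps = reps, base_seed = base_seed),
    scenario_config(250, 83, reps = reps, base_seed = base_seed),
    scenario_config(1000, 100, reps = reps, base_seed = base_seed),
    scenario_config(1000, 333, reps = reps, base_seed = base_seed),
    scenario_config(1000, 100, missing_prop = 0.5, reps = reps, base_seed = base_seed),
    scenario_config(1000, 100, miss_or = 2.0, reps = reps, base_seed = base_seed)
  )
  names(grid) <- vapply(grid, `[[`, character(1), "id")
  grid
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %s\n", x$id))
  cat(sprintf("  n = %d, p = %d (groups %s; mean cor with Y %s)\n",
              x$n, x$p, paste(x$group_sizes, collapse = "/"),
              paste(format(x$group_mean_cor), collapse = "/")))
  cat(sprintf("  missingness: %.0f%% at OR %.1f per SD; power %.0f%% at alpha %.2f\n",
              100 * x$missing_prop, x$miss_or, 100 * x$target_power, x$alpha))
  cat(sprintf("  m = %d imputations, %d repetitions, base seed %d\n",
              x$m, x$reps, x$base_seed))
  invisible(x)
}

#' Read or write a scenario configuration file
#'
#' Scenario files are plain `key: value` text, one key per line, mirroring the
#' fields of [scenario_config()]. Vector fields (`group_sizes`,
#' `group_mean_cor`) are comma separated.
#'
#' @param path File path.
#' @return For `read_scenario_config`, a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1)))
  named <- stats::setNames(as.list(vals), keys)
  num <- function(k, default = NULL) {
    if (is.null(named[[k]])) return(default)
    as.numeric(strsplit(named[[k]], ",", fixed = TRUE)[[1]])
  }
  scenario_config(
    n = num("n"), p = num("p"),
    missing_prop = num("missing_prop", 0.3),
    miss_or = num("miss_or", 1.2),
    group_sizes = if (!is.null(named$group_sizes)) num("group_sizes"),
    group_mean_cor = num("group_mean_cor", c(0.4, 0.2, 0.1)),
    target_power = num("target_power", 0.8),
    alpha = num("alpha", 0.05),
    m = num("m", 30),
    reps = num("reps", 2000),
    base_seed = num("base_seed", 20260918),
    id = if (!is.null(named$id)) named$id
  )
}

#' @rdname read_scenario_config
#' @param cfg A `scenario_config` to write.
#' @export
write_scenario_config <- function(cfg, path) {
  validate_scenario(cfg)
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  keys <- c("id", "n", "p", "group_sizes", "group_mean_cor", "target_power",
            "alpha", "missing_prop", "miss_or", "m", "reps", "base_seed")
  writeLines(vapply(keys, function(k) paste0(k, ": ", fmt(cfg[[k]])), character(1)),
             path)
  invisible(path)
}
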