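#' Summarize simulation performance
#'
#' Computes, per (scenario, strategy, estimand) cell over the converged
#' repetitions: bias (mean estimate minus truth), empirical SE (sample SD of
#' the estimates, divisor M-1), average model SE (root mean of the squared
#' reported SEs), coverage of the nominal 95\% interval, standardized bias
#' (100 x bias / empirical SE), relative bias (100 x bias / truth, undefined
#' and reported NA when the truth is 0), the relative error in the model SE
#' (100 x (model SE / empirical SE - 1)), the convergence rate, and Monte
#' Carlo standard errors for bias and for the empirical SE.
#'
#' @param records A data.frame of repetition-level estimate records as
#'   produced by [run_scenario()]: columns `scenario`, `rep`, `strategy`,
#'   `estimand`, `estimate`, `se`, `ci_low`, `ci_high`, `converged`.
#' @param truth A `true_params` (or list with `muY` and `betaX`) giving the
#'   true values, or a data.frame with columns `scenario`, `estimand`,
#'   `truth` when records span scenarios with different truths.
#' @return A data.frame of class `performance_table`, one row per cell, with
#'   a logical `flagged` column marking cells with fewer than 2 converged
#'   repetitions (their moments are NA).
#' @export
performance_summary <- function(records, truth) {
  stopifnot(all(c("scenario", "strategy", "estimand", "estimate", "se",
                  "ci_low", "ci_high", "converged") %in% names(records)))
  truth_of <- function(scenario, estimand) {
    if (is.data.frame(truth)) {
      hit <- truth$truth[truth$scenario == scenario & truth$estimand == estimand]
      if (length(hit) != 1L) stop("no unique truth for ", scenario, "/", estimand)
      return(hit)
    }
    switch(estimand, muY = truth$muY, betaX = truth$betaX,
           stop("unknown estimand ", estimand))
  }
  cells <- unique(records[c("scenario", "strategy", "estimand")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- records[records$scenario == cell$scenario &
                     records$strategy == cell$strategy &
                     records$estimand == cell$estimand, ]
    theta <- truth_of(cell$scenario, cell$estimand)
    ok <- sub[sub$converged %in% TRUE & is.finite(sub$estimate), ]
    M <- nrow(ok)
    out <- data.frame(scenario = cell$scenario, strategy = cell$strategy,
                      estimand = cell$estimand, truth = theta,
                      M = M, n_total = nrow(sub),
                      convergence_rate = M / nrow(sub),
                      bias = NA_real_, mcse_bias = NA_real_,
                      emp_se = NA_real_, mcse_emp_se = NA_real_,
                      model_se = NA_real_, coverage = NA_real_,
                      std_bias_pct = NA_real_, rel_bias_pct = NA_real_,
                      rel_err_model_se_pct = NA_real_,
                      flagged = M < 2L, stringsAsFactors = FALSE)
    if (M < 2L) return(out)
    est <- ok$estimate
    bias <- mean(est) - theta
    emp_se <- stats::sd(est)
    model_se <- sqrt(mean(ok$se^2))
    out$bias <- bias
    out$mcse_bias <- sqrt(sum((est - mean(est))^2) / (M * (M - 1)))
    out$emp_se <- emp_se
    out$mcse_emp_se <- emp_se / sqrt(2 * (M - 1))
    out$model_se <- model_se
    out$coverage <- mean(ok$ci_low <= theta & theta <= ok$ci_high)
    out$std_bias_pct <- 100 * bias / emp_se
    out$rel_bias_pct <- if (theta == 0) NA_real_ else 100 * bias / theta
    out$rel_err_model_se_pct <- 100 * (model_se / emp_se - 1)
    out
  })
  structure(do.call(rbind, rows), class = c("performance_table", "data.frame"))
}

#' Write a performance table as CSV
#'
#' Emits one row per (scenario, strategy, estimand) with the fixed column
#' order scenario, strategy, estimand, M, bias, mcse_bias, emp_se,
#' mcse_emp_se, model_se, coverage, std_bias_pct, rel_bias_pct,
#' rel_err_model_se_pct, convergence_rate, flagged. Flagged cells (fewer
#' than 2 converged repetitions) are emitted with NA moments and
#' `flagged = TRUE` rather than dropped.
#'
#' @param table A [performance_summary()] result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
result_report <- function(table, path) {
  stopifnot(nrow(table) > 0)
  cols <- c("scenario", "strategy", "estimand", "M", "bias", "mcse_bias",
            "emp_se", "mcse_emp_se", "model_se", "coverage", "std_bias_pct",
            "rel_bias_pct", "rel_err_model_se_pct", "convergence_rate",
            "flagged")
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Plot bias or empirical SE with Monte Carlo intervals
#'
#' Dot-and-interval plot per strategy of the estimated bias (with 95\% Monte
#' Carlo interval bias +/- 1.96 mcse_bias) or empirical SE, faceted by
#' scenario, in the style of the study's headline figures. Requires ggplot2.
#'
#' @param table A [performance_summary()] result.
#' @param measure `"bias"` or `"emp_se"`.
#' @param estimand Which estimand to display.
#' @return A ggplot object.
#' @export
plot_performance <- function(table, measure = c("bias", "emp_se"),
                             estimand = c("muY", "betaX")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_performance requires ggplot2", call. = FALSE)
  }
  measure <- match.arg(measure)
  estimand <- match.arg(estimand)
  df <- as.data.frame(table)
  df <- df[df$estimand == estimand & !df$flagged, ]
  mcse <- if (measure == "bias") df$mcse_bias else df$mcse_emp_se
  df$lo <- df[[measure]] - 1.96 * mcse
  df$hi <- df[[measure]] + 1.96 * mcse
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[measure]],
                                   y = stats::reorder(.data$strategy,
                                                      .data[[measure]]))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                            height = 0.2) +
    ggplot2::facet_wrap(~scenario, scales = "free_x") +
    ggplot2::labs(x = measure, y = NULL,
                  title = sprintf("%s for %s with 95%% Monte Carlo intervals",
                                  measure, estimand)) +
    ggplot2::theme_bw()
}
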