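# The eight auxiliary-variable selection strategies and the two benchmark
# analysis strategies (complete-case analysis and the full imputation model).

#' Specify an analysis strategy
#'
#' @param name One of `"CCA"`, `"Full"`, `"Quickpred-pt2"`, `"Quickpred-pt4"`,
#'   `"PredMiss"`, `"PcAux"`, `"Forward"`, `"Forward-sw"`, `"Forward-FMI"`,
#'   `"LASSO"`.
#' @param cutoff Correlation cutoff for the quickpred strategies (0.2 / 0.4).
#' @param alpha_sel Selection test level for PredMiss, Forward and
#'   Forward-sw.
#' @param var_threshold Fraction of auxiliary variance the retained principal
#'   components must explain (PcAux).
#' @param stop_frac Forward-FMI stopping fraction: selection stops when the
#'   FMI reduction falls below `stop_frac` times the observed missingness
#'   proportion (0.01 for p in 25/83/100, 0.005 for p = 333).
#' @param n_folds Cross-validation folds for the LASSO.
#' @param m_sel Number of imputations used inside Forward-FMI when comparing
#'   candidates (`NULL` = same as the analysis `m`).
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name,
                          cutoff = NULL, alpha_sel = NULL,
                          var_threshold = NULL, stop_frac = NULL,
                          n_folds = NULL, m_sel = NULL) {
  valid <- c("CCA", "Full", "Quickpred-pt2", "Quickpred-pt4", "PredMiss",
             "PcAux", "Forward", "Forward-sw", "Forward-FMI", "LASSO")
  name <- match.arg(name, valid)
  spec <- list(name = name)
  spec$cutoff <- switch(name, `Quickpred-pt2` = cutoff %||% 0.2,
                        `Quickpred-pt4` = cutoff %||% 0.4, NULL)
  if (name %in% c("PredMiss", "Forward", "Forward-sw")) {
    spec$alpha_sel <- alpha_sel %||% 0.05
  }
  if (name == "PcAux") spec$var_threshold <- var_threshold %||% 0.40
  if (name == "Forward-FMI") {
    spec$stop_frac <- stop_frac %||% 0.01
    spec$m_sel <- m_sel
  }
  if (name == "LASSO") spec$n_folds <- n_folds %||% 10L
  structure(spec, class = "strategy_spec")
}

#' The default strategy set of the study
#'
#' All ten analysis strategies: the two benchmarks (CCA, Full) and the eight
#' auxiliary-variable selection strategies. The Forward-FMI stopping fraction
#' is 0.5\% instead of 1\% when `p >= 333`.
#'
#' @param p Number of auxiliary variables in the scenario (sets the
#'   Forward-FMI stopping fraction).
#' @return A named list of [strategy_spec()] objects.
#' @export
default_strategies <- function(p = 25) {
  sf <- if (p >= 333) 0.005 else 0.01
  specs <- list(
    strategy_spec("CCA"), strategy_spec("Full"),
    strategy_spec("Quickpred-pt2"), strategy_spec("Quickpred-pt4"),
    strategy_spec("PredMiss"), strategy_spec("PcAux"),
    strategy_spec("Forward"), strategy_spec("Forward-sw"),
    strategy_spec("Forward-FMI", stop_frac = sf), strategy_spec("LASSO")
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

new_selection <- function(selected = character(0), derived = NULL,
                          diagnostics = NULL) {
  structure(list(selected = selected, derived_predictors = derived,
                 diagnostics = diagnostics),
            class = "selection_result")
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Quickpred correlation screening
#'
#' Selects auxiliary A_i iff the larger of |cor(A_i, Y)| over rows with Y
#' observed and |cor(A_i, M_Y)| over all rows strictly exceeds the cutoff
#' (Pearson correlations). Zero-variance auxiliaries contribute correlation
#' 0.
#'
#' @param data An `incomplete_data`.
#' @param cutoff Correlation cutoff (0.2 or 0.4 in the study).
#' @return A `selection_result`; diagnostics hold both correlations per
#'   candidate.
#' @export
select_quickpred <- function(data, cutoff = 0.2) {
  obs <- data$m_y == 0L
  if (sum(obs) < 3L || sum(!obs) < 3L) {
    stop("need at least 3 observed and 3 missing outcome values", call. = FALSE)
  }
  yobs <- data$y[obs]
  cy <- apply(data$aux[obs, , drop = FALSE], 2, safe_cor, b = yobs)
  cm <- apply(data$aux, 2, safe_cor, b = data$m_y)
  crit <- pmax(abs(cy), abs(cm))
  sel <- colnames(data$aux)[crit > cutoff]
  new_selection(sel, diagnostics = data.frame(
    candidate = colnames(data$aux), cor_y = cy, cor_miss = cm,
    criterion = crit, selected = crit > cutoff, row.names = NULL))
}

#' Selection by tests of the MCAR assumption (PredMiss)
#'
#' Selects auxiliary A_i iff a two-sample Welch t-test of A_i between the
#' missing (M_Y = 1) and observed (M_Y = 0) groups has p < `alpha_sel`:
#' a small p-value indicates the auxiliary predicts missingness, i.e. the
#' data are not missing completely at random with respect to it.
#'
#' @inheritParams select_quickpred
#' @param alpha_sel Selection test level.
#' @return A `selection_result` with per-candidate p-values in diagnostics.
#' @export
select_predmiss <- function(data, alpha_sel = 0.05) {
  stopifnot(is.numeric(alpha_sel), alpha_sel >= 0, alpha_sel <= 1)
  for (grp in 0:1) {
    if (sum(data$m_y == grp) < 2L) {
      stop(sprintf("missingness group M_Y = %d has fewer than 2 rows", grp),
           call. = FALSE)
    }
  }
  mis <- data$m_y == 1L
  pvals <- apply(data$aux, 2, function(a) {
    if (stats::sd(a[mis]) == 0 && stats::sd(a[!mis]) == 0) return(1)
    stats::t.test(a[mis], a[!mis])$p.value
  })
  sel <- colnames(data$aux)[pvals < alpha_sel]
  new_selection(sel, diagnostics = data.frame(
    candidate = colnames(data$aux), p_value = pvals,
    selected = pvals < alpha_sel, row.names = NULL))
}

#' Principal-component auxiliaries (PcAux)
#'
#' Standardizes the (fully observed) auxiliaries, eigendecomposes their
#' correlation matrix and returns as derived predictors the first k
#' principal-component score vectors, where k is the smallest number of
#' components whose cumulative eigenvalue fraction reaches `var_threshold`.
#' No individual auxiliaries are selected; the components replace them in the
#' imputation model.
#'
#' @inheritParams select_quickpred
#' @param var_threshold Required fraction of total auxiliary variance.
#' @return A `selection_result` whose `derived_predictors` are the PC scores
#'   (columns PC1..PCk).
#' @export
select_pcaux <- function(data, var_threshold = 0.40) {
  if (data$p == 0L) stop("no auxiliary variables", call. = FALSE)
  if (anyNA(data$aux)) stop("auxiliaries must be fully observed", call. = FALSE)
  Astd <- scale(data$aux)
  Astd[, attr(Astd, "scale") == 0] <- 0
  R <- stats::cor(data$aux)
  R[!is.finite(R)] <- 0; diag(R) <- 1
  e <- eigen(R, symmetric = TRUE)
  frac <- cumsum(pmax(e$values, 0)) / sum(pmax(e$values, 0))
  k <- which(frac >= var_threshold - 1e-12)[1]
  scores <- Astd %*% e$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  new_selection(character(0), derived = scores,
                diagnostics = data.frame(component = seq_along(e$values),
                                         eigenvalue = e$values,
                                         cum_var_frac = frac))
}

# Wald p-values for a least-squares fit of yobs on the named columns; NA for
# aliased coefficients.
forward_fit_pvals <- function(data, cols, obs) {
  D <- cbind(1, predictor_matrix(data, cols))
  Dobs <- D[obs, , drop = FALSE]
  yobs <- data$y[obs]
  fit <- stats::lm.fit(Dobs, yobs)
  q <- fit$rank
  n_obs <- length(yobs)
  if (n_obs <= q + 1L) return(NULL)
  piv <- fit$qr$pivot[seq_len(q)]
  s2 <- sum(fit$residuals^2) / (n_obs - q)
  Rinv <- backsolve(qr.R(fit$qr)[seq_len(q), seq_len(q), drop = FALSE],
                    diag(q))
  se <- rep(NA_real_, ncol(D))
  se[piv] <- sqrt(s2 * rowSums(Rinv^2))
  tval <- fit$coefficients / se
  p <- 2 * stats::pt(abs(tval), df = n_obs - q, lower.tail = FALSE)
  stats::setNames(p[-1], cols)
}

# Wald p-values for adding each remaining candidate to the current model,
# computed in one pass via partial correlations: the t-statistic of a newly
# added column equals r * sqrt(df / (1 - r^2)) where r is the partial
# correlation of the candidate with Y given the current design and
# df = n_obs - q_current - 1. Exactly equivalent to refitting with each
# candidate; candidates collinear with the current design get NA.
forward_add_pvals <- function(yobs, Dcur, Ccand) {
  n_obs <- length(yobs)
  qrD <- qr(Dcur)
  q <- qrD$rank
  df <- n_obs - q - 1L
  if (df < 1L) return(NULL)
  ry <- qr.resid(qrD, yobs)
  Rc <- qr.resid(qrD, Ccand)
  ss_y <- sum(ry^2)
  ss_c <- colSums(Rc^2)
  rho <- colSums(Rc * ry) / sqrt(pmax(ss_c * ss_y, .Machine$double.xmin))
  rho[ss_c < 1e-10 * n_obs | ss_y == 0] <- NA_real_
  rho <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tval <- rho * sqrt(df / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  stats::setNames(p, colnames(Ccand))
}

#' Forward (stepwise) selection of predictors of Y
#'
#' Forward selection for the regression of the observed Y on X and Z (always
#' retained) plus candidate auxiliaries. At each step the candidate with the
#' smallest Wald p-value is added if that p-value is below `alpha_sel`
#' (ties broken by candidate index). With `allow_removal` (the Forward-sw
#' strategy), after each addition any previously selected auxiliary whose
#' p-value is no longer below `alpha_sel` is removed (X and Z are never
#' removed). Selection runs on the rows with Y observed. Candidates whose
#' addition makes the design singular are skipped.
#'
#' @inheritParams select_predmiss
#' @param allow_removal Logical; enable the removal step.
#' @return A `selection_result`; diagnostics trace each addition/removal.
#' @export
select_forward <- function(data, alpha_sel = 0.05, allow_removal = FALSE) {
  stopifnot(is.numeric(alpha_sel), alpha_sel >= 0, alpha_sel <= 1,
            is.logical(allow_removal))
  obs <- data$m_y == 0L
  yobs <- data$y[obs]
  candidates <- colnames(data$aux)
  selected <- character(0)
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    if (sum(obs) <= 3L + length(selected) + 1L) break
    Dcur <- cbind(1, predictor_matrix(data, c("X", "Z", selected)))[obs, , drop = FALSE]
    pv <- forward_add_pvals(yobs, Dcur, data$aux[obs, remaining, drop = FALSE])
    if (is.null(pv) || all(!is.finite(pv))) break
    best_i <- which.min(pv)  # first minimum: lowest candidate index wins ties
    pbest <- pv[[best_i]]; best <- remaining[best_i]
    if (!is.finite(pbest) || pbest >= alpha_sel) break
    selected <- c(selected, best)
    trace[[length(trace) + 1L]] <- data.frame(step = length(trace) + 1L,
                                              action = "add", variable = best,
                                              p_value = pbest)
    if (allow_removal) {
      repeat {
        pv <- forward_fit_pvals(data, c("X", "Z", selected), obs)
        paux <- pv[selected]
        drop_idx <- which(!is.finite(paux) | paux >= alpha_sel)
        if (length(drop_idx) == 0L) break
        worst <- selected[drop_idx[which.max(paux[drop_idx])]]
        trace[[length(trace) + 1L]] <- data.frame(
          step = length(trace) + 1L, action = "remove", variable = worst,
          p_value = unname(paux[worst]))
        selected <- setdiff(selected, worst)
        if (length(selected) == 0L) break
      }
    }
  }
  new_selection(selected,
                diagnostics = if (length(trace)) do.call(rbind, trace)
                              else data.frame(step = integer(0),
                                              action = character(0),
                                              variable = character(0),
                                              p_value = numeric(0)))
}

#' Build a proxy predictor from an auxiliary subset
#'
#' Fits least squares of the observed Y on an intercept plus the named
#' auxiliaries and returns the fitted values for all n rows. Because the
#' auxiliaries are fully observed the proxy is complete by construction; it
#' carries the subset's information about Y into the imputation model as a
#' single column.
#'
#' @param data An `incomplete_data`.
#' @param subset Nonempty character vector of auxiliary labels.
#' @return Numeric vector of length n (the proxy variable).
#' @export
build_proxy <- function(data, subset) {
  if (length(subset) == 0L) stop("subset must be nonempty", call. = FALSE)
  obs <- data$m_y == 0L
  if (sum(obs) <= length(subset) + 2L) {
    stop("too few observed outcomes for the proxy regression", call. = FALSE)
  }
  D <- cbind(1, data$aux[, subset, drop = FALSE])
  fit <- stats::lm.fit(D[obs, , drop = FALSE], data$y[obs])
  if (fit$rank < ncol(D)) stop("proxy design is singular", call. = FALSE)
  drop(D %*% fit$coefficients)
}

#' Forward selection on the fraction of missing information (Forward-FMI)
#'
#' Greedy forward selection that scores candidate imputation models by the
#' estimated fraction of missing information (FMI) for the mean of Y. In the
#' first step each auxiliary A_j is scored by imputing with predictors
#' {X, Z, A_j} and pooling the mean; the auxiliary with the smallest FMI is
#' selected. In later steps each remaining A_j is scored by the proxy
#' variable built from the selected set plus A_j ([build_proxy()]), imputing
#' with {X, Z, proxy}. A candidate is accepted while the FMI reduction is at
#' least `stop_frac` times the observed missingness proportion of Y; common
#' random numbers (one seed per step) keep candidate comparisons stable, and
#' ties go to the lowest candidate index.
#'
#' @inheritParams select_quickpred
#' @param stop_frac Stopping fraction of the missingness proportion.
#' @param m_sel Number of imputations per candidate evaluation.
#' @param seed Seed governing all imputation draws in the search.
#' @return A `selection_result`; diagnostics record the FMI path.
#' @export
select_forward_fmi <- function(data, stop_frac = 0.01, m_sel = 30, seed = NULL) {
  if (data$p < 1L) stop("need at least one auxiliary", call. = FALSE)
  threshold <- stop_frac * mean(data$m_y)
  candidates <- colnames(data$aux)
  selected <- character(0)
  path <- list()
  fmi_prev <- Inf
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    step_seed <- if (is.null(seed)) NULL else derive_seeds(seed, 1L, paste0("fmi_step", step))
    fmis <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      cand <- remaining[i]
      res <- tryCatch({
        if (length(selected) == 0L) {
          impute_and_pool(data, c("X", "Z", cand), m = m_sel,
                          seed = step_seed, estimands = "mean")
        } else {
          proxy <- build_proxy(data, c(selected, cand))
          impute_and_pool(data, c("X", "Z", "proxy"), m = m_sel,
                          extra = cbind(proxy = proxy),
                          seed = step_seed, estimands = "mean")
        }
      }, error = function(e) NULL)
      if (!is.null(res)) fmis[i] <- res$mean$fmi
    }
    if (all(is.na(fmis))) {
      if (length(selected) == 0L) {
        stop("all Forward-FMI candidate imputations failed", call. = FALSE)
      }
      break
    }
    best_i <- which.min(fmis)  # which.min takes the first (lowest index) tie
    fmi_best <- fmis[best_i]
    accept <- if (length(selected) == 0L) TRUE else
      (fmi_prev - fmi_best) >= threshold
    path[[step]] <- data.frame(step = step, candidate = remaining[best_i],
                               fmi = fmi_best, accepted = accept)
    if (!accept) break
    selected <- c(selected, remaining[best_i])
    fmi_prev <- fmi_best
  }
  derived <- NULL
  if (length(selected) > 1L) {
    derived <- cbind(proxy = build_proxy(data, selected))
  }
  new_selection(selected, derived = derived,
                diagnostics = do.call(rbind, path))
}

#' LASSO auxiliary selection
#'
#' On the rows with Y observed, fits an L1-penalized least-squares path for Y
#' on (X, Z, A1..Ap) with X and Z unpenalized (they are unconditionally part
#' of every imputation model), chooses the penalty by `n_folds`-fold
#' cross-validation with the one-standard-error rule, and selects the
#' auxiliaries with nonzero coefficients at that penalty. The penalized fit
#' is used only for selection, never to parameterize the imputation model.
#'
#' @inheritParams select_quickpred
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed fixing the fold assignment.
#' @return A `selection_result`; diagnostics hold the chosen penalty.
#' @export
select_lasso <- function(data, n_folds = 10, seed = NULL) {
  obs <- data$m_y == 0L
  n_obs <- sum(obs)
  if (n_obs < n_folds) stop("fewer observed outcomes than folds", call. = FALSE)
  yobs <- data$y[obs]
  if (stats::sd(yobs) == 0) return(new_selection(character(0)))
  Xmat <- cbind(X = data$x, Z = data$z, data$aux)[obs, , drop = FALSE]
  foldid <- local_seed(seed, sample(rep(seq_len(n_folds), length.out = n_obs)))
  cv <- glmnet::cv.glmnet(Xmat, yobs, family = "gaussian",
                          penalty.factor = c(0, 0, rep(1, data$p)),
                          foldid = foldid, standardize = TRUE)
  cf <- stats::coef(cv, s = "lambda.1se")
  nz <- rownames(cf)[which(as.numeric(cf) != 0)]
  sel <- intersect(colnames(data$aux), nz)
  new_selection(sel, diagnostics = data.frame(
    lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
    n_selected = length(sel)))
}

#' Apply one analysis strategy to an incomplete dataset
#'
#' Runs the strategy end to end and returns one estimate record per estimand
#' (the marginal mean of Y and the exposure coefficient betaX). CCA analyzes
#' the rows with Y observed directly, with t-based 95\% intervals. Every MI
#' strategy imputes with predictors X and Z plus its selection output
#' (auxiliaries, principal-component scores, or the Forward-FMI proxy),
#' analyzes each completed dataset, and pools by Rubin's rules. If there are
#' no missing outcome values the MI estimate is the complete-data estimate
#' (no imputation is performed). Imputation failures are caught and recorded
#' as non-converged rows, feeding the convergence-rate performance measure.
#'
#' @param data An `incomplete_data`.
#' @param spec A [strategy_spec()].
#' @param m Number of imputations.
#' @param seed Seed for selection (where stochastic) and imputation draws.
#' @return A data.frame with one row per estimand: `strategy`, `estimand`
#'   (`"muY"`, `"betaX"`), `estimate`, `se`, `ci_low`, `ci_high`, `df`,
#'   `fmi`, `n_selected`, `n_predictors`, `converged`.
#' @export
apply_strategy <- function(data, spec, m = 30, seed = NULL) {
  stopifnot(inherits(spec, "strategy_spec"), inherits(data, "incomplete_data"))
  record <- function(estimand, est, se, lo, hi, df, fmi, nsel, npred,
                     converged = TRUE) {
    data.frame(strategy = spec$name, estimand = estimand, estimate = est,
               se = se, ci_low = lo, ci_high = hi, df = df, fmi = fmi,
               n_selected = nsel, n_predictors = npred, converged = converged,
               stringsAsFactors = FALSE)
  }

  if (spec$name == "CCA") {
    obs <- data$m_y == 0L
    yo <- data$y[obs]
    n_obs <- length(yo)
    mn <- complete_data_analysis(yo, data$x[obs], data$z[obs], "mean")
    rg <- complete_data_analysis(yo, data$x[obs], data$z[obs], "regression")
    tc1 <- stats::qt(0.975, mn$df)
    tc2 <- stats::qt(0.975, rg$df)
    return(rbind(
      record("muY", mn$estimate, sqrt(mn$variance),
             mn$estimate - tc1 * sqrt(mn$variance),
             mn$estimate + tc1 * sqrt(mn$variance), mn$df, NA_real_,
             NA_integer_, NA_integer_),
      record("betaX", rg$estimate, sqrt(rg$variance),
             rg$estimate - tc2 * sqrt(rg$variance),
             rg$estimate + tc2 * sqrt(rg$variance), rg$df, NA_real_,
             NA_integer_, NA_integer_)))
  }

  seeds <- derive_seeds(seed %||% 1L, 2L, paste0("strategy_", spec$name))
  sel_seed <- seeds[1]; imp_seed <- seeds[2]

  res <- tryCatch({
    sel <- switch(spec$name,
      "Full" = new_selection(colnames(data$aux)),
      "Quickpred-pt2" = select_quickpred(data, spec$cutoff),
      "Quickpred-pt4" = select_quickpred(data, spec$cutoff),
      "PredMiss" = select_predmiss(data, spec$alpha_sel),
      "PcAux" = select_pcaux(data, spec$var_threshold),
      "Forward" = select_forward(data, spec$alpha_sel, allow_removal = FALSE),
      "Forward-sw" = select_forward(data, spec$alpha_sel, allow_removal = TRUE),
      "Forward-FMI" = select_forward_fmi(data, spec$stop_frac,
                                         m_sel = spec$m_sel %||% m,
                                         seed = sel_seed),
      "LASSO" = select_lasso(data, spec$n_folds, seed = sel_seed)
    )
    # Imputation predictors: X and Z always, plus the strategy's output.
    if (!is.null(sel$derived_predictors)) {
      extra <- sel$derived_predictors
      aux_pred <- colnames(extra)
    } else {
      extra <- NULL
      aux_pred <- sel$selected
    }
    predictors <- c("X", "Z", aux_pred)
    if (sum(data$m_y) == 0L) {
      mn <- complete_data_analysis(data$y, data$x, data$z, "mean")
      rg <- complete_data_analysis(data$y, data$x, data$z, "regression")
      tc1 <- stats::qt(0.975, mn$df); tc2 <- stats::qt(0.975, rg$df)
      list(sel = sel, n_pred = length(predictors),
           mean = list(qbar = mn$estimate, se = sqrt(mn$variance),
                       ci_low = mn$estimate - tc1 * sqrt(mn$variance),
                       ci_high = mn$estimate + tc1 * sqrt(mn$variance),
                       df = mn$df, fmi = 0),
           regression = list(qbar = rg$estimate, se = sqrt(rg$variance),
                             ci_low = rg$estimate - tc2 * sqrt(rg$variance),
                             ci_high = rg$estimate + tc2 * sqrt(rg$variance),
                             df = rg$df, fmi = 0))
    } else {
      pooled <- impute_and_pool(data, predictors, m = m, extra = extra,
                                seed = imp_seed)
      list(sel = sel, n_pred = length(predictors),
           mean = pooled$mean, regression = pooled$regression)
    }
  }, error = function(e) e)

  if (inherits(res, "error")) {
    return(rbind(
      record("muY", NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
             NA_real_, NA_integer_, NA_integer_, converged = FALSE),
      record("betaX", NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
             NA_real_, NA_integer_, NA_integer_, converged = FALSE)))
  }
  nsel <- length(res$sel$selected)
  if (!is.null(res$sel$derived_predictors) && nsel == 0L) {
    nsel <- ncol(res$sel$derived_predictors)
  }
  rbind(
    record("muY", res$mean$qbar, res$mean$se, res$mean$ci_low,
           res$mean$ci_high, res$mean$df, res$mean$fmi, nsel, res$n_pred),
    record("betaX", res$regression$qbar, res$regression$se,
           res$regression$ci_low, res$regression$ci_high, res$regression$df,
           res$regression$fmi, nsel, res$n_pred))
}
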