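# Multiple imputation engine for a single incomplete continuous outcome:
# proper Bayesian linear-regression imputation, complete-data analyses, and
# Rubin's-rules pooling with Barnard-Rubin degrees of freedom.

# Assemble the n x q predictor matrix (no intercept) for the named columns.
# `predictors` may name X, Z, auxiliaries (A1..Ap) and columns of the
# optional `extra` matrix of derived predictors (proxy variables, principal
# component scores), which must be complete.
predictor_matrix <- function(data, predictors, extra = NULL) {
  if (length(predictors) == 0) {
    return(matrix(numeric(0), nrow = data$n, ncol = 0))
  }
  cols <- lapply(predictors, function(nm) {
    if (nm == "X") return(data$x)
    if (nm == "Z") return(data$z)
    if (nm %in% colnames(data$aux)) return(data$aux[, nm])
    if (!is.null(extra) && nm %in% colnames(extra)) return(extra[, nm])
    stop(sprintf("unknown predictor '%s'", nm), call. = FALSE)
  })
  out <- do.call(cbind, cols)
  colnames(out) <- predictors
  if (anyNA(out)) stop("predictors must be fully observed", call. = FALSE)
  out
}

#' Proper Bayesian linear-regression imputation draw
#'
#' One "norm" draw for the missing values of Y: least squares of the observed
#' Y on an intercept plus the named predictors, a draw of the residual
#' variance sigma*^2 from resid_SS / chi^2(n_obs - q), a draw of the
#' coefficients beta* from N(beta_hat, sigma*^2 (D'D)^{-1}), and imputations
#' x_mis' beta* + sigma* epsilon with standard-normal epsilon. Observed
#' entries of Y are returned untouched. When the cross-product matrix is
#' near-singular (condition number > 1e8) its diagonal is inflated by a
#' relative ridge of 1e-5.
#'
#' With a single incomplete variable this one draw is an exact sample from
#' the posterior predictive distribution; no chained-equations iteration is
#' needed.
#'
#' @param data An `incomplete_data`.
#' @param predictors Character labels of the imputation-model predictors
#'   (excluding the intercept).
#' @param extra Optional named matrix of derived predictors (complete).
#' @param seed Optional seed for the draw.
#' @return A completed numeric outcome vector of length n.
#' @export
bayes_draw_impute <- function(data, predictors, extra = NULL, seed = NULL) {
  fit <- norm_draw_setup(data, predictors, extra)
  local_seed(seed, norm_draw_one(fit))
}

# Deterministic part of the norm draw, shared across the m imputations of
# multiple_impute(): observed-data least squares and Cholesky factors.
norm_draw_setup <- function(data, predictors, extra = NULL) {
  stopifnot(inherits(data, "incomplete_data"))
  obs <- data$m_y == 0L
  n_obs <- sum(obs)
  P <- predictor_matrix(data, predictors, extra)
  q <- ncol(P) + 1L  # intercept included
  if (n_obs <= length(predictors) + 2L) {
    stop(structure(class = c("auximp_mi_failure", "error", "condition"),
                   list(message = sprintf(
                     "too few observed outcomes (%d) for %d predictors",
                     n_obs, length(predictors)),
                     call = NULL)))
  }
  D <- cbind(`(Intercept)` = 1, P)
  Dobs <- D[obs, , drop = FALSE]
  yobs <- data$y[obs]
  cross <- crossprod(Dobs)
  if (kappa(cross, exact = FALSE) > 1e8) {
    diag(cross) <- diag(cross) + 1e-5 * diag(cross)
  }
  R <- tryCatch(chol(cross), error = function(e) {
    stop(structure(class = c("auximp_mi_failure", "error", "condition"),
                   list(message = "imputation design matrix is singular",
                        call = NULL)))
  })
  beta_hat <- backsolve(R, forwardsolve(t(R), crossprod(Dobs, yobs)))
  ss <- sum((yobs - drop(Dobs %*% beta_hat))^2)
  list(y = data$y, mis = !obs, Dmis = D[!obs, , drop = FALSE],
       R = R, beta_hat = beta_hat, ss = ss, nu = n_obs - q, q = q)
}

norm_draw_one <- function(fit) {
  y <- fit$y
  n_mis <- sum(fit$mis)
  if (n_mis == 0L) return(y)
  sigma2 <- fit$ss / stats::rchisq(1, df = fit$nu)
  beta_star <- fit$beta_hat +
    sqrt(sigma2) * backsolve(fit$R, stats::rnorm(fit$q))
  y[fit$mis] <- drop(fit$Dmis %*% beta_star) +
    sqrt(sigma2) * stats::rnorm(n_mis)
  y
}

#' Multiply impute the incomplete outcome
#'
#' Performs `m` independent [bayes_draw_impute()] draws, each on its own
#' derived sub-stream of `seed`.
#'
#' @inheritParams bayes_draw_impute
#' @param m Number of imputations (at least 2).
#' @return An object of class `imputation_set`: list with `completed`
#'   (an n x m matrix of completed outcome vectors), `predictors` and `m`.
#' @export
multiple_impute <- function(data, predictors, m, extra = NULL, seed = NULL) {
  stopifnot(m >= 2)
  fit <- norm_draw_setup(data, predictors, extra)
  seeds <- if (is.null(seed)) rep(list(NULL), m) else derive_seeds(seed, m, "impute")
  completed <- vapply(seq_len(m),
                      function(i) local_seed(seeds[[i]], norm_draw_one(fit)),
                      numeric(data$n))
  structure(list(completed = completed, predictors = predictors, m = as.integer(m)),
            class = "imputation_set")
}

#' Complete-data analysis of one completed dataset
#'
#' The two estimands of the study: the marginal mean of Y (estimate ybar,
#' variance s^2/n, df n-1) and the exposure coefficient betaX from least
#' squares of Y on X and Z with intercept (classical variance estimate,
#' df n-3).
#'
#' @param y Completed outcome vector (no missing values).
#' @param x,z Exposure and covariate vectors.
#' @param estimand `"mean"` or `"regression"`.
#' @return List with `estimate`, `variance` and the complete-data `df`.
#' @export
complete_data_analysis <- function(y, x, z, estimand = c("mean", "regression")) {
  estimand <- match.arg(estimand)
  if (anyNA(y)) stop("completed outcome must have no missing values", call. = FALSE)
  n <- length(y)
  if (estimand == "mean") {
    v <- if (n > 1) stats::var(y) / n else 0
    return(list(estimate = mean(y), variance = v, df = n - 1))
  }
  D <- cbind(1, x, z)
  qrD <- qr(D)
  if (qrD$rank < 3L) stop("X and Z are collinear", call. = FALSE)
  coefs <- qr.coef(qrD, y)
  res <- y - drop(D %*% coefs)
  s2 <- sum(res^2) / (n - 3)
  XtXinv <- chol2inv(qr.R(qrD))
  list(estimate = coefs[[2]], variance = s2 * XtXinv[2, 2], df = n - 3)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines m complete-data estimates and variances: pooled estimate
#' qbar = mean of the estimates, within-imputation variance w = mean of the
#' variances, between-imputation variance b = sample variance of the
#' estimates, total variance t = w + (1 + 1/m) b. The fraction of missing
#' information is (b + b/m) / t (the finite-m estimator; the large-m variant
#' b/t is also returned as `fmi_simple`). Degrees of freedom follow the
#' Barnard-Rubin small-sample adjustment against the complete-data df, and
#' the 95\% interval uses the t quantile at those df.
#'
#' @param estimates Numeric vector of m complete-data estimates.
#' @param variances Numeric vector of m complete-data variances.
#' @param df_com Complete-data degrees of freedom (e.g. n-1 for a mean).
#' @param conf_level Confidence level of the pooled interval.
#' @return An object of class `pooled_estimate` with fields `qbar`, `w`, `b`,
#'   `t`, `df`, `se`, `ci_low`, `ci_high`, `fmi`, `fmi_simple`, `m`.
#' @examples
#' pool_rubin(c(0, 1), c(1, 1), df_com = 100)  # t = 1.75, fmi = 0.75/1.75
#' @export
pool_rubin <- function(estimates, variances, df_com = Inf, conf_level = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m)
  qbar <- mean(estimates)
  w <- mean(variances)
  b <- stats::var(estimates)
  t_var <- w + (1 + 1 / m) * b
  if (b <= 0 || t_var <= 0) {
    fmi <- 0
    fmi_simple <- 0
    df <- df_com
  } else {
    fmi <- (b + b / m) / t_var
    fmi_simple <- b / t_var
    df_old <- (m - 1) / fmi^2
    if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - fmi)
      df <- df_old * df_obs / (df_old + df_obs)
    } else {
      df <- df_old
    }
  }
  df <- min(df, df_com)
  se <- sqrt(t_var)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  structure(list(qbar = qbar, w = w, b = b, t = t_var, df = df, se = se,
                 ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
                 fmi = fmi, fmi_simple = fmi_simple, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$qbar, x$se, x$ci_low, x$ci_high))
  cat(sprintf("  m = %d, W = %.4g, B = %.4g, T = %.4g, df = %.1f, FMI = %.3f\n",
              x$m, x$w, x$b, x$t, x$df, x$fmi))
  invisible(x)
}

# Impute, analyze both estimands in each completed dataset, and pool.
# Returns the two pooled_estimate objects plus bookkeeping; used by
# apply_strategy() and select_forward_fmi().
impute_and_pool <- function(data, predictors, m, extra = NULL, seed = NULL,
                            estimands = c("mean", "regression")) {
  imp <- multiple_impute(data, predictors, m, extra = extra, seed = seed)
  out <- lapply(estimands, function(est) {
    res <- apply(imp$completed, 2, function(y)
      complete_data_analysis(y, data$x, data$z, est))
    df_com <- res[[1]]$df
    pool_rubin(vapply(res, `[[`, numeric(1), "estimate"),
               vapply(res, `[[`, numeric(1), "variance"),
               df_com = df_com)
  })
  names(out) <- estimands
  out
}
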