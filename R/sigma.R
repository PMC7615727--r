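#' Construct the scenario correlation matrix
#'
#' Builds the (p+3) x (p+3) correlation matrix Sigma governing the joint
#' multivariate-normal distribution of (Y, X, Z, A1..Ap). Auxiliary variables
#' fall into three groups whose correlations with Y are evenly spaced on
#' `group_mean_cor[g] +/- spread`, so each group's mean correlation with Y
#' equals its target exactly. The remaining structure is exchangeable:
#' `cor_aa_within` between auxiliaries in the same group, `cor_aa_between`
#' otherwise, and a common small correlation of each auxiliary with X and Z.
#'
#' The exposure-outcome correlation is then calibrated so that a two-sided
#' test of the exposure coefficient in the regression of Y on (X, Z) attains
#' `cfg$target_power` at level `cfg$alpha` for the scenario's sample size; see
#' [calibrate_power()] for the two calibration bases. If the assembled matrix
#' is indefinite it is repaired with [nearest_correlation()] and the group
#' means and power calibration are re-verified.
#'
#' @param cfg A [scenario_config()].
#' @param cor_yz,cor_xz Correlations of Y and X with the confounder Z.
#' @param cor_ax,cor_az Correlation of every auxiliary with X and with Z.
#' @param cor_aa_within,cor_aa_between Exchangeable auxiliary correlations
#'   within and between groups.
#' @param spread Half-width of the even spacing of cor(Y, A_i) around the
#'   group mean.
#' @param calibrate Calibrate cor(Y, X) for power? If `FALSE`, `cor_yx` is
#'   used as given.
#' @param cor_yx Exposure-outcome correlation when `calibrate = FALSE`.
#' @param power_basis Passed to [calibrate_power()]; the default `"design"`
#'   uses the design-stage formula with unit residual variance.
#' @return An object of class `cor_design`: a list with the matrix `values`
#'   (dimnames Y, X, Z, A1..Ap), the auxiliary `group_assignment`, and the
#'   generating `cfg`.
#' @examples
#' sig <- build_sigma(scenario_config(250, 25))
#' conditional_regression(sig)$betaX
#' @export
build_sigma <- function(cfg,
                        cor_yz = 0.1, cor_xz = 0.1,
                        cor_ax = 0.1, cor_az = 0.1,
                        cor_aa_within = 0.3, cor_aa_between = 0.1,
                        spread = 0.05,
                        calibrate = TRUE, cor_yx = 0.1,
                        power_basis = c("design", "exact")) {
  validate_scenario(cfg)
  power_basis <- match.arg(power_basis)
  p <- cfg$p
  group <- rep(1:3, cfg$group_sizes)
  ycor <- unlist(lapply(1:3, function(g) {
    k <- cfg$group_sizes[g]
    mu <- cfg$group_mean_cor[g]
    if (k == 1L) mu else seq(mu - spread, mu + spread, length.out = k)
  }), use.names = FALSE)

  d <- p + 3L
  S <- matrix(cor_aa_between, d, d)
  idx_a <- 4:d
  for (g in 1:3) {
    ia <- idx_a[group == g]
    S[ia, ia] <- cor_aa_within
  }
  S[1, idx_a] <- S[idx_a, 1] <- ycor
  S[2, idx_a] <- S[idx_a, 2] <- cor_ax
  S[3, idx_a] <- S[idx_a, 3] <- cor_az
  S[1, 3] <- S[3, 1] <- cor_yz
  S[2, 3] <- S[3, 2] <- cor_xz
  S[1, 2] <- S[2, 1] <- cor_yx
  diag(S) <- 1
  labs <- c("Y", "X", "Z", paste0("A", seq_len(p)))
  dimnames(S) <- list(labs, labs)

  out <- new_cor_design(S, group, cfg)
  if (calibrate) {
    out <- calibrate_power(out, n = cfg$n, target_power = cfg$target_power,
                           alpha = cfg$alpha, basis = power_basis)
  }
  for (attempt in 1:3) {
    ev <- min(eigen(out$values, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= -1e-8) break
    out$values <- nearest_correlation(out$values)
    check_group_means(out, tol = 0.01)
    if (calibrate) {
      out <- calibrate_power(out, n = cfg$n, target_power = cfg$target_power,
                             alpha = cfg$alpha, basis = power_basis)
    }
  }
  ev <- min(eigen(out$values, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    stop(sprintf(
      "correlation design infeasible: smallest eigenvalue %.3g < -1e-8 after repair",
      ev), call. = FALSE)
  }
  check_group_means(out, tol = 0.01)
  out
}

new_cor_design <- function(values, group_assignment, cfg = NULL) {
  structure(list(values = values, group_assignment = group_assignment,
                 cfg = cfg),
            class = "cor_design")
}

check_group_means <- function(sigma, tol = 0.01) {
  cfg <- sigma$cfg
  if (is.null(cfg)) return(invisible(TRUE))
  ycor <- sigma$values[1, -(1:3)]
  for (g in 1:3) {
    mu <- mean(ycor[sigma$group_assignment == g])
    if (abs(mu - cfg$group_mean_cor[g]) > tol) {
      stop(sprintf("group %d mean cor(Y, A) = %.4f misses target %.2f by > %.2f",
                   g, mu, cfg$group_mean_cor[g], tol), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.cor_design <- function(x, ...) {
  d <- ncol(x$values)
  cat(sprintf("Correlation design: %d x %d (Y, X, Z, %d auxiliaries)\n",
              d, d, d - 3L))
  cat(sprintf("  cor(Y,X) = %.4f, cor(Y,Z) = %.3f\n",
              x$values[1, 2], x$values[1, 3]))
  for (g in 1:3) {
    cat(sprintf("  group %d: %d auxiliaries, mean cor with Y = %.3f\n", g,
                sum(x$group_assignment == g),
                mean(x$values[1, -(1:3)][x$group_assignment == g])))
  }
  ev <- min(eigen(x$values, symmetric = TRUE, only.values = TRUE)$values)
  cat(sprintf("  smallest eigenvalue %.4g\n", ev))
  invisible(x)
}

#' Nearest correlation matrix
#'
#' Projects a symmetric unit-diagonal matrix onto the set of positive
#' semidefinite correlation matrices under the Frobenius norm, using Higham's
#' alternating-projections scheme (via [Matrix::nearPD()]). Matrices that are
#' already positive semidefinite are returned unchanged.
#'
#' @param values Symmetric numeric matrix with unit diagonal.
#' @param tol Eigenvalue tolerance below which the input counts as PSD.
#' @return A correlation matrix of the same dimension.
#' @export
nearest_correlation <- function(values, tol = 1e-8) {
  if (!isSymmetric(unname(values), tol = 1e-10)) {
    stop("input must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(values) - 1)) > 1e-10) {
    stop("input must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(values, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol && min(ev) >= 0) return(values)
  if (min(ev) >= -tol) {
    # within tolerance but numerically negative: leave as is
    return(values)
  }
  res <- Matrix::nearPD(values, corr = TRUE, keepDiag = TRUE,
                        maxit = 1000, conv.tol = 1e-10)
  out <- as.matrix(res$mat)
  dimnames(out) <- dimnames(values)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  gap <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (!res$converged && gap < -tol) {
    stop(sprintf("nearest-correlation projection did not converge; eigenvalue gap %.3g",
                 gap), call. = FALSE)
  }
  out
}

#' Export a correlation design as CSV
#'
#' Writes the correlation matrix with a header row naming Y, X, Z, A1..Ap and
#' a leading column of the same names.
#'
#' @param sigma A `cor_design` or a plain correlation matrix.
#' @param path Output file path.
#' @export
write_sigma_csv <- function(sigma, path) {
  S <- if (inherits(sigma, "cor_design")) sigma$values else sigma
  df <- data.frame(variable = rownames(S), S, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
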