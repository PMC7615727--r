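#' Draw a complete multivariate-normal dataset
#'
#' Simulates `n` independent rows of (Y, X, Z, A1..Ap) from a multivariate
#' normal with mean zero and the given correlation matrix, via
#' [MASS::mvrnorm()] (eigendecomposition method).
#'
#' @param sigma A `cor_design` or correlation matrix ordered (Y, X, Z, A...).
#' @param n Number of rows.
#' @param seed Optional seed; the draw is reproducible given the seed and the
#'   caller's RNG state is left untouched.
#' @return An object of class `complete_data`: list with vectors `y`, `x`,
#'   `z`, an `n x p` matrix `aux` (columns A1..Ap), and counts `n`, `p`.
#' @export
draw_complete <- function(sigma, n, seed = NULL) {
  S <- if (inherits(sigma, "cor_design")) sigma$values else sigma
  d <- ncol(S)
  p <- d - 3L
  if (n < p + 3L) {
    message(sprintf("n = %d < p + 3 = %d: downstream selection fits may be rank deficient",
                    n, p + 3L))
  }
  M <- local_seed(seed, MASS::mvrnorm(n, mu = rep(0, d), Sigma = S))
  M <- matrix(M, nrow = n, ncol = d)  # mvrnorm drops dims when n = 1
  aux <- M[, -(1:3), drop = FALSE]
  colnames(aux) <- if (p > 0) paste0("A", seq_len(p)) else NULL
  structure(list(y = M[, 1], x = M[, 2], z = M[, 3], aux = aux,
                 n = as.integer(n), p = p),
            class = "complete_data")
}

#' Specify the missingness model
#'
#' Builds the coefficient set of the logistic missingness model
#' logit P(M_Y = 1) = gamma0 + gammaX X + gammaZ Z + gammaA' A. The slope on
#' X, Z and on the auxiliaries chosen to drive missingness is log(miss_or);
#' the first floor(size/2) auxiliaries of each group (by index) carry the
#' nonzero coefficient, so half of each group is associated with missingness.
#' The intercept is left NA until [calibrate_gamma0()] fixes it.
#'
#' @param sigma A `cor_design` (provides the group assignment), or an integer
#'   group vector.
#' @param miss_or Odds ratio of missingness per 1-SD increase.
#' @return An object of class `missingness_model` with `gamma0`, `gammaX`,
#'   `gammaZ`, `gammaA` and the logical `aux_miss_mask`.
#' @export
missingness_model <- function(sigma, miss_or = 1.2) {
  group <- if (inherits(sigma, "cor_design")) sigma$group_assignment else sigma
  p <- length(group)
  mask <- logical(p)
  for (g in unique(group)) {
    idx <- which(group == g)
    mask[idx[seq_len(length(idx) %/% 2L)]] <- TRUE
  }
  gam <- log(miss_or)
  structure(list(gamma0 = NA_real_, gammaX = gam, gammaZ = gam,
                 gammaA = ifelse(mask, gam, 0), aux_miss_mask = mask,
                 miss_or = miss_or),
            class = "missingness_model")
}

#' Calibrate the missingness-model intercept
#'
#' Solves E[expit(gamma0 + eta)] = `target` for gamma0, where
#' eta = gammaX X + gammaZ Z + gammaA' A is normal with mean 0 and variance
#' g' Sigma_{-Y} g under the design (g the slope vector over (X, Z, A),
#' Sigma_{-Y} the correlation sub-matrix excluding Y). The expectation is
#' evaluated by Gauss-Hermite quadrature and the root located by
#' [stats::uniroot()] to |E - target| < 1e-8.
#'
#' @param model A [missingness_model()].
#' @param sigma The `cor_design` (or correlation matrix) of the scenario.
#' @param target Target marginal missingness proportion in (0, 1).
#' @param nodes Number of quadrature nodes (at least 64).
#' @return The model with `gamma0` filled in. The variance of eta is attached
#'   as attribute `eta_var`.
#' @export
calibrate_gamma0 <- function(model, sigma, target, nodes = 64) {
  if (!(target > 0 && target < 1)) {
    stop("target missingness proportion must lie in (0,1)", call. = FALSE)
  }
  g <- c(model$gammaX, model$gammaZ, model$gammaA)
  if (any(!is.finite(g))) stop("missingness slopes must be finite", call. = FALSE)
  S <- if (inherits(sigma, "cor_design")) sigma$values else sigma
  Sm <- S[-1, -1, drop = FALSE]
  v <- drop(crossprod(g, Sm %*% g))
  rule <- gauss_hermite(max(64, nodes))
  marg <- function(g0) gh_expect(function(e) stats::plogis(g0 + e),
                                 mu = 0, sd = sqrt(max(v, 0)), rule = rule)
  root <- stats::uniroot(function(g0) marg(g0) - target,
                         interval = c(-50, 50), tol = 1e-12)$root
  if (abs(marg(root) - target) > 1e-8) {
    stop("intercept calibration did not reach tolerance 1e-8", call. = FALSE)
  }
  model$gamma0 <- root
  attr(model, "eta_var") <- v
  model
}

#' Impose missing-at-random missingness on Y
#'
#' Sets each Y value to missing independently with probability
#' expit(gamma0 + gammaX x + gammaZ z + gammaA' a). Missingness depends only
#' on the fully observed (X, Z, A), so Y is missing at random by
#' construction.
#'
#' @param data A [draw_complete()] dataset.
#' @param model A calibrated [missingness_model()].
#' @param seed Optional seed for the Bernoulli draws.
#' @return An object of class `incomplete_data`: the `complete_data` fields
#'   with `y` masked (NA) where missing, plus the 0/1 indicator `m_y`.
#' @export
impose_missingness <- function(data, model, seed = NULL) {
  stopifnot(inherits(data, "complete_data"))
  if (is.na(model$gamma0)) {
    stop("missingness model intercept not calibrated; run calibrate_gamma0()",
         call. = FALSE)
  }
  if (length(model$gammaA) != data$p) {
    stop("missingness model dimension does not match data", call. = FALSE)
  }
  eta <- model$gamma0 + model$gammaX * data$x + model$gammaZ * data$z +
    drop(data$aux %*% model$gammaA)
  m_y <- local_seed(seed, stats::rbinom(data$n, 1L, stats::plogis(eta)))
  y <- data$y
  y[m_y == 1L] <- NA_real_
  structure(list(y = y, x = data$x, z = data$z, aux = data$aux,
                 n = data$n, p = data$p, m_y = m_y),
            class = c("incomplete_data", "complete_data"))
}

#' @export
as.data.frame.complete_data <- function(x, ...) {
  df <- data.frame(Y = x$y, X = x$x, Z = x$z)
  if (x$p > 0) df <- cbind(df, as.data.frame(x$aux))
  if (!is.null(x$m_y)) df$M_Y <- x$m_y
  df
}

#' Round-trip an incomplete dataset through CSV
#'
#' Column order Y, X, Z, A1..Ap, M_Y; missing Y written as an empty field.
#'
#' @param data An `incomplete_data`.
#' @param path File path.
#' @return For `read_incomplete_csv`, an `incomplete_data`.
#' @export
write_incomplete_csv <- function(data, path) {
  stopifnot(inherits(data, "incomplete_data"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_incomplete_csv
#' @export
read_incomplete_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = "")
  acols <- grep("^A[0-9]+$", names(df), value = TRUE)
  acols <- acols[order(as.integer(sub("A", "", acols)))]
  aux <- as.matrix(df[acols])
  structure(list(y = df$Y, x = df$X, z = df$Z, aux = aux,
                 n = nrow(df), p = length(acols), m_y = as.integer(df$M_Y)),
            class = c("incomplete_data", "complete_data"))
}
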