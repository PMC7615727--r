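# MI engine: the Bayesian regression draw, pooling and their calibration.

test_that("imputation never alters observed values and is exact when nothing is missing", {
  n <- 60
  set.seed(5)
  x <- rnorm(n); z <- rnorm(n); a <- rnorm(n)
  y <- x + 0.5 * z + rnorm(n)
  full <- ts_make_incomplete(y, x, z, cbind(A1 = a), rep(0L, n))
  expect_identical(bayes_draw_impute(full, c("X", "Z", "A1"), seed = 1), y)

  inc <- ts_make_incomplete(y, x, z, cbind(A1 = a),
                            as.integer(seq_len(n) <= 15))
  imp <- multiple_impute(inc, c("X", "Z", "A1"), m = 5, seed = 9)
  obs <- inc$m_y == 0L
  for (j in 1:5) expect_identical(imp$completed[obs, j], y[obs])
  expect_false(anyNA(imp$completed))
})

test_that("a deterministic relationship is imputed exactly", {
  n <- 400
  set.seed(11)
  x <- rnorm(n)
  y <- 2 * x
  inc <- ts_make_incomplete(y, x, rnorm(n), cbind(A1 = rnorm(n)),
                            as.integer(seq_len(n) <= 100))
  out <- bayes_draw_impute(inc, "X", seed = 3)
  expect_lt(max(abs(out[1:100] - 2 * x[1:100])), 0.01)
})

test_that("too few observed rows is a structured imputation failure", {
  inc <- ts_make_incomplete(c(1, 2, 3, 4, rep(NA, 3)), rnorm(7), rnorm(7),
                            cbind(A1 = rnorm(7), A2 = rnorm(7), A3 = rnorm(7)),
                            c(0L, 0L, 0L, 0L, 1L, 1L, 1L))
  expect_error(bayes_draw_impute(inc, c("A1", "A2", "A3")),
               class = "auximp_mi_failure")
})

test_that("repeated imputation is seed-reproducible with independent draws", {
  inc <- ts_base_incomplete()
  i1 <- multiple_impute(inc, c("X", "Z", "A1"), m = 3, seed = 21)
  i2 <- multiple_impute(inc, c("X", "Z", "A1"), m = 3, seed = 21)
  expect_identical(i1$completed, i2$completed)
  mis <- inc$m_y == 1L
  # different sub-streams: the three completions differ on missing entries
  expect_false(identical(i1$completed[mis, 1], i1$completed[mis, 2]))
})

test_that("imputation draws match the posterior-predictive variance", {
  n <- 40
  set.seed(6)
  x <- rnorm(n)
  y <- 1 + 0.8 * x + rnorm(n, sd = 0.7)
  m_y <- as.integer(seq_len(n) <= 10)
  inc <- ts_make_incomplete(y, x, rnorm(n), cbind(A1 = rnorm(n)), m_y)
  imp <- multiple_impute(inc, "X", m = 4000, seed = 13)
  # closed-form oracle from the observed-data fit
  obs <- inc$m_y == 0L
  D <- cbind(1, x)
  fit <- stats::lm.fit(D[obs, ], y[obs])
  nu <- sum(obs) - 2
  ss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(D[obs, ])))
  for (j in c(1, 5, 10)) {
    h <- drop(D[j, ] %*% XtXinv %*% D[j, ])
    expected_var <- ss / (nu - 2) * (1 + h)
    expect_equal(stats::var(imp$completed[j, ]), expected_var, tolerance = 0.15)
    expect_equal(mean(imp$completed[j, ]), drop(D[j, ] %*% fit$coefficients),
                 tolerance = 0.1)
  }
})

test_that("complete-data analyses match hand computations", {
  mn <- complete_data_analysis(c(0, 0, 2, 2), rnorm(4), rnorm(4), "mean")
  expect_equal(mn$estimate, 1)
  expect_equal(mn$variance, (4 / 3) / 4)
  expect_equal(mn$df, 3)

  set.seed(8)
  x <- rnorm(50); z <- rnorm(50)
  rg <- complete_data_analysis(z, x, z, "regression")  # Y identically Z
  expect_lt(abs(rg$estimate), 1e-10)
  expect_equal(rg$df, 47)

  cst <- complete_data_analysis(rep(2, 10), rnorm(10), rnorm(10), "mean")
  expect_equal(cst$variance, 0)
  expect_error(complete_data_analysis(x, x, x, "regression"), "collinear")
  expect_error(complete_data_analysis(c(1, NA), rnorm(2), rnorm(2), "mean"),
               "missing")
})

test_that("Rubin pooling reproduces the hand-computed example and identities", {
  p <- pool_rubin(c(0, 1), c(1, 1), df_com = 1000)
  expect_equal(p$qbar, 0.5)
  expect_equal(p$w, 1)
  expect_equal(p$b, 0.5)
  expect_equal(p$t, 1.75)
  expect_equal(p$fmi, 0.75 / 1.75)
  expect_equal(p$fmi_simple, 0.5 / 1.75)

  # degenerate: identical estimates
  p0 <- pool_rubin(rep(0.3, 4), rep(0.2, 4), df_com = 50)
  expect_equal(p0$b, 0)
  expect_equal(p0$t, p0$w)
  expect_equal(p0$fmi, 0)
  expect_equal(p0$df, 50)

  # identities on random inputs
  set.seed(30)
  for (i in 1:25) {
    m <- sample(2:40, 1)
    est <- rnorm(m)
    v <- rexp(m)
    df_com <- sample(c(10, 100, 1000), 1)
    p <- pool_rubin(est, v, df_com = df_com)
    expect_equal(p$t, p$w + (1 + 1 / m) * p$b)
    expect_equal(p$qbar, mean(est))
    expect_equal(p$fmi, (p$b + p$b / m) / p$t)
    expect_gte(p$fmi, 0); expect_lt(p$fmi, 1)
    expect_lte(p$df, df_com)
    expect_gt(p$df, 0)
    expect_lt(p$ci_low, p$ci_high)
    expect_equal(p$se, sqrt(p$t))
  }
})

test_that("a strong auxiliary reduces the estimated FMI", {
  # Y correlated 0.6 with A1; impute the mean with no predictors vs with A1
  S <- diag(4)
  S[1, 4] <- S[4, 1] <- 0.6
  S[1, 2] <- S[2, 1] <- 0.2
  dimnames(S) <- list(c("Y", "X", "Z", "A1"), c("Y", "X", "Z", "A1"))
  m_flat <- missingness_model(rep(1L, 1), 1.0)
  m_flat$gamma0 <- stats::qlogis(0.3)
  reps <- 200
  seeds <- auximp:::derive_seeds(606, reps, "fmi")
  fmi_empty <- fmi_aux <- numeric(reps)
  for (r in seq_len(reps)) {
    dat <- draw_complete(S, 150, seed = seeds[r])
    inc <- impose_missingness(dat, m_flat, seed = seeds[r] + 1)
    e <- multiple_impute(inc, character(0), m = 15, seed = seeds[r] + 2)
    a <- multiple_impute(inc, "A1", m = 15, seed = seeds[r] + 2)
    pool_of <- function(imp) {
      res <- apply(imp$completed, 2, function(y)
        complete_data_analysis(y, inc$x, inc$z, "mean"))
      pool_rubin(vapply(res, `[[`, numeric(1), "estimate"),
                 vapply(res, `[[`, numeric(1), "variance"),
                 df_com = res[[1]]$df)$fmi
    }
    fmi_empty[r] <- pool_of(e)
    fmi_aux[r] <- pool_of(a)
  }
  expect_gt(mean(fmi_empty), mean(fmi_aux))
})
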