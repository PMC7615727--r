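# The auxiliary-variable selection strategies.

test_that("quickpred screens on the larger of the two correlations", {
  n <- 400
  set.seed(101)
  y <- rnorm(n)
  a1 <- 0.6 * y + 0.8 * rnorm(n)              # correlated with Y
  m_y <- as.integer(seq_len(n) <= 100)        # fixed pattern (MCAR-like)
  a3 <- 1.5 * m_y + rnorm(n)                  # correlated with M_Y only
  a2 <- rnorm(n)                              # noise
  inc <- ts_make_incomplete(y, rnorm(n), rnorm(n),
                            cbind(A1 = a1, A2 = a2, A3 = a3), m_y)
  res <- select_quickpred(inc, cutoff = 0.2)
  # oracle: recompute the two correlations directly
  obs <- m_y == 0
  crit <- pmax(abs(cor(inc$aux[obs, ], y[obs]))[, 1],
               abs(cor(inc$aux, m_y))[, 1])
  expect_setequal(res$selected, colnames(inc$aux)[crit > 0.2])
  expect_true("A1" %in% res$selected)   # selected through cor with Y
  expect_true("A3" %in% res$selected)   # selected through cor with M_Y
  expect_false("A2" %in% res$selected)
  # degenerate cutoff
  expect_length(select_quickpred(inc, cutoff = 1.0)$selected, 0)
})

test_that("quickpred selection is monotone in the cutoff", {
  sig <- ts_base_sigma(); mm <- ts_base_model()
  for (s in 1:10) {
    inc <- impose_missingness(draw_complete(sig, 250, seed = 1000 + s), mm,
                              seed = 2000 + s)
    s2 <- select_quickpred(inc, 0.2)$selected
    s4 <- select_quickpred(inc, 0.4)$selected
    expect_true(all(s4 %in% s2))
  }
})

test_that("predmiss selects auxiliaries whose distribution shifts with missingness", {
  n <- 200
  set.seed(102)
  m_y <- as.integer(seq_len(n) <= 60)
  a1 <- rnorm(n) + 2 * m_y        # 2 SD shift in the missing group
  a2 <- rnorm(n)
  inc <- ts_make_incomplete(rnorm(n), rnorm(n), rnorm(n),
                            cbind(A1 = a1, A2 = a2), m_y)
  res <- select_predmiss(inc, 0.05)
  expect_true("A1" %in% res$selected)
  # oracle p-value for the shifted variable
  expect_equal(res$diagnostics$p_value[1],
               stats::t.test(a1[m_y == 1], a1[m_y == 0])$p.value)
  expect_length(select_predmiss(inc, alpha_sel = 0)$selected, 0)
  inc_all_obs <- ts_make_incomplete(rnorm(20), rnorm(20), rnorm(20),
                                    cbind(A1 = rnorm(20)), rep(0L, 20))
  expect_error(select_predmiss(inc_all_obs), "fewer than 2")
})

test_that("pcaux retains the fewest components covering the variance target", {
  n <- 300
  set.seed(103)
  base <- rnorm(n)
  # near-duplicated pair: one component carries essentially all variance
  inc1 <- ts_make_incomplete(rnorm(n), rnorm(n), rnorm(n),
                             cbind(A1 = base, A2 = base + rnorm(n, sd = 1e-4)),
                             as.integer(seq_len(n) <= 60))
  r1 <- select_pcaux(inc1, 0.40)
  expect_equal(ncol(r1$derived_predictors), 1)
  expect_gt(r1$diagnostics$cum_var_frac[1], 0.99)
  # independent pair: first component holds about half the variance
  inc2 <- ts_make_incomplete(rnorm(n), rnorm(n), rnorm(n),
                             cbind(A1 = rnorm(n), A2 = rnorm(n)),
                             as.integer(seq_len(n) <= 60))
  r2 <- select_pcaux(inc2, 0.40)
  expect_equal(ncol(r2$derived_predictors), 1)
  expect_lt(abs(r2$diagnostics$cum_var_frac[1] - 0.5), 0.1)
  # full variance requires all components
  r_all <- select_pcaux(inc2, 1.0)
  expect_equal(ncol(r_all$derived_predictors), inc2$p)
  # scores are uncorrelated and complete
  expect_lt(abs(cor(r_all$derived_predictors)[1, 2]), 1e-10)
  expect_false(anyNA(r2$derived_predictors))
  expect_length(r2$selected, 0)
})

test_that("forward selection adds the dominant predictor first", {
  n <- 300
  set.seed(104)
  x <- rnorm(n); z <- rnorm(n)
  aux <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("A", 1:4)))
  y <- x + 3 * aux[, 2] + rnorm(n, sd = 0.5)
  inc <- ts_make_incomplete(y, x, z, aux, as.integer(seq_len(n) <= 60))
  res <- select_forward(inc, 0.05)
  expect_equal(res$diagnostics$variable[1], "A2")
  expect_true("A2" %in% res$selected)
  expect_length(select_forward(inc, alpha_sel = 0)$selected, 0)
})

test_that("forward add-step p-values equal the refitted Wald p-values", {
  inc <- ts_base_incomplete()
  obs <- inc$m_y == 0
  # candidate A5 added to the model (X, Z, A1): compare to a full lm fit
  Dcur <- cbind(1, inc$x, inc$z, inc$aux[, "A1"])[obs, ]
  pv <- auximp:::forward_add_pvals(inc$y[obs], Dcur,
                                   inc$aux[obs, c("A5", "A9"), drop = FALSE])
  fit <- summary(stats::lm(inc$y[obs] ~ inc$x[obs] + inc$z[obs] +
                             inc$aux[obs, "A1"] + inc$aux[obs, "A5"]))
  expect_equal(unname(pv["A5"]), fit$coefficients[5, 4], tolerance = 1e-10)
})

test_that("stepwise removal drops an auxiliary made redundant by later additions", {
  n <- 400
  set.seed(105)
  b2 <- rnorm(n); b3 <- rnorm(n)
  a1 <- (b2 + b3) / sqrt(2) + rnorm(n, sd = 0.3)  # proxy for the true pair
  y <- b2 + b3 + rnorm(n, sd = 0.3)
  inc <- ts_make_incomplete(y, rnorm(n), rnorm(n),
                            cbind(A1 = a1, A2 = b2, A3 = b3),
                            as.integer(seq_len(n) <= 80))
  fwd <- select_forward(inc, 0.05, allow_removal = FALSE)
  sw <- select_forward(inc, 0.05, allow_removal = TRUE)
  # the proxy enters first in both runs
  expect_equal(fwd$diagnostics$variable[1], "A1")
  # with removal enabled it is dropped once the true pair is in
  expect_true("A1" %in% fwd$selected)
  expect_false("A1" %in% sw$selected)
  expect_setequal(sw$selected, c("A2", "A3"))
  expect_true("remove" %in% sw$diagnostics$action)
  # oracle: in the joint model the proxy is not significant
  obs <- inc$m_y == 0
  pj <- summary(stats::lm(y ~ inc$x + inc$z + a1 + b2 + b3,
                          subset = obs))$coefficients["a1", 4]
  expect_gte(pj, 0.05)
})

test_that("proxy variables are least-squares projections", {
  inc <- ts_base_incomplete()
  obs <- inc$m_y == 0
  # single auxiliary equal to Y on observed rows reproduces itself
  n <- 100
  set.seed(106)
  a <- rnorm(n)
  inc1 <- ts_make_incomplete(a, rnorm(n), rnorm(n), cbind(A1 = a),
                             as.integer(seq_len(n) <= 20))
  expect_equal(build_proxy(inc1, "A1"), a, tolerance = 1e-10)
  # two-column proxy equals lm fitted values extended to all rows
  pr <- build_proxy(inc, c("A1", "A2"))
  fit <- stats::lm(inc$y ~ inc$aux[, "A1"] + inc$aux[, "A2"],
                   subset = obs)
  expect_equal(pr, drop(cbind(1, inc$aux[, c("A1", "A2")]) %*% coef(fit)),
               ignore_attr = TRUE, tolerance = 1e-10)
  # projection residual orthogonal to the subset span on observed rows
  resid_obs <- inc$y[obs] - pr[obs]
  expect_lt(max(abs(crossprod(cbind(1, inc$aux[obs, c("A1", "A2")]),
                              resid_obs))), 1e-8)
  expect_error(build_proxy(inc, character(0)), "nonempty")
})

test_that("forward-FMI selects the lone auxiliary and stops at duplicates", {
  n <- 200
  set.seed(107)
  y0 <- rnorm(n); a1 <- 0.7 * y0 + rnorm(n, sd = 0.5)
  m_y <- as.integer(seq_len(n) <= 60)
  inc1 <- ts_make_incomplete(y0, rnorm(n), rnorm(n), cbind(A1 = a1), m_y)
  r1 <- select_forward_fmi(inc1, stop_frac = 0.01, m_sel = 10, seed = 1)
  expect_identical(r1$selected, "A1")

  # a near-duplicate auxiliary cannot reduce the FMI: selection stops
  inc2 <- ts_make_incomplete(y0, rnorm(n), rnorm(n),
                             cbind(A1 = a1, A2 = a1 + rnorm(n, sd = 1e-6)),
                             m_y)
  r2 <- select_forward_fmi(inc2, stop_frac = 0.01, m_sel = 10, seed = 2)
  # one of the two near-identical twins enters; the other cannot reduce the
  # FMI further, so the stopping rule fires before it is added
  expect_length(r2$selected, 1)
  expect_false(utils::tail(r2$diagnostics$accepted, 1))
  # the FMI path is recorded
  expect_true(all(c("step", "candidate", "fmi") %in% names(r2$diagnostics)))
})

test_that("the lasso recovers a strong signal and rejects pure noise", {
  n <- 300; p <- 10
  hits <- 0; clean <- 0; empties <- 0
  for (s in 1:10) {
    set.seed(500 + s)
    x <- rnorm(n); z <- rnorm(n)
    aux <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("A", 1:p)))
    y <- x + 5 * aux[, 1] + rnorm(n, sd = 0.5)
    inc <- ts_make_incomplete(y, x, z, aux, as.integer(seq_len(n) <= 60))
    sel <- select_lasso(inc, 10, seed = s)$selected
    if ("A1" %in% sel) hits <- hits + 1
    if (length(setdiff(sel, "A1")) <= 2) clean <- clean + 1

    ynoise <- rnorm(n)
    incn <- ts_make_incomplete(ynoise, x, z, aux, as.integer(seq_len(n) <= 60))
    if (length(select_lasso(incn, 10, seed = s)$selected) == 0) {
      empties <- empties + 1
    }
  }
  expect_gte(hits, 9)
  expect_gte(clean, 9)
  expect_gte(empties, 9)
})

test_that("apply_strategy wires selection, imputation and pooling together", {
  inc <- ts_base_incomplete()
  # the full model uses every auxiliary plus X and Z
  rec <- apply_strategy(inc, strategy_spec("Full"), m = 5, seed = 3)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$estimand, c("muY", "betaX"))
  expect_equal(unique(rec$n_predictors), inc$p + 2)
  expect_true(all(rec$converged))

  # CCA on a tiny constructed dataset: hand-computed mean and SE
  inc3 <- ts_make_incomplete(c(1, 2, 3, 0, 0), c(0.3, -1, 2, 0.5, 1),
                             c(1.2, 0.1, -0.4, 1, -1),
                             cbind(A1 = rnorm(5)), c(0L, 0L, 0L, 1L, 1L))
  # three complete cases leave zero residual df for the regression estimand,
  # whose record is NaN; the mean record under test is unaffected
  cca <- suppressWarnings(apply_strategy(inc3, strategy_spec("CCA")))
  mu <- cca[cca$estimand == "muY", ]
  expect_equal(mu$estimate, 2)
  expect_equal(mu$se, 1 / sqrt(3))
  expect_equal(mu$ci_low, 2 - stats::qt(0.975, 2) / sqrt(3))

  # no missing data: MI reduces exactly to the complete-data analysis
  sig <- ts_base_sigma()
  m_none <- ts_base_model(); m_none$gamma0 <- -30
  full_obs <- impose_missingness(draw_complete(sig, 100, seed = 51), m_none,
                                 seed = 52)
  expect_equal(sum(full_obs$m_y), 0)
  rec0 <- apply_strategy(full_obs, strategy_spec("Full"), m = 5, seed = 4)
  mn <- complete_data_analysis(full_obs$y, full_obs$x, full_obs$z, "mean")
  expect_identical(rec0$estimate[rec0$estimand == "muY"], mn$estimate)
  expect_identical(rec0$se[rec0$estimand == "muY"], sqrt(mn$variance))

  # every MI strategy includes X and Z among its imputation predictors
  for (nm in setdiff(names(default_strategies(25)), c("CCA", "Forward-FMI"))) {
    r <- apply_strategy(inc, default_strategies(25)[[nm]], m = 4, seed = 7)
    expect_gte(r$n_predictors[1], 2)
    expect_true(all(r$converged), info = nm)
  }
})

test_that("selection frequencies track correlation with the outcome", {
  runs <- ts_selection_freq(100)
  grp <- ts_base_sigma()$group_assignment
  mask <- ts_base_model()$aux_miss_mask
  freq_by <- function(strategy, subset_idx) {
    mean(vapply(runs, function(r) {
      idx <- as.integer(sub("A", "", r[[strategy]]))
      sum(idx %in% subset_idx) / length(subset_idx)
    }, numeric(1)))
  }
  g1 <- which(grp == 1); g3 <- which(grp == 3)
  # strategies screening on association with Y pick the strongly correlated
  # group more often than the weakly correlated one
  for (st in c("Quickpred-pt2", "Quickpred-pt4", "Forward", "Forward-sw",
               "Forward-FMI", "LASSO")) {
    expect_gt(freq_by(st, g1), freq_by(st, g3))
  }
  # predmiss screens on association with missingness: auxiliaries in the
  # missingness model are picked more often than those outside it
  expect_gt(freq_by("PredMiss", which(mask)), freq_by("PredMiss", which(!mask)))
})
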