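# Shared fixtures. Expensive objects (the base-scenario design, the
# selection-frequency study, the benchmark simulation run) are memoized in
# this environment so multiple test files can share one computation.

ts_cache <- new.env(parent = emptyenv())

ts_memo <- function(key, expr) {
  if (!exists(key, envir = ts_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = ts_cache)
  }
  get(key, envir = ts_cache, inherits = FALSE)
}

ts_base_cfg <- function() scenario_config(250, 25, reps = 2000, base_seed = 20260918)

ts_base_sigma <- function() ts_memo("base_sigma", build_sigma(ts_base_cfg()))

ts_base_model <- function() ts_memo("base_model", {
  calibrate_gamma0(missingness_model(ts_base_sigma(), 1.2), ts_base_sigma(), 0.3)
})

# One incomplete dataset from the base scenario, for strategy smoke checks.
ts_base_incomplete <- function(seed = 424242) {
  ts_memo(paste0("base_inc_", seed), {
    dat <- draw_complete(ts_base_sigma(), 250, seed = seed)
    impose_missingness(dat, ts_base_model(), seed = seed + 1)
  })
}

# Construct an incomplete_data object directly from components.
ts_make_incomplete <- function(y, x, z, aux, m_y) {
  aux <- as.matrix(aux)
  if (is.null(colnames(aux))) colnames(aux) <- paste0("A", seq_len(ncol(aux)))
  y[m_y == 1L] <- NA_real_
  structure(list(y = y, x = x, z = z, aux = aux,
                 n = length(y), p = ncol(aux), m_y = as.integer(m_y)),
            class = c("incomplete_data", "complete_data"))
}

# Selection-frequency study on the base scenario: per-repetition selected
# sets for the seven subset-selecting strategies. Used by the strategy
# invariants and by the selection-frequency acceptance check.
ts_selection_freq <- function(reps = 100) {
  ts_memo(paste0("selfreq_", reps), {
    sig <- ts_base_sigma()
    mm <- ts_base_model()
    seeds <- auximp:::derive_seeds(20260918, reps, "selfreq")
    out <- vector("list", reps)
    for (r in seq_len(reps)) {
      s <- auximp:::derive_seeds(seeds[r], 4, "rep")
      dat <- draw_complete(sig, 250, seed = s[1])
      inc <- impose_missingness(dat, mm, seed = s[2])
      out[[r]] <- list(
        "Quickpred-pt2" = select_quickpred(inc, 0.2)$selected,
        "Quickpred-pt4" = select_quickpred(inc, 0.4)$selected,
        "PredMiss"      = select_predmiss(inc, 0.05)$selected,
        "Forward"       = select_forward(inc, 0.05)$selected,
        "Forward-sw"    = select_forward(inc, 0.05, allow_removal = TRUE)$selected,
        "Forward-FMI"   = select_forward_fmi(inc, 0.01, m_sel = 30, seed = s[3])$selected,
        "LASSO"         = select_lasso(inc, 10, seed = s[4])$selected)
    }
    out
  })
}

# Benchmark run shared by the complete-case and full-model acceptance
# checks: CCA + Full on the base scenario at full repetitions.
ts_benchmark_run <- function() {
  ts_memo("benchmark_run", {
    run_scenario(ts_base_cfg(),
                 strategies = default_strategies(25)[c("CCA", "Full")],
                 reps = 2000)
  })
}
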