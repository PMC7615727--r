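# auximp

Simulation framework for evaluating data-driven **auxiliary-variable
selection strategies for multiple imputation** (MI) of a single incomplete
continuous outcome.

## The problem

Auxiliary variables — variables outside the analysis model that predict an
incomplete variable or its missingness — can make MI estimates less biased
and more precise, but large studies offer hundreds of candidates and the
imputation model cannot sensibly hold them all. `auximp` builds a
controlled world in which selection rules can be compared: data
$(Y, X, Z, A_1,\dots,A_p)$ are multivariate normal with a structured
correlation matrix $\Sigma$ (three auxiliary groups correlated 0.4 / 0.2 /
0.1 with $Y$ on average, and $\mathrm{cor}(Y,X)$ calibrated for 80% power
of the exposure test), and the outcome $Y$ is made missing at random
through $\mathrm{logit}\,P(M_Y{=}1) = \gamma_0 + \gamma_X X + \gamma_Z Z +
\gamma_A^\top A$ with $\gamma_0$ calibrated by Gauss–Hermite quadrature to
a target missingness proportion.

Ten analysis strategies are implemented: complete-case analysis (CCA), the
full imputation model, correlation screening at cutoffs 0.2 / 0.4
(quickpred style), selection by tests of the MCAR assumption (PredMiss),
principal-component auxiliaries (PcAux), forward and forward-stepwise Wald
selection, forward selection on the fraction of missing information
(Forward-FMI), and cross-validated LASSO screening with the 1-SE rule.
Each MI strategy feeds a proper Bayesian linear-regression imputation
engine pooled by Rubin's rules ($T = W + (1 + 1/m)B$, Barnard–Rubin
degrees of freedom, FMI $=(B + B/m)/T$). Performance per strategy and
estimand ($\mu_Y$ and $\beta_X$) is summarized as bias, empirical and
model SE, coverage, standardized bias and Monte Carlo standard errors.

## Worked example

```r
library(auximp)

cfg <- scenario_config(250, 25, reps = 200, base_seed = 20260918)
res <- run_scenario(cfg, strategies = default_strategies(25)[c("CCA", "Full", "LASSO")])
res$truth
#> True parameters: muY = 0, betaX = 0.1772, betaZ = 0.0823, Var(Y|X,Z) = 0.9589

perf <- as.data.frame(res$performance)
perf[perf$estimand == "muY",
     c("strategy", "M", "bias", "emp_se", "model_se", "coverage", "std_bias_pct")]
#>  strategy   M    bias emp_se model_se coverage std_bias_pct
#>       CCA 200 -0.1236  0.075    0.075     0.64       -165.6
#>      Full 200  0.0011  0.074    0.076     0.97          1.4
#>     LASSO 200  0.0103  0.074    0.073     0.96         14.0
```

Reading the output: the complete-case mean is biased downward by 0.12 SD —
people with high missingness-model scores have high $Y$, so dropping them
drags the observed mean down — and its nominal 95% interval covers the
truth only 64% of the time at 200 repetitions. MI with the full model or
with LASSO-selected auxiliaries is approximately unbiased (standardized
bias well under 30%) with near-nominal coverage. `run_study()` executes
whole scenario grids (`scenario_grid()` gives the six study scenarios) and
writes records, summaries, selection diagnostics and a manifest as CSV;
`inst/scripts/auximp-cli.R` exposes `run` / `design` / `summarize`
subcommands over the same functions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the study's headline quantities from scratch with the installed
package: the true exposure coefficients implied by the power-calibrated
design at $n = 250$ and $n = 1000$; the empirical power of the exposure
test on complete data; the realized missingness percentages after
intercept calibration at the 30% and 50% targets; complete-case coverage
for the mean; full-model standardized bias and coverage; and coverage
under LASSO selection — each over 2000 simulated repetitions at the given
seed, written as JSON. Runs in a few minutes on one CPU.
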