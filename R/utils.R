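# Internal helpers: reproducible seeding and quadrature.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation functions do not clobber the
# session RNG. A NULL seed leaves the current stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive `n` child seeds from (seed, tag). Used so each repetition, imputation
# and strategy gets an independent, reproducible sub-stream; all derived seeds
# stay below 2^31.
derive_seeds <- function(seed, n, tag = "") {
  tag <- as.character(tag)
  h <- 0
  if (nzchar(tag)) {
    h <- sum(utf8ToInt(tag) * seq_len(nchar(tag))) %% 1000003
  }
  mix <- (abs(as.numeric(seed)) %% 1000003937 + h * 262147) %% 2147483647
  local_seed(as.integer(mix), sample.int(2147483646L, n, replace = FALSE))
}

# Gauss-Hermite nodes and weights (physicists' convention, weight e^{-x^2})
# via Golub-Welsch: eigendecomposition of the symmetric tridiagonal Jacobi
# matrix with off-diagonals sqrt(i/2). For Z ~ N(0,1),
#   E f(Z) = sum_i w_i/sqrt(pi) * f(sqrt(2) x_i).
gauss_hermite <- function(k) {
  stopifnot(k >= 2)
  J <- matrix(0, k, k)
  off <- sqrt(seq_len(k - 1) / 2)
  J[cbind(seq_len(k - 1), seq_len(k - 1) + 1)] <- off
  J[cbind(seq_len(k - 1) + 1, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# E[f(mu + sd * Z)] for Z ~ N(0,1) by Gauss-Hermite quadrature.
gh_expect <- function(f, mu = 0, sd = 1, rule = gauss_hermite(64)) {
  sum(rule$weights / sqrt(pi) * f(mu + sd * sqrt(2) * rule$nodes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
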