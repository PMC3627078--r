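# Internal helpers shared across modules.

# Deterministic seed splitting: derived seeds for component i / stream s so that
# adding components or streams never perturbs draws of earlier ones. Kept below
# 2^31 - 1 (R integers are 32-bit).
split_seed <- function(seed, i, stream = 0L) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(i) +
                15485863 * as.numeric(stream)) %% 2147483647)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Cholesky with additive jitter fallback: start at 1e-8 * mean(diag), double up
# to 3 times before giving up with a message about the conditioning.
chol_safe <- function(K, jitter0 = 1e-8, max_doublings = 3) {
  n <- nrow(K)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (!is.null(L)) return(L)
  base <- jitter0 * mean(diag(K))
  if (!is.finite(base) || base <= 0) base <- jitter0
  for (j in 0:max_doublings) {
    Kj <- K + diag(base * 2^j, n)
    L <- tryCatch(chol(Kj), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  ev <- tryCatch(range(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) c(NA_real_, NA_real_))
  stopf("Cholesky factorization failed even after jitter (eigenvalue range [%g, %g])",
        ev[1], ev[2])
}

symmetrize <- function(M) (M + t(M)) / 2
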