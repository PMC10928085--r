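# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so seeded operations do not perturb
# surrounding simulations.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Dirichlet draws via normalized gamma variates; rows are simplex vectors.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, ncol = k, byrow = TRUE)
  x / rowSums(x)
}

# Mean-one multiplicative lognormal noise at a given coefficient of
# variation; cv = 0 returns exact ones.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Cholesky factor of sigma after verifying positive definiteness;
# errors carry `what` to identify the offending component.
chol_pd <- function(sigma, what = "covariance") {
  R <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(R)) stop("singular ", what, " (not positive definite)", call. = FALSE)
  R
}

# Multivariate normal log-density for rows of x given mean mu and the
# upper-triangular Cholesky factor R of the covariance.
log_dmvnorm_chol <- function(x, mu, R) {
  d <- length(mu)
  z <- backsolve(R, t(x) - mu, transpose = TRUE)
  q <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + q) - sum(log(diag(R)))
}

# Multivariate t log-density (location mu, scale with Cholesky factor R,
# df degrees of freedom) for rows of x.
log_dmvt_chol <- function(x, mu, R, df) {
  d <- length(mu)
  z <- backsolve(R, t(x) - mu, transpose = TRUE)
  q <- colSums(z^2)
  lgamma((df + d) / 2) - lgamma(df / 2) - (d / 2) * log(df * pi) -
    sum(log(diag(R))) - ((df + d) / 2) * log1p(q / df)
}

# log-sum-exp over matrix rows
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stopifnot_scalar <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop("`", name, "` must be a single number >= ", lower, call. = FALSE)
  invisible(x)
}
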