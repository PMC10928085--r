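# Independent oracles used to freeze expected values: these deliberately
# use brute force / enumeration, not the code paths they check.

# Non-negative least squares by exhaustive active-set enumeration: try
# every support set, solve unconstrained least squares on it, keep the
# feasible (x >= 0) candidate with the smallest residual.
nnls_oracle <- function(M, b) {
  n <- ncol(M)
  best <- numeric(n)
  best_r <- sum(b^2)                      # empty support baseline
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0)
    xs <- tryCatch(qr.solve(M[, S, drop = FALSE], b),
                   error = function(e) NULL)
    if (is.null(xs) || any(xs < -1e-12)) next
    x <- numeric(n)
    x[S] <- pmax(xs, 0)
    r <- sum((M %*% x - b)^2)
    if (r < best_r - 1e-12) { best_r <- r; best <- x }
  }
  best
}

# Exact two-sided rank-sum p-value by enumerating all group assignments
# (no ties assumed), using the doubling rule for two-sidedness.
wilcox_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- rank(c(a, b))
  w_obs <- sum(pooled[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  ws <- apply(combs, 2L, function(idx) sum(pooled[idx]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Random well-conditioned impurity-like matrix: diagonally dominant with
# non-negative off-diagonal spill.
random_impurity <- function(n) {
  M <- diag(runif(n, 0.8, 0.95))
  for (j in seq_len(n)) {
    spill <- runif(2, 0, 0.05)
    if (j > 1) M[j - 1, j] <- spill[1]
    if (j < n) M[j + 1, j] <- spill[2]
  }
  M
}

# Small two-class Gaussian marker fixture for classifier tests.
gaussian_markers <- function(n_per_class = 10, d = 4, sep = 2,
                             sd = 0.1, seed = 42) {
  set.seed(seed)
  mu1 <- rep(0, d)
  mu2 <- c(sep, rep(0, d - 1))
  X <- rbind(
    matrix(rnorm(n_per_class * d, sd = sd), ncol = d),
    matrix(rnorm(n_per_class * d, sd = sd), ncol = d) +
      matrix(mu2, n_per_class, d, byrow = TRUE)
  )
  rownames(X) <- sprintf("m%02d", seq_len(2 * n_per_class))
  list(X = X, labels = rep(c("A", "B"), each = n_per_class),
       mu = rbind(mu1, mu2))
}

# Small simulated dataset shared by pipeline-level tests.
small_sim <- function(seed = 3, ...) {
  simulate_dataset(sim_config(n_compartments = 6, n_proteins = 40,
                              markers_per_compartment = 8,
                              dl_fraction = 0.1,
                              partition_fraction = 0.05,
                              seed = seed, ...))
}
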