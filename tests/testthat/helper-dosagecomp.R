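# Shared fixtures and small independent oracles used across test files.

# Headline parameterizations: Ne = 1125 (harem polygyny, N_f = 1000,
# eta = 1), mu = 3e-4, z0 = 1.
headline_params <- function(system = "XY", S_m = 1, S_f = 0.1, rho = 0.8, ...) {
  dc_params(system = system, S_m = S_m, S_f = S_f, rho = rho,
            Ne = 1125, mu = 3e-4, z0 = 1, N = 1000, ...)
}

# Oracle-scale Wright-Fisher demography: N = 50 per sex; equal breeding
# success and multinomial parent sampling imply Ne = 3N/2 at neutrality.
oracle_params <- function(system = "XY", N = 50, ...) {
  dc_params(system = system, N = N, Ne = 1.5 * N, ...)
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigen decomposition of the
# Jacobi matrix (weight exp(-x^2)).
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# E[g(delta_m, delta_f)] under the bivariate normal mutation kernel, by
# tensor-product Gauss-Hermite quadrature. Independent of the closed forms in
# the package.
kernel_expectation <- function(g, sigma2, rho, n_nodes = 40) {
  gh <- gauss_hermite(n_nodes)
  sd <- sqrt(sigma2)
  tot <- 0
  for (i in seq_len(n_nodes)) {
    xi <- sqrt(2) * gh$nodes[i]
    dm <- sd * xi
    for (j in seq_len(n_nodes)) {
      xj <- sqrt(2) * gh$nodes[j]
      df_ <- sd * (rho * xi + sqrt(1 - rho^2) * xj)
      tot <- tot + gh$weights[i] * gh$weights[j] * g(dm, df_)
    }
  }
  tot / pi
}

# Independent step-by-step TMM computation (trimmed, weighted mean of
# M-values) following the published algorithm: reference column by the 75th
# percentile rule, M/A trimming at 30%/5%, inverse-asymptotic-variance
# weights, factors rescaled to geometric mean 1.
hand_tmm <- function(counts, lib = colSums(counts)) {
  n <- ncol(counts)
  # reference: upper quartile of count/lib closest to the mean upper quartile
  f75 <- vapply(seq_len(n), function(j)
    stats::quantile(counts[, j] / lib[j], 0.75, names = FALSE), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(n)
  for (j in seq_len(n)) {
    if (j == ref) { f[j] <- 1; next }
    x <- counts[, j]; xr <- counts[, ref]
    keep0 <- x > 0 & xr > 0
    x <- x[keep0]; xr <- xr[keep0]
    M <- log2((x / lib[j]) / (xr / lib[ref]))
    A <- 0.5 * log2((x / lib[j]) * (xr / lib[ref]))
    w <- (lib[j] - x) / (lib[j] * x) + (lib[ref] - xr) / (lib[ref] * xr)
    ng <- length(M)
    loM <- floor(ng * 0.3) + 1; hiM <- ng + 1 - loM
    loA <- floor(ng * 0.05) + 1; hiA <- ng + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum((M / w)[keep]) / sum((1 / w)[keep]))
  }
  f / exp(mean(log(f)))
}

# Exact Wilcoxon signed-rank V and two-sided p by brute-force enumeration of
# all 2^n sign assignments (no ties, no zeros assumed).
hand_signed_rank <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_V <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- mean(abs(null_V - mu) >= abs(V - mu) - 1e-12)
  list(V = V, p = p)
}

quiet_bcv <- function(...) suppressMessages(estimate_bcv(...))

# Homogametic-sex weight in the linearized fixation probability (independent
# restatement for the quadrature oracle).
hom_w <- function(p) if (p$dominance == "dominant") 8 / 3 else 2
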