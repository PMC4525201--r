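# Stochastic trajectories (Euler-Maruyama) and sex-chromosome effective sizes
# under harem polygyny.

#' Effective population size of the X or Z chromosome under harem polygyny
#'
#' \deqn{N_{eZ} = 9 N_f / (6 + 4\eta), \qquad N_{eX} = 9 N_f / (6 + 2\eta)}
#' where \eqn{N_f} is the number of successfully breeding females and
#' \eqn{\eta} the ratio of breeding females to breeding males. Because males
#' transmit two-thirds of Z copies but only one-third of X copies, male
#' reproductive skew (\eqn{\eta > 1}) depresses \eqn{N_{eZ}} more than
#' \eqn{N_{eX}}.
#'
#' @param N_f Number of successfully breeding females (>= 1).
#' @param eta Ratio of breeding females to breeding males (> 0).
#' @param chromosome "X" or "Z".
#' @return Effective population size (same units as \code{N_f}).
#' @examples
#' effective_size(1000, 1, "X")  # 1125, the headline parameterization
#' @export
effective_size <- function(N_f, eta, chromosome = c("X", "Z")) {
  chromosome <- match.arg(chromosome)
  stopifnot(N_f >= 1, eta > 0)
  if (chromosome == "Z") 9 * N_f / (6 + 4 * eta) else 9 * N_f / (6 + 2 * eta)
}

#' Simulate replicate stochastic expression trajectories
#'
#' Euler-Maruyama integration of the origin-fixation SDE on the rescaled time
#' \eqn{\tau}: drift \code{-M (z + offset)} equal to
#' \code{\link{expected_change}}, plus independent Brownian increments per sex
#' with intensities \eqn{b_1 = \sqrt{15\sigma^2}} (heterogametic sex) and
#' \eqn{b_2 = \sqrt{60\sigma^2}} (homogametic sex). All replicates are
#' advanced together from one seeded RNG stream, so a given seed reproduces
#' the ensemble bit-identically.
#'
#' @param params A \code{\link{dc_params}} object.
#' @param init Initial \code{c(z_m, z_f)} (default: the model's starting
#'   point, see \code{\link{solve_expected}}).
#' @param T_tau Final rescaled time.
#' @param dt Euler step in \eqn{\tau} units; default targets
#'   (largest drift eigenvalue) x dt = 0.01. A warning is issued if
#'   the supplied dt exceeds 0.1 of the stability bound.
#' @param n_replicates Number of replicate paths.
#' @param seed Integer seed.
#' @param n_keep Number of (equispaced) time points stored per path.
#' @param diffusion_scale Multiplier on the noise intensities (testing hook:
#'   0 degenerates the SDE to the deterministic ODE).
#' @return A \code{dc_ensemble}: list with \code{tau} (stored grid),
#'   \code{z_m}, \code{z_f} (time x replicate matrices), \code{params},
#'   \code{seed}.
#' @export
simulate_paths <- function(params, init = NULL, T_tau, dt = NULL,
                           n_replicates = 1, seed = 1, n_keep = 101,
                           diffusion_scale = 1) {
  validate_params(params)
  stopifnot(n_replicates >= 1, T_tau > 0)
  if (is.null(init)) init <- default_init(params)
  M <- drift_matrix(params)
  lam_max <- max(Re(eigen(M, only.values = TRUE)$values))
  if (is.null(dt)) dt <- 0.01 / lam_max
  if (lam_max * dt > 0.1)
    warning(sprintf("dt = %g exceeds the stability heuristic (drift eigenvalue * dt = %.3g > 0.1)",
                    dt, lam_max * dt))
  set.seed(seed)
  n_steps <- ceiling(T_tau / dt)
  keep_at <- unique(round(seq(0, n_steps, length.out = n_keep)))
  b <- diffusion_scale * sqrt(diffusion_variances(params))  # (male, female)
  het <- if (params$system == "XY") 1L else 2L
  gradual <- params$degradation == "gradual"

  zm <- matrix(init[1], 1, n_replicates)
  zf <- matrix(init[2], 1, n_replicates)
  keep_zm <- matrix(NA_real_, length(keep_at), n_replicates)
  keep_zf <- matrix(NA_real_, length(keep_at), n_replicates)
  ki <- 1L
  if (keep_at[1] == 0) { keep_zm[1, ] <- zm; keep_zf[1, ] <- zf; ki <- 2L }
  sdt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    pm <- zm; pf <- zf
    if (gradual) {
      off <- gradual_offset((s - 1) * dt, params)
      if (het == 1L) pm <- pm + off else pf <- pf + off
    }
    zm <- zm - dt * (M[1, 1] * pm + M[1, 2] * pf) + b[1] * sdt * stats::rnorm(n_replicates)
    zf <- zf - dt * (M[2, 1] * pm + M[2, 2] * pf) + b[2] * sdt * stats::rnorm(n_replicates)
    if (ki <= length(keep_at) && s == keep_at[ki]) {
      keep_zm[ki, ] <- zm; keep_zf[ki, ] <- zf; ki <- ki + 1L
    }
  }
  if (gradual) {
    off <- gradual_offset(keep_at * dt, params)
    if (het == 1L) keep_zm <- keep_zm + off else keep_zf <- keep_zf + off
  }
  out <- list(tau = keep_at * dt, z_m = keep_zm, z_f = keep_zf,
              n_replicates = n_replicates, dt = dt, seed = seed, params = params)
  class(out) <- "dc_ensemble"
  out
}

#' Cross-replicate moments of a path ensemble
#'
#' @param ens A \code{dc_ensemble} from \code{\link{simulate_paths}}.
#' @param at_tau Rescaled time at which to summarize (nearest stored point;
#'   default: final time).
#' @return List with \code{tau}, per-sex \code{mean} and \code{var} across
#'   replicates, and \code{het_values}, the heterogametic-sex expression values
#'   of every replicate at that time (the terminal-variance histogram data).
#' @export
ensemble_summary <- function(ens, at_tau = NULL) {
  stopifnot(inherits(ens, "dc_ensemble"))
  if (is.null(at_tau)) at_tau <- max(ens$tau)
  if (at_tau < min(ens$tau) || at_tau > max(ens$tau))
    stop("at_tau outside the stored time grid")
  i <- which.min(abs(ens$tau - at_tau))
  zm <- ens$z_m[i, ]; zf <- ens$z_f[i, ]
  v <- function(x) if (length(x) > 1) stats::var(x) else 0
  het <- if (ens$params$system == "XY") zm else zf
  list(tau = ens$tau[i],
       mean = c(z_m = mean(zm), z_f = mean(zf)),
       var = c(z_m = v(zm), z_f = v(zf)),
       het_values = het)
}

#' @export
print.dc_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic path ensemble (%s): %d replicates, tau in [0, %g], dt = %g, seed = %d\n",
              x$params$system, x$n_replicates, max(x$tau), x$dt, x$seed))
  invisible(x)
}

#' Export a path ensemble as TSV
#'
#' Long format with columns \code{replicate}, \code{t}, \code{tau},
#' \code{z_m}, \code{z_f}.
#'
#' @param ens A \code{dc_ensemble}.
#' @param path Output file path.
#' @export
write_ensemble <- function(ens, path) {
  reps <- ncol(ens$z_m)
  df <- data.frame(
    replicate = rep(seq_len(reps), each = length(ens$tau)),
    t = rep(unscale_time(ens$tau, ens$params$mu), reps),
    tau = rep(ens$tau, reps),
    z_m = as.vector(ens$z_m),
    z_f = as.vector(ens$z_f))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
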