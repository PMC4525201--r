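# Deterministic expected dynamics: time rescaling, exact and numeric solution
# of the expected-trajectory ODEs, the stationary variance of the stochastic
# system, and the gradual Y/W degradation profile.

#' Rescaled evolutionary time
#'
#' Time is rescaled as \eqn{\tau = 2 \mu t / 30}, which makes the expected
#' dynamics independent of the mutation rate (one unit of \eqn{\tau}
#' corresponds to fewer generations when the mutation rate is higher).
#'
#' @param t Time in generations (vector ok).
#' @param mu Mutation rate per gene per generation.
#' @return \code{rescale_time}: \eqn{\tau}; \code{unscale_time}: generations.
#' @examples
#' rescale_time(50000, 3e-4)  # 1
#' @export
rescale_time <- function(t, mu) {
  stopifnot(all(t >= 0), mu > 0)
  2 * mu * t / 30
}

#' @rdname rescale_time
#' @param tau Rescaled time.
#' @export
unscale_time <- function(tau, mu) {
  stopifnot(all(tau >= 0), mu > 0)
  30 * tau / (2 * mu)
}

#' Expression of the degrading Y/W gene copy
#'
#' Under gradual degradation the Y/W copy starts from half the ancestral
#' optimum, \eqn{y(0) = z_0 / 2}, and decays exponentially towards total
#' shut-down: \eqn{y(t) = (z_0/2) e^{-\alpha t}}.
#'
#' @param t Time in generations (vector ok).
#' @param alpha Decay rate, > 0.
#' @param z0 Ancestral contribution parameter (see \code{\link{dc_params}}).
#' @return Expression level of the Y/W copy at \code{t}.
#' @export
degradation_profile <- function(t, alpha, z0) {
  stopifnot(alpha > 0, all(t >= 0))
  (z0 / 2) * exp(-alpha * t)
}

default_init <- function(params) {
  # Instantaneous loss: heterogametic sex starts z0 below the optimum.
  # Gradual loss: both sexes start at the optimum; the deficit builds up as
  # the Y/W copy decays.
  if (params$degradation == "gradual") {
    c(z_m = 0, z_f = 0)
  } else if (params$system == "XY") {
    c(z_m = -params$z0, z_f = 0)
  } else {
    c(z_m = 0, z_f = -params$z0)
  }
}

default_tau_grid <- function(params, n = 201) {
  M <- drift_matrix(params)
  lam <- eigen(M, only.values = TRUE)$values
  lam_min <- min(Re(lam))
  if (lam_min <= 0) stop("dynamics do not converge (need S_m, S_f > 0)")
  seq(0, 8 / lam_min, length.out = n)
}

# Selected heterogametic-sex phenotype offset at rescaled time tau under
# gradual degradation: realized phenotype = evolving copy + y(t) - z0/2.
gradual_offset <- function(tau, params) {
  t_gen <- unscale_time(tau, params$mu)
  degradation_profile(t_gen, params$alpha, params$z0) - params$z0 / 2
}

#' Expected trajectory of male and female expression
#'
#' Solves the expected dynamics \eqn{d(z_m, z_f)/d\tau = -M (z_m, z_f)} (see
#' \code{\link{expected_change}}) from the post-degradation initial state.
#' \code{method = "closed_form"} uses the exact eigen-solution of the linear
#' system and is available for the baseline model (additive mutations,
#' instantaneous Y/W loss); \code{method = "numeric"} integrates the variant
#' right-hand sides (dominance, gradual degradation) with an adaptive RK45
#' scheme (abs/rel tolerance 1e-8).
#'
#' Under gradual degradation the reported heterogametic-sex value is the
#' realized expression, i.e. the evolving X/Z-copy contribution plus the
#' declining Y/W contribution \eqn{y(t) - z_0/2} (so it starts at 0 and the
#' deficit accumulates as the Y/W copy shuts down).
#'
#' @param params A \code{\link{dc_params}} object.
#' @param init Initial \code{c(z_m, z_f)}; default is the model's own starting
#'   point (heterogametic sex at \code{-z0}, homogametic sex at 0, or both at
#'   0 for gradual degradation).
#' @param tau_grid Strictly increasing grid of rescaled times starting at the
#'   initial time; default spans eight slow-mode e-foldings.
#' @param method "closed_form" or "numeric".
#' @return A \code{dc_trajectory}: data frame with columns \code{t} (in
#'   generations), \code{tau}, \code{z_m}, \code{z_f}, carrying the parameter
#'   snapshot as an attribute.
#' @examples
#' p <- dc_params(S_m = 1, S_f = 0.1, rho = 0.8, Ne = 1125)
#' tr <- solve_expected(p)
#' max(tr$z_f) > 0  # female overshoot
#' @export
solve_expected <- function(params, init = NULL,
                           tau_grid = NULL,
                           method = c("closed_form", "numeric")) {
  validate_params(params)
  method <- match.arg(method)
  if (is.null(init)) init <- default_init(params)
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(params)
  stopifnot(length(init) == 2, all(diff(tau_grid) > 0) || length(tau_grid) == 1)

  variant <- params$dominance != "additive" || params$degradation != "instantaneous"
  if (method == "closed_form") {
    if (variant)
      stop("closed_form covers the baseline model only (additive, instantaneous); ",
           "use method = \"numeric\" for variants")
    Z <- expm_trajectory(drift_matrix(params), init, tau_grid)
  } else {
    M <- drift_matrix(params)
    het <- if (params$system == "XY") 1L else 2L
    if (params$degradation == "gradual") {
      rhs <- function(tau, y) {
        ph <- y
        ph[het] <- ph[het] + gradual_offset(tau, params)
        -as.vector(M %*% ph)
      }
    } else {
      rhs <- function(tau, y) -as.vector(M %*% y)
    }
    Z <- rk45_integrate(rhs, init, tau_grid)
    if (params$degradation == "gradual")
      Z[, het] <- Z[, het] + gradual_offset(tau_grid, params)
  }
  out <- data.frame(t = unscale_time(tau_grid, params$mu), tau = tau_grid,
                    z_m = Z[, 1], z_f = Z[, 2])
  attr(out, "params") <- params
  class(out) <- c("dc_trajectory", "data.frame")
  out
}

# Exact solution of dz/dtau = -M z via eigendecomposition (M has real
# eigenvalues here because the off-diagonal product is rho^2 S_m S_f >= 0).
expm_trajectory <- function(M, init, tau_grid) {
  eg <- eigen(M)
  V <- eg$vectors
  lam <- eg$values
  if (Mod(lam[1] - lam[2]) < 1e-12 * max(1, Mod(lam[1]))) {
    # defective/near-degenerate case: fall back to scaling-and-squaring
    Z <- t(vapply(tau_grid, function(s) {
      as.vector(pade_expm(-M * s) %*% init)
    }, numeric(2)))
    return(Z)
  }
  a <- solve(V, init)
  Z <- t(vapply(tau_grid, function(s) {
    Re(as.vector(V %*% (a * exp(-lam * s))))
  }, numeric(2)))
  Z
}

# Minimal scaling-and-squaring matrix exponential (2x2 use only).
pade_expm <- function(A) {
  s <- max(0, ceiling(log2(max(1e-16, norm(A, "1")))))
  A <- A / 2^s
  E <- diag(nrow(A)) + A
  term <- A
  for (k in 2:12) {
    term <- term %*% A / k
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}

#' Stationary variance of heterogametic-sex expression
#'
#' At mutation-selection-drift equilibrium the stochastic system settles into
#' a bivariate normal law with mean zero. This returns the exact stationary
#' variance of heterogametic-sex expression, obtained by solving the 2x2
#' Lyapunov equation \eqn{M \Sigma + \Sigma M' = B B'} of the linear SDE
#' (drift \code{-M} from \code{\link{drift_matrix}}, diffusion
#' \eqn{b_1^2 = 15\sigma^2}, \eqn{b_2^2 = 60\sigma^2} on the \eqn{\tau}
#' scale for the heterogametic/homogametic sex). With \eqn{\rho = 0} it
#' reduces to \eqn{3 / (4 N_e S_{het})}, so smaller effective sizes give more
#' variable expression.
#'
#' @param params A \code{\link{dc_params}} object (baseline model).
#' @return Stationary variance of the heterogametic sex's expression, with the
#'   full 2x2 stationary covariance matrix (male, female order) as attribute
#'   \code{"covariance"}.
#' @export
stationary_variance <- function(params) {
  validate_params(params)
  if (params$S_m <= 0 || params$S_f <= 0)
    stop("stationary variance requires S_m, S_f > 0")
  M <- drift_matrix(params)
  q <- diffusion_variances(params)  # c(male, female) on the tau scale
  # unknowns x = (S11, S12, S22); M Sigma + Sigma M' = diag(q)
  m11 <- M[1, 1]; m12 <- M[1, 2]; m21 <- M[2, 1]; m22 <- M[2, 2]
  A <- rbind(c(2 * m11, 2 * m12, 0),
             c(m21, m11 + m22, m12),
             c(0, 2 * m21, 2 * m22))
  x <- solve(A, c(q[1], 0, q[2]))
  Sigma <- matrix(c(x[1], x[2], x[2], x[3]), 2, 2,
                  dimnames = list(c("z_m", "z_f"), c("z_m", "z_f")))
  het <- if (params$system == "XY") 1L else 2L
  structure(Sigma[het, het], covariance = Sigma)
}

# Diffusion variances (squared noise intensities) of the SDE on the tau scale,
# ordered (male, female). Per generation the origin-fixation jump variance is
# mu*sigma^2 for the heterogametic sex and 4*mu*sigma^2 for the homogametic
# one (whose expression moves by 2*delta per substitution); dividing by
# d tau/dt = 2 mu/30 gives 15 sigma^2 and 60 sigma^2.
diffusion_variances <- function(params) {
  b_het2 <- 15 * params$sigma2
  b_hom2 <- 60 * params$sigma2
  if (params$system == "XY") c(b_het2, b_hom2) else c(b_hom2, b_het2)
}

#' Time for the heterogametic sex to recover a fraction of its deficit
#'
#' First crossing time (linear interpolation on the trajectory grid) at which
#' the heterogametic sex's expression deficit shrinks to
#' \code{(1 - frac) * z0}.
#'
#' @param traj A \code{dc_trajectory} from \code{\link{solve_expected}}.
#' @param frac Fraction of the initial deficit to recover (default 0.9).
#' @param units "tau" or "generations".
#' @return The crossing time, or \code{NA} if not reached on the grid.
#' @export
recovery_time <- function(traj, frac = 0.9, units = c("tau", "generations")) {
  units <- match.arg(units)
  params <- attr(traj, "params")
  het <- if (params$system == "XY") traj$z_m else traj$z_f
  target <- -(1 - frac) * params$z0
  ok <- which(het >= target)
  ok <- ok[ok > 1 | het[1] >= target]
  if (!length(ok)) return(NA_real_)
  i <- min(ok)
  tt <- if (units == "tau") traj$tau else traj$t
  if (i == 1) return(tt[1])
  w <- (target - het[i - 1]) / (het[i] - het[i - 1])
  tt[i - 1] + w * (tt[i] - tt[i - 1])
}

#' @export
print.dc_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Expected expression trajectory (%s), %d points, tau in [%g, %g]\n",
              p$system, nrow(x), min(x$tau), max(x$tau)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Export a trajectory as TSV
#'
#' Columns \code{t}, \code{tau}, \code{z_m}, \code{z_f}.
#'
#' @param traj A \code{dc_trajectory}.
#' @param path Output file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj)[, c("t", "tau", "z_m", "z_f")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
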