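# Core origin-fixation quantities: the mutation kernel, the linearized
# sex-linked fixation probability, and the expected per-substitution drift.

# Weight of the homogametic-sex selection term relative to the heterogametic
# one. Additive (cis) mutations: the diploid sex carries two of the three
# chromosome copies, so its term enters with weight 2. Fully dominant (trans)
# mutations: the heterozygote already expresses the full 2*delta shift, but its
# marginal advantage vanishes as the mutant becomes common (RM -> MM changes
# nothing), so integrating the frequency-dependent coefficient through the
# diffusion gives weight 8/3 rather than a doubling to 4. The Wright-Fisher
# oracle tests pin this constant down.
hom_weight <- function(dominance) if (dominance == "dominant") 8 / 3 else 2

# (S z delta) terms ordered as (heterogametic, homogametic) for a given params.
split_by_gamety <- function(params, z_m, z_f, delta_m = NULL, delta_f = NULL) {
  if (params$system == "XY")
    list(S_het = params$S_m, S_hom = params$S_f, z_het = z_m, z_hom = z_f,
         d_het = delta_m, d_hom = delta_f)
  else
    list(S_het = params$S_f, S_hom = params$S_m, z_het = z_f, z_hom = z_m,
         d_het = delta_f, d_hom = delta_m)
}

#' Draw mutational effects from the bivariate mutation kernel
#'
#' Effects on male and female expression are mean-zero bivariate normal with
#' marginal variance \code{sigma2} and correlation \code{rho}.
#'
#' @param params A \code{\link{dc_params}} object.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A data frame with columns \code{delta_m}, \code{delta_f}.
#' @examples
#' d <- sample_mutation(dc_params(rho = 0.5), n = 5, seed = 1)
#' @export
sample_mutation <- function(params, n = 1, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(params$sigma2)
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  data.frame(delta_m = sd * x1,
             delta_f = sd * (params$rho * x1 + sqrt(1 - params$rho^2) * x2))
}

#' Linearized fixation probability of a sex-linked mutant
#'
#' Probability that a single-copy mutant with expression effects
#' \code{(delta_m, delta_f)} fixes, from the weak-selection linearization of
#' Kimura's diffusion for a sex-linked locus:
#' \deqn{u = \frac{1}{3N}\left[1 - \frac{2 N_e}{3}
#'   \left(S_{het} z_{het} \delta_{het} + c\, S_{hom} z_{hom} \delta_{hom}\right)\right]}
#' with \eqn{c = 2} for additive and \eqn{c = 8/3} for dominant mutations.
#' The homogametic sex's term carries the larger weight because it holds two
#' of the three chromosome copies. \eqn{1/(3N)} is the neutral fixation
#' probability (one copy among \eqn{3N}).
#'
#' The linearization is only valid while the selection term is small; values
#' falling outside \[0, 1\] are clamped and flagged via the \code{"clamped"}
#' attribute (and a warning), rather than silently accepted.
#'
#' @param delta_m,delta_f Mutational effects on male and female expression
#'   (vectors recycle).
#' @param z_m,z_f Current male and female expression (deviation from optimum).
#' @param params A \code{\link{dc_params}} object.
#' @return Numeric vector of probabilities with attribute \code{clamped}
#'   (logical, TRUE where the raw linearization left \[0, 1\]).
#' @export
fixation_prob <- function(delta_m, delta_f, z_m, z_f, params) {
  validate_params(params)
  g <- split_by_gamety(params, z_m, z_f, delta_m, delta_f)
  cc <- hom_weight(params$dominance)
  bracket <- g$S_het * g$z_het * g$d_het + cc * g$S_hom * g$z_hom * g$d_hom
  u <- (1 / (3 * params$N)) * (1 - (2 * params$Ne / 3) * bracket)
  clamped <- u < 0 | u > 1
  if (any(clamped))
    warning(sprintf(
      "%d fixation probabilit%s outside [0,1] before clamping; linearization invalid there",
      sum(clamped), if (sum(clamped) == 1) "y" else "ies"))
  u <- pmin(pmax(u, 0), 1)
  attr(u, "clamped") <- clamped
  u
}

#' Expected change in male and female expression
#'
#' The drift of the origin-fixation process, obtained by integrating
#' (mutation rate) x (effect on fixation) x (expression shift on fixation)
#' over the bivariate mutation kernel. On the rescaled time
#' \eqn{\tau = 2\mu t / 30} and for an XY system with additive mutations:
#' \deqn{dz_m/d\tau = -10\sigma^2 N_{eX} (S_m z_m + 2\rho S_f z_f)}
#' \deqn{dz_f/d\tau = -20\sigma^2 N_{eX} (2 S_f z_f + \rho S_m z_m)}
#' (so that at the standard \eqn{\sigma^2 = 0.1} the prefactors are
#' \eqn{N_{eX}} and \eqn{2 N_{eX}}). The ZW system swaps the roles of the
#' sexes and uses \eqn{N_{eZ}}; the dominant variant replaces the homogametic
#' weight 2 by 8/3. The system is linear in \code{(z_m, z_f)}.
#'
#' @param z_m,z_f Current expression values (selected phenotype deviations).
#' @param params A \code{\link{dc_params}} object.
#' @param scale "tau" (default, per unit rescaled time) or "generation".
#' @return Named numeric vector \code{c(dz_m, dz_f)}.
#' @export
expected_change <- function(z_m, z_f, params, scale = c("tau", "generation")) {
  scale <- match.arg(scale)
  M <- drift_matrix(params, scale = scale)
  dz <- -as.vector(M %*% c(z_m, z_f))
  names(dz) <- c("dz_m", "dz_f")
  dz
}

#' Drift matrix of the expected dynamics
#'
#' Returns the matrix \eqn{M} such that \eqn{d(z_m, z_f)/d\tau = -M (z_m, z_f)}.
#' Row/column order is (male, female).
#'
#' @inheritParams expected_change
#' @keywords internal
#' @export
drift_matrix <- function(params, scale = c("tau", "generation")) {
  validate_params(params)
  scale <- match.arg(scale)
  k <- 10 * params$sigma2 * params$Ne
  if (scale == "generation") k <- k * params$mu / 15  # d tau/dt = 2 mu / 30
  cc <- hom_weight(params$dominance)
  if (params$system == "XY") {
    M <- k * rbind(c(params$S_m,            cc * params$rho * params$S_f),
                   c(2 * params$rho * params$S_m, 2 * cc * params$S_f))
  } else {
    M <- k * rbind(c(2 * cc * params$S_m, 2 * params$rho * params$S_f),
                   c(cc * params$rho * params$S_m, params$S_f))
  }
  dimnames(M) <- list(c("z_m", "z_f"), c("z_m", "z_f"))
  M
}
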