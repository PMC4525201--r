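# Individual-based Wright-Fisher simulator of a single sex-linked locus.
# Used as the brute-force oracle for the linearized fixation probability and
# as an end-to-end origin-fixation simulator.

#' Expression level of a genotype
#'
#' The genotype-to-expression map: the resident allele R gives \code{z_m}
#' (males) or \code{z_f} (females); each mutant copy M adds \eqn{\delta}
#' additively, so a heterozygote is \eqn{z + \delta}, a mutant homozygote
#' \eqn{z + 2\delta}, and a mutant hemizygote \eqn{z + \delta}. Under full
#' dominance the heterozygote expresses the mutant-homozygote level
#' \eqn{z + 2\delta}.
#'
#' @param genotype Character: "R", "M" (hemizygous) or "RR", "RM", "MM".
#' @param sex "male" or "female".
#' @param z_m,z_f Resident expression in males / females.
#' @param delta_m,delta_f Mutant effects.
#' @param params A \code{\link{dc_params}} object (supplies system, dominance).
#' @return Expression level (numeric scalar).
#' @export
expression_of <- function(genotype, sex = c("male", "female"), z_m, z_f,
                          delta_m, delta_f, params) {
  sex <- match.arg(sex)
  validate_params(params)
  hemi <- (sex == "male" && params$system == "XY") ||
    (sex == "female" && params$system == "ZW")
  z <- if (sex == "male") z_m else z_f
  d <- if (sex == "male") delta_m else delta_f
  if (hemi) {
    if (!genotype %in% c("R", "M"))
      stop("ploidy mismatch: heterogametic-sex genotype must be R or M")
    return(if (genotype == "M") z + d else z)
  }
  if (!genotype %in% c("RR", "RM", "MM"))
    stop("ploidy mismatch: homogametic-sex genotype must be RR, RM or MM")
  n_mut <- switch(genotype, RR = 0, RM = 1, MM = 2)
  if (params$dominance == "dominant" && n_mut == 1) n_mut <- 2
  z + n_mut * d
}

#' Gaussian stabilizing-selection fitness
#'
#' \eqn{w(z) = \exp(-S z^2 / 2)}: maximal (1) at the optimum \eqn{z = 0},
#' symmetric, and declining faster for larger \eqn{S}. Its weak-selection
#' expansion, \eqn{w(z + \delta)/w(z) - 1 \approx -S z \delta}, supplies the
#' selection coefficients that enter the linearized fixation probability.
#'
#' @param z Expression level (deviation from optimum).
#' @param S Selection intensity, >= 0.
#' @return Relative fitness in (0, 1].
#' @export
fitness <- function(z, S) {
  stopifnot(all(S >= 0))
  exp(-0.5 * S * z^2)
}

# Order params into the (heterogametic, homogametic) slots the C++ core uses.
wf_slots <- function(params, z_m, z_f, delta_m, delta_f) {
  if (params$system == "XY")
    list(z_het = z_m, d_het = delta_m, S_het = params$S_m,
         z_hom = z_f, d_hom = delta_f, S_hom = params$S_f)
  else
    list(z_het = z_f, d_het = delta_f, S_het = params$S_f,
         z_hom = z_m, d_hom = delta_m, S_hom = params$S_m)
}

#' Replicate invasion trials of a single mutant
#'
#' Introduces one mutant gene copy (uniformly among the \eqn{3N} copies) into
#' a monomorphic population of \code{n_census} males and \code{n_census}
#' females and iterates the Wright-Fisher life cycle -- parents of each
#' offspring drawn with replacement with probability proportional to Gaussian
#' fitness, sex-linked inheritance (in XY a son's X comes from his mother; in
#' ZW a daughter's Z comes from her father) -- until the mutant fixes or is
#' lost.
#'
#' @param params A \code{\link{dc_params}} object.
#' @param z_m,z_f Resident expression levels.
#' @param delta_m,delta_f Mutant effects.
#' @param n_census Individuals per sex (overrides \code{params$N} if given).
#' @param n_reps Number of replicate invasions.
#' @param seed Optional integer seed.
#' @param max_gen Generation cap per invasion; trials still segregating at the
#'   cap are reported as \code{undecided}, never as fixed or lost.
#' @return List with counts \code{fixed}, \code{lost}, \code{undecided}, the
#'   fixation-fraction \code{estimate}, its binomial \code{se}, and
#'   \code{mean_generations}.
#' @export
run_invasions <- function(params, z_m, z_f, delta_m, delta_f,
                          n_census = params$N, n_reps = 1000, seed = NULL,
                          max_gen = 1e6) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  s <- wf_slots(params, z_m, z_f, delta_m, delta_f)
  r <- .wf_invasion_batch(as.integer(n_reps), as.integer(n_census),
                          s$z_het, s$d_het, s$S_het,
                          s$z_hom, s$d_hom, s$S_hom,
                          params$dominance == "dominant", max_gen)
  est <- r$fixed / n_reps
  list(fixed = r$fixed, lost = r$lost, undecided = r$undecided,
       estimate = est, se = sqrt(est * (1 - est) / n_reps),
       mean_generations = r$mean_generations)
}

#' Single invasion trial
#'
#' Convenience wrapper around \code{\link{run_invasions}} with one replicate.
#'
#' @inheritParams run_invasions
#' @return List with \code{outcome} ("fixed", "lost" or "undecided") and the
#'   \code{seed} used.
#' @export
run_invasion <- function(params, z_m, z_f, delta_m, delta_f,
                         n_census = params$N, seed = NULL, max_gen = 1e6) {
  r <- run_invasions(params, z_m, z_f, delta_m, delta_f,
                     n_census = n_census, n_reps = 1, seed = seed,
                     max_gen = max_gen)
  outcome <- if (r$fixed == 1) "fixed" else if (r$lost == 1) "lost" else "undecided"
  list(outcome = outcome, seed = seed)
}

#' Origin-fixation simulation of expression evolution
#'
#' Iterates \code{\link{sample_mutation}} then an invasion trial; every fixed
#' mutation moves heterogametic-sex expression by \eqn{\delta} and
#' homogametic-sex expression by \eqn{2\delta} (its two copies). Time between
#' substitutions is counted as (mutations arisen) / (3 N mu) generations,
#' ignoring segregation time.
#'
#' @inheritParams run_invasions
#' @param n_substitutions Number of substitutions to accumulate.
#' @param init Initial \code{c(z_m, z_f)} (default: model starting point).
#' @param max_attempts Cap on total mutations tried; if hit, the trajectory is
#'   returned truncated with attribute \code{capped = TRUE}.
#' @return A \code{dc_trajectory} data frame (one row per substitution,
#'   beginning at the initial state) with columns \code{t}, \code{tau},
#'   \code{z_m}, \code{z_f} and attributes \code{attempts}, \code{capped}.
#' @export
run_origin_fixation <- function(params, n_substitutions, init = NULL,
                                n_census = params$N, seed = NULL,
                                max_gen = 1e6, max_attempts = 1e7) {
  validate_params(params)
  if (params$degradation != "instantaneous")
    stop("origin-fixation simulator covers instantaneous degradation only")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- default_init(params)
  xy <- params$system == "XY"
  z_het0 <- if (xy) init[1] else init[2]
  z_hom0 <- if (xy) init[2] else init[1]
  S_het <- if (xy) params$S_m else params$S_f
  S_hom <- if (xy) params$S_f else params$S_m
  # rho couples (delta_het, delta_hom) symmetrically, so passing sexes by
  # gametic role preserves the kernel
  r <- .wf_origin_fixation(as.integer(n_census), as.integer(n_substitutions),
                           z_het0, z_hom0, S_het, S_hom,
                           params$rho, params$sigma2,
                           params$dominance == "dominant", max_gen, max_attempts)
  t_gen <- r$attempts / (3 * n_census * params$mu)
  out <- data.frame(t = t_gen, tau = rescale_time(t_gen, params$mu),
                    z_m = if (xy) r$z_het else r$z_hom,
                    z_f = if (xy) r$z_hom else r$z_het)
  attr(out, "params") <- params
  attr(out, "attempts") <- r$attempts
  attr(out, "capped") <- r$capped
  class(out) <- c("dc_trajectory", "data.frame")
  out
}
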