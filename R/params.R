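#' Model parameters for sex-linked dosage-compensation evolution
#'
#' Bundles every parameter of the evolutionary model: the sex-chromosome
#' system, sex-specific stabilizing-selection intensities, the bivariate
#' mutation kernel, population sizes, and the model-variant switches.
#'
#' Expression is measured as a deviation from the shared optimum (set to zero
#' in both sexes). A cis-regulatory mutation shifts male and female expression
#' by a correlated bivariate-normal pair \eqn{(\delta_m, \delta_f)} with
#' marginal variance \code{sigma2} and correlation \code{rho}. Fitness declines
#' as a Gaussian around the optimum, \eqn{w_s(z) = \exp(-S_s z^2/2)} for sex
#' \eqn{s}.
#'
#' @param system "XY" (male heterogametic) or "ZW" (female heterogametic).
#' @param S_m,S_f Stabilizing-selection intensities on male/female expression
#'   (dimensionless, >= 0).
#' @param rho Inter-sexual correlation of mutational effects, in \[-1, 1\].
#' @param sigma2 Variance of mutational effects in each sex (expression
#'   units squared). Default 0.1.
#' @param mu Per-gene mutation rate per generation. Default 3e-4.
#' @param N Census number of individuals of each sex.
#' @param Ne Effective population size of the focal sex chromosome
#'   (\eqn{N_{eX}} or \eqn{N_{eZ}}). Carried independently of \code{N}
#'   because the two play different roles: \code{N} sets the initial frequency
#'   of a new mutant, \code{Ne} the strength of drift. See
#'   \code{\link{effective_size}} for the harem-polygyny values.
#' @param z0 Ancestral expression contribution of the now-degraded Y/W copy;
#'   the heterogametic sex starts at \code{-z0} under instantaneous loss.
#' @param dominance "additive" (cis-acting, default) or "dominant"
#'   (trans-acting: heterozygote expression equals mutant-homozygote
#'   expression in the homogametic sex).
#' @param degradation "instantaneous" (default) or "gradual" (Y/W expression
#'   decays exponentially at rate \code{alpha}).
#' @param alpha Decay rate (per generation) of Y/W-copy expression; used only
#'   when \code{degradation = "gradual"}.
#' @return An object of class \code{dc_params} (a validated list).
#' @examples
#' p <- dc_params(S_m = 1, S_f = 0.1, rho = 0.8, N = 1000, Ne = 1125)
#' p
#' @export
dc_params <- function(system = c("XY", "ZW"), S_m = 1, S_f = 1, rho = 0,
                      sigma2 = 0.1, mu = 3e-4, N = 1000, Ne = 1125,
                      z0 = 1, dominance = c("additive", "dominant"),
                      degradation = c("instantaneous", "gradual"),
                      alpha = 2e-4) {
  p <- list(system = match.arg(system), S_m = S_m, S_f = S_f, rho = rho,
            sigma2 = sigma2, mu = mu, N = N, Ne = Ne, z0 = z0,
            dominance = match.arg(dominance),
            degradation = match.arg(degradation), alpha = alpha)
  class(p) <- "dc_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "dc_params"))
  with(p, {
    if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be > 0")
    if (!is.finite(mu) || mu <= 0) stop("mu must be > 0")
    if (!is.finite(N) || N < 1) stop("N must be >= 1")
    if (!is.finite(Ne) || Ne <= 0) stop("Ne must be > 0")
    if (!is.finite(rho) || abs(rho) > 1) stop("|rho| must be <= 1")
    if (S_m < 0 || S_f < 0) stop("S_m and S_f must be >= 0")
    if (degradation == "gradual" && (!is.finite(alpha) || alpha <= 0))
      stop("alpha must be > 0 for gradual degradation")
  })
  invisible(p)
}

#' @export
print.dc_params <- function(x, ...) {
  cat(sprintf("Dosage-compensation model parameters (%s, %s, %s loss)\n",
              x$system, x$dominance, x$degradation))
  cat(sprintf("  S_m = %g, S_f = %g, rho = %g, sigma2 = %g, mu = %g\n",
              x$S_m, x$S_f, x$rho, x$sigma2, x$mu))
  cat(sprintf("  N = %g per sex, Ne = %g, z0 = %g", x$N, x$Ne, x$z0))
  if (x$degradation == "gradual") cat(sprintf(", alpha = %g", x$alpha))
  cat("\n")
  invisible(x)
}

#' Which sex is heterogametic?
#'
#' @param params A \code{\link{dc_params}} object.
#' @return "male" for XY systems, "female" for ZW systems.
#' @export
heterogametic_sex <- function(params) {
  if (params$system == "XY") "male" else "female"
}

#' Write / read model parameters as a flat key-value file
#'
#' One `key = value` pair per line, plain text, so parameter sets can be
#' version-controlled and passed to the command-line interface.
#'
#' @param params A \code{\link{dc_params}} object.
#' @param path File path.
#' @return \code{read_params} returns a \code{dc_params}; \code{write_params}
#'   returns \code{path} invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  keys <- names(params)
  vals <- vapply(params, function(v)
    if (is.character(v)) v else format(v, digits = 17), character(1))
  writeLines(paste(keys, vals, sep = " = "), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  p <- as.list(vals)
  names(p) <- keys
  num <- setdiff(keys, c("system", "dominance", "degradation"))
  p[num] <- lapply(p[num], as.numeric)
  do.call(dc_params, p)
}
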