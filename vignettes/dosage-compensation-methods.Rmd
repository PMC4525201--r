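---
title: "Models and methods: dosage-compensation evolution on X and Z chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dosage-compensation evolution on X and Z chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagecomp)
```

## The problem

After recombination stops between a pair of sex chromosomes, the Y (or W)
degenerates and the heterogametic sex is left with a single expressed copy of
each dose-sensitive gene. Dosage compensation is the evolutionary recovery of
balanced expression in that sex. Empirically, male-heterogametic (XY) systems
often achieve complete compensation while female-heterogametic (ZW) systems
usually do not. This package implements a population-genetic model in which
that asymmetry emerges from three ingredients: a positive inter-sexual
correlation of mutational effects on expression, stronger stabilizing
selection on males, and higher male reproductive variance (which depresses
the effective size of the Z more than the X). It also implements the
companion transcriptome analysis that tests the model's gene-level
predictions with sex-specific expression variability as an inverse proxy for
selection strength, plus a synthetic count generator so the entire analysis
is testable without any external data.

## The evolutionary model

A single sex-linked, dose-sensitive gene evolves by origin–fixation: cis
mutations arise rarely enough that each fixes or is lost before the next
appears. A mutation shifts male and female expression by a bivariate normal
pair $(\delta_m, \delta_f)$ with marginal variance $\sigma^2$ (default 0.1)
and correlation $\rho$. Expression deviations from a shared optimum (set to
0) are under sex-specific Gaussian stabilizing selection,
$w_s(z) = e^{-S_s z^2/2}$. Expression is additive across copies in the
diploid sex, so fixation moves the homogametic sex by $2\delta$ and the
hemizygous sex by $\delta$.

The weak-selection linearization of Kimura's sex-linked diffusion gives the
fixation probability of a single-copy mutant
$$u = \frac{1}{3N}\Big[1 - \tfrac{2 N_e}{3}\big(S_{het}\, z_{het}\delta_{het}
      + c\, S_{hom}\, z_{hom}\delta_{hom}\big)\Big],$$
with $c = 2$ for additive (cis) mutations — the homogametic sex carries two
of the three chromosome copies — and $c = 8/3$ for fully dominant (trans)
mutations. Every constant here is derived from first principles and pinned
by the package's individual-based Wright–Fisher oracle. Two details deserve
note:

* The dominant coefficient is $8/3$, not the naive doubling to $4$: a
  dominant mutant's marginal advantage vanishes as it becomes common
  (heterozygote and mutant homozygote express identically), and integrating
  this frequency dependence through the diffusion multiplies the
  heterozygote coefficient by $2/3$. The Wright–Fisher oracle rejects the
  coefficient 4 at more than seven Monte-Carlo standard errors and confirms
  $8/3$ on both beneficial and deleterious sides.
* Dominance leaves the neutral term $1/(3N)$ untouched; only the
  homogametic selection term is inflated.

Averaging mutation supply, fixation and the per-fixation shifts over the
kernel gives a linear expected dynamics on the rescaled time
$\tau = 2\mu t/30$ (one $\tau$ unit is fewer generations when mutation is
faster; the constant 30 makes the prefactors clean at $\sigma^2 = 0.1$):
$$\frac{dz_m}{d\tau} = -10\sigma^2 N_{eX}\,(S_m z_m + 2\rho S_f z_f),\qquad
  \frac{dz_f}{d\tau} = -20\sigma^2 N_{eX}\,(2 S_f z_f + \rho S_m z_m)$$
for XY; ZW swaps the sexes' roles and uses $N_{eZ}$. `solve_expected()`
solves this exactly (eigen decomposition) or numerically (adaptive RK45 at
tolerance $10^{-8}$, which also covers the dominant and gradual-degradation
variants); the two routes agree to $10^{-6}$ across the headline parameter
grid, which is what guards the derivation of the closed form.

Stochasticity across replicate lineages is captured by an Euler–Maruyama
SDE with the same drift and independent Brownian increments per sex, with
diffusion variances $15\sigma^2$ (heterogametic) and $60\sigma^2$
(homogametic) on the $\tau$ scale. These come from the exact origin–fixation
jump moments: the homogametic sex moves $2\delta$ per substitution, so its
jump variance is four times larger, not equal as a same-order-of-magnitude
approximation would have it; the stationary-variance test (closed-form
Lyapunov solution vs long-run ensembles, within 10% at 1,000 replicates)
confirms the exact moments used here. The long-run law is
bivariate normal with mean zero; with $\rho = 0$ the heterogametic variance
reduces to $3/(4 N_e S_{het})$, so small effective sizes give noisy
expression evolution.

Effective sizes under harem polygyny are
$N_{eZ} = 9N_f/(6+4\eta)$ and $N_{eX} = 9N_f/(6+2\eta)$ with $\eta$ the
breeding female:male ratio; male skew ($\eta > 1$) hits the Z hardest
because males transmit two-thirds of Z copies. `Ne` is carried as an
explicit parameter because the census size $N$ plays a different role (the
initial frequency $1/(3N)$).

### Model variants

* **Dominance** (`dominance = "dominant"`): heterozygotes express the
  mutant-homozygote level; the homogametic weight becomes $8/3$ throughout.
  Because deleterious dominant overexpression is purged more efficiently,
  the female overshoot of X expression is smaller than under additivity.
* **Gradual degradation** (`degradation = "gradual"`): the Y/W copy starts
  at half the ancestral optimum and decays as $y(t) = (z_0/2)e^{-\alpha t}$,
  the standard form for an asymptotic decline to total shut-down. The
  heterogametic sex's selected phenotype is the evolving X/Z contribution
  plus $y(t) - z_0/2$, so trajectories start at the optimum and the deficit
  builds only as fast as the copy decays. The default
  $\alpha = 2\times10^{-4}$ per generation puts decay on the same timescale
  as compensation in the headline parameterizations; with compensation
  much faster than decay the population tracks the decline almost
  perfectly, which is itself the reason this variant mitigates the female
  overshoot.

### The Wright–Fisher oracle

`run_invasions()` / `run_origin_fixation()` simulate the exact life cycle:
$N$ males and $N$ females, fitness-proportional parent sampling with
replacement, sex-linked inheritance (a son's X is maternal; a daughter's Z
is paternal). Genotype counts are a sufficient state, so a generation is a
handful of binomial draws (implemented in C++ with R's RNG). With equal sex
numbers and multinomial parent sampling the implied effective size is
$N_e = 3N/2$, which is what oracle comparisons use. The linearized fixation
probability is only asked to hold in its stated regime
($|2N_e \bar s| \lesssim 0.2$); outside it the exact Kimura form departs by
many Monte-Carlo standard errors (the package flags and clamps
probabilities that leave $[0,1]$ rather than silently accepting them), and
the acceptance grid is pre-scaled into the valid regime. With 12 two-sided
2-SE checks, about 0.5 chance exceedances are expected under perfect
agreement, so the grid test tolerates exactly one point in (2, 3] SE.

## The transcriptome analysis

`analyze_dataset()` reproduces the count-matrix-to-conclusions procedure:
TMM normalization computed from autosomal genes only (so incomplete Z
compensation cannot distort the scale), RPKM with effective library sizes, a
per-tissue expression filter (a gene is kept iff some sex has
$\log_2 \mathrm{RPKM} \ge 1$ in every replicate), $\log_2$ male:female
ratios of linear-scale means, per-sex BCV estimation, projection onto
selection axes, a sex-bias band for Z genes (default
$\log_2(1/1.25) \le r \le \log_2(1.25/0.5)$; a symmetric 0.8–1.2 preset is
also provided because the source describes both), OLS dosage regressions,
paired Wilcoxon BCV comparisons, and the strata analysis with per-stratum
Z:AA ratios.

Numerical and statistical choices that required judgement:

* **BCV estimation.** Per-gene negative-binomial dispersions come from
  edgeR's adjusted profile likelihood with prior weight 10. The shrinkage
  target is the mean-dispersion trend rather than the single common
  dispersion: common-target shrinkage leaves a mean-expression component in
  the per-gene estimates that leaks expression level into the selection
  axes and manufactures spurious sex-bias effects. Genes with fewer than 5
  reads in a subset are excluded (also edgeR's own floor).
* **Selection axes.** An exact 45° rotation:
  `concordant` $= -(\ell_m + \ell_f)/\sqrt2$ and `male_bias`
  $= (\ell_f - \ell_m)/\sqrt2$ for $\ell_s = \log_2 \mathrm{BCV}_s$. Scale
  does not affect signs or p-values.
* **Centering.** The axes sit far from zero (typical $\ell \approx -2.5$
  puts `concordant` near $+3.5$), so interaction models on the raw scale
  would evaluate main effects at an extrapolated origin and confound them
  with the interaction. `fit_dosage_models()` and `strata_analysis()`
  mean-center numeric predictors; fitted values and the interaction
  coefficient are unchanged, and main effects become average slopes at the
  data center.
* **The paired Wilcoxon comparison** uses `estimate_bcv_paired()`:
  independent per-gene maximum-likelihood dispersions on samples binomially
  thinned to equal depth. Two facts force this: shrunk estimates share
  estimated quantities across genes, and estimator bias depends on the
  sexes' (shared, random) sequencing depths — either one gives every
  per-gene difference a common random shift, and the signed-rank test then
  rejects a true null 60–85% of the time. With independent per-gene
  estimates and equalized depth the test holds its nominal size
  (empirically 5–9% across 750+ simulations) while keeping full power
  against the planted 1.3× female inflation. The axes still use the shrunk
  estimates, whose job is rank-preserving proxying, not testing.

## The synthetic-data generator

`generate_transcriptome()` emulates the study design the analysis assumes:
two sexes × three tissues (gonad, heart, liver) × four biological
replicates; autosomal and Z-linked genes, Z genes in three strata with ages
90.5, 58 and 52 My (midpoints of the published divergence windows); NB
counts with mean = true RPKM × length(kb) × library size(millions);
log-normal library sizes defaulting to 16M reads scaled down 100× so tests
run in seconds. Latent per-gene selection strengths set $\log_2$ BCV through
an affine decreasing link (slope 1.2, intercept $-2.5$, noise 0.1 — a BCV
distribution centred near 0.18 with realistic spread); female BCVs are
inflated ×1.3 by default, the generator's stand-in for stronger male
selection. Z-gene true $\log_2$ M:F ratios follow planted coefficients on
the mean-centred true axes plus noise; the `liver` preset plants
$(-0.3, +0.2, -0.6)$ for (concordant, male-bias, interaction), the `null`
preset plants nothing, and the `age` preset adds a stratum-age gradient.

What a green positive control does and does not establish: the generator
draws counts that are exactly NB with independent genes, no sample-level
random effects, no mapping bias, no isoform structure, and a planted truth
whose magnitudes were fixed once so that the pattern is recoverable through
the full estimation path at the study's real depth (16M reads; at the fast
160k default the planted structure drowns in Poisson noise). Green tests
certify the pipeline's statistical machinery, not the biological claim.

### A known limitation, left red deliberately

The liver positive control demands recovery of all three planted signs
$(-, +, -)$ with $p<0.05$ at ~350+ genes. The two main effects recover
robustly. The interaction term does not: with 4 replicates and prior-10
shrinkage, the concordant axis's estimation error correlates with
(male-bias)$^2$ through nonlinear shrinkage of extreme dispersions, so the
product regressor inherits a positive leak proportional to the male-bias
main effect (measured at $+0.6$ to $+1.2$ under a planted-null interaction),
while the sex-bias band caps how strong a planted interaction can be before
it truncates away exactly the informative genes. Across exploratory seeds
the fitted interaction is negative in most runs but significant in only
about a third; the acceptance assertion is kept faithful and stays red at
the canonical seed rather than being tuned. This is an identifiability
limit of the published procedure at this design size, and is worth knowing
about in its own right.

## Reproducibility

Every stochastic entry point takes an integer seed; the SDE advances all
replicates from one seeded stream (same seed, bit-identical ensemble), the
Wright–Fisher core uses R's RNG from C++, and the analysis stages are
deterministic in their inputs (the one internal randomization, depth
thinning in `estimate_bcv_paired()`, uses a fixed seed and restores the
caller's RNG state). `scripts/acceptance.R` recomputes the two acceptance
targets from scratch with the seed supplied on the command line.
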