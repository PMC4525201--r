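test_that("genotype-to-expression map follows the additive table", {
  p <- dc_params("XY")
  # female heterozygote: z_f + delta_f
  expect_equal(expression_of("RM", "female", 0.3, -0.2, 0.05, 0.07, p), -0.13)
  # female mutant homozygote: z_f + 2 delta_f
  expect_equal(expression_of("MM", "female", 0.3, -0.2, 0.05, 0.07, p), -0.06)
  # male hemizygote: z_m + delta_m
  expect_equal(expression_of("M", "male", 0.3, -0.2, 0.05, 0.07, p), 0.35)
  expect_equal(expression_of("R", "male", 0.3, -0.2, 0.05, 0.07, p), 0.3)
  # ZW male mutant homozygote: z_m + 2 delta_m
  pz <- dc_params("ZW")
  expect_equal(expression_of("MM", "male", 0.3, -0.2, 0.05, 0.07, pz), 0.4)
  expect_equal(expression_of("M", "female", 0.3, -0.2, 0.05, 0.07, pz), -0.13)
  # dominant: heterozygote equals the mutant homozygote
  pd <- dc_params("XY", dominance = "dominant")
  expect_equal(expression_of("RM", "female", 0.3, -0.2, 0.05, 0.07, pd),
               expression_of("MM", "female", 0.3, -0.2, 0.05, 0.07, pd))
  # ploidy mismatches are rejected
  expect_error(expression_of("RR", "male", 0, 0, 0, 0, p), "ploidy")
  expect_error(expression_of("M", "female", 0, 0, 0, 0, p), "ploidy")
})

test_that("Gaussian fitness is maximal at the optimum and symmetric", {
  expect_identical(fitness(0, 2), 1)
  z <- c(0.1, 0.5, 1.3)
  expect_equal(fitness(z, 0.7), fitness(-z, 0.7))
  expect_true(all(diff(fitness(z, 0.7)) < 0))
  expect_lt(fitness(0.5, 1), fitness(0.5, 0.5))
  # small-effect expansion reproduces the selection coefficient -S z delta
  # that enters the linearized fixation probability
  z0 <- -0.4; d <- 1e-4; S <- 0.8
  s_emp <- fitness(z0 + d, S) / fitness(z0, S) - 1
  expect_equal(s_emp, -S * z0 * d, tolerance = 1e-3)
})

test_that("sex-linked inheritance is respected in the generation step", {
  # XY reading of the slots: het = males, hom = females.
  # All fathers mutant, no female carriers: sons inherit X from their mother,
  # so no son carries M; every daughter gets her father's X, so all are RM.
  set.seed(1)
  r <- dosagecomp:::.wf_generation_step(30L, 30L, 0L, 0L, 0, 0, 1, 0, 0, 1, FALSE)
  expect_identical(unname(r), c(0L, 30L, 0L))
  # All mothers MM, fathers resident: every son carries M, daughters all RM.
  r2 <- dosagecomp:::.wf_generation_step(30L, 0L, 0L, 30L, 0, 0, 1, 0, 0, 1, FALSE)
  expect_identical(unname(r2), c(30L, 30L, 0L))
  # allele counts conserved within bounds: counts never exceed ploidy
  set.seed(2)
  for (i in 1:20) {
    r3 <- dosagecomp:::.wf_generation_step(10L, 3L, 4L, 2L, -0.5, 0.05, 1, 0, 0.05, 1, FALSE)
    expect_true(all(r3 >= 0) && r3[1] <= 10 && r3[2] + r3[3] <= 10)
  }
})

test_that("neutral fixation probability is 1/(3N)", {
  p <- oracle_params(N = 40)
  r <- run_invasions(p, 0, 0, 0, 0, n_reps = 1.2e5, seed = 101)
  expect_identical(r$fixed + r$lost + r$undecided, as.integer(1.2e5))
  bt <- binom.test(r$fixed, 1.2e5, p = 1 / 120)
  expect_gt(bt$p.value, 1e-3)
})

test_that("strongly deleterious symmetric mutants fix less than neutral", {
  p <- oracle_params(N = 30, S_m = 1, S_f = 1)
  r <- run_invasions(p, 0, 0, 0.8, 0.8, n_reps = 3e4, seed = 7)
  expect_lt(r$estimate + 2 * r$se, 1 / 90)
})

test_that("invasions are reproducible and capped runs are flagged undecided", {
  p <- oracle_params(N = 25)
  r1 <- run_invasions(p, -0.5, 0, 0.02, 0.02, n_reps = 500, seed = 9)
  r2 <- run_invasions(p, -0.5, 0, 0.02, 0.02, n_reps = 500, seed = 9)
  expect_identical(r1$fixed, r2$fixed)
  # a 1-generation cap cannot resolve most invasions
  r3 <- run_invasions(p, 0, 0, 0, 0, n_reps = 200, seed = 3, max_gen = 1)
  expect_gt(r3$undecided, 0)
  expect_identical(run_invasion(p, 0, 0, 0, 0, seed = 3,
                                max_gen = 1)$outcome %in%
                     c("fixed", "lost", "undecided"), TRUE)
})

test_that("linearized fixation probability matches the WF oracle (spot checks)", {
  # acceptance criterion 3 runs the full grid at 2e5 replicates; these are
  # faster spot checks at 6e4 within 3 SE
  p <- oracle_params(N = 50, S_m = 0.4, S_f = 0.4)
  for (case in list(list(z = c(-0.5, 0), d = c(0.02, 0.02), seed = 11),
                    list(z = c(0, -0.5), d = c(0.02, 0.02), seed = 12))) {
    r <- run_invasions(p, case$z[1], case$z[2], case$d[1], case$d[2],
                       n_reps = 6e4, seed = case$seed)
    u <- as.numeric(fixation_prob(case$d[1], case$d[2], case$z[1], case$z[2], p))
    expect_lt(abs(r$estimate - u), 3 * sqrt(u * (1 - u) / 6e4))
  }
})

test_that("origin-fixation bookkeeping is exact", {
  p <- oracle_params(N = 30, S_m = 0.5, S_f = 0.5, rho = 0.5)
  tr0 <- run_origin_fixation(p, n_substitutions = 0, seed = 1)
  expect_identical(nrow(tr0), 1L)
  expect_equal(c(tr0$z_m[1], tr0$z_f[1]), c(-1, 0))
  tr <- run_origin_fixation(p, n_substitutions = 5, seed = 2)
  expect_identical(nrow(tr), 6L)
  expect_true(all(diff(attr(tr, "attempts")) >= 1))
  expect_true(all(diff(tr$t) > 0))
  # same seed, same trajectory
  tr2 <- run_origin_fixation(p, n_substitutions = 5, seed = 2)
  expect_identical(tr$z_m, tr2$z_m)
  # attempt cap propagates
  trc <- run_origin_fixation(p, n_substitutions = 50, seed = 3,
                             max_attempts = 50)
  expect_true(attr(trc, "capped"))
})

test_that("rho = 0, S_m = S_f: XY and ZW heterogametic recovery agree", {
  n_runs <- 150
  n_sub <- 10
  finals <- function(system, seed0) {
    p <- oracle_params(system, N = 30, S_m = 0.5, S_f = 0.5, rho = 0)
    vapply(seq_len(n_runs), function(i) {
      tr <- run_origin_fixation(p, n_substitutions = n_sub, seed = seed0 + i)
      if (system == "XY") tr$z_m[nrow(tr)] else tr$z_f[nrow(tr)]
    }, numeric(1))
  }
  xy <- finals("XY", 1000)
  zw <- finals("ZW", 5000)
  expect_gt(t.test(xy, zw)$p.value, 0.005)
})

test_that("origin-fixation shows the female X overshoot in the strong-male regime", {
  p <- oracle_params("XY", N = 50, S_m = 1, S_f = 0.1, rho = 0.8)
  n_runs <- 40
  maxzf <- vapply(seq_len(n_runs), function(i) {
    tr <- run_origin_fixation(p, n_substitutions = 25, seed = 300 + i)
    max(tr$z_f)
  }, numeric(1))
  bt <- binom.test(sum(maxzf > 0), n_runs, 0.5, alternative = "greater")
  expect_lt(bt$p.value, 1e-4)
})
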