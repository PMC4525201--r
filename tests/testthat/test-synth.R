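test_that("generation is bit-identical under a fixed seed", {
  d <- study_design(tissues = "liver", n_autosomal = 60, n_z = 30)
  a <- generate_transcriptome(d, truth_config(), seed = 5)
  b <- generate_transcriptome(d, truth_config(), seed = 5)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  c2 <- generate_transcriptome(d, truth_config(), seed = 6)
  expect_false(identical(a$counts, c2$counts))
})

test_that("dataset structure matches the design", {
  d <- study_design(n_reps = 3, n_autosomal = 40, n_z = 20)
  ds <- generate_transcriptome(d, truth_config(), seed = 1)
  expect_identical(dim(ds$counts), c(60L, 3L * 2L * 3L))
  expect_identical(colnames(ds$counts), ds$samples$sample)
  expect_true(all(ds$counts >= 0))
  expect_true(is.integer(ds$counts) || all(ds$counts == round(ds$counts)))
  # every Z gene has exactly one stratum; autosomal genes have none
  expect_true(all(!is.na(ds$annotation$stratum[ds$annotation$chrom == "Z"])))
  expect_true(all(is.na(ds$annotation$stratum[ds$annotation$chrom == "A"])))
  expect_true(all(table(ds$samples$tissue) == 6))
  expect_error(study_design(n_reps = 1), "n_reps")
})

test_that("near-Poisson truth yields near-zero BCV estimates", {
  d <- study_design(tissues = "liver", n_autosomal = 400, n_z = 0,
                    lib_size_sdlog = 0)
  tc <- truth_config(regime = "null", female_bcv_factor = 1,
                     bcv_log2_intercept = -7, bcv_log2_noise = 0.01,
                     mean_log2_rpkm = 7, sd_log2_rpkm = 0.3)
  ds <- generate_transcriptome(d, tc, seed = 2)
  sx <- ds$samples$sex
  bcv <- quiet_bcv(ds$counts[, sx == "male"], prior_df = 10)
  expect_lt(median(bcv$bcv), 0.05)
})

test_that("method-of-moments recovers the planted NB moments", {
  # equal library sizes so each gene's counts are iid NB within a sex
  d <- study_design(tissues = "liver", n_reps = 4, n_autosomal = 500, n_z = 0,
                    lib_size_sdlog = 0)
  tc <- truth_config(regime = "null", female_bcv_factor = 1.3)
  ds <- generate_transcriptome(d, tc, seed = 3)
  sx <- ds$samples$sex
  tr <- ds$truth
  for (s in c("male", "female")) {
    cts <- ds$counts[, sx == s, drop = FALSE]
    mu_expect <- (if (s == "male") 2^(tr$base_log2_rpkm + tr$log2_mf_ratio_true / 2)
                  else 2^(tr$base_log2_rpkm - tr$log2_mf_ratio_true / 2)) *
      (ds$annotation$length / 1000) *
      (ds$samples$lib_size_target[sx == s][1] / 1e6)
    m <- rowMeans(cts)
    # relative mean error, averaged over genes, within 3 SE of zero
    rel <- (m - mu_expect) / mu_expect
    expect_lt(abs(mean(rel)), 3 * sd(rel) / sqrt(length(rel)))
    # dispersion: mean MoM estimate across genes near mean planted dispersion
    v <- apply(cts, 1, var)
    mom <- (v - m) / m^2
    disp_true <- if (s == "male") tr$dispersion_m else tr$dispersion_f
    expect_lt(abs(mean(mom) - mean(disp_true)),
              3 * sd(mom) / sqrt(length(mom)))
  }
})

test_that("autosomal genes carry no systematic sex bias", {
  d <- study_design(tissues = "heart", n_autosomal = 600, n_z = 0)
  ds <- generate_transcriptome(d, truth_config(regime = "null"), seed = 4)
  sx <- ds$samples$sex
  rp <- rpkm_matrix(ds$counts, ds$annotation$length)
  keep <- filter_expressed(rp, sx)
  r <- mf_ratio(rp[keep, ], sx)
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)) + 0.02)
})

test_that("datasets round-trip through TSV files", {
  d <- study_design(tissues = c("gonad", "liver"), n_autosomal = 30, n_z = 15)
  ds <- generate_transcriptome(d, truth_config(), seed = 8)
  dir <- tempfile("synth")
  on.exit(unlink(dir, recursive = TRUE))
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("counts.tsv", "annotation.tsv",
                                               "samples.tsv", "truth.tsv")))))
  back <- read_dataset(dir)
  expect_equal(unname(back$counts), unname(ds$counts))
  expect_identical(back$annotation$gene_id, ds$annotation$gene_id)
  expect_equal(back$truth$log2_mf_ratio_true, ds$truth$log2_mf_ratio_true,
               tolerance = 1e-9)
})

test_that("empty gene sets produce valid header-only files", {
  d <- study_design(tissues = "liver", n_autosomal = 0, n_z = 0)
  ds <- generate_transcriptome(d, truth_config(), seed = 1)
  dir <- tempfile("synth0")
  on.exit(unlink(dir, recursive = TRUE))
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(nrow(back$counts), 0L)
  expect_identical(nrow(back$annotation), 0L)
})

test_that("planted female BCV inflation is visible to the Wilcoxon comparison", {
  d <- study_design(tissues = "liver", n_autosomal = 2000, n_z = 0)
  ds <- generate_transcriptome(d, truth_config(regime = "null",
                                               female_bcv_factor = 1.3),
                               seed = 10)
  sx <- ds$samples$sex
  wb <- suppressMessages(
    estimate_bcv_paired(ds$counts[, sx == "male"], ds$counts[, sx == "female"]))
  w <- compare_bcv_by_sex(wb$male$log2_bcv, wb$female$log2_bcv)
  expect_lt(w$p, 0.05)
})
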