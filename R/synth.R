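# Synthetic chicken-style RNA-seq counts with planted ground truth: two sexes,
# three tissues, four biological replicates, negative-binomial counts whose
# per-gene dispersions encode latent selection strengths, and Z-linked
# male:female ratios tied to the selection axes by planted coefficients.

#' Study design for the synthetic transcriptome
#'
#' @param tissues Tissue names (default gonad, heart, liver; a fourth tissue
#'   may be added, only three are analysed by default downstream).
#' @param n_reps Biological replicates per sex per tissue (>= 2; BCV
#'   estimation needs within-group variance).
#' @param n_autosomal,n_z Numbers of autosomal and Z-linked genes.
#' @param strata_props Proportions of Z genes in strata 1..3 (oldest first).
#' @param strata_ages Stratum ages in My (midpoints of the published
#'   divergence ranges 75-106, 45-71, 36-68).
#' @param lib_size_mean,lib_size_sdlog Log-normal library-size distribution;
#'   default emulates 16M mappable reads scaled down 100x so tests run fast.
#' @param length_meanlog,length_sdlog Log-normal gene-length distribution (bp).
#' @return A \code{dc_design} list.
#' @export
study_design <- function(tissues = c("gonad", "heart", "liver"), n_reps = 4,
                         n_autosomal = 2000, n_z = 500,
                         strata_props = c(0.45, 0.30, 0.25),
                         strata_ages = c(90.5, 58, 52),
                         lib_size_mean = 160000, lib_size_sdlog = 0.15,
                         length_meanlog = log(1500), length_sdlog = 0.45) {
  stopifnot(n_reps >= 2, n_autosomal >= 0, n_z >= 0,
            length(strata_props) == 3, abs(sum(strata_props) - 1) < 1e-8,
            length(strata_ages) == 3)
  d <- list(tissues = tissues, n_reps = n_reps, n_autosomal = n_autosomal,
            n_z = n_z, strata_props = strata_props, strata_ages = strata_ages,
            lib_size_mean = lib_size_mean, lib_size_sdlog = lib_size_sdlog,
            length_meanlog = length_meanlog, length_sdlog = length_sdlog)
  class(d) <- "dc_design"
  d
}

#' Ground-truth configuration for the generator
#'
#' The latent per-gene selection strengths are \code{sel = concordant_latent
#' +/- bias_latent} per sex; log2 BCV is an affine decreasing function of
#' selection strength plus noise, and female BCVs are inflated by
#' \code{female_bcv_factor} (the generator's analogue of stronger male
#' selection). For Z genes the true log2 male:female ratio follows planted
#' coefficients on the true (concordant, male-bias) selection axes:
#' \code{ratio = r0 + rc*concordant + rb*male_bias + rcb*concordant*male_bias
#' + noise}. Presets: \code{"liver"} plants the signs (-, +, -) reported for
#' liver-regime dynamics; \code{"null"} plants no dependence; \code{"age"}
#' adds a stratum-age gradient \code{r_age} per My.
#'
#' @param regime "liver", "null" or "age".
#' @param female_bcv_factor Multiplicative female BCV inflation (default 1.3).
#' @param bcv_log2_intercept,bcv_log2_slope log2 BCV = intercept -
#'   slope * selection + N(0, bcv_log2_noise). The defaults give a BCV
#'   distribution centred near 0.18 with a realistic transcriptome-scale
#'   spread (roughly 0.06-0.5).
#' @param bcv_log2_noise Gene-level log2 BCV noise SD.
#' @param r0,rc,rb,rcb,r_age Ratio model coefficients (defaults depend on
#'   \code{regime}; they apply to the mean-centred true axes).
#' @param ratio_noise SD of gene-level ratio noise.
#' @param mean_log2_rpkm,sd_log2_rpkm Baseline expression distribution.
#' @return A \code{dc_truth_config} list.
#' @export
truth_config <- function(regime = c("liver", "null", "age"),
                         female_bcv_factor = 1.3,
                         bcv_log2_intercept = -2.5, bcv_log2_slope = 1.2,
                         bcv_log2_noise = 0.1,
                         r0 = 0.5, rc = NULL, rb = NULL, rcb = NULL,
                         r_age = NULL, ratio_noise = 0.05,
                         mean_log2_rpkm = 5.5, sd_log2_rpkm = 1.3) {
  regime <- match.arg(regime)
  if (is.null(rc)) rc <- switch(regime, liver = -0.3, null = 0, age = 0)
  if (is.null(rb)) rb <- switch(regime, liver = 0.2, null = 0, age = 0)
  if (is.null(rcb)) rcb <- switch(regime, liver = -0.6, null = 0, age = 0)
  if (is.null(r_age)) r_age <- switch(regime, age = -0.005, 0)
  cfg <- list(regime = regime, female_bcv_factor = female_bcv_factor,
              bcv_log2_intercept = bcv_log2_intercept,
              bcv_log2_slope = bcv_log2_slope, bcv_log2_noise = bcv_log2_noise,
              r0 = r0, rc = rc, rb = rb, rcb = rcb, r_age = r_age,
              ratio_noise = ratio_noise,
              mean_log2_rpkm = mean_log2_rpkm, sd_log2_rpkm = sd_log2_rpkm)
  class(cfg) <- "dc_truth_config"
  cfg
}

#' Generate a synthetic transcriptome dataset
#'
#' Draws gene annotations, per-gene/tissue/sex ground truth and
#' negative-binomial counts with mean = (true RPKM) x (length in kb) x
#' (library size in millions) and per-sex dispersion BCV^2.
#'
#' @param design A \code{\link{study_design}}.
#' @param truth A \code{\link{truth_config}}.
#' @param seed Integer seed (same seed, same design: bit-identical output).
#' @return A list (class \code{dc_dataset}) with \code{counts} (genes x
#'   samples integer matrix), \code{annotation} (gene_id, chrom, length,
#'   stratum, stratum_age), \code{samples} (sample, sex, tissue, replicate)
#'   and \code{truth} (per gene x tissue: baseline RPKM, per-sex selection,
#'   BCV and dispersion, true log2 M:F ratio, true axis coordinates, planted
#'   coefficients as attributes).
#' @export
generate_transcriptome <- function(design = study_design(),
                                   truth = truth_config(), seed = 1) {
  stopifnot(inherits(design, "dc_design"), inherits(truth, "dc_truth_config"))
  set.seed(seed)
  n_genes <- design$n_autosomal + design$n_z
  gene_id <- sprintf("g%05d", seq_len(max(n_genes, 1)))[seq_len(n_genes)]
  chrom <- rep(c("A", "Z"), c(design$n_autosomal, design$n_z))
  stratum <- rep(NA_integer_, n_genes)
  if (design$n_z > 0) {
    k <- design$n_z
    ns <- floor(design$strata_props * k)
    ns[1] <- k - sum(ns[-1])
    stratum[chrom == "Z"] <- rep(1:3, ns)
  }
  stratum_age <- design$strata_ages[stratum]
  len <- pmax(200, round(stats::rlnorm(n_genes, design$length_meanlog,
                                       design$length_sdlog)))
  annotation <- data.frame(gene_id = gene_id, chrom = chrom, length = len,
                           stratum = stratum, stratum_age = stratum_age,
                           stringsAsFactors = FALSE)

  tissues <- design$tissues
  samples <- expand.grid(replicate = seq_len(design$n_reps),
                         sex = c("male", "female"), tissue = tissues,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("sex", "tissue", "replicate")]
  samples$sample <- sprintf("%s_%s_r%d", substr(samples$sex, 1, 1),
                            samples$tissue, samples$replicate)
  samples <- samples[, c("sample", "sex", "tissue", "replicate")]
  lib <- stats::rlnorm(nrow(samples),
                       log(design$lib_size_mean) - design$lib_size_sdlog^2 / 2,
                       design$lib_size_sdlog)
  samples$lib_size_target <- round(lib)

  truth_rows <- list()
  counts <- matrix(0L, n_genes, nrow(samples),
                   dimnames = list(gene_id, samples$sample))
  for (tis in tissues) {
    base_l2rpkm <- stats::rnorm(n_genes, truth$mean_log2_rpkm, truth$sd_log2_rpkm)
    conc_lat <- stats::rnorm(n_genes, 0, 0.5)
    bias_lat <- stats::rnorm(n_genes, 0, 0.5)
    sel_m <- conc_lat + bias_lat
    sel_f <- conc_lat - bias_lat
    l2bcv_m <- truth$bcv_log2_intercept - truth$bcv_log2_slope * sel_m +
      stats::rnorm(n_genes, 0, truth$bcv_log2_noise)
    l2bcv_f <- truth$bcv_log2_intercept - truth$bcv_log2_slope * sel_f +
      stats::rnorm(n_genes, 0, truth$bcv_log2_noise) +
      log2(truth$female_bcv_factor)
    conc_true <- -(l2bcv_m + l2bcv_f) / sqrt(2)
    bias_true <- (l2bcv_f - l2bcv_m) / sqrt(2)
    ratio <- rep(0, n_genes)
    isz <- chrom == "Z"
    age_c <- ifelse(is.na(stratum_age), 0, stratum_age - mean(design$strata_ages))
    # coefficients apply to mean-centered axes so that r0 is the average
    # Z-gene ratio and the planted main effects are local slopes at the data
    # center (the raw axes sit far from zero)
    conc_c <- conc_true - mean(conc_true[isz])   # zero-length Z set: unused
    bias_c <- bias_true - mean(bias_true[isz])
    ratio[isz] <- truth$r0 + truth$rc * conc_c[isz] +
      truth$rb * bias_c[isz] + truth$rcb * conc_c[isz] * bias_c[isz] +
      truth$r_age * age_c[isz] +
      stats::rnorm(sum(isz), 0, truth$ratio_noise)
    rpkm_m <- 2^(base_l2rpkm + ratio / 2)
    rpkm_f <- 2^(base_l2rpkm - ratio / 2)
    disp_m <- (2^l2bcv_m)^2
    disp_f <- (2^l2bcv_f)^2
    sel <- samples$tissue == tis
    for (j in which(sel)) {
      male <- samples$sex[j] == "male"
      mu <- (if (male) rpkm_m else rpkm_f) * (len / 1000) *
        (samples$lib_size_target[j] / 1e6)
      size <- 1 / (if (male) disp_m else disp_f)
      counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = size)
    }
    truth_rows[[tis]] <- data.frame(
      gene_id = gene_id, tissue = rep(tis, n_genes),
      base_log2_rpkm = base_l2rpkm,
      sel_m = sel_m, sel_f = sel_f,
      log2_bcv_m = l2bcv_m, log2_bcv_f = l2bcv_f,
      dispersion_m = disp_m, dispersion_f = disp_f,
      concordant_true = conc_true, male_bias_true = bias_true,
      log2_mf_ratio_true = ratio, stringsAsFactors = FALSE)
  }
  truth_df <- do.call(rbind, truth_rows)
  rownames(truth_df) <- NULL
  attr(truth_df, "coefficients") <- truth[c("r0", "rc", "rb", "rcb", "r_age")]
  out <- list(counts = counts, annotation = annotation,
              samples = samples[, c("sample", "sex", "tissue", "replicate",
                                    "lib_size_target")],
              truth = truth_df, design = design, truth_config = truth,
              seed = seed)
  class(out) <- "dc_dataset"
  out
}

#' @export
print.dc_dataset <- function(x, ...) {
  cat(sprintf("Synthetic transcriptome: %d genes (%d autosomal, %d Z) x %d samples, seed %d\n",
              nrow(x$counts), sum(x$annotation$chrom == "A"),
              sum(x$annotation$chrom == "Z"), ncol(x$counts), x$seed))
  invisible(x)
}

#' Write / read a dataset as TSV files
#'
#' Writes \code{counts.tsv} (gene x sample), \code{annotation.tsv},
#' \code{samples.tsv} and \code{truth.tsv} into \code{dir}. A write/read
#' round trip restores identical values.
#'
#' @param dataset A \code{dc_dataset} (or a list with at least counts,
#'   annotation, samples).
#' @param dir Output directory (created if needed).
#' @return \code{write_dataset}: \code{dir} invisibly; \code{read_dataset}:
#'   a \code{dc_dataset} (without generator config).
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f) {
    path <- file.path(dir, f)
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) stop("failed writing ", path, ": ",
                                conditionMessage(e)))
    ok
  }
  cdf <- data.frame(gene_id = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wt(cdf, "counts.tsv")
  wt(dataset$annotation, "annotation.tsv")
  wt(dataset$samples, "samples.tsv")
  if (!is.null(dataset$truth)) wt(dataset$truth, "truth.tsv")
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  rd <- function(f) utils::read.delim(file.path(dir, f), check.names = FALSE,
                                      stringsAsFactors = FALSE)
  cdf <- rd("counts.tsv")
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- cdf$gene_id
  truth_path <- file.path(dir, "truth.tsv")
  out <- list(counts = counts, annotation = rd("annotation.tsv"),
              samples = rd("samples.tsv"),
              truth = if (file.exists(truth_path)) rd("truth.tsv") else NULL,
              seed = NA_integer_)
  class(out) <- "dc_dataset"
  out
}
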