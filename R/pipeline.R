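# Count-matrix-to-conclusions analysis: TMM normalization on autosomal genes,
# RPKM, expression filtering, BCV estimation with shrinkage (edgeR), selection
# axes, sex-bias filtering, dosage-compensation regressions, paired rank tests
# and strata analyses.

#' TMM normalization factors
#'
#' Weighted trimmed-mean-of-M-values scaling factors (Robinson & Oshlack), as
#' implemented in edgeR. To limit the impact of incomplete dosage compensation
#' on normalization, factors can be computed from autosomal genes only
#' (the default when an annotation is supplied) while library sizes remain the
#' full-matrix column totals. Factors are normalized to geometric mean 1.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @param annotation Optional annotation data frame with \code{gene_id} and
#'   \code{chrom} ("A" for autosomal); required if \code{autosomal_only}.
#' @param autosomal_only Use autosomal genes only (default TRUE when an
#'   annotation is given).
#' @param lib_size Optional library sizes; default full column sums.
#' @return Named vector of normalization factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, annotation = NULL,
                        autosomal_only = !is.null(annotation),
                        lib_size = colSums(counts)) {
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(lib_size == 0)) stop("all-zero sample in count matrix")
  use <- counts
  if (autosomal_only) {
    if (is.null(annotation)) stop("autosomal_only requires an annotation")
    auto <- annotation$gene_id[annotation$chrom == "A"]
    use <- counts[rownames(counts) %in% auto, , drop = FALSE]
  }
  f <- edgeR::calcNormFactors(use, lib.size = lib_size, method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Reads per kilobase per million mapped reads
#'
#' \code{count / (length_kb x effective_library_size_in_millions)}.
#'
#' @param counts Genes x samples count matrix.
#' @param lengths Gene lengths in bp, aligned with \code{rownames(counts)}.
#' @param eff_lib_size Effective library sizes (e.g. column totals x TMM
#'   factors).
#' @return RPKM matrix of the same shape.
#' @export
rpkm_matrix <- function(counts, lengths, eff_lib_size = colSums(counts)) {
  if (length(lengths) != nrow(counts) || anyNA(lengths))
    stop("missing gene length")
  stopifnot(all(lengths > 0), length(eff_lib_size) == ncol(counts))
  sweep(counts / (lengths / 1000), 2, eff_lib_size / 1e6, "/")
}

#' Expression filter
#'
#' A gene is retained iff there exists a sex in which every replicate has
#' \code{log2(RPKM) >= threshold} (genes "not expressed in all individuals of
#' at least one sex" are excluded). Raising the threshold never adds genes.
#'
#' @param rpkm RPKM matrix for one tissue (genes x samples).
#' @param sex Character vector ("male"/"female") per column.
#' @param threshold_log2 log2-RPKM threshold (default 1).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(rpkm, sex, threshold_log2 = 1) {
  stopifnot(length(sex) == ncol(rpkm))
  thr <- 2^threshold_log2
  ok_m <- rowSums(rpkm[, sex == "male", drop = FALSE] < thr) == 0
  ok_f <- rowSums(rpkm[, sex == "female", drop = FALSE] < thr) == 0
  rownames(rpkm)[ok_m | ok_f]
}

#' Per-gene log2 male:female expression ratio
#'
#' \code{log2(mean male RPKM) - log2(mean female RPKM)}; averaging is on the
#' linear scale. Genes with a zero mean in either sex get \code{NA} (flagged,
#' not +-Inf).
#'
#' @inheritParams filter_expressed
#' @return Named numeric vector of log2 ratios.
#' @export
mf_ratio <- function(rpkm, sex) {
  stopifnot(length(sex) == ncol(rpkm))
  m <- rowMeans(rpkm[, sex == "male", drop = FALSE])
  f <- rowMeans(rpkm[, sex == "female", drop = FALSE])
  r <- ifelse(m > 0 & f > 0, log2(m) - log2(f), NA_real_)
  names(r) <- rownames(rpkm)
  r
}

#' Biological coefficient of variation with shrinkage
#'
#' Per-gene negative-binomial dispersions for one tissue x sex subset, by
#' edgeR's adjusted profile likelihood shrunk toward the common (all-gene)
#' dispersion with prior weight \code{prior_df} (default 10, the value used
#' throughout this pipeline). BCV is the square root of the dispersion. Genes
#' with zero counts in every replicate are excluded.
#'
#' @param counts Count matrix for one tissue and one sex (genes x replicates,
#'   >= 2 columns).
#' @param lib_size Optional (effective) library sizes.
#' @param prior_df Shrinkage prior weight; a very large value collapses every
#'   gene onto the shrinkage target.
#' @param trend Shrinkage target: \code{"locfit"} (default) shrinks toward a
#'   mean-dependent dispersion trend, which removes the mean-expression
#'   component from per-gene BCV estimates (low-count genes otherwise inherit
#'   spuriously inflated dispersions that leak expression level into the
#'   selection axes); \code{"none"} shrinks toward the single common
#'   dispersion.
#' @return Data frame \code{gene_id}, \code{dispersion}, \code{bcv},
#'   \code{log2_bcv}, with the common dispersion and prior as attributes.
#'   Genes with fewer than 5 reads in total are excluded (edgeR's own
#'   \code{min.row.sum} default; such genes carry no usable dispersion
#'   information and trip a dimension bug in its no-trend code path).
#' @export
estimate_bcv <- function(counts, lib_size = colSums(counts), prior_df = 10,
                         trend = c("locfit", "none")) {
  trend <- match.arg(trend)
  if (ncol(counts) < 2) stop("need >= 2 replicates")
  keep <- rowSums(counts) >= 5
  counts <- counts[keep, , drop = FALSE]
  y <- edgeR::DGEList(counts = counts, lib.size = lib_size)
  y <- edgeR::estimateDisp(y, design = NULL, prior.df = prior_df,
                           trend.method = trend, tagwise = TRUE,
                           robust = FALSE)
  disp <- y$tagwise.dispersion
  out <- data.frame(gene_id = rownames(counts), dispersion = disp,
                    bcv = sqrt(disp), log2_bcv = log2(sqrt(disp)),
                    stringsAsFactors = FALSE)
  attr(out, "common_dispersion") <- y$common.dispersion
  attr(out, "prior_df") <- prior_df
  out
}

#' Paired per-gene BCV estimation for the male-female comparison
#'
#' Independent per-gene negative-binomial maximum-likelihood dispersions for
#' the two sexes, with library sizes as offsets and no information sharing
#' across genes. The shrunk estimates of \code{\link{estimate_bcv}} borrow
#' strength across genes through shared quantities (common dispersion,
#' quantile-adjusted pseudo-counts, abundance trend), which makes their
#' estimation errors correlated across genes; per-gene male-female
#' differences then inherit a common random shift and the signed-rank test
#' of \code{\link{compare_bcv_by_sex}} rejects a true null far above its
#' nominal level (empirically 60-85 percent). The unshrunk per-gene
#' estimates here are independent and symmetric between sexes, so the
#' signed-rank null is exact; they are used only for the paired comparison,
#' while the selection axes keep the shrunk estimates.
#'
#' All samples are first binomially thinned to the smallest library depth.
#' Estimator bias depends on depth, and the two sexes' depths are shared by
#' every gene, so without thinning a chance depth asymmetry between the
#' sexes shifts all per-gene differences coherently and inflates the
#' signed-rank test's size. Thinning preserves the negative-binomial
#' dispersion exactly and uses a fixed internal seed (the caller's RNG
#' state is saved and restored), so the function remains deterministic in
#' its inputs.
#'
#' @param counts_m,counts_f Count matrices for the two sexes (same genes,
#'   >= 2 replicates each).
#' @param lib_size_m,lib_size_f Optional (effective) library sizes.
#' @return List with data frames \code{male} and \code{female} (columns
#'   \code{gene_id}, \code{dispersion}, \code{bcv}, \code{log2_bcv}),
#'   restricted to genes with at least 5 reads in both sexes, rows aligned.
#' @export
estimate_bcv_paired <- function(counts_m, counts_f,
                                lib_size_m = colSums(counts_m),
                                lib_size_f = colSums(counts_f)) {
  stopifnot(identical(rownames(counts_m), rownames(counts_f)))
  nm <- ncol(counts_m)
  all_counts <- cbind(counts_m, counts_f)
  lib <- c(lib_size_m, lib_size_f)
  if (any(lib <= 0)) stop("non-positive library size")
  rs <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(271828L)
  for (j in seq_len(ncol(all_counts)))
    all_counts[, j] <- stats::rbinom(nrow(all_counts), all_counts[, j],
                                     min(lib) / lib[j])
  if (!is.null(rs)) assign(".Random.seed", rs, envir = globalenv())
  counts_m <- all_counts[, seq_len(nm), drop = FALSE]
  counts_f <- all_counts[, -seq_len(nm), drop = FALSE]
  keep <- rowSums(counts_m) >= 5 & rowSums(counts_f) >= 5
  one_sex <- function(counts, lib) {
    counts <- counts[keep, , drop = FALSE]
    rel <- lib / mean(lib)
    disp <- vapply(seq_len(nrow(counts)), function(g) {
      x <- counts[g, ]
      mu <- (sum(x) / sum(rel)) * rel
      nll <- function(lphi)
        -sum(stats::dnbinom(x, mu = mu, size = exp(-lphi), log = TRUE))
      exp(stats::optimize(nll, c(-14, 3))$minimum)
    }, numeric(1))
    data.frame(gene_id = rownames(counts), dispersion = disp,
               bcv = sqrt(disp), log2_bcv = log2(sqrt(disp)),
               stringsAsFactors = FALSE)
  }
  # offsets re-derived from the thinned matrices
  list(male = one_sex(counts_m, colSums(counts_m)),
       female = one_sex(counts_f, colSums(counts_f)))
}

#' Sex-bias filter
#'
#' Removes strongly sex-biased genes before the dosage-compensation analyses.
#' The default band retains \code{log2(1/1.25) <= ratio <= log2(1.25/0.5)};
#' \code{preset = "symmetric"} uses the narrower 0.8 < ratio < 1.2 band on
#' the linear M:F scale. Both presets exist because both conventions are in
#' use in the dosage-compensation literature; the asymmetric band is the
#' documented default.
#'
#' @param ratios Named vector of log2 M:F ratios.
#' @param lower,upper Band bounds (log2 scale); overridden by \code{preset}.
#' @param preset \code{"asymmetric"} (default) or \code{"symmetric"}.
#' @return Names of retained genes.
#' @export
sexbias_filter <- function(ratios, lower = log2(1 / 1.25),
                           upper = log2(1.25 / 0.5),
                           preset = c("asymmetric", "symmetric")) {
  preset <- match.arg(preset)
  if (preset == "symmetric") { lower <- log2(0.8); upper <- log2(1.2) }
  names(ratios)[!is.na(ratios) & ratios >= lower & ratios <= upper]
}

#' Project sex-specific expression variability onto selection axes
#'
#' A 45-degree (distance-preserving) rotation of \code{(log2 BCV_m,
#' log2 BCV_f)}: \code{concordant = -(log2 BCV_m + log2 BCV_f)/sqrt(2)}
#' grows as selection strengthens in both sexes (both BCVs shrink);
#' \code{male_bias = (log2 BCV_f - log2 BCV_m)/sqrt(2)} grows as selection
#' strengthens in males and/or weakens in females.
#'
#' @param log2_bcv_m,log2_bcv_f Per-gene log2 BCV in males / females (missing
#'   values in either sex give NA in both axes).
#' @return Data frame \code{concordant}, \code{male_bias}.
#' @export
project_axes <- function(log2_bcv_m, log2_bcv_f) {
  stopifnot(length(log2_bcv_m) == length(log2_bcv_f))
  data.frame(concordant = -(log2_bcv_m + log2_bcv_f) / sqrt(2),
             male_bias = (log2_bcv_f - log2_bcv_m) / sqrt(2))
}

coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], row.names = NULL,
             stringsAsFactors = FALSE)
}

check_full_rank <- function(fit) {
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: aliased terms ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  fit
}

#' Linear models of dosage compensation against selection axes
#'
#' Ordinary least squares fits of the log2 male:female expression ratio on
#' the concordant-selection and male-bias coordinates: a pooled model with
#' tissue interactions (\code{ratio ~ concordant * male_bias * tissue}) and
#' per-tissue models (\code{ratio ~ concordant * male_bias}). Genes are
#' treated as statistically independent.
#'
#' The numeric predictors are mean-centered before fitting: the axes sit far
#' from zero on their raw scale (log2 BCVs are strongly negative), so in an
#' interaction model the uncentered main effects would be extrapolations to
#' an origin outside the data and their signs would be confounded with the
#' interaction. Centering makes each main effect the average slope at the
#' data center without changing fitted values or the interaction term.
#'
#' @param data Data frame with columns \code{ratio}, \code{concordant},
#'   \code{male_bias} and \code{tissue}.
#' @return List with \code{pooled} (coefficient table or NULL if a single
#'   tissue), \code{per_tissue} (named list of coefficient tables) and the
#'   fitted model formulas. Errors on rank-deficient designs.
#' @export
fit_dosage_models <- function(data) {
  stopifnot(all(c("ratio", "concordant", "male_bias", "tissue") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("ratio", "concordant", "male_bias")]), ]
  data$concordant <- data$concordant - mean(data$concordant)
  data$male_bias <- data$male_bias - mean(data$male_bias)
  per_tissue <- lapply(split(data, data$tissue), function(d) {
    coef_table(check_full_rank(stats::lm(ratio ~ concordant * male_bias, data = d)))
  })
  pooled <- NULL
  if (length(unique(data$tissue)) > 1) {
    pooled <- coef_table(check_full_rank(
      stats::lm(ratio ~ concordant * male_bias * tissue, data = data)))
  }
  list(pooled = pooled, per_tissue = per_tissue,
       formulas = c(pooled = "ratio ~ concordant * male_bias * tissue",
                    per_tissue = "ratio ~ concordant * male_bias"))
}

#' Paired Wilcoxon comparison of male and female BCV
#'
#' Wilcoxon signed-rank test on per-gene (male - female) log2 BCV. Uses the
#' exact null distribution for n <= 25 and the normal approximation with
#' continuity correction otherwise. If every difference is zero the test is
#' degenerate and reported as such.
#'
#' @param log2_bcv_m,log2_bcv_f Per-gene log2 BCV values (paired; NAs in
#'   either sex are dropped pairwise).
#' @return List with \code{V}, \code{p}, \code{n} (non-zero differences) and
#'   \code{degenerate}.
#' @export
compare_bcv_by_sex <- function(log2_bcv_m, log2_bcv_f) {
  stopifnot(length(log2_bcv_m) == length(log2_bcv_f))
  d <- log2_bcv_m - log2_bcv_f
  d <- d[!is.na(d)]
  if (!length(d) || all(d == 0))
    return(list(V = NA_real_, p = NA_real_, n = sum(d != 0), degenerate = TRUE))
  n_eff <- sum(d != 0)
  ht <- stats::wilcox.test(d, exact = n_eff <= 25, correct = TRUE)
  list(V = unname(ht$statistic), p = ht$p.value, n = n_eff, degenerate = FALSE)
}

#' Dosage compensation across Z-chromosome strata
#'
#' Fits the full-interaction linear model of the log2 M:F ratio on the two
#' selection axes, tissue and stratum age
#' (\code{ratio ~ concordant * male_bias * tissue * age}), and computes
#' per-stratum median Z:AA ratios in each sex (median Z-gene RPKM over the
#' sex's samples divided by the median autosomal RPKM). Strata contributing
#' fewer than 3 genes are flagged low-power.
#'
#' @param data Data frame with \code{ratio}, \code{concordant},
#'   \code{male_bias}, \code{tissue}, \code{age} (stratum age in My) and
#'   \code{stratum} for Z genes with an unambiguous stratum.
#' @param rpkm Optional RPKM matrix (genes x samples) for Z:AA ratios.
#' @param sex Sample sexes aligned with \code{colnames(rpkm)}.
#' @param annotation Annotation with \code{gene_id}, \code{chrom},
#'   \code{stratum}.
#' @return List with \code{model} (coefficient table), \code{za_ratios}
#'   (per stratum x sex medians, or NULL when rpkm not given) and
#'   \code{low_power_strata}.
#' @export
strata_analysis <- function(data, rpkm = NULL, sex = NULL, annotation = NULL) {
  stopifnot(all(c("ratio", "concordant", "male_bias", "tissue", "age",
                  "stratum") %in% names(data)))
  data <- data[stats::complete.cases(
    data[, c("ratio", "concordant", "male_bias", "age")]), ]
  # center numeric predictors (see fit_dosage_models for the rationale)
  for (v in c("concordant", "male_bias", "age"))
    data[[v]] <- data[[v]] - mean(data[[v]])
  single_tissue <- length(unique(data$tissue)) < 2
  fml <- if (single_tissue) ratio ~ concordant * male_bias * age
         else ratio ~ concordant * male_bias * tissue * age
  model <- coef_table(check_full_rank(stats::lm(fml, data = data)))
  tab <- table(data$stratum)
  low <- names(tab)[tab < 3]
  za <- NULL
  if (!is.null(rpkm)) {
    stopifnot(!is.null(sex), !is.null(annotation))
    ann <- annotation[match(rownames(rpkm), annotation$gene_id), ]
    za <- do.call(rbind, lapply(c("male", "female"), function(s) {
      mr <- rowMeans(rpkm[, sex == s, drop = FALSE])
      auto_med <- stats::median(mr[ann$chrom == "A"])
      do.call(rbind, lapply(sort(unique(stats::na.omit(ann$stratum))), function(st) {
        data.frame(sex = s, stratum = st,
                   z_aa = stats::median(mr[!is.na(ann$stratum) &
                                             ann$stratum == st]) / auto_med,
                   n_genes = sum(!is.na(ann$stratum) & ann$stratum == st),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  list(model = model, za_ratios = za, low_power_strata = low,
       formula = deparse(fml))
}

#' End-to-end analysis of a counts dataset
#'
#' Runs the full procedure per tissue: TMM factors from autosomal genes,
#' RPKM with effective library sizes, expression filter, M:F ratios, per-sex
#' BCV estimation (prior weight 10), selection-axis projection, sex-bias
#' filtering of Z genes, per-tissue and pooled dosage regressions, paired
#' Wilcoxon male-vs-female BCV comparisons, and the strata analysis. All
#' stages are deterministic given the inputs. The Wilcoxon stage uses
#' \code{\link{estimate_bcv_paired}} (shared shrinkage target) so the
#' signed-rank null holds; the axes use the per-sex trended estimates of
#' \code{\link{estimate_bcv}}.
#'
#' @param counts Genes x samples integer matrix.
#' @param annotation Data frame \code{gene_id}, \code{chrom}, \code{length},
#'   \code{stratum} (NA off the Z), optionally \code{stratum_age}.
#' @param samples Data frame \code{sample}, \code{sex}, \code{tissue},
#'   \code{replicate}.
#' @param threshold_log2 Expression-filter threshold.
#' @param prior_df BCV shrinkage prior weight.
#' @param sexbias_preset Band preset for \code{\link{sexbias_filter}}.
#' @param strata_ages Ages (My) of strata 1..3 used if the annotation lacks
#'   \code{stratum_age}.
#' @return A \code{dc_analysis} list: per-tissue tables (\code{genes}),
#'   \code{models}, \code{wilcoxon}, \code{strata}, and a \code{report}
#'   summarizing filters and sample sizes per stage.
#' @export
analyze_dataset <- function(counts, annotation, samples, threshold_log2 = 1,
                            prior_df = 10,
                            sexbias_preset = c("asymmetric", "symmetric"),
                            strata_ages = c(90.5, 58, 52)) {
  sexbias_preset <- match.arg(sexbias_preset)
  stopifnot(identical(colnames(counts), samples$sample))
  if (is.null(annotation$stratum_age))
    annotation$stratum_age <- strata_ages[annotation$stratum]
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  tissues <- unique(samples$tissue)
  per_gene <- list()
  wilcoxon <- list()
  report <- list(threshold_log2 = threshold_log2, prior_df = prior_df,
                 sexbias_preset = sexbias_preset, tissues = tissues,
                 stages = list())
  for (tis in tissues) {
    sel <- samples$tissue == tis
    cts <- counts[, sel, drop = FALSE]
    sx <- samples$sex[sel]
    nf <- tmm_factors(cts, annotation = ann, autosomal_only = TRUE)
    eff <- colSums(cts) * nf
    rp <- rpkm_matrix(cts, ann$length, eff)
    keep <- filter_expressed(rp, sx, threshold_log2)
    rp_k <- rp[keep, , drop = FALSE]
    cts_k <- cts[keep, , drop = FALSE]
    ratios <- mf_ratio(rp_k, sx)
    bcv_m <- estimate_bcv(cts_k[, sx == "male", drop = FALSE],
                          lib_size = eff[sx == "male"], prior_df = prior_df)
    bcv_f <- estimate_bcv(cts_k[, sx == "female", drop = FALSE],
                          lib_size = eff[sx == "female"], prior_df = prior_df)
    l2m <- bcv_m$log2_bcv[match(keep, bcv_m$gene_id)]
    l2f <- bcv_f$log2_bcv[match(keep, bcv_f$gene_id)]
    axes <- project_axes(l2m, l2f)
    wb <- estimate_bcv_paired(cts_k[, sx == "male", drop = FALSE],
                              cts_k[, sx == "female", drop = FALSE],
                              lib_size_m = eff[sx == "male"],
                              lib_size_f = eff[sx == "female"])
    gtab <- data.frame(gene_id = keep, tissue = tis,
                       chrom = ann$chrom[match(keep, ann$gene_id)],
                       stratum = ann$stratum[match(keep, ann$gene_id)],
                       age = ann$stratum_age[match(keep, ann$gene_id)],
                       ratio = unname(ratios),
                       log2_bcv_m = l2m, log2_bcv_f = l2f,
                       concordant = axes$concordant,
                       male_bias = axes$male_bias,
                       stringsAsFactors = FALSE)
    per_gene[[tis]] <- gtab
    wilcoxon[[tis]] <- compare_bcv_by_sex(wb$male$log2_bcv, wb$female$log2_bcv)
    report$stages[[tis]] <- list(n_input = nrow(cts),
                                 n_expressed = length(keep),
                                 n_z_expressed = sum(gtab$chrom == "Z"),
                                 tmm_factors = unname(nf))
  }
  genes <- do.call(rbind, per_gene)
  rownames(genes) <- NULL
  zt <- genes[genes$chrom == "Z", ]
  kept_z <- sexbias_filter(stats::setNames(zt$ratio,
                                           paste(zt$gene_id, zt$tissue)),
                           preset = sexbias_preset)
  zt <- zt[paste(zt$gene_id, zt$tissue) %in% kept_z, ]
  for (tis in tissues)
    report$stages[[tis]]$n_z_after_sexbias <- sum(zt$tissue == tis)
  models <- if (nrow(zt) >= 8) fit_dosage_models(zt) else NULL
  strat <- NULL
  zs <- zt[!is.na(zt$stratum), ]
  if (nrow(zs) >= 16) strat <- strata_analysis(zs)
  out <- list(genes = genes, z_genes = zt, models = models,
              wilcoxon = wilcoxon, strata = strat, report = report)
  class(out) <- "dc_analysis"
  out
}

#' Write analysis outputs
#'
#' Writes retained-gene tables, coefficient tables and a JSON run report into
#' \code{dir}.
#'
#' @param analysis A \code{dc_analysis} from \code{\link{analyze_dataset}}.
#' @param dir Output directory.
#' @export
write_analysis <- function(analysis, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(analysis$genes, "genes.tsv")
  wt(analysis$z_genes, "z_genes.tsv")
  if (!is.null(analysis$models)) {
    if (!is.null(analysis$models$pooled)) wt(analysis$models$pooled, "model_pooled.tsv")
    for (tis in names(analysis$models$per_tissue))
      wt(analysis$models$per_tissue[[tis]], sprintf("model_%s.tsv", tis))
  }
  if (!is.null(analysis$strata)) wt(analysis$strata$model, "model_strata.tsv")
  report <- analysis$report
  report$wilcoxon <- lapply(analysis$wilcoxon, function(w)
    w[c("V", "p", "n", "degenerate")])
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
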