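#' Filter low-expression genes on a CPM rule
#'
#' Keeps a gene iff its counts-per-million reach \code{cpm_threshold} in at
#' least \code{min_fraction} of samples.  The pooled log2-CPM skewness of
#' the retained genes is attached as a diagnostic (the aim of the filter is
#' an approximately Gaussian pooled log-CPM distribution).
#'
#' @param counts Integer count matrix, genes x samples.
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_fraction Minimum fraction of samples at or above the cutoff
#'   (default 0.2).
#' @return Filtered count matrix with attribute \code{"skewness"}.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  min_fraction = 0.2) {
  stopifnot(cpm_threshold > 0, min_fraction > 0)
  libsize <- colSums(counts)
  cpm <- sweep(counts, 2L, libsize, `/`) * 1e6
  keep <- rowMeans(cpm >= cpm_threshold) >= min_fraction
  if (!any(keep)) stop("all genes removed by the low-expression filter")
  out <- counts[keep, , drop = FALSE]
  lcpm <- log2(sweep(out + 0.5, 2L, libsize, `/`) * 1e6)
  attr(out, "skewness") <- sample_skewness(as.numeric(lcpm))
  out
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s <- stats::sd(x)
  mean((x - m)^3) / s^3
}

#' TMM normalization factors
#'
#' Per-sample scale factors from the trimmed mean of M-values: the weighted
#' trimmed mean of gene-wise log ratios against a reference sample, with
#' log-ratio trim 0.30, abundance trim 0.05 and inverse-asymptotic-variance
#' weights; genes with a zero in either column of a pair are excluded from
#' that pair's trim.  Factors are rescaled so their geometric mean is 1.
#' The computation is delegated to edgeR's TMM implementation.
#'
#' @param counts Count matrix, genes x samples (>= 2 samples).
#' @param trim_m Log-ratio (M) trim fraction, default 0.30.
#' @param trim_a Abundance (A) trim fraction, default 0.05.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2L) stop("TMM requires at least 2 samples")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    stop("sample(s) with zero library size: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a,
                              doWeighting = TRUE)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Normalized log2 counts per million
#'
#' \code{value = log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)}.
#' With all-ones factors this is plain log-CPM; with TMM factors the
#' effective library size corrects for composition bias.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Per-sample normalization factors (default all ones).
#' @param prior_count Offset avoiding log of zero (default 0.5).
#' @return A \code{normalized_matrix}: numeric matrix of log2-CPM values
#'   with attributes \code{"norm_factors"} and \code{"mode"}.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  if (is.null(factors)) {
    factors <- stats::setNames(rep(1, ncol(counts)), colnames(counts))
  }
  stopifnot(length(factors) == ncol(counts), all(factors > 0))
  eff <- colSums(counts) * factors
  vals <- log2(sweep(counts + prior_count, 2L, eff + 2 * prior_count, `/`) * 1e6)
  structure(vals, norm_factors = factors, mode = "rnaseq",
            class = c("normalized_matrix", class(vals)))
}

#' Median-center a proteomic abundance matrix
#'
#' Proteomic validation cohorts enter the pipeline as already-quantified
#' abundance matrices; each sample is centered on its median so that
#' group comparisons are not driven by loading differences.
#'
#' @param mat Numeric abundance matrix, proteins x samples.
#' @return A \code{normalized_matrix} with \code{mode = "proteomic"}.
#' @export
median_center <- function(mat) {
  med <- apply(mat, 2L, stats::median, na.rm = TRUE)
  vals <- sweep(mat, 2L, med, `-`)
  structure(vals, norm_factors = stats::setNames(rep(1, ncol(mat)), colnames(mat)),
            mode = "proteomic", class = c("normalized_matrix", class(vals)))
}

#' Moderated two-group differential expression on normalized values
#'
#' Per gene: log2 fold change (group A minus group B) and a pooled
#' two-sample t statistic whose variance is shrunk toward a common prior by
#' empirical Bayes: \code{s2_tilde = (d0 * s0^2 + dg * s2_g) / (d0 + dg)},
#' with the prior (d0, s0^2) fitted to the gene-wise variance distribution
#' by moment matching on the log scale (the standard scaled-F fit).  The
#' moderated t is referred to Student's t with d0 + dg degrees of freedom
#' and p-values are BH-adjusted across genes.
#'
#' @param norm A \code{normalized_matrix} (or plain numeric matrix).
#' @param group_a,group_b Disjoint sample-identifier vectors, each >= 2.
#' @param d0_policy \code{"estimate"} (default), or a nonnegative number
#'   forcing the prior degrees of freedom (0 = ordinary t, Inf = common
#'   variance for all genes).
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{t},
#'   \code{df}, \code{p}, \code{padj}, ordered as the input genes; the
#'   fitted (d0, s0^2) is attached as attribute \code{"prior"}.
#' @export
moderated_t_de <- function(norm, group_a, group_b, d0_policy = "estimate") {
  group_a <- intersect(group_a, colnames(norm))
  group_b <- intersect(group_b, colnames(norm))
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1L)
  vb <- rowSums((xb - mb)^2) / (nb - 1L)
  dg <- na + nb - 2L
  s2 <- ((na - 1L) * va + (nb - 1L) * vb) / dg

  if (identical(d0_policy, "estimate")) {
    fit <- limma::fitFDist(s2, df1 = dg)
    d0 <- fit$df2
    s02 <- fit$scale
  } else {
    d0 <- as.numeric(d0_policy)
    if (is.na(d0) || d0 < 0) stop("d0_policy must be 'estimate' or a number >= 0")
    s02 <- mean(s2)
  }
  if (is.infinite(d0)) {
    s2_tilde <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s2_tilde <- (d0 * s02 + dg * s2) / (d0 + dg)
    df_total <- dg + d0
  }
  se <- sqrt(s2_tilde * (1 / na + 1 / nb))
  lfc <- ma - mb
  tstat <- lfc / se
  p <- 2 * stats::pt(abs(tstat), df = df_total, lower.tail = FALSE)
  out <- data.frame(gene = rownames(norm), log2fc = lfc, t = tstat,
                    df = rep(df_total, length(lfc)), p = p,
                    padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "prior") <- c(d0 = d0, s02 = s02)
  out
}
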