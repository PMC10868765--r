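#' Two-proportion z-test
#'
#' Pooled-variance z statistic for the difference of two proportions,
#' without continuity correction:
#' \code{z = (x1/n1 - x2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))} with
#' \code{phat = (x1 + x2) / (n1 + n2)}; two-sided normal p-value.
#' \code{z^2} equals the uncorrected Pearson chi-square statistic of the
#' corresponding 2x2 table.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with \code{z}, \code{p}, \code{p1}, \code{p2},
#'   \code{pooled}.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1) {
    stop("degenerate pooled proportion (", phat, "): variance is zero")
  }
  z <- (x1 / n1 - x2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       p1 = x1 / n1, p2 = x2 / n2, pooled = phat)
}

#' Cross-cohort co-occurrence analysis of SWI/SNF and NRF2 alterations
#'
#' Stratifies cohorts by their NRF2-pathway alteration frequency at
#' \code{threshold} (default 5\%), pools samples within each stratum, and
#' tests whether the high-NRF2 stratum has a higher SWI/SNF alteration
#' proportion with \code{\link{two_proportion_z}}.  With
#' \code{pool = FALSE} cohort frequencies are averaged instead of pooling
#' samples (the test is still computed on pooled counts).
#'
#' @param bundles List of \code{cohort_bundle}s (>= 2 recommended).
#' @param swisnf_panel,nrf2_panel Gene panels.
#' @param threshold NRF2 alteration frequency separating strata.
#' @param pool Pool samples within strata (default TRUE).
#' @return A \code{cooccurrence_report}: list with \code{frequencies} (the
#'   per-cohort table), \code{strata} (per-stratum pooled counts),
#'   \code{z}, \code{p}, \code{threshold}, \code{flag}.
#' @export
cooccurrence_analysis <- function(bundles,
                                  swisnf_panel = c("ARID1A", "ARID1B", "ARID2", "PBRM1"),
                                  nrf2_panel = nrf2_pathway_genes(),
                                  threshold = 0.05, pool = TRUE) {
  freqs <- alteration_frequencies(bundles, swisnf_panel, nrf2_panel)
  freqs$stratum <- ifelse(freqs$freq_nrf2 >= threshold, "high_nrf2", "low_nrf2")
  agg <- function(stratum) {
    f <- freqs[freqs$stratum == stratum, , drop = FALSE]
    list(n_cohorts = nrow(f), n = sum(f$n), x_swisnf = sum(f$n_swisnf),
         prop_swisnf = if (nrow(f)) {
           if (pool) sum(f$n_swisnf) / sum(f$n) else mean(f$freq_swisnf)
         } else NA_real_)
  }
  hi <- agg("high_nrf2"); lo <- agg("low_nrf2")
  if (hi$n_cohorts == 0L || lo$n_cohorts == 0L) {
    return(structure(list(frequencies = freqs,
                          strata = list(high_nrf2 = hi, low_nrf2 = lo),
                          z = NA_real_, p = NA_real_, threshold = threshold,
                          flag = "single_stratum"),
                     class = "cooccurrence_report"))
  }
  test <- two_proportion_z(hi$x_swisnf, hi$n, lo$x_swisnf, lo$n)
  structure(list(frequencies = freqs,
                 strata = list(high_nrf2 = hi, low_nrf2 = lo),
                 z = test$z, p = test$p, threshold = threshold,
                 flag = NA_character_),
            class = "cooccurrence_report")
}

#' @export
print.cooccurrence_report <- function(x, ...) {
  cat("co-occurrence report (NRF2 frequency threshold ",
      x$threshold * 100, "%)\n", sep = "")
  if (!is.na(x$flag)) {
    cat("  test skipped: ", x$flag, "\n", sep = "")
  } else {
    cat(sprintf("  SWI/SNF altered: %.1f%% (high-NRF2, n=%d) vs %.1f%% (low-NRF2, n=%d)\n",
                100 * x$strata$high_nrf2$prop_swisnf, x$strata$high_nrf2$n,
                100 * x$strata$low_nrf2$prop_swisnf, x$strata$low_nrf2$n))
    cat(sprintf("  z = %.3f, two-sided p = %.3g\n", x$z, x$p))
  }
  invisible(x)
}
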