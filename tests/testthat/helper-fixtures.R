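# Fixtures and independent oracles shared across the suite.

# The 6-sample toy cohort: one clean ARID1A mutant, one ARID1A mutant
# confounded by KEAP1, two clean controls, one PBRM1-only mutant, one
# NFE2L2-missense sample.  Every sample carries a silent passenger so the
# MAF covers the cohort.
toy_bundle <- function() {
  samples <- paste0("S", 1:6)
  genes <- c("ARID1A", "ARID1B", "ARID2", "PBRM1",
             "KEAP1", "NFE2L2", "CUL3", "GENE1", "GENE2")
  set.seed(42)
  counts <- matrix(rpois(length(genes) * 6, 100), nrow = length(genes),
                   dimnames = list(genes, samples))
  storage.mode(counts) <- "integer"
  cnv <- matrix(0L, length(genes), 6, dimnames = list(genes, samples))
  variants <- data.frame(
    gene = c("ARID1A", "ARID1A", "KEAP1", "PBRM1", "NFE2L2",
             rep("GENE1", 6)),
    sample = c("S1", "S2", "S2", "S4", "S5", samples),
    variant_class = c(rep("Missense_Mutation", 5), rep("Silent", 6)),
    stringsAsFactors = FALSE)
  harmonize_samples(counts, variants, cnv, barcode_policy = "exact",
                    cohort_name = "TOY")
}

# Minimal bundle with prescribed variant records and CNV entries.
mini_bundle <- function(variants = NULL, cnv_entries = list(),
                        samples = paste0("S", 1:4),
                        genes = c("KEAP1", "NFE2L2", "CUL3", "ARID1A", "BG1")) {
  set.seed(7)
  counts <- matrix(rpois(length(genes) * length(samples), 50),
                   nrow = length(genes), dimnames = list(genes, samples))
  storage.mode(counts) <- "integer"
  cnv <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (e in cnv_entries) cnv[e$gene, e$sample] <- as.integer(e$score)
  base <- data.frame(gene = "BG1", sample = samples,
                     variant_class = "Silent", stringsAsFactors = FALSE)
  variants <- if (is.null(variants)) base else rbind(base, variants)
  harmonize_samples(counts, variants, cnv, barcode_policy = "exact",
                    cohort_name = "MINI")
}

# Brute-force enrichment score: explicit position-by-position running sum,
# independent of the package's incremental implementation.
bf_enrichment_score <- function(scores, hit, weight_p = 1) {
  n <- length(scores)
  nh <- sum(hit)
  sw <- sum(abs(scores[hit])^weight_p)
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- if (hit[i]) {
      acc + (if (sw > 0) abs(scores[i])^weight_p / sw else 1 / nh)
    } else {
      acc - 1 / (n - nh)
    }
    run[i] <- acc
  }
  mx <- max(run); mn <- min(run)
  if (mx + mn >= -1e-12 * max(abs(mx), abs(mn), 1)) mx else mn
}

# Brute-force TMM factor for one sample against an explicit reference
# column: doubly trimmed weighted mean of M-values, written directly from
# the definition.
bf_tmm_factor <- function(obs, ref, trim_m = 0.30, trim_a = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  fin <- is.finite(m) & is.finite(a) & abs(m) < 1e10
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  lo_m <- quantile(m, trim_m); hi_m <- quantile(m, 1 - trim_m)
  lo_a <- quantile(a, trim_a); hi_a <- quantile(a, 1 - trim_a)
  keep2 <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

quick_sim <- function(...) {
  simulate_cohort(simulation_spec(n_genes = 400L, n_samples = 60L,
                                  n_signature_genes = 40L, ...))
}
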