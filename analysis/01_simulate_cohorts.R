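#!/usr/bin/env Rscript
# Generate the study's synthetic cohorts and write them in the pipeline's
# input dialects (counts TSV, MAF-like variants, Gistic TSV, truth JSON).
#
# Three derivation cohorts (2000 genes x 120 samples, 30% NRF2 active,
# 100-gene shared planted core + 50 cohort-private genes) emulate the
# three-cohort signature design; one HNSC-scale screen cohort (n = 500)
# carries the planted subunit structure (ARID1A co-occurring with NRF2
# activity and pushing the signature up, ARID1B pushing it down).
#
# Usage: Rscript analysis/01_simulate_cohorts.R [--seed N]

library(nrf2screen)
args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[which(args == "--seed") + 1]) else 1L
out <- "results/cohorts"

spec3 <- simulation_spec(seed = seed, n_signature_genes = 150L)
sims <- simulate_multi_cohort(spec3, n_cohorts = 3L, shared_core = 100L)
for (nm in names(sims)) {
  write_cohort(sims[[nm]], file.path(out, nm))
  t <- sims[[nm]]$truth
  cat(sprintf("%s: %d samples, %d NRF2 active, %d planted signature genes (%d shared core)\n",
              nm, ncol(sims[[nm]]$bundle$counts), length(t$active_samples),
              length(t$signature_genes), length(t$core_genes)))
}
writeLines(attr(sims, "core_genes"), file.path(out, "planted_core_genes.txt"))

screen_sim <- simulate_cohort(simulation_spec(n_samples = 500L, seed = seed),
                              cohort_name = "SCREEN")
write_cohort(screen_sim, file.path(out, "SCREEN"))
write_gmt(synthetic_nrf2_collection(screen_sim$truth),
          file.path(out, "nrf2_signatures.gmt"))
cat(sprintf("SCREEN: 500 samples, %d NRF2 active; subunit mutants:",
            length(screen_sim$truth$active_samples)))
for (su in names(screen_sim$truth$subunit_mutants)) {
  cat(sprintf(" %s=%d", su, length(screen_sim$truth$subunit_mutants[[su]])))
}
cat("\ncohorts written under", out, "\n")
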