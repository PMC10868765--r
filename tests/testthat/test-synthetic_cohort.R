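test_that("simulation is deterministic under a fixed seed", {
  s1 <- quick_sim(seed = 11)
  s2 <- quick_sim(seed = 11)
  expect_identical(s1$bundle$counts, s2$bundle$counts)
  expect_identical(s1$bundle$variants, s2$bundle$variants)
  expect_identical(s1$bundle$cnv, s2$bundle$cnv)
  expect_identical(s1$truth$active_samples, s2$truth$active_samples)
  s3 <- quick_sim(seed = 12)
  expect_false(identical(s1$bundle$counts, s3$bundle$counts))
})

test_that("active-sample count respects the configured fraction", {
  for (frac in c(0.1, 0.3, 0.5)) {
    sim <- simulate_cohort(simulation_spec(n_genes = 100L, n_samples = 50L,
                                           n_signature_genes = 10L,
                                           frac_nrf2_active = frac, seed = 2))
    expect_identical(length(sim$truth$active_samples),
                     as.integer(round(frac * 50)))
  }
})

test_that("planted events are exactly recoverable when confounders are off", {
  sim <- simulate_cohort(simulation_spec(n_genes = 300L, n_samples = 80L,
                                         n_signature_genes = 30L,
                                         confounder_rate = 0, seed = 5))
  act <- call_nrf2_active(sim$bundle)
  expect_setequal(names(act$altered)[act$altered], sim$truth$active_samples)
  for (su in names(sim$truth$subunit_mutants)) {
    called <- call_any_alteration(sim$bundle, su)
    expect_setequal(names(called$altered)[called$altered],
                    sim$truth$subunit_mutants[[su]])
  }
})

test_that("a zero active fraction plants no pathway events or expression effect", {
  sim <- simulate_cohort(simulation_spec(n_genes = 500L, n_samples = 60L,
                                         n_signature_genes = 50L,
                                         frac_nrf2_active = 0,
                                         subunit_configs = list(
                                           ARID1A = list(rate = 0.1, odds_ratio = 1,
                                                         polarity = 0, magnitude = 0)),
                                         seed = 8))
  expect_length(sim$truth$active_samples, 0)
  expect_false(any(sim$truth$events$kind %in%
                   c("pathway_variant", "deep_deletion", "amplification")))
  expect_true(all(sim$bundle$cnv[c("KEAP1", "CUL3"), ] != -2L))
  expect_true(all(sim$bundle$cnv["NFE2L2", ] != 2L))
  # planted genes are distributionally indistinguishable from background
  lcpm <- log_cpm(sim$bundle$counts)
  sig <- names(sim$truth$signature_genes)
  bg <- setdiff(grep("^SYNG", rownames(lcpm), value = TRUE), sig)
  p <- wilcox.test(rowMeans(lcpm[sig, ]), rowMeans(lcpm[bg, ]))$p.value
  expect_gt(p, 0.01)
})

test_that("planted log2 fold change matches the generating parameter", {
  spec <- simulation_spec(seed = 21)  # 2000 genes, 120 samples, effect 2
  sim <- simulate_cohort(spec)
  truth <- sim$truth
  act <- truth$active_samples
  ina <- setdiff(colnames(sim$bundle$counts), act)
  depth <- truth$libsize[colnames(sim$bundle$counts)]
  norm <- log2(sweep(sim$bundle$counts + 0.5, 2L, depth, `/`))
  # well-expressed planted genes (the log offset is negligible there), in
  # samples free of subunit expression effects
  sig <- names(truth$signature_genes)
  sig <- sig[rowMeans(sim$bundle$counts[sig, , drop = FALSE]) >= 20]
  shifted <- unique(c(truth$subunit_mutants$ARID1A, truth$subunit_mutants$ARID1B))
  lfc <- rowMeans(norm[sig, setdiff(act, shifted), drop = FALSE]) -
         rowMeans(norm[sig, setdiff(ina, shifted), drop = FALSE])
  se <- sd(lfc) / sqrt(length(lfc))
  expect_lt(abs(mean(lfc) - spec$effect_log2fc_mean), 2 * se + 0.05)
})

test_that("multi-cohort simulation shares exactly the configured core", {
  spec <- simulation_spec(n_genes = 600L, n_samples = 40L,
                          n_signature_genes = 60L, seed = 3)
  sims <- simulate_multi_cohort(spec, n_cohorts = 3, shared_core = 40)
  sets <- lapply(sims, function(s) names(s$truth$signature_genes))
  core <- attr(sims, "core_genes")
  expect_length(core, 40)
  for (s in sets) expect_true(all(core %in% s))
  privates <- lapply(sims, function(s) s$truth$private_genes)
  expect_true(all(lengths(privates) == 20))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_identical(intersect(sets[[i]], sets[[j]]), sort(core))
    expect_length(intersect(privates[[i]], privates[[j]]), 0)
  }
  # degenerate extremes
  all_shared <- simulate_multi_cohort(spec, n_cohorts = 2, shared_core = 60)
  expect_identical(names(all_shared[[1]]$truth$signature_genes),
                   names(all_shared[[2]]$truth$signature_genes))
  none_shared <- simulate_multi_cohort(spec, n_cohorts = 2, shared_core = 0)
  expect_length(intersect(names(none_shared[[1]]$truth$signature_genes),
                          names(none_shared[[2]]$truth$signature_genes)), 0)
  expect_error(simulate_multi_cohort(spec, n_cohorts = 1), "at least 2")
})

test_that("higher co-occurrence odds enrich mutants for the active state", {
  frac_active_among_mutants <- function(or, seed) {
    cfg <- list(ARID1A = list(rate = 0.2, odds_ratio = or,
                              polarity = 0, magnitude = 0))
    sim <- simulate_cohort(simulation_spec(n_genes = 50L, n_samples = 400L,
                                           n_signature_genes = 5L,
                                           subunit_configs = cfg, seed = seed))
    mut <- sim$truth$subunit_mutants$ARID1A
    mean(mut %in% sim$truth$active_samples)
  }
  lo <- mean(vapply(1:5, function(s) frac_active_among_mutants(1, s), 1))
  hi <- mean(vapply(1:5, function(s) frac_active_among_mutants(8, s), 1))
  expect_gt(hi, lo)
})

test_that("cohorts round-trip through the on-disk dialects", {
  sim <- quick_sim(seed = 9)
  dir <- tempfile()
  write_cohort(sim, dir)
  suppressMessages(back <- read_cohort(dir, cohort_name = "SYNTH"))
  expect_identical(back$counts, sim$bundle$counts)
  expect_identical(back$cnv, sim$bundle$cnv)
  expect_identical(back$variants$sample, sim$bundle$variants$sample)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(unlist(truth$active_samples), sim$truth$active_samples)
})
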