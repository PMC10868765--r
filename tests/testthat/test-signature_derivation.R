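# small separable training fixture: two clusters displaced on a gene panel
two_cluster_norm <- function(n_genes = 20, n_per_class = 10, delta = 3,
                             seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n_genes * n), n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(n))))
  active <- paste0("S", seq_len(n_per_class))
  x[, active] <- x[, active] + delta
  labels <- setNames(ifelse(colnames(x) %in% active, "active", "inactive"),
                     colnames(x))
  list(x = x, labels = labels)
}

test_that("with one sample per class the centroids are the samples", {
  set.seed(2)
  x <- matrix(rnorm(10 * 4), 10, dimnames = list(paste0("G", 1:10),
                                                 paste0("S", 1:4)))
  labels <- setNames(c("active", "inactive", "active", "inactive"),
                     colnames(x))
  m2 <- train_centroid(x[, 1:2], labels[1:2], rownames(x))
  z <- (x[, 1:2] - m2$center) / m2$scale
  expect_equal(m2$centroid_active, z[, "S1"], tolerance = 1e-12)
  expect_equal(m2$centroid_inactive, z[, "S2"], tolerance = 1e-12)
})

test_that("training is idempotent and recovers the planted effect direction", {
  tc <- two_cluster_norm()
  m1 <- train_centroid(tc$x, tc$labels, rownames(tc$x))
  m2 <- train_centroid(tc$x, tc$labels, rownames(tc$x))
  expect_identical(m1, m2)
  diff_vec <- m1$centroid_active - m1$centroid_inactive
  # planted effect is uniform +delta: the difference vector points that way
  expect_true(all(diff_vec > 0))

  flat <- tc$x; flat["G1", ] <- 1
  expect_warning(m3 <- train_centroid(flat, tc$labels, rownames(flat)),
                 "zero-variance")
  expect_false("G1" %in% m3$panel)
})

test_that("classification margins behave at the endpoints and midpoint", {
  tc <- two_cluster_norm()
  m <- train_centroid(tc$x, tc$labels, rownames(tc$x))
  # a sample placed exactly on the active centroid
  at_centroid <- m$center + m$scale * m$centroid_active
  cl <- classify(m, setNames(at_centroid, m$panel))
  expect_identical(cl$class, "active")
  expect_equal(cl$margin, 1, tolerance = 1e-12)
  expect_equal(cl$axis_position, 1, tolerance = 1e-12)
  # the exact midpoint ties and the tie goes to inactive
  mid <- m$center + m$scale * (m$centroid_active + m$centroid_inactive) / 2
  clm <- classify(m, setNames(mid, m$panel))
  expect_identical(clm$class, "inactive")
  expect_equal(clm$margin, 0, tolerance = 1e-12)
  # orthogonal displacement keeps the class but shrinks the margin
  u <- (m$centroid_active - m$centroid_inactive) / m$intercentroid_distance
  ortho <- rnorm(length(u)); ortho <- ortho - sum(ortho * u) * u
  far <- m$center + m$scale * (m$centroid_active + 5 * ortho)
  clf <- classify(m, setNames(far, m$panel))
  expect_identical(clf$class, "active")
  expect_lt(clf$margin, 1)
  expect_error(classify(m, setNames(at_centroid, rev(m$panel))[-1]),
               "missing panel")
})

test_that("high-confidence filtering removes mislabeled and distant samples", {
  tc <- two_cluster_norm(delta = 4)
  m <- train_centroid(tc$x, tc$labels, rownames(tc$x))
  kept <- select_high_confidence(m, tc$x, tc$labels, tau = 0.45)
  expect_setequal(kept, names(tc$labels))

  wrong <- tc$labels
  wrong["S1"] <- "inactive"  # sits on the active centroid but labeled inactive
  m2 <- train_centroid(tc$x, wrong, rownames(tc$x))
  kept2 <- select_high_confidence(m2, tc$x, wrong, tau = 1)
  expect_false("S1" %in% kept2)
  expect_identical(attr(kept2, "removed")$reason[
    attr(kept2, "removed")$sample == "S1"], "misclassified")

  expect_error(select_high_confidence(m, tc$x, tc$labels, tau = 0),
               "increase tau")
})

test_that("shrinking tau never grows the retained set", {
  tc <- two_cluster_norm(n_genes = 30, delta = 2, seed = 5)
  m <- train_centroid(tc$x, tc$labels, rownames(tc$x))
  taus <- c(0.6, 0.45, 0.3, 0.2)
  kept <- lapply(taus, function(tau) {
    tryCatch(as.character(select_high_confidence(m, tc$x, tc$labels, tau)),
             error = function(e) character(0))
  })
  for (i in seq_along(taus)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("per-cohort derivation recovers planted genes and is deterministic", {
  sim <- simulate_cohort(simulation_spec(n_genes = 800L, n_samples = 100L,
                                         n_signature_genes = 60L, seed = 13))
  r1 <- derive_cohort_signature(sim$bundle,
                                derivation_config(panel_size = 60L))
  r2 <- derive_cohort_signature(sim$bundle,
                                derivation_config(panel_size = 60L))
  expect_identical(r1$final_de, r2$final_de)
  expect_identical(r1$final_panel, r2$final_panel)
  up <- r1$final_de[r1$final_de$log2fc > 0, ]
  top <- up$gene[order(up$p)][1:60]
  expect_gte(sum(top %in% names(sim$truth$signature_genes)), 54)
  # derivation is invariant to sample and gene order
  b <- sim$bundle
  set.seed(1)
  b$counts <- b$counts[sample(nrow(b$counts)), sample(ncol(b$counts))]
  b$cnv <- b$cnv[, colnames(b$counts)]
  b$shared_samples <- colnames(b$counts)
  r3 <- derive_cohort_signature(b, derivation_config(panel_size = 60L))
  expect_setequal(r3$final_panel, r1$final_panel)
})

test_that("an undersized active class skips the cohort with a flag", {
  sim <- simulate_cohort(simulation_spec(n_genes = 200L, n_samples = 30L,
                                         n_signature_genes = 20L,
                                         frac_nrf2_active = 0.05, seed = 2))
  expect_warning(r <- derive_cohort_signature(sim$bundle), "skipped")
  expect_identical(r$flag, "undersized_active_class")
})

test_that("cohort intersection enforces significance and sign in every cohort", {
  de <- data.frame(gene = paste0("G", 1:6),
                   log2fc = c(2, 1.5, 1, -1, 2, 0.5),
                   t = 1, df = 10,
                   p = c(1e-8, 1e-6, 1e-4, 1e-9, 1e-3, 0.5),
                   padj = c(6e-8, 3e-6, 2e-4, 9e-9, 3.6e-3, 0.5),
                   stringsAsFactors = FALSE)
  mk <- function(nm, de) list(cohort_name = nm, final_de = de,
                              flag = NA_character_)
  same <- intersect_cohorts(list(mk("A", de), mk("B", de), mk("C", de)),
                            alpha = 0.05, k = 10)
  # G4 is down, G6 not significant; ranking follows adjusted p
  expect_identical(same$signature, c("G1", "G2", "G3", "G5"))

  flipped <- de; flipped$log2fc[1] <- -2
  r <- intersect_cohorts(list(mk("A", de), mk("B", flipped)), k = 10)
  expect_false("G1" %in% r$signature)
  # max-of-cohorts prioritization uses the worst cohort
  worse <- de; worse$padj[2] <- 4e-3
  r2 <- intersect_cohorts(list(mk("A", de), mk("B", worse)), k = 2)
  expect_identical(r2$signature, c("G1", "G3"))

  none <- de; none$log2fc <- -abs(none$log2fc)
  expect_error(intersect_cohorts(list(mk("A", de), mk("B", none))),
               "no gene")
})

test_that("cross-validation is perfect on separated data and null on shuffled labels", {
  tc <- two_cluster_norm(n_genes = 150, n_per_class = 20, delta = 2, seed = 3)
  cv <- cross_validate(tc$x, tc$labels, n_folds = 5,
                       config = derivation_config(panel_size = 50L))
  expect_equal(cv$accuracy, 1.0)

  set.seed(4)
  shuffled <- setNames(sample(tc$labels), names(tc$labels))
  cvs <- cross_validate(tc$x, shuffled, n_folds = 5,
                        config = derivation_config(panel_size = 50L))
  se <- sqrt(0.25 / length(shuffled))
  expect_lt(abs(cvs$accuracy - 0.5), 3 * se + 1e-9)

  few <- tc$labels[c(1:3, 21:40)]
  expect_error(cross_validate(tc$x, few, n_folds = 5), "fewer samples than folds")
})
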