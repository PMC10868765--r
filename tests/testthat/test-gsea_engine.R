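ranked_from <- function(scores, genes = paste0("g", seq_along(scores))) {
  ord <- order(-scores, genes, method = "radix")
  data.frame(gene = genes[ord], score = scores[ord], stringsAsFactors = FALSE)
}

test_that("signal to noise applies the sd floor and is antisymmetric", {
  a <- c(2, 4); b <- c(1, 1)
  expect_equal(signal_to_noise(a, b), (3 - 1) / (sqrt(2) + 0.2),
               tolerance = 1e-12)
  expect_equal(signal_to_noise(a, b), 1.2390, tolerance = 1e-4)
  expect_equal(signal_to_noise(b, a), -signal_to_noise(a, b),
               tolerance = 1e-15)
  expect_equal(signal_to_noise(c(1, 2, 3), c(3, 2, 1)), 0)
  # zero-mean group gets the absolute floor of 0.2
  expect_equal(signal_to_noise(c(-0.01, 0.01), c(1, 1)),
               (0 - 1) / (max(sd(c(-0.01, 0.01)), 0.2) + 0.2),
               tolerance = 1e-12)
  expect_error(signal_to_noise(1, c(1, 2)), "at least 2")
})

test_that("ranked lists are ordered with a deterministic tie-break", {
  set.seed(1)
  x <- matrix(rnorm(20 * 8), 20, dimnames = list(sprintf("G%02d", 20:1),
                                                 paste0("S", 1:8)))
  x[1:2, ] <- 0  # two all-tied genes (score 0) resolved lexicographically
  r <- rank_signal_to_noise(x, paste0("S", 1:4), paste0("S", 5:8))
  expect_identical(nrow(r), 20L)
  expect_true(all(diff(r$score) <= 1e-15))
  tied <- r$gene[abs(r$score) < 1e-12]
  expect_identical(tied, sort(tied))
})

test_that("enrichment score matches the two hand-worked instances exactly", {
  ranked <- ranked_from(c(3, 2, 1, -1, -2))
  top <- enrichment_score(ranked, c("g1", "g2"))
  expect_equal(top$running, c(0.6, 1.0, 2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(top$es, 1.0, tolerance = 1e-12)
  expect_identical(top$leading_edge, c("g1", "g2"))
  bottom <- enrichment_score(ranked, c("g4", "g5"))
  expect_equal(bottom$running, c(-1 / 3, -2 / 3, -1, -2 / 3, 0),
               tolerance = 1e-12)
  expect_equal(bottom$es, -1.0, tolerance = 1e-12)
  expect_identical(bottom$leading_edge, c("g4", "g5"))

  expect_error(enrichment_score(ranked, c("absent")), "disjoint")
  expect_error(enrichment_score(ranked, paste0("g", 1:5)), "equals")
})

test_that("p = 0 reduces to the classic unweighted KS statistic", {
  set.seed(2)
  scores <- sort(rnorm(30), decreasing = TRUE)
  ranked <- ranked_from(scores)
  gene_set <- sample(ranked$gene, 8)
  hit <- ranked$gene %in% gene_set
  es0 <- enrichment_score(ranked, gene_set, weight_p = 0)$es
  # classic KS: equal hit steps regardless of score
  run <- cumsum(ifelse(hit, 1 / sum(hit), -1 / sum(!hit)))
  expect_equal(es0, run[which.max(abs(run))], tolerance = 1e-12)
})

test_that("incremental ES equals brute force on random instances", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ranked <- ranked_from(scores)
    k <- sample(1:min(10, n - 1), 1)
    gene_set <- sample(ranked$gene, k)
    hit <- ranked$gene %in% gene_set
    p <- sample(c(0, 1, 2), 1)
    expect_equal(enrichment_score(ranked, gene_set, p)$es,
                 bf_enrichment_score(ranked$score, hit, p),
                 tolerance = 1e-12)
  }
})

test_that("ES agrees with the fgsea statistic on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ranked <- ranked_from(scores)
    gene_set <- sample(ranked$gene, 7)
    idx <- which(ranked$gene %in% gene_set)
    expect_equal(enrichment_score(ranked, gene_set, weight_p = 1)$es,
                 fgsea::calcGseaStat(setNames(ranked$score, ranked$gene),
                                     idx, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("reversing the ranked list with negated scores negates ES", {
  set.seed(5)
  scores <- sort(rnorm(40), decreasing = TRUE)
  ranked <- ranked_from(scores)
  rev_ranked <- data.frame(gene = rev(ranked$gene), score = rev(-ranked$score),
                           stringsAsFactors = FALSE)
  for (i in 1:10) {
    gene_set <- sample(ranked$gene, 6)
    expect_equal(enrichment_score(rev_ranked, gene_set)$es,
                 -enrichment_score(ranked, gene_set)$es, tolerance = 1e-12)
  }
})

test_that("the permutation null is reproducible and centered", {
  set.seed(6)
  ranked <- ranked_from(rnorm(200))
  n1 <- permutation_null(ranked, 15, n_perm = 300, seed = 42)
  n2 <- permutation_null(ranked, 15, n_perm = 300, seed = 42)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1)), 3 * sd(n1) / sqrt(length(n1)))
  expect_error(permutation_null(ranked, 200, seed = 1), "smaller")
  expect_error(permutation_null(ranked, 10, n_perm = 50, seed = 1),
               "at least 100")
})

test_that("gsea_batch flags small sets, floors p, and treats duplicates identically", {
  set.seed(7)
  ranked <- ranked_from(sort(rnorm(300), decreasing = TRUE))
  planted <- ranked$gene[1:10]
  coll <- list(PLANTED = planted, PLANTED_COPY = planted,
               TINY = ranked$gene[1:2],
               RANDOM = sample(ranked$gene, 20))
  res <- gsea_batch(ranked, coll, n_perm = 500, seed = 3)
  expect_identical(res$flag[res$set == "TINY"], "skipped_small_set")
  planted_row <- res[res$set == "PLANTED", ]
  expect_gt(planted_row$nes, 0)
  # p sits at the floor of the same-sign permutation estimator
  null_seed <- nrf2screen:::null_seed_for_set(3L, 10L,
                                              ranked$gene[ranked$gene %in% planted])
  null10 <- permutation_null(ranked, 10L, 500L, seed = null_seed)
  expect_equal(planted_row$p, 1 / (1 + sum(null10 > 0)), tolerance = 1e-12)
  copy_row <- res[res$set == "PLANTED_COPY", ]
  expect_equal(planted_row$es, copy_row$es, tolerance = 1e-15)
  expect_equal(planted_row$nes, copy_row$nes, tolerance = 1e-15)
  expect_true(all(res$p > 0, na.rm = TRUE))
  expect_true(all(res$padj >= res$p - 1e-15, na.rm = TRUE))
  expect_true(all(sign(res$nes) == sign(res$es), na.rm = TRUE))
  expect_error(gsea_batch(ranked, list(TINY = ranked$gene[1:2])),
               "every set was skipped")
})

test_that("volcano tables bind collections, highlight patterns, and sort stably", {
  r1 <- data.frame(set = c("HALLMARK_REACTIVE_OXYGEN", "HALLMARK_OTHER"),
                   size = 10L, es = c(0.8, -0.5), nes = c(2.0, -1.1),
                   p = c(0.001, 0.2), padj = c(0.01, 0.3),
                   leading_edge = "", flag = NA_character_,
                   stringsAsFactors = FALSE)
  r2 <- data.frame(set = "NFE2L2_SIG", size = 8L, es = 0.6, nes = 1.5,
                   p = 0.05, padj = 0.1, leading_edge = "",
                   flag = NA_character_, stringsAsFactors = FALSE)
  v <- volcano_table(list(hallmark = r1, oncogene = r2),
                     highlight_patterns = "REACTIVE_OXYGEN")
  expect_identical(nrow(v), 3L)
  expect_identical(v$set[v$highlight], "HALLMARK_REACTIVE_OXYGEN")
  expect_identical(v$set, c("HALLMARK_REACTIVE_OXYGEN", "NFE2L2_SIG",
                            "HALLMARK_OTHER"))
})
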