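#' Signal-to-noise ratio between two groups of values
#'
#' \code{(mean_a - mean_b) / (sd_a* + sd_b*)} with the floor convention of
#' the classic GSEA desktop tool: each sd is floored at 0.2 * |mean| of its
#' group, and at 0.2 when the group mean is zero.  Sample sd uses n - 1.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return The signal-to-noise score (scalar).
#' @export
signal_to_noise <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("signal_to_noise needs at least 2 values per group")
  }
  if (!all(is.finite(values_a)) || !all(is.finite(values_b))) {
    stop("signal_to_noise requires finite values")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  sa <- s2n_floor(stats::sd(values_a), ma)
  sb <- s2n_floor(stats::sd(values_b), mb)
  (ma - mb) / (sa + sb)
}

s2n_floor <- function(s, m) {
  floor_val <- if (m == 0) 0.2 else 0.2 * abs(m)
  max(s, floor_val)
}

#' Rank all genes by signal to noise between two sample groups
#'
#' Builds the ranked list GSEA consumes: genes ordered by descending
#' signal-to-noise score for group A (e.g., mutant) minus group B (control),
#' ties broken by gene symbol (lexicographic) so the order is deterministic.
#'
#' @param norm Normalized expression matrix, genes x samples.
#' @param group_a,group_b Disjoint sample-identifier vectors (>= 2 each).
#' @return data.frame with columns \code{gene}, \code{score}, ordered by
#'   descending score.
#' @export
rank_signal_to_noise <- function(norm, group_a, group_b) {
  group_a <- intersect(group_a, colnames(norm))
  group_b <- intersect(group_b, colnames(norm))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples present in the matrix")
  }
  xa <- norm[, group_a, drop = FALSE]
  xb <- norm[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  sa <- sqrt(rowSums((xa - ma)^2) / (length(group_a) - 1L))
  sb <- sqrt(rowSums((xb - mb)^2) / (length(group_b) - 1L))
  sa <- pmax(sa, ifelse(ma == 0, 0.2, 0.2 * abs(ma)))
  sb <- pmax(sb, ifelse(mb == 0, 0.2, 0.2 * abs(mb)))
  score <- (ma - mb) / (sa + sb)
  ord <- order(-score, rownames(norm), method = "radix")
  out <- data.frame(gene = rownames(norm)[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Weighted running-sum enrichment score
#'
#' The weighted Kolmogorov-Smirnov-like statistic: walking down the ranked
#' list, a gene in the set increments the running sum by
#' \code{|score|^p / sum(|score_hits|^p)} and a gene outside it decrements
#' by \code{1 / (N - N_hits)}; the enrichment score is the signed maximum
#' deviation from zero.  \code{weight_p = 0} recovers the classic
#' unweighted KS statistic.
#'
#' @param ranked data.frame from \code{\link{rank_signal_to_noise}} (or any
#'   \code{gene}/\code{score} frame ordered by descending score).
#' @param gene_set Character vector of gene symbols.
#' @param weight_p Score weight exponent (default 1).
#' @return List with \code{es}, \code{running} (the full running-sum
#'   profile), \code{leading_edge} (gene symbols) and \code{size} (set size
#'   after intersection with the ranked universe).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  genes <- ranked$gene
  scores <- ranked$score
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stop("gene set is disjoint from the ranked universe")
  if (nh == length(genes)) stop("gene set equals the ranked universe")
  run <- running_sum(scores, which(hit), weight_p)
  i_ext <- if (positive_extreme(max(run), min(run))) which.max(run) else which.min(run)
  es <- run[i_ext]
  le <- if (es >= 0) genes[hit & seq_along(genes) <= i_ext]
        else genes[hit & seq_along(genes) >= i_ext]
  list(es = es, running = run, leading_edge = le, size = nh)
}

running_sum <- function(scores, hit_idx, weight_p) {
  n <- length(scores)
  nh <- length(hit_idx)
  w <- abs(scores[hit_idx])^weight_p
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else rep(1 / nh, nh)
  delta <- rep(-1 / (n - nh), n)
  delta[hit_idx] <- inc
  cumsum(delta)
}

# signed maximum deviation of a running sum; a tie in magnitude (to within
# floating-point noise) resolves to the positive deviation
positive_extreme <- function(mx, mn) {
  mx + mn >= -1e-12 * max(abs(mx), abs(mn), 1)
}

# deterministic per-set null seed: base seed, set size, membership hash
null_seed_for_set <- function(seed, size, genes) {
  h <- sum(utf8ToInt(paste(sort(genes), collapse = "|"))) %% 1000003L
  (as.integer(seed) + 131L * as.integer(size) + h) %% .Machine$integer.max
}

es_only <- function(scores, hit_idx, weight_p) {
  run <- running_sum(scores, hit_idx, weight_p)
  if (positive_extreme(max(run), min(run))) max(run) else min(run)
}

#' Permutation null distribution of the enrichment score
#'
#' Draws \code{n_perm} gene sets of the given size uniformly without
#' replacement from the ranked universe and returns their enrichment
#' scores.  Reproducible under the seed.
#'
#' @param ranked Ranked gene/score data.frame.
#' @param set_size Size of the random sets.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed.
#' @param weight_p Score weight exponent.
#' @return Numeric vector of null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000L, seed = 1L,
                             weight_p = 1) {
  n <- nrow(ranked)
  if (set_size >= n) stop("set_size must be smaller than the universe")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  set.seed(seed)
  scores <- ranked$score
  vapply(seq_len(n_perm), function(i) {
    es_only(scores, sample.int(n, set_size), weight_p)
  }, numeric(1L))
}

#' Run GSEA over a gene-set collection
#'
#' Per set: enrichment score, normalized enrichment score (ES divided by
#' the mean |ES| of same-sign permutation nulls), permutation p-value with
#' the +1 correction (the attainable floor is \code{1/(1 + n_same_sign)}
#' since the estimator conditions on same-sign nulls), and BH adjustment
#' across the collection.  Each set's null is generated with a seed derived
#' from \code{seed}, the set size and a hash of the set's membership, so
#' duplicate sets get identical results while distinct sets get independent
#' nulls.  Sets smaller than \code{min_size} after intersection with the
#' ranked universe are skipped with a flag.
#'
#' @param ranked Ranked gene/score data.frame.
#' @param collection Named list of gene-symbol vectors.
#' @param n_perm Permutations per set size (default 1000).
#' @param seed Base seed.
#' @param weight_p Score weight exponent (default 1).
#' @param min_size Minimum post-intersection set size (default 5).
#' @return data.frame with one row per set: \code{set}, \code{size},
#'   \code{es}, \code{nes}, \code{p}, \code{padj}, \code{leading_edge}
#'   (comma-separated), \code{flag}.
#' @export
gsea_batch <- function(ranked, collection, n_perm = 1000L, seed = 1L,
                       weight_p = 1, min_size = 5L) {
  stopifnot(length(collection) > 0, !is.null(names(collection)))
  universe <- ranked$gene
  sizes <- vapply(collection, function(gs) sum(universe %in% gs), integer(1L))
  run_sets <- names(collection)[sizes >= min_size & sizes < length(universe)]
  if (!length(run_sets)) {
    stop("every set was skipped (all below min_size ", min_size,
         " after intersection, or equal to the universe)")
  }
  nulls <- list()
  rows <- lapply(names(collection), function(nm) {
    k <- sizes[[nm]]
    if (!(nm %in% run_sets)) {
      return(data.frame(set = nm, size = k, es = NA_real_, nes = NA_real_,
                        p = NA_real_, padj = NA_real_, leading_edge = "",
                        flag = "skipped_small_set", stringsAsFactors = FALSE))
    }
    er <- enrichment_score(ranked, collection[[nm]], weight_p)
    null_seed <- null_seed_for_set(seed, k,
                                   universe[universe %in% collection[[nm]]])
    key <- as.character(null_seed)
    if (is.null(nulls[[key]])) {
      nulls[[key]] <<- permutation_null(ranked, k, n_perm, null_seed, weight_p)
    }
    null_es <- nulls[[key]]
    same_sign <- null_es[sign(null_es) == sign(er$es) & null_es != 0]
    if (!length(same_sign)) {
      return(data.frame(set = nm, size = k, es = er$es, nes = NA_real_,
                        p = 1 / (n_perm + 1), padj = NA_real_,
                        leading_edge = paste(er$leading_edge, collapse = ","),
                        flag = "no_same_sign_null", stringsAsFactors = FALSE))
    }
    nes <- er$es / mean(abs(same_sign))
    p <- (1 + sum(abs(same_sign) >= abs(er$es))) / (1 + length(same_sign))
    data.frame(set = nm, size = k, es = er$es, nes = nes, p = p,
               padj = NA_real_,
               leading_edge = paste(er$leading_edge, collapse = ","),
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- is.na(out$flag)
  out$padj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}

#' Long-format volcano table across result collections
#'
#' Binds per-collection GSEA results into one table suitable for volcano
#' plotting (NES on x, adjusted p on y), flags sets whose names match the
#' highlight patterns, and sorts by adjusted p then |NES| descending
#' (stable).
#'
#' @param results_by_collection Named list of \code{\link{gsea_batch}}
#'   result data.frames.
#' @param highlight_patterns Character vector of regular expressions.
#' @return data.frame with columns \code{collection}, \code{set},
#'   \code{nes}, \code{p}, \code{padj}, \code{highlight}.
#' @export
volcano_table <- function(results_by_collection, highlight_patterns = character(0)) {
  stopifnot(length(results_by_collection) >= 1L,
            !is.null(names(results_by_collection)))
  rows <- lapply(names(results_by_collection), function(cl) {
    r <- results_by_collection[[cl]]
    data.frame(collection = cl, set = r$set, nes = r$nes, p = r$p,
               padj = r$padj, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$highlight <- FALSE
  for (pat in highlight_patterns) {
    out$highlight <- out$highlight | grepl(pat, out$set)
  }
  ord <- order(out$padj, -abs(out$nes), method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
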