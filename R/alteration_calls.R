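#' Default nonsynonymous variant classes
#'
#' Protein-altering classes counted as mutation evidence: missense,
#' nonsense, and the two frameshift classes.  Splice-site and in-frame
#' indels are excluded by default but can be supplied explicitly to the
#' calling functions.
#' @return Character vector of MAF classification strings.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins")
}

#' Call per-sample alteration status for a gene panel
#'
#' A sample is altered if, for any listed gene, it carries a deep deletion
#' (Gistic -2), a focal amplification (Gistic +2), or a variant whose class
#' is in \code{variant_classes}.  Shallow Gistic events (-1/+1) never count.
#' This is the polarity-blind screen used for complex-level co-occurrence
#' frequencies.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param genes Gene symbols to screen.
#' @param variant_classes Variant classes accepted as evidence.
#' @return A \code{sample_alteration_status}: list with \code{altered}
#'   (named logical over shared samples) and \code{evidence} (named list of
#'   character descriptions).
#' @export
call_any_alteration <- function(bundle, genes,
                                variant_classes = nonsynonymous_classes()) {
  rules <- lapply(genes, function(g) {
    list(deep_deletion = TRUE, amplification = TRUE,
         variant_classes = variant_classes)
  })
  names(rules) <- genes
  apply_alteration_rules(bundle, rules)
}

#' Call per-sample NRF2 pathway activation
#'
#' The polarity-aware rule used to assign preliminary activity labels:
#' a sample is NRF2 active iff it has a KEAP1 or CUL3 deep deletion
#' (Gistic -2), an NFE2L2 amplification (Gistic +2), a nonsynonymous
#' variant in KEAP1 or CUL3, or a missense variant in NFE2L2.  Note the
#' asymmetry: NFE2L2 deep deletion and NFE2L2 truncating variants are not
#' activating evidence (loss of the oncogene itself does not stabilize it).
#'
#' @param bundle A \code{cohort_bundle}.
#' @param variant_classes Nonsynonymous classes used for KEAP1/CUL3.
#' @return A \code{sample_alteration_status}.
#' @export
call_nrf2_active <- function(bundle,
                             variant_classes = nonsynonymous_classes()) {
  rules <- list(
    KEAP1 = list(deep_deletion = TRUE, amplification = FALSE,
                 variant_classes = variant_classes),
    CUL3 = list(deep_deletion = TRUE, amplification = FALSE,
                variant_classes = variant_classes),
    NFE2L2 = list(deep_deletion = FALSE, amplification = TRUE,
                  variant_classes = "Missense_Mutation")
  )
  apply_alteration_rules(bundle, rules)
}

apply_alteration_rules <- function(bundle, rules) {
  samples <- bundle$shared_samples
  evidence <- stats::setNames(vector("list", length(samples)), samples)
  genes <- names(rules)
  absent <- genes[!(genes %in% rownames(bundle$cnv)) &
                  !(genes %in% bundle$variants$gene)]
  if (length(absent)) {
    warning("gene(s) absent from all evidence sources: ",
            paste(absent, collapse = ", "))
  }
  for (g in genes) {
    rule <- rules[[g]]
    if (g %in% rownames(bundle$cnv)) {
      sc <- bundle$cnv[g, samples]
      if (isTRUE(rule$deep_deletion)) {
        for (s in samples[sc == -2L]) {
          evidence[[s]] <- c(evidence[[s]], paste0(g, ":deep_deletion"))
        }
      }
      if (isTRUE(rule$amplification)) {
        for (s in samples[sc == 2L]) {
          evidence[[s]] <- c(evidence[[s]], paste0(g, ":amplification"))
        }
      }
    }
    hits <- bundle$variants[bundle$variants$gene == g &
                            bundle$variants$variant_class %in% rule$variant_classes, ]
    for (i in seq_len(nrow(hits))) {
      s <- hits$sample[i]
      if (s %in% samples) {
        evidence[[s]] <- c(evidence[[s]], paste0(g, ":", hits$variant_class[i]))
      }
    }
  }
  altered <- vapply(evidence, function(e) length(e) > 0L, logical(1L))
  structure(list(altered = altered, evidence = evidence, genes = genes),
            class = "sample_alteration_status")
}

#' Build confound-filtered mutant vs wild-type groups for one subunit
#'
#' Partitions the cohort for a gene of interest: \emph{mutant} samples are
#' altered in the gene of interest, in no other panel subunit, and not NRF2
#' pathway activated; \emph{control} samples carry no panel-subunit
#' alteration and no NRF2 activation; everything else is \emph{excluded}
#' with a per-sample reason.  An undersized mutant group is flagged, not an
#' error.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param gene_of_interest One gene from \code{swisnf_panel}.
#' @param swisnf_panel SWI/SNF subunit panel.
#' @param nrf2_panel NRF2 pathway genes (the activation rule is fixed to the
#'   polarity-aware \code{\link{call_nrf2_active}} predicate).
#' @param min_group_size Mutant groups smaller than this are flagged.
#' @param variant_classes Nonsynonymous classes used throughout.
#' @return A \code{group_assignment}: list with \code{gene_of_interest},
#'   \code{mutant}, \code{control}, \code{excluded} (named character vector
#'   of reasons) and \code{flag}.
#' @export
build_groups <- function(bundle, gene_of_interest,
                         swisnf_panel = c("ARID1A", "ARID1B", "ARID2", "PBRM1"),
                         nrf2_panel = nrf2_pathway_genes(),
                         min_group_size = 5L,
                         variant_classes = nonsynonymous_classes()) {
  if (!gene_of_interest %in% swisnf_panel) {
    stop("gene_of_interest must be a member of swisnf_panel")
  }
  if (length(intersect(swisnf_panel, nrf2_panel))) {
    stop("swisnf_panel and nrf2_panel must be disjoint")
  }
  if (!(gene_of_interest %in% rownames(bundle$cnv)) &&
      !(gene_of_interest %in% bundle$variants$gene)) {
    stop("gene_of_interest '", gene_of_interest,
         "' is absent from every evidence source")
  }
  samples <- bundle$shared_samples
  goi <- call_any_alteration(bundle, gene_of_interest, variant_classes)$altered
  others <- setdiff(swisnf_panel, gene_of_interest)
  other_alt <- if (length(others)) {
    suppressWarnings(call_any_alteration(bundle, others, variant_classes)$altered)
  } else {
    stats::setNames(rep(FALSE, length(samples)), samples)
  }
  nrf2 <- suppressWarnings(call_nrf2_active(bundle, variant_classes))$altered

  mutant <- samples[goi & !other_alt & !nrf2]
  control <- samples[!goi & !other_alt & !nrf2]
  excluded_idx <- !(samples %in% c(mutant, control))
  reasons <- character(0)
  for (s in samples[excluded_idx]) {
    reasons[s] <- if (goi[s] && (other_alt[s] || nrf2[s])) {
      "confounded_mutant"
    } else if (nrf2[s]) {
      "nrf2_pathway_altered"
    } else {
      "other_subunit_altered"
    }
  }
  flag <- if (length(mutant) < min_group_size) {
    sprintf("mutant group undersized (%d < %d)", length(mutant),
            as.integer(min_group_size))
  } else {
    NA_character_
  }
  structure(list(gene_of_interest = gene_of_interest,
                 mutant = mutant, control = control, excluded = reasons,
                 flag = flag, n_samples = length(samples)),
            class = "group_assignment")
}

#' Per-cohort alteration frequency table
#'
#' For each cohort: the fraction of samples with any NRF2-pathway
#' alteration, any SWI/SNF panel alteration, both (coincident), and
#' per-subunit fractions.  Uses the polarity-blind screen on both panels,
#' matching a complex-level frequency landscape.
#'
#' @param bundles List of \code{cohort_bundle}s.
#' @param swisnf_panel SWI/SNF subunit panel.
#' @param nrf2_panel NRF2 pathway panel.
#' @param variant_classes Nonsynonymous classes.
#' @return data.frame, one row per cohort, with columns \code{cohort},
#'   \code{n}, \code{freq_nrf2}, \code{freq_swisnf}, \code{freq_coincident}
#'   and \code{freq_<gene>} per panel gene.
#' @export
alteration_frequencies <- function(bundles,
                                   swisnf_panel = c("ARID1A", "ARID1B", "ARID2", "PBRM1"),
                                   nrf2_panel = nrf2_pathway_genes(),
                                   variant_classes = nonsynonymous_classes()) {
  stopifnot(length(bundles) >= 1L)
  rows <- lapply(bundles, function(b) {
    n <- length(b$shared_samples)
    if (length(nrf2_panel)) {
      nrf2 <- suppressWarnings(call_any_alteration(b, nrf2_panel, variant_classes))$altered
    } else nrf2 <- stats::setNames(rep(FALSE, n), b$shared_samples)
    if (length(swisnf_panel)) {
      sw <- suppressWarnings(call_any_alteration(b, swisnf_panel, variant_classes))$altered
    } else sw <- stats::setNames(rep(FALSE, n), b$shared_samples)
    row <- data.frame(cohort = b$cohort_name, n = n,
                      freq_nrf2 = mean(nrf2), freq_swisnf = mean(sw),
                      freq_coincident = mean(nrf2 & sw),
                      n_nrf2 = sum(nrf2), n_swisnf = sum(sw),
                      stringsAsFactors = FALSE)
    for (g in swisnf_panel) {
      gi <- suppressWarnings(call_any_alteration(b, g, variant_classes))$altered
      row[[paste0("freq_", g)]] <- mean(gi)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("group_assignment for ", x$gene_of_interest, ": ",
      length(x$mutant), " mutant / ", length(x$control), " control / ",
      length(x$excluded), " excluded of ", x$n_samples, "\n", sep = "")
  if (!is.na(x$flag)) cat("  flag: ", x$flag, "\n", sep = "")
  invisible(x)
}
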