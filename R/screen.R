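#' Configuration for the cohort x subunit GSEA screen
#'
#' @param genes_of_interest SWI/SNF subunits screened (each gets a mutant vs
#'   control comparison).
#' @param swisnf_panel Panel used for confound filtering.
#' @param nrf2_panel NRF2 pathway genes.
#' @param collections Named list of gene-set collections (each itself a
#'   named list of gene vectors), e.g. the NRF2 signature panel plus
#'   Hallmark-style sets.
#' @param include_positive_control Add an NRF2-pathway-mutant vs control
#'   comparison row (labelled \code{"NRF2_PATHWAY"}).
#' @param cpm_threshold,min_fraction Low-expression filter parameters.
#' @param prior_count log-CPM offset.
#' @param mode \code{"rnaseq"} (filter + TMM + log-CPM) or
#'   \code{"proteomic"} (median centering only).
#' @param n_perm,weight_p,min_set_size GSEA parameters.
#' @param min_group_size Smaller mutant groups yield flagged rows.
#' @param seed Master seed (recorded in the manifest; drives the GSEA
#'   permutations).
#' @return A \code{screen_config} list.
#' @export
screen_config <- function(genes_of_interest = c("ARID1A", "ARID1B", "ARID2", "PBRM1"),
                          swisnf_panel = c("ARID1A", "ARID1B", "ARID2", "PBRM1"),
                          nrf2_panel = nrf2_pathway_genes(),
                          collections = list(),
                          include_positive_control = TRUE,
                          cpm_threshold = 1, min_fraction = 0.2,
                          prior_count = 0.5, mode = "rnaseq",
                          n_perm = 1000L, weight_p = 1, min_set_size = 5L,
                          min_group_size = 5L, seed = 1L) {
  stopifnot(all(genes_of_interest %in% swisnf_panel),
            mode %in% c("rnaseq", "proteomic"))
  list(genes_of_interest = genes_of_interest, swisnf_panel = swisnf_panel,
       nrf2_panel = nrf2_panel, collections = collections,
       include_positive_control = include_positive_control,
       cpm_threshold = cpm_threshold, min_fraction = min_fraction,
       prior_count = prior_count, mode = mode,
       n_perm = as.integer(n_perm), weight_p = weight_p,
       min_set_size = as.integer(min_set_size),
       min_group_size = as.integer(min_group_size), seed = as.integer(seed))
}

prepare_screen_matrix <- function(bundle, config) {
  if (config$mode == "proteomic") {
    return(median_center(bundle$counts))
  }
  filt <- filter_low_expression(bundle$counts, config$cpm_threshold,
                                config$min_fraction)
  log_cpm(filt, tmm_factors(filt), config$prior_count)
}

screen_groups <- function(bundle, config) {
  groups <- list()
  for (g in config$genes_of_interest) {
    groups[[g]] <- build_groups(bundle, g, config$swisnf_panel,
                                config$nrf2_panel, config$min_group_size)
  }
  if (config$include_positive_control) {
    act <- suppressWarnings(call_nrf2_active(bundle))$altered
    sw <- suppressWarnings(call_any_alteration(bundle, config$swisnf_panel))$altered
    mutant <- names(act)[act & !sw]
    control <- names(act)[!act & !sw]
    flag <- if (length(mutant) < config$min_group_size) {
      sprintf("mutant group undersized (%d < %d)", length(mutant),
              config$min_group_size)
    } else NA_character_
    groups[["NRF2_PATHWAY"]] <- structure(
      list(gene_of_interest = "NRF2_PATHWAY", mutant = mutant,
           control = control, excluded = character(0), flag = flag,
           n_samples = length(act)),
      class = "group_assignment")
  }
  groups
}

#' Run the full cohort x subunit GSEA screen
#'
#' For every cohort and gene of interest: build the confound-filtered
#' mutant vs control groups, normalize the expression data, rank genes by
#' mutant-minus-control signal to noise (positive NES therefore means the
#' set is up in mutants), and run GSEA over every configured collection.
#' A positive-control comparison (NRF2-pathway mutant vs control) is added
#' per cohort.  Undersized groups produce flagged rows, never errors.
#'
#' @param bundles Named list of \code{cohort_bundle}s.
#' @param config A \code{\link{screen_config}}.
#' @return A \code{screen_result}: list with \code{table} (long data.frame:
#'   cohort, gene_of_interest, collection, set, size, es, nes, p, padj,
#'   n_mutant, n_control, flag) and \code{manifest}.
#' @export
run_screen <- function(bundles, config = screen_config()) {
  stopifnot(length(bundles) >= 1L, length(config$collections) >= 1L)
  if (is.null(names(bundles))) {
    names(bundles) <- vapply(bundles, `[[`, character(1L), "cohort_name")
  }
  t0 <- Sys.time()
  rows <- list()
  completed <- character(0)
  diagnostics <- list()
  for (cname in names(bundles)) {
    bundle <- bundles[[cname]]
    res <- tryCatch({
      norm <- prepare_screen_matrix(bundle, config)
      groups <- screen_groups(bundle, config)
      for (g in names(groups)) {
        grp <- groups[[g]]
        if (!is.na(grp$flag) || length(grp$control) < 2L) {
          flag <- if (!is.na(grp$flag)) grp$flag else "control group undersized"
          for (coll in names(config$collections)) {
            for (set in names(config$collections[[coll]])) {
              rows[[length(rows) + 1L]] <- data.frame(
                cohort = cname, gene_of_interest = g, collection = coll,
                set = set, size = NA_integer_, es = NA_real_, nes = NA_real_,
                p = NA_real_, padj = NA_real_,
                n_mutant = length(grp$mutant), n_control = length(grp$control),
                flag = flag, stringsAsFactors = FALSE)
            }
          }
          next
        }
        ranked <- rank_signal_to_noise(norm, grp$mutant, grp$control)
        for (coll in names(config$collections)) {
          gs <- gsea_batch(ranked, config$collections[[coll]],
                           n_perm = config$n_perm, seed = config$seed,
                           weight_p = config$weight_p,
                           min_size = config$min_set_size)
          rows[[length(rows) + 1L]] <- data.frame(
            cohort = cname, gene_of_interest = g, collection = coll,
            set = gs$set, size = gs$size, es = gs$es, nes = gs$nes,
            p = gs$p, padj = gs$padj,
            n_mutant = length(grp$mutant), n_control = length(grp$control),
            flag = gs$flag, stringsAsFactors = FALSE)
        }
      }
      TRUE
    }, error = function(e) e)
    if (isTRUE(res)) {
      completed <- c(completed, cname)
    } else {
      diagnostics[[cname]] <- conditionMessage(res)
    }
  }
  if (!length(completed)) {
    stop("no cohort completed the screen; diagnostics: ",
         paste(names(diagnostics), unlist(diagnostics),
               sep = ": ", collapse = "; "))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  manifest <- list(seed = config$seed, n_perm = config$n_perm,
                   weight_p = config$weight_p, mode = config$mode,
                   genes_of_interest = config$genes_of_interest,
                   collections = lapply(config$collections, names),
                   cohorts = names(bundles), completed = completed,
                   diagnostics = diagnostics,
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  structure(list(table = table, manifest = manifest),
            class = "screen_result")
}

#' Wide NES matrix for heatmap display
#'
#' Pivots the screen's long table into a genes-of-interest x signatures NES
#' matrix for one collection.  Cells from flagged rows are NA in the NES
#' matrix and marked \code{"masked"}; the significance mask marks
#' \code{"sig"} at adjusted p < \code{alpha}, \code{"ns"} otherwise.
#'
#' @param result A \code{screen_result}.
#' @param collection_filter Collection name to pivot.
#' @param cohort Optional cohort name (required when the result spans
#'   several cohorts).
#' @param alpha Significance cutoff for the mask.
#' @return List with \code{nes} (matrix) and \code{mask} (character matrix
#'   of \code{"sig"}/\code{"ns"}/\code{"masked"}).
#' @export
heatmap_table <- function(result, collection_filter, cohort = NULL,
                          alpha = 0.05) {
  tab <- result$table
  tab <- tab[tab$collection == collection_filter, , drop = FALSE]
  if (!is.null(cohort)) tab <- tab[tab$cohort == cohort, , drop = FALSE]
  if (!nrow(tab)) stop("no rows match the requested collection/cohort")
  if (length(unique(tab$cohort)) > 1L) {
    stop("result spans several cohorts; pass `cohort`")
  }
  genes <- unique(tab$gene_of_interest)
  sets <- unique(tab$set)
  nes <- matrix(NA_real_, length(genes), length(sets),
                dimnames = list(genes, sets))
  mask <- matrix("masked", length(genes), length(sets),
                 dimnames = list(genes, sets))
  for (i in seq_len(nrow(tab))) {
    g <- tab$gene_of_interest[i]; s <- tab$set[i]
    if (is.na(tab$flag[i])) {
      nes[g, s] <- tab$nes[i]
      mask[g, s] <- if (!is.na(tab$padj[i]) && tab$padj[i] < alpha) "sig" else "ns"
    }
  }
  list(nes = nes, mask = mask)
}

#' Cross-dataset concordance of screen results
#'
#' Compares two screen results (e.g., an RNA-seq cohort and a proteomic
#' validation cohort) over their shared (gene-of-interest, set) pairs:
#' NES sign agreement per pair and the overall sign-concordance fraction.
#'
#' @param result_a,result_b \code{screen_result}s.
#' @return List with \code{pairs} (data.frame: gene_of_interest, set,
#'   nes_a, nes_b, padj_a, padj_b, sign_agree) and \code{concordance}.
#' @export
validate_cross_dataset <- function(result_a, result_b) {
  key <- function(t) paste(t$gene_of_interest, t$set, sep = "\r")
  ta <- result_a$table[is.na(result_a$table$flag), , drop = FALSE]
  tb <- result_b$table[is.na(result_b$table$flag), , drop = FALSE]
  shared <- intersect(key(ta), key(tb))
  if (!length(shared)) stop("no shared (gene, set) pairs between the results")
  ia <- match(shared, key(ta)); ib <- match(shared, key(tb))
  pairs <- data.frame(gene_of_interest = ta$gene_of_interest[ia],
                      set = ta$set[ia],
                      nes_a = ta$nes[ia], nes_b = tb$nes[ib],
                      padj_a = ta$padj[ia], padj_b = tb$padj[ib],
                      stringsAsFactors = FALSE)
  pairs$sign_agree <- sign(pairs$nes_a) == sign(pairs$nes_b)
  list(pairs = pairs, concordance = mean(pairs$sign_agree, na.rm = TRUE))
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: ", length(unique(x$table$cohort)), " cohort(s), ",
      length(unique(x$table$gene_of_interest)), " gene(s) of interest, ",
      nrow(x$table), " rows (seed ", x$manifest$seed, ")\n", sep = "")
  invisible(x)
}
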