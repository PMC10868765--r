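#' Specification of a synthetic tumor cohort
#'
#' Collects every generative parameter of the cohort simulator and validates
#' it.  The simulator plants: (i) a designated NRF2-active sample subset with
#' upregulated "NRF2 target" genes, (ii) mutation/CNV events consistent with
#' the activity labels (KEAP1/CUL3/NFE2L2 rules), (iii) SWI/SNF-subunit
#' mutants with configurable co-occurrence odds and a direct expression
#' effect on the signature genes (polarity knob), and (iv) optional
#' passenger "confounder" mutations in other subunits that trigger group
#' exclusion downstream.
#'
#' @param n_genes Total genes in the cohort (background genes are named
#'   SYNG000001...; pathway/subunit genes keep their real symbols).
#' @param n_samples Samples in the cohort (TCGA-style 15-character barcodes).
#' @param frac_nrf2_active Fraction of samples planted as NRF2 active.
#' @param n_signature_genes Number of planted NRF2 target genes.
#' @param effect_log2fc_mean,effect_log2fc_sd Per-gene activation effect on
#'   the log2 scale, drawn once per signature gene.
#' @param nb_dispersion Negative-binomial dispersion shared across genes.
#' @param libsize_log_mean,libsize_log_sd Per-sample depth factor, log-normal.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance on
#'   the log2 scale.
#' @param subunit_configs Named list (one entry per SWI/SNF subunit), each a
#'   list with \code{rate} (mutation frequency), \code{odds_ratio}
#'   (co-occurrence with the NRF2-active state), \code{polarity} (direct
#'   effect of the mutation on signature-gene expression: +1, 0 or -1) and
#'   \code{magnitude} (size of that effect in log2 units).
#' @param confounder_rate Per-sample rate of passenger mutations in other
#'   panel subunits (these trigger exclusion downstream but carry no
#'   expression effect).
#' @param shallow_cnv_rate Rate of irrelevant -1/+1 Gistic calls sprinkled
#'   over pathway/subunit genes (must never count as alteration evidence).
#' @param seed Master seed; all randomness derives from it.
#' @return A validated \code{simulation_spec} list.
#' @export
simulation_spec <- function(n_genes = 2000L,
                            n_samples = 120L,
                            frac_nrf2_active = 0.3,
                            n_signature_genes = 100L,
                            effect_log2fc_mean = 2,
                            effect_log2fc_sd = 0.5,
                            nb_dispersion = 0.2,
                            libsize_log_mean = log(2e5),
                            libsize_log_sd = 0.3,
                            baseline_log2_mean = -8,
                            baseline_log2_sd = 2,
                            subunit_configs = default_subunit_configs(),
                            confounder_rate = 0.05,
                            shallow_cnv_rate = 0.05,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples = as.integer(n_samples),
               frac_nrf2_active = frac_nrf2_active,
               n_signature_genes = as.integer(n_signature_genes),
               effect_log2fc_mean = effect_log2fc_mean,
               effect_log2fc_sd = effect_log2fc_sd,
               nb_dispersion = nb_dispersion,
               libsize_log_mean = libsize_log_mean,
               libsize_log_sd = libsize_log_sd,
               baseline_log2_mean = baseline_log2_mean,
               baseline_log2_sd = baseline_log2_sd,
               subunit_configs = subunit_configs,
               confounder_rate = confounder_rate,
               shallow_cnv_rate = shallow_cnv_rate,
               seed = as.integer(seed))
  validate_simulation_spec(spec)
  structure(spec, class = "simulation_spec")
}

#' Default SWI/SNF subunit configuration
#'
#' The four subunits the analysis studies.  ARID1A is planted to co-occur
#' with NRF2 activity and to push signature genes up; ARID1B pushes them
#' down (the mutually exclusive BAF paralog pattern); ARID2 and PBRM1 are
#' neutral PBAF controls.
#' @return Named list of per-subunit configurations.
#' @export
default_subunit_configs <- function() {
  list(
    ARID1A = list(rate = 0.12, odds_ratio = 6, polarity = 1,  magnitude = 1),
    ARID1B = list(rate = 0.10, odds_ratio = 1, polarity = -1, magnitude = 1),
    ARID2  = list(rate = 0.08, odds_ratio = 1, polarity = 0,  magnitude = 0),
    PBRM1  = list(rate = 0.08, odds_ratio = 1, polarity = 0,  magnitude = 0)
  )
}

validate_simulation_spec <- function(spec) {
  stopifnot(spec$n_genes >= 10L, spec$n_samples >= 4L)
  if (spec$frac_nrf2_active < 0 || spec$frac_nrf2_active >= 1) {
    stop("frac_nrf2_active must lie in [0, 1)")
  }
  if (spec$n_signature_genes >= spec$n_genes) {
    stop("n_signature_genes must be smaller than n_genes")
  }
  if (spec$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  for (nm in c("effect_log2fc_sd", "libsize_log_sd", "baseline_log2_sd")) {
    if (spec[[nm]] <= 0) stop(nm, " must be positive")
  }
  for (nm in c("confounder_rate", "shallow_cnv_rate")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  for (su in names(spec$subunit_configs)) {
    cfg <- spec$subunit_configs[[su]]
    if (cfg$rate < 0 || cfg$rate > 1) stop("mutation rate for ", su, " outside [0, 1]")
    if (cfg$odds_ratio <= 0) stop("odds_ratio for ", su, " must be positive")
    if (!cfg$polarity %in% c(-1, 0, 1)) stop("polarity for ", su, " must be -1, 0 or +1")
  }
  invisible(spec)
}

nrf2_pathway_genes <- function() c("KEAP1", "NFE2L2", "CUL3")

#' Simulate one tumor cohort with planted ground truth
#'
#' Counts are drawn from a negative-binomial model with per-gene mean
#' \code{libsize_s * 2^(baseline_g + active_s * effect_g + subunit effects)}
#' and shared dispersion.  NRF2-active samples receive one pathway event
#' drawn from the activating menu (KEAP1/CUL3 nonsynonymous variant, CUL3
#' deep deletion, NFE2L2 missense or amplification); subunit mutants receive
#' a nonsynonymous variant in that subunit; every sample additionally
#' carries a silent passenger variant so the MAF covers the whole cohort.
#' Output is byte-identical under a fixed seed.
#'
#' @param spec A \code{\link{simulation_spec}}.
#' @param cohort_name Label for the emitted bundle.
#' @param signature_genes Optional character vector forcing the planted
#'   signature gene identities (used by \code{\link{simulate_multi_cohort}}).
#' @param seed Optional override of \code{spec$seed}.
#' @return List with \code{bundle} (a \code{cohort_bundle}) and \code{truth}
#'   (a \code{planted_truth}: active samples, signature genes with effects,
#'   per-subunit mutant sets, full event table).
#' @export
simulate_cohort <- function(spec, cohort_name = "SYNTH",
                            signature_genes = NULL, seed = NULL) {
  validate_simulation_spec(spec)
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)

  real_genes <- c(nrf2_pathway_genes(), names(spec$subunit_configs))
  n_bg <- spec$n_genes - length(real_genes)
  bg_genes <- sprintf("SYNG%06d", seq_len(n_bg))
  genes <- c(real_genes, bg_genes)
  samples <- sprintf("TCGA-SM-%04d-01", seq_len(spec$n_samples))

  n_active <- round(spec$frac_nrf2_active * spec$n_samples)
  active <- sort(sample(samples, n_active))
  is_active <- samples %in% active

  if (is.null(signature_genes)) {
    signature_genes <- sort(sample(bg_genes, spec$n_signature_genes))
  } else {
    stopifnot(all(signature_genes %in% bg_genes))
  }
  effects <- stats::rnorm(length(signature_genes),
                          spec$effect_log2fc_mean, spec$effect_log2fc_sd)
  names(effects) <- signature_genes

  # subunit mutant assignment with the configured co-occurrence odds ratio
  a <- n_active / spec$n_samples
  subunit_mutants <- list()
  for (su in names(spec$subunit_configs)) {
    cfg <- spec$subunit_configs[[su]]
    p11 <- solve_joint_prob(a, cfg$rate, cfg$odds_ratio)
    p_act <- if (a > 0) min(1, p11 / a) else 0
    p_ina <- if (a < 1) min(1, (cfg$rate - p11) / (1 - a)) else 0
    p <- ifelse(is_active, p_act, p_ina)
    subunit_mutants[[su]] <- samples[stats::runif(spec$n_samples) < p]
  }

  # expression model
  baseline <- stats::rnorm(spec$n_genes, spec$baseline_log2_mean,
                           spec$baseline_log2_sd)
  names(baseline) <- genes
  libsize <- exp(stats::rnorm(spec$n_samples, spec$libsize_log_mean,
                              spec$libsize_log_sd))
  mu_log2 <- matrix(baseline, nrow = spec$n_genes, ncol = spec$n_samples,
                    dimnames = list(genes, samples))
  mu_log2[signature_genes, is_active] <-
    mu_log2[signature_genes, is_active] + effects
  for (su in names(spec$subunit_configs)) {
    cfg <- spec$subunit_configs[[su]]
    shift <- cfg$polarity * cfg$magnitude
    mut <- samples %in% subunit_mutants[[su]]
    if (shift != 0 && any(mut)) {
      mu_log2[signature_genes, mut] <- mu_log2[signature_genes, mut] + shift
    }
  }
  mu <- sweep(2^mu_log2, 2L, libsize, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / spec$nb_dispersion),
                   nrow = spec$n_genes, dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"

  # event planting
  nonsyn <- c("Missense_Mutation", "Nonsense_Mutation",
              "Frame_Shift_Del", "Frame_Shift_Ins")
  ev <- list()
  add_event <- function(sample, gene, kind, class = NA_character_) {
    ev[[length(ev) + 1L]] <<- data.frame(sample = sample, gene = gene,
                                         kind = kind, variant_class = class,
                                         stringsAsFactors = FALSE)
  }
  cnv <- matrix(0L, nrow = spec$n_genes, ncol = spec$n_samples,
                dimnames = list(genes, samples))
  menu <- c("KEAP1_variant", "CUL3_variant", "CUL3_deep_deletion",
            "NFE2L2_missense", "NFE2L2_amplification")
  for (s in active) {
    pick <- sample(menu, 1L)
    switch(pick,
      KEAP1_variant = add_event(s, "KEAP1", "pathway_variant", sample(nonsyn, 1L)),
      CUL3_variant = add_event(s, "CUL3", "pathway_variant", sample(nonsyn, 1L)),
      CUL3_deep_deletion = { cnv["CUL3", s] <- -2L
                             add_event(s, "CUL3", "deep_deletion") },
      NFE2L2_missense = add_event(s, "NFE2L2", "pathway_variant", "Missense_Mutation"),
      NFE2L2_amplification = { cnv["NFE2L2", s] <- 2L
                               add_event(s, "NFE2L2", "amplification") }
    )
  }
  for (su in names(subunit_mutants)) {
    for (s in subunit_mutants[[su]]) {
      add_event(s, su, "subunit_variant", sample(nonsyn, 1L))
    }
  }
  panel <- names(spec$subunit_configs)
  for (s in samples) {
    if (stats::runif(1L) < spec$confounder_rate) {
      open <- setdiff(panel, names(which(vapply(subunit_mutants,
                                                function(m) s %in% m, logical(1L)))))
      if (length(open)) {
        add_event(s, sample(open, 1L), "confounder_variant", sample(nonsyn, 1L))
      }
    }
    # silent passenger so the MAF mentions every sample barcode
    add_event(s, sample(bg_genes, 1L), "silent_passenger", "Silent")
  }
  # shallow copy-number noise that must never count as evidence
  for (g in real_genes) {
    hit <- stats::runif(spec$n_samples) < spec$shallow_cnv_rate
    hit <- hit & cnv[g, ] == 0L
    cnv[g, hit] <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
  }

  events <- do.call(rbind, ev)
  variants <- events[!is.na(events$variant_class),
                     c("gene", "sample", "variant_class")]
  rownames(variants) <- NULL

  bundle <- harmonize_samples(counts, variants, cnv,
                              barcode_policy = "exact",
                              cohort_name = cohort_name)
  truth <- structure(list(
    active_samples = active,
    signature_genes = effects,
    subunit_mutants = subunit_mutants,
    events = events,
    libsize = stats::setNames(libsize, samples),
    seed = seed
  ), class = "planted_truth")
  list(bundle = bundle, truth = truth)
}

# joint P(mutant & active) for given marginals and odds ratio (Plackett)
solve_joint_prob <- function(a, m, or) {
  if (a <= 0 || m <= 0) return(0)
  if (abs(or - 1) < 1e-12) return(a * m)
  B <- or * (a + m) + (1 - a - m)
  disc <- B^2 - 4 * (or - 1) * or * a * m
  p11 <- (B - sqrt(disc)) / (2 * (or - 1))
  min(max(p11, max(0, a + m - 1)), min(a, m))
}

#' Simulate several cohorts sharing a planted signature core
#'
#' Emulates a multi-cohort design (e.g., head-neck plus two lung cohorts):
#' all cohorts share exactly \code{shared_core} planted signature genes;
#' the remaining planted genes are cohort-private and pairwise disjoint.
#' Per-cohort seeds are derived deterministically from the master seed.
#'
#' @param spec A \code{\link{simulation_spec}}; \code{spec$seed} is the
#'   master seed.
#' @param n_cohorts Number of cohorts (>= 2).
#' @param shared_core Number of signature genes common to all cohorts
#'   (<= \code{spec$n_signature_genes}).
#' @return Named list of \code{list(bundle, truth)} as from
#'   \code{\link{simulate_cohort}}, plus attribute \code{"core_genes"}.
#' @export
simulate_multi_cohort <- function(spec, n_cohorts = 3L, shared_core = 100L) {
  validate_simulation_spec(spec)
  n_cohorts <- as.integer(n_cohorts)
  if (n_cohorts < 2L) stop("n_cohorts must be at least 2")
  if (shared_core > spec$n_signature_genes) {
    stop("shared_core cannot exceed n_signature_genes")
  }
  n_private <- spec$n_signature_genes - shared_core
  real_genes <- c(nrf2_pathway_genes(), names(spec$subunit_configs))
  bg_genes <- sprintf("SYNG%06d", seq_len(spec$n_genes - length(real_genes)))
  if (shared_core + n_cohorts * n_private > length(bg_genes)) {
    stop("not enough background genes for disjoint private signature sets")
  }
  set.seed(spec$seed)
  pool <- sample(bg_genes, shared_core + n_cohorts * n_private)
  core <- sort(pool[seq_len(shared_core)])
  rest <- pool[-seq_len(shared_core)]
  out <- vector("list", n_cohorts)
  names(out) <- paste0("COHORT_", LETTERS[seq_len(n_cohorts)])
  for (i in seq_len(n_cohorts)) {
    private <- if (n_private > 0) {
      rest[((i - 1L) * n_private + 1L):(i * n_private)]
    } else character(0)
    sig <- sort(c(core, private))
    cohort_seed <- (spec$seed + i * 7919L) %% .Machine$integer.max
    out[[i]] <- simulate_cohort(spec, cohort_name = names(out)[i],
                                signature_genes = sig, seed = cohort_seed)
    out[[i]]$truth$private_genes <- sort(private)
    out[[i]]$truth$core_genes <- core
  }
  attr(out, "core_genes") <- core
  out
}

#' Synthetic NRF2 signature collection
#'
#' Builds a five-set collection of NRF2 activity signatures from the planted
#' truth, standing in for the published signature panel the screen assays:
#' the full planted set plus four random subsets of it.
#'
#' @param truth A \code{planted_truth}.
#' @param subset_sizes Sizes of the four subset signatures.
#' @param seed Seed for subset sampling.
#' @return Named list of gene-symbol vectors suitable for
#'   \code{\link{write_gmt}} and \code{\link{gsea_batch}}.
#' @export
synthetic_nrf2_collection <- function(truth,
                                      subset_sizes = c(60L, 50L, 40L, 30L),
                                      seed = 1L) {
  genes <- names(truth$signature_genes)
  stopifnot(length(genes) >= max(subset_sizes))
  set.seed(seed)
  sets <- c(list(genes),
            lapply(subset_sizes, function(k) sort(sample(genes, k))))
  names(sets) <- c("NRF2_SYN_FULL", paste0("NRF2_SYN_SUB", seq_along(subset_sizes)))
  sets
}

#' Write a simulated cohort to disk in the pipeline's input dialects
#'
#' Emits counts.tsv (genes x samples), variants.maf (MAF-like TSV),
#' gistic.tsv (one metadata column) and truth.json into \code{dir}.
#'
#' @param sim Result of \code{\link{simulate_cohort}}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  b <- sim$bundle
  cdf <- data.frame(gene = rownames(b$counts), b$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  maf <- data.frame(Hugo_Symbol = b$variants$gene,
                    Tumor_Sample_Barcode = b$variants$sample,
                    Variant_Classification = b$variants$variant_class,
                    stringsAsFactors = FALSE)
  utils::write.table(maf, file.path(dir, "variants.maf"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gdf <- data.frame(`Gene Symbol` = rownames(b$cnv), b$cnv,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(gdf, file.path(dir, "gistic.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  jsonlite::write_json(list(
    active_samples = truth$active_samples,
    signature_genes = as.list(truth$signature_genes),
    subunit_mutants = truth$subunit_mutants,
    events = truth$events,
    seed = truth$seed
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir Directory containing counts.tsv, variants.maf, gistic.tsv.
#' @param cohort_name Label for the bundle (defaults to the directory name).
#' @return A \code{cohort_bundle}.
#' @export
read_cohort <- function(dir, cohort_name = basename(dir)) {
  counts <- read_counts(file.path(dir, "counts.tsv"))
  variants <- read_variants_maf(file.path(dir, "variants.maf"))
  cnv <- read_gistic(file.path(dir, "gistic.tsv"))
  harmonize_samples(counts, variants, cnv, barcode_policy = "exact",
                    cohort_name = cohort_name)
}
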