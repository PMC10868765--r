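---
title: "Linking SWI/SNF subunit mutations to NRF2 pathway activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking SWI/SNF subunit mutations to NRF2 pathway activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrf2screen)
```

## The question and the pipeline

NRF2 (encoded by *NFE2L2*) drives antioxidant and cytoprotective
transcription. It is held in check by the KEAP1–CUL3 ubiquitin-ligase
complex; tumors activate it either by stabilizing mutations in *NFE2L2*
itself or by loss of *KEAP1*/*CUL3*. SWI/SNF chromatin-remodeling
subunits — *ARID1A* and *ARID1B* (mutually exclusive BAF subunits),
*ARID2* and *PBRM1* (PBAF) — are recurrently mutated in many of the same
tumor types. `nrf2screen` implements, end to end, an analysis that asks
whether SWI/SNF subunit mutations are associated with NRF2 transcriptional
output:

1. **Alteration calling** from somatic variants and discretized copy
   number, with confound-filtered mutant vs wild-type group construction.
2. **Expression preprocessing**: low-expression filtering, TMM
   normalization, log2-CPM, and moderated-t differential expression.
3. **Signature derivation**: a nearest-centroid NRF2-activity classifier
   trained on mutation-defined preliminary labels, refined by
   high-confidence sample filtering, applied per cohort, and intersected
   across cohorts into a 100-gene activity signature.
4. **GSEA** with signal-to-noise ranking, a gene-permutation null,
   normalized enrichment scores and BH FDR.
5. **Co-occurrence statistics** (two-proportion z-test across cohort
   strata).

Because the real inputs are consortium-scale tumor downloads, every stage
is validated instead on synthetic cohorts with planted ground truth
(`simulate_cohort()`), generated in exactly the file dialects the readers
consume.

## Alteration semantics

Copy-number evidence uses the discretized five-level calls: only −2 (deep
deletion) and +2 (amplification) ever count; shallow ±1 events never do.
Nonsynonymous variant classes default to missense, nonsense and the two
frameshift classes; splice-site and in-frame events are excluded unless
configured otherwise, since the underlying class vocabulary of the source
pipelines is not fully standardized.

Two predicates coexist deliberately. The *polarity-blind* screen
(`call_any_alteration()`) counts any qualifying event in a panel and is
used for complex-level alteration frequencies. The *polarity-aware*
activity rule (`call_nrf2_active()`) encodes the biology of the pathway:
deep deletion or nonsynonymous mutation of *KEAP1*/*CUL3* is activating,
but for *NFE2L2* only amplification or missense mutation counts — deleting
or truncating the oncogene itself does not stabilize it. The two are never
mixed implicitly; group construction for expression comparisons always
uses the polarity-aware rule.

Group construction for a gene of interest removes confounded samples: a
mutant must carry no alteration in any other panel subunit and no NRF2
pathway activation; a control carries neither. Mutant groups smaller than
`min_group_size` (default 5) are flagged rather than analyzed, since
undersized groups produce unstable signal-to-noise rankings.

## Signature derivation choices

The derivation recipe per cohort: preliminary active/inactive labels from
mutational status → moderated-t differential expression → classifier panel
of the top 100 genes by p-value (either direction) → per-gene
z-standardized centroids → high-confidence filtering → refit on the
retained samples. Cross-cohort, a candidate must be significantly up in
the active class (BH p < 0.05, a conventional choice) in *every* cohort,
and candidates are ranked by their *worst* per-cohort adjusted p before
taking the top 100 — a gene enters only on consistent evidence.

Two numerical decisions deserve emphasis:

* **The confidence radius.** The derivation procedure's source describes
  removing samples "more than 0.25% of the inter-centroid distance" from
  their centroid. Read literally (τ = 0.0025) this empties any cohort with
  realistic within-class spread. We therefore (a) measure the distance
  *along the inter-centroid axis* (the projection), which removes the
  curse-of-dimensionality inflation of full Euclidean distance in
  100-gene space, and (b) default to τ = 0.25, treating the published
  figure as a probable percent/fraction slip. Both the literal and the
  default value are plain parameters (`derivation_config(tau = ...)`), and
  the τ = 0.0025 path is exercised in tests (it triggers the advisory
  error).
* **Tie-breaking.** A sample exactly equidistant from both centroids is
  assigned *inactive* — the conservative direction, since the active class
  is the discovery class. Ranked-list ties break lexicographically on the
  gene symbol so every ordering is deterministic.

One filtering round is the default (`n_iter = 1`): the procedure is
described as remove-then-refit; iterating is supported but the first round
removes nearly all removable samples on realistic data.

Cross-validation (`cross_validate()`) repeats the *entire* derivation —
differential expression, panel selection, centroid fit, confidence
filtering — inside each training fold. Selecting the panel on the full
data before splitting leaks label information and inflates accuracy on
null data; the leakage-free path is the only one offered.

## Differential expression

Moderated t-statistics are computed on normalized log2-CPM directly
(trend-free), with the prior (d~0~, s~0~²) fitted to the gene-wise variance
distribution by the standard scaled-F moment fit. Precision weights for
the count-level mean–variance trend are *not* applied: downstream
consumers are p-value ranks and top-k sets, which are insensitive to this
refinement, and the `d0_policy` argument exposes the two limit cases
(d~0~ = 0, ordinary pooled t; d~0~ = ∞, fully pooled variance) that anchor
the tests. Proteomic matrices skip count preprocessing and are
median-centered per sample before the same moderated comparison.

log2-CPM uses `(count + 0.5) / (libsize * factor + 1) * 1e6`; the 0.5
prior bounds the deviation under pure depth changes at about
`0.5 / ((c + 0.5) ln 2)` for a gene with count c — about 0.035 at c = 10 —
which is the bound the tests assert.

## GSEA engine

Genes are ranked by the signal-to-noise ratio with the classic floor on
each group standard deviation (0.2·|mean|, or 0.2 at mean zero).
Enrichment uses the weighted running-sum statistic (weight exponent 1 by
default; 0 recovers the unweighted KS statistic). When the maximal
positive and negative deviations tie in magnitude to within floating-point
noise, the positive one is reported.

The null is a *gene-permutation* null: random same-size sets from the
ranked universe. Phenotype permutation would require rerunning the
differential model per permutation and is out of scope. Each set's null is
seeded deterministically from the base seed, the set size, and a hash of
the set's membership — duplicate sets are byte-identical, distinct sets
have independent nulls. (An earlier shared-null-per-size design was
rejected because it correlates p-values across sets; the suite's
uniformity calibration detects exactly that.) p-values use the +1
permutation correction and are conditioned on same-sign nulls, so the
attainable floor is 1/(1 + n same-sign nulls), roughly 2/n_perm for a
balanced null; NES divides ES by the mean |ES| of same-sign nulls. If no
same-sign null exists the set is flagged with a missing NES rather than
failing. Defaults (1,000 permutations in the bundled analyses, weight 1,
minimum post-intersection set size 5) follow the conventions of the
surrounding tooling; none are stated by the source analysis.

## What the simulator plants — and what it does not

`simulate_cohort()` draws counts from a negative binomial with mean
`libsize_s · 2^(baseline_g + active_s · effect_g + subunit effects)` and a
common dispersion (0.2 by default; per-gene dispersion is deliberately not
modeled). Planted structure:

* a designated NRF2-active fraction (default 30%, typical of
  NRF2-activated squamous cohorts) whose signature genes (default
  mean log2FC 2, SD 0.5) are upregulated;
* pathway events consistent with the activity labels — each active sample
  receives one event from the activating menu (*KEAP1*/*CUL3*
  nonsynonymous variant, *CUL3* deep deletion, *NFE2L2* missense or
  amplification) — so the mutation-defined preliminary labels recover the
  planted truth exactly;
* per-subunit mutants with a configurable 2×2 odds ratio of co-occurrence
  with the active state, and a *direct* expression effect on the signature
  genes (polarity ±1 and magnitude in log2 units);
* passenger "confounder" variants in other panel subunits (never in
  pathway genes, so labels stay truthful) and shallow ±1 copy-number noise
  that must never count as evidence;
* a silent passenger variant in every sample, so the variant table covers
  the cohort the way a real somatic MAF does.

The default subunit configuration plants the pattern the screen is built
to detect: *ARID1A* co-occurs with NRF2 activity (odds ratio 6) and pushes
signature genes up (+1 log2); *ARID1B* pushes them down; *ARID2* and
*PBRM1* are neutral controls. Note that co-occurrence alone cannot produce
enrichment in the screen's mutant group: active samples carry pathway
events and are therefore excluded as confounded, by design. The
directional readout rests on the direct polarity effect — the simulator
separates "travels with NRF2 activation" from "shifts NRF2 output," and
the screen only sees the latter. This is why the screen analyses use an
HNSC-scale cohort (500 samples, chosen to match the real cohort's order of
magnitude): with a 12% mutation rate and strong co-occurrence, the
confound-filtered *ARID1A* mutant group of a 120-sample cohort would fall
below the group-size guard.

Not modeled: mutation signatures, copy-number segment structure, tumor
purity, batch effects, library-preparation artifacts, HPV status, or any
realistic gene–gene correlation beyond the planted effects. Passing tests
therefore demonstrate that the pipeline recovers structure *of the kind it
assumes*; they cannot certify behavior under real-data pathologies such as
purity-driven global shifts.

## Problem sizes and defaults in the bundled analyses

The shipped analyses and validation suite use three derivation cohorts of
2,000 genes × 120 samples, one screen cohort of 500 samples, 1,000
permutations per gene set, and 5-fold cross-validation — sizes at which
every planted effect is comfortably detectable and the full run finishes
in well under a minute on a laptop. The statistical machinery is
size-agnostic; consortium-scale matrices simply take longer.

## Reproducing the analysis

```{r, eval = FALSE}
# from the repository root
# Rscript analysis/01_simulate_cohorts.R --seed 1
# Rscript analysis/02_alteration_landscape.R --seed 1
# Rscript analysis/03_derive_signature.R --seed 1
# Rscript analysis/04_gsea_screen.R --seed 1
# Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

A compact in-session version of the screen:

```{r, eval = FALSE}
sim <- simulate_cohort(simulation_spec(n_samples = 500L, seed = 1L),
                       cohort_name = "SCREEN")
coll <- synthetic_nrf2_collection(sim$truth)
res <- run_screen(list(sim$bundle),
                  screen_config(collections = list(nrf2 = coll),
                                n_perm = 1000L, seed = 1L))
heatmap_table(res, "nrf2")
```

## Known limitations

* The variance-moderated comparison omits count-level precision weights;
  at very small group sizes with highly variable library sizes this can
  reorder borderline genes.
* The permutation p floor (about 2/n_perm) limits how small multiple-test
  adjusted values can get for small collections; raise `n_perm` when exact
  tail behavior matters.
* The confound filter treats any nonsynonymous variant in a panel gene as
  disqualifying; it does not weigh variant impact, matching the
  all-mutations-count assumption of the upstream analysis.
* Sample-identifier harmonization supports only truncation-based barcode
  matching; cross-platform aliasing is out of scope.
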