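#' Read a gene-by-sample count matrix from TSV
#'
#' Reads per-gene quantified read counts as distributed by TCGA-style
#' pipelines: a tab-delimited table with one identifier column (or row,
#' depending on orientation).  Duplicate gene symbols -- typically the result
#' of multi-transcript collapse -- are combined according to \code{dup_policy}.
#' Fractional values (some quantifiers emit expected counts) are rounded
#' half-to-even with a warning so downstream normalization stays well-defined
#' on integers.
#'
#' @param path Path to a TSV file.
#' @param orientation \code{"genes_rows"} (default) or \code{"genes_cols"}.
#' @param dup_policy How to collapse duplicated gene symbols: \code{"sum"}
#'   (default), \code{"max"} or \code{"first"}.
#' @return Integer matrix, genes x samples, with unique dimnames.
#' @export
read_counts <- function(path, orientation = c("genes_rows", "genes_cols"),
                        dup_policy = c("sum", "max", "first")) {
  orientation <- match.arg(orientation)
  dup_policy <- match.arg(dup_policy)
  tab <- read_tsv_table(path)
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    stop("count file '", path, "' is empty or has no sample columns")
  }
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  bad <- which(!is.finite(suppressWarnings(as.numeric(mat))) | is.na(mat))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(mat))
    stop("non-numeric count at row ", rc[1L], " ('", ids[rc[1L]],
         "'), column '", colnames(mat)[rc[2L]], "' in '", path, "'")
  }
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "genes_cols") mat <- t(mat)
  neg <- which(mat < 0)
  if (length(neg)) {
    rc <- arrayInd(neg[1L], dim(mat))
    stop("negative count for gene '", rownames(mat)[rc[1L]], "', sample '",
         colnames(mat)[rc[2L]], "' in '", path, "'")
  }
  if (any(mat != floor(mat))) {
    warning("fractional counts in '", path, "' rounded half-to-even")
    mat <- round(mat)
  }
  mat <- collapse_duplicate_genes(mat, dup_policy)
  if (anyDuplicated(colnames(mat))) {
    stop("duplicate sample identifiers in '", path, "'")
  }
  storage.mode(mat) <- "integer"
  mat
}

collapse_duplicate_genes <- function(mat, dup_policy) {
  if (!anyDuplicated(rownames(mat))) return(mat)
  warning("duplicate gene symbols collapsed by '", dup_policy, "'")
  g <- factor(rownames(mat), levels = unique(rownames(mat)))
  out <- switch(dup_policy,
    sum = rowsum(mat, g, reorder = FALSE),
    max = do.call(rbind, lapply(split.data.frame(mat, g), function(x) {
      apply(x, 2L, max)
    })),
    first = mat[!duplicated(rownames(mat)), , drop = FALSE]
  )
  rownames(out) <- levels(g)
  out
}

#' Read somatic variant calls from a MAF-like table
#'
#' Expects a tab-delimited file with at least a gene-symbol, sample-barcode
#' and variant-classification column (standard MAF headers by default;
#' \code{column_map} renames).  Comment lines starting with '#' are skipped.
#' No class filtering is applied here: silent and unknown classes are
#' retained (unknown classes flagged with a warning) and filtered downstream
#' by the alteration-calling rules.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping the canonical names
#'   \code{gene}, \code{sample}, \code{variant_class} to the file's columns.
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{variant_class} (all character).
#' @export
read_variants_maf <- function(path,
                              column_map = c(gene = "Hugo_Symbol",
                                             sample = "Tumor_Sample_Barcode",
                                             variant_class = "Variant_Classification")) {
  req <- c("gene", "sample", "variant_class")
  if (!all(req %in% names(column_map))) {
    stop("column_map must name: ", paste(req, collapse = ", "))
  }
  tab <- read_tsv_table(path, comment.char = "#")
  missing_cols <- setdiff(unname(column_map[req]), colnames(tab))
  if (length(missing_cols)) {
    stop("MAF file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(gene = as.character(tab[[column_map[["gene"]]]]),
                    sample = as.character(tab[[column_map[["sample"]]]]),
                    variant_class = as.character(tab[[column_map[["variant_class"]]]]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) warning("MAF file '", path, "' contains no records")
  unknown <- setdiff(unique(out$variant_class), variant_class_vocabulary())
  if (length(unknown)) {
    warning("variant classes outside the known vocabulary retained: ",
            paste(unknown, collapse = ", "))
  }
  out
}

#' Known MAF variant-classification vocabulary
#' @return Character vector of recognized classification strings.
#' @export
variant_class_vocabulary <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site", "Silent", "Intron",
    "3'UTR", "5'UTR", "3'Flank", "5'Flank", "RNA", "IGR",
    "Targeted_Region")
}

#' Read a discretized Gistic2 copy-number matrix
#'
#' Gistic emits per-gene integer calls in -2..+2 (-2 deep deletion, -1
#' shallow deletion, 0 neutral, +1 gain, +2 amplification).  Two common
#' dialects are supported: a single gene-symbol column, or three leading
#' metadata columns (gene symbol / locus id / cytoband).
#'
#' @param path Path to the TSV.
#' @param dialect \code{"auto"} (default; detected from the header),
#'   \code{"one_col"} or \code{"three_col"}.
#' @return Integer matrix, genes x samples, values in -2..+2.
#' @export
read_gistic <- function(path, dialect = c("auto", "one_col", "three_col")) {
  dialect <- match.arg(dialect)
  tab <- read_tsv_table(path)
  if (nrow(tab) == 0L) stop("Gistic file '", path, "' is empty")
  if (dialect == "auto") {
    meta_names <- tolower(colnames(tab)[seq_len(min(3L, ncol(tab)))])
    dialect <- if (length(meta_names) >= 3L &&
                   any(grepl("locus|cytoband", meta_names[2:3]))) {
      "three_col"
    } else "one_col"
  }
  n_meta <- if (dialect == "three_col") 3L else 1L
  if (ncol(tab) <= n_meta) stop("Gistic file '", path, "' has no sample columns")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -seq_len(n_meta), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  bad <- which(is.na(mat) | !(mat %in% c(-2, -1, 0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(mat))
    stop("Gistic score outside {-2..+2} for gene '", rownames(mat)[rc[1L]],
         "', sample '", colnames(mat)[rc[2L]], "' in '", path, "'")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate gene symbols in '", path, "'")
  storage.mode(mat) <- "integer"
  mat
}

#' Read a GMT gene-set collection
#'
#' Standard MSigDB format: one set per line, tab-delimited as
#' name, description, gene, gene, ...  Duplicate genes within a set are
#' removed with a warning; order is preserved.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors; each element carries its
#'   description in the \code{"description"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("GMT file '", path, "' is empty")
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " in '", path, "' has fewer than 3 fields")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicated gene(s) in set '", fields[1L], "' removed")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("GMT set '", fields[1L], "' is empty")
    attr(genes, "description") <- fields[2L]
    sets[[i]] <- genes
    nms[i] <- fields[1L]
  }
  if (anyDuplicated(nms)) stop("duplicate set names in '", path, "'")
  names(sets) <- nms
  sets
}

#' Write a gene-set collection as GMT
#'
#' Inverse of \code{\link{read_gmt}}: \code{read_gmt(write_gmt(x, p))} is the
#' identity on well-formed collections.
#'
#' @param collection Named list of character vectors (optionally with a
#'   \code{"description"} attribute per set).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.list(collection), length(collection) > 0,
            !is.null(names(collection)))
  lines <- vapply(names(collection), function(nm) {
    genes <- collection[[nm]]
    desc <- attr(genes, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(genes)), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Harmonize sample identifiers across expression, variant and CNV sources
#'
#' TCGA aliquot barcodes carry trailing portion/analyte fields, so variant
#' barcodes are typically longer than expression barcodes.  Under the
#' default policy identifiers that look like TCGA barcodes are truncated to
#' the 15-character sample barcode before intersecting; otherwise exact
#' matching is used.  All three sources are subset and reordered to the
#' shared samples.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param variants Variant data.frame from \code{\link{read_variants_maf}}.
#' @param cnv Integer Gistic matrix (genes x samples).
#' @param barcode_policy \code{"auto"} (default: truncate to 15 characters
#'   when identifiers look like TCGA barcodes), \code{"tcga15"},
#'   \code{"exact"}, or an integer truncation length.
#' @param cohort_name Label stored in the bundle.
#' @return A \code{cohort_bundle}: list with \code{cohort_name},
#'   \code{counts}, \code{variants}, \code{cnv}, \code{shared_samples}.
#' @export
harmonize_samples <- function(counts, variants, cnv,
                              barcode_policy = "auto",
                              cohort_name = "cohort") {
  trunc_len <- resolve_barcode_policy(barcode_policy,
                                      c(colnames(counts), variants$sample,
                                        colnames(cnv)))
  norm_id <- function(x) {
    if (is.na(trunc_len)) x else substr(x, 1L, trunc_len)
  }
  colnames(counts) <- norm_id(colnames(counts))
  colnames(cnv) <- norm_id(colnames(cnv))
  variants$sample <- norm_id(variants$sample)
  shared <- intersect(intersect(colnames(counts), colnames(cnv)),
                      unique(variants$sample))
  if (!length(shared)) {
    stop("no samples shared across counts, variants and CNV after ",
         "barcode normalization")
  }
  dropped_counts <- ncol(counts) - length(shared)
  dropped_cnv <- ncol(cnv) - length(shared)
  dropped_var <- length(setdiff(unique(variants$sample), shared))
  if (dropped_counts + dropped_cnv + dropped_var > 0) {
    message("harmonize_samples: dropped ", dropped_counts, " count, ",
            dropped_cnv, " CNV sample(s); ", dropped_var,
            " variant barcode(s) outside the shared set")
  }
  structure(list(
    cohort_name = cohort_name,
    counts = counts[, shared, drop = FALSE],
    variants = variants[variants$sample %in% shared, , drop = FALSE],
    cnv = cnv[, shared, drop = FALSE],
    shared_samples = shared
  ), class = "cohort_bundle")
}

resolve_barcode_policy <- function(policy, ids) {
  if (is.numeric(policy)) return(as.integer(policy))
  switch(as.character(policy),
    exact = NA_integer_,
    tcga15 = 15L,
    auto = {
      looks_tcga <- mean(grepl("^TCGA-", ids)) > 0.5
      if (looks_tcga) 15L else NA_integer_
    },
    stop("unknown barcode_policy: ", policy)
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle '", x$cohort_name, "': ",
      nrow(x$counts), " genes x ", length(x$shared_samples), " samples, ",
      nrow(x$variants), " variant records, ",
      nrow(x$cnv), " CNV genes\n", sep = "")
  invisible(x)
}

read_tsv_table <- function(path, comment.char = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    check.names = FALSE, comment.char = comment.char,
                    stringsAsFactors = FALSE)
}
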