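# Cohort input/output and methylation QC.
#
# On-disk conventions: matrices are tab-delimited, oriented site/gene x
# sample with the first column holding the identifier and "NA" denoting
# missing; MAF-like mutation files carry at least (sample, gene,
# variant_class) columns; gene lists are one symbol per line; promoter maps
# are BED-like (chrom, start, end, gene, site_id; strand ignored).

#' Construct a cohort bundle
#'
#' A cohort bundle holds one tumor type's aligned multi-omics matrices:
#' a binary somatic mutation matrix (samples x genes), a CpG methylation
#' beta-value matrix (sites x samples, values in \[0,1\], missing allowed)
#' and a non-negative expression matrix (genes x samples). Sample IDs need
#' not be identical across modalities: samples shared between mutation and
#' methylation define the methylation-analysis set, and samples shared
#' between mutation and expression define the expression-analysis set.
#'
#' @param cohort_id tumor-type label.
#' @param mutation samples x genes matrix of 0/1 calls.
#' @param methylation sites x samples numeric matrix in \[0,1\] (NA allowed).
#' @param expression genes x samples non-negative numeric matrix.
#' @return an object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(cohort_id, mutation, methylation = NULL, expression = NULL) {
  stopifnot(is.character(cohort_id), length(cohort_id) == 1L)
  if (!is.matrix(mutation) || is.null(rownames(mutation)) || is.null(colnames(mutation)))
    stopf("cohort '%s': mutation must be a samples x genes matrix with dimnames", cohort_id)
  if (anyDuplicated(colnames(mutation)))
    stopf("cohort '%s': duplicate gene identifiers in mutation matrix", cohort_id)
  bad <- !(mutation %in% c(0, 1))
  if (any(bad))
    stopf("cohort '%s': mutation matrix must be binary 0/1", cohort_id)
  if (!is.null(methylation)) {
    if (!is.matrix(methylation) || is.null(rownames(methylation)))
      stopf("cohort '%s': methylation must be a sites x samples matrix", cohort_id)
    if (anyDuplicated(rownames(methylation)))
      stopf("cohort '%s': duplicate site identifiers", cohort_id)
    rng <- range(methylation, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stopf("cohort '%s': beta values outside [0,1] (range %.4g..%.4g)",
            cohort_id, rng[1], rng[2])
    if (!length(intersect(rownames(mutation), colnames(methylation))))
      stopf("cohort '%s': no samples shared between mutation and methylation data", cohort_id)
  }
  if (!is.null(expression)) {
    if (!is.matrix(expression) || is.null(rownames(expression)))
      stopf("cohort '%s': expression must be a genes x samples matrix", cohort_id)
    if (anyDuplicated(rownames(expression)))
      stopf("cohort '%s': duplicate gene identifiers in expression matrix", cohort_id)
    if (min(expression, na.rm = TRUE) < 0)
      stopf("cohort '%s': expression values must be non-negative", cohort_id)
    if (!length(intersect(rownames(mutation), colnames(expression))))
      stopf("cohort '%s': no samples shared between mutation and expression data", cohort_id)
  }
  structure(list(cohort_id = cohort_id, mutation = mutation,
                 methylation = methylation, expression = expression),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle '%s': %d samples x %d genes mutated", x$cohort_id,
              nrow(x$mutation), ncol(x$mutation)))
  if (!is.null(x$methylation))
    cat(sprintf("; %d CpG sites x %d samples", nrow(x$methylation), ncol(x$methylation)))
  if (!is.null(x$expression))
    cat(sprintf("; %d expr genes x %d samples", nrow(x$expression), ncol(x$expression)))
  cat("\n")
  invisible(x)
}

# Samples usable for a modality (mutation calls plus modality data).
modality_samples <- function(bundle, modality = c("methylation", "expression")) {
  modality <- match.arg(modality)
  m <- bundle[[modality]]
  if (is.null(m)) return(character())
  intersect(rownames(bundle$mutation), colnames(m))
}

.read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Collapse MAF-like mutation records to a binary matrix
#'
#' A gene is considered mutated in a sample as soon as any mutation record
#' for that gene/sample pair exists, regardless of variant class or
#' multiplicity.
#'
#' @param maf data frame with at least columns `sample` and `gene`
#'   (a `variant_class` column, if present, is ignored for the call).
#' @param samples,genes optional identifier universes fixing matrix
#'   dimensions; defaults to the identifiers observed in `maf`.
#' @return samples x genes 0/1 matrix.
#' @export
collapse_maf <- function(maf, samples = NULL, genes = NULL) {
  if (!all(c("sample", "gene") %in% names(maf)))
    stopf("MAF-like input needs 'sample' and 'gene' columns")
  samples <- samples %||% sort(unique(as.character(maf$sample)))
  genes <- genes %||% sort(unique(as.character(maf$gene)))
  m <- matrix(0L, length(samples), length(genes), dimnames = list(samples, genes))
  i <- match(as.character(maf$sample), samples)
  j <- match(as.character(maf$gene), genes)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- 1L
  m
}

#' Load one cohort from disk
#'
#' Reads the mutation, methylation and expression files for one tumor type
#' and returns a validated [cohort_bundle()]. The mutation file may either
#' be a gene x sample 0/1 matrix or a MAF-like record table with `sample`
#' and `gene` columns; the latter is collapsed with [collapse_maf()].
#'
#' @param cohort_id tumor-type label.
#' @param mutation_file,methylation_file,expression_file file paths;
#'   methylation/expression may be `NULL` for single-modality use.
#' @param mutation_format `"auto"` (default), `"matrix"` or `"maf"`.
#' @return a [cohort_bundle()].
#' @export
load_cohort <- function(cohort_id, mutation_file, methylation_file = NULL,
                        expression_file = NULL,
                        mutation_format = c("auto", "matrix", "maf")) {
  mutation_format <- match.arg(mutation_format)
  if (!file.exists(mutation_file)) stopf("file not found: %s", mutation_file)
  hdr <- names(data.table::fread(mutation_file, sep = "\t", nrows = 0L))
  is_maf <- switch(mutation_format,
                   maf = TRUE, matrix = FALSE,
                   auto = all(c("sample", "gene") %in% hdr))
  mut <- if (is_maf) {
    collapse_maf(data.table::fread(mutation_file, sep = "\t", data.table = FALSE))
  } else {
    m <- .read_matrix_tsv(mutation_file)  # genes x samples on disk
    storage.mode(m) <- "integer"
    t(m)
  }
  meth <- if (!is.null(methylation_file)) .read_matrix_tsv(methylation_file)
  expr <- if (!is.null(expression_file)) .read_matrix_tsv(expression_file)
  cohort_bundle(cohort_id, mut, meth, expr)
}

#' Write a cohort bundle to disk
#'
#' Inverse of [load_cohort()]: writes `mutation.tsv` (gene x sample 0/1),
#' `methylation.tsv` and `expression.tsv` under `dir`.
#'
#' @param bundle a [cohort_bundle()].
#' @param dir output directory (created if absent).
#' @return invisibly, the files written.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_matrix <- function(m, id_col, path) {
    df <- data.table::data.table(id = rownames(m))
    data.table::setnames(df, "id", id_col)
    data.table::fwrite(cbind(df, data.table::as.data.table(m)), path,
                       sep = "\t", na = "NA", quote = FALSE)
    path
  }
  files <- .write_matrix(t(bundle$mutation), "gene", file.path(dir, "mutation.tsv"))
  if (!is.null(bundle$methylation))
    files <- c(files, .write_matrix(bundle$methylation, "site_id",
                                    file.path(dir, "methylation.tsv")))
  if (!is.null(bundle$expression))
    files <- c(files, .write_matrix(bundle$expression, "gene",
                                    file.path(dir, "expression.tsv")))
  invisible(files)
}

#' Methylation quality-control filter
#'
#' Drops CpG sites on an exclusion list (e.g. SNP-overlapping or
#' sex-chromosome sites) and sites whose missing fraction strictly exceeds
#' `max_missing` (default 5% of the cohort's methylation samples; a site
#' missing in exactly 5% of samples is kept). Missingness is computed over
#' all methylation samples of the cohort. The two filters commute.
#'
#' @param bundle a [cohort_bundle()].
#' @param exclude_sites character vector of site IDs to drop.
#' @param max_missing maximal tolerated missing fraction per site.
#' @return the filtered bundle, with a `qc_report` attribute (list with
#'   `n_sites_in`, `n_excluded`, `n_high_missing`, `n_removed`, `n_kept`).
#' @export
qc_filter_methylation <- function(bundle, exclude_sites = character(),
                                  max_missing = 0.05) {
  stopifnot(inherits(bundle, "cohort_bundle"), !is.null(bundle$methylation),
            max_missing >= 0, max_missing <= 1)
  meth <- bundle$methylation
  excl <- rownames(meth) %in% exclude_sites
  miss <- rowMeans(is.na(meth)) > max_missing
  keep <- !(excl | miss)
  if (!any(keep)) {
    dominant <- if (sum(excl) >= sum(miss)) "site exclusion list" else
      sprintf("missingness > %g filter", max_missing)
    stopf("cohort '%s': QC removed all %d sites (dominant filter: %s)",
          bundle$cohort_id, nrow(meth), dominant)
  }
  out <- bundle
  out$methylation <- meth[keep, , drop = FALSE]
  attr(out, "qc_report") <- list(n_sites_in = nrow(meth),
                                 n_excluded = sum(excl),
                                 n_high_missing = sum(miss),
                                 n_removed = sum(!keep),
                                 n_kept = sum(keep))
  out
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a BED-like promoter map
#'
#' Expects tab-delimited columns (chrom, start, end, gene, site_id) with no
#' header, mapping each gene to the CpG sites within its promoter window
#' (1,500 bp upstream of the TSS by the package's convention); strand is
#' ignored.
#'
#' @param path file path.
#' @return data frame with columns gene, site_id, chrom, start, end.
#' @export
read_promoter_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(dt) < 5L) stopf("promoter map needs >= 5 columns (chrom,start,end,gene,site_id)")
  names(dt)[1:5] <- c("chrom", "start", "end", "gene", "site_id")
  dt[, c("gene", "site_id", "chrom", "start", "end")]
}

#' Write result tables
#'
#' Writes every data frame in `tables` as `<name>.tsv` under `outdir`.
#' Numeric values are written at full double precision so a written table
#' re-read with [data.table::fread()] reproduces the values. Empty tables
#' produce header-only files. p-value columns produced by the callers carry
#' companion `*_label` columns in which an exact zero is rendered as
#' `"<1/B"` (see [p_floor_label()]).
#'
#' @param tables named list of data frames.
#' @param outdir output directory (created if absent).
#' @return invisibly, the files written.
#' @export
write_results <- function(tables, outdir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    ok <- tryCatch({
      data.table::fwrite(tables[[nm]], path, sep = "\t", na = "NA",
                         quote = FALSE)
      TRUE
    }, error = function(e) stopf("failed writing %s: %s", path, conditionMessage(e)))
    files <- c(files, path)
  }
  invisible(files)
}
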