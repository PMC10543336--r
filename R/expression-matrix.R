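#' Construct a gene-by-sample expression matrix
#'
#' The central container of the package: a dense, non-negative TPM matrix
#' (genes in rows, samples in columns) together with a per-sample metadata
#' tibble. All downstream steps (staging, specificity, module detection,
#' guide networks) consume this object.
#'
#' @param values Numeric matrix of TPM values, genes x samples, with unique
#'   rownames (gene ids) and colnames (sample ids). All values must be
#'   finite and >= 0; missing values are not allowed.
#' @param samples Optional tibble/data.frame of per-sample metadata with a
#'   `sample_id` column matching `colnames(values)`, and optionally
#'   `tissue` (character), `daf` (integer days after flowering) and
#'   `replicate` (integer) columns. Absent fields are filled with `NA`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `samples` (a tibble with columns `sample_id`,
#'   `tissue`, `daf`, `replicate`).
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' expression_matrix(m)
expression_matrix <- function(values, samples = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have rownames (gene ids) and colnames (sample ids)",
         call. = FALSE)
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) {
    stop("duplicated gene id(s): ", paste(unique(dup_g), collapse = ", "),
         call. = FALSE)
  }
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite or negative expression value for gene '",
         gene_ids[bad[1, 1]], "', sample '", sample_ids[bad[1, 2]], "'",
         call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = sample_ids)
  }
  samples <- tibble::as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    stop("`samples` must contain a sample_id column", call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  missing_meta <- setdiff(sample_ids, samples$sample_id)
  if (length(missing_meta)) {
    stop("sample metadata missing for: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("tissue", "daf", "replicate")) {
    if (!col %in% names(samples)) samples[[col]] <- NA
  }
  samples$tissue <- as.character(samples$tissue)
  samples$daf <- as.integer(samples$daf)
  samples$replicate <- as.integer(samples$replicate)
  # align metadata rows to column order
  samples <- samples[match(sample_ids, samples$sample_id),
                     c("sample_id", "tissue", "daf", "replicate")]
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  n_tis <- dplyr::n_distinct(x$samples$tissue, na.rm = TRUE)
  if (n_tis > 0) cat("  tissues: ", n_tis, sep = "")
  if (any(!is.na(x$samples$daf))) {
    cat("  DAF range: ", min(x$samples$daf, na.rm = TRUE), "-",
        max(x$samples$daf, na.rm = TRUE), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Convert an expression matrix to a long tibble
#'
#' One row per (gene, sample) pair, joined with the sample metadata, ready
#' for dplyr/ggplot2 pipelines.
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `tpm`, `tissue`,
#'   `daf`, `replicate`.
#' @method as_tibble expr_matrix
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    tpm = as.vector(x$values)
  )
  dplyr::left_join(long, x$samples, by = "sample_id")
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and gene
#' ids in the first column (the canonical dense TPM export). An optional
#' metadata TSV keyed by `sample_id` supplies `tissue`, `daf` and
#' `replicate` fields; absent fields are recorded as `NA`.
#'
#' Loading is strict: duplicate ids, non-numeric cells, negative or missing
#' values abort with a message naming the offending row or column, and no
#' row is ever silently dropped.
#'
#' @param path Path to the expression TSV.
#' @param meta_path Optional path to the sample-metadata TSV.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path, meta_path = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tab) < 2) stop("expression TSV needs gene ids plus >= 1 sample column",
                          call. = FALSE)
  gene_ids <- tab[[1]]
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (nrow(tab) == 1) num <- matrix(num, nrow = 1)
  bad_col <- which(colSums(is.na(num) & !is.na(vals)) > 0)
  if (length(bad_col)) {
    j <- bad_col[1]
    i <- which(is.na(num[, j]) & !is.na(vals[, j]))[1]
    stop("non-numeric value '", vals[i, j], "' for gene '", gene_ids[i],
         "', column '", colnames(vals)[j], "'", call. = FALSE)
  }
  rownames(num) <- gene_ids
  colnames(num) <- colnames(vals)
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- readr::read_tsv(meta_path, col_types = readr::cols(), progress = FALSE)
  }
  em <- expression_matrix(num, meta)
  stopifnot(nrow(em$values) == nrow(tab))  # loaders never drop rows
  em
}

#' Write an expression matrix (and its metadata) to TSV
#'
#' @param em An `expr_matrix`.
#' @param path Output path for the expression TSV.
#' @param meta_path Optional output path for the sample-metadata TSV.
#' @return `em`, invisibly.
#' @export
write_expression <- function(em, path, meta_path = NULL) {
  stopifnot(inherits(em, "expr_matrix"))
  tab <- tibble::as_tibble(em$values, rownames = "gene_id")
  readr::write_tsv(tab, path, progress = FALSE)
  if (!is.null(meta_path)) {
    readr::write_tsv(em$samples, meta_path, progress = FALSE)
  }
  invisible(em)
}

#' Apply the log2(TPM + 1) transform
#'
#' The standard variance-stabilizing transform used before PCA, staging and
#' correlation steps; zeros map to zero.
#'
#' @param em An `expr_matrix` of raw TPM values.
#' @return An `expr_matrix` with transformed values.
#' @export
log_transform <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  em$values <- log2(em$values + 1)
  em
}
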