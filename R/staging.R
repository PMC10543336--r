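#' Squared Pearson correlation between replicate pairs
#'
#' Replicate-level quality control: for every time point (tissue, DAF)
#' with at least two replicates, reports the squared Pearson correlation
#' R^2 of every replicate pair, computed on the stored expression values.
#' Pairs below the QC threshold are flagged; a pair involving a
#' zero-variance replicate is reported with `r2 = NA` (undefined) rather
#' than raising an error.
#'
#' @param em An `expr_matrix` with `daf` and `replicate` metadata.
#' @param qc_threshold Pairs with `r2` below this value are flagged
#'   (default 0.90, the conventional replicate-quality cut).
#' @return A tibble with columns `tissue`, `daf`, `rep_a`, `rep_b`,
#'   `sample_a`, `sample_b`, `r2`, `low_quality`.
#' @export
replicate_correlation <- function(em, qc_threshold = 0.90) {
  stopifnot(inherits(em, "expr_matrix"))
  meta <- em$samples
  groups <- split(seq_len(nrow(meta)),
                  paste(meta$tissue, meta$daf, sep = "\r"))
  if (!any(vapply(groups, length, 1L) >= 2)) {
    stop("no time point has >= 2 replicates", call. = FALSE)
  }
  rows <- purrr::map(groups, function(idx) {
    if (length(idx) < 2) return(NULL)
    pairs <- utils::combn(idx, 2)
    purrr::map(seq_len(ncol(pairs)), function(p) {
      i <- pairs[1, p]; j <- pairs[2, p]
      xi <- em$values[, i]; xj <- em$values[, j]
      r2 <- if (sd(xi) == 0 || sd(xj) == 0) NA_real_ else cor(xi, xj)^2
      tibble::tibble(
        tissue = meta$tissue[i], daf = meta$daf[i],
        rep_a = meta$replicate[i], rep_b = meta$replicate[j],
        sample_a = meta$sample_id[i], sample_b = meta$sample_id[j],
        r2 = r2
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  out <- dplyr::arrange(out, .data$daf, .data$tissue, .data$rep_a, .data$rep_b)
  out$low_quality <- !is.na(out$r2) & out$r2 < qc_threshold
  out
}

#' Average replicates to one column per time point
#'
#' Collapses replicate columns to their arithmetic mean TPM, one column
#' per (tissue, DAF) combination; metadata collapses to `tissue` and
#' `daf`. A time point with a single replicate passes through unchanged.
#'
#' @param em An `expr_matrix` with replicate metadata.
#' @return An `expr_matrix` with one column per time point, ordered by
#'   DAF then tissue; sample ids become `<tissue>_<daf>daf` (or the tissue
#'   label when DAF is absent).
#' @export
average_replicates <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  meta <- em$samples
  key <- paste(meta$tissue, meta$daf, sep = "\r")
  ord <- order(meta$daf, meta$tissue)
  keys <- unique(key[ord])
  vals <- vapply(keys, function(k) {
    idx <- which(key == k)
    rowMeans(em$values[, idx, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (!is.matrix(vals)) {  # single-gene matrix: vapply returns a vector
    vals <- matrix(vals, nrow = 1, dimnames = list(rownames(em$values), NULL))
  }
  first <- match(keys, key)
  ids <- ifelse(is.na(meta$daf[first]), meta$tissue[first],
                paste0(meta$tissue[first], "_", meta$daf[first], "daf"))
  colnames(vals) <- ids
  expression_matrix(vals, tibble::tibble(
    sample_id = ids, tissue = meta$tissue[first], daf = meta$daf[first]
  ))
}

#' Project samples onto principal components
#'
#' PCA of the samples (observations) over genes (features, centered), as
#' used to visualize the relatedness of time points. Expects
#' log-transformed input.
#'
#' @param em An `expr_matrix`, typically averaged and log-transformed.
#' @param k Number of components to return (`k <= n_samples - 1`).
#' @return A list of class `pca_projection` with elements `scores` (tibble:
#'   `sample_id`, `daf`, `PC1..PCk`) and `var_explained` (fraction of
#'   variance per returned component). A constant matrix yields all-zero
#'   scores and zero explained variance.
#' @export
pca_project <- function(em, k = 2) {
  stopifnot(inherits(em, "expr_matrix"))
  n <- ncol(em$values)
  if (k > n - 1) stop("k must be <= number of samples - 1", call. = FALSE)
  x <- t(em$values)
  keep <- apply(x, 2, function(v) var(v) > 0)
  if (!any(keep)) {
    scores <- matrix(0, n, k, dimnames = list(rownames(x), paste0("PC", seq_len(k))))
    ev <- rep(0, k)
  } else {
    pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
    kk <- min(k, ncol(pc$x))
    scores <- matrix(0, n, k, dimnames = list(rownames(x), paste0("PC", seq_len(k))))
    scores[, seq_len(kk)] <- pc$x[, seq_len(kk)]
    ev <- rep(0, k)
    ev[seq_len(kk)] <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(kk)]
  }
  out <- dplyr::left_join(
    tibble::tibble(sample_id = colnames(em$values)),
    em$samples, by = "sample_id")
  scores_tb <- dplyr::bind_cols(out[, c("sample_id", "daf")],
                                tibble::as_tibble(scores))
  structure(list(scores = scores_tb, var_explained = ev),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat("<pca_projection> ", nrow(x$scores), " samples, ",
      length(x$var_explained), " components\n", sep = "")
  cat("  variance explained:",
      paste0(sprintf("%.1f", 100 * x$var_explained), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Assign time points to developmental stages
#'
#' Hierarchical clustering of time-point expression profiles using
#' Pearson correlation distance (1 - r between sample columns), cut into
#' `K` stages. Stages are renumbered 1..K by ascending mean DAF so stage
#' 1 is the earliest. Input should be replicate-averaged and
#' log-transformed.
#'
#' A zero-variance time-point profile has undefined correlations; its
#' distance to every other point is set to 1 with a warning.
#'
#' @param em An `expr_matrix` (averaged, log2-transformed).
#' @param K Number of stages (default 5).
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return A tibble of class `stage_assignment` with columns `sample_id`,
#'   `daf`, `stage`, carrying the `hclust` tree in attribute `"tree"` and
#'   `K` in attribute `"K"`.
#' @export
assign_stages <- function(em, K = 5, linkage = "average") {
  stopifnot(inherits(em, "expr_matrix"))
  n <- ncol(em$values)
  if (K > n) stop("K exceeds the number of time points", call. = FALSE)
  sds <- apply(em$values, 2, sd)
  cc <- suppressWarnings(cor(em$values))
  if (any(sds == 0)) {
    warning("zero-variance time-point profile(s): ",
            paste(colnames(em$values)[sds == 0], collapse = ", "),
            "; correlation treated as 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
    diag(cc) <- 1
  }
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = linkage)
  raw <- cutree(tree, k = K)
  # renumber by ascending mean DAF (column order when DAF absent)
  daf <- em$samples$daf
  rank_key <- if (all(is.na(daf))) seq_len(n) else daf
  mean_pos <- vapply(seq_len(K), function(g) mean(rank_key[raw == g]), 1)
  relabel <- match(seq_len(K), order(mean_pos))
  stage <- relabel[raw]
  out <- tibble::tibble(sample_id = colnames(em$values), daf = daf,
                        stage = as.integer(stage))
  class(out) <- c("stage_assignment", class(out))
  attr(out, "tree") <- tree
  attr(out, "K") <- K
  out
}

#' @method tidy stage_assignment
#' @export
tidy.stage_assignment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "stage_assignment")
  attr(out, "tree") <- NULL
  attr(out, "K") <- NULL
  out
}

#' @method glance stage_assignment
#' @export
glance.stage_assignment <- function(x, ...) {
  tibble::tibble(
    n_timepoints = nrow(x),
    K = attr(x, "K"),
    stage_sizes = paste(table(x$stage), collapse = ","),
    contiguous = is_contiguous_staging(x)
  )
}

#' Are stages contiguous blocks along the DAF axis?
#'
#' @param stages A `stage_assignment`.
#' @return `TRUE` when every stage occupies a contiguous run of time
#'   points ordered by DAF.
#' @export
is_contiguous_staging <- function(stages) {
  ord <- order(stages$daf)
  runs <- rle(stages$stage[ord])$values
  !anyDuplicated(runs)
}

#' Plot PCA scores colored by stage
#'
#' @param object A `pca_projection`.
#' @param stages Optional `stage_assignment` used to color points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_projection
#' @export
autoplot.pca_projection <- function(object, stages = NULL, ...) {
  df <- object$scores
  if (!is.null(stages)) {
    df <- dplyr::left_join(df, tidy(stages)[, c("sample_id", "stage")],
                           by = "sample_id")
    df$stage <- factor(df$stage)
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(stages)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}
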