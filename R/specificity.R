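#' Tau specificity index of a single expression profile
#'
#' The quantile-free specificity index on a vector of per-tissue (or
#' per-stage) log-scale expression values: with `x_hat = x / max(x)`,
#' `tau = sum(1 - x_hat) / (N - 1)`. Returns 1 when exactly one entry is
#' nonzero, 0 when all entries are equal, and `NA` when all are zero.
#'
#' @param x Non-negative numeric vector of log-scale expression values,
#'   one per tissue.
#' @return Tau in \[0, 1\], or `NA` for an all-zero profile.
#' @export
#' @examples
#' tau_index(c(4, 2, 1, 1))  # 2/3
tau_index <- function(x) {
  m <- max(x)
  if (m <= 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

#' Tau tissue-specificity index per gene
#'
#' Computes the quantile-free tau index on per-tissue mean expression.
#' Samples are first collapsed to one column per tissue label (mean TPM);
#' genes whose maximum per-tissue TPM is at or below `min_tpm` are
#' excluded from scoring. On the log2(TPM + 1) tissue profile x, with
#' `x_hat = x / max(x)`, tau = sum(1 - x_hat) / (N - 1) over the N
#' tissues: 1 for single-tissue expression, 0 for uniform expression.
#'
#' @param em An `expr_matrix` whose samples carry tissue labels (samples
#'   without a label count as their own tissue).
#' @param min_tpm Expression floor; genes never exceeding it are excluded
#'   (default 1.0 TPM).
#' @param threshold Tau above which a gene is called tissue-specific
#'   (default 0.9).
#' @return A tibble with columns `gene_id`, `tau`, `argmax_tissue`,
#'   `max_tpm`, `specific`, `excluded`. Excluded genes have `tau = NA`.
#' @export
compute_tau <- function(em, min_tpm = 1.0, threshold = 0.9) {
  stopifnot(inherits(em, "expr_matrix"))
  tissue <- em$samples$tissue
  tissue[is.na(tissue)] <- em$samples$sample_id[is.na(tissue)]
  labels <- unique(tissue)
  if (length(labels) < 2) {
    stop("tau is undefined for a single tissue", call. = FALSE)
  }
  means <- vapply(labels, function(tl) {
    rowMeans(em$values[, tissue == tl, drop = FALSE])
  }, numeric(nrow(em$values)))
  max_tpm <- unname(apply(means, 1, max))
  lx <- log2(means + 1)
  tau <- unname(apply(lx, 1, tau_index))
  argmax <- unname(labels[apply(lx, 1, which.max)])
  excluded <- max_tpm <= min_tpm | is.na(tau)
  tau[excluded] <- NA_real_
  argmax[excluded] <- NA_character_
  tibble::tibble(
    gene_id = rownames(em$values),
    tau = tau,
    argmax_tissue = argmax,
    max_tpm = max_tpm,
    specific = !excluded & !is.na(tau) & tau > threshold,
    excluded = excluded
  )
}

#' Seed-specific genes from a multi-tissue atlas
#'
#' A gene is seed-specific when its tau over the atlas exceeds the
#' threshold *and* its peak tissue is a seed tissue.
#'
#' @param atlas An `expr_matrix` spanning seed and non-seed tissues.
#' @param seed_tissues Character vector of tissue labels counted as seed.
#' @param threshold Tau threshold (default 0.9).
#' @param min_tpm Expression floor passed to [compute_tau()].
#' @return A tibble (`gene_id`, `tau`, `argmax_tissue`) of the
#'   seed-specific genes, sorted by gene id.
#' @export
seed_specific_genes <- function(atlas, seed_tissues, threshold = 0.9,
                                min_tpm = 1.0) {
  tissues <- unique(atlas$samples$tissue)
  if (!any(seed_tissues %in% tissues) ||
      !length(setdiff(tissues, seed_tissues))) {
    stop("atlas must contain at least one seed and one non-seed tissue",
         call. = FALSE)
  }
  tau <- compute_tau(atlas, min_tpm = min_tpm, threshold = threshold)
  out <- dplyr::filter(tau, .data$specific,
                       .data$argmax_tissue %in% seed_tissues)
  dplyr::arrange(out[, c("gene_id", "tau", "argmax_tissue")], .data$gene_id)
}

#' Stage-marker genes within the seed time course
#'
#' Screens for genes expressed predominantly in one developmental stage:
#' per-gene stage profiles are the means of log2(TPM + 1) over the time
#' points of each stage; a gene marks stage s when the tau index over its
#' K stage means exceeds `tau_stage`, its peak stage is s, and its raw
#' TPM exceeds `min_tpm` somewhere in the course.
#'
#' @param em An `expr_matrix` of raw TPM, averaged per time point.
#' @param stages A `stage_assignment` for the columns of `em`.
#' @param tau_stage Stage-level tau threshold (default 0.8; stages are
#'   few, so the single-tissue limit of 0.9 is relaxed).
#' @param min_tpm Expression floor on raw TPM (default 1.0).
#' @return A tibble with columns `gene_id`, `stage`, `tau` listing each
#'   marker gene once.
#' @export
stage_markers <- function(em, stages, tau_stage = 0.8, min_tpm = 1.0) {
  stopifnot(inherits(em, "expr_matrix"))
  idx <- match(colnames(em$values), stages$sample_id)
  if (anyNA(idx)) stop("stage assignment does not cover all samples", call. = FALSE)
  st <- stages$stage[idx]
  K <- max(st)
  lx <- log2(em$values + 1)
  stage_means <- vapply(seq_len(K), function(s) {
    rowMeans(lx[, st == s, drop = FALSE])
  }, numeric(nrow(em$values)))
  tau <- apply(stage_means, 1, tau_index)
  peak <- apply(stage_means, 1, which.max)
  max_tpm <- apply(em$values, 1, max)
  keep <- !is.na(tau) & tau > tau_stage & max_tpm > min_tpm
  tibble::tibble(
    gene_id = rownames(em$values)[keep],
    stage = as.integer(peak[keep]),
    tau = tau[keep]
  ) %>% dplyr::arrange(.data$stage, .data$gene_id)
}
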