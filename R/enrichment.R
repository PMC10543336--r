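#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: with p-values sorted ascending,
#' `q_(i) = min over j >= i of p_(j) * m / j`, clipped at 1 and returned
#' in input order (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Vector of BH-adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' One-sided over-representation p-value
#'
#' The upper-tail hypergeometric probability behind the one-sided
#' Fisher test: P(X >= k) for X ~ Hypergeom(N, K, n), i.e. the chance
#' of drawing at least `k` category genes when sampling `n` genes from
#' a universe of `N` containing `K` category genes.
#'
#' @param k Observed category hits in the gene set.
#' @param n Gene-set size.
#' @param K Category hits in the universe.
#' @param N Universe size.
#' @return The one-sided enrichment p-value (vectorized).
#' @export
hypergeom_tail <- function(k, n, K, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Functional-category over-representation per gene set
#'
#' One-sided Fisher's exact test of category enrichment in each module
#' (or stage) gene set: for a module of size n containing k genes of a
#' category with K hits among the N universe genes, the p-value is the
#' hypergeometric upper tail P(X >= k). Benjamini-Hochberg correction is
#' applied jointly across all (module, category) tests, with
#' significance called at FDR < 0.05.
#'
#' @param gene_sets Named list of character vectors (module id -> genes),
#'   or a data frame with columns `module` and `gene_id`.
#' @param category_map Data frame with columns `gene_id`, `category`
#'   (one row per label; multi-label genes appear on several rows).
#'   Genes outside the universe are ignored; categories with zero
#'   universe hits are skipped.
#' @param universe Character vector of background genes. Every module
#'   gene must belong to it.
#' @param fdr Significance level on the adjusted values (default 0.05).
#' @return A tibble with columns `module`, `category`, `k`, `n`, `K`,
#'   `N`, `p`, `q`, `significant`, sorted by `q` within module.
#' @export
fisher_enrichment <- function(gene_sets, category_map, universe, fdr = 0.05) {
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("module", "gene_id") %in% names(gene_sets)))
    gene_sets <- split(gene_sets$gene_id, gene_sets$module)
  }
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  outside <- setdiff(unique(unlist(gene_sets)), universe)
  if (length(outside)) {
    stop("module gene(s) outside the universe: ",
         paste(head(outside, 5), collapse = ", "), call. = FALSE)
  }
  category_map <- dplyr::filter(tibble::as_tibble(category_map),
                                .data$gene_id %in% universe)
  category_map <- dplyr::distinct(category_map, .data$gene_id, .data$category)
  cats <- split(category_map$gene_id, category_map$category)
  N <- length(universe)
  rows <- purrr::imap(gene_sets, function(genes, mod) {
    genes <- unique(genes)
    n <- length(genes)
    purrr::imap(cats, function(hits, cat_label) {
      K <- length(hits)
      k <- length(intersect(genes, hits))
      tibble::tibble(module = mod, category = cat_label,
                     k = k, n = n, K = K, N = N,
                     p = hypergeom_tail(k, n, K, N))
    }) %>% dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(tibble::tibble(
    module = character(), category = character(), k = integer(),
    n = integer(), K = integer(), N = integer(), p = numeric(),
    q = numeric(), significant = logical()))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr
  dplyr::arrange(out, .data$module, .data$q, .data$category)
}
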