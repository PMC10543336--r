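#' Expand a guide-gene set into a correlation network
#'
#' Starting from pathway-annotated guide genes, retains every candidate
#' gene whose absolute Pearson correlation with at least one guide
#' exceeds `r_retain` (the first-shell partners, P1), then stores all
#' guide-guide, guide-partner and partner-partner edges passing the same
#' threshold. Correlations are computed on the stored expression values,
#' which should be replicate-averaged log2(TPM + 1).
#'
#' @param em An `expr_matrix` (averaged, log-transformed).
#' @param guides Character vector of guide gene ids.
#' @param candidates Character vector of candidate gene ids (typically
#'   the genes assigned to co-expression modules).
#' @param r_retain Absolute-correlation retention threshold
#'   (default 0.8).
#' @return An object of class `guide_network`: list with `nodes` (tibble:
#'   `gene_id`, `role` in guide/partner), `edges` (tibble: `from`, `to`,
#'   `r`, with `from < to`), and the thresholds used.
#' @export
expand_guides <- function(em, guides, candidates, r_retain = 0.8) {
  stopifnot(inherits(em, "expr_matrix"))
  genes <- rownames(em$values)
  guides_in <- sort(intersect(unique(guides), genes))
  if (!length(guides_in)) stop("no guide gene present in the matrix", call. = FALSE)
  cand_in <- sort(setdiff(intersect(unique(candidates), genes), guides_in))
  # candidate x guide correlations decide retention
  cg <- suppressWarnings(cor(t(em$values[cand_in, , drop = FALSE]),
                             t(em$values[guides_in, , drop = FALSE])))
  cg[is.na(cg)] <- 0
  p1 <- cand_in[apply(abs(cg) > r_retain, 1, any)]
  nodes <- tibble::tibble(
    gene_id = c(guides_in, p1),
    role = c(rep("guide", length(guides_in)), rep("partner", length(p1)))
  )
  all_ids <- nodes$gene_id
  cc <- suppressWarnings(cor(t(em$values[all_ids, , drop = FALSE])))
  cc[is.na(cc)] <- 0
  keep <- which(abs(cc) > r_retain & upper.tri(cc), arr.ind = TRUE)
  edges <- tibble::tibble(
    from = all_ids[keep[, 1]],
    to = all_ids[keep[, 2]],
    r = cc[keep]
  )
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(nodes = nodes, edges = edges, r_retain = r_retain),
            class = "guide_network")
}

#' @export
print.guide_network <- function(x, ...) {
  cat("<guide_network> ", sum(x$nodes$role == "guide"), " guides, ",
      sum(x$nodes$role == "partner"), " partners, ", nrow(x$edges),
      " edges (|r| > ", x$r_retain, ")\n", sep = "")
  invisible(x)
}

#' @method tidy guide_network
#' @export
tidy.guide_network <- function(x, ...) x$edges

#' @method glance guide_network
#' @export
glance.guide_network <- function(x, ...) {
  tibble::tibble(
    n_guides = sum(x$nodes$role == "guide"),
    n_partners = sum(x$nodes$role == "partner"),
    n_edges = nrow(x$edges),
    r_retain = x$r_retain
  )
}

#' Hub genes of a module network
#'
#' A gene is a hub when it is a transcription factor assigned to a
#' module, or when it ranks in the top `top_frac` of intramodular
#' connectivity within its module (count `ceiling(top_frac * module
#' size)`, so even a one-gene module yields a hub; ties break by gene id
#' ascending).
#'
#' @param network A `coex_network`, or a connectivity tibble as returned
#'   by [gene_connectivity()].
#' @param tf_genes Character vector of transcription-factor gene ids.
#' @param top_frac Fraction of each module called hubs by connectivity
#'   (default 0.10).
#' @param use Rank on intramodular `"k_within"` (default) or
#'   whole-network `"k"`.
#' @return A tibble with columns `gene_id`, `module`, `k`, `k_within`,
#'   `is_tf`, `top_connectivity`, sorted by module then gene id.
#' @export
hub_genes <- function(network, tf_genes = character(), top_frac = 0.10,
                      use = c("k_within", "k")) {
  use <- match.arg(use)
  conn <- if (inherits(network, "coex_network")) network$connectivity
          else tibble::as_tibble(network)
  stopifnot(all(c("gene_id", "module", "k", "k_within") %in% names(conn)))
  conn <- dplyr::filter(conn, .data$module != 0)
  # per module: the ceiling(top_frac * size) genes of highest connectivity
  tops <- conn %>%
    dplyr::group_by(.data$module) %>%
    dplyr::group_modify(function(df, key) {
      n_top <- ceiling(top_frac * nrow(df))
      df[order(-df[[use]], df$gene_id), ][seq_len(n_top), ]
    }) %>%
    dplyr::ungroup()
  out <- conn %>%
    dplyr::mutate(
      is_tf = .data$gene_id %in% tf_genes,
      top_connectivity = .data$gene_id %in% tops$gene_id
    ) %>%
    dplyr::filter(.data$is_tf | .data$top_connectivity) %>%
    dplyr::arrange(.data$module, .data$gene_id)
  out
}

#' Restrict a guide network to its display threshold
#'
#' Networks are retained at a permissive threshold but visualized at a
#' stricter one: keeps only edges with `|r| > r_view` and drops nodes
#' left isolated.
#'
#' @param network A `guide_network` built at `r_retain <= r_view`.
#' @param r_view Display threshold (default 0.9).
#' @return A `guide_network` with filtered edges and nodes.
#' @export
display_subnetwork <- function(network, r_view = 0.9) {
  stopifnot(inherits(network, "guide_network"))
  if (r_view < network$r_retain) {
    stop("r_view must be >= the network's retention threshold", call. = FALSE)
  }
  edges <- dplyr::filter(network$edges, abs(.data$r) > r_view)
  keep <- union(edges$from, edges$to)
  nodes <- dplyr::filter(network$nodes, .data$gene_id %in% keep)
  structure(list(nodes = nodes, edges = edges, r_retain = network$r_retain,
                 r_view = r_view), class = "guide_network")
}
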