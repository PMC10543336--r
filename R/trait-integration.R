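#' Expression-trait correlation across an accession panel
#'
#' For every gene, the Pearson correlation between its expression (TPM,
#' as plotted against the trait in association panels) and a trait
#' across accessions, with a two-sided p-value from the t distribution
#' on n - 2 degrees of freedom. Accessions missing the trait value are
#' dropped per gene; a zero-variance expression profile is reported with
#' `pcc = NA` and excluded from ranking.
#'
#' @param pop_expr An `expr_matrix` whose columns are accessions.
#' @param traits Data frame with an `accession_id` column and one column
#'   per trait (e.g. `SOC`, `SCC`, in percent).
#' @param trait Name of the trait column to use.
#' @return A tibble with columns `gene_id`, `trait`, `n`, `pcc`, `p`,
#'   sorted by p-value.
#' @export
trait_correlation <- function(pop_expr, traits, trait) {
  stopifnot(inherits(pop_expr, "expr_matrix"))
  traits <- tibble::as_tibble(traits)
  if (!trait %in% names(traits)) stop("unknown trait: ", trait, call. = FALSE)
  y <- traits[[trait]][match(colnames(pop_expr$values), traits$accession_id)]
  usable <- !is.na(y)
  if (sum(usable) < 3) stop("need >= 3 accessions with trait values", call. = FALSE)
  yv <- y[usable]
  x <- pop_expr$values[, usable, drop = FALSE]
  n <- length(yv)
  sds <- apply(x, 1, sd)
  r <- suppressWarnings(as.vector(cor(t(x), yv)))
  r[sds == 0] <- NA_real_
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  p[!is.na(r) & abs(r) == 1] <- 0
  out <- tibble::tibble(gene_id = rownames(x), trait = trait, n = n,
                        pcc = r, p = p)
  dplyr::arrange(out, is.na(.data$pcc), .data$p)
}

#' Candidates supported by both TWAS and network hubs
#'
#' The "overlap" integration route: genes present in both the
#' TWAS-significant list and the co-expression hub list.
#'
#' @param twas_genes Character vector of TWAS-significant gene ids.
#' @param hub_genes Character vector of hub gene ids (or the tibble from
#'   [hub_genes()]).
#' @return A tibble of class `candidate_set` with columns `gene_id`,
#'   `method` (= "overlap"), `in_twas`, `in_hubs`.
#' @export
overlap_candidates <- function(twas_genes, hub_genes) {
  if (is.data.frame(hub_genes)) hub_genes <- hub_genes$gene_id
  genes <- sort(intersect(unique(twas_genes), unique(hub_genes)))
  out <- tibble::tibble(gene_id = genes, method = "overlap",
                        in_twas = TRUE, in_hubs = TRUE)
  class(out) <- c("candidate_set", class(out))
  out
}

#' Mine trait candidates through guide-enriched modules
#'
#' The second integration route: (1) find the co-expression modules
#' over-represented for guide genes (hypergeometric upper-tail p <
#' `enrich_p`, universe = all genes assigned to modules); (2) keep the
#' TWAS genes that belong to an enriched module *and* correlate with at
#' least one guide gene at `|r| >= r_min` (Pearson, on the expression
#' matrix provided). Provenance records each candidate's module and its
#' best-supporting guide.
#'
#' @param twas_genes Character vector of TWAS-significant gene ids.
#' @param guides Character vector of guide gene ids.
#' @param network A `coex_network` (or a named label vector).
#' @param em An `expr_matrix` (averaged, log-transformed) for the
#'   guide correlations.
#' @param enrich_p Module guide-enrichment cutoff (default 0.05).
#' @param r_min Minimum absolute guide correlation (default 0.8).
#' @return A tibble of class `candidate_set` with columns `gene_id`,
#'   `method` (= "mining"), `module`, `best_guide`, `guide_r`.
#' @export
mine_candidates <- function(twas_genes, guides, network, em,
                            enrich_p = 0.05, r_min = 0.8) {
  labels <- if (inherits(network, "coex_network")) network$labels else network
  stopifnot(inherits(em, "expr_matrix"))
  assigned <- names(labels)[labels != 0]
  N <- length(assigned)
  guides_net <- intersect(unique(guides), assigned)
  K <- length(guides_net)
  mods <- sort(unique(labels[labels != 0]))
  enr <- purrr::map_dbl(mods, function(m) {
    members <- names(labels)[labels == m]
    k <- length(intersect(members, guides_net))
    hypergeom_tail(k, length(members), K, N)
  })
  enriched <- mods[enr < enrich_p]
  empty <- tibble::tibble(gene_id = character(), method = character(),
                          module = integer(), best_guide = character(),
                          guide_r = numeric())
  class(empty) <- c("candidate_set", class(empty))
  if (!length(enriched)) {
    warning("no module is enriched for guide genes")
    return(empty)
  }
  pool <- intersect(unique(twas_genes),
                    names(labels)[labels %in% enriched])
  pool <- intersect(pool, rownames(em$values))
  guides_expr <- intersect(unique(guides), rownames(em$values))
  if (!length(pool) || !length(guides_expr)) return(empty)
  cg <- suppressWarnings(cor(t(em$values[pool, , drop = FALSE]),
                             t(em$values[guides_expr, , drop = FALSE])))
  cg[is.na(cg)] <- 0
  # a gene that is itself a guide must be supported by another guide
  self <- cbind(seq_along(pool), match(pool, guides_expr))
  cg[self[!is.na(self[, 2]), , drop = FALSE]] <- 0
  best <- apply(abs(cg), 1, which.max)
  best_r <- cg[cbind(seq_along(pool), best)]
  keep <- abs(best_r) >= r_min
  out <- tibble::tibble(
    gene_id = pool[keep], method = "mining",
    module = as.integer(labels[pool[keep]]),
    best_guide = guides_expr[best[keep]],
    guide_r = best_r[keep]
  ) %>% dplyr::arrange(.data$gene_id)
  class(out) <- c("candidate_set", class(out))
  out
}

#' Student's t test between the two major haplotype groups
#'
#' Splits the accessions carrying a gene's two most frequent haplotypes
#' and compares a response (a trait, or the gene's own expression)
#' between the groups with a two-sample Student's t test (pooled
#' variance by default; set `var_equal = FALSE` for Welch). Genes whose
#' two major haplotype groups do not both reach `min_group` accessions
#' are skipped with a reason.
#'
#' @param haps Data frame with columns `gene_id`, `accession_id`,
#'   `haplotype`.
#' @param response Named numeric vector (names = accession ids), or a
#'   data frame with columns `accession_id` and `value`.
#' @param gene Gene id to test.
#' @param min_group Minimum accessions per haplotype group (default 10).
#' @param var_equal Pooled-variance Student's t (default `TRUE`).
#' @return A one-row tibble with columns `gene_id`, `hap_a`, `hap_b`,
#'   `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `p`, `skipped`, `reason`.
#' @export
haplotype_test <- function(haps, response, gene, min_group = 10,
                           var_equal = TRUE) {
  haps <- tibble::as_tibble(haps)
  stopifnot(all(c("gene_id", "accession_id", "haplotype") %in% names(haps)))
  if (is.data.frame(response)) {
    response <- setNames(response$value, response$accession_id)
  }
  hg <- dplyr::filter(haps, .data$gene_id == gene)
  if (!nrow(hg)) stop("gene not present in the haplotype table: ", gene,
                      call. = FALSE)
  skipped <- function(reason) tibble::tibble(
    gene_id = gene, hap_a = NA_character_, hap_b = NA_character_,
    n_a = NA_integer_, n_b = NA_integer_, mean_a = NA_real_,
    mean_b = NA_real_, t = NA_real_, p = NA_real_,
    skipped = TRUE, reason = reason)
  counts <- sort(table(hg$haplotype), decreasing = TRUE)
  counts <- counts[order(-counts, names(counts))]
  if (length(counts) < 2) return(skipped("fewer than two haplotypes"))
  top2 <- names(counts)[1:2]
  ga <- hg$accession_id[hg$haplotype == top2[1]]
  gb <- hg$accession_id[hg$haplotype == top2[2]]
  ya <- response[ga]; yb <- response[gb]
  ya <- ya[!is.na(ya)]; yb <- yb[!is.na(yb)]
  if (length(ya) < min_group || length(yb) < min_group) {
    return(skipped(sprintf("major haplotype groups below min_group (%d vs %d)",
                           length(ya), length(yb))))
  }
  if (sd(ya) == 0 && sd(yb) == 0) {
    # degenerate: no within-group variance
    if (mean(ya) == mean(yb)) tt <- list(statistic = 0, p.value = 1)
    else tt <- list(statistic = sign(mean(ya) - mean(yb)) * Inf, p.value = 0)
  } else {
    tt <- t.test(ya, yb, var.equal = var_equal)
  }
  tibble::tibble(
    gene_id = gene, hap_a = top2[1], hap_b = top2[2],
    n_a = length(ya), n_b = length(yb),
    mean_a = mean(ya), mean_b = mean(yb),
    t = unname(tt$statistic), p = tt$p.value,
    skipped = FALSE, reason = NA_character_
  )
}
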