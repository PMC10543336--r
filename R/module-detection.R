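#' Two-pass gene filter for network construction
#'
#' The standard pre-filter before building a co-expression network: keep
#' the `n_expressed` genes with the highest mean TPM, then, among those,
#' the `n_cv` genes with the highest coefficient of variation (sd/mean).
#' The order of the two passes is fixed. Ties break by the metric
#' descending, then gene id ascending; a constant gene (sd = 0) has CV 0
#' and ranks last.
#'
#' @param em An `expr_matrix`, averaged per time point.
#' @param n_expressed Genes kept by the expression pass (default 50000).
#' @param n_cv Genes kept by the variability pass (default 15000).
#' @return The filtered `expr_matrix` (row order preserved from input).
#' @export
filter_genes <- function(em, n_expressed = 50000, n_cv = 15000) {
  stopifnot(inherits(em, "expr_matrix"))
  if (n_cv > n_expressed) stop("n_cv must be <= n_expressed", call. = FALSE)
  v <- em$values
  means <- rowMeans(v)
  ord1 <- order(-means, rownames(v))
  keep1 <- sort(ord1[seq_len(min(n_expressed, nrow(v)))])
  v1 <- v[keep1, , drop = FALSE]
  sds <- apply(v1, 1, sd)
  cv <- ifelse(rowMeans(v1) > 0, sds / rowMeans(v1), 0)
  cv[sds == 0] <- 0
  ord2 <- order(-cv, rownames(v1))
  keep2 <- sort(ord2[seq_len(min(n_cv, nrow(v1)))])
  expression_matrix(v1[keep2, , drop = FALSE], em$samples)
}

#' Gene-gene correlation matrix
#'
#' Pairwise Spearman (default, rank-based with average ranks for ties) or
#' Pearson correlation between gene expression profiles. A zero-variance
#' gene has undefined correlations; they are set to 0 with a warning and
#' its diagonal entry stays 1.
#'
#' @param em An `expr_matrix` with >= 3 samples.
#' @param method `"spearman"` or `"pearson"`.
#' @return A symmetric genes x genes correlation matrix in \[-1, 1\].
#' @export
correlation_matrix <- function(em, method = c("spearman", "pearson")) {
  stopifnot(inherits(em, "expr_matrix"))
  method <- match.arg(method)
  if (ncol(em$values) < 3) stop("need >= 3 samples", call. = FALSE)
  cc <- suppressWarnings(cor(t(em$values), method = method))
  if (anyNA(cc)) {
    warning("zero-variance gene(s); their correlations set to 0")
    cc[is.na(cc)] <- 0
    diag(cc) <- 1
  }
  cc
}

#' Signed soft-threshold adjacency
#'
#' Converts correlations to connection strengths with the signed
#' soft-threshold map `a_ij = ((1 + r_ij) / 2)^beta`: perfectly
#' positively correlated pairs get weight 1, perfectly anti-correlated
#' pairs get 0, and the soft power `beta` suppresses weak correlations
#' while keeping the network weighted. The diagonal is set to 0 so that
#' row sums are network connectivities.
#'
#' @param corr Symmetric correlation matrix in \[-1, 1\].
#' @param beta Positive integer soft-threshold power (default 12).
#' @return Adjacency matrix in \[0, 1\] with zero diagonal.
#' @export
adjacency_matrix <- function(corr, beta = 12) {
  stopifnot(beta >= 1)
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 0
  a
}

#' Choose the soft-threshold power by scale-free fit
#'
#' For each candidate power, computes network connectivities
#' `k_i = sum_j a_ij`, bins `log10(k)` into `n_bins` equal-occupancy
#' bins, and regresses `log10(p(k))` on `log10(mean k per bin)`. The
#' scale-free fit index is the regression R^2, signed negative when the
#' slope is positive (a scale-free degree distribution must decay).
#' Returns the smallest power whose fit reaches `r2_target`, or the
#' best-fitting power if none does, together with the full fit table.
#'
#' @param corr Correlation matrix.
#' @param grid Candidate powers (default 1:10 then even powers to 20).
#' @param r2_target Fit considered adequate (default 0.8).
#' @param n_bins Equal-occupancy bins for the degree histogram
#'   (default 10).
#' @return A list of class `beta_fit`: `beta` (the chosen power) and
#'   `fit_table` (tibble: `beta`, `fit`, `slope`, `mean_k`, `median_k`,
#'   `max_k`).
#' @export
pick_beta <- function(corr, grid = c(1:10, seq(12, 20, 2)), r2_target = 0.8,
                      n_bins = 10) {
  stopifnot(length(grid) >= 1)
  rows <- purrr::map(grid, function(b) {
    a <- adjacency_matrix(corr, b)
    k <- rowSums(a)
    if (all(k == 0)) stop("degenerate network: all connectivities zero",
                          call. = FALSE)
    sf <- scale_free_fit(k, n_bins)
    tibble::tibble(beta = b, fit = sf$r2_signed, slope = sf$slope,
                   mean_k = mean(k), median_k = stats::median(k),
                   max_k = max(k))
  })
  tab <- dplyr::bind_rows(rows)
  ok <- which(tab$fit >= r2_target)
  beta <- if (length(ok)) tab$beta[ok[1]] else tab$beta[which.max(tab$fit)]
  structure(list(beta = beta, fit_table = tab), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("<beta_fit> chosen power:", x$beta, "\n")
  print(x$fit_table)
  invisible(x)
}

# Scale-free topology fit of a connectivity vector: equal-occupancy
# binning of log10(k), then log-log regression of the degree *density*
# (bin count / bin width in log10 k -- with equal-occupancy bins the raw
# frequencies are constant by construction, only the density carries the
# shape) on the bin mean connectivity. Genes with k == 0 cannot enter
# the log-log fit.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  lk <- log10(k)
  breaks <- unique(quantile(lk, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 4) return(list(r2_signed = 0, slope = NA_real_))
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  counts <- tapply(lk, bin, length)
  widths <- diff(breaks)
  dens <- counts / (length(lk) * widths)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(dens) & dens > 0 & widths > 0
  if (sum(keep) < 3) return(list(r2_signed = 0, slope = NA_real_))
  fit <- lm(log10(dens[keep]) ~ log10(kmean[keep]))
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[[2]]
  list(r2_signed = if (!is.na(slope) && slope > 0) -r2 else r2, slope = slope)
}

#' Topological overlap from an adjacency matrix
#'
#' The topological overlap similarity combines direct adjacency with
#' shared-neighbour strength:
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; `TOM_ii = 1`.
#' Module detection clusters genes on the dissimilarity `1 - TOM`.
#'
#' @param adj Symmetric adjacency in \[0, 1\] with zero diagonal.
#' @return The TOM similarity matrix in \[0, 1\] with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  stopifnot(isSymmetric(unname(adj)), all(diag(adj) == 0))
  k <- rowSums(adj)
  l <- adj %*% adj
  tom <- (l + adj) / (outer(k, k, pmin) + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Cut the gene dendrogram into co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity,
#' followed by four deterministic refinement steps replacing the dynamic
#' hybrid tree cut: (1) a static cut at the `cut_quantile` quantile of
#' the merge heights; (2) clusters smaller than `min_module_size` are
#' unassigned (label 0); (3) modules whose eigengenes are closer than
#' `merge_threshold` (eigengene dissimilarity 1 - r) are merged
#' iteratively, closest pair first; (4) a membership-pruning step drops
#' genes whose Pearson correlation with their own module eigengene (kME)
#' is below `kme_min` in absolute value -- under average linkage,
#' unrelated background genes chain onto real modules just below the cut
#' height, and pruning on eigengene membership removes them the same way
#' the PAM stage of the dynamic hybrid cut does. Labels are renumbered
#' 1, 2, ... by decreasing module size.
#'
#' @param dissim TOM dissimilarity matrix (`1 - tom_similarity(adj)`).
#' @param em The `expr_matrix` the network was built from (used for
#'   eigengenes and kME).
#' @param min_module_size Smallest retained module (default 30).
#' @param cut_quantile Quantile of merge heights for the static cut
#'   (default 0.99).
#' @param merge_threshold Eigengene dissimilarity below which two modules
#'   merge (default 0.25).
#' @param kme_min Minimum absolute module membership (default 0.5).
#' @param linkage Agglomeration method (default `"average"`).
#' @return Named integer vector of module labels (0 = unassigned), one
#'   per gene.
#' @export
cut_modules <- function(dissim, em, min_module_size = 30, cut_quantile = 0.99,
                        merge_threshold = 0.25, kme_min = 0.5,
                        linkage = "average") {
  stopifnot(inherits(em, "expr_matrix"), isSymmetric(unname(dissim)))
  genes <- rownames(em$values)
  tree <- hclust(as.dist(dissim), method = linkage)
  labels <- cutree(tree, h = quantile(tree$height, cut_quantile))
  labels <- drop_small_modules(labels, min_module_size)
  labels <- merge_close_modules(labels, em, merge_threshold)
  labels <- prune_membership(labels, em, kme_min)
  labels <- drop_small_modules(labels, min_module_size)
  labels <- relabel_by_size(labels)
  if (all(labels == 0)) warning("no module passed the size filter")
  setNames(as.integer(labels), genes)
}

drop_small_modules <- function(labels, min_size) {
  sizes <- table(labels[labels != 0])
  small <- as.integer(names(sizes)[sizes < min_size])
  labels[labels %in% small] <- 0L
  labels
}

relabel_by_size <- function(labels) {
  sizes <- table(labels[labels != 0])
  if (!length(sizes)) return(labels)
  ord <- names(sizes)[order(-as.integer(sizes), as.integer(names(sizes)))]
  map <- setNames(seq_along(ord), ord)
  out <- labels
  out[labels != 0] <- map[as.character(labels[labels != 0])]
  out
}

# Iteratively merge the closest pair of module eigengenes while their
# dissimilarity (1 - Pearson r) is below the threshold.
merge_close_modules <- function(labels, em, merge_threshold) {
  repeat {
    mods <- sort(unique(labels[labels != 0]))
    if (length(mods) < 2) return(labels)
    eg <- module_eigengenes(em, labels)$eigengenes
    dd <- 1 - cor(t(eg))
    diag(dd) <- Inf
    if (min(dd) >= merge_threshold) return(labels)
    idx <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- mods[idx[1]]; b <- mods[idx[2]]
    labels[labels == b] <- a
  }
}

prune_membership <- function(labels, em, kme_min) {
  z <- standardize_genes(em$values)
  for (m in sort(unique(labels[labels != 0]))) {
    idx <- which(labels == m)
    eg <- module_eigengene_one(z[idx, , drop = FALSE])$eigengene
    kme <- as.vector(suppressWarnings(cor(t(z[idx, , drop = FALSE]), eg)))
    kme[is.na(kme)] <- 0
    labels[idx[abs(kme) < kme_min]] <- 0L
  }
  labels
}

# Per-gene standardization over samples; constant genes become all-zero.
standardize_genes <- function(v) {
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  z <- (v - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

# First principal component of a standardized module (genes x samples):
# the eigengene is the leading right singular vector, sign-aligned with
# the module's mean profile, unit norm.
module_eigengene_one <- function(z) {
  if (nrow(z) == 1) {
    eg <- as.vector(z)
    n <- sqrt(sum(eg^2))
    if (n > 0) eg <- eg / n
    return(list(eigengene = eg, var_explained = 1))
  }
  sv <- svd(z, nu = 0, nv = 1)
  eg <- sv$v[, 1]
  mean_prof <- colMeans(z)
  if (sum(eg * mean_prof) < 0) eg <- -eg
  ve <- sv$d[1]^2 / sum(sv$d^2)
  list(eigengene = eg, var_explained = ve)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' per-gene standardized expression (zero mean, unit variance over
#' samples): a unit-norm sample profile representing the module,
#' sign-aligned so that it correlates positively with the module's mean
#' standardized expression. A single-gene module's eigengene is that
#' gene's standardized profile.
#'
#' @param em An `expr_matrix`.
#' @param labels Named (or positional) integer module labels per gene;
#'   label 0 = unassigned, skipped.
#' @return A list: `eigengenes` (module x sample matrix, rows `ME<id>`)
#'   and `var_explained` (named fraction of module variance captured).
#' @export
module_eigengenes <- function(em, labels) {
  stopifnot(inherits(em, "expr_matrix"))
  if (length(labels) != nrow(em$values)) {
    stop("one label per gene required", call. = FALSE)
  }
  z <- standardize_genes(em$values)
  mods <- sort(unique(labels[labels != 0]))
  if (!length(mods)) stop("no assigned module", call. = FALSE)
  eg <- matrix(0, length(mods), ncol(em$values),
               dimnames = list(paste0("ME", mods), colnames(em$values)))
  ve <- setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    res <- module_eigengene_one(z[labels == mods[i], , drop = FALSE])
    eg[i, ] <- res$eigengene
    ve[i] <- res$var_explained
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Whole-network and intramodular connectivity
#'
#' `k` is a gene's total connection strength (row sum of the adjacency);
#' `k_within` counts only connections to genes of its own module.
#'
#' @param adj Adjacency matrix with zero diagonal.
#' @param labels Integer module labels per gene (0 = unassigned).
#' @return A tibble with columns `gene_id`, `module`, `k`, `k_within`.
#' @export
gene_connectivity <- function(adj, labels) {
  genes <- rownames(adj)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(adj)))
  k <- rowSums(adj)
  kw <- vapply(seq_len(nrow(adj)), function(i) {
    same <- labels == labels[i] & seq_len(nrow(adj)) != i
    sum(adj[i, same])
  }, 1)
  tibble::tibble(gene_id = genes, module = as.integer(labels),
                 k = unname(k), k_within = kw)
}

#' Detect co-expression modules end to end
#'
#' Convenience wrapper chaining [correlation_matrix()],
#' [adjacency_matrix()], [tom_similarity()], [cut_modules()],
#' [module_eigengenes()] and [gene_connectivity()] into a fitted network
#' model.
#'
#' @param em An `expr_matrix`, typically averaged, log-transformed and
#'   filtered with [filter_genes()].
#' @param beta Soft-threshold power (default 12); set `beta = NULL` to
#'   choose it with [pick_beta()].
#' @param method Correlation method (default `"spearman"`).
#' @param ... Further arguments passed to [cut_modules()].
#' @return An object of class `coex_network`: list with `genes`,
#'   `method`, `beta`, `adjacency`, `tom`, `labels`, `eigengenes`,
#'   `var_explained`, `connectivity` and the input `em`.
#' @export
coexpression_network <- function(em, beta = 12, method = "spearman", ...) {
  cc <- correlation_matrix(em, method = method)
  if (is.null(beta)) beta <- pick_beta(cc)$beta
  a <- adjacency_matrix(cc, beta)
  tom <- tom_similarity(a)
  labels <- cut_modules(1 - tom, em, ...)
  eig <- module_eigengenes(em, labels)
  conn <- gene_connectivity(a, labels)
  structure(list(
    genes = rownames(em$values), method = method, beta = beta,
    adjacency = a, tom = tom, labels = labels,
    eigengenes = eig$eigengenes, var_explained = eig$var_explained,
    connectivity = conn, em = em
  ), class = "coex_network")
}

#' @export
print.coex_network <- function(x, ...) {
  nm <- length(unique(x$labels[x$labels != 0]))
  cat("<coex_network> ", length(x$genes), " genes, ", nm, " modules (",
      sum(x$labels == 0), " unassigned), ", x$method, " correlation, beta = ",
      x$beta, "\n", sep = "")
  invisible(x)
}

#' @describeIn coexpression_network One row per gene: module label,
#'   connectivity.
#' @param x A `coex_network`.
#' @method tidy coex_network
#' @export
tidy.coex_network <- function(x, ...) {
  x$connectivity
}

#' @describeIn coexpression_network One-row model summary.
#' @method glance coex_network
#' @export
glance.coex_network <- function(x, ...) {
  mods <- x$labels[x$labels != 0]
  tibble::tibble(
    n_genes = length(x$genes),
    n_modules = length(unique(mods)),
    n_unassigned = sum(x$labels == 0),
    largest_module = if (length(mods)) max(table(mods)) else 0L,
    beta = x$beta,
    method = x$method,
    mean_var_explained = mean(x$var_explained)
  )
}

#' Plot module eigengene profiles
#'
#' Eigengene expression across samples, one facet line per module --
#' the module-level summary used to relate modules to stages.
#'
#' @param object A `coex_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coex_network
#' @export
autoplot.coex_network <- function(object, ...) {
  eg <- tibble::as_tibble(object$eigengenes, rownames = "module")
  long <- tidyr::pivot_longer(eg, -"module", names_to = "sample_id",
                              values_to = "eigengene")
  long$sample_id <- factor(long$sample_id, levels = colnames(object$eigengenes))
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$eigengene,
                                     group = .data$module,
                                     colour = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~module) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   legend.position = "none") +
    ggplot2::labs(x = "sample", y = "eigengene score")
}
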