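test_that("two-pass gene filter matches an explicit two-pass sort", {
  withr::with_seed(8, v <- matrix(rexp(20 * 6, 0.1), 20, 6))
  rownames(v) <- sprintf("g%02d", 1:20); colnames(v) <- paste0("s", 1:6)
  em <- expression_matrix(v)
  out <- filter_genes(em, n_expressed = 10, n_cv = 5)
  # independent oracle: sort by mean, then by CV among survivors
  top10 <- names(sort(rowMeans(v), decreasing = TRUE))[1:10]
  cv <- apply(v[top10, ], 1, sd) / rowMeans(v[top10, ])
  oracle <- sort(names(sort(cv, decreasing = TRUE))[1:5])
  expect_setequal(rownames(out$values), oracle)
  expect_equal(dim(out)[1], 5)

  # permissive first pass is the identity
  all1 <- filter_genes(em, n_expressed = 100, n_cv = 20)
  expect_equal(rownames(all1$values), rownames(v))

  # a constant gene ranks last by CV
  v2 <- rbind(v, const = rep(1000, 6))
  em2 <- expression_matrix(v2)
  out2 <- filter_genes(em2, n_expressed = 21, n_cv = 20)
  expect_false("const" %in% rownames(out2$values))

  expect_error(filter_genes(em, n_expressed = 5, n_cv = 10), "n_cv")
})

test_that("Spearman correlation equals explicit rank-then-Pearson", {
  em <- em_fix(rbind(x = c(1, 2, 3), y = c(6, 5, 4)))
  cc <- correlation_matrix(em, "spearman")
  expect_equal(diag(cc), c(x = 1, y = 1))
  expect_equal(cc["x", "y"], -1)

  withr::with_seed(9, v <- matrix(rnorm(10 * 20), 10, 20))
  em2 <- em_fix(pmax(v + 5, 0))
  got <- correlation_matrix(em2, "spearman")
  ranks <- t(apply(em2$values, 1, rank))  # average ranks for ties
  oracle <- cor(t(ranks), method = "pearson")
  expect_lt(max(abs(got - oracle)), 1e-12)

  flat <- em_fix(rbind(a = c(1, 1, 1), b = c(1, 2, 3)))
  expect_warning(cf <- correlation_matrix(flat), "zero-variance")
  expect_equal(cf["a", "b"], 0)
  expect_equal(diag(cf), c(a = 1, b = 1))
})

test_that("signed adjacency follows ((1+r)/2)^beta exactly and monotonically", {
  corr <- matrix(c(1, 1, -1, 0.6,
                   1, 1, 0, 0,
                   -1, 0, 1, 0,
                   0.6, 0, 0, 1), 4, 4)
  a <- adjacency_matrix(corr, 12)
  expect_equal(a[1, 2], 1)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 4], 0.068719476736, tolerance = 1e-12)
  expect_equal(diag(a), rep(0, 4))

  rho <- seq(-1, 1, by = 0.05)
  vals <- ((1 + rho) / 2)^7
  expect_true(all(diff(vals) >= 0))
})

test_that("TOM matches its formula on hand and brute-force instances", {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.5
  a[2, 3] <- a[3, 2] <- 0.5
  tom <- tom_similarity(a)
  expect_equal(tom[1, 2], 0.7, tolerance = 1e-12)

  z <- matrix(0, 4, 4)
  tz <- tom_similarity(z)
  expect_equal(unname(diag(tz)), rep(1, 4))
  expect_true(all(tz[upper.tri(tz)] == 0))

  # brute-force triple loop oracle on random instances
  withr::with_seed(10, {
    for (rep in 1:5) {
      n <- sample(5:10, 1)
      a <- matrix(runif(n * n), n, n)
      a <- (a + t(a)) / 2
      diag(a) <- 0
      got <- tom_similarity(a)
      oracle <- diag(n)
      k <- rowSums(a)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        l <- 0
        for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
        oracle[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
      }
      expect_lt(max(abs(got - oracle)), 1e-10)
      expect_true(all(got >= 0 & got <= 1))
      expect_equal(got, t(got))
    }
  })
})

test_that("the scale-free fit table matches an independent binning oracle", {
  s <- synth_default()
  cc <- correlation_matrix(s$lavg, "spearman")
  pb <- pick_beta(cc, grid = c(6, 12))
  # oracle: redo the equal-occupancy density binning by hand
  for (row in seq_len(nrow(pb$fit_table))) {
    b <- pb$fit_table$beta[row]
    k <- rowSums(adjacency_matrix(cc, b))
    expect_equal(pb$fit_table$mean_k[row], mean(k))
    lk <- log10(k[k > 0])
    br <- unique(quantile(lk, seq(0, 1, 0.1)))
    bin <- cut(lk, br, include.lowest = TRUE)
    dens <- as.vector(table(bin)) / (length(lk) * diff(br))
    km <- tapply(10^lk, bin, mean)
    keep <- dens > 0
    fit <- lm(log10(dens[keep]) ~ log10(km[keep]))
    r2 <- summary(fit)$r.squared
    if (coef(fit)[[2]] > 0) r2 <- -r2
    expect_equal(pb$fit_table$fit[row], r2, tolerance = 1e-10)
  }
})

test_that("beta selection honours the grid and the target rule", {
  s <- synth_default()
  cc <- correlation_matrix(s$lavg, "spearman")
  expect_equal(pick_beta(cc, grid = 12)$beta, 12)  # singleton grid
  # any fit beats a target of -1: smallest power wins
  expect_equal(pick_beta(cc, grid = c(4, 8, 12), r2_target = -1)$beta, 4)
  # unreachable target: the best-fitting power wins
  pb <- pick_beta(cc, grid = c(4, 8, 12), r2_target = 2)
  expect_equal(pb$beta, pb$fit_table$beta[which.max(pb$fit_table$fit)])
})

test_that("module cutting recovers planted blocks and respects size rules", {
  withr::with_seed(12, {
    base1 <- rnorm(20); base2 <- rnorm(20)
    v <- rbind(
      t(sapply(1:50, function(i) base1 * runif(1, 0.8, 1.2) + rnorm(20, 0, 0.3))),
      t(sapply(1:50, function(i) base2 * runif(1, 0.8, 1.2) + rnorm(20, 0, 0.3))))
  })
  rownames(v) <- sprintf("g%03d", 1:100); colnames(v) <- paste0("s", 1:20)
  em <- expression_matrix(v - min(v))
  cc <- correlation_matrix(em, "pearson")
  tom <- tom_similarity(adjacency_matrix(cc, 6))
  labels <- cut_modules(1 - tom, em, min_module_size = 10)
  expect_equal(length(unique(labels[labels != 0])), 2)
  expect_equal(ari(labels, rep(1:2, each = 50)), 1)

  # min size above the gene count leaves everything unassigned
  expect_warning(
    none <- cut_modules(1 - tom, em, min_module_size = 200),
    "no module")
  expect_true(all(none == 0))
})

test_that("eigengene merging never increases the module count", {
  s <- synth_default()
  em <- s$lavg
  cc <- correlation_matrix(em, "spearman")
  tom <- tom_similarity(adjacency_matrix(cc, 12))
  no_merge <- cut_modules(1 - tom, em, merge_threshold = 0)
  merged <- cut_modules(1 - tom, em, merge_threshold = 0.6)
  n_mod <- function(l) length(unique(l[l != 0]))
  expect_lte(n_mod(merged), n_mod(no_merge))
})

test_that("module eigengenes equal the covariance eigendecomposition", {
  # identical genes: eigengene is the shared standardized profile
  prof <- c(1, 3, 7, 5, 2, 8)
  v <- matrix(rep(prof, each = 5), 5, 6)
  rownames(v) <- paste0("g", 1:5); colnames(v) <- paste0("s", 1:6)
  em <- expression_matrix(v)
  eig <- module_eigengenes(em, rep(1L, 5))
  zs <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(eig$eigengenes[1, ]), zs / sqrt(sum(zs^2)),
               tolerance = 1e-10)
  expect_equal(unname(eig$var_explained[1]), 1)
  # sign convention: positively correlated with the module mean profile
  expect_gt(cor(eig$eigengenes[1, ], colMeans(v)), 0)

  withr::with_seed(16, v2 <- matrix(rexp(40 * 12), 40, 12))
  em2 <- em_fix(v2)
  eig2 <- module_eigengenes(em2, rep(1L, 40))
  z <- t(scale(t(v2)))
  ed <- eigen(t(z) %*% z, symmetric = TRUE)
  oracle <- ed$vectors[, 1]
  if (sum(oracle * colMeans(z)) < 0) oracle <- -oracle
  expect_lt(max(abs(eig2$eigengenes[1, ] - oracle)), 1e-8)
  expect_equal(unname(eig2$var_explained[1]), ed$values[1] / sum(ed$values),
               tolerance = 1e-8)

  # single-gene module
  eig3 <- module_eigengenes(em2, c(1L, rep(0L, 39)))
  zz <- z[1, ] / sqrt(sum(z[1, ]^2))
  expect_equal(unname(eig3$eigengenes[1, ]), unname(zz), tolerance = 1e-10)
})

test_that("eigengene variance explained matches the equicorrelation closed form", {
  rho <- 0.6; m <- 30; n <- 200
  withr::with_seed(17, {
    shared <- rnorm(n)
    v <- t(sapply(seq_len(m), function(i)
      sqrt(rho) * shared + sqrt(1 - rho) * rnorm(n)))
  })
  em <- em_fix(v - min(v))
  ve <- module_eigengenes(em, rep(1L, m))$var_explained[[1]]
  closed <- (1 + (m - 1) * rho) / m
  expect_gte(ve, closed - 0.02)  # the closed form is a lower bound in sample
  expect_lt(abs(ve - closed), 0.1)
})

test_that("connectivity equals independent row sums, whole and within module", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  rownames(star) <- colnames(star) <- paste0("g", 1:5)
  conn <- gene_connectivity(star, c(1L, 1L, 1L, 2L, 0L))
  expect_equal(conn$k[1], 4)
  expect_equal(conn$k_within[1], 2)  # g2, g3 share module 1

  iso <- matrix(0, 3, 3)
  expect_equal(gene_connectivity(iso, rep(1L, 3))$k, rep(0, 3))

  withr::with_seed(18, {
    a <- matrix(runif(64), 8, 8); a <- (a + t(a)) / 2; diag(a) <- 0
  })
  lab <- rep(1:2, each = 4)
  conn2 <- gene_connectivity(a, lab)
  expect_equal(conn2$k, unname(rowSums(a)))
  oracle_within <- sapply(1:8, function(i)
    sum(a[i, setdiff(which(lab == lab[i]), i)]))
  expect_equal(conn2$k_within, oracle_within)
})

test_that("planted modules are recovered on the synthetic defaults", {
  s <- synth_default()
  net <- coexpression_network(s$lavg, beta = 12)
  expect_gte(ari(net$labels, s$tc$annotation$module), 0.8)
  # tidy/glance surface
  td <- tidy(net)
  expect_true(all(c("gene_id", "module", "k", "k_within") %in% names(td)))
  expect_equal(glance(net)$n_genes, 2000L)
  # adjacency and TOM live in [0,1], eigengene rows are unit norm
  expect_true(all(net$tom >= 0 & net$tom <= 1))
  expect_equal(unname(rowSums(net$eigengenes^2)),
               rep(1, nrow(net$eigengenes)), tolerance = 1e-8)
})
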