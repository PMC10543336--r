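test_that("replicate R^2 is 1 for identical or sign-flipped replicates and NA for flat ones", {
  prof <- matrix(seq(1, 40), 10, 4)
  em <- em_replicated(prof, n_rep = 2, sd = 0)
  qc <- replicate_correlation(em)
  expect_equal(qc$r2, rep(1, 4), tolerance = 1e-12)
  expect_false(any(qc$low_quality))

  # squared correlation is sign-invariant: replicate vs a reversed copy
  v <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), 4, 2)
  em2 <- em_fix(v, tibble::tibble(sample_id = c("s001", "s002"),
                                  tissue = "seed", daf = 14L,
                                  replicate = 1:2))
  qc2 <- replicate_correlation(em2)
  expect_equal(qc2$r2, 1)

  # zero-variance replicate flagged undefined, no error
  v3 <- cbind(rep(2, 4), c(1, 2, 3, 4))
  colnames(v3) <- c("a", "b"); rownames(v3) <- paste0("g", 1:4)
  em3 <- expression_matrix(v3, tibble::tibble(
    sample_id = c("a", "b"), tissue = "seed", daf = 14L, replicate = 1:2))
  expect_true(is.na(replicate_correlation(em3)$r2))
})

test_that("replicate R^2 matches its construction correlation", {
  rho <- 0.95
  withr::with_seed(21, {
    n <- 500
    shared <- matrix(rnorm(n * 4), n, 4)
    prof <- NULL
    reps <- lapply(1:3, function(r)
      sqrt(rho) * shared + sqrt(1 - rho) * matrix(rnorm(n * 4), n, 4))
  })
  vals <- do.call(cbind, lapply(seq_len(4), function(tp)
    sapply(reps, function(m) m[, tp]))) + 10
  colnames(vals) <- sprintf("tp%d_r%d", rep(1:4, each = 3), rep(1:3, 4))
  rownames(vals) <- sprintf("g%03d", 1:500)
  em <- expression_matrix(vals, tibble::tibble(
    sample_id = colnames(vals), tissue = "seed",
    daf = rep(c(14L, 16L, 18L, 20L), each = 3),
    replicate = rep(1:3, 4)))
  qc <- replicate_correlation(em)
  expect_equal(mean(qc$r2), rho^2, tolerance = 0.03 / rho^2)
})

test_that("replicate averaging equals per-gene means computed independently", {
  v <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("g1", c("a", "b", "c")))
  em <- expression_matrix(v, tibble::tibble(
    sample_id = c("a", "b", "c"), tissue = "seed", daf = 14L,
    replicate = 1:3))
  expect_equal(unname(average_replicates(em)$values[1, 1]), 2)

  # single replicate passes through
  one <- em_replicated(matrix(1:8, 2, 4), n_rep = 1)
  expect_equal(unname(average_replicates(one)$values), unname(one$values))

  withr::with_seed(31, prof <- matrix(runif(60, 0, 50), 10, 6))
  em2 <- em_replicated(prof, n_rep = 3, sd = 1, seed = 32)
  avg <- average_replicates(em2)
  daf <- em2$samples$daf
  for (tp in unique(daf)) {
    direct <- rowMeans(em2$values[, daf == tp, drop = FALSE])
    expect_equal(unname(avg$values[, which(unique(daf) == tp)]),
                 unname(direct))
  }
})

test_that("log transform maps 0,1,7 to 0,1,3", {
  em <- em_fix(matrix(c(0, 1, 7, 3), 2, 2))
  expect_equal(unname(log_transform(em)$values),
               matrix(c(0, 1, 3, 2), 2, 2))
})

test_that("PCA projection reproduces the covariance eigendecomposition", {
  # two distinct samples: PC1 explains everything
  em <- em_fix(matrix(c(1, 2, 3, 3, 2, 1), 3, 2))
  p <- pca_project(em, k = 1)
  expect_equal(p$var_explained[1], 1)

  # identical samples: all scores zero
  em2 <- em_fix(matrix(rep(c(1, 2, 3), 2), 3, 2))
  p2 <- pca_project(em2, k = 1)
  expect_true(all(p2$scores$PC1 == 0))
  expect_equal(p2$var_explained, 0)

  withr::with_seed(7, vals <- matrix(rexp(200 * 26), 200, 26))
  em3 <- em_fix(vals)
  k <- 4
  p3 <- pca_project(em3, k = k)
  x <- scale(t(vals), center = TRUE, scale = FALSE)
  ed <- eigen(cov(x), symmetric = TRUE)
  oracle <- x %*% ed$vectors[, seq_len(k)]
  got <- as.matrix(p3$scores[, paste0("PC", seq_len(k))])
  for (j in seq_len(k)) {
    expect_lt(min(max(abs(got[, j] - oracle[, j])),
                  max(abs(got[, j] + oracle[, j]))), 1e-8)
  }
  expect_equal(p3$var_explained,
               (ed$values / sum(ed$values))[seq_len(k)], tolerance = 1e-8)
  expect_error(pca_project(em3, k = 26), "samples")
})

test_that("stage assignment recovers planted blocks and respects invariances", {
  withr::with_seed(13, {
    prof <- rbind(
      cbind(matrix(5, 40, 5), matrix(0.5, 40, 5)),
      cbind(matrix(0.5, 40, 5), matrix(5, 40, 5)))
    noisy <- prof + matrix(rnorm(80 * 10, 0, 0.1), 80, 10)
  })
  noisy <- pmax(noisy, 0)
  rownames(noisy) <- sprintf("g%02d", 1:80)
  colnames(noisy) <- sprintf("t%02d", 1:10)
  em <- expression_matrix(noisy, tibble::tibble(
    sample_id = colnames(noisy), tissue = "seed",
    daf = seq(14L, by = 2L, length.out = 10)))
  st <- assign_stages(em, K = 2)
  expect_equal(st$stage, rep(1:2, each = 5))

  # K = n gives singleton stages; K > n errors
  stn <- assign_stages(em, K = 10)
  expect_equal(sort(stn$stage), 1:10)
  expect_error(assign_stages(em, K = 11), "K exceeds")

  # invariant to gene order and per-gene positive affine rescaling
  perm <- withr::with_seed(14, sample(1:80))
  em_perm <- expression_matrix(noisy[perm, ], em$samples)
  expect_equal(assign_stages(em_perm, K = 2)$stage, st$stage)
  scl <- withr::with_seed(15, runif(80, 0.5, 3))
  em_aff <- expression_matrix(noisy * scl + 1, em$samples)
  expect_equal(assign_stages(em_aff, K = 2)$stage, st$stage)

  # stage labels partition the time points
  expect_equal(sum(table(st$stage)), 10)
})

test_that("a zero-variance time point is distance 1 from everything, with a warning", {
  v <- cbind(c(1, 2, 3, 4), c(2, 4, 1, 3), rep(1, 4))
  rownames(v) <- paste0("g", 1:4); colnames(v) <- c("a", "b", "c")
  em <- expression_matrix(v, tibble::tibble(
    sample_id = c("a", "b", "c"), tissue = "seed", daf = c(14L, 16L, 18L)))
  expect_warning(st <- assign_stages(em, K = 2), "zero-variance")
  expect_equal(sum(table(st$stage)), 3)
})

test_that("synthetic five-stage course is recovered exactly and contiguously", {
  s <- synth_default()
  st <- assign_stages(s$lavg, K = 5)
  expect_true(is_contiguous_staging(st))
  expect_equal(st$stage,
               s$tc$truth$stages$stage[match(st$daf, s$tc$truth$stages$daf)])
  expect_equal(glance(st)$K, 5)
})
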