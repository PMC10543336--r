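#' Configuration for the synthetic seed-development study
#'
#' Collects every parameter of the synthetic data generators in one
#' validated object. The defaults emulate the study design the package
#' targets: a 26-time-point seed series (14-64 days after flowering at
#' 2-day intervals) with 3 replicates, five contiguous developmental
#' stages carrying one planted co-expression module each, a multi-tissue
#' atlas with planted seed-specific and housekeeping genes, and an
#' accession panel in which biallelic haplotypes drive expression and
#' two antagonistic traits (seed oil content SOC, seed coat content
#' SCC).
#'
#' @param seed Integer RNG seed; every generator output is a pure
#'   function of this configuration.
#' @param n_timepoints Number of time points (default 26).
#' @param n_replicates Replicates per time point (default 3).
#' @param stage_sizes Time points per stage; must sum to `n_timepoints`
#'   (default 6, 4, 6, 4, 6).
#' @param genes_per_module Genes in each planted module (default 150).
#' @param n_background Unstructured background genes (default 1250).
#' @param noise_sd Gaussian noise SD on the log2 scale (default 0.2).
#' @param daf_start,daf_step Sampling grid in days after flowering
#'   (defaults 14 and 2).
#' @param amplitude_sdlog SD of the log-normal per-gene amplitude
#'   (default 0.25).
#' @param baseline,peak Latent log2 level outside/at the top of a
#'   module's stage bump (defaults 0.5 and 8).
#' @param bump_floor Fraction of the bump height retained across the
#'   whole stage block (default 0.5): the raised cosine rides on this
#'   pedestal so every time point of a stage expresses the stage's
#'   module well above baseline.
#' @param tf_frac Fraction of module genes flagged as transcription
#'   factors (default 0.2).
#' @param guide_frac Fraction of the two designated guide modules
#'   labelled as guide genes (default 0.6).
#' @param lipid_module,phenylpropane_module Which planted module plays
#'   the acyl-lipid / phenylpropane guide set (defaults: the stage-II
#'   and stage-I modules, mirroring seed-filling oil synthesis and
#'   early-seed flavonoid synthesis).
#' @param n_nonseed_tissues Non-seed tissue labels in the atlas
#'   (default 10; the atlas collapses its non-seed samples to these).
#' @param n_seed_specific Planted seed-specific genes (default 200).
#' @param n_housekeeping Planted housekeeping genes (default 100).
#' @param n_accessions Accession panel size (default 300; a desk-scale
#'   stand-in for the hundreds-strong natural population).
#' @param allele_freq Alternate-allele frequency (default 0.3).
#' @param allele_effect Expression shift of the alternate haplotype, in
#'   within-group SDs (default 1.0).
#' @param n_trait_genes Per guide module, genes given a nonzero trait
#'   weight (default 20).
#' @param trait_weight Absolute per-gene trait weight (default 0.5;
#'   positive for lipid-module genes on SOC, negative for
#'   phenylpropane-module genes, mirrored for SCC).
#' @param trait_noise_sd Trait residual SD in percentage points
#'   (default 1).
#' @param soc_base,scc_base Trait means in percent (defaults 40 and 30).
#' @param n_twas_decoys Null genes added to the synthetic TWAS list
#'   (default 20).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1,
                         n_timepoints = 26, n_replicates = 3,
                         stage_sizes = c(6, 4, 6, 4, 6),
                         genes_per_module = 150, n_background = 1250,
                         noise_sd = 0.2,
                         daf_start = 14, daf_step = 2,
                         amplitude_sdlog = 0.25,
                         baseline = 0.5, peak = 8, bump_floor = 0.5,
                         tf_frac = 0.2, guide_frac = 0.6,
                         lipid_module = 2, phenylpropane_module = 1,
                         n_nonseed_tissues = 10,
                         n_seed_specific = 200, n_housekeeping = 100,
                         n_accessions = 300, allele_freq = 0.3,
                         allele_effect = 1.0,
                         n_trait_genes = 20, trait_weight = 0.5,
                         trait_noise_sd = 1,
                         soc_base = 40, scc_base = 30,
                         n_twas_decoys = 20) {
  cfg <- as.list(environment())
  cfg$n_modules <- length(stage_sizes)
  if (sum(stage_sizes) != n_timepoints) {
    stop("stage_sizes must sum to n_timepoints", call. = FALSE)
  }
  counts <- c(n_timepoints, n_replicates, genes_per_module, n_background,
              n_nonseed_tissues, n_accessions, stage_sizes)
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (lipid_module == phenylpropane_module ||
      max(lipid_module, phenylpropane_module) > cfg$n_modules) {
    stop("guide modules must be two distinct planted modules", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed ", x$seed, ": ", x$n_timepoints, " timepoints x ",
      x$n_replicates, " reps, ", x$n_modules, " modules x ",
      x$genes_per_module, " genes + ", x$n_background, " background, ",
      x$n_accessions, " accessions\n", sep = "")
  invisible(x)
}

# Latent log2 profile of each module: a raised-cosine bump over its
# stage's time points, sampled at half-step phase offsets and riding on
# a pedestal of `bump_floor` of the bump height. The pedestal keeps
# every time point of a stage clearly elevated for the stage's module:
# a bump vanishing at the block edges would make edge time points of
# different stages indistinguishable, contradicting the block structure
# a staged time course is meant to carry.
latent_profiles <- function(cfg) {
  stage_of_tp <- rep(seq_len(cfg$n_modules), cfg$stage_sizes)
  lat <- matrix(cfg$baseline, cfg$n_modules, cfg$n_timepoints)
  for (m in seq_len(cfg$n_modules)) {
    idx <- which(stage_of_tp == m)
    w <- 0.5 * (1 - cos(2 * pi * (seq_along(idx) - 0.5) / length(idx)))
    w <- cfg$bump_floor + (1 - cfg$bump_floor) * w
    lat[m, idx] <- cfg$baseline + (cfg$peak - cfg$baseline) * w
  }
  lat
}

#' Generate the synthetic seed time course with planted truth
#'
#' Simulates a replicate-level gene x sample TPM matrix. Each planted
#' module is tied to one developmental stage: its latent log2 profile is
#' a raised-cosine bump over the stage's DAF block (baseline 0.5, peak
#' 8); gene expression is `amplitude_g * latent + N(0, noise_sd^2)` per
#' replicate, with log-normal per-gene amplitudes. Background genes sit
#' at a gene-specific constant level plus noise. TPM = 2^x - 1, clipped
#' at 0. A fifth of module genes are flagged transcription factors, and
#' 60% of the two designated guide modules form the acyl-lipid and
#' phenylpropane guide sets. Output is deterministic given the
#' configuration.
#'
#' @param cfg A [synth_config()].
#' @return A list: `em` (replicate-level `expr_matrix`), `annotation`
#'   (tibble: `gene_id`, `module`, `is_tf`, `guide_set`, `seed_specific`,
#'   `housekeeping`), `truth` (list of class `synth_truth` with the
#'   planted stage map, module labels, flags and the generator seed).
#' @export
generate_timecourse <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    n_gene <- cfg$n_modules * cfg$genes_per_module + cfg$n_background
    gene_ids <- sprintf("gene%04d", seq_len(n_gene))
    module <- c(rep(seq_len(cfg$n_modules), each = cfg$genes_per_module),
                rep(0L, cfg$n_background))
    daf <- cfg$daf_start + cfg$daf_step * (seq_len(cfg$n_timepoints) - 1)
    stage_of_tp <- rep(seq_len(cfg$n_modules), cfg$stage_sizes)
    lat <- latent_profiles(cfg)
    amp <- exp(stats::rnorm(n_gene, 0, cfg$amplitude_sdlog))
    bg_level <- stats::runif(n_gene, 0.5, 5)  # only used where module == 0
    mean_log2 <- matrix(0, n_gene, cfg$n_timepoints)
    in_mod <- module > 0
    mean_log2[in_mod, ] <- amp[in_mod] * lat[module[in_mod], , drop = FALSE]
    mean_log2[!in_mod, ] <- bg_level[!in_mod]
    ncol_total <- cfg$n_timepoints * cfg$n_replicates
    x <- mean_log2[, rep(seq_len(cfg$n_timepoints), each = cfg$n_replicates)] +
      stats::rnorm(n_gene * ncol_total, 0, cfg$noise_sd)
    tpm <- pmax(2^x - 1, 0)
    sample_daf <- rep(daf, each = cfg$n_replicates)
    sample_rep <- rep(seq_len(cfg$n_replicates), times = cfg$n_timepoints)
    sample_ids <- sprintf("seed_%02ddaf_r%d", sample_daf, sample_rep)
    dimnames(tpm) <- list(gene_ids, sample_ids)
    em <- expression_matrix(tpm, tibble::tibble(
      sample_id = sample_ids, tissue = "seed", daf = sample_daf,
      replicate = sample_rep))
    # annotation flags
    is_tf <- rep(FALSE, n_gene)
    for (m in seq_len(cfg$n_modules)) {
      idx <- which(module == m)
      is_tf[sample(idx, round(cfg$tf_frac * length(idx)))] <- TRUE
    }
    guide_set <- rep(NA_character_, n_gene)
    for (gs in c("lipid", "phenylpropane")) {
      m <- if (gs == "lipid") cfg$lipid_module else cfg$phenylpropane_module
      idx <- which(module == m)
      guide_set[sample(idx, round(cfg$guide_frac * length(idx)))] <- gs
    }
    seed_specific <- rep(FALSE, n_gene)
    seed_specific[sample(which(in_mod), cfg$n_seed_specific)] <- TRUE
    housekeeping <- rep(FALSE, n_gene)
    housekeeping[sample(which(!in_mod), cfg$n_housekeeping)] <- TRUE
    annotation <- tibble::tibble(
      gene_id = gene_ids, module = module, is_tf = is_tf,
      guide_set = guide_set, seed_specific = seed_specific,
      housekeeping = housekeeping)
    truth <- structure(list(
      genes = annotation,
      stages = tibble::tibble(daf = daf, stage = stage_of_tp),
      amplitudes = setNames(amp, gene_ids),
      config = cfg, seed = cfg$seed), class = "synth_truth")
    list(em = em, annotation = annotation, truth = truth)
  })
}

#' Generate the synthetic multi-tissue atlas
#'
#' Builds a seed + non-seed expression atlas over the time-course genes
#' for tau screening: planted seed-specific genes peak (log2 level =
#' `peak`) in a single seed tissue and stay at log2 <= 0.1 everywhere
#' else; planted housekeeping genes sit at a uniform level across all
#' tissues; the remaining genes take independent moderate levels per
#' tissue. Seed tissues are the 26 time points (one column each);
#' non-seed samples are collapsed to `n_nonseed_tissues` labels.
#'
#' @param cfg A [synth_config()].
#' @param timecourse Output of [generate_timecourse()] (supplies gene
#'   ids and planted flags).
#' @return A list: `em` (the atlas `expr_matrix`) and `seed_tissues`
#'   (character vector of seed tissue labels).
#' @export
generate_atlas <- function(cfg, timecourse) {
  stopifnot(inherits(cfg, "synth_config"))
  ann <- timecourse$annotation
  withr::with_seed(cfg$seed + 1L, {
    daf <- cfg$daf_start + cfg$daf_step * (seq_len(cfg$n_timepoints) - 1)
    seed_tissues <- sprintf("seed_%02ddaf", daf)
    nonseed <- sprintf("tissue_%02d", seq_len(cfg$n_nonseed_tissues))
    tissues <- c(seed_tissues, nonseed)
    n_gene <- nrow(ann)
    x <- matrix(stats::runif(n_gene * length(tissues), 0, 4),
                n_gene, length(tissues),
                dimnames = list(ann$gene_id, tissues))
    hk <- which(ann$housekeeping)
    x[hk, ] <- 4 + stats::rnorm(length(hk) * length(tissues), 0, 0.05)
    ss <- which(ann$seed_specific)
    x[ss, ] <- stats::runif(length(ss) * length(tissues), 0, 0.1)
    home <- sample(seq_along(seed_tissues), length(ss), replace = TRUE)
    x[cbind(ss, home)] <- cfg$peak
    tpm <- pmax(2^x - 1, 0)
    em <- expression_matrix(tpm, tibble::tibble(
      sample_id = tissues, tissue = tissues,
      daf = c(daf, rep(NA_integer_, length(nonseed))),
      replicate = NA_integer_))
    list(em = em, seed_tissues = seed_tissues)
  })
}

#' Generate the synthetic accession panel
#'
#' Simulates expression, biallelic haplotypes and two antagonistic
#' traits across an accession panel. Panel genes are the trait-weighted
#' genes of the two guide modules, the TWAS decoys, and background
#' filler. Each panel gene carries two haplotype labels
#' (`hap.<5 bases>`); trait-weighted genes and decoys get an additive
#' expression effect of `allele_effect` SDs for the alternate
#' haplotype. SOC is a weighted sum of the trait genes' centered
#' expression (positive weights for lipid-module genes, negative for
#' phenylpropane-module genes) plus noise; SCC uses the mirrored
#' weights, producing the antagonistic oil/coat structure. The TWAS
#' gene list is the weighted genes (|w| >= `trait_weight`) plus
#' `n_twas_decoys` null decoys.
#'
#' @param cfg A [synth_config()].
#' @param truth The `synth_truth` from [generate_timecourse()].
#' @return A list: `em` (accession-level `expr_matrix`), `traits`
#'   (tibble: `accession_id`, `SOC`, `SCC`), `haplotypes` (tibble:
#'   `gene_id`, `accession_id`, `haplotype`), `twas_genes` (character),
#'   `weights` (tibble: `gene_id`, `module`, `w_soc`, `w_scc`,
#'   `allele_effect`, `twas`, `decoy`).
#' @export
generate_population <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  ann <- truth$genes
  withr::with_seed(cfg$seed + 2L, {
    acc <- sprintf("acc%03d", seq_len(cfg$n_accessions))
    lipid_genes <- ann$gene_id[ann$module == cfg$lipid_module]
    phen_genes <- ann$gene_id[ann$module == cfg$phenylpropane_module]
    trait_lipid <- sort(sample(lipid_genes, cfg$n_trait_genes))
    trait_phen <- sort(sample(phen_genes, cfg$n_trait_genes))
    decoys <- sort(sample(ann$gene_id[ann$module == 0], cfg$n_twas_decoys))
    bg_pool <- setdiff(ann$gene_id[ann$module == 0], decoys)
    filler <- sort(sample(bg_pool, min(140L, length(bg_pool))))
    panel_genes <- unique(c(trait_lipid, trait_phen, decoys, filler))
    n_g <- length(panel_genes)
    effect <- setNames(rep(0, n_g), panel_genes)
    effect[c(trait_lipid, trait_phen, decoys)] <- cfg$allele_effect
    w_soc <- setNames(rep(0, n_g), panel_genes)
    w_soc[trait_lipid] <- cfg$trait_weight
    w_soc[trait_phen] <- -cfg$trait_weight
    w_scc <- -w_soc
    # biallelic haplotypes with opaque 5-base labels
    hap_labels <- vapply(seq_len(n_g), function(i) {
      paste0("hap.", paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                           collapse = ""))
    }, "")
    alt_labels <- vapply(seq_len(n_g), function(i) {
      repeat {
        lab <- paste0("hap.", paste(sample(c("A", "C", "G", "T"), 5,
                                           replace = TRUE), collapse = ""))
        if (lab != hap_labels[i]) return(lab)
      }
    }, "")
    alt <- matrix(stats::rbinom(n_g * cfg$n_accessions, 1, cfg$allele_freq),
                  n_g, cfg$n_accessions,
                  dimnames = list(panel_genes, acc))
    mu <- stats::runif(n_g, 4, 10)
    expr <- mu + alt * effect +
      matrix(stats::rnorm(n_g * cfg$n_accessions), n_g, cfg$n_accessions)
    expr <- pmax(expr, 0)
    dimnames(expr) <- list(panel_genes, acc)
    em <- expression_matrix(expr, tibble::tibble(
      sample_id = acc, tissue = "seed", daf = NA_integer_,
      replicate = NA_integer_))
    centred <- expr - rowMeans(expr)
    soc <- cfg$soc_base + as.vector(w_soc %*% centred) +
      stats::rnorm(cfg$n_accessions, 0, cfg$trait_noise_sd)
    scc <- cfg$scc_base + as.vector(w_scc %*% centred) +
      stats::rnorm(cfg$n_accessions, 0, cfg$trait_noise_sd)
    traits <- tibble::tibble(accession_id = acc, SOC = soc, SCC = scc)
    haplotypes <- tibble::tibble(
      gene_id = rep(panel_genes, each = cfg$n_accessions),
      accession_id = rep(acc, times = n_g),
      haplotype = ifelse(as.vector(t(alt)) == 1,
                         rep(alt_labels, each = cfg$n_accessions),
                         rep(hap_labels, each = cfg$n_accessions)))
    twas_genes <- sort(c(names(w_soc)[abs(w_soc) >= cfg$trait_weight], decoys))
    weights <- tibble::tibble(
      gene_id = panel_genes,
      module = ann$module[match(panel_genes, ann$gene_id)],
      w_soc = unname(w_soc), w_scc = unname(w_scc),
      allele_effect = unname(effect),
      twas = panel_genes %in% twas_genes,
      decoy = panel_genes %in% decoys)
    list(em = em, traits = traits, haplotypes = haplotypes,
         twas_genes = twas_genes, weights = weights)
  })
}
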