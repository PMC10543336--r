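# Shared fixture builders; everything is generated in code.

# Quick expr_matrix from a bare numeric matrix (auto ids when missing).
em_fix <- function(values, samples = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  expression_matrix(values, samples)
}

# Replicated time course: `profiles` is a genes x timepoints matrix of
# mean values; replicates get iid N(0, sd) noise (clipped at 0).
em_replicated <- function(profiles, n_rep = 3, sd = 0, seed = 1) {
  withr::with_seed(seed, {
    n_tp <- ncol(profiles)
    vals <- profiles[, rep(seq_len(n_tp), each = n_rep), drop = FALSE] +
      matrix(rnorm(nrow(profiles) * n_tp * n_rep, 0, sd),
             nrow(profiles), n_tp * n_rep)
    vals <- pmax(vals, 0)
    daf <- rep(seq_len(n_tp) * 2 + 12, each = n_rep)
    reps <- rep(seq_len(n_rep), times = n_tp)
    ids <- sprintf("tp%02d_r%d", daf, reps)
    colnames(vals) <- ids
    if (is.null(rownames(vals))) {
      rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
    }
    expression_matrix(vals, tibble::tibble(
      sample_id = ids, tissue = "seed", daf = daf, replicate = reps))
  })
}

# Adjusted Rand index between two labelings (independent of the
# package's clustering path; mclust is the reference implementation).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# The default synthetic study, computed once per test run and reused.
synth_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 42)
      tc <- generate_timecourse(cfg)
      cache <<- list(
        cfg = cfg, tc = tc,
        atlas = generate_atlas(cfg, tc),
        pop = generate_population(cfg, tc$truth),
        avg = average_replicates(tc$em))
      cache$lavg <<- log_transform(cache$avg)
    }
    cache
  }
})
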