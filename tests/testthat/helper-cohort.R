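# Shared fixtures, built in code.

# A scaled-down cohort for fast unit tests: same structure as the default
# study conditions, fewer samples and probes.
tiny_config <- function(...) {
  args <- list(n_pmtbi = 40, n_hc = 30, n_ec_pmtbi = 34,
               n_two_member_families = 4, n_probes = 500,
               n_pathway_probes = 60, n_true_components = 3,
               component_amplitudes = c(6, 5, 4),
               component_effect_weights = c(3, 3, -4),
               n_batches = 2, seed = 11)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}

tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(tiny_config())
    cache
  }
})

# A small beta matrix with dimnames, values away from the boundaries.
random_betas <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples, 0.2, 0.8), n_probes, n_samples,
         dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

small_pipeline_config <- function() {
  pipeline_config(synthetic = tiny_config(),
                  ica_candidates = 2:5, ica_runs = 4,
                  lambda_grid_length = 8, n_perm = 99, seed = 5)
}

# Memoized small pipeline run shared across test files.
small_pipeline_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(run_pipeline(small_pipeline_config()))
    cache
  }
})

# Minimal sample table for mixed-model tests.
make_table <- function(n, n_families = n, seed = 1, group = NULL) {
  set.seed(seed)
  fam <- sprintf("F%02d", sort(rep_len(seq_len(n_families), n)))
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    family_id = fam,
    group = if (is.null(group)) rep(c("pmTBI", "HC"), length.out = n) else group,
    age = rnorm(n, 15, 2), sex = sample(c("F", "M"), n, TRUE),
    bmi = rnorm(n, 22, 4),
    race = sample(c("White", "African-American", "other"), n, TRUE,
                  prob = c(0.8, 0.1, 0.1)),
    buccal = runif(n, 0.2, 0.9),
    PC2 = rnorm(n), PC3 = rnorm(n), PC4 = rnorm(n),
    stringsAsFactors = FALSE)
}
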