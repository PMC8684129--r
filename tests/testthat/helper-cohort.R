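# Shared fixtures: cohorts are generated in code, once per test run.

.fixtures <- new.env(parent = emptyenv())

# small cohort with genome/tracks/peaks, for IO and motif tests
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    spec <- cohort_spec(n_tumors = c(8, 8, 8), n_regions = 400,
                        n_signature_per_group = 30, seed = 11)
    .fixtures$small <- generate_cohort(spec)
  }
  .fixtures$small
}

# noise-free cohort (matrix only), for exact-recovery checks
noisefree_cohort <- function() {
  if (is.null(.fixtures$noisefree)) {
    spec <- cohort_spec(n_tumors = c(10, 10, 10), n_regions = 600,
                        n_signature_per_group = 40, noise_sd = 0, seed = 23)
    .fixtures$noisefree <- generate_cohort(spec, emit = character(0))
  }
  .fixtures$noisefree
}

truth_groups <- function(cohort) {
  setNames(as.integer(cohort$truth$group), names(cohort$truth$group))
}

random_region_set <- function(n, max_pos = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sort(sample.int(max_pos - 1L, n))
  e <- s + sample.int(50, n)
  region_set(rep("chr1", n), s, pmin(e, max_pos))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
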