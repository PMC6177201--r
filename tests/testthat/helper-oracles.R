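# Canonical signature of a balanced assignment: the sorted global subclass
# ids of new class 1, with label swap resolved by taking whichever of the two
# sides contains subclass 1 (class-A subclasses are 1..K, class-B K+1..2K).
assignment_signature <- function(a1, b1, K) {
  side1 <- sort(c(a1, K + b1))
  side2 <- sort(setdiff(seq_len(2L * K), side1))
  paste(if (1L %in% side1) side1 else side2, collapse = ",")
}

# Brute-force enumeration oracle: count distinct balanced reassignments by
# generating every (A-subset, B-subset) pair and deduplicating under label
# swap via the canonical signature.
brute_force_assignments <- function(K) {
  half <- K %/% 2L
  a_sets <- utils::combn(seq_len(K), half)
  b_sets <- utils::combn(seq_len(K), half)
  sigs <- character(0)
  for (ia in seq_len(ncol(a_sets)))
    for (ib in seq_len(ncol(b_sets)))
      sigs <- c(sigs, assignment_signature(a_sets[, ia], b_sets[, ib], K))
  unique(sigs)
}

# Mean CCR (and its standard error) of the chosen classifier over freshly
# simulated datasets; used by calibration and trend checks.
mean_cv_ccr <- function(n_datasets, d, K, N, sigma_C = 0, sigma_S = 0,
                        classifier = "mean_diff_lda", cv_kind = "2fold",
                        seed0 = 1, cost = 1) {
  ccrs <- vapply(seq_len(n_datasets), function(r) {
    dat <- generate_dataset(sim_params(d = d, K = K, N = N, sigma_C = sigma_C,
                                       sigma_S = sigma_S, seed = seed0 + r))
    cross_validate(dat, classifier, cv_scheme(cv_kind, seed = seed0 + r),
                   cost = cost)$ccr
  }, numeric(1))
  list(mean = mean(ccrs), se = stats::sd(ccrs) / sqrt(n_datasets), ccrs = ccrs)
}

# A tiny perfectly separable two-cluster dataset in 2-D.
separable_toy <- function(n_per_class = 2, gap = 20) {
  n <- 2L * n_per_class
  nested_data(
    features = cbind(c(rep(-gap / 2, n_per_class), rep(gap / 2, n_per_class)),
                     stats::rnorm(n, 0, 0.1)),
    class_labels = rep(c(1L, 2L), each = n_per_class),
    subclass_labels = rep(c(1L, 2L), each = n_per_class))
}
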