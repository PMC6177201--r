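test_that("balanced-assignment count matches the closed form and the oracle", {
  expect_equal(count_balanced_assignments(2), 2)
  expect_equal(count_balanced_assignments(4), 18)
  expect_equal(count_balanced_assignments(10), 31752)
  expect_error(count_balanced_assignments(5), "odd")
  for (K in c(2L, 4L, 6L, 8L)) {
    oracle <- brute_force_assignments(K)
    expect_equal(count_balanced_assignments(K), length(oracle))
    enum <- enumerate_balanced_assignments(K)
    expect_length(enum, length(oracle))
    sigs <- vapply(enum, function(a) assignment_signature(a$a1, a$b1, K),
                   character(1))
    expect_setequal(sigs, oracle)          # distinct, swap-free, complete
  }
})

test_that("every enumerated assignment is balanced and canonical", {
  K <- 6L
  for (a in enumerate_balanced_assignments(K)) {
    expect_length(a$a1, K / 2)
    expect_length(a$b1, K / 2)
    expect_true(1L %in% a$a1)              # canonical side contains subclass 1
    expect_true(all(a$a1 %in% seq_len(K)) && all(a$b1 %in% seq_len(K)))
  }
  expect_error(enumerate_balanced_assignments(10, max_enumerate = 100),
               "sample_balanced_assignments")
})

test_that("rank sampling draws distinct valid assignments without replacement", {
  smp <- sample_balanced_assignments(10, 500, seed = 1)
  expect_false(attr(smp, "exhaustive"))
  expect_length(smp, 500)
  sigs <- vapply(smp, function(a) assignment_signature(a$a1, a$b1, 10L),
                 character(1))
  expect_length(unique(sigs), 500)         # no repeats
  for (a in smp[1:20]) {
    expect_length(a$a1, 5L); expect_length(a$b1, 5L)
    expect_true(1L %in% a$a1)
  }
  # requesting at least the full count returns the exhaustive enumeration
  all18 <- sample_balanced_assignments(4, 50, seed = 2)
  expect_true(attr(all18, "exhaustive"))
  expect_setequal(
    vapply(all18, function(a) assignment_signature(a$a1, a$b1, 4L), character(1)),
    brute_force_assignments(4L))
})

test_that("relabelling keeps subclasses intact and balanced across origins", {
  dat <- generate_dataset(sim_params(d = 3, K = 4, N = 5, sigma_S = 0.5,
                                     seed = 7))
  for (a in enumerate_balanced_assignments(4)) {
    perm <- apply_assignment(dat, a)
    spans <- tapply(perm$class, perm$subclass, function(cl) length(unique(cl)))
    expect_true(all(spans == 1L))          # subclass integrity preserved
    for (new_cl in 1:2) {
      subs <- unique(perm$subclass[perm$class == new_cl])
      from_a <- sum(subs <= 4)             # original class-1 subclasses are 1..K
      expect_equal(from_a, 2L)             # exactly K/2 from each origin
    }
    expect_identical(perm$features, dat$features)
  }
})

test_that("block null is exhaustive for small designs and reproducible", {
  dat <- generate_dataset(sim_params(d = 20, K = 4, N = 10, sigma_S = 0.6,
                                     seed = 21))
  null <- block_permutation_null(dat, "mean_diff_lda", cv_scheme(), n_perm = 100,
                                 seed = 5)
  expect_true(null$exhaustive)
  expect_equal(null$n_draws, 18L)
  again <- block_permutation_null(dat, "mean_diff_lda", cv_scheme(), n_perm = 100,
                                  seed = 5)
  expect_identical(null$ccrs, again$ccrs)
  expect_true(all(null$ccrs >= 0 & null$ccrs <= 1))
})

test_that("block null retains the subclass inflation that trial null removes", {
  dat <- generate_dataset(sim_params(d = 50, K = 4, N = 15, sigma_C = 0,
                                     sigma_S = 0.8, seed = 31))
  block <- block_permutation_null(dat, "mean_diff_lda", cv_scheme(), n_perm = 18,
                                  seed = 1)
  trial <- trial_permutation_null(dat, "mean_diff_lda", cv_scheme(), n_perm = 99,
                                  seed = 1)
  expect_gt(mean(block$ccrs), 0.55)        # inflated null mean
  expect_lt(abs(mean(trial$ccrs) - 0.5), 0.05)
  expect_gt(mean(block$ccrs), mean(trial$ccrs))

  flat <- generate_dataset(sim_params(d = 50, K = 4, N = 15, sigma_C = 0,
                                      sigma_S = 0, seed = 32))
  b0 <- block_permutation_null(flat, "mean_diff_lda", cv_scheme(), n_perm = 18,
                               seed = 2)
  t0 <- trial_permutation_null(flat, "mean_diff_lda", cv_scheme(), n_perm = 99,
                               seed = 2)
  expect_lt(abs(mean(b0$ccrs) - 0.5), 0.05)
  expect_lt(abs(mean(b0$ccrs) - mean(t0$ccrs)), 0.05)
})

test_that("unbalanced or odd designs are rejected for block permutation", {
  dat <- generate_dataset(sim_params(d = 2, K = 3, N = 4, sigma_S = 0.3,
                                     seed = 1))
  expect_error(block_permutation_null(dat, "mean_diff_lda", cv_scheme()), "even")
  lop <- nested_data(matrix(rnorm(20), 10, 2),
                     c(rep(1L, 6), rep(2L, 4)),
                     c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  expect_error(block_permutation_null(lop, "mean_diff_lda", cv_scheme()), "equal number")
})

test_that("p-values follow the add-one and exhaustive conventions", {
  null999 <- nestedmvpa:::new_null_distribution(seq(0.3, 0.6, length.out = 999),
                                                "trial_wise", FALSE, 1)
  expect_equal(p_value(0.9, null999), 1 / 1000)     # above all draws
  expect_equal(p_value(0.1, null999), 1)            # below all draws
  null1000 <- nestedmvpa:::new_null_distribution(seq(0, 1, length.out = 1000),
                                                 "trial_wise", FALSE, 1)
  expect_lt(abs(p_value(stats::median(null1000$ccrs), null1000) - 0.5), 0.01)
  ex <- nestedmvpa:::new_null_distribution(seq(0.4, 0.7, length.out = 18),
                                           "subclass_wise_balanced", TRUE, 1)
  expect_equal(p_value(0.9, ex), 1 / 18)            # floored at one outcome
  expect_equal(p_value(0.55, ex), sum(ex$ccrs >= 0.55) / 18)
})

test_that("group-level null matches the exhaustive product-space oracle", {
  set.seed(8)
  nulls <- lapply(1:5, function(i)
    nestedmvpa:::new_null_distribution(round(runif(4, 0.4, 0.8), 3),
                                       "subclass_wise_balanced", FALSE, i))
  observed <- c(0.62, 0.58, 0.71, 0.55, 0.66)
  res <- group_null(nulls, observed, n_resample = 40000, seed = 99)
  # exact tail probability over the 4^5 product space
  grids <- expand.grid(lapply(nulls, function(x) x$ccrs))
  exact <- mean(rowMeans(as.matrix(grids)) >= mean(observed))
  expect_lt(abs(res$p_value - exact), 0.02)
  expect_equal(res$observed, mean(observed))
})

test_that("group-level null reduces to the single-subject test", {
  set.seed(9)
  nd <- nestedmvpa:::new_null_distribution(runif(200, 0.4, 0.8),
                                           "subclass_wise_balanced", FALSE, 1)
  single <- p_value(0.7, nd)
  grp <- group_null(list(nd), 0.7, n_resample = 20000, seed = 1)
  expect_lt(abs(grp$p_value - single), 0.02)

  degenerate <- lapply(1:3, function(i)
    nestedmvpa:::new_null_distribution(rep(0.5, 10), "trial_wise", FALSE, i))
  res <- group_null(degenerate, rep(0.6, 3), n_resample = 500, seed = 2)
  expect_equal(res$p_value, 1 / 501)
  expect_error(group_null(list(), numeric(0)), "at least one")
})
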