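test_that("generator respects design sizes, nesting and seed determinism", {
  p <- sim_params(d = 100, K = 10, N = 12, sigma_C = 0, sigma_S = 0.3,
                  sigma_W = 1, seed = 11)
  dat <- generate_dataset(p)
  expect_equal(nrow(dat$features), 240L)
  expect_equal(as.vector(table(dat$class)), c(120L, 120L))
  expect_equal(ncol(dat$features), 100L)

  # identical params (incl. seed) give bit-identical data
  expect_identical(dat$features, generate_dataset(p)$features)

  # nesting invariant across a spread of designs
  for (s in 1:5) {
    q <- sim_params(d = 3, K = sample(2:6, 1), N = sample(2:5, 1),
                    sigma_C = 0.2, sigma_S = 0.5, seed = s)
    g <- generate_dataset(q)
    spans <- tapply(g$class, g$subclass, function(cl) length(unique(cl)))
    expect_true(all(spans == 1L))
    expect_equal(length(unique(g$subclass)), 2L * q$K)
  }
})

test_that("degenerate variances give identical all-zero trials", {
  dat <- generate_dataset(sim_params(d = 4, K = 3, N = 5, sigma_C = 0,
                                     sigma_S = 0, sigma_W = 0, seed = 1))
  expect_true(all(dat$features == 0))
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(sim_params(d = 0, K = 2, N = 2), "positive")
  expect_error(sim_params(d = 2, K = 2, N = 2, sigma_S = -1), ">= 0")
  expect_error(nested_data(matrix(0, 4, 2), c(1, 1, 2, 2), c(1, 2, 2, 3)),
               "nesting")
  expect_error(nested_data(matrix(0, 4, 2), c(1, 1, 1, 1), c(1, 1, 2, 2)),
               "both classes")
})

test_that("icc arithmetic matches the variance-ratio definition", {
  expect_identical(icc(0, 1), 0)
  expect_identical(icc(1, 1), 0.5)
  # sigma_S^2 / (sigma_S^2 + 1) = 0.1  =>  sigma_S^2 = 1/9
  expect_equal(icc(sqrt(1 / 9), 1), 0.1)
  expect_error(icc(0, 0), "undefined")
  expect_error(icc(-1, 1), ">= 0")
})

test_that("collapsing two nested levels adds variances", {
  expect_equal(collapse_levels(0, 3), 3)
  expect_equal(collapse_levels(3, 4), 5)

  # two-level generative model vs collapsed one-level model: pooled
  # subclass-centroid variance estimates agree (moment comparison)
  sigma_a <- 0.4; sigma_b <- 0.3
  J <- 4L; K2 <- 3L; N <- 10L; reps <- 150L
  set.seed(42)
  est_two <- replicate(reps, {
    # level-1 centroids shared by K2 nested level-2 subclasses each
    A <- rep(rnorm(J, 0, sigma_a), each = K2)
    S <- A + rnorm(J * K2, 0, sigma_b)
    x <- rep(S, each = N) + rnorm(J * K2 * N)
    m <- tapply(x, rep(seq_len(J * K2), each = N), mean)
    msw <- mean(tapply(x, rep(seq_len(J * K2), each = N), var))
    var(m) - msw / N
  })
  est_one <- replicate(reps, {
    S <- rnorm(J * K2, 0, collapse_levels(sigma_a, sigma_b))
    x <- rep(S, each = N) + rnorm(J * K2 * N)
    m <- tapply(x, rep(seq_len(J * K2), each = N), mean)
    msw <- mean(tapply(x, rep(seq_len(J * K2), each = N), var))
    var(m) - msw / N
  })
  nominal <- sigma_a^2 + sigma_b^2
  expect_lt(abs(mean(est_two) - mean(est_one)),
            3 * sqrt(var(est_two) / reps + var(est_one) / reps))
  expect_lt(abs(mean(est_one) - nominal) / nominal, 0.15)
})

test_that("pooled moment estimates recover the generative variances", {
  reps <- 200L
  s2 <- w2 <- c2 <- numeric(reps)
  d <- 5L; K <- 10L; N <- 12L
  for (r in seq_len(reps)) {
    dat <- generate_dataset(sim_params(d = d, K = K, N = N, sigma_C = 0.5,
                                       sigma_S = 0.5, sigma_W = 1,
                                       seed = 500 + r))
    est <- estimate_icc(dat)
    s2[r] <- est$sigma_S2; w2[r] <- est$sigma_W2
    m1 <- colMeans(dat$features[dat$class == 1L, , drop = FALSE])
    m2 <- colMeans(dat$features[dat$class == 2L, , drop = FALSE])
    c2[r] <- mean((m1 - m2)^2) / 2 - est$sigma_S2 / K - est$sigma_W2 / (K * N)
  }
  expect_lt(abs(mean(s2) - 0.25) / 0.25, 0.10)   # sigma_S^2
  expect_lt(abs(mean(w2) - 1.00) / 1.00, 0.10)   # sigma_W^2
  expect_lt(abs(mean(c2) - 0.25) / 0.25, 0.10)   # sigma_C^2
})

test_that("moment ICC estimator is consistent and handles the extremes", {
  big <- generate_dataset(sim_params(d = 10, K = 20, N = 30, sigma_S = 1,
                                     sigma_W = 1, seed = 9))
  expect_lt(abs(estimate_icc(big)$icc - 0.5), 0.05)

  none <- generate_dataset(sim_params(d = 10, K = 10, N = 12, sigma_S = 0,
                                      seed = 10))
  expect_lt(estimate_icc(none)$icc, 0.05)

  pure <- generate_dataset(sim_params(d = 5, K = 6, N = 8, sigma_S = 1,
                                      sigma_W = 0, seed = 11))
  expect_equal(estimate_icc(pure)$icc, 1)

  single_trial <- nested_data(matrix(rnorm(8), 4, 2), c(1, 1, 2, 2),
                              c(1, 2, 3, 4))
  expect_error(estimate_icc(single_trial), "single-trial")
})

test_that("dataset files round-trip and the loader validates nesting", {
  dat <- generate_dataset(sim_params(d = 3, K = 2, N = 4, sigma_S = 0.5,
                                     seed = 3))
  f <- tempfile(fileext = ".csv")
  write_dataset(dat, f)
  back <- read_dataset(f)
  expect_equal(back$features, dat$features, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_identical(back$class, dat$class)
  expect_identical(back$subclass, dat$subclass)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("trial_id,class,subclass,f1",
               "1,1,7,0.1", "2,2,7,0.2", "3,1,8,0.3", "4,2,9,0.4"), bad)
  expect_error(read_dataset(bad), "nesting")
})

test_that("simulation parameters serialise through the config format", {
  p <- sim_params(d = 20, K = 6, N = 10, sigma_C = 0.1, sigma_S = 0.4,
                  sigma_W = 1, seed = 77)
  f <- tempfile(fileext = ".yaml")
  write_config(p, f)
  q <- sim_params_from_config(read_config(f))
  expect_equal(unclass(q), unclass(p))
})
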