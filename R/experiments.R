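#' Specification of a simulation sweep
#'
#' Defines the grid and scale of the Monte-Carlo experiments: the class- and
#' subclass-variance grids (per-dimension standard deviations `sigma_C`,
#' `sigma_S`), dimensionality, subclasses per class, trials per class,
#' repetitions per cell, significance level, classifier, cross-validation
#' scheme and seed. Defaults follow the reference simulation design —
#' standard-deviation grid `0, 0.1, ..., 0.6`, unit trial noise, 120 trials
#' per class — at a reduced number of repetitions suitable for interactive
#' runs; raise `n_reps` (and `n_perm`) for publication-scale estimates.
#'
#' @param sigma_C_grid,sigma_S_grid Numeric grids of non-negative standard
#'   deviations.
#' @param d Dimensionality (reference design: 10 or 100).
#' @param K Subclasses per class (reference design: 2 or 10).
#' @param trials_per_class Trials per class; must be divisible by `K`
#'   (default 120).
#' @param sigma_W Within-subclass standard deviation (default 1).
#' @param n_reps Simulated datasets per grid cell (default 500).
#' @param n_perm Permutation draws per dataset for per-dataset nulls
#'   (default 200).
#' @param alpha Significance level (default 0.05).
#' @param classifier `"mean_diff_lda"` or `"linear_svm"`.
#' @param cv A [cv_scheme()] (default stratified 2-fold).
#' @param cost SVM cost (default 1).
#' @param seed Master seed; every dataset and permutation seed in the sweep
#'   is derived from it, so sweep outputs are reproducible bit for bit.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(sigma_C_grid = seq(0, 0.6, by = 0.1),
                       sigma_S_grid = seq(0, 0.6, by = 0.1),
                       d = 100, K = 10, trials_per_class = 120,
                       sigma_W = 1, n_reps = 500, n_perm = 200,
                       alpha = 0.05,
                       classifier = c("mean_diff_lda", "linear_svm"),
                       cv = cv_scheme(), cost = 1, seed = 1) {
  classifier <- match.arg(classifier)
  if (any(sigma_C_grid < 0) || any(sigma_S_grid < 0))
    stop("grid values must be >= 0")
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (trials_per_class %% K != 0)
    stop("'trials_per_class' must be divisible by 'K'")
  structure(list(sigma_C_grid = sigma_C_grid, sigma_S_grid = sigma_S_grid,
                 d = as.integer(d), K = as.integer(K),
                 trials_per_class = as.integer(trials_per_class),
                 sigma_W = sigma_W, n_reps = as.integer(n_reps),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 classifier = classifier, cv = cv, cost = cost,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

# Deterministic stream of sub-seeds below 2^31 derived from a master seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# CCRs of n_reps freshly simulated datasets for one (sigma_C, sigma_S) cell.
cell_ccrs <- function(spec, sigma_C, sigma_S, seeds) {
  N <- spec$trials_per_class %/% spec$K
  vapply(seq_len(spec$n_reps), function(r) {
    dat <- generate_dataset(sim_params(d = spec$d, K = spec$K, N = N,
                                       sigma_C = sigma_C, sigma_S = sigma_S,
                                       sigma_W = spec$sigma_W,
                                       seed = seeds[r]))
    cvi <- spec$cv; cvi$seed <- seeds[r] %% (.Machine$integer.max - 2L) + 1L
    cross_validate(dat, spec$classifier, cvi, cost = spec$cost)$ccr
  }, numeric(1))
}

#' Mean CCR surface over the class/subclass variance grid
#'
#' For every cell of the `(sigma_C, sigma_S)` grid, simulates `n_reps`
#' datasets, cross-validates the chosen classifier on each, and records the
#' mean and standard deviation of the CCR. At `sigma_C = 0` the mean CCR
#' traces the pure subclass-driven inflation: it grows with `sigma_S`, is
#' larger for fewer subclasses, and larger in higher dimension.
#'
#' @param spec A [sweep_spec()].
#' @return A data frame with columns `sigma_C`, `sigma_S`, `d`, `K`,
#'   `mean_ccr`, `sd_ccr`, `n_reps`.
#' @export
run_ccr_surface <- function(spec) {
  if (!inherits(spec, "sweep_spec")) stop("'spec' must be a sweep_spec object")
  grid <- expand.grid(sigma_C = spec$sigma_C_grid, sigma_S = spec$sigma_S_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cell_seeds <- matrix(derive_seeds(spec$seed, nrow(grid) * spec$n_reps),
                       nrow = nrow(grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ccrs <- cell_ccrs(spec, grid$sigma_C[i], grid$sigma_S[i], cell_seeds[i, ])
    data.frame(sigma_C = grid$sigma_C[i], sigma_S = grid$sigma_S[i],
               d = spec$d, K = spec$K,
               mean_ccr = mean(ccrs), sd_ccr = stats::sd(ccrs),
               n_reps = spec$n_reps)
  })
  do.call(rbind, res)
}

#' Theory-versus-simulation comparison table
#'
#' Compares the closed-form expected CCR ([expected_ccr_closed_form()]) and the
#' quadrature form ([expected_ccr_integral()], at zero signal) with the
#' Monte-Carlo oracle ([mc_ccr_oracle()]) over a grid of total subclass
#' counts and intraclass correlations.
#'
#' @param total_subclasses Total numbers of subclasses (both classes
#'   combined); each must be even. Default `c(4, 8, 16)`.
#' @param icc_grid Intraclass correlations in `[0, 1)`.
#' @param n_reps Monte-Carlo repetitions per cell (default 2000).
#' @param N Trials per subclass for the oracle (default 100).
#' @param seed Master seed.
#' @return A data frame with columns `total_subclasses`, `K`, `icc`,
#'   `ccr_closed_form`, `ccr_integral`, `mc_mean`, `mc_stderr`, `abs_diff`
#'   (|closed form - Monte Carlo|).
#' @export
run_theory_validation <- function(total_subclasses = c(4, 8, 16),
                                  icc_grid = seq(0.1, 0.7, by = 0.2),
                                  n_reps = 2000, N = 100, seed = 1) {
  if (any(total_subclasses %% 2 != 0))
    stop("'total_subclasses' must be even (equal split across two classes)")
  grid <- expand.grid(total = total_subclasses, icc = icc_grid,
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    K <- grid$total[i] %/% 2L
    tp <- theory_params(K = K, icc = grid$icc[i])
    closed <- expected_ccr_closed_form(K, grid$icc[i])
    quadr <- expected_ccr_integral(tp)
    mc <- mc_ccr_oracle(tp, N = N, n_reps = n_reps, seed = seeds[i])
    data.frame(total_subclasses = grid$total[i], K = K, icc = grid$icc[i],
               ccr_closed_form = closed, ccr_integral = quadr,
               mc_mean = mc$mean_ccr, mc_stderr = mc$stderr,
               abs_diff = abs(closed - mc$mean_ccr))
  })
  do.call(rbind, res)
}

#' Significance bias of permutation schemes over the variance grid
#'
#' For every `(sigma_C, sigma_S)` cell, simulates `n_reps` datasets, tests
#' each for an above-chance CCR with the chosen permutation scheme, and
#' records the proportion `P` of significant results at level `alpha`. The
#' significance bias of a cell is the excess proportion relative to the
#' matched cell without subclass variance,
#' \deqn{SB = P_{\sigma_S \ne 0} - P_{\sigma_S = 0},}
#' computed against the `sigma_S = 0` entry of the same `sigma_C` row, so
#' `SB = 0` identically on the `sigma_S = 0` column. A trial-wise scheme
#' shows `SB > 0` (spurious significance) as soon as subclass variance is
#' present with little or no class effect; the balanced subclass-wise scheme
#' stays near zero, turning mildly conservative only when subclass variance
#' dominates a small class effect.
#'
#' Two null constructions are supported. `"per_dataset"` (the procedure one
#' would use on real data) builds a permutation null from each simulated
#' dataset via [trial_permutation_null()] or [block_permutation_null()] with
#' `spec$n_perm` draws. `"population"` instead pools the observed CCRs of
#' `n_reps` reference datasets simulated under the scheme's null — no class
#' and no subclass effect for the trial-wise scheme; no class effect but the
#' cell's own subclass variance for the block-wise scheme — and compares each
#' test dataset's CCR against that pool, which reproduces the
#' population-level analysis of the significance-bias maps at a fraction of
#' the cost.
#'
#' @param spec A [sweep_spec()].
#' @param scheme `"trial_wise"` or `"subclass_wise_balanced"`.
#' @param null_mode `"per_dataset"` (default) or `"population"`.
#' @return An object of class `"sb_result"`: a data frame with columns
#'   `sigma_C`, `sigma_S`, `P`, `SB` plus attributes `scheme`, `null_mode`,
#'   `alpha`.
#' @export
run_significance_bias <- function(spec,
                                  scheme = c("trial_wise",
                                             "subclass_wise_balanced"),
                                  null_mode = c("per_dataset", "population")) {
  if (!inherits(spec, "sweep_spec")) stop("'spec' must be a sweep_spec object")
  scheme <- match.arg(scheme)
  null_mode <- match.arg(null_mode)
  grid <- expand.grid(sigma_C = spec$sigma_C_grid, sigma_S = spec$sigma_S_grid,
                      KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(grid)
  seeds <- matrix(derive_seeds(spec$seed, n_cells * spec$n_reps), nrow = n_cells)

  if (null_mode == "population") {
    # One reference pool per distinct null condition.
    null_sigmas <- if (scheme == "trial_wise") 0 else unique(grid$sigma_S)
    pool_seeds <- matrix(derive_seeds(spec$seed + 1L,
                                      length(null_sigmas) * spec$n_reps),
                         nrow = length(null_sigmas))
    pools <- lapply(seq_along(null_sigmas), function(j)
      new_null_distribution(
        cell_ccrs(spec, sigma_C = 0, sigma_S = null_sigmas[j], pool_seeds[j, ]),
        scheme, FALSE, spec$seed))
    names(pools) <- as.character(null_sigmas)
    P <- vapply(seq_len(n_cells), function(i) {
      pool <- if (scheme == "trial_wise") pools[["0"]] else
        pools[[as.character(grid$sigma_S[i])]]
      ccrs <- cell_ccrs(spec, grid$sigma_C[i], grid$sigma_S[i], seeds[i, ])
      mean(vapply(ccrs, p_value, numeric(1), null = pool) <= spec$alpha)
    }, numeric(1))
  } else {
    N <- spec$trials_per_class %/% spec$K
    P <- vapply(seq_len(n_cells), function(i) {
      rej <- vapply(seq_len(spec$n_reps), function(r) {
        s <- seeds[i, r]
        dat <- generate_dataset(sim_params(d = spec$d, K = spec$K, N = N,
                                           sigma_C = grid$sigma_C[i],
                                           sigma_S = grid$sigma_S[i],
                                           sigma_W = spec$sigma_W, seed = s))
        cvi <- spec$cv; cvi$seed <- s %% (.Machine$integer.max - 2L) + 1L
        obs <- cross_validate(dat, spec$classifier, cvi, cost = spec$cost)$ccr
        null <- if (scheme == "trial_wise")
          trial_permutation_null(dat, spec$classifier, spec$cv,
                                 n_perm = spec$n_perm, seed = s,
                                 cost = spec$cost)
        else
          block_permutation_null(dat, spec$classifier, spec$cv,
                                 n_perm = spec$n_perm, seed = s,
                                 cost = spec$cost)
        p_value(obs, null) <= spec$alpha
      }, logical(1))
      mean(rej)
    }, numeric(1))
  }

  if (!0 %in% grid$sigma_S)
    stop("the sigma_S grid must contain 0 to define the significance bias")
  out <- data.frame(sigma_C = grid$sigma_C, sigma_S = grid$sigma_S, P = P)
  base_rows <- which(out$sigma_S == 0)
  out$SB <- out$P - out$P[base_rows[match(out$sigma_C, out$sigma_C[base_rows])]]
  attr(out, "scheme") <- scheme
  attr(out, "null_mode") <- null_mode
  attr(out, "alpha") <- spec$alpha
  class(out) <- c("sb_result", class(out))
  out
}
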