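#' Simulation parameters for the multilevel trial model
#'
#' Bundles the generative parameters of the nested two-class Gaussian model
#' \deqn{y_{ijk} = C_i + S_{ij} + \epsilon_{ijk}}
#' in which every trial is the sum of a class centroid \eqn{C_i}, the centroid
#' offset \eqn{S_{ij}} of the subclass it belongs to, and trial noise
#' \eqn{\epsilon_{ijk}}. All three components are isotropic Gaussians with
#' per-dimension standard deviations `sigma_C`, `sigma_S` and `sigma_W`.
#' The design is always two-class and balanced: `K` subclasses per class and
#' `N` trials per subclass, so `K * N` trials per class.
#'
#' @param d Dimensionality of the feature space (>= 1).
#' @param K Number of subclasses per class (>= 1). Balanced block permutation
#'   additionally requires an even `K`, but that is enforced only when a
#'   permutation scheme is requested, not here.
#' @param N Number of trials per subclass (>= 1).
#' @param sigma_C Standard deviation of the class centroids (per dimension).
#' @param sigma_S Standard deviation of the subclass centroids around their
#'   class centroid (per dimension).
#' @param sigma_W Within-subclass (trial noise) standard deviation.
#' @param seed Optional integer seed; when set, [generate_dataset()] is fully
#'   deterministic.
#'
#' @return An object of class `"sim_params"`.
#' @seealso [generate_dataset()], [icc()]
#' @export
#' @examples
#' sim_params(d = 10, K = 4, N = 30, sigma_S = 0.4, seed = 1)
sim_params <- function(d, K, N, sigma_C = 0, sigma_S = 0, sigma_W = 1,
                       seed = NULL) {
  stopifnot(length(d) == 1L, length(K) == 1L, length(N) == 1L)
  d <- as.integer(d); K <- as.integer(K); N <- as.integer(N)
  if (is.na(d) || d < 1L) stop("'d' must be a positive integer")
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  if (is.na(N) || N < 1L) stop("'N' must be a positive integer")
  for (s in c(sigma_C = sigma_C, sigma_S = sigma_S, sigma_W = sigma_W)) {
    if (!is.finite(s) || s < 0) stop("all sigmas must be finite and >= 0")
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(d = d, K = K, N = N,
         sigma_C = sigma_C, sigma_S = sigma_S, sigma_W = sigma_W,
         n_classes = 2L, seed = seed),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Multilevel simulation parameters\n")
  cat(sprintf("  d = %d, K = %d subclasses/class, N = %d trials/subclass\n",
              x$d, x$K, x$N))
  cat(sprintf("  sigma_C = %g, sigma_S = %g, sigma_W = %g, seed = %s\n",
              x$sigma_C, x$sigma_S, x$sigma_W,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Construct a labelled nested dataset
#'
#' Low-level constructor that validates the nesting invariant: every subclass
#' identifier must map to exactly one class, both classes must be present, and
#' label vectors must match the feature matrix rows.
#'
#' @param features Numeric matrix, trials in rows.
#' @param class_labels Integer vector of class labels in `{1, 2}`.
#' @param subclass_labels Integer vector of subclass identifiers, globally
#'   unique across classes (a subclass never spans classes).
#' @param params Optional [sim_params()] provenance.
#' @param validate Check the nesting invariant (default `TRUE`).
#'
#' @return An object of class `"nested_data"` with elements `features`,
#'   `class`, `subclass` and `params`.
#' @export
nested_data <- function(features, class_labels, subclass_labels,
                        params = NULL, validate = TRUE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  class_labels <- as.integer(class_labels)
  subclass_labels <- as.integer(subclass_labels)
  n <- nrow(features)
  if (length(class_labels) != n || length(subclass_labels) != n)
    stop("label vectors must have one entry per feature-matrix row")
  if (!all(class_labels %in% c(1L, 2L)))
    stop("class labels must be 1 or 2")
  if (validate) {
    if (length(unique(class_labels)) < 2L)
      stop("both classes must be present")
    per_sub <- tapply(class_labels, subclass_labels,
                      function(cl) length(unique(cl)))
    if (any(per_sub > 1L))
      stop("nesting violated: a subclass spans both classes")
  }
  structure(list(features = features, class = class_labels,
                 subclass = subclass_labels, params = params),
            class = "nested_data")
}

#' @export
print.nested_data <- function(x, ...) {
  cat(sprintf("Nested dataset: %d trials x %d features\n",
              nrow(x$features), ncol(x$features)))
  for (cl in sort(unique(x$class))) {
    idx <- x$class == cl
    cat(sprintf("  class %d: %d trials in %d subclasses\n",
                cl, sum(idx), length(unique(x$subclass[idx]))))
  }
  invisible(x)
}

#' Generate a dataset from the multilevel Gaussian model
#'
#' Draws one realisation of \eqn{y_{ijk} = C_i + S_{ij} + \epsilon_{ijk}}:
#' class centroids \eqn{C_i \sim N(0, \sigma_C^2 I_d)}, subclass centroids
#' \eqn{S_{ij} \sim N(0, \sigma_S^2 I_d)} and trial noise
#' \eqn{\epsilon_{ijk} \sim N(0, \sigma_W^2 I_d)}. Subclass identifiers are
#' globally unique (`1..K` for class 1, `K+1..2K` for class 2), so the design
#' is nested by construction.
#'
#' Draws are consumed in a fixed, documented order so seeds are portable:
#' first the two class centroids (class 1 then class 2, `d` values each), then
#' the `K` subclass centroids of class 1 row by row, then those of class 2,
#' then the trial noise of class 1 (subclass by subclass, trial by trial) and
#' finally the trial noise of class 2.
#'
#' @param params A [sim_params()] object.
#' @return A [nested_data()] object with `2 * K * N` trials.
#' @export
#' @examples
#' dat <- generate_dataset(sim_params(d = 10, K = 10, N = 12,
#'                                    sigma_S = 0.3, seed = 7))
#' dat
generate_dataset <- function(params) {
  if (!inherits(params, "sim_params")) stop("'params' must be a sim_params object")
  if (!is.null(params$seed)) set.seed(params$seed)
  d <- params$d; K <- params$K; N <- params$N
  C <- matrix(stats::rnorm(2L * d, 0, params$sigma_C), nrow = 2L, byrow = TRUE)
  S1 <- matrix(stats::rnorm(K * d, 0, params$sigma_S), nrow = K, byrow = TRUE)
  S2 <- matrix(stats::rnorm(K * d, 0, params$sigma_S), nrow = K, byrow = TRUE)
  E1 <- matrix(stats::rnorm(K * N * d, 0, params$sigma_W), nrow = K * N, byrow = TRUE)
  E2 <- matrix(stats::rnorm(K * N * d, 0, params$sigma_W), nrow = K * N, byrow = TRUE)
  sub_idx <- rep(seq_len(K), each = N)
  x1 <- C[rep(1L, K * N), , drop = FALSE] + S1[sub_idx, , drop = FALSE] + E1
  x2 <- C[rep(2L, K * N), , drop = FALSE] + S2[sub_idx, , drop = FALSE] + E2
  nested_data(
    features = rbind(x1, x2),
    class_labels = rep(c(1L, 2L), each = K * N),
    subclass_labels = c(sub_idx, K + sub_idx),
    params = params,
    validate = FALSE)
}

#' Intraclass correlation from variance components
#'
#' The intraclass correlation of the nested model is the fraction of
#' class-unrelated variance attributable to subclass membership,
#' \eqn{ICC = \sigma_S^2 / (\sigma_S^2 + \sigma_W^2)}.
#'
#' @param sigma_S Subclass-centroid standard deviation (>= 0).
#' @param sigma_W Within-subclass standard deviation (>= 0). At least one of
#'   the two must be positive.
#' @return The ICC, a proportion in `[0, 1]`.
#' @export
#' @examples
#' icc(0.5, 1)      # 0.2
#' icc(1, 1)        # 0.5
icc <- function(sigma_S, sigma_W) {
  if (any(sigma_S < 0) || any(sigma_W < 0)) stop("sigmas must be >= 0")
  tot <- sigma_S^2 + sigma_W^2
  if (any(tot == 0)) stop("ICC undefined: sigma_S and sigma_W are both zero")
  sigma_S^2 / tot
}

#' Collapse two nested subclass levels into one
#'
#' A design with two levels of nested subclasses,
#' \eqn{y = C_i + S_{ij} + S_{ijk} + \epsilon}, is distributionally equivalent
#' to a single-level design whose subclass component has variance equal to the
#' sum of the two level variances. This helper returns the collapsed standard
#' deviation \eqn{\sqrt{\sigma_1^2 + \sigma_2^2}}, which can be fed straight
#' into [sim_params()] as `sigma_S`.
#'
#' @param sigma_level1,sigma_level2 Standard deviations of the two nested
#'   levels (>= 0).
#' @return The collapsed standard deviation.
#' @export
#' @examples
#' collapse_levels(3, 4)   # 5
collapse_levels <- function(sigma_level1, sigma_level2) {
  if (any(sigma_level1 < 0) || any(sigma_level2 < 0)) stop("sigmas must be >= 0")
  sqrt(sigma_level1^2 + sigma_level2^2)
}

#' Moment-based ICC estimate from a nested dataset
#'
#' One-way random-effects variance decomposition computed per class and per
#' feature dimension, then pooled: the within-subclass mean square estimates
#' \eqn{\sigma_W^2} and the between-subclass mean square, corrected for the
#' within component and the per-subclass trial count, estimates
#' \eqn{\sigma_S^2}. Negative subclass-variance estimates are truncated at
#' zero and the resulting ICC is clipped to `[0, 1]`.
#'
#' @param data A [nested_data()] object with at least 2 subclasses per class
#'   and at least 2 trials in every subclass.
#' @return List with `icc`, `sigma_S2` and `sigma_W2` (pooled estimates).
#' @export
estimate_icc <- function(data) {
  if (!inherits(data, "nested_data")) stop("'data' must be a nested_data object")
  sw2 <- 0; sw_df <- 0
  ss2_terms <- numeric(0)
  for (cl in sort(unique(data$class))) {
    idx <- which(data$class == cl)
    X <- data$features[idx, , drop = FALSE]
    g <- factor(data$subclass[idx])
    K <- nlevels(g)
    if (K < 2L) stop("need >= 2 subclasses per class to estimate the ICC")
    nj <- as.vector(table(g))
    if (any(nj < 2L)) stop("single-trial subclasses: within-subclass variance undefined")
    n_tot <- length(idx)
    M <- rowsum(X, g) / nj                       # subclass means, K x d
    SSW <- colSums((X - M[g, , drop = FALSE])^2)
    MSW <- SSW / (n_tot - K)
    grand <- colMeans(X)
    SSB <- colSums(nj * sweep(M, 2L, grand)^2)
    MSB <- SSB / (K - 1)
    n0 <- (n_tot - sum(nj^2) / n_tot) / (K - 1)  # balanced: n0 = N
    sw2 <- sw2 + sum(MSW); sw_df <- sw_df + length(MSW)
    ss2_terms <- c(ss2_terms, (MSB - MSW) / n0)
  }
  sigma_W2 <- sw2 / sw_df
  sigma_S2 <- max(mean(ss2_terms), 0)
  list(icc = min(max(sigma_S2 / (sigma_S2 + sigma_W2), 0), 1),
       sigma_S2 = sigma_S2, sigma_W2 = sigma_W2)
}

#' Two-dimensional toy dataset with visually separated subclasses
#'
#' A small demonstration fixture: two classes with identical centroids
#' (no class effect) and `K` well-separated subclasses each, in two
#' dimensions. Defaults (`sigma_S = 1`, `sigma_W = 0.2`) place the subclass
#' clusters far apart relative to trial noise so that the subclass-driven
#' inflation of cross-validated accuracy is plainly visible. The fixture is a
#' demonstration of the machinery, not a calibrated reference.
#'
#' @param K Subclasses per class (default 4).
#' @param N Trials per subclass (default 10).
#' @param sigma_S,sigma_W Subclass and trial-noise standard deviations.
#' @param seed RNG seed.
#' @return A [nested_data()] object.
#' @export
toy_subclass_data <- function(K = 4, N = 10, sigma_S = 1, sigma_W = 0.2,
                              seed = 1) {
  generate_dataset(sim_params(d = 2, K = K, N = N, sigma_C = 0,
                              sigma_S = sigma_S, sigma_W = sigma_W,
                              seed = seed))
}
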