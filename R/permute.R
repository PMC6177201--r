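#' Number of distinct balanced subclass-to-class reassignments
#'
#' A balanced block (subclass-wise) relabelling builds two new classes, each
#' receiving exactly `K/2` subclasses from each of the two original classes.
#' There are \eqn{\binom{K}{K/2}^2 / 2} distinct such reassignments: the
#' factor 1/2 removes the duplicate obtained by swapping the two new class
#' labels. With 4 subclasses per class this gives 18; with 10, 31752. Six
#' subclasses per class is the smallest design whose count exceeds 100, i.e.
#' the smallest design that supports permutation p-values down to 0.01.
#'
#' @param K Number of subclasses per class; must be even.
#' @return The number of distinct balanced assignments (a double; exact for
#'   all practically enumerable `K`).
#' @export
#' @examples
#' count_balanced_assignments(4)   # 18
#' count_balanced_assignments(10)  # 31752
count_balanced_assignments <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("'K' must be an integer >= 2")
  if (K %% 2L != 0L)
    stop("balanced assignment undefined for odd 'K': each new class needs K/2 subclasses from each original class")
  choose(K, K %/% 2L)^2 / 2
}

# Lexicographic unranking of the r-th k-subset of 1..n (r in 1..choose(n,k)).
unrank_combination <- function(n, k, r) {
  out <- integer(k); x <- 1L
  for (i in seq_len(k)) {
    repeat {
      c_rest <- choose(n - x, k - i)
      if (r <= c_rest) break
      r <- r - c_rest; x <- x + 1L
    }
    out[i] <- x; x <- x + 1L
  }
  out
}

# Build a balanced_assignment from subset indices. a1/b1 index into 1..K and
# denote the subclasses (of original class A resp. B) placed in new class 1.
new_assignment <- function(a1, b1, K) {
  structure(list(a1 = as.integer(a1), b1 = as.integer(b1), K = as.integer(K)),
            class = "balanced_assignment")
}

#' Enumerate all distinct balanced assignments
#'
#' Yields every distinct balanced reassignment exactly once. Label-swap
#' duplicates are removed constructively by canonicalisation: new class 1 is
#' required to contain the first subclass of original class A, which realises
#' the factor 1/2 in [count_balanced_assignments()].
#'
#' @param K Number of subclasses per class; even.
#' @param max_enumerate Safety cap on the number of assignments (default
#'   `1e5`); above the cap an error instructs the caller to sample instead
#'   (see [sample_balanced_assignments()]).
#' @return A list of `"balanced_assignment"` objects, each with elements
#'   `a1`, `b1` (indices in `1..K` of the class-A and class-B subclasses
#'   placed in new class 1) and `K`.
#' @export
#' @examples
#' length(enumerate_balanced_assignments(4))  # 18
enumerate_balanced_assignments <- function(K, max_enumerate = 1e5) {
  n_total <- count_balanced_assignments(K)
  if (n_total > max_enumerate)
    stop(sprintf("%.0f assignments exceed the enumeration cap (%g); use sample_balanced_assignments()",
                 n_total, max_enumerate))
  half <- K %/% 2L
  a_sets <- if (half == 1L) matrix(1L, nrow = 1L) else
    rbind(1L, utils::combn(2:K, half - 1L))        # all half-subsets containing 1
  b_sets <- utils::combn(seq_len(K), half)
  out <- vector("list", ncol(a_sets) * ncol(b_sets))
  i <- 0L
  for (ia in seq_len(ncol(a_sets))) {
    for (ib in seq_len(ncol(b_sets))) {
      i <- i + 1L
      out[[i]] <- new_assignment(a_sets[, ia], b_sets[, ib], K)
    }
  }
  out
}

#' Sample balanced assignments uniformly without replacement
#'
#' When the total count is at most `n`, the full enumeration is returned
#' (an exhaustive null); otherwise `n` distinct assignments are drawn
#' uniformly without replacement by sampling ranks and unranking the two
#' half-subsets combinatorially, so arbitrarily large designs need no
#' explicit enumeration.
#'
#' @param K Number of subclasses per class; even.
#' @param n Number of assignments requested.
#' @param seed Optional RNG seed.
#' @return List of `"balanced_assignment"` objects with attribute
#'   `exhaustive` (`TRUE` when the full enumeration was returned).
#' @export
sample_balanced_assignments <- function(K, n, seed = NULL) {
  n_total <- count_balanced_assignments(K)
  if (n >= n_total) {
    out <- enumerate_balanced_assignments(K, max_enumerate = Inf)
    attr(out, "exhaustive") <- TRUE
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  half <- K %/% 2L
  n_b <- choose(K, half)
  ranks <- sample(n_total, n)                   # distinct ranks, 1..n_total
  out <- lapply(ranks, function(r) {
    ia <- (r - 1) %/% n_b + 1
    ib <- (r - 1) %% n_b + 1
    a1 <- if (half == 1L) 1L else c(1L, unrank_combination(K - 1L, half - 1L, ia) + 1L)
    new_assignment(a1, unrank_combination(K, half, ib), K)
  })
  attr(out, "exhaustive") <- FALSE
  out
}

#' Relabel a dataset according to a balanced assignment
#'
#' Rewrites the class labels of all trials so that new class 1 consists of
#' the assignment's chosen subclasses (`K/2` from each original class) and
#' new class 2 of the complement. Subclass memberships are untouched, so the
#' within-subclass dependence structure survives the relabelling.
#'
#' @param data A [nested_data()] object with equally many subclasses per class.
#' @param assignment A `"balanced_assignment"` (see
#'   [enumerate_balanced_assignments()]).
#' @return A relabelled [nested_data()] object.
#' @export
apply_assignment <- function(data, assignment) {
  if (!inherits(assignment, "balanced_assignment"))
    stop("'assignment' must be a balanced_assignment object")
  subs1 <- sort(unique(data$subclass[data$class == 1L]))
  subs2 <- sort(unique(data$subclass[data$class == 2L]))
  K <- assignment$K
  if (length(subs1) != K || length(subs2) != K)
    stop("assignment and data disagree on the number of subclasses per class")
  class1_subs <- c(subs1[assignment$a1], subs2[assignment$b1])
  new_class <- ifelse(data$subclass %in% class1_subs, 1L, 2L)
  nested_data(data$features, new_class, data$subclass,
              params = data$params, validate = FALSE)
}

new_null_distribution <- function(ccrs, scheme, exhaustive, seed) {
  structure(list(ccrs = as.numeric(ccrs), scheme = scheme,
                 n_draws = length(ccrs), exhaustive = isTRUE(exhaustive),
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Permutation null (%s%s): %d draws, mean CCR = %.4f\n",
              x$scheme, if (x$exhaustive) ", exhaustive" else "",
              x$n_draws, mean(x$ccrs)))
  invisible(x)
}

#' Subclass-wise (block) permutation null distribution
#'
#' Builds the null distribution of the CCR under balanced subclass-level
#' relabelling: for each draw, whole subclasses are reassigned to two new
#' classes (exactly `K/2` from each original class per new class), the
#' cross-validated CCR of the relabelled data is computed, and the collection
#' of CCRs forms the null. Because subclasses are never broken up, the null
#' retains the accuracy inflation caused by subclass structure — its mean
#' lies above 50% whenever the subclass variance is positive — and therefore
#' provides the correct reference for the observed CCR.
#'
#' If the total number of distinct assignments is at most `n_perm` the
#' enumeration is used exhaustively; otherwise `n_perm` assignments are drawn
#' uniformly without replacement. The observed (identity) labelling is not a
#' balanced assignment and is never part of the null. Each draw receives a
#' fresh fold split seeded from `seed`, mirroring the seed policy of the
#' observed statistic.
#'
#' @param data A [nested_data()] object with an equal, even number of
#'   subclasses per class.
#' @param classifier `"mean_diff_lda"` or `"linear_svm"`.
#' @param cv A [cv_scheme()].
#' @param n_perm Maximum number of permutation draws (default 1000).
#' @param seed RNG seed for assignment sampling and fold splits.
#' @param cost SVM cost, ignored for `"mean_diff_lda"`.
#' @return A `"null_distribution"` object.
#' @export
block_permutation_null <- function(data, classifier = "mean_diff_lda",
                                   cv = cv_scheme(), n_perm = 1000,
                                   seed = NULL, cost = 1) {
  subs1 <- unique(data$subclass[data$class == 1L])
  subs2 <- unique(data$subclass[data$class == 2L])
  if (length(subs1) != length(subs2))
    stop("block permutation requires an equal number of subclasses per class")
  K <- length(subs1)
  if (K %% 2L != 0L) stop("block permutation requires an even number of subclasses per class")
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  assignments <- sample_balanced_assignments(K, n_perm)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, length(assignments))
  ccrs <- vapply(seq_along(assignments), function(i) {
    perm <- apply_assignment(data, assignments[[i]])
    cvi <- cv; cvi$seed <- fold_seeds[i]
    cross_validate(perm, classifier, cvi, cost = cost)$ccr
  }, numeric(1))
  new_null_distribution(ccrs, "subclass_wise_balanced",
                        attr(assignments, "exhaustive"), seed)
}

#' Trial-wise permutation null distribution
#'
#' The conventional permutation null: each draw shuffles the class labels
#' over all trials (class sizes preserved), ignoring subclass membership, and
#' records the cross-validated CCR. This destroys class-related *and*
#' subclass-related structure, so the null is centred at chance (50%) even
#' when the data contain subclasses — which is exactly why it understates the
#' null CCR, and overstates significance, for nested designs.
#'
#' @inheritParams block_permutation_null
#' @return A `"null_distribution"` object.
#' @export
trial_permutation_null <- function(data, classifier = "mean_diff_lda",
                                   cv = cv_scheme(), n_perm = 1000,
                                   seed = NULL, cost = 1) {
  if (length(unique(data$class)) < 2L) stop("both classes must be present")
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  ccrs <- vapply(seq_len(n_perm), function(i) {
    perm <- nested_data(data$features, sample(data$class), data$subclass,
                        params = data$params, validate = FALSE)
    cvi <- cv; cvi$seed <- fold_seeds[i]
    cross_validate(perm, classifier, cvi, cost = cost)$ccr
  }, numeric(1))
  new_null_distribution(ccrs, "trial_wise", FALSE, seed)
}

#' Permutation p-value
#'
#' For sampled nulls the add-one estimator
#' \eqn{p = (1 + \#\{CCR_{null} \ge CCR_{obs}\}) / (1 + n)} is used, which
#' counts the observed statistic as one realisation and can never return
#' zero. For exhaustive nulls the plain proportion
#' \eqn{\#\{CCR_{null} \ge CCR_{obs}\} / n} is used, floored at `1/n` so the
#' observed arrangement again counts as one attainable outcome.
#'
#' @param observed Observed CCR (scalar in `[0, 1]`).
#' @param null A `"null_distribution"` object.
#' @return A p-value in `(0, 1]`.
#' @export
p_value <- function(observed, null) {
  if (!inherits(null, "null_distribution"))
    stop("'null' must be a null_distribution object")
  if (null$n_draws < 1L) stop("empty null distribution")
  hits <- sum(null$ccrs >= observed)
  if (null$exhaustive) max(hits, 1L) / null$n_draws
  else (1 + hits) / (1 + null$n_draws)
}

#' Group-level permutation test across subjects
#'
#' Small designs admit too few balanced assignments for useful per-subject
#' p-values. The group-level alternative tests the mean observed CCR across
#' subjects against a null distribution formed by repeatedly drawing one CCR
#' from each subject's subclass-level permutation null and averaging the
#' draws.
#'
#' @param per_subject_nulls List of `"null_distribution"` objects, one per
#'   subject (or session).
#' @param observed_ccrs Numeric vector of observed CCRs, same length.
#' @param n_resample Number of resampled group means (default 10000).
#' @param seed Optional RNG seed.
#' @return List with `p_value` (add-one estimator), `observed` (the group
#'   mean CCR) and `null` (a `"null_distribution"` of resampled means).
#' @export
group_null <- function(per_subject_nulls, observed_ccrs, n_resample = 10000,
                       seed = NULL) {
  if (length(per_subject_nulls) == 0L || length(observed_ccrs) == 0L)
    stop("need at least one subject")
  if (length(per_subject_nulls) != length(observed_ccrs))
    stop("one observed CCR per subject null is required")
  ok <- vapply(per_subject_nulls, inherits, logical(1), "null_distribution")
  if (!all(ok)) stop("'per_subject_nulls' must be null_distribution objects")
  if (any(vapply(per_subject_nulls, function(x) x$n_draws, integer(1)) < 1L))
    stop("empty per-subject null distribution")
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(per_subject_nulls,
                  function(nd) sample(nd$ccrs, n_resample, replace = TRUE),
                  numeric(n_resample))
  means <- if (n_resample == 1L) mean(draws) else rowMeans(draws)
  null <- new_null_distribution(means, "group_mean", FALSE, seed)
  obs <- mean(observed_ccrs)
  list(p_value = p_value(obs, null), observed = obs, null = null)
}
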