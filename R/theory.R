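#' Parameters of the chance-level theory
#'
#' Collects the quantities the expected-CCR theory depends on: the number of
#' subclasses per class `K`, the intraclass correlation
#' \eqn{\rho = \sigma_S^2 / \sigma^2} (with \eqn{\sigma^2 = \sigma_S^2 +
#' \sigma_W^2} the total class-unrelated variance), the projected class-mean
#' separation \eqn{\delta = \hat\mu - \hat\nu}, and the total standard
#' deviation \eqn{\sigma}. Two derived quantities are reported:
#' `lambda`, with \eqn{\lambda^2 = \rho / (2(K - \rho))}, the arctangent
#' argument of the zero-signal closed form, and `delta_tilde`, the signal
#' normalised by the null spread of the estimated class-mean difference,
#' \eqn{\tilde\delta = \delta / (\sigma\sqrt{2\rho/K})} (infinite at
#' \eqn{\rho = 0}, where the class-mean difference is noiseless under the
#' model).
#'
#' @param K Subclasses per class (>= 1).
#' @param icc Intraclass correlation in `[0, 1)`.
#' @param delta Class-mean separation along the discriminant axis (same units
#'   as `sigma_total`); default 0 (no class effect).
#' @param sigma_total Total class-unrelated standard deviation (> 0),
#'   default 1.
#' @return An object of class `"theory_params"`.
#' @export
theory_params <- function(K, icc, delta = 0, sigma_total = 1) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("'K' must be a positive integer")
  if (!is.finite(icc) || icc < 0 || icc >= 1)
    stop("'icc' must lie in [0, 1)")
  if (!is.finite(sigma_total) || sigma_total <= 0)
    stop("'sigma_total' must be > 0")
  if (!is.finite(delta)) stop("'delta' must be finite")
  lambda <- sqrt(icc / (2 * (K - icc)))
  delta_tilde <- if (icc > 0) delta / (sigma_total * sqrt(2 * icc / K)) else
    (if (delta == 0) 0 else sign(delta) * Inf)
  structure(list(K = K, icc = icc, delta = delta, sigma_total = sigma_total,
                 lambda = lambda, delta_tilde = delta_tilde),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("Theory parameters: K = %d, ICC = %g, delta = %g, sigma = %g\n",
              x$K, x$icc, x$delta, x$sigma_total))
  cat(sprintf("  lambda = %g, delta_tilde = %g\n", x$lambda, x$delta_tilde))
  invisible(x)
}

#' Closed-form expected CCR at zero class effect
#'
#' For the mean-difference linear discriminant applied to nested two-class
#' data with no class effect, the expected correct classification rate
#' depends only on the number of subclasses per class and the intraclass
#' correlation:
#' \deqn{CCR(K, ICC) = 1 - \frac{1}{\pi}\arctan\sqrt{2\left(\frac{K}{ICC} - 1\right)}
#'   \;=\; \frac12 + \frac{1}{\pi}\arctan\lambda,\qquad
#'   \lambda^2 = \frac{ICC}{2(K - ICC)}.}
#' It equals exactly 1/2 at `icc = 0`, increases strictly in `icc` and
#' decreases strictly in `K`: more subclass variance means more inflation,
#' more subclasses dilute it.
#'
#' @param K Subclasses per class (>= 1); vectorised.
#' @param icc Intraclass correlation in `[0, 1]`; vectorised.
#' @return Expected CCR in `[0.5, 1]`.
#' @export
#' @examples
#' expected_ccr_closed_form(4, 0)     # 0.5
#' expected_ccr_closed_form(2, 0.3)   # above expected_ccr_closed_form(10, 0.3)
expected_ccr_closed_form <- function(K, icc) {
  if (any(K < 1)) stop("'K' must be >= 1")
  if (any(!is.finite(icc)) || any(icc < 0) || any(icc > 1))
    stop("'icc' must lie in [0, 1]")
  out <- ifelse(icc == 0, 0.5, 1 - atan(sqrt(2 * (K / icc - 1))) / pi)
  as.numeric(out)
}

#' Expected CCR with a class effect: one-dimensional quadrature
#'
#' Evaluates the expected CCR of the mean-difference linear discriminant for
#' nested data with class-mean separation \eqn{\delta} by adaptive quadrature
#' of a one-dimensional integral over the standardised class-mean difference
#' \eqn{q}:
#' \deqn{CCR = \int_{-\infty}^{\infty} \phi(q)\,
#'   \Phi\!\left(\frac{\left|\delta + q\,\sigma\sqrt{2\rho/K}\right|}
#'   {2\sigma\sqrt{1 - \rho/K}}\right) dq,}
#' where \eqn{\phi,\Phi} are the standard normal density and CDF,
#' \eqn{\rho} the intraclass correlation and \eqn{\sigma} the total
#' class-unrelated standard deviation. The integrand is split at the kink of
#' the absolute value and each half is integrated to an absolute tolerance of
#' `1e-10`. At \eqn{\delta = 0} the integral reduces exactly to
#' [expected_ccr_closed_form()]; as \eqn{\delta/\sigma \to \infty} it tends to 1. The
#' boundary \eqn{\rho = 0} is handled analytically as
#' \eqn{\Phi(|\delta| / (2\sigma))}.
#'
#' @param params A [theory_params()] object.
#' @return Expected CCR.
#' @export
#' @examples
#' expected_ccr_integral(theory_params(K = 4, icc = 0.5))  # = expected_ccr_closed_form(4, 0.5)
expected_ccr_integral <- function(params) {
  if (!inherits(params, "theory_params"))
    stop("'params' must be a theory_params object")
  rho <- params$icc; K <- params$K
  delta <- params$delta; sigma <- params$sigma_total
  if (rho == 0) return(stats::pnorm(abs(delta) / (2 * sigma)))
  a <- sigma * sqrt(2 * rho / K)            # null sd of the class-mean difference
  s <- 2 * sigma * sqrt(1 - rho / K)        # conditional spread of a test trial
  f <- function(q) stats::dnorm(q) * stats::pnorm(abs(delta + q * a) / s)
  # break at the kink of |.| and at the centre of the Gaussian weight, so no
  # semi-infinite piece has its mass far from an endpoint
  breaks <- sort(unique(c(-Inf, -delta / a, 0, Inf)))
  res <- tryCatch({
    pieces <- lapply(seq_len(length(breaks) - 1L), function(i)
      stats::integrate(f, breaks[i], breaks[i + 1L],
                       abs.tol = 1e-10, rel.tol = 1e-10))
    list(value = sum(vapply(pieces, `[[`, numeric(1), "value")),
         abs.error = sum(vapply(pieces, `[[`, numeric(1), "abs.error")))
  }, error = function(e) stop("quadrature failed: ", conditionMessage(e)))
  if (res$abs.error > 1e-8)
    stop(sprintf("quadrature did not reach the requested tolerance (error %.2e)",
                 res$abs.error))
  res$value
}

#' Monte-Carlo oracle for the expected CCR
#'
#' Independent simulation check of the analytic results, faithful to the
#' sampling scheme the theory describes: per repetition, `K` subclass
#' centroids per class are drawn around fixed class means `+delta/2` and
#' `-delta/2` (placed on the first feature dimension), `N` training trials
#' per subclass determine the empirical class means of the mean-difference
#' rule, and `N` fresh test trials per subclass — from the *same* subclass
#' centroids, with independent noise — are classified. The rate of correct
#' test classifications, averaged over repetitions, estimates the expected
#' CCR. Note there is deliberately no cross-validation split here: the theory
#' models the regime in which the tested trials share their subclasses with
#' the training data, which is the source of the inflation.
#'
#' @param params A [theory_params()] object.
#' @param N Trials per subclass (default 100; large `N` matches the theory's
#'   assumption that empirical subclass means are well estimated).
#' @param d Feature dimensionality (default 1, the space in which the theory
#'   lives; the projected model is one-dimensional).
#' @param n_reps Number of simulated datasets (>= 100).
#' @param seed RNG seed.
#' @return List with `mean_ccr`, `stderr` and `n_reps`.
#' @export
mc_ccr_oracle <- function(params, N = 100, d = 1, n_reps = 2000, seed = NULL) {
  if (!inherits(params, "theory_params"))
    stop("'params' must be a theory_params object")
  if (n_reps < 100) stop("'n_reps' must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  K <- params$K
  sigma_S <- sqrt(params$icc) * params$sigma_total
  sigma_W <- sqrt(1 - params$icc) * params$sigma_total
  offset <- c(params$delta / 2, rep(0, d - 1L))
  sub_idx <- rep(seq_len(K), each = N)
  ccrs <- vapply(seq_len(n_reps), function(r) {
    S1 <- matrix(stats::rnorm(K * d, 0, sigma_S), K, d) +
      matrix(offset, K, d, byrow = TRUE)
    S2 <- matrix(stats::rnorm(K * d, 0, sigma_S), K, d) -
      matrix(offset, K, d, byrow = TRUE)
    centers <- rbind(S1[sub_idx, , drop = FALSE], S2[sub_idx, , drop = FALSE])
    train <- centers + matrix(stats::rnorm(2 * K * N * d, 0, sigma_W), 2 * K * N, d)
    cl <- rep(c(1L, 2L), each = K * N)
    fit <- .lda_fit(train, cl)
    test <- centers + matrix(stats::rnorm(2 * K * N * d, 0, sigma_W), 2 * K * N, d)
    mean(.lda_predict(fit, test) == cl)
  }, numeric(1))
  list(mean_ccr = mean(ccrs), stderr = stats::sd(ccrs) / sqrt(n_reps),
       n_reps = n_reps)
}
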