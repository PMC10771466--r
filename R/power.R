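#' Fit a Gaussian scale mixture to standardized effect sizes
#'
#' Models concatenated association z-scores (beta/se across all traits) as
#' a K-component zero-mean Gaussian scale mixture: marginally
#' z ~ sum_k pi_k Normal(0, N_fit * tau2_k + 1), where tau2_k are the
#' variances of standardized true effects and the +1 is the sampling
#' variance at the fitting sample size. Component 1 is pinned at
#' tau2 = 0 (the null spike); the remaining components are free.
#' Estimation is maximum likelihood by EM with multiple seeded restarts;
#' the likelihood is non-decreasing across iterations and convergence is
#' declared when it changes by less than `tol`. After convergence,
#' components whose marginal variance lies within 5% of the null's
#' (N_fit * tau2 < 0.05) are folded onto the spike: below that
#' resolution non-null mass is not identifiable from the z-scores.
#'
#' @param z vector of finite z-scores.
#' @param N_fit sample size the summary statistics were computed at.
#' @param K number of mixture components (>= 2), including the null spike.
#' @param seed RNG seed for the restarts.
#' @param n_restarts number of EM restarts (best likelihood kept).
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood convergence tolerance.
#' @return object of class `effect_size_mixture`: weights, tau2, K,
#'   N_fit, n_tests, loglik, ll_trace (of the winning restart), converged.
#' @export
fit_effect_mixture <- function(z, N_fit, K = 4, seed = 1, n_restarts = 5,
                               max_iter = 2000, tol = 1e-8) {
  stopifnot(all(is.finite(z)), K >= 2, N_fit > 0)
  z2 <- z^2
  em_once <- function(tau2_init, pi_init) {
    tau2 <- tau2_init
    pi_k <- pi_init / sum(pi_init)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      s <- N_fit * tau2 + 1
      # log density matrix: n x K
      logd <- vapply(seq_len(K), function(k) {
        -0.5 * (log(2 * pi * s[k]) + z2 / s[k]) + log(pi_k[k])
      }, numeric(length(z)))
      mx <- apply(logd, 1, max)
      w <- exp(logd - mx)
      rs <- rowSums(w)
      ll <- sum(mx + log(rs))
      ll_trace <- c(ll_trace, ll)
      resp <- w / rs
      nk <- colSums(resp)
      pi_k <- nk / length(z)
      pi_k <- pi_k / sum(pi_k)
      s_new <- colSums(resp * z2) / pmax(nk, 1e-300)
      tau2 <- pmax((s_new - 1) / N_fit, 0)
      tau2[1] <- 0  # pinned null spike
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(pi = pi_k, tau2 = tau2, loglik = ll, ll_trace = ll_trace,
         converged = converged)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_substream(seed, paste0("mixture_restart_", r), {
      scale0 <- max(mean(z2) - 1, 0.5) / N_fit
      tau2_init <- c(0, scale0 * exp(runif(K - 1, -2, 2)))
      pi_init <- c(runif(1, 0.5, 0.95), runif(K - 1))
      list(tau2 = tau2_init, pi = pi_init)
    })
    res <- em_once(init$tau2, init$pi)
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  # components below identifiability resolution (marginal variance within
  # 5% of the null's) are effectively null and folded onto the spike
  tiny <- N_fit * best$tau2 < 0.05
  best$tau2[tiny] <- 0
  ord <- c(1, 1 + order(best$tau2[-1]))
  structure(list(
    weights = best$pi[ord], tau2 = best$tau2[ord], K = K,
    N_fit = N_fit, n_tests = length(z),
    loglik = best$loglik, ll_trace = best$ll_trace,
    converged = best$converged
  ), class = "effect_size_mixture")
}

#' @export
print.effect_size_mixture <- function(x, ...) {
  cat("effect-size mixture (K =", x$K, ", fit at N =", x$N_fit, ")\n")
  print(data.frame(component = seq_len(x$K), weight = x$weights,
                   tau2 = x$tau2), row.names = FALSE, digits = 4)
  cat("log-likelihood:", format(x$loglik),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' Project expected discoveries at larger sample sizes
#'
#' For each sample size N, adds sampling variance 1/N to the inferred
#' true-effect distribution and evaluates the two-sided tail beyond the
#' significance threshold: the expected significant fraction is
#' sum_k pi_k * 2 Phi(-z* / sqrt(N tau2_k + 1)) with z* the normal
#' quantile of 1 - p*/2; the expected count is that fraction times the
#' number of tests. The null spike contributes exactly T * p* false
#' positives.
#'
#' @param mix an [fit_effect_mixture()] result.
#' @param N_grid sample sizes to project to.
#' @param p_star significance threshold in (0, 1) (2.2e-8 for the rare
#'   burden analysis at full scale).
#' @param n_tests total number of tests T (defaults to the number of
#'   z-scores the mixture was fit on).
#' @return data.frame (N, expected_fraction, expected_count), class
#'   `power_projection`.
#' @export
project_discoveries <- function(mix, N_grid, p_star,
                                n_tests = mix$n_tests) {
  stopifnot(inherits(mix, "effect_size_mixture"))
  if (p_star <= 0 || p_star >= 1) stop("p_star must be in (0, 1)")
  z_star <- qnorm(p_star / 2, lower.tail = FALSE)
  frac <- vapply(N_grid, function(N) {
    sum(mix$weights * 2 * pnorm(-z_star / sqrt(N * mix$tau2 + 1)))
  }, 1.0)
  out <- data.frame(N = N_grid, expected_fraction = frac,
                    expected_count = n_tests * frac)
  class(out) <- c("power_projection", "data.frame")
  out
}

#' LD pruning for the common-variant mixture fit
#'
#' The indep-pairwise setting used before fitting the effect-size mixture
#' to common-variant summary statistics: 50-variant windows shifting by 5,
#' r-squared threshold 0.2. Delegates to [ld_prune()] in count mode.
#'
#' @param genotypes a [genotype_set()] of QC'd common variants.
#' @return character vector of retained variant ids.
#' @export
prune_for_common_fit <- function(genotypes) {
  ld_prune(genotypes, mode = "count", r2_max = 0.2, window = 50, step = 5)
}
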