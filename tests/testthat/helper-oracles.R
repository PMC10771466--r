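# Independent reference implementations (oracles) used to cross-check the
# package's algorithms. Each is written as directly as possible —
# enumeration, explicit loops, textbook formulas — and stays independent
# of the code paths it validates.

# Exact HWE test by direct enumeration of heterozygote counts conditional
# on the allele counts, using the unnormalized textbook probability
#   P(h | n, nA) = n! nA! na! 2^h / (hom1! h! hom2! (2n)!)
# evaluated term by term (no max-shift normalization trick).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na_ <- 2 * n - nA
  if (nA == 0 || na_ == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na_), by = 2)
  probs <- vapply(hs, function(h) {
    hom1 <- (nA - h) / 2
    hom2 <- (na_ - h) / 2
    exp(lfactorial(n) + lfactorial(nA) + lfactorial(na_) + h * log(2) -
          lfactorial(hom1) - lfactorial(h) - lfactorial(hom2) -
          lfactorial(2 * n))
  }, 1.0)
  obs <- probs[match(n_Aa, hs)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Greedy composite-trait selection, re-implemented with explicit loops
# over trait pairs (no matrix algebra).
oracle_composite <- function(matrices, threshold = 0.9) {
  traits <- colnames(matrices[[1]])
  pool <- traits
  kept <- character(0)
  over <- function(a, b) {
    any(vapply(matrices, function(m) {
      r <- m[a, b]
      !is.na(r) && abs(r) >= threshold
    }, TRUE))
  }
  while (length(pool) > 0) {
    counts <- integer(length(pool))
    for (i in seq_along(pool)) {
      for (m in matrices) {
        for (j in seq_along(pool)) {
          if (i == j) next
          r <- m[pool[i], pool[j]]
          if (!is.na(r) && abs(r) >= threshold) {
            counts[i] <- counts[i] + 1L
          }
        }
      }
    }
    if (all(counts == 0)) {
      kept <- c(kept, sort(pool))
      break
    }
    hub <- sort(pool[counts == max(counts)])[1]
    removed <- hub
    for (j in pool) {
      if (j != hub && over(hub, j)) removed <- c(removed, j)
    }
    kept <- c(kept, hub)
    pool <- setdiff(pool, removed)
  }
  kept
}

# OLS reference through one QR decomposition of the full design [C | x]:
# textbook beta-hat and covariance, one predictor at a time.
oracle_ols <- function(y, x, C) {
  X <- cbind(C, x)
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- nrow(X) - qrX$rank
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  k <- ncol(X)
  b <- unname(beta[k]); s <- unname(se[k])
  list(beta = b, se = s, t = b / s, p = 2 * pt(-abs(b / s), df))
}

# Balanced one-way random-effects ANOVA method-of-moments components.
oracle_anova_components <- function(y, group) {
  group <- factor(group)
  m <- length(y) / nlevels(group)   # per-group size (balanced)
  gm <- tapply(y, group, mean)
  msa <- m * sum((gm - mean(y))^2) / (nlevels(group) - 1)
  mse <- sum((y - gm[group])^2) / (length(y) - nlevels(group))
  c(group = max(0, (msa - mse) / m), residual = mse)
}

# Closed-form expected significant fraction for a mixture of zero-mean
# normals: P(|Z| > z*) with Z ~ N(0, N tau2 + 1), written with the
# sd-parameterized normal tail rather than a standardized quantile.
oracle_projection_fraction <- function(weights, tau2, N, p_star) {
  z_star <- qnorm(p_star / 2, lower.tail = FALSE)
  sum(weights * 2 * pnorm(z_star, mean = 0, sd = sqrt(N * tau2 + 1),
                          lower.tail = FALSE))
}
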