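# Vectorized OLS association engine.
#
# For each predictor column x and response column y, fits
#   y ~ x + C   (C = covariate matrix including the intercept)
# by ordinary least squares and returns the coefficient, standard error,
# t statistic and two-sided p-value for x. Implemented by the
# Frisch-Waugh-Lovell partialling-out identity: residualize X and Y on C
# through one QR decomposition, then each (x, y) slope is a simple
# regression of residuals with error degrees of freedom n - rank(C) - 1.
# This is algebraically exact OLS, not an approximation, and lets a full
# scan (many predictors x many traits) run as two matrix products.

ols_scan_engine <- function(Y, X, C, x_tol = 1e-10) {
  stopifnot(is.matrix(Y), is.matrix(X), is.matrix(C),
            nrow(Y) == nrow(X), nrow(Y) == nrow(C))
  n <- nrow(Y)
  qrC <- qr(C)
  r <- qrC$rank
  df <- n - r - 1
  if (df < 1) stop("ols_scan_engine: not enough residual degrees of freedom")
  Ry <- qr.resid(qrC, Y)
  Rx <- qr.resid(qrC, X)
  ss_x <- colSums(Rx^2)
  ss_y <- colSums(Ry^2)
  xy <- crossprod(Rx, Ry)            # predictors x traits
  usable <- ss_x > x_tol * n         # predictor collinear with covariates?
  beta <- sweep(xy, 1, ifelse(usable, ss_x, NA_real_), "/")
  rss <- pmax(outer(rep(1, length(ss_x)), ss_y) - beta^2 * ss_x, 0)
  se <- sqrt(rss / df / ss_x)
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), df)
  list(beta = beta, se = se, t = tstat, p = p, n = n, df = df,
       usable = usable)
}

# Build the standard covariate matrix for association scans:
# intercept, age, sex, ancestry PCs 1-4, plate indicators, and (colony
# context only) the donor's mean neighbor count.
association_covariates <- function(donors, metadata, pcs, plate_of,
                                   mean_neighbors = NULL,
                                   context = c("colony", "isolate"),
                                   n_pcs = 4) {
  context <- match.arg(context)
  md <- metadata[match(donors, metadata$donor_id), , drop = FALSE]
  if (anyNA(md$donor_id)) stop("metadata missing for some donors")
  plate <- factor(plate_of[donors])
  C <- cbind(
    `(Intercept)` = 1,
    age = as.numeric(md$age),
    sex = as.numeric(factor(md$sex)) - 1
  )
  pcs_use <- pcs[donors, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
  C <- cbind(C, pcs_use)
  if (nlevels(plate) > 1) {
    pm <- model.matrix(~plate)[, -1, drop = FALSE]
    C <- cbind(C, pm)
  }
  if (context == "colony") {
    if (is.null(mean_neighbors)) {
      stop("colony context requires donor mean neighbor counts")
    }
    C <- cbind(C, neighbors = mean_neighbors[donors])
  }
  rownames(C) <- donors
  C
}
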