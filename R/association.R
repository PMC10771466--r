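#' Bonferroni significance threshold
#'
#' @param alpha family-wise error level.
#' @param n_tests number of tests.
#' @return `alpha / n_tests`. At full study scale this gives the rare
#'   burden threshold 0.05 / (246 x 9105) = 2.2e-8 and the common-variant
#'   threshold 5e-8 / 246 = 2e-10.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, n_tests >= 1)
  alpha / n_tests
}

#' Genomic inflation factor lambda
#'
#' Ratio of the median observed association chi-square (1 df, from
#' two-sided p-values) to the null median `qchisq(0.5, 1)` (0.4549).
#' Lambda near 1 indicates well-calibrated tests.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return lambda.
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (!length(p_values)) stop("genomic_lambda: no p-values")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  chisq <- qchisq(p_values, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

# Tidy one engine result into the long association table.
.assoc_table <- function(fit, targets, traits, context, covariate_names) {
  keep <- fit$usable
  grid <- expand.grid(target = targets[keep], trait = traits,
                      stringsAsFactors = FALSE)
  out <- data.frame(
    trait = grid$trait,
    target = grid$target,
    context = context,
    beta = as.vector(fit$beta[keep, , drop = FALSE]),
    se = as.vector(fit$se[keep, , drop = FALSE]),
    t = as.vector(fit$t[keep, , drop = FALSE]),
    p = as.vector(fit$p[keep, , drop = FALSE]),
    n = fit$n,
    stringsAsFactors = FALSE
  )
  attr(out, "covariates") <- covariate_names
  attr(out, "skipped") <- targets[!keep]
  out
}

#' Gene-level rare-variant burden regression
#'
#' For every gene x trait pair, ordinary least squares of the donor-level
#' gaussianized trait on the gene's carrier indicator with covariates age,
#' sex, ancestry PCs 1-4, plate indicators and — in the colony context —
#' the donor's mean neighbor count. Two-sided t-test p-values for the
#' burden coefficient.
#'
#' @param traits donor-by-trait data.frame from [pseudo_bulk()].
#' @param burden result of [collapse_rare_burden()] (or a binary donor x
#'   gene matrix).
#' @param metadata donor metadata (donor_id, sex, age, ...).
#' @param pcs donor x PC matrix from [pca_from_grm()].
#' @param plate_of named character vector donor -> plate.
#' @param context "colony" or "isolate".
#' @return association table (one row per gene-trait pair) with columns
#'   trait, target, context, beta, se, t, p, n. Genes whose indicator is
#'   collinear with the covariates are skipped and listed in the
#'   `skipped` attribute.
#' @export
burden_regression <- function(traits, burden, metadata, pcs, plate_of,
                              context = c("colony", "isolate")) {
  context <- match.arg(context)
  if (is.list(burden) && !is.null(burden$burden)) burden <- burden$burden
  donors <- intersect(traits$donor_id, rownames(burden))
  if (!length(donors)) stop("burden_regression: no shared donors")
  tr_names <- trait_names(traits)
  Y <- as.matrix(traits[match(donors, traits$donor_id), tr_names,
                        drop = FALSE])
  rownames(Y) <- donors
  X <- burden[donors, , drop = FALSE]
  mn <- setNames(traits$mean_neighbors, traits$donor_id)
  C <- association_covariates(donors, metadata, pcs, plate_of,
                              mean_neighbors = mn, context = context)
  fit <- ols_scan_engine(Y, X, C)
  .assoc_table(fit, colnames(X), tr_names, context, colnames(C))
}

#' Common-variant association scan
#'
#' Per variant x trait OLS of the donor-level trait on additive dosage
#' (0/1/2) with the same covariates as [burden_regression()]. Donors with
#' a missing dosage are dropped for that variant's tests; variants
#' monomorphic after missingness are skipped.
#'
#' @inheritParams burden_regression
#' @param genotypes a QC'd [genotype_set()] of common variants.
#' @return association table as in [burden_regression()].
#' @export
common_variant_scan <- function(traits, genotypes, metadata, pcs, plate_of,
                                context = c("colony", "isolate")) {
  context <- match.arg(context)
  donors <- intersect(traits$donor_id, genotypes$donors)
  if (!length(donors)) stop("common_variant_scan: no shared donors")
  tr_names <- trait_names(traits)
  Y <- as.matrix(traits[match(donors, traits$donor_id), tr_names,
                        drop = FALSE])
  rownames(Y) <- donors
  D <- genotypes$dosage[donors, , drop = FALSE]
  mn <- setNames(traits$mean_neighbors, traits$donor_id)
  C <- association_covariates(donors, metadata, pcs, plate_of,
                              mean_neighbors = mn, context = context)

  complete <- colSums(is.na(D)) == 0
  out <- list()
  if (any(complete)) {
    fit <- ols_scan_engine(Y, D[, complete, drop = FALSE], C)
    out[[1]] <- .assoc_table(fit, colnames(D)[complete], tr_names, context,
                             colnames(C))
  }
  # per-variant fallback for variants with missing dosages
  for (j in which(!complete)) {
    obs <- !is.na(D[, j])
    x <- D[obs, j, drop = FALSE]
    if (length(unique(x)) < 2) next  # monomorphic after missingness
    fit <- ols_scan_engine(Y[obs, , drop = FALSE], x,
                           C[obs, , drop = FALSE])
    out[[length(out) + 1]] <-
      .assoc_table(fit, colnames(D)[j], tr_names, context, colnames(C))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation null for association scans
#'
#' Re-runs a full scan `n_perm` times with donor labels permuted on one
#' side: `shuffle_traits` permutes trait values across donors (the rare
#' burden validation), `shuffle_genotypes` permutes genotype labels (the
#' common-variant validation). Returns the pooled null p-value
#' distribution and per-permutation genomic inflation.
#'
#' @param traits donor-by-trait data.frame.
#' @param predictor burden result or `genotype_set` (matched to `arm`).
#' @param metadata,pcs,plate_of covariate inputs as in
#'   [burden_regression()].
#' @param arm "burden" or "common".
#' @param mode "shuffle_traits" or "shuffle_genotypes".
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed; fixed seed gives an identical permutation
#'   sequence.
#' @param context "colony" or "isolate".
#' @return list with `p_values` (list of per-permutation vectors),
#'   `lambda` (per permutation), `min_p` (per permutation).
#' @export
permutation_null <- function(traits, predictor, metadata, pcs, plate_of,
                             arm = c("burden", "common"),
                             mode = c("shuffle_traits",
                                      "shuffle_genotypes"),
                             n_perm = 10, seed = 1,
                             context = c("colony", "isolate")) {
  arm <- match.arg(arm)
  mode <- match.arg(mode)
  context <- match.arg(context)
  if (n_perm < 1) stop("permutation_null: n_perm must be >= 1")
  tr_names <- trait_names(traits)
  run <- function(tr, pred) {
    if (arm == "burden") {
      burden_regression(tr, pred, metadata, pcs, plate_of, context)
    } else {
      common_variant_scan(tr, pred, metadata, pcs, plate_of, context)
    }
  }
  with_substream(seed, "permutation", {
    res <- lapply(seq_len(n_perm), function(i) {
      if (mode == "shuffle_traits") {
        tr <- traits
        perm <- sample(nrow(tr))
        tr[tr_names] <- tr[perm, tr_names, drop = FALSE]
        tr$mean_neighbors <- tr$mean_neighbors[perm]
        run(tr, predictor)
      } else {
        pred <- predictor
        if (inherits(pred, "genotype_set")) {
          perm <- sample(length(pred$donors))
          pred$dosage <- pred$dosage[perm, , drop = FALSE]
          rownames(pred$dosage) <- pred$donors
        } else {
          if (is.list(pred) && !is.null(pred$burden)) pred <- pred$burden
          rn <- rownames(pred)
          pred <- pred[sample(nrow(pred)), , drop = FALSE]
          rownames(pred) <- rn
        }
        run(traits, pred)
      }
    })
    list(p_values = lapply(res, `[[`, "p"),
         lambda = vapply(res, function(r) genomic_lambda(r$p), 1.0),
         min_p = vapply(res, function(r) min(r$p), 1.0))
  })
}
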