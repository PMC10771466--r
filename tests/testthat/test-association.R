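test_that("Bonferroni thresholds reproduce the printed study values", {
  expect_equal(signif(bonferroni_threshold(0.05, 246 * 9105), 2), 2.2e-8)
  expect_equal(signif(bonferroni_threshold(5e-8, 246), 1), 2e-10)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("the scan engine agrees with the QR reference oracle", {
  withr::with_seed(3, {
    n <- 120
    C <- cbind(1, rnorm(n), rnorm(n), rbinom(n, 1, 0.5))
    X <- vapply(runif(8, 0.1, 0.5), function(p) rbinom(n, 2, p),
                numeric(n))
    Y <- matrix(rnorm(n * 5), n)
    fit <- ols_scan_engine(Y, X, C)
    for (g in seq_len(ncol(X))) {
      for (tr in seq_len(ncol(Y))) {
        ref <- oracle_ols(Y[, tr], X[, g], C)
        expect_equal(fit$beta[g, tr], ref$beta, tolerance = 1e-10)
        expect_equal(fit$se[g, tr], ref$se, tolerance = 1e-10)
        expect_equal(fit$p[g, tr], ref$p, tolerance = 1e-10)
      }
    }
  })
})

test_that("burden regression is shift-invariant and flags collinearity", {
  traits <- null_donor_traits(80, 3, seed = 5)
  cov_in <- null_covariate_inputs(traits$donor_id, seed = 6)
  burden <- withr::with_seed(7, {
    b <- vapply(rep(0.08, 4), function(p) rbinom(80, 1, p), numeric(80))
    dimnames(b) <- list(traits$donor_id, sprintf("G%04d", 1:4))
    b
  })
  a1 <- burden_regression(traits, burden, cov_in$metadata, cov_in$pcs,
                          cov_in$plate_of, "colony")
  shifted <- traits
  shifted[trait_names(shifted)] <- shifted[trait_names(shifted)] + 100
  a2 <- burden_regression(shifted, burden, cov_in$metadata, cov_in$pcs,
                          cov_in$plate_of, "colony")
  expect_equal(a1$beta, a2$beta, tolerance = 1e-9)
  expect_equal(a1$p, a2$p, tolerance = 1e-9)
  # an all-zero gene indicator is collinear with the intercept
  burden0 <- cbind(burden, G9999 = 0)
  a3 <- burden_regression(traits, burden0, cov_in$metadata, cov_in$pcs,
                          cov_in$plate_of, "colony")
  expect_true("G9999" %in% attr(a3, "skipped"))
})

test_that("planted burden effects are estimated within their noise", {
  # beta is recovered within +-2 SE in at least 95% of replicates
  n <- 300; beta <- -1.2
  hits <- 0; reps <- 100
  for (i in seq_len(reps)) {
    res <- withr::with_seed(2000 + i, {
      donors <- sprintf("D%04d", 1:n)
      carrier <- rbinom(n, 1, 0.03)
      y <- beta * carrier + rnorm(n)
      traits <- data.frame(donor_id = donors, n_wells = 1L,
                           mean_neighbors = 3, trait_001 = y,
                           stringsAsFactors = FALSE)
      b <- matrix(carrier, dimnames = list(donors, "G0001"))
      ci <- null_covariate_inputs(donors, seed = 2000 + i)
      if (sum(carrier) < 2) NULL else
        burden_regression(traits, b, ci$metadata, ci$pcs, ci$plate_of,
                          "colony")
    })
    if (is.null(res)) next
    if (abs(res$beta - beta) <= 2 * res$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("null burden p-values are uniform", {
  traits <- null_donor_traits(250, 20, seed = 9)
  cov_in <- null_covariate_inputs(traits$donor_id, seed = 10)
  burden <- withr::with_seed(11, {
    b <- vapply(runif(50, 0.05, 0.2), function(p) rbinom(250, 1, p),
                numeric(250))
    dimnames(b) <- list(traits$donor_id, sprintf("G%04d", 1:50))
    b
  })
  a <- burden_regression(traits, burden, cov_in$metadata, cov_in$pcs,
                         cov_in$plate_of, "colony")
  expect_equal(nrow(a), 1000)
  ks <- suppressWarnings(ks.test(a$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(genomic_lambda(a$p), 1, tolerance = 0.15)
})

test_that("common-variant scan power matches the non-central t oracle", {
  withr::with_seed(21, {
    n <- 300; maf <- 0.3; b <- 0.8; alpha <- 1e-4
    reps <- 400
    C <- matrix(1, n, 1)
    sig <- logical(reps)
    for (i in seq_len(reps)) {
      x <- rbinom(n, 2, maf)
      y <- b * x + rnorm(n)
      fit <- ols_scan_engine(matrix(y), matrix(x), C)
      sig[i] <- fit$p[1, 1] < alpha
    }
    df <- n - 2
    ncp <- b * sqrt(n * 2 * maf * (1 - maf))
    tcrit <- qt(1 - alpha / 2, df)
    power <- pt(tcrit, df, ncp, lower.tail = FALSE) +
      pt(-tcrit, df, ncp)
    expect_equal(mean(sig), power, tolerance = 0.05)
  })
})

test_that("scan results are invariant to row and column order", {
  cfg <- tiny_config(seed = 25, n_donors = 50, n_common_variants = 30,
                     n_genes = 5)
  g <- simulate_genotypes(cfg)$genotypes
  common <- subset_variants(g, g$variants$id[g$variants$type == "common"])
  traits <- null_donor_traits(50, 3, seed = 26)
  ci <- null_covariate_inputs(traits$donor_id, seed = 27)
  a1 <- common_variant_scan(traits, common, ci$metadata, ci$pcs,
                            ci$plate_of, "isolate")
  # shuffle donor rows of the trait matrix (and of the genotype set)
  perm <- withr::with_seed(1, sample(50))
  traits2 <- traits[perm, ]
  a2 <- common_variant_scan(traits2, common, ci$metadata, ci$pcs,
                            ci$plate_of, "isolate")
  expect_equal(a1$beta, a2$beta, tolerance = 1e-10)
  # duplicated variant gives identical statistics
  dup <- common
  dup$dosage <- cbind(dup$dosage, dup$dosage[, 1, drop = FALSE])
  colnames(dup$dosage)[ncol(dup$dosage)] <- "vdup"
  dv <- rbind(dup$variants, within(dup$variants[1, ], id <- "vdup"))
  dup <- genotype_set(dup$dosage, dv, dup$annotation)
  a3 <- common_variant_scan(traits, dup, ci$metadata, ci$pcs,
                            ci$plate_of, "isolate")
  expect_equal(a3$beta[a3$target == "vdup"],
               a3$beta[a3$target == dup$variants$id[1]])
})

test_that("missing dosages drop donors per variant", {
  traits <- null_donor_traits(60, 2, seed = 31)
  ci <- null_covariate_inputs(traits$donor_id, seed = 32)
  withr::with_seed(33, {
    dos <- cbind(v1 = rbinom(60, 2, 0.3), v2 = rbinom(60, 2, 0.3))
    dos[1:5, 2] <- NA
    mode(dos) <- "integer"
    dimnames(dos) <- list(traits$donor_id, c("v1", "v2"))
    v <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(100L, 200L),
                    ref = "A", alt = "G", filter = "PASS",
                    stringsAsFactors = FALSE)
    g <- genotype_set(dos, v)
    a <- common_variant_scan(traits, g, ci$metadata, ci$pcs, ci$plate_of,
                             "isolate")
    expect_equal(unique(a$n[a$target == "v1"]), 60)
    expect_equal(unique(a$n[a$target == "v2"]), 55)
    # monomorphic-after-missingness variant is skipped
    dos2 <- dos
    dos2[, 2] <- 0L; dos2[1:3, 2] <- NA
    g2 <- genotype_set(dos2, v)
    a2 <- common_variant_scan(traits, g2, ci$metadata, ci$pcs,
                              ci$plate_of, "isolate")
    expect_false("v2" %in% a2$target)
  })
})

test_that("genomic lambda behaves at its landmarks", {
  expect_equal(genomic_lambda(rep(0.5, 10)), 1)
  withr::with_seed(40, {
    p <- runif(1e5)
    expect_equal(genomic_lambda(p), 1, tolerance = 0.02)
    # doubling the chi-square doubles lambda
    chi <- qchisq(p, 1, lower.tail = FALSE)
    p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
    expect_equal(genomic_lambda(p2), 2 * genomic_lambda(p),
                 tolerance = 1e-10)
  })
  expect_error(genomic_lambda(numeric(0)), "no p-values")
})

test_that("permutation nulls are seeded, uniform and signal-free", {
  cfg <- tiny_config(seed = 50, n_donors = 200, n_genes = 25,
                     rare_variants_per_gene = c(2L, 6L), n_traits = 6,
                     cells_per_well_mean = 10,
                     planted_effects = list(
                       list(target = "G0002", trait = 1, beta = 2)))
  st <- simulate_study(cfg)
  w <- inverse_normal_transform(
    aggregate_wells(split_context(qc_cells(st$cells))$colony))
  traits <- pseudo_bulk(w)
  burden <- collapse_rare_burden(st$genotypes)
  ci <- null_covariate_inputs(traits$donor_id, seed = 51)
  pn1 <- permutation_null(traits, burden, ci$metadata, ci$pcs,
                          st$truth$plate_of, arm = "burden",
                          mode = "shuffle_traits", n_perm = 5, seed = 99)
  pn2 <- permutation_null(traits, burden, ci$metadata, ci$pcs,
                          st$truth$plate_of, arm = "burden",
                          mode = "shuffle_traits", n_perm = 5, seed = 99)
  expect_identical(pn1$p_values, pn2$p_values)
  pooled <- unlist(pn1$p_values)
  frac <- mean(pooled < 0.05)
  ci_bin <- qbinom(c(0.005, 0.995), length(pooled), 0.05) / length(pooled)
  expect_gte(frac, ci_bin[1])
  expect_lte(frac, ci_bin[2])
  # shuffling destroys the planted signal: no permutation reaches the
  # study-scale burden threshold
  expect_true(all(pn1$min_p > 2.2e-8))
  expect_error(permutation_null(traits, burden, ci$metadata, ci$pcs,
                                st$truth$plate_of, n_perm = 0),
               "n_perm")
})
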