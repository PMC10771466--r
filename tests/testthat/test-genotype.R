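test_that("HWE exact test behaves at its landmarks", {
  # perfect 1:2:1 is the most probable configuration
  expect_equal(hwe_exact_test(25, 50, 25), 1, tolerance = 1e-9)
  # no heterozygotes at n = 100 is a gross violation
  expect_lt(hwe_exact_test(50, 0, 50), 1e-5)
  expect_equal(hwe_exact_test(50, 0, 50), oracle_hwe(50, 0, 50))
  # monomorphic: nothing to test
  expect_equal(hwe_exact_test(30, 0, 0), 1)
})

test_that("HWE enumeration probabilities are a proper distribution", {
  # the oracle's unnormalized probabilities must sum to 1
  for (cfg in list(c(3, 4, 3), c(10, 5, 2), c(0, 7, 13))) {
    n <- sum(cfg)
    nA <- 2 * cfg[1] + cfg[2]
    hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
    total <- sum(vapply(hs, function(h) {
      hom1 <- (nA - h) / 2; hom2 <- (2 * n - nA - h) / 2
      exp(lfactorial(n) + lfactorial(nA) + lfactorial(2 * n - nA) +
            h * log(2) - lfactorial(hom1) - lfactorial(h) -
            lfactorial(hom2) - lfactorial(2 * n))
    }, 1.0))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("common-variant QC filters each planted failure class", {
  withr::with_seed(42, {
    n <- 120
    mk <- function(p) as.integer(rbinom(n, 2, p))
    good <- vapply(runif(20, 0.2, 0.45), mk, integer(n))
    colnames(good) <- sprintf("good%02d", 1:20)
    dos <- cbind(
      good,
      low_maf = mk(0.01),
      hwe_bad = as.integer(2 * rbinom(n, 1, 0.4)),
      missing = {x <- mk(0.3); x[1:10] <- NA; x},
      sex_chrom = mk(0.3),
      long_indel = mk(0.3),
      dup_a = mk(0.3), dup_b = mk(0.3),
      multi = mk(0.3),
      fail_filter = mk(0.3)
    )
    rownames(dos) <- sprintf("D%04d", 1:n)
    m <- ncol(dos)
    v <- data.frame(
      id = colnames(dos),
      chrom = c(rep("1", 23), "X", rep("2", 5)),
      pos = c(seq(1000, by = 1000, length.out = 26),
              26000, 28000, 29000),   # dup_a/dup_b share position 26000
      ref = c(rep("A", 24), "ACGTACG", rep("A", 4)),
      alt = c(rep("G", 24), "A", "G", "G", "G,T", "G"),
      filter = c(rep("PASS", m - 1), "VQSRTrancheSNP"),
      stringsAsFactors = FALSE
    )
    g <- genotype_set(dos, v)
    out <- qc_common_variants(g)
    expect_setequal(out$variants$id, colnames(good))
    log <- attr(out, "qc_log")
    expect_equal(log$n_non_autosomal, 1)
    expect_equal(log$n_multiallelic, 1)
    expect_equal(log$n_dup_position, 2)
    expect_equal(log$n_long_indel, 1)
    expect_equal(log$n_filter_fail, 1)
    expect_equal(log$n_low_maf, 1)
    expect_gte(log$n_hwe_fail, 1)
    # all-pass fixture is the identity
    gp <- genotype_set(dos[, 1:3], v[1:3, ])
    expect_identical(qc_common_variants(gp)$dosage, gp$dosage)
  })
})

test_that("donors with high missingness are dropped before variant QC", {
  withr::with_seed(7, {
    n <- 60
    dos <- vapply(rep(0.3, 30), function(p) as.integer(rbinom(n, 2, p)),
                  integer(n))
    dos[1, 1:10] <- NA  # donor 1 missing 1/3 of genotypes
    dimnames(dos) <- list(sprintf("D%04d", 1:n), sprintf("v%03d", 1:30))
    v <- data.frame(id = colnames(dos), chrom = "1",
                    pos = seq(1000, by = 1000, length.out = 30),
                    ref = "A", alt = "G", filter = "PASS",
                    stringsAsFactors = FALSE)
    out <- qc_common_variants(genotype_set(dos, v))
    expect_false("D0001" %in% out$donors)
    expect_equal(attr(out, "qc_log")$donors_dropped, "D0001")
  })
})

test_that("LD pruning keeps one variant per block and respects r2", {
  g <- block_genotypes(blocks = 5, block_size = 8, n = 300, seed = 3)
  kept <- ld_prune(g, mode = "count", r2_max = 0.2, window = 50, step = 5)
  expect_equal(length(kept), 5)
  # exhaustive pairwise oracle: no retained pair above threshold
  d <- g$dosage[, kept, drop = FALSE]
  r2 <- cor(d)^2
  expect_true(all(r2[upper.tri(r2)] <= 0.2))
  # every removed variant is in LD with a retained one (block structure)
  removed <- setdiff(g$variants$id, kept)
  r2all <- cor(g$dosage)^2
  expect_true(all(apply(r2all[removed, kept, drop = FALSE], 1, max) > 0.2))

  # two perfect duplicates: one survives; independents all survive
  withr::with_seed(1, {
    x <- as.integer(rbinom(100, 2, 0.3))
    y <- as.integer(rbinom(100, 2, 0.4))
    dos <- cbind(a = x, b = x, c = y)
    dimnames(dos) <- list(sprintf("D%04d", 1:100), c("a", "b", "c"))
    v <- data.frame(id = c("a", "b", "c"), chrom = "1",
                    pos = c(100L, 200L, 300L), ref = "A", alt = "G",
                    filter = "PASS", stringsAsFactors = FALSE)
    gg <- genotype_set(dos, v)
    kept2 <- ld_prune(gg, mode = "count")
    expect_equal(length(kept2), 2)
    expect_true("c" %in% kept2)
  })
})

test_that("LD pruning honors mode parameters and sorting/exclusions", {
  g <- block_genotypes(blocks = 3, block_size = 4, n = 200, seed = 5)
  expect_equal(sort(ld_prune(g, mode = "bp", r2_max = 0.1,
                             window = 50000, step = 10000)),
               sort(ld_prune(g, mode = "count")))
  # unsorted input errors
  g2 <- g
  g2$variants$pos <- rev(g2$variants$pos)
  expect_error(ld_prune(g2, mode = "bp"), "not position-sorted")
  # exclusion regions are removed first (BED half-open, 0-based)
  excl <- data.frame(chrom = "1", start = 0, end = 4000)
  kept <- ld_prune(g, mode = "count", exclude_regions = excl)
  expect_false(any(g$variants$id[g$variants$pos <= 4000] %in% kept))
})

test_that("GRM matches the explicit double-loop oracle", {
  withr::with_seed(9, {
    n <- 25; m <- 40
    dos <- vapply(runif(m, 0.1, 0.5), function(p) {
      as.integer(rbinom(n, 2, p))
    }, integer(n))
    dimnames(dos) <- list(sprintf("D%04d", 1:n), sprintf("v%03d", 1:m))
    v <- data.frame(id = colnames(dos), chrom = "1",
                    pos = seq_len(m) * 100L, ref = "A", alt = "G",
                    filter = "PASS", stringsAsFactors = FALSE)
    g <- genotype_set(dos, v)
    grm <- compute_grm(g)
    p <- colMeans(dos) / 2
    poly <- p > 0 & p < 1
    oracle <- matrix(0, n, n)
    for (j in which(poly)) {
      for (a in 1:n) for (b in 1:n) {
        oracle[a, b] <- oracle[a, b] +
          (dos[a, j] - 2 * p[j]) * (dos[b, j] - 2 * p[j]) /
          (2 * p[j] * (1 - p[j]))
      }
    }
    oracle <- oracle / sum(poly)
    grm_plain <- matrix(as.numeric(grm), n, n)
    expect_equal(grm_plain, oracle, tolerance = 1e-10)
  })
})

test_that("GRM diagonal is near 1 under HWE and duplicates are detected", {
  cfg <- tiny_config(seed = 10, n_donors = 40, n_common_variants = 2000,
                     n_genes = 2)
  g <- simulate_genotypes(cfg)$genotypes
  common <- subset_variants(g, g$variants$id[g$variants$type == "common"])
  grm <- compute_grm(common)
  expect_equal(mean(diag(grm)), 1, tolerance = 0.1)
  # duplicate a donor: off-diagonal ~ diagonal
  dup <- common
  dup$dosage <- rbind(dup$dosage, dup$dosage[1, , drop = FALSE])
  rownames(dup$dosage)[41] <- "D_dup"
  dup <- genotype_set(dup$dosage, dup$variants, dup$annotation)
  grm2 <- compute_grm(dup)
  expect_equal(grm2["D0001", "D_dup"], grm2["D0001", "D0001"],
               tolerance = 1e-10)
})

test_that("GRM PCA separates planted populations and bounds spectra", {
  withr::with_seed(12, {
    n <- 60; m <- 500
    pop <- rep(c(0, 1), each = n / 2)
    p1 <- runif(m, 0.1, 0.5)
    p2 <- pmin(0.95, pmax(0.05, p1 + sample(c(-1, 1), m, TRUE) * 0.25))
    dos <- vapply(seq_len(m), function(j) {
      as.integer(rbinom(n, 2, ifelse(pop == 0, p1[j], p2[j])))
    }, integer(n))
    dimnames(dos) <- list(sprintf("D%04d", 1:n), sprintf("v%04d", 1:m))
    v <- data.frame(id = colnames(dos), chrom = "1",
                    pos = seq_len(m) * 100L, ref = "A", alt = "G",
                    filter = "PASS", stringsAsFactors = FALSE)
    grm <- compute_grm(genotype_set(dos, v))
    pca <- pca_from_grm(grm, k = 10)
    pc1 <- pca$pcs[, 1]
    # silhouette of the two planted populations on PC1
    sil <- vapply(seq_len(n), function(i) {
      own <- mean(abs(pc1[i] - pc1[pop == pop[i]][-which(
        which(pop == pop[i]) == i)]))
      oth <- mean(abs(pc1[i] - pc1[pop != pop[i]]))
      (oth - own) / max(own, oth)
    }, 1.0)
    expect_gt(mean(sil), 0.8)
    # eigenvalue sum bounded by the trace; k > n errors
    expect_lte(sum(pca$eigenvalues), sum(diag(grm)) + 1e-8)
    expect_error(pca_from_grm(grm, k = n + 1), "exceeds")
    # eigen-decomposition reproduces the GRM at full rank
    e <- eigen(grm, symmetric = TRUE)
    rec <- e$vectors %*% diag(e$values) %*% t(e$vectors)
    expect_equal(rec, matrix(as.numeric(grm), n, n), tolerance = 1e-8)
  })
})

test_that("rare-variant burden collapsing matches the generator registry", {
  cfg <- tiny_config(seed = 14, n_donors = 297, n_genes = 40,
                     rare_variants_per_gene = c(2L, 6L))
  sim <- simulate_genotypes(cfg)
  burden <- collapse_rare_burden(sim$genotypes)
  # the full-scale carrier floor: ceil(0.02 x 297) = 6
  expect_equal(burden$min_carriers, 6)
  expect_true(all(colSums(burden$burden) >= 6))
  expect_true(all(burden$burden %in% 0:1))
  # carrier counts agree with the generator's registry for kept genes,
  # as long as all gene variants kept their sub-threshold observed MAF
  st <- variant_stats(sim$genotypes)
  maf_ok <- vapply(names(burden$variants_per_gene), function(gn) {
    vs <- sim$genotypes$annotation$variant_id[
      sim$genotypes$annotation$gene == gn &
        sim$genotypes$annotation$impact %in% c("HIGH", "MODERATE")]
    all(st$maf[match(vs, st$id)] < 0.01)
  }, TRUE)
  for (gn in names(burden$variants_per_gene)[maf_ok]) {
    expect_equal(sum(burden$burden[, gn]),
                 length(sim$truth$carriers[[gn]]),
                 info = gn)
  }
  # dosage 2 at a qualifying variant is a carrier
  gn1 <- names(burden$variants_per_gene)[1]
  vs <- burden$variants_per_gene[[gn1]]
  hom <- which(sim$genotypes$dosage[, vs, drop = FALSE] == 2,
               arr.ind = TRUE)
  if (nrow(hom)) {
    expect_equal(burden$burden[hom[1, 1], gn1], 1L)
  }
})

test_that("VCF round-trip preserves dosages and metadata", {
  cfg <- tiny_config(seed = 20, n_donors = 15, n_common_variants = 20,
                     n_genes = 4, variant_missing_rate = 0.05)
  g <- simulate_genotypes(cfg)$genotypes
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(g, path)
  g2 <- read_genotypes_vcf(path, annotation = g$annotation)
  expect_identical(unname(g2$dosage), unname(g$dosage))
  expect_identical(g2$variants$id, g$variants$id)
  expect_identical(g2$variants$pos, g$variants$pos)
  expect_identical(g2$donors, g$donors)
})
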