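# Shared fixture builders, all generated in code at test time.

tiny_config <- function(seed = 1, ...) {
  defaults <- list(
    n_donors = 60, n_plates = 3, wells_per_donor = 4,
    cells_per_well_mean = 25, n_traits = 10,
    n_common_variants = 200, n_genes = 30,
    rare_variants_per_gene = c(2L, 5L), seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# A block-correlated trait correlation matrix: `blocks` blocks of size
# `block_size` with within-block correlation `r`, ~0 between blocks.
block_cor_matrix <- function(blocks, block_size, r = 0.95, seed = 1) {
  withr::with_seed(seed, {
    n_per_block <- 200
    cols <- lapply(seq_len(blocks), function(b) {
      base <- rnorm(n_per_block)
      vapply(seq_len(block_size), function(j) {
        sqrt(r) * base + sqrt(1 - r) * rnorm(n_per_block)
      }, numeric(n_per_block))
    })
    m <- do.call(cbind, cols)
    colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
    cor(m)
  })
}

# A genotype set of `blocks` LD blocks: within a block the variants are
# near-copies of one ancestor haplotype (pairwise r2 ~ 1), between blocks
# independent. All on one chromosome, positions sorted.
block_genotypes <- function(blocks, block_size, n = 200, seed = 1,
                            flip_rate = 0.02) {
  withr::with_seed(seed, {
    dos <- NULL
    for (b in seq_len(blocks)) {
      base <- rbinom(n, 2, runif(1, 0.2, 0.4))
      blk <- vapply(seq_len(block_size), function(j) {
        flip <- rbinom(n, 1, flip_rate)
        x <- ifelse(flip == 1, sample(0:2, n, replace = TRUE), base)
        as.integer(x)
      }, integer(n))
      dos <- cbind(dos, blk)
    }
    m <- ncol(dos)
    ids <- sprintf("v%03d", seq_len(m))
    dimnames(dos) <- list(sprintf("D%04d", seq_len(n)), ids)
    variants <- data.frame(
      id = ids, chrom = "1", pos = as.integer(seq_len(m) * 1000),
      ref = "A", alt = "G", filter = "PASS", stringsAsFactors = FALSE
    )
    genotype_set(dos, variants)
  })
}

# Donor-level null trait matrix in pseudo-bulk layout.
null_donor_traits <- function(n_donors, n_traits, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_donors * n_traits), n_donors)
    colnames(m) <- sprintf("trait_%03d", seq_len(n_traits))
    cbind(data.frame(donor_id = sprintf("D%04d", seq_len(n_donors)),
                     n_wells = 1L, mean_neighbors = runif(n_donors, 2, 4),
                     stringsAsFactors = FALSE),
          as.data.frame(m))
  })
}

# Minimal covariate scaffolding for association tests.
null_covariate_inputs <- function(donors, seed = 1) {
  withr::with_seed(seed, {
    n <- length(donors)
    metadata <- data.frame(
      donor_id = donors,
      sex = sample(c("female", "male"), n, replace = TRUE),
      age = round(runif(n, 20, 70)),
      disease = sample(c("yes", "no"), n, replace = TRUE),
      source_tissue = sample(c("fibroblast", "Bcell"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    pcs <- matrix(rnorm(n * 4), n, dimnames = list(donors, paste0("PC", 1:4)))
    plate_of <- setNames(sample(sprintf("P%02d", 1:4), n, replace = TRUE),
                         donors)
    list(metadata = metadata, pcs = pcs, plate_of = plate_of)
  })
}
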