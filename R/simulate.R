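#' Simulation configuration for a synthetic cmQTL study
#'
#' Defines the cohort shape, genotype panel, trait panel, variance structure
#' and planted genetic effects of a synthetic study. The defaults mirror the
#' discovery cohort the pipeline is designed around: 297 donors imaged on 7
#' plates with 8 wells per donor, roughly 2.5% of cells isolated (no
#' touching neighbors), plate effects dominating well-level trait variance
#' (~60%) and donor identity explaining ~17%. The per-well retained cell
#' count and the number of abstract traits are desk-scale choices; both are
#' freely configurable and tests typically shrink them further.
#'
#' @param n_donors number of donors (cell lines).
#' @param n_plates number of imaging plates; each donor sits on exactly one
#'   plate, so plate and donor effects are partially confounded as in a
#'   real one-plate-per-line layout.
#' @param wells_per_donor wells imaged per donor (all on the donor's plate).
#' @param cells_per_well_mean mean of the per-well retained-cell count
#'   (Poisson, truncated at 1).
#' @param n_traits number of abstract morphology traits.
#' @param n_common_variants number of independent common variants.
#' @param n_genes number of genes carrying rare variants.
#' @param rare_variants_per_gene integer range `c(min, max)` of rare
#'   variants per gene.
#' @param maf_range_common minor allele frequency range for common variants,
#'   inside (0.05, 0.5).
#' @param maf_range_rare allele frequency range for rare variants, inside
#'   (0, 0.01).
#' @param variance_fractions named fractions for `plate`, `well`, `donor`
#'   and `residual` variance components; must sum to 1.
#' @param planted_effects list of planted genetic effects, each a list with
#'   `target` (a gene or variant id), `trait` (trait index) and `beta`
#'   (standardized effect size, in units of total trait SD).
#' @param isolate_fraction probability that a cell has zero neighbors.
#' @param missing_cell_fraction fraction of cells given missing trait
#'   values (to exercise cell QC).
#' @param missing_trait_fraction fraction of traits set missing within an
#'   affected cell.
#' @param variant_missing_rate per-entry genotype missingness rate.
#' @param n_hwe_violations number of common variants generated without
#'   heterozygotes (gross Hardy-Weinberg violations, for QC tests).
#' @param rare_low_impact_fraction fraction of rare variants annotated LOW
#'   or MODIFIER instead of HIGH/MODERATE.
#' @param seed integer base seed; fully determines all output.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_donors = 297,
                              n_plates = 7,
                              wells_per_donor = 8,
                              cells_per_well_mean = 120,
                              n_traits = 40,
                              n_common_variants = 1000,
                              n_genes = 120,
                              rare_variants_per_gene = c(1L, 6L),
                              maf_range_common = c(0.05, 0.5),
                              maf_range_rare = c(0.001, 0.01),
                              variance_fractions = c(plate = 0.60,
                                                     well = 0.05,
                                                     donor = 0.17,
                                                     residual = 0.18),
                              planted_effects = list(),
                              isolate_fraction = 0.0252,
                              missing_cell_fraction = 0,
                              missing_trait_fraction = 0,
                              variant_missing_rate = 0,
                              n_hwe_violations = 0,
                              rare_low_impact_fraction = 0,
                              seed = 1L) {
  counts <- c(n_donors = n_donors, n_plates = n_plates,
              wells_per_donor = wells_per_donor,
              cells_per_well_mean = cells_per_well_mean,
              n_traits = n_traits, n_common_variants = n_common_variants,
              n_genes = n_genes)
  if (any(counts < 1)) {
    stop("simulation_config: all counts must be positive (",
         paste(names(counts)[counts < 1], collapse = ", "), ")")
  }
  need <- c("plate", "well", "donor", "residual")
  if (!all(need %in% names(variance_fractions))) {
    stop("variance_fractions must name plate, well, donor and residual")
  }
  variance_fractions <- variance_fractions[need]
  if (any(variance_fractions < 0) ||
      abs(sum(variance_fractions) - 1) > 1e-9) {
    stop("variance_fractions must be non-negative and sum to 1")
  }
  stopifnot(length(rare_variants_per_gene) == 2,
            rare_variants_per_gene[1] >= 1,
            rare_variants_per_gene[2] >= rare_variants_per_gene[1],
            maf_range_common[1] >= 0.05 - 1e-12,
            maf_range_common[2] <= 0.5,
            maf_range_rare[1] > 0, maf_range_rare[2] <= 0.01,
            isolate_fraction > 0, isolate_fraction < 1,
            missing_cell_fraction >= 0, missing_cell_fraction < 1,
            missing_trait_fraction >= 0, missing_trait_fraction <= 1,
            variant_missing_rate >= 0, variant_missing_rate < 1)
  for (pe in planted_effects) {
    if (!all(c("target", "trait", "beta") %in% names(pe))) {
      stop("each planted effect needs fields target, trait, beta")
    }
  }
  structure(list(
    n_donors = as.integer(n_donors), n_plates = as.integer(n_plates),
    wells_per_donor = as.integer(wells_per_donor),
    cells_per_well_mean = cells_per_well_mean,
    n_traits = as.integer(n_traits),
    n_common_variants = as.integer(n_common_variants),
    n_genes = as.integer(n_genes),
    rare_variants_per_gene = as.integer(rare_variants_per_gene),
    maf_range_common = maf_range_common,
    maf_range_rare = maf_range_rare,
    variance_fractions = variance_fractions,
    planted_effects = planted_effects,
    isolate_fraction = isolate_fraction,
    missing_cell_fraction = missing_cell_fraction,
    missing_trait_fraction = missing_trait_fraction,
    variant_missing_rate = variant_missing_rate,
    n_hwe_violations = as.integer(n_hwe_violations),
    rare_low_impact_fraction = rare_low_impact_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

donor_ids <- function(n) sprintf("D%04d", seq_len(n))

#' Simulate donor genotypes with annotated rare variants
#'
#' Draws an independent-variant genotype panel: common variants with allele
#' frequencies uniform on `maf_range_common` and rare variants grouped into
#' genes with frequencies on `maf_range_rare`, genotypes sampled from
#' Hardy-Weinberg proportions at each variant's frequency. Rare variants
#' carry HIGH/MODERATE impact annotations (a configurable fraction LOW or
#' MODIFIER). Optional per-entry missingness and gross HWE-violating
#' variants support QC testing.
#'
#' @param config a [simulation_config()].
#' @return a list with `genotypes` (a `genotype_set`) and `truth` (carrier
#'   lists per gene, true allele frequencies, planted QC failures).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_donors < 1 ||
      (config$n_common_variants + config$n_genes) < 1) {
    stop("need at least one donor and one variant")
  }
  n <- config$n_donors
  donors <- donor_ids(n)
  with_substream(config$seed, "genotypes", {
    n_cv <- config$n_common_variants
    cv_id <- sprintf("cv%05d", seq_len(n_cv))
    cv_chrom <- sort(rep_len(1:22, n_cv))
    cv_pos <- unlist(lapply(split(seq_len(n_cv), cv_chrom), function(idx) {
      cumsum(sample(500:5000, length(idx), replace = TRUE))
    }), use.names = FALSE)
    cv_maf <- runif(n_cv, config$maf_range_common[1],
                    config$maf_range_common[2])
    cv_dos <- vapply(cv_maf, function(p) rbinom(n, 2L, p), integer(n))
    # gross HWE violations: no heterozygotes at all
    if (config$n_hwe_violations > 0) {
      idx <- seq_len(min(config$n_hwe_violations, n_cv))
      for (j in idx) cv_dos[, j] <- 2L * rbinom(n, 1L, cv_maf[j])
    }

    genes <- sprintf("G%04d", seq_len(config$n_genes))
    k_per_gene <- sample(seq(config$rare_variants_per_gene[1],
                             config$rare_variants_per_gene[2]),
                         config$n_genes, replace = TRUE)
    n_rv <- sum(k_per_gene)
    rv_gene <- rep(genes, k_per_gene)
    rv_id <- sprintf("rv%05d", seq_len(n_rv))
    rv_chrom <- sort(rep_len(1:22, n_rv))
    rv_pos <- unlist(lapply(split(seq_len(n_rv), rv_chrom), function(idx) {
      cumsum(sample(500:5000, length(idx), replace = TRUE)) + 10000000L
    }), use.names = FALSE)
    rv_maf <- runif(n_rv, config$maf_range_rare[1], config$maf_range_rare[2])
    rv_dos <- vapply(rv_maf, function(p) rbinom(n, 2L, p), integer(n))
    rv_impact <- sample(c("HIGH", "MODERATE"), n_rv, replace = TRUE,
                        prob = c(0.3, 0.7))
    if (config$rare_low_impact_fraction > 0) {
      n_low <- round(config$rare_low_impact_fraction * n_rv)
      if (n_low > 0) {
        low_idx <- sample(n_rv, n_low)
        rv_impact[low_idx] <- sample(c("LOW", "MODIFIER"), n_low,
                                     replace = TRUE)
      }
    }

    bases <- c("A", "C", "G", "T")
    m <- n_cv + n_rv
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")

    dosage <- cbind(cv_dos, rv_dos)
    mode(dosage) <- "integer"
    rownames(dosage) <- donors
    colnames(dosage) <- c(cv_id, rv_id)
    if (config$variant_missing_rate > 0) {
      miss <- runif(length(dosage)) < config$variant_missing_rate
      dosage[miss] <- NA_integer_
    }

    variants <- data.frame(
      id = c(cv_id, rv_id),
      chrom = as.character(c(cv_chrom, rv_chrom)),
      pos = as.integer(c(cv_pos, rv_pos)),
      ref = ref, alt = alt,
      filter = "PASS",
      type = rep(c("common", "rare"), c(n_cv, n_rv)),
      stringsAsFactors = FALSE
    )
    annotation <- data.frame(
      variant_id = rv_id, gene = rv_gene, impact = rv_impact,
      stringsAsFactors = FALSE
    )
    g <- genotype_set(dosage, variants, annotation)

    qual <- rv_id[rv_impact %in% c("HIGH", "MODERATE")]
    carriers <- lapply(split(annotation$variant_id, annotation$gene),
                       function(vs) {
                         vs <- intersect(vs, qual)
                         if (!length(vs)) return(character(0))
                         d <- dosage[, vs, drop = FALSE]
                         donors[rowSums(d >= 1, na.rm = TRUE) > 0]
                       })
    truth <- list(
      maf = setNames(c(cv_maf, rv_maf), c(cv_id, rv_id)),
      carriers = carriers[genes],
      genes = genes,
      hwe_violations = if (config$n_hwe_violations > 0)
        cv_id[seq_len(min(config$n_hwe_violations, n_cv))] else character(0)
    )
    list(genotypes = g, truth = truth)
  })
}

# Assign each donor's wells to positions on a rows x cols plate grid;
# returns per-donor well labels plus edge flags.
.assign_wells <- function(n_donors, n_plates, wells_per_donor,
                          rows = 16L, cols = 24L) {
  plate_of <- rep(seq_len(n_plates), length.out = n_donors)
  per_plate <- table(factor(plate_of, levels = seq_len(n_plates)))
  need <- max(per_plate) * wells_per_donor
  while (rows * cols < need) cols <- cols + 8L  # widen grid if oversubscribed
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  out <- vector("list", n_donors)
  for (p in seq_len(n_plates)) {
    dset <- which(plate_of == p)
    slots <- sample(nrow(grid), length(dset) * wells_per_donor)
    for (i in seq_along(dset)) {
      take <- slots[((i - 1) * wells_per_donor + 1):(i * wells_per_donor)]
      out[[dset[i]]] <- data.frame(
        row = grid$row[take], col = grid$col[take]
      )
    }
  }
  list(plate_of = plate_of, wells = out, rows = rows, cols = cols)
}

#' Simulate single-cell morphology profiles over a genotyped cohort
#'
#' Generates a per-cell trait table with an additive variance structure:
#' trait value = plate effect + well-position effect + donor effect +
#' residual, each component an independent Gaussian scaled to its requested
#' variance fraction (total variance 1). Planted genetic effects enter the
#' donor component as `beta` x carrier status (gene targets) or `beta` x
#' dosage (variant targets), in total-SD units. Each cell receives a
#' neighbor count (0 with probability `isolate_fraction`, else
#' 1 + Poisson(3)) and, optionally, missing values in a random trait
#' subset.
#'
#' @param config a [simulation_config()].
#' @param genotypes the result of [simulate_genotypes()] for this config.
#' @return a list with `cells` (single-cell table), `metadata` (donor
#'   metadata), and `truth` (true variance fractions, effect registry,
#'   donor-plate map).
#' @export
simulate_profiles <- function(config, genotypes) {
  stopifnot(inherits(config, "sim_config"))
  g <- genotypes$genotypes
  n <- config$n_donors
  donors <- donor_ids(n)
  if (!identical(rownames(g$dosage), donors)) {
    stop("genotype donors do not match the configured cohort")
  }
  traits <- sprintf("trait_%03d", seq_len(config$n_traits))
  # validate planted effects up front
  for (pe in config$planted_effects) {
    if (pe$trait < 1 || pe$trait > config$n_traits) {
      stop("planted effect targets nonexistent trait index ", pe$trait)
    }
    known <- pe$target %in% colnames(g$dosage) ||
      pe$target %in% genotypes$truth$genes
    if (!known) stop("planted effect targets unknown gene/variant ",
                     pe$target)
  }

  fr <- config$variance_fractions
  metadata <- with_substream(config$seed, "metadata", data.frame(
    donor_id = donors,
    sex = sample(c("female", "male"), n, replace = TRUE),
    age = round(runif(n, 20, 70)),
    disease = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.4, 0.6)),
    source_tissue = sample(c("fibroblast", "Bcell"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  ))

  cells <- with_substream(config$seed, "profiles", {
    layout <- .assign_wells(n, config$n_plates, config$wells_per_donor)
    plate_of <- layout$plate_of

    plate_eff <- matrix(rnorm(config$n_plates * config$n_traits,
                              sd = sqrt(fr["plate"])),
                        config$n_plates, config$n_traits)
    well_pos <- expand.grid(row = seq_len(layout$rows),
                            col = seq_len(layout$cols))
    well_lab <- sprintf("R%02dC%02d", well_pos$row, well_pos$col)
    well_eff <- matrix(rnorm(nrow(well_pos) * config$n_traits,
                             sd = sqrt(fr["well"])),
                       nrow(well_pos), config$n_traits,
                       dimnames = list(well_lab, NULL))
    donor_eff <- matrix(rnorm(n * config$n_traits, sd = sqrt(fr["donor"])),
                        n, config$n_traits)
    registry <- list()
    for (pe in config$planted_effects) {
      if (pe$target %in% genotypes$truth$genes) {
        carrier <- as.numeric(donors %in%
                                genotypes$truth$carriers[[pe$target]])
        donor_eff[, pe$trait] <- donor_eff[, pe$trait] + pe$beta * carrier
        registry[[length(registry) + 1]] <-
          data.frame(target = pe$target, kind = "gene",
                     trait = traits[pe$trait], beta = pe$beta,
                     n_carriers = sum(carrier))
      } else {
        dos <- g$dosage[, pe$target]
        dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
        donor_eff[, pe$trait] <- donor_eff[, pe$trait] + pe$beta * dos
        registry[[length(registry) + 1]] <-
          data.frame(target = pe$target, kind = "variant",
                     trait = traits[pe$trait], beta = pe$beta,
                     n_carriers = sum(dos > 0))
      }
    }

    rows <- vector("list", n)
    for (d in seq_len(n)) {
      wl <- layout$wells[[d]]
      lab <- sprintf("R%02dC%02d", wl$row, wl$col)
      edge <- wl$row == 1L | wl$row == layout$rows |
        wl$col == 1L | wl$col == layout$cols
      n_cells <- pmax(1L, rpois(nrow(wl), config$cells_per_well_mean))
      widx <- rep(seq_len(nrow(wl)), n_cells)
      total <- sum(n_cells)
      iso <- runif(total) < config$isolate_fraction
      nb <- ifelse(iso, 0L, rpois(total, 3) + 1L)
      mu <- plate_eff[plate_of[d], , drop = FALSE][rep(1, total), ,
                                                   drop = FALSE] +
        well_eff[lab[widx], , drop = FALSE] +
        donor_eff[rep(d, total), , drop = FALSE]
      vals <- mu + matrix(rnorm(total * config$n_traits,
                                sd = sqrt(fr["residual"])),
                          total, config$n_traits)
      df <- data.frame(
        plate_id = sprintf("P%02d", plate_of[d]),
        well_id = lab[widx],
        on_edge = edge[widx],
        donor_id = donors[d],
        neighbor_count = nb,
        stringsAsFactors = FALSE
      )
      rows[[d]] <- cbind(df, setNames(as.data.frame(vals), traits))
    }
    cells <- do.call(rbind, rows)
    cells <- cbind(cell_id = sprintf("c%07d", seq_len(nrow(cells))), cells)
    attr(cells, "registry") <-
      if (length(registry)) do.call(rbind, registry) else
        data.frame(target = character(0), kind = character(0),
                   trait = character(0), beta = numeric(0),
                   n_carriers = integer(0))
    attr(cells, "plate_of") <- setNames(sprintf("P%02d", plate_of), donors)
    cells
  })

  n_missing_cells <- 0L
  if (config$missing_cell_fraction > 0 && config$missing_trait_fraction > 0) {
    cells <- with_substream(config$seed, "missingness", {
      n_mc <- round(config$missing_cell_fraction * nrow(cells))
      n_mt <- max(1L, ceiling(config$missing_trait_fraction *
                                config$n_traits))
      pick <- sample(nrow(cells), n_mc)
      for (i in pick) {
        cols <- sample(traits, n_mt)
        cells[i, cols] <- NA_real_
      }
      attr(cells, "missing_cells") <- cells$cell_id[sort(pick)]
      cells
    })
    n_missing_cells <- length(attr(cells, "missing_cells"))
  }

  truth <- list(
    variance_fractions = fr,
    registry = attr(cells, "registry"),
    plate_of = attr(cells, "plate_of"),
    missing_cells = attr(cells, "missing_cells"),
    n_missing_cells = n_missing_cells,
    traits = traits
  )
  attr(cells, "registry") <- NULL
  attr(cells, "plate_of") <- NULL
  attr(cells, "missing_cells") <- NULL
  list(cells = cells, metadata = metadata, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_profiles()].
#'
#' @param config a [simulation_config()].
#' @return list with `cells`, `metadata`, `genotypes`, `truth` (merged
#'   genotype and profile ground truth).
#' @export
simulate_study <- function(config) {
  geno <- simulate_genotypes(config)
  prof <- simulate_profiles(config, geno)
  list(cells = prof$cells, metadata = prof$metadata,
       genotypes = geno$genotypes,
       truth = c(geno$truth, prof$truth))
}
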