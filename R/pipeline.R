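#' Pipeline configuration
#'
#' Collects every stage threshold (defaults are the full-study values) and
#' the simulation settings into one serializable object.
#'
#' @param sim a [simulation_config()] describing the synthetic study.
#' @param max_missing_fraction cell QC threshold (0.05).
#' @param trait_blocklist traits dropped a priori.
#' @param composite_threshold correlation threshold for composite-trait
#'   selection (0.9).
#' @param maf_min,miss_max,hwe_p_min,donor_miss_max common-variant QC
#'   thresholds.
#' @param rare_maf_max,rare_call_rate_min,min_carrier_fraction rare burden
#'   thresholds.
#' @param alpha family-wise level for the burden Bonferroni threshold.
#' @param genomewide common-variant genome-wide level (5e-8).
#' @param suggestive_burden suggestive burden p threshold (1e-6).
#' @param n_pcs ancestry PCs to compute (20, capped at donors - 1).
#' @param varcomp_traits how many traits get a full variance
#'   decomposition (they are slow; 3 by default at desk scale).
#' @param power_K mixture components for the effect-size fit.
#' @param power_N_grid sample sizes for the discovery projection.
#' @param contexts contexts to analyze.
#' @param seed base seed (defaults to the simulation's).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            max_missing_fraction = 0.05,
                            trait_blocklist = character(0),
                            composite_threshold = 0.9,
                            maf_min = 0.05, miss_max = 0.05,
                            hwe_p_min = 1e-5, donor_miss_max = 0.10,
                            rare_maf_max = 0.01,
                            rare_call_rate_min = 0.95,
                            min_carrier_fraction = 0.02,
                            alpha = 0.05, genomewide = 5e-8,
                            suggestive_burden = 1e-6,
                            n_pcs = 20,
                            varcomp_traits = 3,
                            power_K = 4,
                            power_N_grid = c(297, 500, 1000, 2000),
                            contexts = c("colony", "isolate"),
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"),
            max_missing_fraction > 0, max_missing_fraction < 1,
            composite_threshold > 0, composite_threshold < 1,
            maf_min >= 0, maf_min < 0.5, hwe_p_min > 0, hwe_p_min < 1,
            rare_maf_max > 0, rare_maf_max < 0.5,
            min_carrier_fraction > 0, min_carrier_fraction < 1,
            alpha > 0, alpha < 1, genomewide > 0,
            all(contexts %in% c("colony", "isolate")))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full cmQTL analysis end-to-end on synthetic data
#'
#' Sequences every stage: simulation, cell/trait QC, context split, well
#' aggregation, inverse normal transformation, composite-trait selection,
#' pseudo-bulking, variance decomposition, genotype QC, LD pruning, GRM +
#' ancestry PCA, rare-variant burden collapsing, burden and common-variant
#' association in both contexts, genomic-inflation diagnostics, and the
#' effect-size mixture with discovery projection. Stage outputs are
#' written as TSV/JSON under `out_dir` (if given) together with a run
#' manifest of checksums; identical config and seed reproduce identical
#' checksums.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing files.
#' @return list with all stage results and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name) message("[morphoqtl] stage: ", name)

  stage("simulate")
  study <- simulate_study(config$sim)

  stage("profile QC")
  cells <- qc_cells(study$cells, config$max_missing_fraction)
  qc_cells_log <- attr(cells, "qc_log")
  cells <- qc_traits(cells, config$trait_blocklist)
  qc_traits_log <- attr(cells, "qc_log")
  ctx <- split_context(cells)
  ctx <- ctx[intersect(c("colony", "isolate"), config$contexts)]

  stage("aggregate + INT")
  wells <- lapply(ctx, function(tab) {
    inverse_normal_transform(aggregate_wells(tab))
  })

  stage("composite traits")
  donor_all <- lapply(wells, pseudo_bulk)
  cors <- lapply(donor_all, donor_correlation)
  composite <- select_composite_traits(cors, config$composite_threshold)
  donors_traits <- lapply(wells, pseudo_bulk, traits = composite)

  stage("genotype QC")
  geno <- study$genotypes
  common <- qc_common_variants(geno, config$maf_min, config$miss_max,
                               config$hwe_p_min, config$donor_miss_max)
  pruned_ids <- ld_prune(common, mode = "bp")
  grm <- compute_grm(subset_variants(common, pruned_ids))
  k <- min(config$n_pcs, nrow(grm) - 1)
  pca <- pca_from_grm(grm, k = k)
  burden <- collapse_rare_burden(
    geno, maf_max = config$rare_maf_max,
    call_rate_min = config$rare_call_rate_min,
    min_carrier_fraction = config$min_carrier_fraction)

  stage("variance components")
  vc_traits <- head(intersect(composite$traits,
                              trait_names(wells[[1]])),
                    config$varcomp_traits)
  varcomp <- lapply(vc_traits, function(tr) {
    fit_variance_components(
      wells[[1]], tr, study$metadata, pca$pcs,
      context = names(wells)[1],
      n_traits_for_correction = length(composite$traits),
      test_components = FALSE)
  })
  names(varcomp) <- vc_traits

  stage("association")
  plate_of <- study$truth$plate_of
  assoc <- list()
  for (cx in names(donors_traits)) {
    assoc[[paste0("burden_", cx)]] <- burden_regression(
      donors_traits[[cx]], burden, study$metadata, pca$pcs, plate_of, cx)
    assoc[[paste0("common_", cx)]] <- common_variant_scan(
      donors_traits[[cx]], common, study$metadata, pca$pcs, plate_of, cx)
  }
  n_traits <- length(composite$traits)
  n_genes <- ncol(burden$burden)
  thresholds <- list(
    burden_significant = bonferroni_threshold(
      config$alpha, n_traits * n_genes),
    burden_suggestive = config$suggestive_burden,
    common_significant = bonferroni_threshold(config$genomewide, n_traits),
    common_suggestive = bonferroni_threshold(1e-5, n_traits)
  )
  burden_hits <- do.call(rbind, lapply(
    assoc[grep("^burden", names(assoc))], function(a) {
      a[a$p < thresholds$burden_significant, , drop = FALSE]
    }))
  common_hits <- do.call(rbind, lapply(
    assoc[grep("^common", names(assoc))], function(a) {
      a[a$p < thresholds$common_significant, , drop = FALSE]
    }))
  lambdas <- vapply(assoc, function(a) genomic_lambda(a$p), 1.0)

  stage("power projection")
  z_burden <- do.call(c, lapply(assoc[grep("^burden", names(assoc))],
                                function(a) a$t))
  mix <- fit_effect_mixture(z_burden, N_fit = length(unique(
    donors_traits[[1]]$donor_id)), K = config$power_K, seed = config$seed)
  projection <- project_discoveries(mix, config$power_N_grid,
                                    p_star = thresholds$burden_significant)

  result <- list(
    config = config,
    composite = composite,
    wells = wells,
    donor_traits = donors_traits,
    varcomp = varcomp,
    genotypes_common = common,
    pruned_ids = pruned_ids,
    grm = grm, pca = pca, burden = burden,
    association = assoc,
    thresholds = thresholds,
    burden_hits = burden_hits,
    common_hits = common_hits,
    lambda = lambdas,
    mixture = mix,
    projection = projection,
    truth = study$truth,
    logs = list(qc_cells = qc_cells_log, qc_traits = qc_traits_log,
                qc_variants = attr(common, "qc_log"))
  )
  if (!is.null(out_dir)) {
    result$manifest <- write_pipeline_outputs(result, out_dir)
  }
  result
}

# Serialize stage outputs under out_dir and build the run manifest
# (config hash + per-file md5 checksums; deterministic for a fixed seed).
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_list <- cfg
  cfg_list$sim <- unclass(cfg$sim)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(lapply(unclass(cfg_list), function(x) {
    if (inherits(x, "sim_config")) unclass(x) else x
  }), cfg_path)

  paths <- c(config = cfg_path)
  wt <- function(x, name) {
    p <- file.path(out_dir, name)
    write_trait_tsv(x, p)
    p
  }
  for (cx in names(result$donor_traits)) {
    paths[paste0("donor_traits_", cx)] <-
      wt(result$donor_traits[[cx]], paste0("donor_traits_", cx, ".tsv"))
  }
  paths["composite"] <- wt(
    data.frame(trait = result$composite$traits,
               order = seq_along(result$composite$traits)),
    "composite_traits.tsv")
  if (length(result$varcomp)) {
    paths["varcomp"] <- wt(
      do.call(rbind, lapply(result$varcomp, `[[`, "table")),
      "variance_components.tsv")
  }
  for (nm in names(result$association)) {
    paths[nm] <- wt(result$association[[nm]], paste0(nm, ".tsv"))
  }
  paths["burden_hits"] <- wt(result$burden_hits, "burden_hits.tsv")
  paths["common_hits"] <- wt(result$common_hits, "common_hits.tsv")
  paths["projection"] <- wt(as.data.frame(result$projection),
                            "power_projection.tsv")
  jsonlite::write_json(
    list(thresholds = result$thresholds, lambda = as.list(result$lambda),
         mixture = list(weights = result$mixture$weights,
                        tau2 = result$mixture$tau2,
                        K = result$mixture$K,
                        N_fit = result$mixture$N_fit)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  paths["summary"] <- file.path(out_dir, "summary.json")

  manifest <- list(
    config_checksum = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(setNames(unname(tools::md5sum(unname(paths))),
                                 names(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
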