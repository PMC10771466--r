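# Shared configuration for the analysis workflow (scripts 01-06).
#
# One synthetic study at the discovery cohort's shape: 297 donors across
# 7 plates, 8 wells per donor, ~2.5% isolated cells, plate effects
# dominating trait variance and a modest donor component. Two genetic
# effects are planted: a near-monogenic one (recovery demonstration) and
# a moderate one comparable to the largest real burden effects
# (estimation demonstration). Single-cell tables are regenerated
# deterministically from the seed by each script rather than serialized
# (they are large; everything downstream of the well level is written
# under results/).

library(morphoqtl)

ANALYSIS_SEED <- 20260921L
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

analysis_sim_config <- function(planted = TRUE) {
  effects <- if (planted) {
    list(list(target = "G0012", trait = 2, beta = 5),
         list(target = "G0030", trait = 5, beta = -1.2))
  } else list()
  simulation_config(
    n_donors = 297, n_plates = 7, wells_per_donor = 8,
    cells_per_well_mean = 12, n_traits = 12,
    n_common_variants = 400, n_genes = 150,
    rare_variants_per_gene = c(2L, 6L),
    planted_effects = effects,
    seed = ANALYSIS_SEED
  )
}

analysis_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(analysis_sim_config())
    cache
  }
})

res_path <- function(...) file.path(RESULTS_DIR, ...)
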