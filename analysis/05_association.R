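#!/usr/bin/env Rscript
# Stage 5 — association scans in both contexts: gene-level rare-variant
# burden regression and the common-variant dosage scan, with Bonferroni
# thresholds, genomic inflation, and a permutation null check.
source("analysis/00_config.R")

st <- analysis_study()
ann <- read_annotation_tsv(res_path("annotation.tsv"))
geno <- read_genotypes_vcf(res_path("genotypes.vcf"), annotation = ann)
common <- qc_common_variants(geno)
metadata <- read_trait_tsv(res_path("donor_metadata.tsv"))
pcs_df <- read_trait_tsv(res_path("ancestry_pcs.tsv"))
pcs <- as.matrix(pcs_df[-1]); rownames(pcs) <- pcs_df$donor_id
burden_df <- read_trait_tsv(res_path("gene_burden.tsv"))
burden <- as.matrix(burden_df[-1]); rownames(burden) <- burden_df$donor_id
plate_of <- st$truth$plate_of

scans <- list()
for (cx in c("colony", "isolate")) {
  traits <- read_trait_tsv(res_path(sprintf("donor_traits_%s.tsv", cx)))
  scans[[paste0("burden_", cx)]] <-
    burden_regression(traits, burden, metadata, pcs, plate_of, cx)
  scans[[paste0("common_", cx)]] <-
    common_variant_scan(traits, common, metadata, pcs, plate_of, cx)
}

n_traits <- length(trait_names(read_trait_tsv(
  res_path("donor_traits_colony.tsv"))))
thr_burden <- bonferroni_threshold(0.05, n_traits * ncol(burden))
thr_common <- bonferroni_threshold(5e-8, n_traits)

for (nm in names(scans)) {
  a <- scans[[nm]]
  thr <- if (grepl("^burden", nm)) thr_burden else thr_common
  lam <- genomic_lambda(a$p)
  hits <- a[a$p < thr, ]
  cat(sprintf("%s: %d tests, lambda = %.2f, %d significant (p < %.2g)\n",
              nm, nrow(a), lam, nrow(hits), thr))
  if (nrow(hits)) {
    print(hits[order(hits$p), c("trait", "target", "beta", "se", "p")],
          row.names = FALSE)
  }
  write_trait_tsv(a, res_path(sprintf("assoc_%s.tsv", nm)))
}
all_hits <- do.call(rbind, lapply(names(scans), function(nm) {
  thr <- if (grepl("^burden", nm)) thr_burden else thr_common
  h <- scans[[nm]][scans[[nm]]$p < thr, ]
  if (nrow(h)) cbind(scan = nm, h) else NULL
}))
if (!is.null(all_hits)) write_trait_tsv(all_hits, res_path("hits.tsv"))

# permutation null: shuffling trait values across donors must leave no
# signal and a calibrated p distribution
traits_col <- read_trait_tsv(res_path("donor_traits_colony.tsv"))
perm <- permutation_null(traits_col, burden, metadata, pcs, plate_of,
                         arm = "burden", mode = "shuffle_traits",
                         n_perm = 5, seed = ANALYSIS_SEED)
cat(sprintf("permutation null: lambda in [%.2f, %.2f], min p = %.2g (threshold %.2g)\n",
            min(perm$lambda), max(perm$lambda), min(perm$min_p),
            thr_burden))
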