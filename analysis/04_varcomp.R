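#!/usr/bin/env Rscript
# Stage 4 — variance decomposition of well-level traits under the full
# study design model (random: disease, source tissue, sex, plate, well,
# edge, donor; fixed: age, ancestry PCs 1-4, neighbor count in colony).
source("analysis/00_config.R")

wells <- read_trait_tsv(res_path("wells_colony.tsv"))
metadata <- read_trait_tsv(res_path("donor_metadata.tsv"))
pcs_df <- read_trait_tsv(res_path("ancestry_pcs.tsv"))
pcs <- as.matrix(pcs_df[-1])
rownames(pcs) <- pcs_df$donor_id
composite <- read_trait_tsv(res_path("composite_traits.tsv"))$trait

tested <- utils::head(composite, 3)
tables <- lapply(tested, function(tr) {
  vd <- fit_variance_components(wells, tr, metadata, pcs,
                                context = "colony",
                                n_traits_for_correction =
                                  length(composite))
  vd$table
})
out <- do.call(rbind, tables)
write_trait_tsv(out, res_path("variance_components.tsv"))

cat("variance decomposition (colony context):\n")
for (tr in tested) {
  tab <- out[out$trait == tr, ]
  top <- tab[order(-tab$fraction), ][1:3, ]
  cat(sprintf("  %s: %s\n", tr,
              paste(sprintf("%s %.1f%%", top$component,
                            100 * top$fraction), collapse = ", ")))
}
sig <- out[!is.na(out$p_bonferroni) & out$p_bonferroni < 0.05, ]
cat(sprintf("%d of %d component tests significant after Bonferroni\n",
            nrow(sig), sum(!is.na(out$p))))
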